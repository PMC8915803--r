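# Shared fixtures, built in code.

test_vocab <- function() {
  vocabulary(data.frame(
    term_id = c("CGA", "SHH", "WNT1", "PAX6", "NEURULATION", "CELLCYCLE",
                "MIR21", "LET7"),
    name = c("glycoprotein hormones alpha chain", "sonic hedgehog protein",
             "proto-oncogene Wnt-1", "paired box protein Pax-6",
             "neurulation", "cell cycle", "miR-21", "let-7"),
    class = c("gene", "gene", "gene", "gene", "process", "process",
              "miRNA", "miRNA"),
    synonyms = c("CGA|GPHA1", "SHH|hedgehog homolog", "WNT1|Wnt-1",
                 "PAX6", "neural tube closure", "cell division cycle",
                 "microRNA-21", "lethal-7"),
    stringsAsFactors = FALSE
  ))
}

# small random planted-corpus truth over the test vocabulary
random_truth <- function(seed, stages = c("neurulation", "gastrulation")) {
  set.seed(seed)
  vocab <- test_vocab()
  planted <- expand.grid(stage = stages, term_id = vocab$term_id,
                         stringsAsFactors = FALSE)
  planted$count <- rpois(nrow(planted), 2)
  corpus_truth(planted, seed = seed)
}

httr_concs <- c(1, 3.16, 10, 31.6, 100, 316)
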