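# Synthetic inputs with known ground truth for every pipeline stage.
# Every generator is a pure function of (parameters, seed): identical
# inputs give identical outputs.

decoy_wordlist <- function() {
  c("lorem", "ipsum", "dolor", "amet", "consectetur", "adipiscing", "elit",
    "vestibulum", "sagittis", "lacinia", "sollicitudin", "pellentesque",
    "habitant", "morbi", "tristique", "senectus", "netus", "malesuada",
    "fames", "turpis", "egestas", "aliquam", "erat", "volutpat", "integer",
    "placerat", "feugiat", "ultricies", "curabitur", "blandit", "tincidunt",
    "mauris", "fermentum", "ullamcorper", "pharetra", "maximus", "dapibus",
    "porttitor", "vulputate", "scelerisque", "hendrerit", "venenatis",
    "posuere", "cubilia", "curae", "aenean", "euismod", "bibendum", "laoreet",
    "suspendisse", "potenti", "nullam", "rutrum", "congue", "lectus",
    "aliquet", "vivamus", "commodo", "fringilla", "faucibus", "interdum",
    "primis", "luctus", "ultrices", "sodales", "imperdiet", "convallis",
    "gravida", "pretium", "consequat", "tempor", "viverra", "donec",
    "porta", "mollis", "efficitur", "finibus", "dictum", "nascetur",
    "ridiculus", "penatibus", "montes", "parturient")
}

#' Ground truth for a synthetic literature corpus
#'
#' @param planted data.frame with columns `stage`, `term_id`, `count`
#'   (integer >= 0): intended whole-word occurrences of each term within
#'   each stage's abstracts. May have zero rows (pure decoy corpus).
#' @param seed integer seed.
#' @param synonym_frac fraction of plantings that use a randomly chosen
#'   synonym instead of the canonical name (exercises synonym resolution).
#' @param n_decoy_records number of additional pure-decoy records per
#'   stage.
#' @param decoy_stages stages to emit when `planted` is empty.
#' @return a `corpus_truth` object.
#' @export
corpus_truth <- function(planted, seed = 1, synonym_frac = 0.5,
                         n_decoy_records = 2, decoy_stages = "general") {
  if (nrow(planted)) {
    stop_if_not(all(c("stage", "term_id", "count") %in% names(planted)),
                "planted needs columns stage, term_id, count")
    stop_if_not(all(planted$count >= 0), "planted counts must be >= 0")
  }
  structure(list(planted = planted, seed = seed, synonym_frac = synonym_frac,
                 n_decoy_records = n_decoy_records, decoy_stages = decoy_stages),
            class = "corpus_truth")
}

# decoys that cannot collide with any vocabulary pattern, nor form part of
# a multi-word vocabulary term by adjacency
safe_decoys <- function(vocab) {
  words <- decoy_wordlist()
  pats <- vocab_patterns(vocab)$pattern
  term_words <- unique(tolower(unlist(strsplit(pats, "[^A-Za-z0-9_]+"))))
  ok <- !(tolower(words) %in% c(tolower(pats), term_words))
  out <- words[ok]
  stop_if_not(length(out) >= 10, "vocabulary collides with almost all decoy words")
  out
}

#' Generate a synthetic abstract corpus with planted vocabulary terms
#'
#' Abstracts are shuffled decoy-word sentences with term occurrences
#' inserted at word boundaries; each planted term is followed by a decoy
#' word so that plantings can never merge into a longer spurious match.
#' An exhaustive whole-word scan of the emitted corpus recovers exactly
#' the planted per-stage counts.
#'
#' @param vocab a [vocabulary()].
#' @param truth a [corpus_truth()]; all `term_id`s must exist in `vocab`.
#' @return data.frame with columns `id`, `stage`, `title`, `abstract`.
#' @export
gen_corpus <- function(vocab, truth) {
  stop_if_not(inherits(vocab, "dars_vocabulary"), "vocab must be a dars_vocabulary")
  stop_if_not(inherits(truth, "corpus_truth"), "truth must be a corpus_truth")
  unknown <- setdiff(truth$planted$term_id, vocab$term_id)
  if (length(unknown)) {
    stop("unknown term_id in truth: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  decoys <- safe_decoys(vocab)
  with_seed(truth$seed, {
    stages <- if (nrow(truth$planted)) unique(truth$planted$stage) else truth$decoy_stages
    recs <- list()
    rid <- 0
    mk_record <- function(stage, units) {
      rid <<- rid + 1
      title <- paste(sample(decoys, 4, replace = TRUE), collapse = " ")
      data.frame(id = sprintf("rec%05d", rid), stage = stage, title = title,
                 abstract = paste(unlist(units), collapse = " "),
                 stringsAsFactors = FALSE)
    }
    for (st in stages) {
      sub <- truth$planted[nrow(truth$planted) > 0 & truth$planted$stage == st, , drop = FALSE]
      # expand occurrences and chunk them over records (<= 8 per record)
      occ <- rep(sub$term_id, sub$count)
      if (length(occ)) occ <- sample(occ)
      chunks <- if (length(occ)) split(occ, ceiling(seq_along(occ) / 8)) else list()
      for (ch in chunks) {
        units <- as.list(sample(decoys, 12, replace = TRUE))
        for (tid in ch) {
          i <- match(tid, vocab$term_id)
          syns <- vocab$synonyms[[i]]
          use_syn <- length(syns) > 0 && stats::runif(1) < truth$synonym_frac
          term <- if (use_syn) sample(syns, 1) else vocab$name[i]
          unit <- paste(term, sample(decoys, 1))
          pos <- sample(length(units) + 1, 1)
          units <- append(units, list(unit), after = pos - 1)
        }
        recs[[length(recs) + 1]] <- mk_record(st, units)
      }
      for (k in seq_len(truth$n_decoy_records)) {
        recs[[length(recs) + 1]] <-
          mk_record(st, as.list(sample(decoys, 15, replace = TRUE)))
      }
    }
    out <- do.call(rbind, recs)
    rownames(out) <- NULL
    out
  })
}

#' Generate a baseline count matrix with a planted expressed-gene set
#'
#' Expressed genes draw counts of at least 5 in every sample (so mean and
#' median are both >= 5); non-expressed genes draw counts capped at 4 (so
#' mean and median are both < 5). The mean/median-5 expression filter
#' therefore recovers the planted set exactly.
#'
#' @param n_genes,n_samples matrix dimensions (positive).
#' @param expressed_fraction fraction of genes planted as expressed.
#' @param seed integer seed.
#' @return list with `counts` (genes x samples integer matrix) and
#'   `expressed` (character vector of planted expressed gene names).
#' @export
gen_baseline_counts <- function(n_genes, expressed_fraction, n_samples, seed = 1) {
  stop_if_not(n_genes > 0 && n_samples >= 1, "dimensions must be positive")
  stop_if_not(expressed_fraction >= 0 && expressed_fraction <= 1,
              "expressed_fraction must lie in [0, 1]")
  with_seed(seed, {
    genes <- sprintf("G%05d", seq_len(n_genes))
    n_expr <- round(expressed_fraction * n_genes)
    expressed <- sort(sample(genes, n_expr))
    counts <- matrix(0L, n_genes, n_samples,
                     dimnames = list(genes, sprintf("S%03d", seq_len(n_samples))))
    is_expr <- genes %in% expressed
    counts[is_expr, ] <- 5L + stats::rpois(sum(is_expr) * n_samples, 45)
    counts[!is_expr, ] <- pmin(stats::rpois(sum(!is_expr) * n_samples, 1), 4L)
    list(counts = counts, expressed = expressed)
  })
}

#' Ground truth for dose-response generators
#'
#' @param pod true PoD (uM) of the hinge response.
#' @param beta effect slope on the log count scale per decade of
#'   concentration.
#' @param sigma scale of the Student's-t noise on the log rate (>= 0).
#' @param nu degrees of freedom of the t noise (> 2).
#' @param mu0 baseline log count.
#' @param size_factors optional per-sample log size factors; when NULL
#'   they are drawn log-normal with SD 0.2.
#' @param ic50,hill true IC50 (uM) and Hill slope for binding curves.
#' @param null_gene set TRUE to permit a PoD outside the tested
#'   concentration range (no effect within range).
#' @return a `dose_response_truth` object.
#' @export
dose_response_truth <- function(pod = 10, beta = 1, sigma = 0.2, nu = 5,
                                mu0 = log(100), size_factors = NULL,
                                ic50 = 5, hill = 1, null_gene = FALSE) {
  stop_if_not(sigma >= 0, "sigma must be >= 0")
  stop_if_not(nu > 2, "nu must exceed 2")
  stop_if_not(pod > 0 && ic50 > 0, "pod and ic50 must be positive")
  structure(list(pod = pod, beta = beta, sigma = sigma, nu = nu, mu0 = mu0,
                 size_factors = size_factors, ic50 = ic50, hill = hill,
                 null_gene = null_gene),
            class = "dose_response_truth")
}

#' Generate transcriptomic counts with a hinge concentration response
#'
#' Counts are Poisson with log-rate `mu0 + size_factor +
#' beta * max(0, log10 c - log10 PoD) + eps`, `eps ~ t(nu, 0, sigma)`:
#' below the PoD there is no systematic effect.
#'
#' @param truth a [dose_response_truth()]; the PoD must lie within the
#'   concentration hull unless `null_gene = TRUE`.
#' @param concentrations strictly positive, sorted ascending (uM).
#' @param n_reps replicates per concentration (>= 1).
#' @param seed integer seed.
#' @return data.frame with columns `conc`, `replicate`, `count`,
#'   `size_factor`.
#' @export
gen_httr_counts <- function(truth, concentrations, n_reps, seed = 1) {
  stop_if_not(all(concentrations > 0), "concentrations must be positive")
  stop_if_not(!is.unsorted(concentrations, strictly = TRUE),
              "concentrations must be sorted, strictly increasing")
  stop_if_not(n_reps >= 1, "n_reps must be >= 1")
  if (!truth$null_gene &&
      (truth$pod < min(concentrations) || truth$pod > max(concentrations))) {
    stop("true PoD lies outside the tested concentration range; ",
         "flag the probe as null_gene to permit this", call. = FALSE)
  }
  with_seed(seed, {
    conc <- rep(concentrations, each = n_reps)
    n <- length(conc)
    sf <- truth$size_factors %||% stats::rnorm(n, 0, 0.2)
    stop_if_not(length(sf) == n, "size_factors length must match samples")
    eps <- if (truth$sigma > 0) truth$sigma * stats::rt(n, truth$nu) else 0
    eta <- truth$mu0 + sf + truth$beta * pmax(0, log10(conc) - log10(truth$pod)) + eps
    data.frame(conc = conc,
               replicate = rep(seq_len(n_reps), times = length(concentrations)),
               count = stats::rpois(n, exp(eta)),
               size_factor = sf)
  })
}

#' Generate a percent-inhibition binding curve
#'
#' Mean inhibition at dose x is `100 x^h / (IC50^h + x^h)` (bottom 0%, top
#' 100%) plus Gaussian noise.
#'
#' @param truth a [dose_response_truth()] supplying `ic50` and `hill`.
#' @param doses positive doses (uM).
#' @param noise_sd Gaussian noise SD in percent (>= 0).
#' @param n_reps replicates per dose.
#' @param seed integer seed.
#' @return data.frame with columns `dose`, `replicate`, `inhibition`.
#' @export
gen_binding_curve <- function(truth, doses, noise_sd = 5, n_reps = 2, seed = 1) {
  stop_if_not(all(doses > 0), "doses must be positive")
  stop_if_not(noise_sd >= 0, "noise_sd must be >= 0")
  with_seed(seed, {
    x <- rep(doses, each = n_reps)
    mean_inh <- 100 * x^truth$hill / (truth$ic50^truth$hill + x^truth$hill)
    data.frame(dose = x,
               replicate = rep(seq_len(n_reps), times = length(doses)),
               inhibition = mean_inh + stats::rnorm(length(x), 0, noise_sd))
  })
}

#' Generate sparse noisy PK observations around a simulated profile
#'
#' Applies multiplicative log-normal noise with the stated coefficient of
#' variation to the simulated concentration at the requested sampling
#' times (concentrations are positive, so a multiplicative error model is
#' the natural choice).
#'
#' @param profile a `pk_profile` from [simulate_pbk()].
#' @param times sampling times (h); must lie within the simulated horizon.
#' @param cv coefficient of variation, `0 <= cv < 1`.
#' @param seed integer seed.
#' @param compartment compartment to sample (default maternal `"plasma"`).
#' @return data.frame with columns `time`, `conc`.
#' @export
gen_pk_observations <- function(profile, times, cv, seed = 1,
                                compartment = "plasma") {
  stop_if_not(cv >= 0 && cv < 1, "cv must lie in [0, 1)")
  if (any(times < min(profile$time)) || any(times > max(profile$time))) {
    stop("sampling times outside the simulated horizon", call. = FALSE)
  }
  sim <- stats::approx(profile$time, profile$conc[, compartment], xout = times,
                       ties = "ordered")$y
  with_seed(seed, {
    sdlog <- sqrt(log(1 + cv^2))
    fac <- if (cv > 0) exp(stats::rnorm(length(times), 0, sdlog)) else 1
    data.frame(time = times, conc = sim * fac)
  })
}

#' Synthetic four-cell-line membership structure at study scale
#'
#' Builds four expressed-gene sets, a marker list, a gap annotation and an
#' assay-panel target list whose set arithmetic has exactly the requested
#' cardinalities. The defaults emulate a realistic four-cell-line
#' baseline-expression study: per-line totals 8,931 / 9,261 / 10,819 /
#' 11,483, union 14,225, four-way intersection 6,564, per-line uniques
#' 186 / 145 / 781 / 2,319, a 3,551-gene marker list of which 2,730 are
#' covered, and 41 GPCR-annotated gaps of which 6 sit on the panel. All
#' gene identifiers are synthetic (`G000001`, ...).
#'
#' @param lines names of the four cell lines.
#' @param cells named integer vector of Venn-cell sizes; names are
#'   `+`-separated subsets of `lines`.
#' @param n_markers marker list size; `n_covered` of them are drawn from
#'   the union (spread over all occupied Venn cells), the rest are fresh
#'   symbols absent from every line.
#' @param gap_classes named integer vector: annotation classes assigned to
#'   the uncovered markers (remainder unclassified).
#' @param n_panel_overlap number of GPCR-class gaps also present on the
#'   synthetic panel target list.
#' @return list with `sets` (named list of gene sets), `markers`,
#'   `annotation` (data.frame gene, class), `panel`.
#' @export
gen_membership_structure <- function(
    lines = c("MCF7", "HepG2", "HepaRG", "iPSC"),
    cells = c("MCF7" = 186, "HepG2" = 145, "HepaRG" = 781, "iPSC" = 2319,
              "MCF7+HepaRG" = 581, "HepG2+HepaRG" = 549, "HepG2+iPSC" = 256,
              "HepaRG+iPSC" = 497,
              "MCF7+HepG2+HepaRG" = 500, "MCF7+HepG2+iPSC" = 500,
              "MCF7+HepaRG+iPSC" = 600, "HepG2+HepaRG+iPSC" = 747,
              "MCF7+HepG2+HepaRG+iPSC" = 6564),
    n_markers = 3551, n_covered = 2730,
    gap_classes = c(GPCR = 41, HTH_transcription_factor = 67,
                    intercellular_signalling = 83),
    n_panel_overlap = 6) {
  stop_if_not(n_covered <= n_markers, "n_covered cannot exceed n_markers")
  stop_if_not(sum(gap_classes) <= n_markers - n_covered,
              "gap classes exceed the number of uncovered markers")
  total <- sum(cells)
  stop_if_not(n_covered <= total, "n_covered exceeds the union size")
  genes <- sprintf("G%06d", seq_len(total + (n_markers - n_covered)))
  sets <- stats::setNames(vector("list", length(lines)), lines)
  idx <- 0
  cell_genes <- list()
  for (nm in names(cells)) {
    g <- genes[idx + seq_len(cells[[nm]])]
    idx <- idx + cells[[nm]]
    cell_genes[[nm]] <- g
    for (ln in strsplit(nm, "+", fixed = TRUE)[[1]]) {
      sets[[ln]] <- c(sets[[ln]], g)
    }
  }
  # covered markers: spread proportionally over the occupied Venn cells
  union_genes <- genes[seq_len(total)]
  quota <- round(cells / total * n_covered)
  # fix rounding so the quotas sum exactly
  excess <- sum(quota) - n_covered
  k <- 1
  while (excess != 0) {
    adj <- if (excess > 0) -1 else 1
    if (quota[k] + adj >= 0 && quota[k] + adj <= cells[k]) {
      quota[k] <- quota[k] + adj
      excess <- excess + adj
    }
    k <- k %% length(quota) + 1
  }
  covered <- unlist(Map(function(g, q) g[seq_len(q)], cell_genes, as.list(quota)),
                    use.names = FALSE)
  missing <- genes[total + seq_len(n_markers - n_covered)]
  ann_class <- rep("unclassified", length(missing))
  pos <- 0
  for (cl in names(gap_classes)) {
    ann_class[pos + seq_len(gap_classes[[cl]])] <- cl
    pos <- pos + gap_classes[[cl]]
  }
  gpcr <- missing[ann_class == "GPCR"]
  panel <- c(gpcr[seq_len(min(n_panel_overlap, length(gpcr)))],
             sprintf("PANEL%03d", seq_len(54)))
  list(sets = lapply(sets, sort),
       markers = sort(c(covered, missing)),
       annotation = data.frame(gene = missing, class = ann_class,
                               stringsAsFactors = FALSE),
       panel = panel)
}
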