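test_that("vocabulary validation rejects duplicates, bad classes and ambiguous synonyms", {
  expect_error(vocabulary(data.frame(term_id = c("A", "A"), name = c("x", "y"),
                                     class = "gene")), "duplicated")
  expect_error(vocabulary(data.frame(term_id = "A", name = "x", class = "protein")),
               "unknown class")
  expect_error(vocabulary(data.frame(term_id = c("A", "B"),
                                     name = c("shared name", "other"),
                                     class = "gene",
                                     synonyms = c("", "shared name"))),
               "ambiguous")
  # same synonym across classes is fine
  expect_s3_class(vocabulary(data.frame(term_id = c("A", "B"),
                                        name = c("alpha", "alpha"),
                                        class = c("gene", "process"))),
                  "dars_vocabulary")
})

test_that("hit counting matches the brute-force scanner on synthetic corpora", {
  vocab <- test_vocab()
  for (seed in c(11, 12, 13)) {
    truth <- random_truth(seed)
    corp <- gen_corpus(vocab, truth)
    tab <- count_hits(corp, vocab)
    for (st in unique(corp$stage)) {
      sub <- corp[corp$stage == st, ]
      oracle <- oracle_scan(paste(sub$title, sub$abstract), vocab)
      got <- setNames(tab$hit_count[tab$stage_id == st],
                      tab$term_id[tab$stage_id == st])
      expect_identical(got[names(oracle)], oracle)
    }
  }
})

test_that("planted counts are recovered exactly, per stage, and synonyms resolve", {
  vocab <- test_vocab()
  truth <- corpus_truth(data.frame(stage = "neurulation", term_id = "SHH",
                                   count = 12), seed = 7)
  corp <- gen_corpus(vocab, truth)
  tab <- count_hits(corp, vocab)
  expect_equal(tab$hit_count[tab$stage_id == "neurulation" & tab$term_id == "SHH"], 12)
  expect_true(all(tab$hit_count[tab$term_id != "SHH"] == 0))

  # synonym-only plantings accrue to the canonical term id
  truth_syn <- corpus_truth(data.frame(stage = "s1", term_id = "WNT1", count = 9),
                            seed = 8, synonym_frac = 1)
  tab_syn <- count_hits(gen_corpus(vocab, truth_syn), vocab)
  expect_equal(tab_syn$hit_count[tab_syn$term_id == "WNT1"], 9)
})

test_that("matching is longest-first and short terms are case-sensitive", {
  vocab <- vocabulary(data.frame(
    term_id = c("FD", "DEV", "SHH"),
    name = c("fetal development", "development", "SHH"),
    class = "gene", stringsAsFactors = FALSE))
  recs <- data.frame(id = "r1", stage = "s",
                     title = "",
                     abstract = "fetal development and shh but SHH again")
  tab <- count_hits(recs, vocab)
  cnt <- setNames(tab$hit_count, tab$term_id)
  expect_equal(cnt[["FD"]], 1)    # the long match wins the span
  expect_equal(cnt[["DEV"]], 0)   # no leftover inner match
  expect_equal(cnt[["SHH"]], 1)   # 3-char term: 'shh' does not match
})

test_that("hyphen acts as a word boundary and matches are whole-word", {
  vocab <- vocabulary(data.frame(term_id = "WNT1", name = "Wnt-1",
                                 class = "gene", stringsAsFactors = FALSE))
  recs <- data.frame(id = "r", stage = "s", title = "",
                     abstract = "Wnt-1 signalling but not Wnt-10 nor aWnt-1")
  tab <- count_hits(recs, vocab)
  expect_equal(tab$hit_count, 1L)
})

test_that("document mode counts records, not occurrences", {
  vocab <- test_vocab()
  truth <- corpus_truth(data.frame(stage = "s", term_id = "SHH", count = 7),
                        seed = 5, synonym_frac = 0)
  corp <- gen_corpus(vocab, truth)  # 7 occurrences in one record chunk
  occ <- count_hits(corp, vocab, mode = "occurrence")
  doc <- count_hits(corp, vocab, mode = "document")
  expect_equal(occ$hit_count[occ$term_id == "SHH"], 7)
  expect_lte(doc$hit_count[doc$term_id == "SHH"],
             occ$hit_count[occ$term_id == "SHH"])
  expect_gte(doc$hit_count[doc$term_id == "SHH"], 1)
})

test_that("corpus filtering equals brute-force boolean evaluation", {
  vocab <- test_vocab()
  corp <- gen_corpus(vocab, random_truth(21))
  # salt some records with query vocabulary
  set.seed(21)
  extras <- c("embryonic development", "fetal development", "signalling",
              "infections", "gene")
  corp$abstract <- paste(corp$abstract,
                         sapply(seq_len(nrow(corp)), function(i) {
                           paste(sample(extras, sample(0:3, 1)), collapse = " ")
                         }))
  q <- stage_query("s", include = list(c("embryonic development", "fetal development"),
                                       c("signalling", "gene")),
                   exclude = "infections")
  kept <- filter_corpus(corp, q)
  oracle_keep <- vapply(seq_len(nrow(corp)),
                        function(i) oracle_query_keep(corp[i, ], q), logical(1))
  expect_identical(kept$id, corp$id[oracle_keep])

  # direct examples: both groups present -> retained; exclusion term -> dropped
  r_in <- data.frame(id = "a", stage = "s", title = "x",
                     abstract = "fetal development via signalling")
  r_ex <- data.frame(id = "b", stage = "s", title = "x",
                     abstract = "fetal development via signalling in infections")
  expect_equal(nrow(filter_corpus(rbind(r_in, r_ex), q)), 1)
  expect_error(filter_corpus(corp, stage_query("s", list(character(0)))),
               "include group")
})

test_that("sifter check partitions the corpus by keyword presence", {
  recs <- data.frame(id = c("a", "b"), stage = "cns", title = c("x", "y"),
                     abstract = c("astrocyte biology", "nothing relevant"))
  res <- sift_check(recs, c("central nervous", "spinal", "neuron", "astrocyte"))
  expect_identical(res$kept$id, "a")
  expect_identical(res$flagged$id, "b")
  expect_setequal(c(res$kept$id, res$flagged$id), recs$id)
  expect_length(intersect(res$kept$id, res$flagged$id), 0)
  expect_error(sift_check(recs, character(0)), "non-empty")
})

test_that("class thresholds retain at the boundary and drop below it", {
  mk <- function(counts, class) {
    structure(data.frame(stage_id = "s", term_id = paste0("t", seq_along(counts)),
                         class = class, hit_count = counts),
              class = c("hit_table", "data.frame"))
  }
  gene <- apply_thresholds(mk(c(11924, 10, 9), "gene"), "gene")$s
  expect_setequal(gene$terms$term_id, c("t1", "t2"))
  proc <- apply_thresholds(mk(c(5, 4), "process"), "process")$s
  expect_identical(proc$terms$term_id, "t1")
  mir <- apply_thresholds(mk(c(2, 1), "miRNA"), "miRNA")$s
  expect_identical(mir$terms$term_id, "t1")
  expect_error(apply_thresholds(mk(1, "gene"), "lipid"), "unknown class")
})

test_that("thresholding is monotone in added records", {
  vocab <- test_vocab()
  truth1 <- corpus_truth(data.frame(stage = "s",
                                    term_id = c("SHH", "WNT1"),
                                    count = c(10, 12)), seed = 31)
  corp1 <- gen_corpus(vocab, truth1)
  corp2 <- rbind(corp1, gen_corpus(vocab, corpus_truth(
    data.frame(stage = "s", term_id = "SHH", count = 3), seed = 32)))
  s1 <- apply_thresholds(count_hits(corp1, vocab), "gene")$s$terms$term_id
  s2 <- apply_thresholds(count_hits(corp2, vocab), "gene")$s$terms$term_id
  expect_true(all(s1 %in% s2))
})

test_that("pooling unions stages, sums counts and keeps the accounting identity", {
  mk_set <- function(stage, ids, counts) {
    structure(list(stage_id = stage, class = "gene",
                   terms = data.frame(term_id = ids, hit_count = counts),
                   threshold = 10), class = "marker_set")
  }
  a <- mk_set("s1", c("A", "B", "C"), c(20, 15, 12))
  b <- mk_set("s2", c("D", "E", "F", "G"), c(30, 11, 10, 10))
  pool <- pool_markers(list(a, b))
  expect_equal(nrow(pool$terms), 7)
  expect_equal(pool$n_duplicates, 0)

  dup <- pool_markers(list(a, a))
  expect_equal(nrow(dup$terms), 3)
  expect_equal(dup$terms$total_hits[dup$terms$term_id == "A"], 40)
  expect_equal(dup$n_duplicates, 3)

  # random sets vs brute-force union with summed counts
  set.seed(41)
  sets <- lapply(1:4, function(i) {
    ids <- sample(LETTERS, 8)
    mk_set(paste0("s", i), ids, sample(10:99, 8))
  })
  pool <- pool_markers(sets)
  all_rows <- do.call(rbind, lapply(sets, function(s) s$terms))
  brute <- tapply(all_rows$hit_count, all_rows$term_id, sum)
  expect_equal(setNames(pool$terms$total_hits, pool$terms$term_id)[names(brute)],
               setNames(as.integer(brute), names(brute)))
  expect_equal(nrow(pool$terms) + pool$n_duplicates, nrow(all_rows))
  # ranking: totals descending, ties lexicographic
  expect_true(all(diff(pool$terms$total_hits) <= 0))
  ties <- split(pool$terms$term_id, pool$terms$total_hits)
  expect_true(all(vapply(ties, function(v) !is.unsorted(v), logical(1))))

  cset <- mk_set("s3", "X", 5); cset$class <- "process"
  expect_error(pool_markers(list(a, cset)), "mixed classes")
})

test_that("overrepresentation matches exhaustive hypergeometric enumeration", {
  universe <- sprintf("g%04d", 1:1000)
  markers <- universe[1:10]
  ann <- list(hit_cat = universe[1:10], null_cat = universe[500:599])
  res <- overrepresentation(markers, ann, universe)
  # brute force: sum over the hypergeometric pmf tail
  brute_p <- function(k, K, n, N) sum(dhyper(k:min(K, n), K, N - K, n))
  expect_equal(res$p_value[res$category == "hit_cat"], brute_p(10, 10, 10, 1000))
  expect_equal(res$p_value[res$category == "null_cat"], brute_p(0, 100, 10, 1000))
  # k = 0 category never outranks the full-overlap category
  expect_identical(res$category[1], "hit_cat")
  # BH values non-decreasing in raw-p order
  expect_true(all(diff(res$p_adjust) >= -1e-12))
  # degenerate: category equal to the universe
  res2 <- overrepresentation(markers, list(all = universe), universe)
  expect_equal(res2$p_value, 1)
  expect_error(overrepresentation(c(markers, "NOTIN"), ann, universe),
               "NOTIN")
})
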