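# Dictionary-based hit counting and marker-set assembly.
#
# Matching semantics (fixed so results are oracle-checkable):
#  * whole-word: a match may not be flanked by [A-Za-z0-9_]; hyphen and
#    slash act as word boundaries;
#  * case-insensitive for patterns longer than three characters,
#    case-sensitive otherwise;
#  * longest-match-first, non-overlapping: every matched character span is
#    attributed to exactly one term.

term_regex <- function(pattern) {
  esc <- gsub("([][^$.|?*+(){}\\\\])", "\\\\\\1", pattern)
  paste0("(?<![A-Za-z0-9_])", esc, "(?![A-Za-z0-9_])")
}

# all candidate spans of all patterns in one text
candidate_spans <- function(text, patterns) {
  out <- vector("list", nrow(patterns))
  for (i in seq_len(nrow(patterns))) {
    pat <- patterns$pattern[i]
    m <- gregexpr(term_regex(pat), text, perl = TRUE,
                  ignore.case = nchar(pat) > 3)[[1]]
    if (m[1] == -1L) next
    out[[i]] <- data.frame(start = as.integer(m),
                           len = attr(m, "match.length"),
                           term_id = patterns$term_id[i],
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# resolve overlaps: longest span first, ties by start then term_id
resolve_spans <- function(spans) {
  if (is.null(spans) || nrow(spans) == 0) return(spans)
  spans <- spans[order(-spans$len, spans$start, spans$term_id), , drop = FALSE]
  end <- spans$start + spans$len - 1L
  taken_start <- integer(0); taken_end <- integer(0)
  keep <- logical(nrow(spans))
  for (i in seq_len(nrow(spans))) {
    s <- spans$start[i]; e <- end[i]
    if (!any(s <= taken_end & e >= taken_start)) {
      keep[i] <- TRUE
      taken_start <- c(taken_start, s)
      taken_end <- c(taken_end, e)
    }
  }
  spans[keep, , drop = FALSE]
}

scan_term_counts <- function(texts, patterns) {
  counts <- stats::setNames(integer(length(unique(patterns$term_id))),
                            unique(patterns$term_id))
  for (txt in texts) {
    sp <- resolve_spans(candidate_spans(txt, patterns))
    if (!is.null(sp) && nrow(sp)) {
      tab <- table(sp$term_id)
      counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
    }
  }
  counts
}

record_text <- function(records) paste(records$title, records$abstract)

#' Boolean stage query
#'
#' Represents one literature query for a developmental stage: a conjunction
#' of OR-groups of include terms, optional exclude terms, and optional
#' sifter terms (relevance keywords used by [sift_check()]).
#'
#' @param stage_id stage label.
#' @param include list of character vectors; each vector is an OR-group and
#'   all groups must be satisfied (AND).
#' @param exclude character vector of exclusion terms.
#' @param sifter character vector of relevance keywords.
#' @return an object of class `stage_query`.
#' @export
stage_query <- function(stage_id, include, exclude = character(), sifter = character()) {
  if (is.character(include)) include <- list(include)
  stop_if_not(length(include) >= 1 && all(vapply(include, length, integer(1)) >= 1),
              "query needs at least one non-empty include group")
  structure(list(stage_id = as.character(stage_id), include = include,
                 exclude = as.character(exclude), sifter = as.character(sifter)),
            class = "stage_query")
}

query_term_hits <- function(texts, term) {
  grepl(term_regex(term), texts, perl = TRUE, ignore.case = TRUE)
}

#' Filter a corpus by a boolean stage query
#'
#' A record is retained iff every include group has at least one whole-word,
#' case-insensitive match in title + abstract and no exclude term matches.
#' Input order is preserved.
#'
#' @param records data.frame with columns `id`, `stage`, `title`, `abstract`.
#' @param query a [stage_query()].
#' @return the retained subset of `records`.
#' @export
filter_corpus <- function(records, query) {
  stop_if_not(inherits(query, "stage_query"), "query must be a stage_query")
  stop_if_not(all(c("title", "abstract") %in% names(records)),
              "records must carry title and abstract text")
  texts <- record_text(records)
  keep <- rep(TRUE, nrow(records))
  for (grp in query$include) {
    hit <- Reduce(`|`, lapply(grp, function(t) query_term_hits(texts, t)))
    keep <- keep & hit
  }
  for (t in query$exclude) keep <- keep & !query_term_hits(texts, t)
  records[keep, , drop = FALSE]
}

#' Relevance sifting of query results
#'
#' Flags records containing none of the sifter keywords (key terms from the
#' biology of interest) for manual exclusion; all others are kept.
#'
#' @param records corpus data.frame.
#' @param sifter_terms non-empty character vector of keywords.
#' @return list with elements `kept` and `flagged`, a disjoint partition of
#'   `records`.
#' @export
sift_check <- function(records, sifter_terms) {
  stop_if_not(length(sifter_terms) >= 1, "sifter term list must be non-empty")
  texts <- record_text(records)
  hit <- Reduce(`|`, lapply(sifter_terms, function(t) query_term_hits(texts, t)))
  list(kept = records[hit, , drop = FALSE],
       flagged = records[!hit, , drop = FALSE])
}

#' Count vocabulary hits per stage
#'
#' Aligns each record's title + abstract to the vocabulary and counts, per
#' (stage, term), either every matched occurrence (default; the scale on
#' which top literature terms accumulate thousands of hits) or the number of
#' matching documents.
#'
#' @param records corpus data.frame with columns `stage`, `title`, `abstract`.
#' @param vocab a [vocabulary()].
#' @param mode `"occurrence"` (default) or `"document"`.
#' @return a `hit_table` data.frame with one row per (stage, term):
#'   columns `stage_id`, `term_id`, `class`, `hit_count`.
#' @export
count_hits <- function(records, vocab, mode = c("occurrence", "document")) {
  mode <- match.arg(mode)
  stop_if_not(inherits(vocab, "dars_vocabulary"), "vocab must be a dars_vocabulary")
  pats <- vocab_patterns(vocab)
  stages <- unique(as.character(records$stage))
  rows <- lapply(stages, function(st) {
    texts <- record_text(records[records$stage == st, , drop = FALSE])
    if (mode == "occurrence") {
      cnt <- scan_term_counts(texts, pats)
    } else {
      per_doc <- lapply(texts, function(txt) {
        sp <- resolve_spans(candidate_spans(txt, pats))
        unique(if (is.null(sp)) character(0) else sp$term_id)
      })
      cnt <- stats::setNames(integer(nrow(vocab)), vocab$term_id)
      tab <- table(unlist(per_doc))
      cnt[names(tab)] <- as.integer(tab)
    }
    data.frame(stage_id = st, term_id = vocab$term_id,
               class = vocab$class,
               hit_count = as.integer(cnt[vocab$term_id]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(stage_id = character(), term_id = character(),
                      class = character(), hit_count = integer())
  }
  rownames(out) <- NULL
  structure(out, class = c("hit_table", "data.frame"))
}

#' Class-specific hit-count thresholds
#'
#' Default thresholds retain a gene term at >= 10 hits, a process term at
#' >= 5 hits and a miRNA term at >= 2 hits within a stage.
#'
#' @param gene,process,miRNA minimum hit counts per class.
#' @return named numeric vector of thresholds.
#' @export
dars_thresholds <- function(gene = 10, process = 5, miRNA = 2) {
  c(gene = gene, process = process, miRNA = miRNA)
}

#' Apply class-specific hit-count thresholds
#'
#' Retains, within each stage, the terms of the given class whose hit count
#' meets the class threshold, yielding one marker set per stage.
#'
#' @param table a `hit_table` from [count_hits()].
#' @param class one of `"gene"`, `"process"`, `"miRNA"`.
#' @param thresholds named vector as from [dars_thresholds()].
#' @return named list of `marker_set` objects, one per stage. Each has
#'   fields `stage_id`, `class`, `terms` (data.frame term_id, hit_count) and
#'   `threshold`.
#' @export
apply_thresholds <- function(table, class, thresholds = dars_thresholds()) {
  if (!class %in% names(thresholds)) {
    stop("unknown class '", class, "'", call. = FALSE)
  }
  thr <- thresholds[[class]]
  tab <- table[table$class == class, , drop = FALSE]
  stages <- unique(tab$stage_id)
  sets <- lapply(stages, function(st) {
    sub <- tab[tab$stage_id == st & tab$hit_count >= thr, , drop = FALSE]
    sub <- sub[order(-sub$hit_count, sub$term_id), c("term_id", "hit_count")]
    rownames(sub) <- NULL
    structure(list(stage_id = st, class = class, terms = sub, threshold = thr),
              class = "marker_set")
  })
  stats::setNames(sets, stages)
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("Marker set [%s] stage '%s': %d terms at threshold >= %g\n",
              x$class, x$stage_id, nrow(x$terms), x$threshold))
  invisible(x)
}

#' Pool per-stage marker sets into a single ranked list
#'
#' Unions the retained terms of all stages; per-term totals are the sum of
#' per-stage hit counts, provenance records the contributing stages, and the
#' pool is ranked by total descending with ties broken lexicographically by
#' term id.
#'
#' @param sets list of `marker_set` objects sharing one class.
#' @return a `dars_pool` object with fields `class`, `terms` (data.frame
#'   term_id, total_hits, n_stages), `provenance` (list term_id -> stages)
#'   and `n_duplicates` (sum of stage set sizes minus pool size).
#' @export
pool_markers <- function(sets) {
  stop_if_not(length(sets) >= 1, "no marker sets supplied")
  cls <- unique(vapply(sets, function(s) s$class, character(1)))
  if (length(cls) != 1) {
    stop("marker sets of mixed classes cannot be pooled: ",
         paste(cls, collapse = ", "), call. = FALSE)
  }
  all_rows <- do.call(rbind, lapply(sets, function(s) {
    cbind(s$terms, stage_id = s$stage_id, stringsAsFactors = FALSE)
  }))
  total <- tapply(all_rows$hit_count, all_rows$term_id, sum)
  prov <- lapply(split(all_rows$stage_id, all_rows$term_id), unique)
  terms <- data.frame(term_id = names(total),
                      total_hits = as.integer(total),
                      n_stages = vapply(prov[names(total)], length, integer(1)),
                      stringsAsFactors = FALSE)
  terms <- terms[order(-terms$total_hits, terms$term_id), ]
  rownames(terms) <- NULL
  structure(list(class = cls, terms = terms, provenance = prov,
                 n_duplicates = nrow(all_rows) - nrow(terms)),
            class = "dars_pool")
}

#' @export
print.dars_pool <- function(x, ...) {
  cat(sprintf("Pooled marker list [%s]: %d unique terms (%d stage-level duplicates absorbed)\n",
              x$class, nrow(x$terms), x$n_duplicates))
  if (nrow(x$terms)) {
    top <- utils::head(x$terms, 3)
    cat("  top terms:", paste(sprintf("%s (%d)", top$term_id, top$total_hits),
                              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Hypergeometric overrepresentation of marker sets
#'
#' For each annotation category, tests whether the markers overlap the
#' category more than expected under hypergeometric sampling from the
#' universe (upper-tail P(X >= k)), with Benjamini-Hochberg adjustment
#' across categories. Output is sorted by ascending p-value.
#'
#' @param markers character vector of term ids (must be a subset of
#'   `universe`).
#' @param annotation named list category -> character vector of term ids, or
#'   a data.frame with columns `term_id`, `category`.
#' @param universe character vector: the term universe.
#' @param top if non-NULL, return only the `top` smallest p-values.
#' @return data.frame with columns `category`, `K` (category size), `k`
#'   (overlap), `p_value`, `p_adjust`.
#' @export
overrepresentation <- function(markers, annotation, universe, top = NULL) {
  markers <- unique(markers)
  universe <- unique(universe)
  off <- setdiff(markers, universe)
  if (length(off)) {
    stop("markers not in universe: ", paste(utils::head(off, 10), collapse = ", "),
         call. = FALSE)
  }
  if (is.data.frame(annotation)) {
    annotation <- split(annotation$term_id, annotation$category)
  }
  stop_if_not(length(annotation) >= 1, "annotation categories must be non-empty")
  N <- length(universe); n <- length(markers)
  rows <- lapply(names(annotation), function(cat) {
    catset <- intersect(unique(annotation[[cat]]), universe)
    K <- length(catset)
    k <- length(intersect(markers, catset))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(category = cat, K = K, k = k, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjust <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$category), ]
  rownames(out) <- NULL
  if (!is.null(top)) out <- utils::head(out, top)
  out
}
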