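# Regex-free brute-force oracles, independent of the package's matcher.

# exhaustive character-level whole-word scan: every candidate span of every
# pattern, resolved longest-first, non-overlapping (ties: start, term_id)
oracle_scan <- function(texts, vocab) {
  pats <- do.call(rbind, lapply(seq_len(nrow(vocab)), function(i) {
    data.frame(term_id = vocab$term_id[i],
               pattern = c(vocab$name[i], vocab$synonyms[[i]]),
               stringsAsFactors = FALSE)
  }))
  is_wordchar <- function(ch) grepl("^[A-Za-z0-9_]$", ch)
  counts <- setNames(integer(nrow(vocab)), vocab$term_id)
  for (txt in texts) {
    chars <- strsplit(txt, "")[[1]]
    n <- length(chars)
    cand <- list()
    for (r in seq_len(nrow(pats))) {
      pat <- pats$pattern[r]
      L <- nchar(pat)
      fold <- nchar(pat) > 3
      target <- if (fold) tolower(pat) else pat
      for (s in seq_len(max(0, n - L + 1))) {
        before_ok <- s == 1 || !is_wordchar(chars[s - 1])
        after_ok <- s + L - 1 == n || !is_wordchar(chars[s + L])
        if (!before_ok || !after_ok) next
        piece <- paste(chars[s:(s + L - 1)], collapse = "")
        if (fold) piece <- tolower(piece)
        if (piece == target) {
          cand[[length(cand) + 1]] <- data.frame(
            start = s, len = L, term_id = pats$term_id[r],
            stringsAsFactors = FALSE)
        }
      }
    }
    if (!length(cand)) next
    cand <- do.call(rbind, cand)
    cand <- cand[order(-cand$len, cand$start, cand$term_id), , drop = FALSE]
    covered <- logical(n)
    for (i in seq_len(nrow(cand))) {
      idx <- cand$start[i]:(cand$start[i] + cand$len[i] - 1)
      if (!any(covered[idx])) {
        covered[idx] <- TRUE
        counts[cand$term_id[i]] <- counts[cand$term_id[i]] + 1L
      }
    }
  }
  counts
}

# substring presence with word boundaries, case-insensitive (query semantics)
oracle_contains <- function(text, term) {
  tl <- tolower(text); pl <- tolower(term)
  L <- nchar(pl)
  chars <- strsplit(tl, "")[[1]]
  n <- length(chars)
  is_wordchar <- function(ch) grepl("^[a-z0-9_]$", ch)
  if (n < L) return(FALSE)
  for (s in seq_len(n - L + 1)) {
    if (paste(chars[s:(s + L - 1)], collapse = "") == pl &&
        (s == 1 || !is_wordchar(chars[s - 1])) &&
        (s + L - 1 == n || !is_wordchar(chars[s + L]))) {
      return(TRUE)
    }
  }
  FALSE
}

oracle_query_keep <- function(record, query) {
  text <- paste(record$title, record$abstract)
  for (grp in query$include) {
    if (!any(vapply(grp, function(t) oracle_contains(text, t), logical(1)))) {
      return(FALSE)
    }
  }
  !any(vapply(query$exclude, function(t) oracle_contains(text, t), logical(1)))
}
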