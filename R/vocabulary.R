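#' Controlled vocabulary of biomarker terms
#'
#' A vocabulary drives dictionary-based named-entity hit counting: each entry
#' has a canonical name, a class (`gene`, `process` or `miRNA`) and an
#' optional set of synonyms. Matching downstream is whole-word and
#' case-insensitive, except that terms of three characters or fewer are
#' matched case-sensitively (short gene symbols collide with English words).
#'
#' Validation enforces that term ids are unique, names are non-empty, and
#' that no synonym (or canonical name) resolves to two different term ids of
#' the same class, so every matched span can be attributed unambiguously.
#'
#' @param df data.frame with columns `term_id`, `name`, `class`, and
#'   optionally `synonyms` (list column, or pipe-separated strings) and
#'   `annotation_class` (free-text protein-class/pathway label used for gap
#'   classification).
#' @return an object of class `dars_vocabulary`.
#' @examples
#' vocabulary(data.frame(term_id = "CGA", name = "glycoprotein hormones alpha chain",
#'                       class = "gene", synonyms = "CGA|GPHa"))
#' @export
vocabulary <- function(df) {
  stop_if_not(is.data.frame(df) && nrow(df) > 0, "vocabulary must be a non-empty data.frame")
  stop_if_not(all(c("term_id", "name", "class") %in% names(df)),
              "vocabulary needs columns term_id, name, class")
  df$term_id <- as.character(df$term_id)
  df$name <- as.character(df$name)
  df$class <- as.character(df$class)
  if (anyDuplicated(df$term_id)) {
    stop("duplicated term_id: ", paste(unique(df$term_id[duplicated(df$term_id)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- !df$class %in% c("gene", "process", "miRNA")
  if (any(bad)) stop("unknown class: ", paste(unique(df$class[bad]), collapse = ", "), call. = FALSE)
  stop_if_not(all(nzchar(df$name)), "term names must be non-empty")
  if (is.null(df$synonyms)) {
    df$synonyms <- vector("list", nrow(df))
  } else if (!is.list(df$synonyms)) {
    df$synonyms <- lapply(strsplit(as.character(df$synonyms), "|", fixed = TRUE),
                          function(s) s[nzchar(trimws(s))])
  }
  if (is.null(df$annotation_class)) df$annotation_class <- NA_character_
  # ambiguity check within class, under the matching case convention
  for (cl in unique(df$class)) {
    sub <- df[df$class == cl, ]
    keys <- unlist(lapply(seq_len(nrow(sub)), function(i) {
      pats <- c(sub$name[i], sub$synonyms[[i]])
      paste0(sub$term_id[i], "\r", match_key(pats))
    }))
    ids <- sub("\r.*$", "", keys)
    pat <- sub("^.*\r", "", keys)
    tab <- split(ids, pat)
    amb <- names(tab)[vapply(tab, function(v) length(unique(v)) > 1, logical(1))]
    if (length(amb)) {
      stop("synonym(s) ambiguous within class '", cl, "': ",
           paste(amb, collapse = ", "), call. = FALSE)
    }
  }
  structure(df, class = c("dars_vocabulary", "data.frame"))
}

# canonical matching key of a pattern: terms > 3 chars fold case
match_key <- function(x) {
  ifelse(nchar(x) > 3, tolower(x), x)
}

#' Read a vocabulary from TSV
#'
#' Expects tab-separated columns `term_id`, `name`, `class`, `synonyms`
#' (pipe-separated, may be empty) and optionally `annotation_class`.
#'
#' @param path file path.
#' @return a [vocabulary()] object.
#' @export
read_vocabulary <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                          stringsAsFactors = FALSE, na.strings = character())
  vocabulary(df)
}

#' Write a vocabulary to TSV
#' @param vocab a [vocabulary()] object.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_vocabulary <- function(vocab, path) {
  out <- as.data.frame(vocab)
  out$synonyms <- vapply(out$synonyms, paste, character(1), collapse = "|")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# flat table of every matchable pattern with its owner term
vocab_patterns <- function(vocab) {
  n <- vapply(vocab$synonyms, length, integer(1))
  data.frame(
    term_id = rep(vocab$term_id, n + 1L),
    class = rep(vocab$class, n + 1L),
    pattern = unlist(Map(function(nm, syn) c(nm, syn), vocab$name, vocab$synonyms),
                     use.names = FALSE),
    stringsAsFactors = FALSE
  )
}

#' @export
print.dars_vocabulary <- function(x, ...) {
  cat("Controlled vocabulary:", nrow(x), "terms (",
      paste(sprintf("%s: %d", names(table(x$class)), table(x$class)), collapse = ", "),
      ")\n")
  invisible(x)
}
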