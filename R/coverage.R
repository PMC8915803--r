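# Baseline-expression filtering, universe pooling and coverage reports.

#' Expressed genes from a targeted sequencing count baseline
#'
#' A probe is discarded if its mean count or its median count across samples
#' falls below the threshold (default 5, OR-discard). With
#' `rule = "and"` a probe is discarded only when both fall below the
#' threshold. Surviving probes are mapped to gene symbols and de-duplicated:
#' a gene is expressed if at least one of its probes survives.
#'
#' @param counts numeric matrix, probes x samples, non-negative integers;
#'   rownames are probe ids.
#' @param probe_map optional data.frame with columns `probe`, `gene`; when
#'   NULL, rownames are taken as gene symbols directly.
#' @param threshold count threshold (default 5).
#' @param rule `"or"` (default: discard if mean < threshold OR median <
#'   threshold) or `"and"`.
#' @return character vector of harmonized expressed gene symbols, sorted.
#' @export
filter_expressed_counts <- function(counts, probe_map = NULL, threshold = 5,
                                    rule = c("or", "and")) {
  rule <- match.arg(rule)
  counts <- as.matrix(counts)
  stop_if_not(ncol(counts) >= 1, "need at least one sample")
  if (any(counts < 0)) stop("negative counts are not allowed", call. = FALSE)
  mn <- rowMeans(counts)
  md <- apply(counts, 1, stats::median)
  discard <- if (rule == "or") (mn < threshold) | (md < threshold)
             else (mn < threshold) & (md < threshold)
  probes <- rownames(counts)[!discard]
  genes <- if (is.null(probe_map)) {
    probes
  } else {
    probe_map$gene[match(probes, probe_map$probe)]
  }
  sort(unique(harmonize_symbols(genes[!is.na(genes)])))
}

#' Expressed genes from a log2 microarray baseline
#'
#' A gene is considered expressed if it exceeds the noise cut-off (default
#' 7.5 log2 units, inclusive) in at least one sample.
#'
#' @param mat numeric matrix, genes x samples, log2 intensities; rownames
#'   are gene symbols.
#' @param cutoff noise cut-off in log2 units (default 7.5).
#' @param inclusive if TRUE (default) the comparison is `>= cutoff`.
#' @return character vector of harmonized expressed gene symbols, sorted.
#' @export
filter_expressed_microarray <- function(mat, cutoff = 7.5, inclusive = TRUE) {
  mat <- as.matrix(mat)
  mx <- apply(mat, 1, max)
  keep <- if (inclusive) mx >= cutoff else mx > cutoff
  sort(unique(harmonize_symbols(rownames(mat)[keep])))
}

#' Pool per-cell-line expressed gene sets into a gene universe
#'
#' Computes the union, the boolean membership matrix (gene x line), the
#' full intersection, and per-line unique genes (expressed in exactly one
#' line).
#'
#' @param sets named list (>= 2 elements) of character gene sets.
#' @return a `gene_universe` object with fields `sets`, `union`,
#'   `membership` (logical matrix), `intersection`, `uniques` (named list).
#' @export
pool_universe <- function(sets) {
  stop_if_not(is.list(sets) && length(sets) >= 2, "need at least two gene sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("gene sets must be named", call. = FALSE)
  }
  sets <- lapply(sets, function(s) sort(unique(harmonize_symbols(s))))
  un <- sort(Reduce(union, sets))
  membership <- vapply(sets, function(s) un %in% s, logical(length(un)))
  if (is.null(dim(membership))) membership <- matrix(membership, nrow = length(un))
  rownames(membership) <- un
  nlines <- rowSums(membership)
  uniques <- lapply(stats::setNames(names(sets), names(sets)), function(nm) {
    un[membership[, nm] & nlines == 1]
  })
  structure(list(sets = sets, union = un, membership = membership,
                 intersection = un[nlines == ncol(membership)],
                 uniques = uniques),
            class = "gene_universe")
}

#' @export
print.gene_universe <- function(x, ...) {
  cat("Gene universe over", length(x$sets), "cell lines\n")
  cat("  union:", length(x$union), " full intersection:", length(x$intersection), "\n")
  for (nm in names(x$sets)) {
    cat(sprintf("  %s: %d genes (%d unique)\n", nm, length(x$sets[[nm]]),
                length(x$uniques[[nm]])))
  }
  invisible(x)
}

#' Coverage of a marker list by a gene universe
#'
#' Intersects a marker gene list (after symbol harmonization) with the
#' pooled expressed-gene universe and reports covered and missing genes.
#'
#' @param markers a `dars_pool` of class `"gene"` or a character vector of
#'   gene symbols.
#' @param universe a [pool_universe()] result.
#' @return a `coverage_report` with fields `n_markers`, `n_covered`,
#'   `n_missing`, `fraction`, `covered`, `missing`, `per_line_unique`.
#' @export
compute_coverage <- function(markers, universe) {
  if (inherits(markers, "dars_pool")) markers <- markers$terms$term_id
  markers <- unique(harmonize_symbols(markers))
  stop_if_not(length(markers) >= 1, "marker list must be non-empty")
  stop_if_not(inherits(universe, "gene_universe"), "universe must be a gene_universe")
  covered <- sort(intersect(markers, universe$union))
  missing <- sort(setdiff(markers, universe$union))
  structure(list(n_markers = length(markers),
                 n_covered = length(covered),
                 n_missing = length(missing),
                 fraction = length(covered) / length(markers),
                 covered = covered, missing = missing,
                 per_line_unique = universe$uniques),
            class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("Marker coverage: %d / %d covered (%.1f%%), %d missing\n",
              x$n_covered, x$n_markers, 100 * x$fraction, x$n_missing))
  invisible(x)
}

#' Classify coverage gaps by annotation class
#'
#' Tallies the missing genes by their annotation class (e.g., protein
#' class); genes without an annotation are reported under `"unclassified"`.
#'
#' @param missing character vector of missing gene symbols.
#' @param annotation named character vector or data.frame (`gene`, `class`)
#'   mapping genes to annotation classes.
#' @return data.frame with columns `class`, `n`, sorted by `n` descending.
#' @export
classify_gaps <- function(missing, annotation) {
  missing <- unique(harmonize_symbols(missing))
  if (length(missing) == 0) {
    return(data.frame(class = character(), n = integer()))
  }
  if (is.data.frame(annotation)) {
    annotation <- stats::setNames(as.character(annotation$class),
                                  harmonize_symbols(annotation$gene))
  } else {
    names(annotation) <- harmonize_symbols(names(annotation))
  }
  cls <- annotation[missing]
  cls[is.na(cls) | !nzchar(cls)] <- "unclassified"
  tab <- sort(table(cls), decreasing = TRUE)
  out <- data.frame(class = names(tab), n = as.integer(tab), stringsAsFactors = FALSE)
  out[order(-out$n, out$class), , drop = FALSE]
}

#' Coverage of genes by an assay panel target list
#'
#' @param genes character vector of gene symbols.
#' @param panel non-empty character vector of panel target gene symbols.
#' @return list with `covered` (sorted intersection) and `n_covered`.
#' @export
panel_coverage <- function(genes, panel) {
  stop_if_not(length(panel) >= 1, "panel target list must be non-empty")
  covered <- sort(intersect(unique(harmonize_symbols(genes)),
                            unique(harmonize_symbols(panel))))
  list(covered = covered, n_covered = length(covered))
}
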