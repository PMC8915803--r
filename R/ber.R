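# Bioactivity-exposure ratios and the risk-assessment decision flow.

#' Bioactivity-exposure ratio
#'
#' Ratio between the nominal in vitro concentration at which a PoD is
#' defined and the relevant plasma Cmax; no in vitro distribution
#' corrections are applied.
#'
#' @param pod PoD (uM), > 0.
#' @param cmax plasma Cmax (uM), > 0.
#' @return dimensionless BER = pod / cmax.
#' @export
compute_ber <- function(pod, cmax) {
  if (any(pod <= 0) || any(cmax <= 0)) {
    stop("pod and cmax must be positive", call. = FALSE)
  }
  pod / cmax
}

#' BER table over endpoints and exposure estimates
#'
#' Forms the Cartesian product of bioactivity endpoints and exposure
#' estimates, with per-route min/max BER summaries and the most sensitive
#' endpoint (smallest PoD, ties broken by label).
#'
#' @param pods data.frame with columns `label`, `pod` (uM) and optionally
#'   `source`.
#' @param exposures data.frame with columns `route`, `cmax` (uM) and
#'   optionally `subject`, `ga`.
#' @return a `ber_table` object: `records` (one row per endpoint x
#'   exposure with a `ber` column), `summary` (per-route min/max),
#'   `most_sensitive` endpoint label.
#' @export
ber_table <- function(pods, exposures) {
  stop_if_not(is.data.frame(pods) && nrow(pods) > 0, "pods must be non-empty")
  stop_if_not(is.data.frame(exposures) && nrow(exposures) > 0,
              "exposures must be non-empty")
  stop_if_not(all(c("label", "pod") %in% names(pods)),
              "pods needs columns label, pod")
  stop_if_not(all(c("route", "cmax") %in% names(exposures)),
              "exposures needs columns route, cmax")
  recs <- merge(pods, exposures, by = NULL)  # Cartesian product
  recs$ber <- compute_ber(recs$pod, recs$cmax)
  ord <- order(recs$label, recs$route, recs$cmax)
  recs <- recs[ord, , drop = FALSE]
  rownames(recs) <- NULL
  summ <- do.call(rbind, lapply(split(recs, recs$route), function(d) {
    data.frame(route = d$route[1], min_ber = min(d$ber), max_ber = max(d$ber))
  }))
  summ <- summ[order(summ$route), , drop = FALSE]
  rownames(summ) <- NULL
  ms <- pods$label[order(pods$pod, pods$label)][1]
  structure(list(records = recs, summary = summ, most_sensitive = ms),
            class = "ber_table")
}

#' @export
print.ber_table <- function(x, ...) {
  cat("BER table:", nrow(x$records), "endpoint x exposure combinations\n")
  print(x$summary, row.names = FALSE)
  cat("most sensitive endpoint:", x$most_sensitive, "\n")
  invisible(x)
}

#' Risk-assessment decision from a BER table
#'
#' If biological coverage is insufficient the verdict is
#' `insufficient-information` regardless of the ratios; otherwise the
#' verdict is `low-risk` when the minimum BER meets the threshold and
#' `potential-concern` (naming the driver endpoint) when it does not.
#'
#' @param table a [ber_table()].
#' @param threshold BER decision threshold (default 1; uncertainty factors
#'   must be supplied by the assessor as multipliers).
#' @param coverage_ok whether the NAM toolbox coverage of the relevant
#'   biology was judged sufficient.
#' @return a `ber_decision` with fields `verdict`, `driver`, `min_ber`,
#'   `rationale`.
#' @export
decide <- function(table, threshold = 1.0, coverage_ok = TRUE) {
  stop_if_not(inherits(table, "ber_table"), "table must be a ber_table")
  recs <- table$records
  min_i <- which.min(recs$ber)
  min_ber <- recs$ber[min_i]
  if (!isTRUE(coverage_ok)) {
    verdict <- "insufficient-information"
    rationale <- "biological coverage judged insufficient; generate data addressing the gaps"
    driver <- NA_character_
  } else if (min_ber >= threshold) {
    verdict <- "low-risk"
    driver <- recs$label[min_i]
    rationale <- sprintf(
      "minimum BER %.3g (endpoint '%s') meets the threshold %g: exposure below bioactive concentrations",
      min_ber, driver, threshold)
  } else {
    verdict <- "potential-concern"
    driver <- recs$label[min_i]
    rationale <- sprintf(
      "minimum BER %.3g < %g, driven by endpoint '%s': exposure may reach bioactive concentrations",
      min_ber, threshold, driver)
  }
  structure(list(verdict = verdict, driver = driver, min_ber = min_ber,
                 threshold = threshold, rationale = rationale),
            class = "ber_decision")
}

#' @export
print.ber_decision <- function(x, ...) {
  cat("Decision:", x$verdict, "\n  ", x$rationale, "\n", sep = "")
  invisible(x)
}
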