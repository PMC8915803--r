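`%||%` <- function(x, y) if (is.null(x)) y else x

#' Harmonize gene symbols
#'
#' Uppercases and strips surrounding whitespace so that symbol sets from
#' different platforms can be intersected. No fuzzy alias resolution is
#' performed; aliases must be resolved through a vocabulary synonym table.
#'
#' @param x character vector of gene symbols.
#' @return character vector of harmonized symbols.
#' @export
harmonize_symbols <- function(x) {
  toupper(trimws(as.character(x)))
}

stop_if_not <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

# deterministic RNG scope: evaluates expr under a seed, restoring state
with_seed <- function(seed, expr) {
  stop_if_not(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
              "seed must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# weighted quantiles of a discrete grid distribution by linear interpolation
# of the cumulative weights; used by the grid posterior summaries
grid_quantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  w <- w / sum(w)
  cw <- cumsum(w)
  vapply(probs, function(p) {
    i <- which(cw >= p)[1]
    if (is.na(i)) return(x[length(x)])
    if (i == 1) return(x[1])
    # interpolate between grid points straddling p
    x[i - 1] + (x[i] - x[i - 1]) * (p - cw[i - 1]) / (cw[i] - cw[i - 1])
  }, numeric(1))
}
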