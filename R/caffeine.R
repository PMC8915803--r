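# Caffeine case-study inputs and end-to-end demo.

#' Published caffeine Cmax predictions used by the worked example
#'
#' Steady-state maternal and foetal plasma Cmax predictions for the
#' caffeine case study (oral 200 mg/day; dermal 0.1% caffeine in a body
#' lotion applied daily) at gestational weeks 6, 20 and 30. No foetal
#' value exists at week 6, where the foetal circulation is only just
#' established. These values are consumed as exposure inputs by the BER
#' worked example; they were produced with a full proprietary pregnancy
#' physiology and are not reproduced by the reduced simulator shipped
#' here.
#'
#' @return data.frame with columns `route`, `week`, `subject`, `cmax`
#'   (uM).
#' @export
caffeine_cmax_table <- function() {
  data.frame(
    route = rep(c("oral", "dermal"), each = 6),
    week = rep(c(6, 20, 30), times = 4),
    subject = rep(rep(c("maternal", "foetal"), each = 3), times = 2),
    cmax = c(34.97, 38.51, 39.72, NA, 22.02, 25.27,
             0.42, 0.42, 0.46, NA, 0.27, 0.32),
    stringsAsFactors = FALSE
  )
}

#' Caffeine bioactivity points of departure used by the worked example
#'
#' The adenosine 2A receptor IC50 from in vitro pharmacological profiling
#' (the most sensitive endpoint), the gamma-H2AX cell-stress PoD, and the
#' low/high ends of the transcriptomic global PoD range across cell
#' models.
#'
#' @return data.frame with columns `label`, `pod` (uM), `source`.
#' @export
caffeine_pods <- function() {
  data.frame(
    label = c("adenosine 2A receptor", "gamma-H2AX", "HTTr (most sensitive model)",
              "HTTr (least sensitive model)"),
    pod = c(5.3, 304, 11, 96),
    source = c("IPP IC50", "CSP biomarker", "HTTr global PoD", "HTTr global PoD"),
    stringsAsFactors = FALSE
  )
}

#' End-to-end caffeine demonstration
#'
#' Wires exposure estimates and bioactivity PoDs through the BER decision
#' flow for both exposure scenarios: computes foetal/maternal Cmax ratios
#' from the shipped exposure table, builds the BER table over all
#' endpoints and exposure estimates, and renders a per-route decision.
#' Optionally also runs the reduced maternal-foetal PBK simulator for a
#' qualitative comparison.
#'
#' @param simulate if TRUE, additionally run [simulate_pbk()] at
#'   gestational week 20 for both routes (slower).
#' @return list with `fm_ratios` (per route/week), `ber` (a [ber_table()]),
#'   `decisions` (per route), and optionally `profiles`.
#' @export
run_caffeine_demo <- function(simulate = FALSE) {
  cm <- caffeine_cmax_table()
  wide <- merge(cm[cm$subject == "maternal", c("route", "week", "cmax")],
                cm[cm$subject == "foetal", c("route", "week", "cmax")],
                by = c("route", "week"), suffixes = c("_maternal", "_foetal"))
  wide <- wide[!is.na(wide$cmax_foetal), ]
  wide$fm_ratio <- fm_ratio(wide$cmax_foetal, wide$cmax_maternal)

  exposures <- cm[!is.na(cm$cmax), c("route", "week", "subject", "cmax")]
  bt <- ber_table(caffeine_pods(), exposures)
  decisions <- lapply(split(bt$records, bt$records$route), function(d) {
    sub <- bt
    sub$records <- d
    decide(sub, threshold = 1, coverage_ok = TRUE)
  })

  out <- list(fm_ratios = wide, ber = bt, decisions = decisions)
  if (simulate) {
    phys <- build_physiology(20)
    params <- pbk_params()
    out$profiles <- list(
      oral = simulate_pbk(params, phys, exposure_scenario("oral", dose_mg = 200)),
      dermal = simulate_pbk(params, phys,
                            exposure_scenario("dermal", product_pct = 0.1,
                                              product_g = 7.82))
    )
  }
  out
}
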