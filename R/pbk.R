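# Reduced maternal-foetal PBK model.
#
# Perfusion-limited, well-stirred tissues around a single maternal plasma
# pool; liver eliminates by Michaelis-Menten CYP1A2 metabolism on unbound
# liver concentration (scaled by a trimester activity multiplier), kidney
# by linear renal clearance on unbound plasma. The placenta is the one
# permeability-limited tissue: maternal-foetal transfer is passive
# diffusion through the permeability-surface-area product PStc = Pe * SA.
# Units: amounts umol, volumes L, flows L/h, time h, concentrations uM.

#' Default pregnancy physiology configuration
#'
#' Base (non-pregnant) tissue volumes and plasma flows for a ~60 kg woman
#' and gestational-age tables for the quantities that change in pregnancy
#' (plasma volume, uterus, placenta, amniotic fluid, foetal compartments,
#' placental exchange surface area). Values are plausible literature-scale
#' defaults assembled for demonstration and are not an authoritative
#' physiology; they are config inputs and can be replaced wholesale.
#'
#' Placental surface area grows from ~5e2 cm2 at week 6 to ~1.25e5 cm2 at
#' term and is interpolated linearly in gestational age.
#'
#' @return nested list with elements `volumes`, `flows`, `pregnancy`
#'   (gestational-age tables) and `cyp1a2_multipliers`.
#' @export
default_physiology_config <- function() {
  list(
    volumes = c(plasma = 2.4, gut = 1.1, liver = 1.4, kidney = 0.28,
                skin = 2.6, adipose = 17, rest = 28, uterus = 0.08),
    flows = c(gut = 43, liver_arterial = 19, kidney = 44, skin = 7,
              adipose = 9, rest = 55, uterus = 1.5),
    pregnancy = list(
      ga = c(6, 13, 20, 27, 30, 40),
      plasma_volume = c(2.5, 2.7, 3.0, 3.3, 3.4, 3.7),
      uterus_volume = c(0.15, 0.30, 0.55, 0.80, 0.90, 1.10),
      uterus_flow = c(2, 3.5, 6, 10, 12, 20),
      placenta_volume = c(0.02, 0.08, 0.25, 0.45, 0.50, 0.64),
      placenta_flow = c(1, 3, 8, 14, 16, 25),
      amniotic_volume = c(0.005, 0.05, 0.40, 0.80, 0.85, 0.80),
      fetal_plasma_volume = c(0.002, 0.010, 0.050, 0.120, 0.150, 0.300),
      fetal_tissue_volume = c(0.002, 0.040, 0.300, 0.900, 1.300, 3.200),
      fetal_tissue_flow = c(0.05, 0.3, 2, 6, 8, 15),
      surface_area = c(5e2, 4e3, 3.2e4, 6.0e4, 7.3e4, 1.25e5)
    ),
    cyp1a2_multipliers = c(nonpregnant = 1.0, T1 = 0.7, T2 = 0.5, T3 = 0.35)
  )
}

interp_ga <- function(ga, xs, ys, base) {
  if (ga <= xs[1]) {
    # linear ramp from the non-pregnant base to the first table entry
    base + (ys[1] - base) * ga / xs[1]
  } else {
    stats::approx(xs, ys, xout = min(ga, max(xs)), rule = 2)$y
  }
}

#' Build pregnancy physiology at a gestational age
#'
#' Gestational age 0 reproduces the non-pregnant base exactly. Before week
#' 6 only maternal quantities (plasma volume, uterus) are scaled and no
#' foetal compartments exist; from week 6 the placenta, amniotic fluid and
#' foetal circulation are instantiated, with the placental exchange surface
#' area interpolated from the config table. The CYP1A2 activity multiplier
#' is selected by trimester (T1 < 13, T2 13-27, T3 >= 28 weeks).
#'
#' @param ga gestational age in weeks (0 = non-pregnant); must be <= 42.
#' @param config physiology configuration, see
#'   [default_physiology_config()].
#' @return a `physiology` object with fields `ga`, `volumes`, `flows`,
#'   `surface_area`, `cyp1a2_multiplier`, `has_foetus`.
#' @export
build_physiology <- function(ga, config = default_physiology_config()) {
  stop_if_not(is.numeric(ga) && length(ga) == 1 && ga >= 0, "ga must be a single number >= 0")
  if (ga > 42) stop("gestational age above 42 weeks is not supported", call. = FALSE)
  vols <- config$volumes
  flows <- config$flows
  pg <- config$pregnancy
  has_foetus <- ga >= 6
  if (ga > 0) {
    vols["plasma"] <- interp_ga(ga, pg$ga, pg$plasma_volume, config$volumes[["plasma"]])
    vols["uterus"] <- interp_ga(ga, pg$ga, pg$uterus_volume, config$volumes[["uterus"]])
    flows["uterus"] <- interp_ga(ga, pg$ga, pg$uterus_flow, config$flows[["uterus"]])
  }
  sa <- 0
  if (has_foetus) {
    at <- function(y) stats::approx(pg$ga, y, xout = min(ga, max(pg$ga)), rule = 2)$y
    vols["placenta"] <- at(pg$placenta_volume)
    flows["placenta"] <- at(pg$placenta_flow)
    vols["amniotic"] <- at(pg$amniotic_volume)
    vols["fetal_plasma"] <- at(pg$fetal_plasma_volume)
    vols["fetal_tissue"] <- at(pg$fetal_tissue_volume)
    flows["fetal_tissue"] <- at(pg$fetal_tissue_flow)
    sa <- at(pg$surface_area)
  }
  mult <- if (ga == 0) config$cyp1a2_multipliers[["nonpregnant"]]
          else if (ga < 13) config$cyp1a2_multipliers[["T1"]]
          else if (ga < 28) config$cyp1a2_multipliers[["T2"]]
          else config$cyp1a2_multipliers[["T3"]]
  stop_if_not(all(vols > 0) && all(flows > 0), "volumes and flows must be positive")
  structure(list(ga = ga, volumes = vols, flows = flows, surface_area = sa,
                 cyp1a2_multiplier = mult, has_foetus = has_foetus),
            class = "physiology")
}

#' @export
print.physiology <- function(x, ...) {
  cat(sprintf("Physiology at GA %.0f wk: %s, CYP1A2 multiplier %.2f\n", x$ga,
              if (x$has_foetus) sprintf("foetal compartments present (SA %.3g cm2)", x$surface_area)
              else "no foetal compartments", x$cyp1a2_multiplier))
  invisible(x)
}

#' Chemical-specific PBK parameters
#'
#' Defaults are caffeine-like values assembled from literature-scale
#' estimates for demonstration; they are config inputs, not an
#' authoritative parameterization. Partition coefficients are taken as
#' inputs (no in-silico partitioning method is applied).
#'
#' @param mw molecular weight (g/mol).
#' @param fu,fu_f maternal and foetal fraction unbound in plasma.
#' @param kp named tissue:plasma partition coefficients (`gut`, `liver`,
#'   `kidney`, `skin`, `adipose`, `rest`, `uterus`, `placenta`,
#'   `fetal_tissue`).
#' @param ka oral absorption rate (1/h); `fabs_oral` fraction absorbed.
#' @param kderm dermal release rate from applied product (1/h);
#'   `fabs_dermal` absorbable fraction of the applied dose.
#' @param km,vmax CYP1A2 Michaelis constant (uM) and maximal rate (umol/h).
#' @param clr renal clearance (L/h), applied to unbound plasma.
#' @param pe apparent placental permeability (cm/h).
#' @param amniotic_exchange optional first-order foetal-amniotic exchange
#'   (L/h); defaults to 0 (inert amniotic volume).
#' @return a `pbk_params` object.
#' @export
pbk_params <- function(mw = 194.19, fu = 0.65, fu_f = 0.65,
                       kp = c(gut = 0.9, liver = 0.9, kidney = 0.9, skin = 0.8,
                              adipose = 0.3, rest = 0.8, uterus = 0.9,
                              placenta = 0.9, fetal_tissue = 0.9),
                       ka = 3, fabs_oral = 1,
                       kderm = 0.05, fabs_dermal = 0.5,
                       km = 250, vmax = 2300, clr = 0.12,
                       pe = 0.005, amniotic_exchange = 0) {
  stop_if_not(fu > 0 && fu <= 1 && fu_f > 0 && fu_f <= 1, "0 < fu <= 1 required")
  stop_if_not(km > 0, "Km must be positive")
  stop_if_not(all(c(ka, kderm, vmax, clr, pe, amniotic_exchange) >= 0),
              "rates and clearances must be non-negative")
  stop_if_not(all(kp > 0), "partition coefficients must be positive")
  structure(list(mw = mw, fu = fu, fu_f = fu_f, kp = kp, ka = ka,
                 fabs_oral = fabs_oral, kderm = kderm, fabs_dermal = fabs_dermal,
                 km = km, vmax = vmax, clr = clr, pe = pe,
                 amniotic_exchange = amniotic_exchange),
            class = "pbk_params")
}

#' Exposure scenario
#'
#' @param route `"oral"`, `"dermal"` or `"iv"`.
#' @param dose_mg dose in mg/day (oral, iv); for dermal, derived from
#'   `product_pct` and `product_g` when NULL.
#' @param product_pct dermal product strength (% w/w).
#' @param product_g dermal applied product mass (g/day).
#' @param dose_times hours within the day at which doses are given.
#' @param duration_days maximum number of simulated days.
#' @return an `exposure_scenario` object.
#' @export
exposure_scenario <- function(route = c("oral", "dermal", "iv"), dose_mg = NULL,
                              product_pct = NULL, product_g = NULL,
                              dose_times = 0, duration_days = 20) {
  route <- match.arg(route)
  if (route == "dermal" && is.null(dose_mg)) {
    stop_if_not(!is.null(product_pct) && !is.null(product_g),
                "dermal scenario needs product_pct and product_g (or dose_mg)")
    dose_mg <- product_pct / 100 * product_g * 1000
  }
  stop_if_not(is.numeric(dose_mg) && dose_mg >= 0, "dose must be non-negative")
  stop_if_not(all(dose_times >= 0 & dose_times < 24), "dose_times must lie in [0, 24)")
  structure(list(route = route, dose_mg = dose_mg, dose_times = sort(dose_times),
                 duration_days = duration_days),
            class = "exposure_scenario")
}

#' Placental transfer flux by passive diffusion
#'
#' Flux (umol/h) across the placenta for an unbound concentration gradient,
#' `PStc * (Cm_unbound - Cf_unbound)` with the permeability-surface-area
#' product `PStc = Pe * SA` converted from cm3/h to L/h. Positive flux is
#' maternal-to-foetal.
#'
#' @param cm_unbound,cf_unbound maternal and foetal unbound concentrations
#'   (uM).
#' @param pe apparent permeability (cm/h).
#' @param sa exchange surface area (cm2).
#' @return flux in umol/h.
#' @export
placental_transfer_rate <- function(cm_unbound, cf_unbound, pe, sa) {
  if (any(cm_unbound < 0) || any(cf_unbound < 0)) {
    stop("negative concentrations are not allowed", call. = FALSE)
  }
  stop_if_not(pe >= 0 && sa >= 0, "Pe and SA must be non-negative")
  pstc <- pe * sa / 1000  # cm3/h -> L/h
  pstc * (cm_unbound - cf_unbound)
}

#' Solver and steady-state control settings
#' @param atol,rtol absolute (uM) and relative integration tolerances.
#' @param dt_out output grid step (h).
#' @param ss_tol relative change in successive-day maternal Cmax below
#'   which the simulation is declared at steady state.
#' @return list of control settings.
#' @export
pbk_control <- function(atol = 1e-9, rtol = 1e-6, dt_out = 0.05, ss_tol = 0.01) {
  list(atol = atol, rtol = rtol, dt_out = dt_out, ss_tol = ss_tol)
}

pbk_deriv <- function(t, y, p) {
  with(p, {
    Cp <- y[["plasma"]] / Vp
    Cv <- function(nm) y[[nm]] / V[[nm]] / Kp[[nm]]
    vmet_u <- fu * Cv("liver")
    vmet <- mult * vmax * vmet_u / (km + vmet_u)
    ren <- clr * fu * Cp
    dy <- stats::setNames(numeric(length(y)), names(y))
    dy["depot"] <- -k_abs * y[["depot"]]
    # absorption target depends on route
    dy[abs_target] <- dy[abs_target] + k_abs * y[["depot"]]
    dy["gut"] <- dy["gut"] + Q[["gut"]] * (Cp - Cv("gut"))
    dy["liver"] <- Q[["liver_arterial"]] * Cp + Q[["gut"]] * Cv("gut") -
      (Q[["liver_arterial"]] + Q[["gut"]]) * Cv("liver") - vmet
    for (nm in c("kidney", "skin", "adipose", "rest", "uterus")) {
      dy[nm] <- dy[nm] + Q[[nm]] * (Cp - Cv(nm))
    }
    venous_return <- (Q[["liver_arterial"]] + Q[["gut"]]) * Cv("liver") +
      sum(vapply(c("kidney", "skin", "adipose", "rest", "uterus"),
                 function(nm) Q[[nm]] * Cv(nm), numeric(1)))
    Qtot <- Q[["liver_arterial"]] + Q[["gut"]] + Q[["kidney"]] + Q[["skin"]] +
      Q[["adipose"]] + Q[["rest"]] + Q[["uterus"]]
    if (has_foetus) {
      Cfpl <- y[["fetal_plasma"]] / V[["fetal_plasma"]]
      J <- pstc * (fu * Cv("placenta") - fu_f * Cfpl)
      dy["placenta"] <- Q[["placenta"]] * (Cp - Cv("placenta")) - J
      Camn <- y[["amniotic"]] / V[["amniotic"]]
      amn <- k_amn * (fu_f * Cfpl - Camn)
      dy["fetal_plasma"] <- J +
        Q[["fetal_tissue"]] * (Cv("fetal_tissue") - Cfpl) - amn
      dy["fetal_tissue"] <- Q[["fetal_tissue"]] * (Cfpl - Cv("fetal_tissue"))
      dy["amniotic"] <- amn
      venous_return <- venous_return + Q[["placenta"]] * Cv("placenta")
      Qtot <- Qtot + Q[["placenta"]]
    }
    dy["plasma"] <- venous_return - Qtot * Cp - ren
    dy["met"] <- vmet
    dy["ren"] <- ren
    list(dy)
  })
}

#' Simulate the maternal-foetal PBK model
#'
#' Integrates the compartmental system under repeated daily dosing until
#' either the successive-day maternal plasma Cmax changes by less than the
#' steady-state tolerance or the scenario duration is reached. Oral dosing
#' enters a first-order depot emptying into the gut (hepatic first pass via
#' the portal inflow); dermal dosing enters an applied-product depot
#' releasing into skin; iv dosing is a bolus into plasma. The foetus has no
#' elimination.
#'
#' @param params [pbk_params()].
#' @param phys [build_physiology()] result.
#' @param scen [exposure_scenario()].
#' @param control [pbk_control()].
#' @return a `pk_profile` object: `time` (h), `conc` (matrix, uM per
#'   compartment), `cmax_maternal`, `cmax_foetal` (NA without foetal
#'   compartments), `steady_state`, `dosed_umol`, `balance_error` (maximum
#'   relative mass-balance error over the output grid).
#' @export
simulate_pbk <- function(params, phys, scen, control = pbk_control()) {
  stop_if_not(inherits(params, "pbk_params"), "params must be pbk_params")
  stop_if_not(inherits(phys, "physiology"), "phys must be a physiology")
  stop_if_not(inherits(scen, "exposure_scenario"), "scen must be an exposure_scenario")
  V <- as.list(phys$volumes); Q <- as.list(phys$flows)
  has_foetus <- phys$has_foetus
  state_names <- c("depot", "unabs", "gut", "liver", "kidney", "skin",
                   "adipose", "rest", "uterus", "plasma",
                   if (has_foetus) c("placenta", "amniotic", "fetal_plasma", "fetal_tissue"),
                   "met", "ren")
  y <- stats::setNames(numeric(length(state_names)), state_names)
  abs_target <- switch(scen$route, oral = "gut", dermal = "skin", iv = "plasma")
  k_abs <- switch(scen$route, oral = params$ka, dermal = params$kderm, iv = 0)
  fabs <- switch(scen$route, oral = params$fabs_oral, dermal = params$fabs_dermal, iv = 1)
  dose_umol <- scen$dose_mg * 1000 / params$mw
  pars <- list(Vp = V$plasma, V = V, Q = Q, Kp = as.list(params$kp),
               fu = params$fu, fu_f = params$fu_f, mult = phys$cyp1a2_multiplier,
               vmax = params$vmax, km = params$km, clr = params$clr,
               k_abs = k_abs, abs_target = abs_target, has_foetus = has_foetus,
               pstc = params$pe * phys$surface_area / 1000,
               k_amn = params$amniotic_exchange)

  day_grid <- seq(0, 24, by = control$dt_out)
  traj <- list(); dosed_rows <- list(); dosed <- 0
  prev_cmax <- NA_real_; steady <- FALSE
  day <- 0
  while (day < scen$duration_days) {
    day <- day + 1
    bounds <- sort(unique(c(0, scen$dose_times, 24)))
    day_out <- NULL; day_dosed <- NULL
    for (k in seq_len(length(bounds) - 1)) {
      t0 <- bounds[k]; t1 <- bounds[k + 1]
      if (t0 %in% scen$dose_times && dose_umol > 0) {
        if (scen$route == "iv") {
          y["plasma"] <- y["plasma"] + dose_umol
        } else {
          y["depot"] <- y["depot"] + dose_umol * fabs
          y["unabs"] <- y["unabs"] + dose_umol * (1 - fabs)
        }
        dosed <- dosed + dose_umol
      }
      tt <- unique(sort(c(t0, day_grid[day_grid >= t0 & day_grid <= t1], t1)))
      sol <- deSolve::lsoda(y, tt, pbk_deriv, pars,
                            atol = control$atol, rtol = control$rtol)
      if (attr(sol, "istate")[1] < 0) {
        stop("ODE solver failed to converge (istate ",
             attr(sol, "istate")[1], ")", call. = FALSE)
      }
      y <- sol[nrow(sol), -1]
      day_out <- rbind(day_out, sol)
      day_dosed <- c(day_dosed, rep(dosed, nrow(sol)))
    }
    if (min(day_out[, -1]) < -1e-6 * max(abs(day_out[, -1]), 1e-12)) {
      stop("negative state encountered during integration", call. = FALSE)
    }
    day_out[, "time"] <- day_out[, "time"] + (day - 1) * 24
    traj[[day]] <- day_out
    dosed_rows[[day]] <- day_dosed
    cmax_day <- max(day_out[, "plasma"]) / V$plasma
    if (!is.na(prev_cmax) &&
        abs(cmax_day - prev_cmax) / max(prev_cmax, 1e-300) < control$ss_tol) {
      steady <- TRUE
      break
    }
    prev_cmax <- cmax_day
  }
  sol <- do.call(rbind, traj)
  time <- sol[, "time"]
  amounts <- sol[, state_names, drop = FALSE]
  # concentrations per compartment
  conc_names <- setdiff(state_names, c("depot", "unabs", "met", "ren"))
  conc <- sapply(conc_names, function(nm) amounts[, nm] / V[[nm]])
  # mass balance: everything in the system plus eliminated vs dosed so far
  dosed_cum <- unlist(dosed_rows)
  total <- rowSums(amounts)
  balance <- if (dosed > 0) {
    max(abs(total - dosed_cum) / pmax(dosed_cum, dose_umol))
  } else max(abs(total))
  final_day <- time >= max(time) - 24
  cmax_m <- max(conc[final_day, "plasma"])
  cmax_f <- if (has_foetus) max(conc[final_day, "fetal_plasma"]) else NA_real_
  structure(list(time = time, conc = conc, amounts = amounts,
                 volumes = phys$volumes, ga = phys$ga,
                 cmax_maternal = cmax_m, cmax_foetal = cmax_f,
                 steady_state = steady, dosed_umol = dosed,
                 dosed_cum = dosed_cum,
                 balance_error = balance, route = scen$route),
            class = "pk_profile")
}

#' @export
print.pk_profile <- function(x, ...) {
  cat(sprintf("PK profile (%s, GA %.0f wk, %.1f days simulated%s)\n", x$route, x$ga,
              max(x$time) / 24, if (x$steady_state) ", steady state" else ""))
  cat(sprintf("  maternal plasma Cmax: %.4g uM\n", x$cmax_maternal))
  if (!is.na(x$cmax_foetal)) {
    cat(sprintf("  foetal plasma Cmax:   %.4g uM (F/M %.2f)\n", x$cmax_foetal,
                x$cmax_foetal / x$cmax_maternal))
  }
  invisible(x)
}

#' @export
summary.pk_profile <- function(object, ...) {
  final_day <- object$time >= max(object$time) - 24
  data.frame(compartment = colnames(object$conc),
             cmax = apply(object$conc[final_day, , drop = FALSE], 2, max),
             row.names = NULL)
}

#' @export
plot.pk_profile <- function(x, compartments = c("plasma", "fetal_plasma"), ...) {
  compartments <- intersect(compartments, colnames(x$conc))
  graphics::matplot(x$time, x$conc[, compartments, drop = FALSE], type = "l",
                    lty = 1, xlab = "time (h)", ylab = "concentration (uM)", ...)
  graphics::legend("topright", legend = compartments, lty = 1,
                   col = seq_along(compartments), bty = "n")
  invisible(x)
}

#' Foetal-to-maternal Cmax ratio
#'
#' @param x a `pk_profile` with foetal compartments, or a numeric foetal
#'   Cmax.
#' @param maternal maternal Cmax when `x` is numeric.
#' @return dimensionless F/M ratio.
#' @export
fm_ratio <- function(x, maternal = NULL) {
  if (inherits(x, "pk_profile")) {
    if (is.na(x$cmax_foetal)) {
      stop("profile has no foetal compartment (GA < 6 weeks)", call. = FALSE)
    }
    return(x$cmax_foetal / x$cmax_maternal)
  }
  stop_if_not(is.numeric(x) && is.numeric(maternal), "need foetal and maternal Cmax")
  x / maternal
}

#' Compare predicted and observed concentrations
#'
#' Computes the observed/simulated Cmax ratio for maternal plasma and flags
#' whether it lies within the conventional 2-fold acceptance band
#' (|log2 ratio| <= 1).
#'
#' @param profile a `pk_profile`.
#' @param observed data.frame with columns `time` (h), `conc` (uM).
#' @return list with `ratio`, `within_twofold`, `obs_cmax`, `sim_cmax`.
#' @export
validate_predictions <- function(profile, observed) {
  stop_if_not(is.data.frame(observed) && nrow(observed) > 0,
              "observations must be a non-empty data.frame")
  if (max(observed$time) > max(profile$time) || min(observed$time) < min(profile$time)) {
    stop("observation times outside the simulated horizon", call. = FALSE)
  }
  sim_window <- profile$time >= min(observed$time) & profile$time <= max(observed$time)
  sim_cmax <- max(profile$conc[sim_window, "plasma"])
  obs_cmax <- max(observed$conc)
  ratio <- obs_cmax / sim_cmax
  list(ratio = ratio, within_twofold = abs(log2(ratio)) <= 1,
       obs_cmax = obs_cmax, sim_cmax = sim_cmax)
}
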