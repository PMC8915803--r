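# helper: config collapsing the system to (almost) one well-mixed compartment
one_compartment_config <- function(V = 30) {
  cfg <- default_physiology_config()
  cfg$volumes <- c(plasma = V, gut = 1e-3, liver = 1e-3, kidney = 1e-3,
                   skin = 1e-3, adipose = 1e-3, rest = 1e-3, uterus = 1e-3)
  cfg$flows <- c(gut = 500, liver_arterial = 500, kidney = 500, skin = 500,
                 adipose = 500, rest = 500, uterus = 500)
  cfg
}

unit_kp <- function() {
  c(gut = 1, liver = 1, kidney = 1, skin = 1, adipose = 1, rest = 1,
    uterus = 1, placenta = 1, fetal_tissue = 1)
}

test_that("physiology construction honours the gestational stages", {
  base <- build_physiology(0)
  cfg <- default_physiology_config()
  expect_equal(base$volumes[names(cfg$volumes)], cfg$volumes)
  expect_equal(base$flows[names(cfg$flows)], cfg$flows)
  expect_false(base$has_foetus)
  expect_equal(base$cyp1a2_multiplier, 1.0)

  early <- build_physiology(5)
  expect_false(early$has_foetus)
  expect_false("fetal_plasma" %in% names(early$volumes))
  expect_gt(early$volumes[["uterus"]], base$volumes[["uterus"]])

  mid <- build_physiology(20); late <- build_physiology(30)
  expect_true(mid$has_foetus)
  expect_lte(mid$surface_area, late$surface_area)
  expect_equal(mid$cyp1a2_multiplier, cfg$cyp1a2_multipliers[["T2"]])
  expect_equal(late$cyp1a2_multiplier, cfg$cyp1a2_multipliers[["T3"]])
  expect_error(build_physiology(43), "42")
})

test_that("placental transfer follows PStc times the unbound gradient", {
  expect_equal(placental_transfer_rate(2, 2, 0.01, 1e4), 0)
  expect_equal(placental_transfer_rate(5, 1, 0, 1e4), 0)
  # Pe 1e-3 cm/h x SA 1e4 cm2 = 10 cm3/h = 0.01 L/h; gradient 1 uM -> 0.01 umol/h
  expect_equal(placental_transfer_rate(1, 0, 1e-3, 1e4), 0.01)
  expect_lt(placental_transfer_rate(0, 1, 1e-3, 1e4), 0)  # sign = direction
  expect_error(placental_transfer_rate(-1, 0, 1e-3, 1e4), "negative")
})

test_that("zero dose gives identically zero concentrations", {
  prof <- simulate_pbk(pbk_params(), build_physiology(0),
                       exposure_scenario("oral", dose_mg = 0, duration_days = 2))
  expect_true(all(prof$conc == 0))
})

test_that("mass is conserved without elimination and balanced with it", {
  # single iv bolus, no elimination: total amount constant to 1e-6 relative
  p <- pbk_params(vmax = 0, clr = 0)
  prof <- simulate_pbk(p, build_physiology(20),
                       exposure_scenario("iv", dose_mg = 100, duration_days = 1),
                       control = pbk_control(ss_tol = 0))
  total <- rowSums(prof$amounts)
  expect_lt(max(abs(total - prof$dosed_umol)) / prof$dosed_umol, 1e-6)

  # full scenarios: balance closes to 1e-6 relative at every output time
  for (scen in list(exposure_scenario("oral", dose_mg = 200, duration_days = 3),
                    exposure_scenario("dermal", product_pct = 0.1,
                                      product_g = 7.82, duration_days = 3),
                    exposure_scenario("iv", dose_mg = 50, duration_days = 3))) {
    for (ga in c(0, 20)) {
      prof <- simulate_pbk(pbk_params(), build_physiology(ga), scen)
      expect_lt(prof$balance_error, 1e-6)
    }
  }
})

test_that("the one-compartment limit matches closed-form Cmax and half-life", {
  V <- 30; CL <- 3
  p <- pbk_params(fu = 1, kp = unit_kp(), vmax = 0, clr = CL)
  phys <- build_physiology(0, one_compartment_config(V))
  dose_mg <- 100
  prof <- simulate_pbk(p, phys, exposure_scenario("iv", dose_mg = dose_mg,
                                                  duration_days = 1),
                       control = pbk_control(ss_tol = 0))
  dose_umol <- dose_mg * 1000 / p$mw
  v_tot <- sum(phys$volumes)
  c0 <- dose_umol / v_tot
  expect_lt(abs(prof$cmax_maternal - c0) / c0, 0.01)
  # terminal half-life from log-linear regression over the elimination phase
  sel <- prof$time > 4 & prof$time < 20
  k <- -coef(lm(log(prof$conc[sel, "plasma"]) ~ prof$time[sel]))[[2]]
  t_half <- log(2) / k
  expect_lt(abs(t_half - log(2) * v_tot / CL) / (log(2) * v_tot / CL), 0.01)
})

test_that("kinetics are linear in dose when metabolism is far from saturation", {
  p <- pbk_params(km = 1e7, vmax = 1e7 * 0.03)  # effectively linear CLint
  phys <- build_physiology(20)
  p1 <- simulate_pbk(p, phys, exposure_scenario("oral", dose_mg = 100, duration_days = 3),
                     control = pbk_control(ss_tol = 0))
  p2 <- simulate_pbk(p, phys, exposure_scenario("oral", dose_mg = 200, duration_days = 3),
                     control = pbk_control(ss_tol = 0))
  expect_lt(max(abs(p2$conc - 2 * p1$conc)) / max(p2$conc), 1e-3)
})

test_that("F/M ratio is at most one and monotone in placental permeability", {
  phys <- build_physiology(20)
  scen <- exposure_scenario("oral", dose_mg = 200, duration_days = 6)
  ratios <- vapply(c(0.001, 0.005, 0.02), function(pe) {
    fm_ratio(simulate_pbk(pbk_params(pe = pe), phys, scen))
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
  expect_true(all(ratios <= 1))
  # no placental transfer -> no foetal exposure
  expect_equal(fm_ratio(simulate_pbk(pbk_params(pe = 0), phys, scen)), 0)
  expect_error(fm_ratio(simulate_pbk(pbk_params(), build_physiology(0), scen)),
               "foetal")
  expect_equal(fm_ratio(22.02, 38.51), 22.02 / 38.51)
})

test_that("maternal steady-state Cmax rises as CYP1A2 activity falls", {
  scen <- exposure_scenario("oral", dose_mg = 200, duration_days = 8)
  cmax <- vapply(c(1.0, 0.5, 0.35), function(m) {
    cfg <- default_physiology_config()
    cfg$cyp1a2_multipliers[] <- m
    simulate_pbk(pbk_params(), build_physiology(20, cfg), scen)$cmax_maternal
  }, numeric(1))
  expect_true(all(diff(cmax) > 0))
})

test_that("prediction validation flags the two-fold band correctly", {
  prof <- simulate_pbk(pbk_params(), build_physiology(0),
                       exposure_scenario("oral", dose_mg = 200, duration_days = 2))
  exact <- data.frame(time = c(2, 6, 12), conc = NA)
  exact$conc <- approx(prof$time, prof$conc[, "plasma"], xout = exact$time,
                       ties = "ordered")$y
  exact$conc[which.max(exact$conc)] <- prof$cmax_maternal
  v <- validate_predictions(prof, exact)
  expect_true(v$within_twofold)
  inflated <- transform(exact, conc = conc * 2.5)
  expect_false(validate_predictions(prof, inflated)$within_twofold)
  expect_error(validate_predictions(prof, data.frame(time = 1e5, conc = 1)),
               "horizon")

  # noisy observations from the generator stay within two-fold
  for (s in 1:3) {
    obs <- gen_pk_observations(prof, times = seq(1, 40, by = 4), cv = 0.1, seed = s)
    expect_true(validate_predictions(prof, obs)$within_twofold)
  }
})

test_that("PK observation noise realizes the requested coefficient of variation", {
  prof <- simulate_pbk(pbk_params(), build_physiology(0),
                       exposure_scenario("oral", dose_mg = 200, duration_days = 1))
  exact <- gen_pk_observations(prof, times = c(2, 5), cv = 0, seed = 1)
  expect_equal(exact$conc,
               approx(prof$time, prof$conc[, "plasma"], xout = c(2, 5),
                      ties = "ordered")$y)
  obs <- gen_pk_observations(prof, times = rep(6, 200), cv = 0.2, seed = 2)
  cv_hat <- sd(obs$conc) / mean(obs$conc)
  expect_lt(abs(cv_hat - 0.2), 0.05)
  expect_identical(gen_pk_observations(prof, times = rep(6, 5), cv = 0.2, seed = 3),
                   gen_pk_observations(prof, times = rep(6, 5), cv = 0.2, seed = 3))
})
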