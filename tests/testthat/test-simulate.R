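test_that("mass balance holds for arbitrary mixed regimens", {
  regimen <- rbind(single_dose_regimen(1, 30, "oral", 0),
                   dose_event(7.3, "iv", 12000),
                   dose_event(25, "oral", 18000),
                   dose_event(49.6, "oral", 9000))
  tc <- simulate_pbpk(default_phys, default_drug, regimen, 120,
                      output_grid = seq(0, 120, by = 0.5))
  expect_lt(tc$mass_balance_error, 1e-6)
  expect_true(all(tc$amounts >= -1e-9))
  expect_true(all(diff(tc$cumulative$urine) >= -1e-9))
  expect_true(all(diff(tc$cumulative$feces) >= -1e-9))
})

test_that("an IV dose is fully accounted for by the elimination sinks", {
  tc <- simulate_pbpk(default_phys, default_drug,
                      single_dose_regimen(1, 30, "iv"), 30000,
                      output_grid = c(seq(0, 96, 1), seq(100, 30000, 100)))
  n <- length(tc$times)
  sinks <- tc$cumulative$urine[n] + tc$cumulative$feces[n] +
    tc$cumulative$hepatic[n]
  expect_equal(sinks / 30000, 1, tolerance = 1e-3)
})

test_that("oral absorption delays the plasma peak into the hours range", {
  tco <- simulate_pbpk(default_phys, default_drug,
                       single_dose_regimen(1, 30, "oral"), 96)
  tmax_oral <- tco$times[which.max(tco$conc[, "plasma"])]
  expect_gt(tmax_oral, 1)
  tci <- simulate_pbpk(default_phys, default_drug,
                       single_dose_regimen(1, 30, "iv"), 96)
  tmax_iv <- tci$times[which.max(tci$conc[, "plasma"])]
  expect_lt(tmax_iv, 0.2)
  expect_gt(max(tci$conc[, "plasma"]), max(tco$conc[, "plasma"]))
})

test_that("the system is linear: doubled doses double every concentration", {
  reg1 <- daily_oral_regimen(3, 1, 30)
  reg2 <- daily_oral_regimen(3, 2, 30)
  grid <- seq(0, 120, by = 1)
  tc1 <- simulate_pbpk(default_phys, default_drug, reg1, 120, grid)
  tc2 <- simulate_pbpk(default_phys, default_drug, reg2, 120, grid)
  expect_equal(tc2$conc, 2 * tc1$conc, tolerance = 1e-6)
})

test_that("repeated dosing equals superposition of shifted single doses", {
  grid <- seq(0, 240, by = 1)
  tc1 <- simulate_pbpk(default_phys, default_drug,
                       single_dose_regimen(1, 30, "oral"), 240, grid)
  tcn <- simulate_pbpk(default_phys, default_drug,
                       daily_oral_regimen(5, 1, 30), 240, grid)
  single <- tc1$conc[, "plasma"]
  super <- numeric(length(grid))
  for (k in 0:4) {
    shift <- k * 24
    idx <- grid >= shift
    super[idx] <- super[idx] + single[seq_len(sum(idx))]
  }
  expect_equal(tcn$conc[, "plasma"], super,
               tolerance = 1e-5)
})

test_that("membrane-limited tissues approach flow-limited behavior as Pa grows", {
  # With a large permeability the vascular and cellular sub-compartments
  # equilibrate: C_blood ~= C_tissue/P, i.e. venous outflow leaves at
  # C_tissue/P exactly as in a flow-limited organ.
  drug_hi <- default_drug
  drug_hi$permeability_fraction[] <- 1e4
  tc <- simulate_pbpk(default_phys, drug_hi,
                      single_dose_regimen(1, 30, "oral"), 48,
                      output_grid = seq(1, 48, 1))
  V <- default_resolved$volumes
  cb <- tc$amounts[, "muscle_blood"] / V[["muscle_blood"]]
  ct <- tc$amounts[, "muscle_tissue"] / V[["muscle_tissue"]]
  expect_equal(cb, ct / default_drug$partition[["muscle"]],
               tolerance = 1e-3)

  # Convergence is monotone in Pa: successive decades move the muscle
  # curve toward the high-Pa limit.
  curve_for <- function(pp) {
    d <- default_drug
    d$permeability_fraction[["muscle"]] <- pp
    simulate_pbpk(default_phys, d, single_dose_regimen(1, 30, "oral"),
                  48, output_grid = seq(1, 48, 1))$conc[, "muscle"]
  }
  lim <- curve_for(1e5)
  dev <- vapply(c(1, 10, 100, 1000), function(pp)
    max(abs(curve_for(pp) - lim)), numeric(1))
  expect_true(all(diff(dev) < 0))
  expect_lt(dev[4] / max(lim), 0.01)
})

test_that("fraction absorbed after a single oral dose equals Ka/(Ka+Kgut)", {
  tc <- simulate_pbpk(default_phys, default_drug,
                      single_dose_regimen(1, 30, "oral"), 400,
                      output_grid = seq(0, 400, 5))
  n <- length(tc$times)
  f_feces <- tc$cumulative$feces[n] / 30000
  f_expected <- default_drug$k_gut /
    (default_drug$k_absorption + default_drug$k_gut)
  expect_equal(f_feces, f_expected, tolerance = 1e-4)
})

test_that("solutions are converged with respect to solver tolerances", {
  reg <- single_dose_regimen(1, 30, "oral")
  grid <- seq(0, 96, 1)
  tc1 <- simulate_pbpk(default_phys, default_drug, reg, 96, grid,
                       options = pbpk_options(rtol = 1e-8, atol = 1e-10))
  tc2 <- simulate_pbpk(default_phys, default_drug, reg, 96, grid,
                       options = pbpk_options(rtol = 5e-9, atol = 5e-11))
  rel <- abs(tc1$conc[-1, ] - tc2$conc[-1, ]) / pmax(tc2$conc[-1, ], 1e-6)
  expect_lt(max(rel), 1e-4)
})

test_that("washout ends in log-linear terminal decay in every tissue", {
  reg <- daily_oral_regimen(3, 1, 30)
  t_end <- 1400
  tc <- simulate_pbpk(default_phys, default_drug, reg, t_end,
                      output_grid = seq(0, t_end, 4))
  window <- tc$times >= t_end - 168
  for (m in c("plasma", "muscle", "liver", "kidney", "fat")) {
    y <- log(tc$conc[window, m])
    fit <- stats::lm(y ~ tc$times[window])
    expect_gt(summary(fit)$r.squared, 0.999)
    expect_lt(stats::coef(fit)[2], 0)
  }
})

test_that("predicted_at interpolates and refuses extrapolation", {
  grid <- seq(0, 96, 1)
  tc <- simulate_pbpk(default_phys, default_drug,
                      single_dose_regimen(1, 30, "oral"), 96, grid)
  # Identity at grid points.
  expect_equal(predicted_at(tc, "plasma", c(4, 24)),
               tc$conc[match(c(4, 24), tc$times), "plasma"])
  # Arithmetic mean between neighbors under linear interpolation.
  expect_equal(predicted_at(tc, "plasma", 10.5, interp = "linear"),
               mean(tc$conc[match(c(10, 11), tc$times), "plasma"]))
  # Dense and coarse grids agree at off-grid query points.
  tc_fine <- simulate_pbpk(default_phys, default_drug,
                           single_dose_regimen(1, 30, "oral"), 96,
                           seq(0, 96, 0.1))
  q <- c(6.55, 17.23, 48.91)
  expect_equal(predicted_at(tc, "plasma", q),
               predicted_at(tc_fine, "plasma", q), tolerance = 5e-3)
  expect_error(predicted_at(tc, "plasma", 200), "outside")
  expect_error(predicted_at(tc, "bone", 10), "unknown matrix")
})
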