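test_that("tolerance order-statistic index matches a brute-force scan", {
  brute <- function(n, p, conf) {
    for (k in 1:n) if (stats::pbinom(k - 1, n, p) >= conf) return(k)
    NA_integer_
  }
  expect_identical(tolerance_index(500, 0.95, 0.95), brute(500, 0.95, 0.95))
  expect_identical(tolerance_index(500, 0.95, 0.95), 484L)
  for (n in c(59, 100, 250, 1000))
    expect_identical(tolerance_index(n, 0.95, 0.95), brute(n, 0.95, 0.95))
  expect_error(tolerance_index(58, 0.95, 0.95), "n >= 59")
})

test_that("the 95/95 bound behaves like an upper tolerance limit", {
  expect_equal(wt_95_95(rep(72, 100)), 72)  # degenerate distribution
  expect_error(wt_95_95(1:20), "at least 59")
  set.seed(11)
  x <- stats::runif(500)
  b <- wt_95_95(x)
  expect_gte(b, stats::quantile(x, 0.95, type = 1))
  expect_gte(wt_95_95(x), stats::median(x))
  # Bound approaches the true 95th percentile from above as n grows.
  set.seed(12)
  big <- wt_95_95(stats::runif(20000))
  expect_lt(abs(big - 0.95), 0.01)
})

test_that("withdrawal time is read off a depletion curve by final crossing", {
  times <- seq(0, 600, by = 1)
  reg <- dose_event(0, "oral", 1)
  # Exponential closed form: 900 exp(-0.01 t) crosses 90 at ln(10)/0.01.
  tc <- synthetic_timecourse(times, list(kidney = 900 * exp(-0.01 * times)),
                             reg)
  expect_equal(withdrawal_time_curve(tc, "kidney", 90, t_last_dose = 0),
               log(10) / 0.01, tolerance = 1e-4)
  # Already below the limit: zero withdrawal time.
  tc0 <- synthetic_timecourse(times, list(kidney = 50 * exp(-0.01 * times)),
                              reg)
  expect_equal(withdrawal_time_curve(tc0, "kidney", 90, 0), 0)
  # Non-monotone curve: take the final down-crossing (brute-force scan
  # oracle over the grid).
  bump <- 120 * exp(-0.02 * times) + 80 * exp(-((times - 250) / 40)^2)
  tcb <- synthetic_timecourse(times, list(kidney = bump), reg)
  wt <- withdrawal_time_curve(tcb, "kidney", 90, 0)
  above <- which(bump >= 90)
  expect_gt(wt, times[max(above)] - 1)
  expect_lt(wt, times[max(above) + 1] + 1)
  expect_true(all(bump[times > wt + 1] < 90))
  # Still above at the end of the horizon: explicit error.
  tch <- synthetic_timecourse(times, list(kidney = rep(100, length(times))),
                              reg)
  expect_error(withdrawal_time_curve(tch, "kidney", 90, 0), "extend t_end")
})

test_that("population sampling is reproducible, centered and truncated", {
  spec <- population_spec(n_individuals = 500, cv = 0.2, seed = 99)
  pop1 <- sample_population(default_drug, spec)
  pop2 <- sample_population(default_drug, spec)
  expect_identical(pop1, pop2)
  expect_length(pop1, 500)

  # cv -> 0 degenerates to the base parameter set.
  pop0 <- sample_population(default_drug,
                            population_spec(n_individuals = 5, cv = 0,
                                            seed = 1))
  expect_identical(pop0[[3]], default_drug)

  # Mean-preserving lognormal: sample mean within 3 SE of the base.
  for (path in c("cl_hepatic", "partition.muscle")) {
    vals <- vapply(pop1, get_drug_param, numeric(1), path = path)
    base <- get_drug_param(default_drug, path)
    se <- stats::sd(vals) / sqrt(length(vals))
    expect_lt(abs(mean(vals) - base), 3 * se)
    # log-scale truncation at 3 SD
    sdlog <- sqrt(log(1 + 0.2^2))
    expect_true(all(abs(log(vals) - (log(base) - sdlog^2 / 2)) <=
                      3 * sdlog + 1e-12))
  }
  # Unlisted parameters stay at base values.
  expect_equal(pop1[[7]]$partition[["brain"]],
               default_drug$partition[["brain"]])
})

test_that("withdrawal report matches the deterministic run at zero variability", {
  pop0 <- population_spec(n_individuals = 60, cv = 0, seed = 5)
  rep0 <- withdrawal_report(default_phys, default_drug,
                            regimen = daily_oral_regimen(3, 1, 30),
                            population = pop0, washout = 30 * 24,
                            options = fast_opts)
  # Deterministic single simulation with the same grid.
  reg <- daily_oral_regimen(3, 1, 30)
  t_last <- 48; t_end <- t_last + 30 * 24
  grid <- sort(unique(c(seq(0, t_last, 2), seq(t_last, t_end, 1))))
  tc <- simulate_pbpk(default_phys, default_drug, reg, t_end, grid,
                      options = fast_opts)
  for (tis in c("muscle", "liver", "kidney", "fat")) {
    wt_det <- withdrawal_time_curve(tc, tis, mrl_set()[[tis]], t_last)
    row <- rep0[rep0$tissue == tis, ]
    expect_equal(row$wt_95_95_h, wt_det, tolerance = 1e-6)
    expect_identical(row$wt_days, ceiling(row$wt_95_95_h / 24))
  }
})

test_that("withdrawal time is monotone in MRL, dose and exposure length", {
  pop <- population_spec(n_individuals = 60, cv = 0.2, seed = 17)
  base <- withdrawal_report(default_phys, default_drug,
                            regimen = daily_oral_regimen(3, 1, 30),
                            population = pop, washout = 30 * 24,
                            options = fast_opts)
  halved <- withdrawal_report(default_phys, default_drug,
                              regimen = daily_oral_regimen(3, 1, 30),
                              population = pop,
                              mrls = mrl_set(5, 5, 20, 45),
                              washout = 30 * 24, options = fast_opts)
  higher <- withdrawal_report(default_phys, default_drug,
                              regimen = daily_oral_regimen(3, 2, 30),
                              population = pop, washout = 30 * 24,
                              options = fast_opts)
  longer <- withdrawal_report(default_phys, default_drug,
                              regimen = daily_oral_regimen(6, 1, 30),
                              population = pop, washout = 30 * 24,
                              options = fast_opts)
  for (tis in c("muscle", "liver", "kidney", "fat")) {
    b <- base$wt_95_95_h[base$tissue == tis]
    expect_gte(halved$wt_95_95_h[halved$tissue == tis], b)
    expect_gte(higher$wt_95_95_h[higher$tissue == tis], b)
    expect_gte(longer$wt_95_95_h[longer$tissue == tis], b)
    expect_gte(b, base$wt_median_h[base$tissue == tis])
  }
})
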