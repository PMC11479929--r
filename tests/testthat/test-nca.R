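test_that("lambda-z recovers exact mono-exponential decay", {
  t <- c(0.5, 1, 2, 4, 8, 12, 24)
  fit <- fit_lambda_z(t, 100 * exp(-0.1 * t))
  expect_equal(fit$lambda_z, 0.1, tolerance = 1e-10)
  expect_equal(fit$t_half, log(2) / 0.1, tolerance = 1e-10)
  expect_equal(fit$r2_adj, 1, tolerance = 1e-10)

  expect_error(fit_lambda_z(c(1, 2, 3), c(5, 4, 3)),
               "at least 3")          # only 2 post-peak points
  expect_error(fit_lambda_z(1:5, 1:5), "at least 3")  # peak is last point
  conc_up <- c(10, 5, 5.5, 6, 6.8, 8)  # rising tail after the peak
  expect_error(fit_lambda_z(1:6, conc_up), "terminal decay")
})

test_that("below-LOQ tail points are excluded from the lambda-z fit", {
  t <- c(1, 2, 4, 8, 12, 24, 48, 72)
  conc <- 100 * exp(-0.1 * t)
  conc[t >= 48] <- 0.2                # censored garbage below LOQ 0.5
  fit <- fit_lambda_z(t, conc, loq = 0.5)
  expect_equal(fit$lambda_z, 0.1, tolerance = 1e-8)
  expect_true(all(conc[match(fit$points_used, seq_along(t))] >= 0.5))
})

test_that("the terminal window slides past the fast phase of a biexponential", {
  biexp <- function(t) 80 * exp(-0.5 * t) + 20 * exp(-0.05 * t)
  t_late <- c(24, 36, 48, 60, 72, 96)
  fit <- fit_lambda_z(c(0.5, 1, t_late), biexp(c(0.5, 1, t_late)))
  expect_equal(fit$lambda_z, 0.05, tolerance = 0.02)
})

test_that("trapezoid rules integrate known areas", {
  # Rectangle under the linear rule.
  a <- auc_aumc(c(0, 10), c(100, 100))
  expect_equal(a$auc_last, 1000)
  # Log-down trapezoid is exact for exponential decay.
  t <- seq(0, 60, by = 2)
  a2 <- auc_aumc(t, 100 * exp(-0.1 * t), lambda_z = 0.1)
  expect_equal(a2$auc_inf, 1000, tolerance = 1e-10)
  expect_equal(a2$aumc_inf / a2$auc_inf, 10, tolerance = 1e-10)
  # Biexponential analytic integral 80/0.5 + 20/0.05 = 560.
  t3 <- seq(0, 200, by = 0.25)
  biexp <- 80 * exp(-0.5 * t3) + 20 * exp(-0.05 * t3)
  a3 <- auc_aumc(t3, biexp, lambda_z = 0.05)
  expect_equal(a3$auc_inf, 560, tolerance = 5e-4)
  # All-linear rule converges from above for convex decay.
  a4 <- auc_aumc(t, 100 * exp(-0.1 * t), lambda_z = 0.1,
                 method = "linear")
  expect_gt(a4$auc_last, a2$auc_last)
  expect_equal(a4$auc_inf, 1000, tolerance = 1e-2)
  expect_error(auc_aumc(c(0, 1), c(1, -1)), "negative")
})

test_that("IV NCA reproduces one-compartment closed forms", {
  t <- seq(0.25, 96, by = 0.25)
  res <- nca_summary(t, 100 * exp(-0.1 * t), route = "iv",
                     dose_per_kg = 1000)
  expect_equal(res$c0, 100, tolerance = 1e-6)
  expect_equal(res$t_half, 6.931, tolerance = 1e-3)
  expect_equal(res$auc_inf, 1000, tolerance = 1e-6)
  expect_equal(res$mrt, 10, tolerance = 1e-6)
  expect_equal(res$cl, 1.0, tolerance = 1e-6)
  expect_equal(res$vz, 10, tolerance = 1e-6)
  expect_equal(res$vss, 10, tolerance = 1e-6)

  oral <- nca_summary(t, 100 * exp(-0.1 * t), route = "oral",
                      dose_per_kg = 1000)
  expect_null(oral$c0)
  expect_null(oral$vz)
  expect_null(oral$vss)
  expect_equal(oral$mrt, oral$aumc_inf / oral$auc_inf)
})

test_that("bioavailability percentages follow the AUC ratio", {
  expect_equal(round(bioavailability_from_auc(4636.91, 8449.43), 2),
               54.88)
  expect_equal(bioavailability_from_auc(500, 500), 100)
  expect_equal(bioavailability_from_auc(0, 500), 0)
  expect_equal(bioavailability_from_auc(500, 500, dose_ratio = 2), 50)
  expect_error(bioavailability_from_auc(1, 0), "auc_iv")
  expect_error(bioavailability_from_auc(1, 1, 0), "dose_ratio")
})

test_that("NCA on simulated profiles links back to the model", {
  # Independent oracle: the model is linear, so the exact area under any
  # transient state is a linear solve, integral(y) = -M^-1 y0 over the
  # non-sink states; the exact plasma AUC (and hence the effective
  # plasma clearance dose/AUC) follows without any quadrature.
  M <- pbpk_matrix(default_resolved, default_drug)
  sinks <- c("feces", "hepatic_eliminated", "urine")
  trans <- setdiff(rownames(M), sinks)
  y0 <- apply_dose(empty_state(), dose_event(0, "iv", 30000))
  area <- solve(M[trans, trans], -y0[trans])
  auc_exact <- area[["venous"]] / default_resolved$volumes[["venous"]]
  cl_exact <- 1000 / auc_exact      # dose 1000 ug/kg, L/h/kg

  grid <- sort(unique(c(seq(0, 96, 0.25), seq(96, 1500, 2))))
  tciv <- simulate_pbpk(default_phys, default_drug,
                        single_dose_regimen(1, 30, "iv"), 1500, grid)
  prof_t <- grid[grid >= 0.25]
  prof_c <- predicted_at(tciv, "plasma", prof_t)
  res_iv <- nca_summary(prof_t, prof_c, "iv", dose_per_kg = 1000)
  expect_equal(res_iv$cl, cl_exact, tolerance = 0.01)

  # F from matched oral/IV NCA equals Ka/(Ka+Kgut) under the standard
  # absorption form.
  tcor <- simulate_pbpk(default_phys, default_drug,
                        single_dose_regimen(1, 30, "oral"), 1500, grid)
  res_or <- nca_summary(prof_t, predicted_at(tcor, "plasma", prof_t),
                        "oral", dose_per_kg = 1000)
  f_nca <- bioavailability_from_auc(res_or$auc_inf, res_iv$auc_inf)
  expect_equal(f_nca / 100, bioavailability(default_drug),
               tolerance = 0.02)
})

test_that("per-animal NCA tables append mean and sd rows", {
  ns <- noise_spec(proportional_cv = 0.1, n_animals = 3, seed = 7)
  obs <- generate_observed(default_phys, default_drug,
                           single_dose_regimen(1, 30, "iv"),
                           SAMPLING_IV, "plasma", ns)
  tab <- nca_by_animal(obs, route = "iv", dose_per_kg = 1000)
  expect_equal(nrow(tab), 5)  # 3 animals + mean + sd
  expect_true(all(c("mean", "sd") %in% tab$animal_id))
  expect_true(all(is.finite(tab$cl[tab$animal_id != "sd"])))
})
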