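# Synthetic observed-data generator: model-based residue datasets with
# the statistical structure of the in-vivo study (proportional assay
# noise, LOQ/LOD censoring, the study sampling schedules), used to test
# NCA, fitting and validation without the original raw data.

#' Plasma sampling schedules of the pharmacokinetic study
#'
#' Times (h) at which blood was drawn after a single oral gavage or a
#' single intravenous injection.
#' @name sampling_schedules
#' @export
SAMPLING_ORAL <- c(5 / 60, 10 / 60, 20 / 60, 30 / 60, 1, 2, 4, 6, 8, 12,
                   24, 36, 48, 72, 96)

#' @rdname sampling_schedules
#' @export
SAMPLING_IV <- c(1 / 60, 5 / 60, 10 / 60, 20 / 60, 30 / 60, 1, 2, 4, 6, 8,
                 12, 24, 36, 48, 60, 72, 84, 96)

#' Assay noise specification
#'
#' Proportional (multiplicative lognormal) assay error with LOQ/LOD
#' censoring, emulating a residue assay quantification limit of
#' 0.5 ug/kg (or ug/L) and detection limit of 0.15 ug/kg.
#'
#' @param proportional_cv Coefficient of variation of the multiplicative
#'   error (in `[0, 1)`; default 0.15).
#' @param loq Limit of quantification (values below are flagged
#'   `"<LOQ"`).
#' @param lod Limit of detection (values below are dropped); must be
#'   below `loq`.
#' @param n_animals Number of virtual animals.
#' @param seed Integer seed.
#' @return List of class `noise_spec`.
#' @export
noise_spec <- function(proportional_cv = 0.15, loq = 0.5, lod = 0.15,
                       n_animals = 6, seed = 1) {
  if (proportional_cv < 0 || proportional_cv >= 1)
    stop("noise_spec: proportional_cv must lie in [0, 1)")
  if (lod >= loq) stop("noise_spec: lod must be < loq")
  structure(list(proportional_cv = proportional_cv, loq = loq, lod = lod,
                 n_animals = as.integer(n_animals),
                 seed = as.integer(seed)),
            class = "noise_spec")
}

#' Generate a synthetic observed dataset
#'
#' Simulates the noise-free model prediction (one shared code path with
#' the simulator: [simulate_pbpk()]), then applies independent
#' median-preserving lognormal multiplicative noise per animal and
#' sample, flags values below the LOQ as censored, and drops values
#' below the LOD.  Deterministic under `noise$seed`.
#'
#' @param physiology A [physio_profile()].
#' @param drug A [drug_params()].
#' @param regimen Dosing regimen.
#' @param sampling_times Observation times (h).
#' @param matrices Output matrices to sample (e.g. `"plasma"`,
#'   `"kidney"`).
#' @param noise A [noise_spec()].
#' @param options A [pbpk_options()].
#' @return Data frame with columns `animal_id`, `time_h`, `matrix`,
#'   `concentration`, `unit`, `status` (`"ok"` or `"<LOQ"`).
#' @export
generate_observed <- function(physiology, drug, regimen, sampling_times,
                              matrices = "plasma", noise = noise_spec(),
                              options = pbpk_options()) {
  t_end <- max(sampling_times) + 1
  grid <- sort(unique(c(default_grid(regimen, t_end), sampling_times)))
  tc <- simulate_pbpk(physiology, drug, regimen, t_end,
                      output_grid = grid, options = options)

  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(noise$seed)
  sdlog <- sqrt(log(1 + noise$proportional_cv^2))

  rows <- list()
  for (m in matrices) {
    pred <- predicted_at(tc, m, sampling_times)
    for (animal in seq_len(noise$n_animals)) {
      obs <- pred * exp(stats::rnorm(length(pred), 0, sdlog))
      keep <- obs >= noise$lod
      status <- ifelse(obs < noise$loq, "<LOQ", "ok")
      rows[[length(rows) + 1]] <- data.frame(
        animal_id = sprintf("goat%02d", animal),
        time_h = sampling_times[keep],
        matrix = m,
        concentration = obs[keep],
        unit = if (m == "plasma") "ug/L" else "ug/kg",
        status = status[keep],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a synthetic tissue residue-depletion dataset
#'
#' The validation scenario: 28 daily oral gavages of 1 mg/kg, with nine
#' matrices sampled at fixed withdrawal days after the last dose.
#'
#' @param physiology,drug,noise,options As in [generate_observed()].
#' @param withdrawal_days Days after the last dose at which tissues are
#'   sampled.
#' @param matrices Matrices sampled (default: the nine study matrices).
#' @param dose_mg_per_kg,n_doses The exposure scenario.
#' @return As [generate_observed()].
#' @export
generate_validation_set <- function(physiology, drug,
                                    noise = noise_spec(),
                                    withdrawal_days = c(1, 3, 5, 7, 14, 21),
                                    matrices = c("plasma", ALL_TISSUES[
                                      ALL_TISSUES != "rest"]),
                                    dose_mg_per_kg = 1, n_doses = 28,
                                    options = pbpk_options()) {
  regimen <- daily_oral_regimen(n_doses, dose_mg_per_kg,
                                physiology$body_mass)
  t_last <- max(regimen$time)
  generate_observed(physiology, drug, regimen,
                    sampling_times = t_last + withdrawal_days * 24,
                    matrices = matrices, noise = noise, options = options)
}

#' Observed-versus-predicted validation regressions
#'
#' Per-matrix ordinary least squares of observed on predicted
#' concentration over matched `(matrix, time)` pairs: a slope near 1 and
#' intercept near 0 indicate good simulation.  Matrices with fewer than
#' three matched pairs are skipped with a message.
#'
#' @param observed Data frame with `matrix`, `time_h`, `concentration`.
#' @param predicted Same layout (noise-free model predictions), or a
#'   `rac_timecourse` from which predictions are interpolated.
#' @return Data frame with `matrix`, `slope`, `intercept`, `r2`, `n`;
#'   residuals (observed - predicted) per pair in
#'   `attr(, "residuals")`.
#' @export
validate_predictions <- function(observed, predicted) {
  if (inherits(predicted, "rac_timecourse")) {
    tc <- predicted
    predicted <- do.call(rbind, lapply(unique(observed$matrix), function(m)
      data.frame(matrix = m, time_h = unique(observed$time_h),
                 concentration = predicted_at(
                   tc, m, unique(observed$time_h)),
                 stringsAsFactors = FALSE)))
  }
  key <- function(d) paste(d$matrix, signif(d$time_h, 12))
  pred_map <- stats::setNames(predicted$concentration, key(predicted))
  obs <- observed
  obs$predicted <- pred_map[key(obs)]
  obs <- obs[is.finite(obs$predicted), , drop = FALSE]

  resid_tab <- data.frame(matrix = obs$matrix, time_h = obs$time_h,
                          observed = obs$concentration,
                          predicted = obs$predicted,
                          residual = obs$concentration - obs$predicted,
                          stringsAsFactors = FALSE)
  rows <- list()
  for (m in unique(obs$matrix)) {
    sub <- obs[obs$matrix == m, ]
    if (nrow(sub) < 3) {
      message("validate_predictions: matrix '", m,
              "' skipped (fewer than 3 matched pairs)")
      next
    }
    fit <- stats::lm(concentration ~ predicted, data = sub)
    # summary.lm warns on an essentially perfect fit, the expected case
    # for noise-free self-consistency checks.
    r2 <- suppressWarnings(summary(fit)$r.squared)
    rows[[m]] <- data.frame(
      matrix = m,
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      r2 = r2,
      n = nrow(sub), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "residuals") <- resid_tab
  out
}
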