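# Parameter estimation: bounded nonlinear least squares of model
# predictions against observed multi-matrix concentration data, on the
# log scale by default (residue data span three decades).

#' Fitting specification
#'
#' Declares which drug parameters are free, their bounds and starting
#' values, the objective, and the datasets fitted against.  Each dataset
#' is a list with elements `matrix` (output matrix name), `regimen`
#' (dose events) and an observed table (`time_h`, `concentration`;
#' multiple animals are pooled).
#'
#' @param free_parameters Character vector of [get_drug_param()] paths.
#' @param initial Named numeric vector of starting values (defaults to
#'   the base drug values).
#' @param lower,upper Named numeric vectors of bounds (defaults: a
#'   factor of 10 around the starting value).
#' @param objective `"log_ssr"` (sum of squared log-residuals with
#'   offset `loq/2`) or `"weighted_ssr"` (residuals scaled by the
#'   observation, floored at the LOQ).
#' @param datasets List of datasets (see above).
#' @param loq Quantification limit used for the log offset/weight floor.
#' @return List of class `fit_spec`.
#' @export
fit_spec <- function(free_parameters, datasets, initial = NULL,
                     lower = NULL, upper = NULL,
                     objective = c("log_ssr", "weighted_ssr"),
                     loq = 0.5) {
  objective <- match.arg(objective)
  stopifnot(length(free_parameters) >= 1, length(datasets) >= 1)
  for (d in datasets)
    stopifnot(is.character(d$matrix), is.data.frame(d$regimen),
              is.data.frame(d$observed),
              all(c("time_h", "concentration") %in% names(d$observed)))
  structure(list(free_parameters = free_parameters,
                 initial = initial, lower = lower, upper = upper,
                 objective = objective, datasets = datasets, loq = loq),
            class = "fit_spec")
}

resolve_fit_vectors <- function(spec, drug) {
  paths <- spec$free_parameters
  base <- vapply(paths, function(p) get_drug_param(drug, p), numeric(1))
  initial <- if (is.null(spec$initial)) base else {
    stopifnot(all(paths %in% names(spec$initial)))
    spec$initial[paths]
  }
  lower <- if (is.null(spec$lower)) initial / 10 else spec$lower[paths]
  upper <- if (is.null(spec$upper)) initial * 10 else spec$upper[paths]
  if (any(initial < lower - 1e-12) || any(initial > upper + 1e-12))
    stop("fit_spec: initial values must lie within bounds")
  list(paths = paths, initial = initial, lower = lower, upper = upper)
}

# Residual vector at a parameter point; simulation failure yields a
# large-but-finite penalty residual so bounded optimizers can recover.
fit_residuals <- function(par, spec, drug, resolved, options) {
  d <- drug
  for (i in seq_along(spec$free_parameters))
    d <- set_drug_param(d, spec$free_parameters[i], par[i])
  eps <- spec$loq / 2
  res <- tryCatch({
    unlist(lapply(spec$datasets, function(ds) {
      t_end <- max(ds$observed$time_h) + 1
      grid <- sort(unique(c(default_grid(ds$regimen, t_end),
                            ds$observed$time_h)))
      tc <- simulate_pbpk(resolved, d, ds$regimen, t_end,
                          output_grid = grid, options = options)
      pred <- predicted_at(tc, ds$matrix, ds$observed$time_h)
      obs <- ds$observed$concentration
      if (spec$objective == "log_ssr") {
        log(pred + eps) - log(obs + eps)
      } else {
        (pred - obs) / pmax(obs, spec$loq)
      }
    }))
  }, error = function(e) e)
  if (inherits(res, "error")) {
    message("fit: simulation failed at a parameter point (",
            conditionMessage(res), "); penalized")
    n <- sum(vapply(spec$datasets, function(ds) nrow(ds$observed),
                    numeric(1)))
    return(rep(1e3, n))
  }
  res
}

#' Scalar fitting objective
#'
#' Sum of squared residuals of the model against the spec's datasets at
#' a given parameter vector; the quantity minimized by [fit_params()].
#'
#' @param par Numeric vector, in the order of `spec$free_parameters`.
#' @param spec A [fit_spec()].
#' @param drug Base [drug_params()] supplying all fixed parameters.
#' @param physiology A [physio_profile()].
#' @param options A [pbpk_options()].
#' @return Scalar loss.
#' @export
fit_objective <- function(par, spec, drug, physiology,
                          options = pbpk_options()) {
  resolved <- resolve_physiology(physiology)
  sum(fit_residuals(par, spec, drug, resolved, options)^2)
}

#' Estimate model parameters from observed data
#'
#' Bounded Levenberg-Marquardt nonlinear least squares
#' (`minpack.lm::nls.lm`) from the spec's starting point.  Per-parameter
#' standard deviations are approximated from the Jacobian at the optimum
#' (linearization).  Deterministic given the spec.
#'
#' @inheritParams fit_objective
#' @return List of class `fit_result` with `estimates` (named vector),
#'   `sd` (approximate), `objective_value`, `converged`,
#'   `n_evaluations` and `message`.
#' @export
fit_params <- function(spec, drug, physiology,
                       options = pbpk_options()) {
  resolved <- resolve_physiology(physiology)
  v <- resolve_fit_vectors(spec, drug)
  out <- minpack.lm::nls.lm(
    par = v$initial, lower = v$lower, upper = v$upper,
    fn = fit_residuals, spec = spec, drug = drug,
    resolved = resolved, options = options,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- stats::setNames(as.numeric(out$par), v$paths)
  sds <- tryCatch({
    sm <- summary(out)
    stats::setNames(sm$coefficients[, "Std. Error"], v$paths)
  }, error = function(e) stats::setNames(rep(NA_real_, length(est)),
                                         v$paths))
  structure(list(estimates = est, sd = sds,
                 objective_value = out$deviance,
                 converged = out$info %in% 1:4,
                 n_evaluations = out$niter,
                 message = out$message),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("PBPK fit (", if (x$converged) "converged" else "NOT converged",
      ", ", x$n_evaluations, " iterations):\n", sep = "")
  tab <- data.frame(estimate = x$estimates, approx_sd = x$sd)
  print(tab, digits = 5)
  cat(sprintf("objective: %.6g\n", x$objective_value))
  invisible(x)
}

#' One-dimensional cardiac-output calibration
#'
#' Cardiac output is not measurable from residue data alone and enters
#' every regional flow; this helper tunes it against an observed plasma
#' profile by golden-section minimization of the log-scale sum of
#' squares.
#'
#' @param physiology A [physio_profile()] (its `cardiac_output` is the
#'   starting point; all other values are held fixed).
#' @param drug A [drug_params()].
#' @param regimen Dose events matching the observed profile.
#' @param observed Data frame with `time_h`, `concentration` (plasma).
#' @param interval Search interval (L/h/kg).
#' @param options A [pbpk_options()].
#' @return List with `cardiac_output` (L/h/kg) and `objective`.
#' @export
calibrate_cardiac_output <- function(physiology, drug, regimen, observed,
                                     interval = c(1, 20),
                                     options = pbpk_options()) {
  loss <- function(co) {
    p <- physiology
    p$cardiac_output <- co
    t_end <- max(observed$time_h) + 1
    tc <- simulate_pbpk(p, drug, regimen, t_end,
                        output_grid = sort(unique(c(
                          default_grid(regimen, t_end),
                          observed$time_h))),
                        options = options)
    pred <- predicted_at(tc, "plasma", observed$time_h)
    sum((log(pred + 0.25) - log(observed$concentration + 0.25))^2)
  }
  opt <- stats::optimize(loss, interval = interval)
  list(cardiac_output = opt$minimum, objective = opt$objective)
}
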