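# Non-compartmental analysis of concentration-time profiles, following
# the conventions of standard PK software: terminal slope by best-fit
# (maximum adjusted R^2) log-linear regression, linear-up/log-down
# trapezoids, and tail extrapolation from Clast/lambda_z.

#' Terminal elimination rate constant (lambda-z)
#'
#' Log-linear regression on the terminal portion of a profile.  The
#' point window is chosen by the "best fit" rule: among all candidate
#' terminal windows of at least three points that start strictly after
#' the observed maximum, the one maximizing the adjusted R^2 is used
#' (ties broken in favor of more points).  Non-positive, missing, and
#' below-LOQ concentrations are excluded beforehand.
#'
#' @param time,conc Numeric vectors (h; ug/L or ug/kg).
#' @param loq Lower limit of quantification; concentrations below it are
#'   excluded from the fit (`NULL` to disable).
#' @return List with `lambda_z` (1/h), `t_half` (h), `r2_adj`,
#'   `n_points`, `intercept` (log-scale at t = 0) and `points_used`
#'   (indices into the input).
#' @export
#' @examples
#' t <- c(1, 2, 4, 8, 12, 24)
#' fit_lambda_z(t, 100 * exp(-0.1 * t))$lambda_z   # 0.1
fit_lambda_z <- function(time, conc, loq = NULL) {
  stopifnot(length(time) == length(conc))
  ord <- order(time)
  time <- time[ord]; conc <- conc[ord]
  usable <- is.finite(conc) & conc > 0
  if (!is.null(loq)) usable <- usable & conc >= loq
  imax <- which.max(ifelse(usable, conc, -Inf))
  cand <- which(usable & seq_along(conc) > imax)
  if (length(cand) < 3)
    stop("fit_lambda_z: need at least 3 usable post-peak concentrations",
         call. = FALSE)

  # Closed-form log-linear regression per candidate window (faster and
  # quieter than lm() on the potentially dense profiles handled here).
  loglin <- function(idx) {
    x <- time[idx]; y <- log(conc[idx]); n <- length(idx)
    mx <- mean(x); my <- mean(y)
    sxx <- sum((x - mx)^2); sxy <- sum((x - mx) * (y - my))
    syy <- sum((y - my)^2)
    slope <- sxy / sxx
    r2 <- if (syy > 0) sxy^2 / (sxx * syy) else 1
    list(slope = slope, intercept = my - slope * mx,
         r2_adj = 1 - (1 - r2) * (n - 1) / (n - 2))
  }
  best <- NULL
  for (s in seq_len(length(cand) - 2)) {
    idx <- cand[s:length(cand)]
    fit <- loglin(idx)
    if (is.null(best) || fit$r2_adj > best$r2_adj + 1e-12 ||
        (abs(fit$r2_adj - best$r2_adj) <= 1e-12 &&
           length(idx) > best$n_points)) {
      best <- list(slope = fit$slope, intercept = fit$intercept,
                   r2_adj = fit$r2_adj, n_points = length(idx),
                   points_used = ord[idx])
    }
  }
  if (best$slope >= 0)
    stop("fit_lambda_z: no terminal decay (non-negative slope)",
         call. = FALSE)
  list(lambda_z = -best$slope, t_half = log(2) / -best$slope,
       r2_adj = best$r2_adj, n_points = best$n_points,
       intercept = best$intercept, points_used = best$points_used)
}

#' Area under the curve and first-moment curve
#'
#' Trapezoidal AUC/AUMC to the last quantifiable point with exponential
#' tail extrapolation.  The default rule is linear-up/log-down: the
#' logarithmic trapezoid (exact for mono-exponential decline) is used on
#' strictly decreasing positive intervals, the linear one elsewhere.
#' Missing concentrations are treated as absent samples, not zeros.
#'
#' @param time,conc Numeric vectors.
#' @param lambda_z Terminal rate constant for the tail; `NULL` suppresses
#'   extrapolation (then `auc_inf`/`aumc_inf` are `NA`).
#' @param method `"linuplogdown"` or `"linear"`.
#' @return List with `auc_last`, `auc_inf` (h*ug/L), `aumc_last`,
#'   `aumc_inf` (h^2*ug/L), `t_last` and `c_last`.
#' @export
auc_aumc <- function(time, conc, lambda_z = NULL,
                     method = c("linuplogdown", "linear")) {
  method <- match.arg(method)
  keep <- is.finite(conc)
  time <- time[keep]; conc <- conc[keep]
  ord <- order(time)
  time <- time[ord]; conc <- conc[ord]
  if (any(conc < 0)) stop("auc_aumc: negative concentrations")
  n <- length(time)
  if (n < 2) stop("auc_aumc: need at least two points")

  auc <- aumc <- 0
  for (i in seq_len(n - 1)) {
    t1 <- time[i]; t2 <- time[i + 1]; c1 <- conc[i]; c2 <- conc[i + 1]
    dt <- t2 - t1
    if (method == "linuplogdown" && c1 > c2 && c2 > 0) {
      k <- log(c1 / c2) / dt
      auc <- auc + (c1 - c2) / k
      aumc <- aumc + (t1 * c1 - t2 * c2) / k + (c1 - c2) / k^2
    } else {
      auc <- auc + dt * (c1 + c2) / 2
      aumc <- aumc + dt * (t1 * c1 + t2 * c2) / 2
    }
  }
  t_last <- time[n]; c_last <- conc[n]
  if (!is.null(lambda_z)) {
    if (!is.finite(lambda_z) || lambda_z <= 0)
      stop("auc_aumc: lambda_z must be > 0 for tail extrapolation")
    auc_inf <- auc + c_last / lambda_z
    aumc_inf <- aumc + c_last * t_last / lambda_z + c_last / lambda_z^2
  } else {
    auc_inf <- NA_real_; aumc_inf <- NA_real_
  }
  list(auc_last = auc, auc_inf = auc_inf,
       aumc_last = aumc, aumc_inf = aumc_inf,
       t_last = t_last, c_last = c_last)
}

#' Non-compartmental analysis summary
#'
#' Full NCA of a single-animal plasma profile.  For intravenous dosing,
#' `c0` is obtained by log-linear back-extrapolation of the first two
#' positive concentrations to time zero and the profile is anchored at
#' `(0, c0)` before the trapezoids; clearance `cl = dose/auc_inf`,
#' `vz = dose/(lambda_z * auc_inf)` and `vss = cl * mrt` are reported.
#' For oral dosing those fields are absent and `mrt = aumc_inf/auc_inf`
#' is reported without intravenous correction.
#'
#' @param time,conc The profile (h; ug/L).
#' @param route `"iv"` or `"oral"`.
#' @param dose_per_kg Dose (ug per kg body weight).
#' @param loq LOQ passed to [fit_lambda_z()].
#' @param method Trapezoid rule, see [auc_aumc()].
#' @return Object of class `nca_result`: a list with `lambda_z`,
#'   `t_half`, `auc_last`, `auc_inf`, `aumc_inf`, `mrt`,
#'   `n_lambda_points`, `r2_adj_lambda`, and for iv also `c0`, `cl`,
#'   `vz`, `vss`.
#' @export
#' @examples
#' t <- seq(0.25, 48, by = 0.25)
#' res <- nca_summary(t, 100 * exp(-0.1 * t), "iv", dose_per_kg = 1000)
#' c(res$cl, res$vss)   # 1 L/h/kg, 10 L/kg
nca_summary <- function(time, conc, route = c("iv", "oral"), dose_per_kg,
                        loq = NULL, method = c("linuplogdown", "linear")) {
  route <- match.arg(route)
  method <- match.arg(method)
  ord <- order(time)
  time <- time[ord]; conc <- conc[ord]
  lz <- fit_lambda_z(time, conc, loq = loq)

  c0 <- NULL
  if (route == "iv" && time[1] > 0) {
    pos <- which(is.finite(conc) & conc > 0)
    if (length(pos) >= 2) {
      i1 <- pos[1]; i2 <- pos[2]
      c0 <- if (conc[i1] > conc[i2]) {
        exp(log(conc[i1]) - time[i1] *
              (log(conc[i2]) - log(conc[i1])) / (time[i2] - time[i1]))
      } else conc[i1]
    } else c0 <- conc[pos[1]]
    time <- c(0, time); conc <- c(c0, conc)
  }

  area <- auc_aumc(time, conc, lambda_z = lz$lambda_z, method = method)
  mrt <- area$aumc_inf / area$auc_inf
  res <- list(route = route, dose_per_kg = dose_per_kg,
              lambda_z = lz$lambda_z, t_half = lz$t_half,
              auc_last = area$auc_last, auc_inf = area$auc_inf,
              aumc_inf = area$aumc_inf, mrt = mrt,
              n_lambda_points = lz$n_points,
              r2_adj_lambda = lz$r2_adj)
  if (route == "iv") {
    cl <- dose_per_kg / area$auc_inf
    res$c0 <- c0
    res$cl <- cl
    res$vz <- dose_per_kg / (lz$lambda_z * area$auc_inf)
    res$vss <- cl * mrt
  }
  structure(res, class = "nca_result")
}

#' @export
print.nca_result <- function(x, ...) {
  cat("NCA (", x$route, ", dose ", x$dose_per_kg, " ug/kg):\n", sep = "")
  cat(sprintf("  lambda_z %.5g 1/h (t1/2 %.4g h; %d points, adj-R2 %.4f)\n",
              x$lambda_z, x$t_half, x$n_lambda_points, x$r2_adj_lambda))
  cat(sprintf("  AUC_last %.6g  AUC_inf %.6g h*ug/L  MRT %.4g h\n",
              x$auc_last, x$auc_inf, x$mrt))
  if (x$route == "iv")
    cat(sprintf("  C0 %.5g ug/L  Cl %.4g L/h/kg  Vz %.4g  Vss %.4g L/kg\n",
                x$c0, x$cl, x$vz, x$vss))
  invisible(x)
}

#' Absolute oral bioavailability from AUC ratio
#'
#' `F (%) = 100 * (auc_oral / auc_iv) / dose_ratio`, with
#' `dose_ratio = dose_oral / dose_iv`.
#'
#' @param auc_oral,auc_iv AUCs at matched units (h*ug/L); `auc_iv > 0`.
#' @param dose_ratio Oral:iv dose ratio (> 0); 1 at equal dosing.
#' @return Bioavailability in percent.
#' @export
#' @examples
#' bioavailability_from_auc(4636.91, 8449.43)   # 54.88
bioavailability_from_auc <- function(auc_oral, auc_iv, dose_ratio = 1) {
  if (!is.finite(auc_iv) || auc_iv <= 0)
    stop("bioavailability_from_auc: auc_iv must be > 0")
  if (!is.finite(dose_ratio) || dose_ratio <= 0)
    stop("bioavailability_from_auc: dose_ratio must be > 0")
  if (!is.finite(auc_oral) || auc_oral < 0)
    stop("bioavailability_from_auc: auc_oral must be >= 0")
  100 * (auc_oral / auc_iv) / dose_ratio
}

#' Per-animal NCA over an observed data table
#'
#' Runs [nca_summary()] for every animal in a long observed table (as
#' produced by [generate_observed()] or read by [read_observed()]) and
#' appends arithmetic mean and SD rows, mirroring the convention of
#' reporting means of individual-animal NCA parameters.
#'
#' @param observed Data frame with columns `animal_id`, `time_h`,
#'   `matrix`, `concentration`, and optionally `status` (rows flagged
#'   `"<LOQ"` are excluded from the lambda-z fit via `loq`).
#' @param route,dose_per_kg,loq,method Passed to [nca_summary()].
#' @param matrix Which matrix to analyze (default `"plasma"`).
#' @return Data frame, one row per animal plus `mean` and `sd` rows.
#' @export
nca_by_animal <- function(observed, route, dose_per_kg, loq = 0.5,
                          matrix = "plasma",
                          method = c("linuplogdown", "linear")) {
  obs <- observed[observed$matrix == matrix, , drop = FALSE]
  ids <- unique(obs$animal_id)
  fields <- c("lambda_z", "t_half", "auc_last", "auc_inf", "aumc_inf",
              "mrt", "c0", "cl", "vz", "vss")
  rows <- lapply(ids, function(id) {
    sub <- obs[obs$animal_id == id, ]
    res <- nca_summary(sub$time_h, sub$concentration, route = route,
                       dose_per_kg = dose_per_kg, loq = loq,
                       method = method)
    vals <- vapply(fields, function(f)
      if (is.null(res[[f]])) NA_real_ else res[[f]], numeric(1))
    data.frame(animal_id = as.character(id), t(vals),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  num <- tab[, fields, drop = FALSE]
  summary_rows <- data.frame(
    animal_id = c("mean", "sd"),
    rbind(colMeans(num), apply(num, 2, stats::sd)),
    stringsAsFactors = FALSE)
  rbind(tab, summary_rows)
}
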