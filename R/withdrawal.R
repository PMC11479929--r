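# Monte Carlo population simulation and regulatory withdrawal-time (WT)
# estimation against maximum residue limits (MRLs).

#' Maximum residue limits for ractopamine in edible goat tissues
#'
#' CAC limits: 10 ug/kg muscle, 10 ug/kg fat, 40 ug/kg liver, 90 ug/kg
#' kidney.
#'
#' @param muscle,fat,liver,kidney Limits in ug/kg (all > 0).
#' @return Named numeric vector of class `mrl_set`.
#' @export
mrl_set <- function(muscle = 10, fat = 10, liver = 40, kidney = 90) {
  v <- c(muscle = muscle, fat = fat, liver = liver, kidney = kidney)
  if (any(!is.finite(v) | v <= 0)) stop("mrl_set: all MRLs must be > 0")
  structure(v, class = "mrl_set")
}

# Drug parameters varied in the Monte Carlo population: the drug-specific
# members of the sensitive set (|NSC| >= 0.25 under the 28-day regimen
# with the post-exposure concentration functional).
DEFAULT_VARIED <- c("cl_hepatic", "k_stomach", "k_absorption", "k_gut",
                    "partition.liver", "partition.kidney",
                    "partition.muscle", "partition.rest",
                    "permeability_fraction.muscle",
                    "permeability_fraction.rest")

#' Monte Carlo population specification
#'
#' Inter-individual variability for the withdrawal-time simulation:
#' selected drug parameters are drawn from mean-preserving lognormal
#' distributions truncated at plus/minus `truncation` standard
#' deviations on the log scale.
#'
#' @param n_individuals Number of virtual animals (default 500).
#' @param varied_parameters Character vector of [get_drug_param()] paths.
#' @param cv Coefficient of variation, either a single value applied to
#'   all varied parameters (default 0.2) or a named vector by path.
#' @param truncation Truncation bound in log-scale SDs (default 3).
#' @param seed Integer seed making the population reproducible.
#' @return List of class `population_spec`.
#' @export
population_spec <- function(n_individuals = 500,
                            varied_parameters = DEFAULT_VARIED,
                            cv = 0.2, truncation = 3, seed = 1) {
  if (n_individuals < 1) stop("population_spec: n_individuals must be >= 1")
  if (any(cv < 0)) stop("population_spec: cv must be >= 0")
  if (length(cv) > 1 && !all(varied_parameters %in% names(cv)))
    stop("population_spec: named cv must cover all varied parameters")
  structure(list(n_individuals = as.integer(n_individuals),
                 varied_parameters = varied_parameters,
                 cv = cv, truncation = truncation,
                 seed = as.integer(seed)),
            class = "population_spec")
}

#' Sample a virtual population of drug parameter sets
#'
#' Each varied parameter is drawn independently per individual from a
#' lognormal distribution whose arithmetic mean equals the base value
#' (`meanlog = log(base) - sdlog^2/2`, `sdlog = sqrt(log(1 + cv^2))`),
#' truncated at `truncation` SDs on the log scale by rejection.
#' Unlisted parameters are identical to the base set.  The draw is
#' deterministic given `spec$seed`.
#'
#' @param drug Base [drug_params()].
#' @param spec A [population_spec()].
#' @return List of `spec$n_individuals` `drug_params` objects.
#' @export
sample_population <- function(drug, spec) {
  n <- spec$n_individuals
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(spec$seed)

  draws <- list()
  for (path in spec$varied_parameters) {
    base <- get_drug_param(drug, path)
    cvp <- if (length(spec$cv) > 1) spec$cv[[path]] else spec$cv
    if (cvp == 0) { draws[[path]] <- rep(base, n); next }
    sdlog <- sqrt(log(1 + cvp^2))
    meanlog <- log(base) - sdlog^2 / 2
    x <- numeric(0)
    attempts <- 0
    while (length(x) < n) {
      m <- 2 * (n - length(x))
      z <- stats::rnorm(m)
      z <- z[abs(z) <= spec$truncation]
      x <- c(x, exp(meanlog + sdlog * z))
      attempts <- attempts + m
      if (attempts > 10 * n && length(x) == 0)
        stop("sample_population: truncation rejection exceeded 10x n draws")
    }
    draws[[path]] <- x[seq_len(n)]
  }

  lapply(seq_len(n), function(i) {
    d <- drug
    for (path in spec$varied_parameters)
      d <- set_drug_param(d, path, draws[[path]][i])
    d
  })
}

#' Withdrawal time from a simulated time course
#'
#' The time after the last dose at which the tissue concentration falls
#' below the MRL and stays below it for the remainder of the simulation.
#' The crossing is located at the final down-crossing of the grid curve,
#' refined by linear interpolation of log concentration between the
#' bracketing grid points.
#'
#' @param timecourse A `rac_timecourse` extending beyond the crossing.
#' @param tissue Tissue name (column of `timecourse$conc`).
#' @param mrl Maximum residue limit (ug/kg).
#' @param t_last_dose Time of the last administration (h); defaults to
#'   the last dose in the time course's regimen.
#' @return Withdrawal time in hours after the last dose (0 when the
#'   concentration is already permanently below the MRL at the last
#'   dose).
#' @export
withdrawal_time_curve <- function(timecourse, tissue, mrl,
                                  t_last_dose = NULL) {
  if (is.null(t_last_dose)) t_last_dose <- max(timecourse$regimen$time)
  keep <- timecourse$times >= t_last_dose
  tt <- timecourse$times[keep]
  cc <- timecourse$conc[keep, tissue]
  above <- cc >= mrl
  if (above[length(above)])
    stop("withdrawal_time_curve: concentration still at/above MRL at ",
         "t_end; extend t_end", call. = FALSE)
  if (!any(above)) return(0)
  i <- max(which(above))          # final down-crossing
  c1 <- cc[i]; c2 <- cc[i + 1]
  t_cross <- if (c1 > 0 && c2 > 0 && c1 != c2) {
    tt[i] + (tt[i + 1] - tt[i]) * (log(c1) - log(mrl)) / (log(c1) - log(c2))
  } else {
    tt[i] + (tt[i + 1] - tt[i]) * (c1 - mrl) / (c1 - c2)
  }
  max(0, t_cross - t_last_dose)
}

#' Order-statistic index for a one-sided tolerance bound
#'
#' Smallest `k` such that the `k`-th order statistic of an i.i.d. sample
#' of size `n` is an upper tolerance bound covering a fraction `p` of
#' the population with confidence `conf`:
#' `P(Binomial(n, p) <= k - 1) >= conf`.
#'
#' @param n Sample size.
#' @param p Population fraction covered (default 0.95).
#' @param conf Confidence level (default 0.95).
#' @return Integer index in `1..n`.
#' @export
#' @examples
#' tolerance_index(500)   # 484
tolerance_index <- function(n, p = 0.95, conf = 0.95) {
  k <- suppressWarnings(stats::qbinom(conf, n, p) + 1L)
  if (k > n)
    stop(sprintf(
      "tolerance_index: n = %d too small for a %g/%g bound (need n >= %d)",
      n, p, conf, minimum_tolerance_n(p, conf)), call. = FALSE)
  as.integer(k)
}

minimum_tolerance_n <- function(p = 0.95, conf = 0.95) {
  ceiling(log(1 - conf) / log(p))
}

#' Nonparametric 95/95 upper tolerance bound of withdrawal times
#'
#' Distribution-free one-sided upper tolerance bound: the
#' [tolerance_index()]-th order statistic of the per-individual
#' withdrawal times.
#'
#' @param wts Numeric vector of per-individual withdrawal times (h).
#' @param p,conf Coverage and confidence (defaults 0.95/0.95).
#' @return Bound in hours.
#' @export
wt_95_95 <- function(wts, p = 0.95, conf = 0.95) {
  n <- length(wts)
  nmin <- minimum_tolerance_n(p, conf)
  if (n < nmin)
    stop("wt_95_95: need at least ", nmin, " individuals, got ", n,
         call. = FALSE)
  sort(wts)[tolerance_index(n, p, conf)]
}

#' Monte Carlo withdrawal-time report
#'
#' Simulates the dosing scenario for every individual of a Monte Carlo
#' population, computes per-tissue withdrawal times against the MRLs,
#' and summarizes each tissue with the nonparametric 95/95 upper
#' tolerance bound, reported in hours and rounded up to whole days.
#'
#' @param physiology A [physio_profile()].
#' @param drug Base [drug_params()].
#' @param regimen Dosing regimen; defaults to 28 daily oral doses of
#'   1 mg/kg.
#' @param population A [population_spec()].
#' @param mrls An [mrl_set()].
#' @param washout Post-dose simulation horizon (h).
#' @param options A [pbpk_options()].
#' @return Data frame of class `wt_result` with one row per tissue:
#'   `tissue`, `mrl`, `wt_median_h`, `wt_p95_h`, `wt_95_95_h`,
#'   `wt_days`; the per-individual WT matrix is in
#'   `attr(, "individual")` and the number of dropped individuals in
#'   `attr(, "n_failed")`.
#' @export
withdrawal_report <- function(physiology, drug,
                              regimen = daily_oral_regimen(
                                28, 1, physiology$body_mass),
                              population = population_spec(),
                              mrls = mrl_set(),
                              washout = 45 * 24,
                              options = pbpk_options()) {
  resolved <- resolve_physiology(physiology)
  t_last <- max(regimen$time)
  t_end <- t_last + washout
  grid <- sort(unique(c(seq(0, t_last, by = 2), seq(t_last, t_end, by = 1))))
  pop <- sample_population(drug, population)
  tissues <- names(mrls)

  wt <- matrix(NA_real_, nrow = length(pop), ncol = length(tissues),
               dimnames = list(NULL, tissues))
  n_failed <- 0
  for (i in seq_along(pop)) {
    res <- tryCatch({
      tc <- simulate_pbpk(resolved, pop[[i]], regimen, t_end,
                          output_grid = grid, options = options)
      vapply(tissues, function(tis)
        withdrawal_time_curve(tc, tis, mrls[[tis]], t_last), numeric(1))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      n_failed <- n_failed + 1
      if (n_failed > max(1, 0.01 * length(pop)))
        stop("withdrawal_report: too many failed individuals (",
             n_failed, "); last error: ", conditionMessage(res),
             call. = FALSE)
    } else {
      wt[i, ] <- res
    }
  }
  if (n_failed > 0)
    message("withdrawal_report: dropped ", n_failed, " failed individuals")
  ok <- stats::complete.cases(wt)
  wt <- wt[ok, , drop = FALSE]

  out <- do.call(rbind, lapply(tissues, function(tis) {
    b <- wt_95_95(wt[, tis])
    data.frame(tissue = tis, mrl = mrls[[tis]],
               wt_median_h = stats::median(wt[, tis]),
               wt_p95_h = unname(stats::quantile(wt[, tis], 0.95,
                                                 type = 1)),
               wt_95_95_h = b,
               wt_days = ceiling(b / 24),
               stringsAsFactors = FALSE)
  }))
  attr(out, "individual") <- wt
  attr(out, "n_failed") <- n_failed
  class(out) <- c("wt_result", class(out))
  out
}
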