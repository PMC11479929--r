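# Local sensitivity analysis: sensitivity coefficients by finite
# difference, normalized to elasticities (NSC), and a full parameter x
# output sweep over the PBPK model.

#' Finite-difference sensitivity coefficient
#'
#' `SC = (f(x + dx) - f(x)) / dx` with `dx = delta_fraction * x`
#' (forward difference), or the central variant
#' `(f(x + dx) - f(x - dx)) / (2 dx)`.
#'
#' @param f Scalar function of a scalar parameter.
#' @param x Base parameter value (non-zero).
#' @param delta_fraction Relative perturbation (> 0; default 0.01).
#' @param method `"forward"` or `"central"`.
#' @return The sensitivity coefficient (output units per parameter unit).
#' @export
#' @examples
#' sensitivity_coefficient(function(x) x^2, 2, 0.01)   # 4.02
sensitivity_coefficient <- function(f, x, delta_fraction = 0.01,
                                    method = c("forward", "central")) {
  method <- match.arg(method)
  if (delta_fraction <= 0)
    stop("sensitivity_coefficient: delta_fraction must be > 0")
  if (!is.finite(x) || x == 0)
    stop("sensitivity_coefficient: x must be finite and non-zero")
  dx <- delta_fraction * x
  up <- tryCatch(f(x + dx), error = function(e)
    stop("sensitivity_coefficient: f failed at perturbed point: ",
         conditionMessage(e), call. = FALSE))
  if (method == "forward") {
    (up - f(x)) / dx
  } else {
    (up - f(x - dx)) / (2 * dx)
  }
}

#' Normalized sensitivity coefficient (elasticity)
#'
#' `NSC = SC * x / f(x)`; dimensionless, sign-preserving.  A parameter
#' is conventionally called sensitive when `|NSC| >= 0.25`.
#'
#' @inheritParams sensitivity_coefficient
#' @return The NSC.
#' @export
#' @examples
#' nsc(function(x) 3 * x^2, 2)   # ~2 (power-law elasticity)
nsc <- function(f, x, delta_fraction = 0.01,
                method = c("forward", "central")) {
  fx <- f(x)
  if (!is.finite(fx) || fx == 0)
    stop("nsc: f(x) must be finite and non-zero")
  sc <- sensitivity_coefficient(f, x, delta_fraction, method)
  sc * x / fx
}

# ---------------------------------------------------------------------------
# Parameter registry: named perturbations of the (resolved physiology,
# drug) pair.  Flow perturbations act on the resolved absolute flows, so
# they deliberately unbalance the circulatory flows; the mass-balance
# matrix conserves drug mass regardless.  Body-mass perturbation scales
# volumes, flows and (per-kg) clearances while the dose events, already
# resolved to ug, stay fixed.

scale_flow <- function(resolved, organ, factor) {
  if (organ == "lung") {
    resolved$flows <- resolved$flows * factor   # cardiac output
  } else if (organ == "liver") {
    resolved$flows[["liver_total"]] <- resolved$flows[["liver_total"]] * factor
  } else {
    resolved$flows[[organ]] <- resolved$flows[[organ]] * factor
  }
  resolved$flows[["liver_arterial"]] <-
    resolved$flows[["liver_total"]] - resolved$flows[["spleen"]]
  resolved
}

sens_parameter_registry <- function(drug) {
  reg <- list()
  add <- function(name, base, apply) reg[[name]] <<- list(
    base = base, apply = apply)

  add("bw", quote(resolved$body_mass), function(resolved, drug, f) {
    resolved$body_mass <- resolved$body_mass * f
    resolved$volumes <- resolved$volumes * f
    resolved$flows <- resolved$flows * f
    list(resolved = resolved, drug = drug)
  })
  flow_names <- c(qclu = "lung", qcli = "liver", qcki = "kidney",
                  qcmu = "muscle", qcfa = "fat", qche = "heart",
                  qcbr = "brain", qcre = "rest", qcsp = "spleen")
  for (nm in names(flow_names)) {
    organ <- flow_names[[nm]]
    local({
      org <- organ
      add(nm, bquote(resolved$flows[[.(
        if (org == "liver") "liver_total" else org)]]),
        function(resolved, drug, f)
          list(resolved = scale_flow(resolved, org, f), drug = drug))
    })
  }
  drug_scalar <- c(clhe = "cl_hepatic", clre = "cl_renal",
                   kst = "k_stomach", ka = "k_absorption",
                   kint = "k_gut")
  for (nm in names(drug_scalar)) {
    local({
      field <- drug_scalar[[nm]]
      add(nm, bquote(drug[[.(field)]]), function(resolved, drug, f) {
        drug[[field]] <- drug[[field]] * f
        list(resolved = resolved, drug = drug)
      })
    })
  }
  part_names <- c(pli = "liver", pki = "kidney", psp = "spleen",
                  phe = "heart", plu = "lung", pmu = "muscle",
                  pfa = "fat", pbr = "brain", pre = "rest")
  for (nm in names(part_names)) {
    local({
      tis <- part_names[[nm]]
      add(nm, bquote(drug$partition[[.(tis)]]),
          function(resolved, drug, f) {
            drug$partition[[tis]] <- drug$partition[[tis]] * f
            list(resolved = resolved, drug = drug)
          })
    })
  }
  perm_names <- c(ppmu = "muscle", ppfa = "fat", ppbr = "brain",
                  ppre = "rest")
  for (nm in names(perm_names)) {
    local({
      tis <- perm_names[[nm]]
      add(nm, bquote(drug$permeability_fraction[[.(tis)]]),
          function(resolved, drug, f) {
            drug$permeability_fraction[[tis]] <-
              drug$permeability_fraction[[tis]] * f
            list(resolved = resolved, drug = drug)
          })
    })
  }
  # Plasma protein binding, active only when a bound fraction exists.
  if (drug$free_fraction < 1) {
    add("pbind", quote(1 - drug$free_fraction),
        function(resolved, drug, f) {
          drug$free_fraction <- 1 - f * (1 - drug$free_fraction)
          list(resolved = resolved, drug = drug)
        })
  }
  reg
}

#' Names of the perturbable model parameters
#'
#' @param drug A [drug_params()] (the binding parameter is listed only
#'   when `free_fraction < 1`).
#' @return Character vector of parameter names accepted by
#'   [sensitivity_table()].
#' @export
sensitivity_parameters <- function(drug = drug_params()) {
  names(sens_parameter_registry(drug))
}

#' Local sensitivity sweep of the PBPK model
#'
#' Computes the normalized sensitivity coefficient of one or more model
#' output functionals with respect to every (active) model parameter by
#' relative finite differences.  The default functional is the output
#' concentration at a fixed time in the post-exposure (withdrawal)
#' period, since the sensitivity screen targets the residue-depletion
#' phase; exposure-window AUC and Cmax functionals are available.
#'
#' @param physiology A [physio_profile()].
#' @param drug A [drug_params()].
#' @param regimen Dosing regimen; defaults to 28 daily oral doses of
#'   1 mg/kg.
#' @param outputs Output matrices to analyze.
#' @param parameters Parameter names (see [sensitivity_parameters()]);
#'   `NULL` for all.
#' @param delta_fraction Relative perturbation (default 0.01).
#' @param functional `"conc_post"` (concentration at
#'   `time_post` hours after the last dose), `"auc_window"` (AUC from 0
#'   to one day after the last dose) or `"cmax"`.
#' @param time_post Post-exposure evaluation time (h after last dose).
#' @param method Difference scheme, see [sensitivity_coefficient()].
#' @param options A [pbpk_options()].
#' @return Data frame with columns `output`, `parameter`, `base_value`,
#'   `f_base`, `sc`, `nsc`, `sensitive` (`|nsc| >= 0.25`) and
#'   `delta_fraction`, sorted by `|nsc|` within output.  Parameters
#'   whose perturbed simulation fails are recorded with `NA` and
#'   skipped.
#' @export
sensitivity_table <- function(physiology, drug,
                              regimen = daily_oral_regimen(
                                28, 1, physiology$body_mass),
                              outputs = c("plasma", "liver", "kidney"),
                              parameters = NULL,
                              delta_fraction = 0.01,
                              functional = c("conc_post", "auc_window",
                                             "cmax"),
                              time_post = 168,
                              method = c("forward", "central"),
                              options = pbpk_options()) {
  functional <- match.arg(functional)
  method <- match.arg(method)
  resolved <- resolve_physiology(physiology)
  reg <- sens_parameter_registry(drug)
  if (is.null(parameters)) parameters <- names(reg)
  unknown <- setdiff(parameters, names(reg))
  if (length(unknown) > 0)
    stop("sensitivity_table: unknown parameter(s): ",
         paste(unknown, collapse = ", "))

  t_last <- max(regimen$time)
  t_end <- switch(functional,
                  conc_post = t_last + time_post + 24,
                  t_last + 48)
  grid <- seq(0, t_end, by = 1)

  eval_outputs <- function(res, dr) {
    tc <- simulate_pbpk(res, dr, regimen, t_end, output_grid = grid,
                        options = options)
    vapply(outputs, function(out) {
      y <- tc$conc[, out]
      switch(functional,
             conc_post = y[match(t_last + time_post, tc$times)],
             cmax = max(y),
             auc_window = {
               keep <- tc$times <= t_last + 24
               sum(diff(tc$times[keep]) *
                     (y[keep][-1] + y[keep][-sum(keep)]) / 2)
             })
    }, numeric(1))
  }

  f_base <- eval_outputs(resolved, drug)

  rows <- list()
  for (par in parameters) {
    entry <- reg[[par]]
    base_val <- eval(entry$base,
                     list(resolved = resolved, drug = drug))
    f_up <- tryCatch({
      mod <- entry$apply(resolved, drug, 1 + delta_fraction)
      eval_outputs(mod$resolved, mod$drug)
    }, error = function(e) e)
    if (inherits(f_up, "error")) {
      warning("sensitivity_table: parameter '", par, "' skipped: ",
              conditionMessage(f_up))
      rows[[par]] <- data.frame(output = outputs, parameter = par,
                                base_value = base_val, f_base = f_base,
                                sc = NA_real_, nsc = NA_real_,
                                sensitive = NA,
                                delta_fraction = delta_fraction)
      next
    }
    if (method == "central") {
      mod <- entry$apply(resolved, drug, 1 - delta_fraction)
      f_dn <- eval_outputs(mod$resolved, mod$drug)
      sc <- (f_up - f_dn) / (2 * delta_fraction * base_val)
    } else {
      sc <- (f_up - f_base) / (delta_fraction * base_val)
    }
    nsc_val <- sc * base_val / f_base
    rows[[par]] <- data.frame(output = outputs, parameter = par,
                              base_value = base_val, f_base = f_base,
                              sc = sc, nsc = nsc_val,
                              sensitive = abs(nsc_val) >= 0.25,
                              delta_fraction = delta_fraction,
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$output, -abs(out$nsc)), ]
}
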