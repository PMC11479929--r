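# State layout of the ODE system.  All states are drug AMOUNTS (ug), never
# concentrations, so that conservation of mass is directly assertable:
# the sum of all states equals the cumulative administered dose at all
# times.  Concentrations are derived on output.
STATE_NAMES <- c(
  "gastric", "intestine", "feces",
  "liver", "spleen", "kidney", "heart", "lung",
  "arterial", "venous",
  "muscle_blood", "muscle_tissue", "fat_blood", "fat_tissue",
  "brain_blood", "brain_tissue", "rest_blood", "rest_tissue",
  "hepatic_eliminated", "urine")

#' Empty state vector
#'
#' @return Named numeric vector of 20 zero amounts (ug), one per model
#'   compartment or cumulative sink.
#' @export
empty_state <- function() {
  stats::setNames(numeric(length(STATE_NAMES)), STATE_NAMES)
}

#' Oral bioavailability from absorption rate constants
#'
#' The fraction of an oral dose absorbed from the intestine,
#' `F = Ka / (Ka + Kgut)`: intestinal absorption competes with first-order
#' fecal loss.
#'
#' @param drug A [drug_params()], or a single numeric `k_absorption`.
#' @param k_gut Fecal loss rate constant (1/h); only used when `drug` is
#'   numeric.
#' @return Dimensionless fraction in `[0, 1]`.
#' @export
#' @examples
#' bioavailability(drug_params())          # 0.5224 at the fitted values
#' bioavailability(0.9861, 0.9016)
bioavailability <- function(drug, k_gut = NULL) {
  if (inherits(drug, "drug_params")) {
    ka <- drug$k_absorption; kg <- drug$k_gut
  } else {
    ka <- drug; kg <- k_gut
  }
  if (ka + kg <= 0)
    stop("bioavailability: Ka + Kgut must be > 0", call. = FALSE)
  ka / (ka + kg)
}

#' Build the mass-balance coefficient matrix
#'
#' The model is linear in the drug amounts, so the whole right-hand side
#' is `dA/dt = M A` with a constant matrix `M`.  Each flow term appears
#' exactly once as a source and once as a sink (every column of `M` sums
#' to zero), which makes drug mass conserved by construction even when a
#' perturbation analysis unbalances the blood flows.
#'
#' Structure, per compartment (amounts `A`, concentrations `C = A/V`):
#' gastric emptying at `Kst`; intestinal absorption into the liver and
#' fecal loss; flow-limited liver (arterial plus splenic inflow, venous
#' outflow at `Cli/Pli`, hepatic elimination `Clhe*Pfree*Cli/Pli`),
#' spleen, kidney (renal elimination `Clre*Pfree*Cki/Pki` to urine),
#' heart, and lung (fed by venous blood); membrane-limited muscle, fat,
#' brain and remaining tissue as vascular/cellular sub-compartment pairs
#' exchanging at `Pa_i*(C_blood - C_tissue/P_i)`; arterial blood fed by
#' the lung and drained by all regional flows; venous blood collecting
#' all tissue outflows.
#'
#' Two typographical repairs to the printed equation table are applied:
#' the liver accumulation volume is `Vli` (not the blood volume), and the
#' spleen/kidney/heart rows use `Q*(Cab - C/P)`; the brain row mirrors
#' the muscle row with brain symbols throughout.
#'
#' @param physiology An [resolve_physiology()] result.
#' @param drug A [drug_params()].
#' @param options A [pbpk_options()].
#' @return A 20 x 20 matrix with rows/columns named by state.
#' @export
pbpk_matrix <- function(physiology, drug, options = pbpk_options()) {
  if (!inherits(physiology, "absolute_physiology"))
    stop("pbpk_matrix: physiology must be resolved (resolve_physiology)")
  V <- physiology$volumes
  Q <- physiology$flows
  P <- drug$partition
  bw <- physiology$body_mass

  cl_he <- drug$cl_hepatic * bw * drug$free_fraction
  cl_re <- drug$cl_renal * bw * drug$free_fraction
  ka <- drug$k_absorption
  kgut <- drug$k_gut
  kst <- drug$k_stomach

  # Permeability-area cross-flows for the membrane-limited tissues.
  pa <- vapply(MEMBRANE_LIMITED, function(tis) {
    switch(options$permeability_mode,
           flow = drug$permeability_fraction[[tis]] * Q[[tis]],
           absolute = drug$permeability_fraction[[tis]] * bw)
  }, numeric(1))

  n <- length(STATE_NAMES)
  M <- matrix(0, n, n, dimnames = list(STATE_NAMES, STATE_NAMES))

  # --- GI tract ---
  M["gastric", "gastric"] <- -kst
  M["intestine", "gastric"] <- kst
  if (options$absorption_form == "standard") {
    ka_liver <- ka            # absorbed flux Ka*Ainc
    M["intestine", "intestine"] <- -(kgut + ka)
  } else {                    # literal printed form: F inside both rows
    f <- ka / (ka + kgut)
    ka_liver <- f * ka
    M["intestine", "intestine"] <- -(kgut + f * ka)
  }
  M["feces", "intestine"] <- kgut
  M["liver", "intestine"] <- ka_liver

  # --- liver (flow-limited, arterial + splenic inflow, metabolism) ---
  k_li_out <- 1 / (V[["liver"]] * P[["liver"]])
  M["liver", "arterial"] <- M["liver", "arterial"] +
    Q[["liver_arterial"]] / V[["arterial"]]
  M["liver", "spleen"] <- Q[["spleen"]] / (V[["spleen"]] * P[["spleen"]])
  M["liver", "liver"] <- -(Q[["liver_total"]] + cl_he) * k_li_out
  M["venous", "liver"] <- Q[["liver_total"]] * k_li_out
  M["hepatic_eliminated", "liver"] <- cl_he * k_li_out

  # --- spleen ---
  M["spleen", "arterial"] <- M["spleen", "arterial"] +
    Q[["spleen"]] / V[["arterial"]]
  M["spleen", "spleen"] <- -Q[["spleen"]] / (V[["spleen"]] * P[["spleen"]])

  # --- kidney (renal elimination to urine) ---
  k_ki_out <- 1 / (V[["kidney"]] * P[["kidney"]])
  M["kidney", "arterial"] <- M["kidney", "arterial"] +
    Q[["kidney"]] / V[["arterial"]]
  M["kidney", "kidney"] <- -(Q[["kidney"]] + cl_re) * k_ki_out
  M["venous", "kidney"] <- Q[["kidney"]] * k_ki_out
  M["urine", "kidney"] <- cl_re * k_ki_out

  # --- heart ---
  M["heart", "arterial"] <- M["heart", "arterial"] +
    Q[["heart"]] / V[["arterial"]]
  M["heart", "heart"] <- -Q[["heart"]] / (V[["heart"]] * P[["heart"]])
  M["venous", "heart"] <- Q[["heart"]] / (V[["heart"]] * P[["heart"]])

  # --- lung (receives the whole venous return) ---
  M["lung", "venous"] <- Q[["lung"]] / V[["venous"]]
  M["lung", "lung"] <- -Q[["lung"]] / (V[["lung"]] * P[["lung"]])
  M["arterial", "lung"] <- Q[["lung"]] / (V[["lung"]] * P[["lung"]])

  # --- membrane-limited tissues ---
  for (tis in MEMBRANE_LIMITED) {
    b <- paste0(tis, "_blood"); tt <- paste0(tis, "_tissue")
    vb <- V[[b]]; vt <- V[[tt]]
    M[b, "arterial"] <- M[b, "arterial"] + Q[[tis]] / V[["arterial"]]
    M[b, b] <- -(Q[[tis]] + pa[[tis]]) / vb
    M[b, tt] <- pa[[tis]] / (vt * P[[tis]])
    M[tt, b] <- pa[[tis]] / vb
    M[tt, tt] <- -pa[[tis]] / (vt * P[[tis]])
    M["venous", b] <- Q[[tis]] / vb
  }

  # --- blood pools ---
  q_out_arterial <- Q[["liver_arterial"]] + Q[["spleen"]] + Q[["kidney"]] +
    Q[["heart"]] + Q[["muscle"]] + Q[["fat"]] + Q[["brain"]] + Q[["rest"]]
  M["arterial", "arterial"] <- -q_out_arterial / V[["arterial"]]
  M["venous", "venous"] <- -Q[["lung"]] / V[["venous"]]

  M
}

#' Mass-balance derivatives
#'
#' Evaluates the right-hand side `dA/dt` (ug/h) at a state.  The sum of
#' all derivatives (compartments plus the fecal, hepatic and urinary
#' sinks) is identically zero: dosing is handled as instantaneous state
#' jumps, never as forcing terms.
#'
#' @param state Named amounts vector as from [empty_state()].
#' @param physiology A [resolve_physiology()] result.
#' @param drug A [drug_params()].
#' @param options A [pbpk_options()].
#' @param matrix Optionally a precomputed [pbpk_matrix()].
#' @return Named numeric vector of derivatives.
#' @export
pbpk_rhs <- function(state, physiology, drug, options = pbpk_options(),
                     matrix = NULL) {
  if (is.null(matrix)) matrix <- pbpk_matrix(physiology, drug, options)
  d <- drop(matrix %*% state[STATE_NAMES])
  if (any(!is.finite(d))) {
    bad <- STATE_NAMES[!is.finite(d)]
    stop("pbpk_rhs: non-finite derivative in compartment(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  stats::setNames(d, STATE_NAMES)
}

#' Apply a dosing event to a state
#'
#' Oral doses are added to the gastric contents; intravenous doses to
#' venous blood.  All other entries are unchanged.
#'
#' @param state Named amounts vector.
#' @param event A [dose_event()] row (or one-row data frame).
#' @return Updated state vector.
#' @export
apply_dose <- function(state, event) {
  if (is.data.frame(event)) {
    if (nrow(event) != 1) stop("apply_dose: one event at a time")
    route <- event$route; amount <- event$amount
  } else {
    route <- event[["route"]]; amount <- as.numeric(event[["amount"]])
  }
  if (amount < 0) stop("apply_dose: amount must be >= 0")
  target <- switch(route, oral = "gastric", iv = "venous",
                   stop("apply_dose: unknown route '", route, "'"))
  state[[target]] <- state[[target]] + amount
  state
}
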