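#' @keywords internal
"_PACKAGE"

# Compartment name sets used throughout the package.
FLOW_LIMITED  <- c("liver", "spleen", "kidney", "heart", "lung")
MEMBRANE_LIMITED <- c("muscle", "fat", "brain", "rest")
EDIBLE_TISSUES <- c("muscle", "liver", "kidney", "fat")
ALL_TISSUES <- c("liver", "kidney", "spleen", "heart", "lung",
                 "muscle", "fat", "brain", "rest")

#' Goat physiological profile
#'
#' Container for the anatomical and physiological parameters of the goat:
#' body mass, cardiac output, organ weights and regional blood flows as
#' fractions, blood volume and its arterial/venous split, the vascular
#' (blood) fraction of each membrane-limited tissue, and hematocrit.
#' Defaults encode the study animal: a 30 kg goat with literature organ
#' weight and blood flow fractions.
#'
#' Organ masses are expressed as fractions of body weight and blood flows
#' as fractions of cardiac output.  Two compartments have no measured flow
#' fraction of their own: the brain receives `brain_flow_fraction`
#' (carved out of the remaining-tissue flow) and the spleen receives
#' `spleen_flow_fraction` (carved out of the total hepatic inflow, since
#' splenic venous blood drains through the liver).  Blood volume is
#' carved out of the remaining-tissue mass so that masses still sum to 1.
#'
#' @param body_mass Body mass (kg).
#' @param cardiac_output Cardiac output (L/h per kg body weight); this is
#'   the lung (total) blood flow basis.
#' @param organ_mass_fraction Named numeric vector: fraction of body
#'   weight for liver, kidney, muscle, lung, fat, brain, spleen, heart and
#'   the remaining tissue (`rest`).
#' @param organ_flow_fraction Named numeric vector: fraction of cardiac
#'   output for liver (total hepatic inflow, including the splenic
#'   contribution), kidney, muscle, fat, heart and remaining tissue.
#' @param brain_flow_fraction Fraction of cardiac output perfusing the
#'   brain; subtracted from the remaining-tissue flow.
#' @param spleen_flow_fraction Fraction of cardiac output perfusing the
#'   spleen; part of (not additional to) the total hepatic inflow.
#' @param blood_volume_fraction Blood volume as a fraction of body weight;
#'   subtracted from the remaining-tissue mass.
#' @param arterial_fraction Fraction of blood volume that is arterial.
#' @param tissue_blood_fraction Named numeric vector: fraction of each
#'   membrane-limited tissue's volume that is its vascular sub-compartment
#'   (muscle, fat, brain, rest).
#' @param hematocrit Packed cell volume (dimensionless).
#'
#' @return An object of class `physio_profile`.
#' @export
#' @examples
#' phys <- physio_profile()
#' phys$organ_flow_fraction[["liver"]]
physio_profile <- function(body_mass = 30,
                           cardiac_output = 5.97,
                           organ_mass_fraction = c(
                             liver = 0.0129, kidney = 0.0031,
                             muscle = 0.3527, lung = 0.0078,
                             fat = 0.0274, brain = 0.0032,
                             spleen = 0.0028, heart = 0.0035,
                             rest = 0.5866),
                           organ_flow_fraction = c(
                             liver = 0.4832, kidney = 0.1705,
                             muscle = 0.1400, fat = 0.0850,
                             heart = 0.0498, rest = 0.0715),
                           brain_flow_fraction = 0.02,
                           spleen_flow_fraction = 0.02,
                           blood_volume_fraction = 0.07,
                           arterial_fraction = 1 / 3,
                           tissue_blood_fraction = c(
                             muscle = 0.04, fat = 0.02,
                             brain = 0.04, rest = 0.04),
                           hematocrit = 0.30) {
  obj <- structure(list(
    body_mass = as.numeric(body_mass),
    cardiac_output = as.numeric(cardiac_output),
    organ_mass_fraction = unlist(organ_mass_fraction),
    organ_flow_fraction = unlist(organ_flow_fraction),
    brain_flow_fraction = as.numeric(brain_flow_fraction),
    spleen_flow_fraction = as.numeric(spleen_flow_fraction),
    blood_volume_fraction = as.numeric(blood_volume_fraction),
    arterial_fraction = as.numeric(arterial_fraction),
    tissue_blood_fraction = unlist(tissue_blood_fraction),
    hematocrit = as.numeric(hematocrit)),
    class = "physio_profile")
  validate_physio(obj)
  obj
}

validate_physio <- function(p) {
  stop_if <- function(cond, msg) if (cond) stop(msg, call. = FALSE)
  stop_if(!is.finite(p$body_mass) || p$body_mass <= 0,
          "physio_profile: body_mass must be > 0")
  stop_if(!is.finite(p$cardiac_output) || p$cardiac_output <= 0,
          "physio_profile: cardiac_output must be > 0")
  need_mass <- c("liver", "kidney", "muscle", "lung", "fat", "brain",
                 "spleen", "heart", "rest")
  missing_m <- setdiff(need_mass, names(p$organ_mass_fraction))
  stop_if(length(missing_m) > 0,
          paste0("physio_profile: organ_mass_fraction missing: ",
                 paste(missing_m, collapse = ", ")))
  need_flow <- c("liver", "kidney", "muscle", "fat", "heart", "rest")
  missing_f <- setdiff(need_flow, names(p$organ_flow_fraction))
  stop_if(length(missing_f) > 0,
          paste0("physio_profile: organ_flow_fraction missing: ",
                 paste(missing_f, collapse = ", ")))
  fracs <- c(p$organ_mass_fraction, p$organ_flow_fraction,
             brain_flow = p$brain_flow_fraction,
             spleen_flow = p$spleen_flow_fraction,
             blood_volume = p$blood_volume_fraction,
             arterial = p$arterial_fraction,
             p$tissue_blood_fraction,
             hematocrit = p$hematocrit)
  bad <- names(fracs)[!is.finite(fracs) | fracs <= 0 | fracs >= 1]
  stop_if(length(bad) > 0,
          paste0("physio_profile: fractions must lie strictly in (0, 1); ",
                 "violated by: ", paste(bad, collapse = ", ")))
  stop_if(sum(p$organ_mass_fraction) > 1 + 1e-9,
          sprintf("physio_profile: organ mass fractions sum to %.6f > 1",
                  sum(p$organ_mass_fraction)))
  stop_if(p$spleen_flow_fraction >= p$organ_flow_fraction[["liver"]],
          "physio_profile: spleen flow must be below total hepatic flow")
  stop_if(p$brain_flow_fraction >= p$organ_flow_fraction[["rest"]],
          "physio_profile: brain flow must be below remaining-tissue flow")
  stop_if(p$blood_volume_fraction >= p$organ_mass_fraction[["rest"]],
          "physio_profile: blood volume must be below remaining-tissue mass")
  # Brain flow is carved out of rest and spleen flow out of the hepatic
  # total, so the perfused-compartment flows sum to the cardiac output
  # exactly when the six tabulated fractions sum to 1.
  stop_if(abs(sum(p$organ_flow_fraction) - 1) > 1e-9,
          sprintf("physio_profile: organ flow fractions must sum to 1 (got %.10f)",
                  sum(p$organ_flow_fraction)))
  invisible(p)
}

#' Ractopamine drug-specific parameters
#'
#' Container for the compound-specific constants of the model:
#' tissue:plasma partition coefficients, membrane permeability fractions
#' for the four membrane-limited tissues, hepatic and renal clearances,
#' the gastric-emptying (`k_stomach`), intestinal-absorption
#' (`k_absorption`) and fecal-loss (`k_gut`) rate constants, and the free
#' fraction in plasma available for elimination.  Defaults are the fitted
#' final values for ractopamine in the goat.
#'
#' Permeability fractions are converted to permeability-area cross-flows
#' at resolution time: `Pa_i = permeability_fraction[i] * Q_i` (fraction
#' of the tissue's regional blood flow; the usual PBPK convention), or
#' `Pa_i = permeability_fraction[i] * body_mass` when
#' `permeability_mode = "absolute"` (L/h/kg interpretation).
#'
#' @param partition Named numeric vector of tissue:plasma partition
#'   coefficients (liver, kidney, spleen, heart, lung, muscle, fat,
#'   brain, rest).
#' @param permeability_fraction Named numeric vector for muscle, fat,
#'   brain and rest (dimensionless).
#' @param cl_hepatic Hepatic clearance (L/h per kg body weight).
#' @param cl_renal Renal clearance (L/h per kg body weight).
#' @param k_stomach Gastric emptying rate constant (1/h).
#' @param k_absorption Intestinal absorption rate constant (1/h).
#' @param k_gut Fecal loss rate constant from the intestine (1/h).
#' @param free_fraction Unbound fraction in plasma, in (0, 1].
#'
#' @return An object of class `drug_params`.
#' @export
#' @examples
#' drug <- drug_params()
#' bioavailability(drug)   # Ka / (Ka + Kgut)
drug_params <- function(partition = c(
                          liver = 2.5584, kidney = 1.7734,
                          spleen = 1.0047, heart = 1.3839,
                          lung = 1.5333, muscle = 1.0686,
                          fat = 0.7526, brain = 0.6896,
                          rest = 9.0888),
                        permeability_fraction = c(
                          muscle = 0.0271, fat = 0.0054,
                          brain = 0.0068, rest = 0.0021),
                        cl_hepatic = 0.0624,
                        cl_renal = 0.0001,
                        k_stomach = 0.0910,
                        k_absorption = 0.9861,
                        k_gut = 0.9016,
                        free_fraction = 1.0) {
  obj <- structure(list(
    partition = unlist(partition),
    permeability_fraction = unlist(permeability_fraction),
    cl_hepatic = as.numeric(cl_hepatic),
    cl_renal = as.numeric(cl_renal),
    k_stomach = as.numeric(k_stomach),
    k_absorption = as.numeric(k_absorption),
    k_gut = as.numeric(k_gut),
    free_fraction = as.numeric(free_fraction)),
    class = "drug_params")
  validate_drug(obj)
  obj
}

validate_drug <- function(d) {
  stop_if <- function(cond, msg) if (cond) stop(msg, call. = FALSE)
  missing_p <- setdiff(ALL_TISSUES, names(d$partition))
  stop_if(length(missing_p) > 0,
          paste0("drug_params: partition missing: ",
                 paste(missing_p, collapse = ", ")))
  missing_pp <- setdiff(MEMBRANE_LIMITED, names(d$permeability_fraction))
  stop_if(length(missing_pp) > 0,
          paste0("drug_params: permeability_fraction missing: ",
                 paste(missing_pp, collapse = ", ")))
  stop_if(any(!is.finite(d$partition) | d$partition <= 0),
          "drug_params: all partition coefficients must be > 0")
  stop_if(any(!is.finite(d$permeability_fraction) |
                d$permeability_fraction < 0),
          "drug_params: permeability fractions must be >= 0")
  rates <- c(cl_hepatic = d$cl_hepatic, cl_renal = d$cl_renal,
             k_stomach = d$k_stomach, k_absorption = d$k_absorption,
             k_gut = d$k_gut)
  bad <- names(rates)[!is.finite(rates) | rates < 0]
  stop_if(length(bad) > 0,
          paste0("drug_params: rates/clearances must be >= 0; violated by: ",
                 paste(bad, collapse = ", ")))
  stop_if(!is.finite(d$free_fraction) || d$free_fraction <= 0 ||
            d$free_fraction > 1,
          "drug_params: free_fraction must lie in (0, 1]")
  invisible(d)
}

#' Model options
#'
#' Numerical and structural switches for the simulator.
#'
#' @param absorption_form `"standard"` (absorb `Ka*Ainc` into the liver,
#'   lose `Kgut*Ainc` to feces; the absorbed fraction then equals
#'   `Ka/(Ka+Kgut)`) or `"as_printed"` (the literal tabulated form, with
#'   the bioavailability factor `F` inside both the intestinal and hepatic
#'   terms, so the absorbed fraction is `F*Ka/(Kgut+F*Ka)`).
#' @param permeability_mode `"flow"` (`Pa_i` is a fraction of the tissue's
#'   blood flow) or `"absolute"` (`Pa_i` in L/h/kg body weight).
#' @param blood_plasma_ratio Blood:plasma concentration ratio used to
#'   convert venous blood concentration to plasma concentration.
#' @param interp `"linear"` or `"monotone"` (monotone Hermite cubic)
#'   interpolation for [predicted_at()].
#' @param rtol,atol Relative and absolute solver tolerances (atol in ug).
#'
#' @return A list of class `pbpk_options`.
#' @export
pbpk_options <- function(absorption_form = c("standard", "as_printed"),
                         permeability_mode = c("flow", "absolute"),
                         blood_plasma_ratio = 1.0,
                         interp = c("linear", "monotone"),
                         rtol = 1e-8, atol = 1e-10) {
  structure(list(
    absorption_form = match.arg(absorption_form),
    permeability_mode = match.arg(permeability_mode),
    blood_plasma_ratio = as.numeric(blood_plasma_ratio),
    interp = match.arg(interp),
    rtol = rtol, atol = atol), class = "pbpk_options")
}

#' Resolve a physiological profile to absolute volumes and flows
#'
#' Converts fractional organ weights and regional flow fractions into
#' absolute compartment volumes (L; tissue density taken as 1 kg/L) and
#' blood flows (L/h) for a given body mass.  The remaining-tissue mass is
#' reduced by the blood volume and the remaining-tissue flow by the brain
#' flow; the splenic flow is carved out of the total hepatic inflow.  By
#' construction the flows of all perfused compartments sum exactly to the
#' lung (cardiac output) flow.
#'
#' @param profile A [physio_profile()].
#' @return A list of class `absolute_physiology` with elements `volumes`
#'   (L; includes the membrane-limited vascular/cellular split),
#'   `flows` (L/h), `body_mass` and `hematocrit`.
#' @export
#' @examples
#' resolve_physiology(physio_profile())$volumes[["liver"]]   # 0.387 L
resolve_physiology <- function(profile) {
  validate_physio(profile)
  bw <- profile$body_mass
  mf <- profile$organ_mass_fraction
  ff <- profile$organ_flow_fraction

  v_blood <- profile$blood_volume_fraction * bw
  volumes <- c(
    liver = mf[["liver"]] * bw, kidney = mf[["kidney"]] * bw,
    spleen = mf[["spleen"]] * bw, heart = mf[["heart"]] * bw,
    lung = mf[["lung"]] * bw, muscle = mf[["muscle"]] * bw,
    fat = mf[["fat"]] * bw, brain = mf[["brain"]] * bw,
    rest = (mf[["rest"]] - profile$blood_volume_fraction) * bw,
    arterial = profile$arterial_fraction * v_blood,
    venous = (1 - profile$arterial_fraction) * v_blood)
  tbf <- profile$tissue_blood_fraction
  for (tis in MEMBRANE_LIMITED) {
    volumes[[paste0(tis, "_blood")]] <- tbf[[tis]] * volumes[[tis]]
    volumes[[paste0(tis, "_tissue")]] <- (1 - tbf[[tis]]) * volumes[[tis]]
  }

  q_total <- profile$cardiac_output * bw
  flows <- c(
    lung = q_total,
    liver_total = ff[["liver"]] * q_total,
    spleen = profile$spleen_flow_fraction * q_total,
    kidney = ff[["kidney"]] * q_total,
    heart = ff[["heart"]] * q_total,
    muscle = ff[["muscle"]] * q_total,
    fat = ff[["fat"]] * q_total,
    brain = profile$brain_flow_fraction * q_total,
    rest = (ff[["rest"]] - profile$brain_flow_fraction) * q_total)
  flows[["liver_arterial"]] <- flows[["liver_total"]] - flows[["spleen"]]

  structure(list(volumes = volumes, flows = flows, body_mass = bw,
                 hematocrit = profile$hematocrit),
            class = "absolute_physiology")
}

#' Single dosing event
#'
#' @param time Time of administration (h), >= 0.
#' @param route `"oral"` (into gastric contents) or `"iv"` (into venous
#'   blood).
#' @param amount Dose amount (ug), pre-resolved from mg/kg x body mass.
#' @return One-row data frame with columns `time`, `route`, `amount`.
#' @export
dose_event <- function(time, route = c("oral", "iv"), amount) {
  route <- match.arg(route)
  if (!is.finite(time) || time < 0) stop("dose_event: time must be >= 0")
  if (!is.finite(amount) || amount < 0) stop("dose_event: amount must be >= 0")
  data.frame(time = time, route = route, amount = amount,
             stringsAsFactors = FALSE)
}

#' Repeated daily oral regimen
#'
#' Convenience constructor for the residue-depletion dosing scenario:
#' `n_doses` daily oral gavages at `dose_mg_per_kg` mg/kg body weight.
#'
#' @param n_doses Number of daily doses.
#' @param dose_mg_per_kg Dose in mg per kg body weight.
#' @param body_mass Body mass (kg).
#' @param interval Dosing interval (h).
#' @param start Time of the first dose (h).
#' @return Data frame of dose events (amounts in ug).
#' @export
#' @examples
#' daily_oral_regimen(28, 1, 30)   # the 28-day exposure scenario
daily_oral_regimen <- function(n_doses, dose_mg_per_kg, body_mass,
                               interval = 24, start = 0) {
  amount <- dose_mg_per_kg * 1000 * body_mass
  do.call(rbind, lapply(seq_len(n_doses) - 1L, function(i)
    dose_event(start + i * interval, "oral", amount)))
}

#' @rdname daily_oral_regimen
#' @export
single_dose_regimen <- function(dose_mg_per_kg, body_mass,
                                route = c("oral", "iv"), time = 0) {
  dose_event(time, match.arg(route), dose_mg_per_kg * 1000 * body_mass)
}

# ---------------------------------------------------------------------------
# Config file handling (YAML)

#' Load a model configuration file
#'
#' Reads a hierarchical YAML configuration with sections `physiology`,
#' `drug` and `options` and returns validated parameter objects.  Any key
#' omitted from the file is filled from the documented package default and
#' reported via a message (the "load log").
#'
#' @param path Path to a YAML configuration file.
#' @param quiet Suppress the messages listing defaulted keys.
#' @return A list with elements `physiology` ([physio_profile()]),
#'   `drug` ([drug_params()]), `options` ([pbpk_options()]) and
#'   `defaults_used` (character vector of keys that fell back to
#'   defaults).
#' @export
load_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("load_config: no such file: ", path)
  cfg <- tryCatch(yaml::read_yaml(path),
                  error = function(e)
                    stop("load_config: cannot parse ", path, ": ",
                         conditionMessage(e), call. = FALSE))
  if (!is.list(cfg)) stop("load_config: top level must be a mapping")

  take <- function(section, formal_defaults) {
    given <- cfg[[section]]
    if (is.null(given)) given <- list()
    used <- character(0)
    out <- list()
    for (key in names(formal_defaults)) {
      if (!is.null(given[[key]])) {
        val <- given[[key]]
        if (is.list(val)) val <- unlist(val)
        out[[key]] <- val
      } else {
        out[[key]] <- formal_defaults[[key]]
        used <- c(used, paste0(section, ".", key))
      }
    }
    extra <- setdiff(names(given), names(formal_defaults))
    if (length(extra) > 0)
      stop("load_config: unknown key(s) in section '", section, "': ",
           paste(extra, collapse = ", "))
    list(values = out, defaults_used = used)
  }

  phys_defaults <- formals(physio_profile)
  phys_defaults <- lapply(phys_defaults, eval, envir = baseenv())
  drug_defaults <- lapply(formals(drug_params), eval, envir = baseenv())
  opt_defaults <- list(absorption_form = "standard",
                       permeability_mode = "flow",
                       blood_plasma_ratio = 1.0,
                       interp = "linear", rtol = 1e-8, atol = 1e-10)

  ph <- take("physiology", phys_defaults)
  dr <- take("drug", drug_defaults)
  op <- take("options", opt_defaults)

  physiology <- do.call(physio_profile, ph$values)
  drug <- do.call(drug_params, dr$values)
  options <- do.call(pbpk_options, op$values)

  defaults_used <- c(ph$defaults_used, dr$defaults_used, op$defaults_used)
  if (!quiet && length(defaults_used) > 0)
    message("load_config: defaults applied for: ",
            paste(defaults_used, collapse = ", "))
  list(physiology = physiology, drug = drug, options = options,
       defaults_used = defaults_used)
}

#' Serialize a configuration to YAML
#'
#' Round-trip companion of [load_config()]: `load_config(write_config(x))`
#' reproduces all values.
#'
#' @param physiology A [physio_profile()].
#' @param drug A [drug_params()].
#' @param options A [pbpk_options()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(physiology, drug, options = pbpk_options(),
                         path) {
  delist <- function(x) {
    x <- unclass(x)
    lapply(x, function(v) if (length(v) > 1) as.list(v) else v)
  }
  # Full-precision numeric scalars (bit-exact round trip).  A decimal
  # point is enforced so YAML reads the value back as a float, never as
  # an integer or string ("30" -> "30.0", "1e-10" -> "1.0e-10").
  num_handler <- function(v) {
    s <- sprintf("%.17g", v)
    no_dot <- !grepl(".", s, fixed = TRUE)
    s[no_dot] <- ifelse(grepl("e", s[no_dot], fixed = TRUE),
                        sub("e", ".0e", s[no_dot], fixed = TRUE),
                        paste0(s[no_dot], ".0"))
    structure(s, class = "verbatim")
  }
  yaml::write_yaml(list(physiology = delist(physiology),
                        drug = delist(drug),
                        options = delist(options)),
                   path, handlers = list(numeric = num_handler))
  invisible(path)
}
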