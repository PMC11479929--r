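# Dotted-path access to drug_params fields, e.g. "cl_hepatic",
# "partition.liver", "permeability_fraction.rest".  Used by the fitting
# and Monte Carlo population modules.

#' Get or set a drug parameter by dotted path
#'
#' @param drug A [drug_params()].
#' @param path Character path: a scalar field name (`"cl_hepatic"`,
#'   `"k_absorption"`, ...) or `"partition.<tissue>"` /
#'   `"permeability_fraction.<tissue>"`.
#' @param value Replacement value (for `set_drug_param`).
#' @return The numeric value, or the modified `drug_params` object.
#' @export
get_drug_param <- function(drug, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (length(parts) == 1) {
    v <- drug[[parts]]
    if (is.null(v) || length(v) != 1)
      stop("get_drug_param: no scalar field '", path, "'")
    v
  } else if (length(parts) == 2) {
    vec <- drug[[parts[1]]]
    if (is.null(vec) || !parts[2] %in% names(vec))
      stop("get_drug_param: no field '", path, "'")
    vec[[parts[2]]]
  } else stop("get_drug_param: bad path '", path, "'")
}

#' @rdname get_drug_param
#' @export
set_drug_param <- function(drug, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (length(parts) == 1) {
    if (!parts %in% names(drug))
      stop("set_drug_param: no field '", path, "'")
    drug[[parts]] <- as.numeric(value)
  } else if (length(parts) == 2) {
    if (!parts[1] %in% names(drug) ||
        !parts[2] %in% names(drug[[parts[1]]]))
      stop("set_drug_param: no field '", path, "'")
    drug[[parts[1]]][[parts[2]]] <- as.numeric(value)
  } else stop("set_drug_param: bad path '", path, "'")
  validate_drug(drug)
  drug
}
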