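#' Default model parameters
#'
#' Constructs the full parameter set of the coupled P2Y2R--IP3R--P2X7R
#' calcium model. Defaults reproduce the published whole-cell model of
#' ATP-induced Ca2+ signaling in murine osteoblasts: a two-compartment
#' (cytosol/ER) flux-balance model with Li-Rinzel IP3R gating, Hill-type
#' SERCA/PMCA pumps, ATP-driven IP3 production, and a 12-state Markov
#' scheme for P2X7R channel gating.
#'
#' Units: concentrations in uM except `[ATP]`, which is molar (M) throughout
#' the package because the P2X7R binding rates are per molar. Fluxes are
#' uM/s referenced to the cytosolic compartment. `g_X7` is a whole-cell
#' conductance in siemens; `V_mem` and `E` in volts; `V_osteo` in litres.
#'
#' @param ... named overrides of any default value (unknown names error).
#' @return An object of class `ca_params`: a named list of parameters.
#'
#' @details Key groups:
#' * Buffering/geometry: `f_c`, `f_ER` (free Ca2+ fractions, 0 < f_c < f_ER < 1),
#'   `gamma` (cytosol:ER volume ratio).
#' * Plasma membrane: `J_INleak` (constant inward leak, uM/s), `v_PMCA`,
#'   `k_PMCA` (Hill pump).
#' * ER membrane: `v_SERCA`, `k_SERCA`, `v_ERleak` (1/s leak rate).
#' * Li-Rinzel IP3R: dissociation constants `d1`, `d2`, `d3`, `d5` (uM),
#'   inactivation binding rate `a2` (1/(uM s)), `v_IP3R` (uM/s).
#' * P2X7R Markov model: conductance `g_X7` (S), reversal `E` (V), membrane
#'   potential `V_mem` (V), unbinding rates `k1`, `k3`, `k5` (1/s), binding
#'   rates `k2`, `k4`, `k6`, `k7` (1/(M s)), naive/sensitized row exchange
#'   `L1`, `L2`, `L3` (1/s), desensitized-row recovery `H1` (1/s) and
#'   state-dependent desensitization rates `H2_C2 < H2_Q1 < H2_Q2` (1/s),
#'   calcium fraction of current `f_Ca`, cell volume `V_osteo` (L), valence
#'   `z`, Faraday constant `F`.
#' * IP3 dynamics: `alpha_ATP` (uM/s, maximal production), `k_ATP`
#'   (half-maximal `[ATP]`, uM), `delta` (1/s degradation).
#' * Switches: `use_multiplicity` applies statistical binding/unbinding
#'   multiplicity factors (3,2,1 / 1,2,3) along each Markov row (default
#'   `FALSE`); `desensitized_ladder` keeps ATP binding/unbinding transitions
#'   within the desensitized row (default `TRUE`); `g_X7_raw_units`
#'   interprets `g_X7` literally as printed (M/s) instead of as a
#'   whole-cell conductance in siemens (default `FALSE`).
#'
#' @examples
#' p <- model_params()
#' p$v_IP3R
#' p2 <- model_params(v_IP3R = 0) # no CICR
#' @export
model_params <- function(...) {
  p <- list(
    # buffering & scaling
    f_c = 0.01, f_ER = 0.025, gamma = 9,
    # plasma membrane fluxes
    J_INleak = 0.15, v_PMCA = 30, k_PMCA = 0.45,
    # ER fluxes
    v_SERCA = 22.5, k_SERCA = 0.105, v_ERleak = 0.03,
    # Li-Rinzel IP3R
    d1 = 0.13, d2 = 1.049, d3 = 0.9434, d5 = 0.08234,
    a2 = 0.2, v_IP3R = 15,
    # P2X7R Markov model
    g_X7 = 2.5e-8, E = 0, V_mem = -0.06,
    k1 = 0.3, k2 = 1265, k3 = 2.4, k4 = 1581, k5 = 1.58, k6 = 221, k7 = 316,
    L1 = 1e-4, L2 = 0.004, L3 = 0.3,
    H1 = 0.001, H2_C2 = 0.01, H2_Q1 = 0.05, H2_Q2 = 0.8,
    f_Ca = 0.046, V_osteo = 6.5e-12, z = 2, F = 96485,
    # IP3 dynamics
    alpha_ATP = 0.03, k_ATP = 1, delta = 0.01,
    # structural switches
    use_multiplicity = FALSE,
    desensitized_ladder = TRUE,
    g_X7_raw_units = FALSE
  )
  ov <- list(...)
  if (length(ov)) {
    if (is.null(names(ov)) || any(names(ov) == ""))
      stop("all parameter overrides must be named")
    unknown <- setdiff(names(ov), names(p))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    p[names(ov)] <- ov
  }
  class(p) <- "ca_params"
  validate_params(p)
  p
}

#' Validate a parameter set
#'
#' Checks positivity, buffering-fraction ordering (0 < f_c < f_ER < 1) and
#' the desensitization-rate ordering H2_C2 < H2_Q1 < H2_Q2 (desensitization
#' accelerates with ATP occupancy).
#'
#' @param p a `ca_params` object.
#' @return `p`, invisibly; errors on violation.
#' @export
validate_params <- function(p) {
  stopifnot(inherits(p, "ca_params"))
  pos <- c("f_c", "f_ER", "gamma", "k_PMCA", "v_SERCA", "k_SERCA",
           "d1", "d2", "d3", "d5", "a2",
           "k1", "k2", "k3", "k4", "k5", "k6", "k7",
           "L1", "L2", "L3", "H1", "H2_C2", "H2_Q1", "H2_Q2",
           "f_Ca", "V_osteo", "F", "k_ATP", "delta")
  bad <- pos[vapply(pos, function(nm) !(is.numeric(p[[nm]]) && p[[nm]] > 0), logical(1))]
  if (length(bad))
    stop("parameters must be strictly positive: ", paste(bad, collapse = ", "))
  if (!(p$f_c > 0 && p$f_c < p$f_ER && p$f_ER < 1))
    stop("buffering fractions must satisfy 0 < f_c < f_ER < 1")
  if (!(p$H2_C2 < p$H2_Q1 && p$H2_Q1 < p$H2_Q2))
    stop("desensitization rates must satisfy H2_C2 < H2_Q1 < H2_Q2")
  # maxima that may legitimately be zeroed in reduced submodels
  nn <- c("J_INleak", "v_PMCA", "v_ERleak", "v_IP3R", "alpha_ATP", "g_X7")
  badn <- nn[vapply(nn, function(nm) !(is.numeric(p[[nm]]) && p[[nm]] >= 0), logical(1))]
  if (length(badn))
    stop("parameters must be non-negative: ", paste(badn, collapse = ", "))
  invisible(p)
}

#' @export
print.ca_params <- function(x, ...) {
  cat("<ca_params> P2Y2/P2X7 calcium model parameters\n")
  num <- x[vapply(x, is.numeric, logical(1))]
  print(unlist(num))
  cat("switches: use_multiplicity =", x$use_multiplicity,
      "| desensitized_ladder =", x$desensitized_ladder,
      "| g_X7_raw_units =", x$g_X7_raw_units, "\n")
  invisible(x)
}

#' Read / write parameter configuration files
#'
#' Parameters serialize to a flat key-value mapping in YAML or JSON
#' (chosen by file extension). The file shipped at
#' `system.file("extdata", "default_params.yaml", package = "P2CaSim")`
#' reproduces the published parameter table verbatim.
#'
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @param p a `ca_params` object (for writing).
#' @return `read_params()` returns a `ca_params`; `write_params()` returns
#'   `path` invisibly.
#' @export
read_params <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported config extension: ", ext)
  )
  do.call(model_params, vals)
}

#' @rdname read_params
#' @export
write_params <- function(p, path) {
  validate_params(p)
  vals <- unclass(p)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    yaml = , yml = yaml::write_yaml(vals, path),
    json = jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE),
    stop("unsupported config extension: ", ext)
  )
  invisible(path)
}

# uM/s calcium flux through P2X7R per unit open fraction (positive inward
# for V_mem < E). Collapses Eqs for current and flux: J = -f_Ca I/(z F V),
# I = g (V - E), converted M -> uM once here.
x7_flux_coefficient <- function(p) {
  if (isTRUE(p$g_X7_raw_units)) {
    # literal reading of the printed units (M/s): treat g_X7 as a molar
    # flux scale; per-volt scaling retained for comparability
    return(-p$f_Ca * p$g_X7 * (p$V_mem - p$E) * 1e6)
  }
  I_per_open <- p$g_X7 * (p$V_mem - p$E)      # amperes at sum(Q) = 1
  -p$f_Ca * I_per_open / (p$z * p$F * p$V_osteo) * 1e6
}
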