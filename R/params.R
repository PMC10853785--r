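#' Circuit kinetic and regulatory parameters
#'
#' Bundles every kinetic constant of the self-activation switch with an
#' auxiliary repressive link: basal and regulated AraC production, TetR
#' production, intrinsic degradation, the AraC--pBad binding activity bounds
#' and their L-arabinose dependence, the TetR repression gate and its aTc
#' dependence, and the cellular burden factors that couple protein load to
#' host growth.
#'
#' Concentrations are in arbitrary per-cell units (the ON-state AraC level is
#' of order one under the defaults), time is in hours, L-arabinose doses are
#' percent (w/v) and aTc doses are ng/ml.
#'
#' @param k0_a Basal AraC production rate (conc/h).
#' @param k1_a Maximal regulated AraC production rate (conc/h).
#' @param k0_t TetR production rate (conc/h).
#' @param db_a,db_t Intrinsic (basal) degradation rate constants for AraC and
#'   TetR (1/h); growth adds a dilution term on top of these.
#' @param C_min,C_max Minimum and maximum AraC--pBad binding activity
#'   (1/conc^2); `C_max >= C_min >= 0`.
#' @param K_a L-arabinose half-activation constant (percent).
#' @param n L-arabinose Hill coefficient (dimensionless).
#' @param lam Repression gate: 0 disables the TetR arm (control circuit),
#'   positive values enable it (experimental circuit).
#' @param K_t TetR--promoter binding constant (conc).
#' @param K_aTc aTc--TetR binding constant (ng/ml).
#' @param m aTc--TetR Hill coefficient.
#' @param n_t TetR--promoter Hill coefficient.
#' @param J_a,J_t Cellular burden factors for AraC and TetR (conc); the two
#'   proteins are assumed to load the host roughly equally, so the defaults
#'   are identical.
#'
#' @return An object of class `circuit_params` (a validated named list).
#' @seealso [growth_params()], [inducers()], [default_circuit()]
#' @examples
#' p <- circuit_params()              # experimental circuit defaults
#' p0 <- circuit_params(lam = 0)      # control circuit: repression inert
#' @export
circuit_params <- function(k0_a = 0.0061, k1_a = 0.394, k0_t = 0.164,
                           db_a = 0.164, db_t = 0.164,
                           C_min = 0.05, C_max = 118, K_a = 8e-3, n = 2,
                           lam = 2.49, K_t = 1, K_aTc = 20, m = 2, n_t = 4,
                           J_a = 60, J_t = 60) {
  p <- list(k0_a = k0_a, k1_a = k1_a, k0_t = k0_t,
            db_a = db_a, db_t = db_t,
            C_min = C_min, C_max = C_max, K_a = K_a, n = n,
            lam = lam, K_t = K_t, K_aTc = K_aTc, m = m, n_t = n_t,
            J_a = J_a, J_t = J_t)
  validate_circuit_params(p)
  structure(p, class = "circuit_params")
}

validate_circuit_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (nm in names(p)) {
    if (!num1(p[[nm]])) stop("parameter '", nm, "' must be a single finite number")
    if (p[[nm]] < 0) stop("parameter '", nm, "' must be nonnegative")
  }
  for (nm in c("K_a", "K_t", "K_aTc", "J_a", "J_t")) {
    if (p[[nm]] <= 0) stop("parameter '", nm, "' must be strictly positive")
  }
  if (p$C_max < p$C_min) stop("C_max must be >= C_min")
  invisible(p)
}

#' Host growth parameters
#'
#' Logistic growth of the cell population: maximum specific growth rate and
#' carrying capacity. Density is normalised so the default carrying capacity
#' is one.
#'
#' @param k_g Maximum specific growth rate (1/h); 0 freezes growth (and with
#'   it growth-dependent dilution).
#' @param N0 Carrying capacity (density units, default 1).
#' @return An object of class `growth_params`.
#' @examples
#' growth_params(k_g = 0.2)   # the measured low-growth condition
#' @export
growth_params <- function(k_g = 0.75, N0 = 1) {
  if (!is.numeric(k_g) || length(k_g) != 1L || !is.finite(k_g) || k_g < 0)
    stop("k_g must be a single finite nonnegative number")
  if (!is.numeric(N0) || length(N0) != 1L || !is.finite(N0) || N0 <= 0)
    stop("N0 must be a single finite positive number")
  structure(list(k_g = k_g, N0 = N0), class = "growth_params")
}

#' Inducer doses
#'
#' @param lara L-arabinose dose (percent, w/v); activates AraC--pBad binding.
#' @param atc aTc dose (ng/ml); deactivates TetR operator binding.
#' @return An object of class `inducers`.
#' @examples
#' inducers(lara = 2.6e-3, atc = 0)
#' @export
inducers <- function(lara = 0, atc = 0) {
  if (!is.numeric(lara) || length(lara) != 1L || !is.finite(lara) || lara < 0)
    stop("lara must be a single finite nonnegative number")
  if (!is.numeric(atc) || length(atc) != 1L || !is.finite(atc) || atc < 0)
    stop("atc must be a single finite nonnegative number")
  structure(list(lara = lara, atc = atc), class = "inducers")
}

#' System state
#'
#' Per-cell AraC (tracked by GFP) and TetR (tracked by RFP) concentrations
#' plus population density.
#'
#' @param araC Per-cell AraC concentration (>= 0).
#' @param tetR Per-cell TetR concentration (>= 0).
#' @param N Population density (0 <= N, nominally <= carrying capacity).
#' @return An object of class `system_state` (named numeric vector).
#' @export
system_state <- function(araC = 0, tetR = 0, N = 1) {
  x <- c(araC = araC, tetR = tetR, N = N)
  if (!all(is.finite(x)) || any(x < 0)) stop("state components must be finite and nonnegative")
  structure(x, class = "system_state")
}

#' Frozen default parameter set
#'
#' Returns the versioned default parameterisation of the circuit. No
#' quantitative parameter table accompanies the published system, so these
#' values are a calibrated set, frozen at package version 0.1.0: they were
#' chosen so that (i) the zero-growth circuit is bistable over an
#' intermediate L-arabinose range inside the experimentally used 0--2.6e-3
#' percent window, and (ii) the growth-rate collapse thresholds of the
#' ON-state dilution assay land at approximately 0.15/h (control) and
#' 0.23/h (experimental). They are a calibrated synthetic convention, not
#' measured constants.
#'
#' @param circuit `"experimental"` (repressive link active, `lam = 2.49`) or
#'   `"control"` (`lam = 0`; tetO replaced by lacO, so TetR cannot bind).
#' @return A `circuit_params` object.
#' @examples
#' default_circuit("control")$lam   # 0
#' @export
default_circuit <- function(circuit = c("experimental", "control")) {
  circuit <- match.arg(circuit)
  circuit_params(lam = if (circuit == "experimental") 2.49 else 0)
}

#' Reference assay conditions
#'
#' The inducer doses and protocol constants used as defaults across the
#' analysis: the fully activating L-arabinose dose, the aTc dose present in
#' the ON-induction medium, the aTc dose held during assays, and the 5
#' ul-into-200 ul loading dilution factor. ON preconditioning uses
#' `lara_high` plus `atc_induction` (aTc-assisted induction); OFF
#' preconditioning uses plain medium; assays run at `atc_assay`.
#'
#' @return A named list with elements `lara_high`, `atc_induction`,
#'   `atc_assay`, `dilution_factor`.
#' @export
assay_defaults <- function() {
  list(lara_high = 2.6e-3, atc_induction = 40, atc_assay = 20,
       dilution_factor = 41)
}

#' @export
print.circuit_params <- function(x, ...) {
  cat("Circuit parameters (", if (x$lam > 0) "experimental: repression active"
      else "control: repression inert", ")\n", sep = "")
  v <- unlist(x)
  cat(paste0("  ", format(names(v), width = 6), " = ", signif(v, 6), collapse = "\n"), "\n")
  invisible(x)
}

#' @export
print.growth_params <- function(x, ...) {
  cat("Growth: k_g =", x$k_g, "/h, carrying capacity N0 =", x$N0, "\n")
  invisible(x)
}

#' Read model configuration from a YAML/JSON file
#'
#' A flat key-to-number mapping. Keys are partitioned into circuit parameters
#' (see [circuit_params()]) and growth parameters (`k_g`, `N0`). Unknown keys
#' are an error; keys absent from the file fall back to the documented
#' defaults with a warning naming them.
#'
#' @param path Path to a YAML (or JSON; YAML is a superset) file.
#' @return A list with elements `params` (`circuit_params`) and `growth`
#'   (`growth_params`).
#' @seealso [write_config()]
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a mapping of keys to numbers")
  circuit_keys <- names(formals(circuit_params))
  growth_keys <- c("k_g", "N0")
  unknown <- setdiff(names(cfg), c(circuit_keys, growth_keys))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  missing <- setdiff(c(circuit_keys, growth_keys), names(cfg))
  if (length(missing))
    warning("config keys missing, using defaults: ", paste(missing, collapse = ", "))
  p <- do.call(circuit_params, cfg[intersect(names(cfg), circuit_keys)])
  g <- do.call(growth_params, cfg[intersect(names(cfg), growth_keys)])
  list(params = p, growth = g)
}

#' Write model configuration to a YAML file
#'
#' @param params A `circuit_params` object.
#' @param growth A `growth_params` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(params, growth, path) {
  stopifnot(inherits(params, "circuit_params"), inherits(growth, "growth_params"))
  yaml::write_yaml(c(unclass(params), unclass(growth)), path)
  invisible(path)
}
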