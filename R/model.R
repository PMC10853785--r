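#' Self-activation Hill function
#'
#' Activating Hill term for AraC binding its own pBad promoter,
#' `F_A = S_a * A^2 / (1 + S_a * A^2)`. The cooperativity exponent is fixed
#' at 2 (it is part of the model structure, not a tunable parameter).
#'
#' @param araC AraC concentration(s), >= 0 (vectorised).
#' @param S_a Binding activity between AraC and the promoter, >= 0; see
#'   [s_A()] for its L-arabinose dependence.
#' @return Values in `[0, 1)`, monotone nondecreasing in both arguments.
#' @examples
#' f_A(1, 1)          # 0.5
#' f_A(0, 10)         # 0
#' @export
f_A <- function(araC, S_a) {
  if (any(araC < 0) || any(S_a < 0)) stop("f_A: inputs must be nonnegative")
  x <- S_a * araC^2
  x / (1 + x)
}

#' Repressive Hill function of TetR, tunable by aTc
#'
#' Repression of the pBad-tetO promoter by TetR,
#' `F_T = 1 / (1 + (lam * T / (K_t * (1 + (aTc/K_aTc) * (K_t/T))^m))^n_t)`.
#' aTc sequesters TetR and so raises `F_T` back towards 1. With `lam = 0`
#' (control circuit, lacO instead of tetO) the function is identically 1.
#'
#' The closed form is singular when evaluated naively at `tetR = 0` with
#' `atc > 0` (a 0 * Inf product); its limit there is 1, and concentrations
#' below 1e-12 are mapped to that limit.
#'
#' @param tetR TetR concentration(s), >= 0 (vectorised).
#' @param atc aTc dose (ng/ml), >= 0.
#' @param params A [circuit_params()] object (uses `lam`, `K_t`, `K_aTc`,
#'   `m`, `n_t`).
#' @return Values in `(0, 1]`; nonincreasing in `tetR`, nondecreasing in
#'   `atc`.
#' @examples
#' p <- circuit_params(lam = 1, m = 1, n_t = 1)
#' f_T(p$K_t, 0, p)   # 0.5
#' @export
f_T <- function(tetR, atc, params) {
  if (any(tetR < 0) || any(atc < 0)) stop("f_T: inputs must be nonnegative")
  if (params$lam == 0) return(rep(1, length(tetR)))
  out <- rep(1, length(tetR))
  live <- tetR >= 1e-12
  if (any(live)) {
    tt <- tetR[live]
    u <- params$lam * tt /
      (params$K_t * (1 + (atc / params$K_aTc) * (params$K_t / tt))^params$m)
    out[live] <- 1 / (1 + u^params$n_t)
  }
  out
}

#' L-arabinose-dependent AraC binding activity
#'
#' Interpolates the AraC--pBad binding activity between its minimum and
#' maximum as a Hill function of the L-arabinose dose:
#' `S_a = C_min + (C_max - C_min) * L^n / (L^n + K_a^n)`.
#'
#' @param lara L-arabinose dose(s) (percent), >= 0 (vectorised).
#' @param params A [circuit_params()] object (uses `C_min`, `C_max`, `K_a`,
#'   `n`).
#' @return Binding activity in `[C_min, C_max]`.
#' @export
s_A <- function(lara, params) {
  if (any(lara < 0)) stop("s_A: lara must be nonnegative")
  h <- lara^params$n / (lara^params$n + params$K_a^params$n)
  params$C_min + (params$C_max - params$C_min) * h
}

#' Cellular burden factor on host growth
#'
#' The factor `F_g = 1 / (1 + araC/J_a + tetR/J_t)` by which circuit protein
#' load slows host growth: unity when the circuit is inactive (both proteins
#' zero) and monotonically decreasing in each protein concentration.
#'
#' @param araC,tetR Protein concentrations, >= 0 (vectorised).
#' @param params A [circuit_params()] object (uses `J_a`, `J_t`).
#' @return Values in `(0, 1]`.
#' @export
f_G <- function(araC, tetR, params) {
  if (any(araC < 0) || any(tetR < 0)) stop("f_G: inputs must be nonnegative")
  1 / (1 + araC / params$J_a + tetR / params$J_t)
}

#' Population growth rate (burden-coupled logistic)
#'
#' `dN/dt = k_g * F_g * (1 - N/N0) * N`.
#'
#' @param state A [system_state()] (or named vector with `araC`, `tetR`, `N`).
#' @param params A [circuit_params()] object.
#' @param growth A [growth_params()] object.
#' @return Growth rate in density/h; nonnegative for `N` in `[0, N0]`.
#' @export
growth_rate <- function(state, params, growth) {
  fg <- f_G(state[["araC"]], state[["tetR"]], params)
  growth$k_g * fg * (1 - state[["N"]] / growth$N0) * state[["N"]]
}

#' Growth-dependent dilution rate
#'
#' The specific rate `(1/N) dN/dt = k_g * F_g * (1 - N/N0)` at which per-cell
#' protein is diluted by population expansion. It augments the intrinsic
#' degradation of each protein: `d_eff = d_b + dilution`. At `N = 0` the
#' continuous limit `k_g * F_g` is returned.
#'
#' @inheritParams growth_rate
#' @return Dilution rate (1/h), always >= 0 for `N <= N0`.
#' @export
dilution_rate <- function(state, params, growth) {
  fg <- f_G(state[["araC"]], state[["tetR"]], params)
  growth$k_g * fg * (1 - state[["N"]] / growth$N0)
}

#' Right-hand side of the coupled circuit/growth ODE system
#'
#' The three coupled equations:
#' `d(araC)/dt = k0_a + k1_a * F_A * F_T - (db_a + dilution) * araC`,
#' `d(tetR)/dt = k0_t - (db_t + dilution) * tetR`,
#' `dN/dt = k_g * F_g * (1 - N/N0) * N`.
#' Reporter proteins (GFP for AraC, RFP for TetR) are assumed to track their
#' targets, so only the two regulator concentrations are modelled.
#'
#' @param state Named numeric vector or [system_state()] with `araC`,
#'   `tetR`, `N`.
#' @param induc An [inducers()] object.
#' @param params A [circuit_params()] object.
#' @param growth A [growth_params()] object.
#' @return Named numeric vector of derivatives (`araC`, `tetR`, `N`).
#' @export
rhs <- function(state, induc, params, growth) {
  a <- state[["araC"]]; t <- state[["tetR"]]; N <- state[["N"]]
  if (any(!is.finite(c(a, t, N)))) stop("rhs: non-finite state")
  dil <- dilution_rate(state, params, growth)
  sa <- s_A(induc$lara, params)
  da <- params$k0_a + params$k1_a * f_A(a, sa) * f_T(t, induc$atc, params) -
    (params$db_a + dil) * a
  dt <- params$k0_t - (params$db_t + dil) * t
  dN <- growth_rate(state, params, growth)
  if (any(!is.finite(c(da, dt, dN)))) stop("rhs: non-finite derivative")
  c(araC = da, tetR = dt, N = dN)
}
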