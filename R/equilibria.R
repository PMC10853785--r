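#' Rate-balance curves and their intersections
#'
#' At a saturated, non-growing population (`N = N0`, dilution zero) the TetR
#' equation decouples and settles at `tetR* = k0_t/db_t`, leaving a
#' one-dimensional balance for AraC: production
#' `P(a) = k0_a + k1_a * F_A(a, S_a(lara)) * F_T(tetR*, atc)` against linear
#' degradation `D(a) = d_eff * a`. The intersections of the two curves are
#' the steady states; a bistable dose shows three, a monostable dose one.
#'
#' @param params A [circuit_params()] object.
#' @param lara L-arabinose dose (percent).
#' @param atc aTc dose (ng/ml).
#' @param d_eff Effective degradation rate (1/h); `db_a` for zero growth,
#'   larger values emulate growth-enhanced dilution.
#' @param araC_grid Strictly increasing grid on which the curves are
#'   evaluated; defaults to 1000 log-spaced points spanning the feasible
#'   root interval `[k0_a/d_eff, (k0_a + k1_a)/d_eff]` (widened 100-fold
#'   below and 2-fold above).
#' @return A list with `grid`, `production`, `degradation`
#'   (vectors on the grid) and `intersections` (roots of `P - D`, polished
#'   by bisection to 1e-12 relative).
#' @export
rate_balance <- function(params, lara, atc = 0, d_eff = params$db_a,
                         araC_grid = NULL) {
  tetR_star <- params$k0_t / params$db_t
  if (is.null(araC_grid)) {
    lo <- params$k0_a / d_eff / 100
    hi <- 2 * (params$k0_a + params$k1_a) / d_eff
    araC_grid <- exp(seq(log(max(lo, 1e-12)), log(hi), length.out = 1000))
  }
  if (!length(araC_grid)) stop("araC_grid must be nonempty")
  if (is.unsorted(araC_grid, strictly = TRUE)) stop("araC_grid must be strictly increasing")
  ft <- f_T(tetR_star, atc, params)
  prod_fn <- function(a) params$k0_a + params$k1_a * f_A(a, s_A(lara, params)) * ft
  production <- prod_fn(araC_grid)
  degradation <- d_eff * araC_grid
  net <- function(a) prod_fn(a) - d_eff * a
  resid <- production - degradation
  roots <- numeric(0)
  s <- sign(resid)
  for (i in seq_len(length(araC_grid) - 1L)) {
    if (s[i] == 0) { roots <- c(roots, araC_grid[i]); next }
    if (s[i] * s[i + 1L] < 0) {
      r <- stats::uniroot(net, lower = araC_grid[i], upper = araC_grid[i + 1L],
                          tol = 1e-12 * max(1, araC_grid[i + 1L]))
      roots <- c(roots, r$root)
    }
  }
  if (s[length(s)] == 0) roots <- c(roots, araC_grid[length(araC_grid)])
  list(grid = araC_grid, production = production, degradation = degradation,
       intersections = sort(unique(roots)))
}

#' Zero-growth fixed points of the switch
#'
#' All steady states of the AraC balance at `N = N0` with `d_eff = db_a`,
#' with linear stability read off the slope of the net rate (negative slope
#' means stable). A bistable dose yields the ordered triple
#' stable < unstable < stable.
#'
#' @inheritParams rate_balance
#' @return A data frame with columns `araC`, `tetR`, `stability`
#'   (`"stable"`/`"unstable"`), ordered by `araC`.
#' @export
fixed_points <- function(params, lara, atc = 0) {
  rb <- rate_balance(params, lara, atc)
  tetR_star <- params$k0_t / params$db_t
  ft <- f_T(tetR_star, atc, params)
  net <- function(a) params$k0_a +
    params$k1_a * f_A(a, s_A(lara, params)) * ft - params$db_a * a
  roots <- rb$intersections
  slope <- vapply(roots, function(a) {
    da <- max(1e-8, 1e-6 * a)
    (net(a + da) - net(max(a - da, 0))) / (a + da - max(a - da, 0))
  }, 0)
  data.frame(araC = roots, tetR = tetR_star,
             stability = ifelse(slope < 0, "stable", "unstable"))
}

#' Separatrix of the zero-growth switch
#'
#' The unstable fixed point's AraC level when the dose is bistable: initial
#' conditions above it are drawn to the high attractor and below it to the
#' low attractor under zero-growth dynamics. `NA` when monostable.
#'
#' @inheritParams rate_balance
#' @return A single numeric AraC threshold, or `NA_real_`.
#' @export
separatrix <- function(params, lara, atc = 0) {
  fp <- fixed_points(params, lara, atc)
  u <- fp$araC[fp$stability == "unstable"]
  if (length(u) == 1L) u else NA_real_
}

#' ON/OFF classification threshold
#'
#' The zero-growth separatrix at the assay dose; where the assay dose is
#' monostable, the geometric mean of the two stable AraC levels at a
#' reference bistable dose (the midpoint of the zero-growth bistable region,
#' or the assay-defaults dose if none is found).
#'
#' @inheritParams rate_balance
#' @return A positive AraC threshold.
#' @export
classification_threshold <- function(params, lara, atc = 0) {
  sep <- separatrix(params, lara, atc)
  if (!is.na(sep)) return(sep)
  ref <- tryCatch({
    reg <- static_bistable_region(params, atc)
    if (reg$width > 0) (reg$lower + reg$upper) / 2 else NA_real_
  }, error = function(e) NA_real_)
  if (is.na(ref)) ref <- assay_defaults()$lara_assay
  fp <- fixed_points(params, ref, atc)
  st <- fp$araC[fp$stability == "stable"]
  if (length(st) >= 2L) return(sqrt(st[1L] * st[length(st)]))
  # degenerate: no bistable reference either; fall back to the single
  # attractor bracketed geometrically between basal and maximal levels
  sqrt((params$k0_a / params$db_a) * ((params$k0_a + params$k1_a) / params$db_a))
}

#' Static (zero-growth) bistable dose region
#'
#' Dose interval over which the zero-growth switch has three fixed points,
#' located by sign changes of the root count over a fine dose grid and
#' refined by bisection on the saddle-node boundaries.
#'
#' @inheritParams rate_balance
#' @param dose_max Upper end of the dose search range (percent).
#' @param n_grid Dose grid resolution for the initial scan.
#' @return A list with `lower`, `upper`, `width` (0 when never bistable).
#' @export
static_bistable_region <- function(params, atc = 0, dose_max = 2.6e-3,
                                   n_grid = 121) {
  doses <- seq(0, dose_max, length.out = n_grid)
  nb <- vapply(doses, function(d) nrow(fixed_points(params, d, atc)), 0L)
  bi <- nb >= 3L
  if (!any(bi)) return(list(lower = NA_real_, upper = NA_real_, width = 0))
  refine <- function(lo, hi, want_bi_at_hi) {
    for (i in 1:40) {
      mid <- (lo + hi) / 2
      if ((nrow(fixed_points(params, mid, atc)) >= 3L) == want_bi_at_hi) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  i1 <- which(bi)[1L]; i2 <- which(bi)[sum(bi)]
  lower <- if (i1 == 1L) doses[1L] else refine(doses[i1 - 1L], doses[i1], TRUE)
  upper <- if (i2 == n_grid) doses[n_grid] else refine(doses[i2 + 1L], doses[i2], TRUE)
  list(lower = lower, upper = upper, width = upper - lower)
}

#' Default L-arabinose dose grid
#'
#' Eleven equally spaced doses spanning the experimentally used 0 to
#' 2.6e-3 percent range.
#'
#' @return Numeric vector of 11 doses (percent).
#' @export
default_dose_grid <- function() seq(0, 2.6e-3, length.out = 11)

#' Per-circuit reference assay dose
#'
#' The geometric midpoint of the circuit's zero-growth bistable dose window
#' at the assay aTc dose. Because the repressive link shifts the
#' experimental circuit's bistable window relative to the control's,
#' growth-robustness assays compare the two circuits at comparable positions
#' within their own windows rather than at one shared dose; this reference
#' dose is that position.
#'
#' @inheritParams rate_balance
#' @return A single L-arabinose dose (percent).
#' @export
reference_dose <- function(params, atc = assay_defaults()$atc_assay) {
  reg <- static_bistable_region(params, atc)
  if (reg$width == 0) stop("circuit is not bistable at any dose; no reference dose")
  sqrt(reg$lower * reg$upper)
}

default_assay_protocol <- function(dose, atc, k_g, dilution_factor = 41,
                                   duration = NULL, relax_h = 50) {
  if (is.null(duration)) {
    # long enough for the culture to saturate and the circuit to relax to
    # its post-growth attractor; relaxation is rate-limited by basal
    # degradation, so callers scale relax_h with 1/db_a
    duration <- min(1200, relax_h + 3 * log(dilution_factor) / max(k_g, 0.03))
  }
  stage(duration, inducers(lara = dose, atc = atc),
        dilution_factor = dilution_factor)
}

#' Transient dose-response branch under growth
#'
#' For each dose: precondition the circuit to the requested branch state
#' (ON: saturated culture at the fully activating dose; OFF: no inducer),
#' dilute it into fresh media at the assay dose, integrate the coupled
#' growth/circuit dynamics through log phase and back to saturation, and
#' classify the endpoint ON/OFF against the zero-growth separatrix at the
#' assay dose (see [classification_threshold()] for the monostable case).
#'
#' @param params A [circuit_params()] object.
#' @param growth A [growth_params()] object (its `k_g` is the assay growth
#'   rate).
#' @param atc aTc dose held fixed across the assay (ng/ml).
#' @param doses Nonempty vector of L-arabinose doses.
#' @param branch `"ON"` or `"OFF"` preconditioning.
#' @param protocol_template Optional function `(dose) -> stage` overriding
#'   the default single-stage 41-fold-dilution assay.
#' @param grid_step Integration output step (hours).
#' @return A data frame with columns `dose`, `branch`, `endpoint_class`
#'   (`"ON"`/`"OFF"`), `araC_final`.
#' @export
dose_response <- function(params, growth, atc = 0, doses, branch = c("ON", "OFF"),
                          protocol_template = NULL, grid_step = 0.5) {
  branch <- match.arg(branch)
  if (!length(doses)) stop("doses must be nonempty")
  ad <- assay_defaults()
  pre_induc <- if (branch == "ON")
    inducers(lara = ad$lara_high, atc = ad$atc_induction) else inducers(0, 0)
  pre <- steady_precondition(pre_induc, params, growth)
  if (is.null(protocol_template))
    protocol_template <- function(dose) default_assay_protocol(dose, atc, growth$k_g,
                                                               relax_h = 8 / params$db_a)
  res <- lapply(doses, function(d) {
    fp <- fixed_points(params, d, atc)
    stable <- fp$araC[fp$stability == "stable"]
    if (length(stable) < 2L) {
      # monostable dose: every trajectory is drawn to the unique attractor,
      # so the asymptotic class is the attractor's identity (this avoids
      # misreading slow saddle-node-ghost passages as retained memory)
      cls <- if (stable[1L] > classification_threshold(params, d, atc)) "ON" else "OFF"
      return(data.frame(dose = d, branch = branch, endpoint_class = cls,
                        araC_final = stable[1L]))
    }
    tr <- simulate_stage(pre, protocol_template(d), params, growth,
                         grid_step = grid_step)
    af <- tr$araC[nrow(tr)]
    thr <- classification_threshold(params, d, atc)
    data.frame(dose = d, branch = branch,
               endpoint_class = if (af > thr) "ON" else "OFF",
               araC_final = af)
  })
  do.call(rbind, res)
}

#' Bistable dose region of the transient assay
#'
#' The contiguous dose interval over which the ON- and OFF-preconditioned
#' branches of [dose_response()] disagree; its width is the hysteresis
#' extent at the assay growth rate, and zero width marks complete collapse.
#' The interval is reported at grid resolution: a dose grid samples the
#' underlying continuous disagreement region, so its bounds are taken at
#' the midpoints towards the nearest agreeing neighbours (a single
#' disagreeing dose therefore still spans one grid cell rather than a
#' zero-width point). A numerically non-contiguous disagreement set
#' (possible near collapse) is reported as its envelope with a warning.
#'
#' @inheritParams dose_response
#' @return A list with `lower`, `upper`, `width`, and the two branch tables
#'   (`on_branch`, `off_branch`).
#' @export
bistable_region <- function(params, growth, atc = 0, doses,
                            protocol_template = NULL, grid_step = 0.5) {
  on <- dose_response(params, growth, atc, doses, "ON", protocol_template, grid_step)
  off <- dose_response(params, growth, atc, doses, "OFF", protocol_template, grid_step)
  disagree <- on$endpoint_class != off$endpoint_class
  if (!any(disagree))
    return(list(lower = NA_real_, upper = NA_real_, width = 0,
                on_branch = on, off_branch = off))
  idx <- which(disagree)
  if (any(diff(idx) > 1L))
    warning("non-contiguous bistable set; reporting its envelope")
  i1 <- min(idx); i2 <- max(idx)
  lower <- if (i1 > 1L) (doses[i1 - 1L] + doses[i1]) / 2 else doses[i1]
  upper <- if (i2 < length(doses)) (doses[i2] + doses[i2 + 1L]) / 2 else doses[i2]
  list(lower = lower, upper = upper, width = upper - lower,
       on_branch = on, off_branch = off)
}

assay_endpoint_on <- function(params, growth_template, k_g, lara, atc,
                              pre = NULL, grid_step = 0.5) {
  growth <- growth_params(k_g = k_g, N0 = growth_template$N0)
  if (is.null(pre))
    pre <- steady_precondition(inducers(lara = assay_defaults()$lara_high,
                                        atc = assay_defaults()$atc_induction),
                               params, growth)
  tr <- simulate_stage(pre, default_assay_protocol(lara, atc, k_g,
                                                   relax_h = 8 / params$db_a),
                       params, growth, grid_step = grid_step)
  af <- tr$araC[nrow(tr)]
  af > classification_threshold(params, lara, atc)
}

#' Growth-rate collapse threshold of the ON state
#'
#' Bisects the maximum specific growth rate `k_g` at which an
#' ON-preconditioned culture, diluted into fresh media at the assay dose,
#' first ends in the OFF state: below the threshold the transient dip in
#' AraC stays above the separatrix and the switch recovers; above it,
#' growth-enhanced dilution pushes the state across and memory is lost.
#'
#' @param params A [circuit_params()] object.
#' @param growth_template A [growth_params()] object supplying `N0`.
#' @param lara Assay L-arabinose dose (percent); defaults to the circuit's
#'   own [reference_dose()], so the two circuits are assayed at comparable
#'   positions within their respective bistable windows.
#' @param atc Assay aTc dose (ng/ml).
#' @param kg_lo,kg_hi Bracket (1/h); the endpoint must be ON at `kg_lo` and
#'   OFF at `kg_hi`.
#' @param tol Bracket width at which bisection stops (1/h, default 1e-3).
#' @return The threshold `k_g*` (midpoint of the final bracket).
#' @export
collapse_threshold <- function(params, growth_template = growth_params(),
                               lara = NULL,
                               atc = assay_defaults()$atc_assay,
                               kg_lo = 0.02, kg_hi = 1, tol = 1e-3) {
  if (is.null(lara)) lara <- reference_dose(params, atc)
  # the ON precondition is a saturated, non-growing culture, hence
  # independent of k_g: compute it once
  pre <- steady_precondition(inducers(lara = assay_defaults()$lara_high,
                                      atc = assay_defaults()$atc_induction),
                             params,
                             growth_params(k_g = kg_lo, N0 = growth_template$N0))
  on_lo <- assay_endpoint_on(params, growth_template, kg_lo, lara, atc, pre)
  on_hi <- assay_endpoint_on(params, growth_template, kg_hi, lara, atc, pre)
  if (!on_lo || on_hi)
    stop("no ON->OFF sign change in [", kg_lo, ", ", kg_hi, "]")
  while (kg_hi - kg_lo > tol) {
    mid <- (kg_lo + kg_hi) / 2
    if (assay_endpoint_on(params, growth_template, mid, lara, atc, pre))
      kg_lo <- mid else kg_hi <- mid
  }
  (kg_lo + kg_hi) / 2
}

#' Growth rate at which transient hysteresis collapses
#'
#' Scans an increasing grid of growth rates and returns the first at which
#' the transient bistable region width reaches zero.
#'
#' @inheritParams dose_response
#' @param growth_template A [growth_params()] object supplying `N0`.
#' @param kg_grid Increasing vector of growth rates to scan (1/h).
#' @return A list with `k_g_collapse` (first grid value of zero width, or
#'   `Inf` when the grid never collapses) and `widths` (a data frame of
#'   `k_g`, `width`).
#' @export
hysteresis_collapse_threshold <- function(params, growth_template = growth_params(),
                                          atc = assay_defaults()$atc_assay,
                                          doses = default_dose_grid(),
                                          kg_grid = c(0.1, 0.5, 1, 1.5, 2)) {
  if (is.unsorted(kg_grid, strictly = TRUE)) stop("kg_grid must be increasing")
  widths <- vapply(kg_grid, function(kg) {
    g <- growth_params(k_g = kg, N0 = growth_template$N0)
    bistable_region(params, g, atc, doses)$width
  }, 0)
  hit <- which(widths == 0)
  list(k_g_collapse = if (length(hit)) kg_grid[hit[1L]] else Inf,
       widths = data.frame(k_g = kg_grid, width = widths))
}
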