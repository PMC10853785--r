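#' Fit a logistic growth curve to an OD series
#'
#' Least-squares fit of the burden-free logistic solution
#' `N(t) = N0 * N_i * exp(k_g t) / (N0 + N_i * (exp(k_g t) - 1))`
#' to an optical-density time series, estimating the maximum specific
#' growth rate `k_g`, the carrying capacity `N0` and the inoculum `N_i`.
#'
#' @param od_series Data frame with columns `time_h` and `od` (>= 10
#'   points spanning log and plateau phases).
#' @param bounds Named list of `lower`/`upper` numeric vectors over
#'   `(k_g, N0, N_i)`; defaults are permissive.
#' @param seed Integer seed for the jittered restarts used when the
#'   initial fit fails to converge.
#' @return A list with `k_g`, `N0`, `N_i`, `converged` (logical),
#'   `identifiable` (logical, `FALSE` when the series shows no exponential
#'   phase), and `rss`.
#' @export
fit_growth_curve <- function(od_series, bounds = NULL, seed = 1L) {
  stopifnot(all(c("time_h", "od") %in% names(od_series)))
  if (nrow(od_series) < 10) stop("need at least 10 points")
  t <- od_series$time_h; y <- od_series$od
  identifiable <- (min(y) < 0.8 * max(y)) && stats::sd(y) > 0
  if (!identifiable)
    return(list(k_g = NA_real_, N0 = max(y), N_i = NA_real_,
                converged = FALSE, identifiable = FALSE, rss = NA_real_))
  logistic <- function(t, k_g, N0, N_i) {
    e <- exp(pmin(k_g * t, 500))
    N0 * N_i * e / (N0 + N_i * (e - 1))
  }
  if (is.null(bounds))
    bounds <- list(lower = c(k_g = 1e-4, N0 = max(y) / 10, N_i = 1e-10),
                   upper = c(k_g = 10, N0 = max(y) * 10, N_i = max(y)))
  # crude initialisation from the early log-slope and the plateau
  N0g <- max(y); Nig <- max(min(y[y > 0]), 1e-8)
  half <- which(y >= N0g / 2)[1L]
  kg0 <- if (!is.na(half) && t[half] > 0) log(N0g / Nig) / t[half] else 0.5
  starts <- list(c(kg0, N0g, Nig))
  jit <- withr::with_seed(seed, lapply(1:5, function(i)
    c(kg0 * stats::runif(1, 0.3, 3), N0g * stats::runif(1, 0.8, 1.2),
      Nig * stats::runif(1, 0.3, 3))))
  starts <- c(starts, jit)
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(od ~ logistic(time_h, k_g, N0, N_i),
                        data = od_series,
                        start = list(k_g = s[1], N0 = s[2], N_i = s[3]),
                        lower = bounds$lower, upper = bounds$upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss)
        best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best))
    return(list(k_g = NA_real_, N0 = NA_real_, N_i = NA_real_,
                converged = FALSE, identifiable = TRUE, rss = NA_real_))
  cf <- stats::coef(best$fit)
  list(k_g = unname(cf["k_g"]), N0 = unname(cf["N0"]), N_i = unname(cf["N_i"]),
       converged = TRUE, identifiable = TRUE, rss = best$rss)
}

#' Fit specification for circuit parameter calibration
#'
#' Declares which parameters are free, their box bounds, and how the loss
#' is computed from plate-reader tables.
#'
#' @param free Character vector of free parameter names: any of the
#'   [circuit_params()] fields or `"k_g"`/`"N0"`.
#' @param lower,upper Named numeric vectors of bounds for every free
#'   parameter (finite, ordered).
#' @param channels Channels entering the loss: subset of `"gfp"`, `"rfp"`,
#'   `"od"`.
#' @param per_od Divide fluorescence channels by OD before residuals
#'   (per-cell proxy, matching the model's per-cell state; default `TRUE`).
#' @param log_transform Compare on `log1p` scale (default `FALSE`).
#' @return An object of class `fit_spec`.
#' @export
fit_spec <- function(free, lower, upper, channels = c("gfp", "od"),
                     per_od = TRUE, log_transform = FALSE) {
  if (!length(free)) stop("free set must be nonempty")
  if (!all(free %in% names(lower)) || !all(free %in% names(upper)))
    stop("bounds must cover every free parameter")
  lo <- unlist(lower[free]); up <- unlist(upper[free])
  if (any(!is.finite(lo)) || any(!is.finite(up)) || any(lo >= up))
    stop("bounds must be finite and ordered")
  stopifnot(all(channels %in% c("gfp", "rfp", "od")))
  structure(list(free = free, lower = lo, upper = up, channels = channels,
                 per_od = per_od, log_transform = log_transform),
            class = "fit_spec")
}

assemble_params <- function(theta, spec, base_params, base_growth) {
  p <- unclass(base_params); g <- unclass(base_growth)
  for (nm in spec$free) {
    if (nm %in% names(p)) p[[nm]] <- theta[[nm]]
    else if (nm %in% names(g)) g[[nm]] <- theta[[nm]]
    else stop("unknown free parameter: ", nm)
  }
  list(params = do.call(circuit_params, p),
       growth = growth_params(k_g = g$k_g, N0 = g$N0))
}

circuit_loss <- function(theta, spec, tables, base_params, base_growth,
                         assay, gains) {
  pg <- tryCatch(assemble_params(theta, spec, base_params, base_growth),
                 error = function(e) NULL)
  if (is.null(pg)) return(1e12)
  tr <- tryCatch(
    simulate_stage(assay$state0, assay$stage, pg$params, pg$growth,
                   grid_step = assay$grid_step),
    error = function(e) NULL)
  if (is.null(tr)) return(1e12)
  pred <- list(od = tr$N,
               gfp = gains[["gain_g"]] * tr$araC * tr$N,
               rfp = gains[["gain_r"]] * tr$tetR * tr$N)
  loss <- 0
  for (tab in tables) {
    idx <- match(round(tab$time_h, 9), round(tr$time_h, 9))
    if (any(is.na(idx))) return(1e12)
    for (ch in spec$channels) {
      obs <- tab[[ch]]; mod <- pred[[ch]][idx]
      if (spec$per_od && ch %in% c("gfp", "rfp")) {
        obs <- obs / tab$od
        mod <- mod / pred$od[idx]
      }
      if (spec$log_transform) { obs <- log1p(obs); mod <- log1p(mod) }
      # scale residuals by the observed magnitude so channels with
      # different units (OD vs fluorescence) carry comparable weight
      sc <- mean(abs(obs))
      if (sc <= 0) sc <- 1
      loss <- loss + sum(((obs - mod) / sc)^2)
    }
  }
  loss
}

#' Calibrate circuit parameters against plate-reader tables
#'
#' Bounded multi-start local optimisation (L-BFGS-B from Latin-hypercube
#' starting points) of the sum of squared residuals between simulated and
#' observed channels. By default fluorescence is compared per OD unit (a
#' per-cell proxy), matching the model's per-cell state variables.
#'
#' @param tables List of `plate_reader_table`s (replicates of one
#'   condition).
#' @param spec A [fit_spec()].
#' @param base_params,base_growth Fixed values for every parameter not in
#'   the free set.
#' @param assay List describing the protocol that generated the tables:
#'   `state0` (initial [system_state()]), `stage` (a [stage()]), and
#'   `grid_step` matching the table cadence.
#' @param gains Named vector with `gain_g`, `gain_r` used by the readout
#'   model.
#' @param n_starts Number of multi-start points (default 8).
#' @param seed Integer seed (Latin hypercube draw); the fit is
#'   deterministic given seed and start count.
#' @return A list with `estimates` (named vector over the free set),
#'   `loss`, `converged`, `n_eval`.
#' @export
fit_circuit <- function(tables, spec, base_params = default_circuit(),
                        base_growth = growth_params(), assay,
                        gains = c(gain_g = 1000, gain_r = 1000),
                        n_starts = 8, seed = 1L) {
  stopifnot(inherits(spec, "fit_spec"))
  for (ch in spec$channels)
    if (!all(vapply(tables, function(tb) ch %in% names(tb), TRUE)))
      stop("channel '", ch, "' missing from tables")
  k <- length(spec$free)
  cube <- withr::with_seed(seed, lhs::randomLHS(n_starts, k))
  starts <- sweep(sweep(cube, 2, spec$upper - spec$lower, "*"), 2, spec$lower, "+")
  colnames(starts) <- spec$free
  n_eval <- 0L
  obj <- function(v) {
    n_eval <<- n_eval + 1L
    circuit_loss(stats::setNames(as.list(v), spec$free), spec, tables,
                 base_params, base_growth, assay, gains)
  }
  best <- NULL
  for (i in seq_len(n_starts)) {
    o <- tryCatch(
      stats::optim(starts[i, ], obj, method = "L-BFGS-B",
                   lower = spec$lower, upper = spec$upper,
                   control = list(maxit = 200, factr = 1e7)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) stop("all optimisation starts failed")
  list(estimates = stats::setNames(best$par, spec$free), loss = best$value,
       converged = best$convergence == 0, n_eval = n_eval)
}

#' Profile the loss along one free parameter
#'
#' At each grid value of the profiled parameter, the loss is minimised over
#' the remaining free parameters (or evaluated directly when it is the only
#' free parameter).
#'
#' @inheritParams fit_circuit
#' @param parameter Name of the profiled parameter (must be in the free
#'   set).
#' @param grid Values at which to profile.
#' @return Data frame with columns `value`, `loss`.
#' @export
profile_loss <- function(tables, spec, parameter, grid,
                         base_params = default_circuit(),
                         base_growth = growth_params(), assay,
                         gains = c(gain_g = 1000, gain_r = 1000),
                         n_starts = 4, seed = 1L) {
  if (!parameter %in% spec$free) stop("parameter not in free set")
  others <- setdiff(spec$free, parameter)
  loss_at <- function(v) {
    if (!length(others)) {
      circuit_loss(stats::setNames(list(v), parameter), spec, tables,
                   base_params, base_growth, assay, gains)
    } else {
      sub <- fit_spec(others, as.list(spec$lower[others]),
                      as.list(spec$upper[others]), spec$channels,
                      spec$per_od, spec$log_transform)
      fixed_p <- unclass(base_params); fixed_g <- unclass(base_growth)
      if (parameter %in% names(fixed_p)) fixed_p[[parameter]] <- v
      else fixed_g[[parameter]] <- v
      fit_circuit(tables, sub, do.call(circuit_params, fixed_p),
                  growth_params(k_g = fixed_g$k_g, N0 = fixed_g$N0),
                  assay, gains, n_starts = n_starts, seed = seed)$loss
    }
  }
  data.frame(value = grid, loss = vapply(grid, loss_at, 0))
}
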