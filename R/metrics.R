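#' Pulse sensitivity of a time series
#'
#' Peak strength of a trajectory channel after normalising its steady-state
#' level to unity: `max(channel) / steady_state(channel)`. A monotonically
#' saturating or constant trace scores exactly 1; a transient overshoot
#' scores above 1.
#'
#' Steady state is taken as the final value; a warning is issued when the
#' relative change of the channel over the final 10 percent of the trace
#' exceeds 1e-4 (plateau not reached).
#'
#' @param traj A `trajectory` data frame (see [simulate_stage()]).
#' @param channel Column name, default `"araC"` (the GFP-tracked output).
#' @return A single number >= 1.
#' @export
pulse_sensitivity <- function(traj, channel = "araC") {
  x <- traj[[channel]]
  if (is.null(x)) stop("no such channel: ", channel)
  n <- length(x)
  ss <- x[n]
  if (ss <= 0) stop("steady-state value is not positive")
  tail_start <- max(1L, floor(0.9 * n))
  rel <- abs(diff(range(x[tail_start:n]))) / ss
  if (rel > 1e-4)
    warning("plateau criterion not met (relative tail change ",
            signif(rel, 3), "); using final value")
  max(x) / ss
}

#' Time of the trajectory peak
#'
#' @inheritParams pulse_sensitivity
#' @return Time (hours, relative to the trajectory origin) at which the
#'   channel attains its maximum.
#' @export
peak_time <- function(traj, channel = "araC") {
  x <- traj[[channel]]
  if (is.null(x)) stop("no such channel: ", channel)
  traj$time_h[which.max(x)] - traj$time_h[1L]
}

#' Percent fall in output over an observation window
#'
#' `100 * (x(0) - min over [0, window]) / x(0)`: how far the output drops,
#' relative to its starting level, within the first hours after dilution
#' into fresh media.
#'
#' @inheritParams pulse_sensitivity
#' @param window Window length in hours from the trajectory origin
#'   (default 10).
#' @return Percentage in `[0, 100]` (0 for a non-decreasing trace).
#' @export
percent_fall <- function(traj, channel = "araC", window = 10) {
  x <- traj[[channel]]
  if (is.null(x)) stop("no such channel: ", channel)
  t <- traj$time_h - traj$time_h[1L]
  if (window > t[length(t)] + 1e-9) stop("window exceeds trajectory span")
  if (x[1L] <= 0) stop("starting value is not positive")
  m <- min(x[t <= window + 1e-9])
  100 * (x[1L] - min(m, x[1L])) / x[1L]
}

#' Fold increase of the experimental minimum over the control minimum
#'
#' Ratio of the two trajectories' minima within the observation window,
#' after normalising each trajectory to its own starting level (the
#' drop-rescue comparison: both circuits are followed from their respective
#' ON states, so output loss is measured relative to where each started).
#'
#' @param traj_exp,traj_ctrl Trajectories of the experimental and control
#'   circuits over a common protocol.
#' @param channel Column name, default `"araC"`.
#' @param window Window length (hours), default 10.
#' @param normalize Normalise each trace to its starting value before
#'   taking minima (default `TRUE`).
#' @return Ratio > 0; values above 1 mean the experimental circuit kept its
#'   output higher.
#' @export
fold_min_increase <- function(traj_exp, traj_ctrl, channel = "araC",
                              window = 10, normalize = TRUE) {
  mn <- function(traj) {
    x <- traj[[channel]]
    if (is.null(x)) stop("no such channel: ", channel)
    t <- traj$time_h - traj$time_h[1L]
    if (normalize) x <- x / x[1L]
    min(x[t <= window + 1e-9])
  }
  me <- mn(traj_exp); mc <- mn(traj_ctrl)
  if (mc <= 0) stop("control minimum is not positive")
  if (me <= 0) stop("experimental minimum is not positive")
  me / mc
}

#' Percent of events above a threshold
#'
#' Fraction (in percent) of per-cell fluorescence events classified ON.
#'
#' @param events Numeric vector of per-event intensities (nonempty).
#' @param threshold Gate value; events strictly above it count as ON.
#' @return Percentage in `[0, 100]`.
#' @export
percent_on <- function(events, threshold) {
  if (!length(events)) stop("events must be nonempty")
  100 * mean(events > threshold)
}

#' Hysteresis curve pair
#'
#' Percent-ON values of the off-to-on and on-to-off branches on a common
#' dose grid.
#'
#' @param dose Dose grid (strictly increasing).
#' @param off_to_on,on_to_off Percent-ON values per dose for the two
#'   branches.
#' @param normalized Whether the curves are already max-to-100 normalised.
#' @return An object of class `hysteresis_pair`.
#' @export
hysteresis_pair <- function(dose, off_to_on, on_to_off, normalized = FALSE) {
  if (length(dose) != length(off_to_on) || length(dose) != length(on_to_off))
    stop("mismatched grids")
  if (is.unsorted(dose, strictly = TRUE)) stop("dose grid must be strictly increasing")
  structure(list(dose = dose, off_to_on = off_to_on, on_to_off = on_to_off,
                 normalized = normalized), class = "hysteresis_pair")
}

#' Hysteresis score: area between the branches
#'
#' Trapezoidal integral over dose of `off_to_on - on_to_off` after
#' max-to-100 normalisation of each branch. Identical branches score 0.
#' The integral is signed; under the usual orientation (the on-to-off
#' branch retains more ON cells at a given dose) the reported score is the
#' magnitude of the area, and the sign records the orientation.
#'
#' @param pair A [hysteresis_pair()].
#' @return Signed area in percent x dose units.
#' @export
hysteresis_score <- function(pair) {
  stopifnot(inherits(pair, "hysteresis_pair"))
  a <- pair$off_to_on; b <- pair$on_to_off
  if (!pair$normalized) {
    if (max(a) > 0) a <- 100 * a / max(a)
    if (max(b) > 0) b <- 100 * b / max(b)
  }
  d <- pair$dose
  diffs <- a - b
  sum(diff(d) * (diffs[-length(diffs)] + diffs[-1L]) / 2)
}

#' Normalise a trajectory channel or a curve
#'
#' @param x A `trajectory` data frame or a numeric vector.
#' @param mode `"steady_state"` (divide by the final value), `"start"`
#'   (divide by the first value), or `"max100"` (scale so the maximum is
#'   100).
#' @param channel Channel to normalise when `x` is a trajectory.
#' @return Same shape as the input with the channel rescaled.
#' @export
normalize_output <- function(x, mode = c("steady_state", "start", "max100"),
                             channel = "araC") {
  mode <- match.arg(mode)
  vec <- if (is.data.frame(x)) x[[channel]] else x
  if (is.null(vec)) stop("no such channel: ", channel)
  ref <- switch(mode,
                steady_state = vec[length(vec)],
                start = vec[1L],
                max100 = max(vec))
  if (ref <= 0) stop("normalisation reference is not positive")
  out <- switch(mode, max100 = 100 * vec / ref, vec / ref)
  if (is.data.frame(x)) { x[[channel]] <- out; x } else out
}
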