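#' Generate a plate-reader-style table from a trajectory
#'
#' Emulates timed absorbance/fluorescence readout of a growing culture: OD
#' proportional to population density, fluorescence proportional to total
#' (per-cell concentration times density) reporter amount, plus optical
#' backgrounds and multiplicative Gaussian measurement noise of a stated
#' coefficient of variation. Reproducible under a fixed seed.
#'
#' @param traj A `trajectory` (see [simulate_stage()]); its time grid should
#'   be at the plate-reader cadence (15- or 30-minute steps).
#' @param gain_g,gain_r Fluorescence gains for GFP (tracks AraC) and RFP
#'   (tracks TetR), in instrument units per concentration-density.
#' @param od_scale OD units per density unit.
#' @param noise_cv Coefficient of variation of multiplicative Gaussian
#'   measurement noise (0 disables noise).
#' @param background Named list/vector with `od`, `gfp`, `rfp` background
#'   levels (defaults 0).
#' @param replicate Replicate index recorded in the table.
#' @param seed Integer seed; the generator is a pure function of its inputs
#'   and the seed.
#' @return A data frame (class `plate_reader_table`) with columns `time_h`,
#'   `od`, `gfp`, `rfp`, `replicate`.
#' @export
gen_plate_reader <- function(traj, gain_g = 1000, gain_r = 1000,
                             od_scale = 1, noise_cv = 0.05,
                             background = c(od = 0, gfp = 0, rfp = 0),
                             replicate = 1L, seed = 1L) {
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  bg <- c(od = 0, gfp = 0, rfp = 0)
  bg[names(background)] <- unlist(background)
  n <- nrow(traj)
  eps <- withr::with_seed(seed, matrix(stats::rnorm(3L * n, 0, noise_cv), ncol = 3L))
  if (noise_cv == 0) eps[] <- 0
  out <- data.frame(
    time_h = traj$time_h,
    od = bg[["od"]] + od_scale * traj$N * (1 + eps[, 1L]),
    gfp = bg[["gfp"]] + gain_g * traj$araC * traj$N * (1 + eps[, 2L]),
    rfp = bg[["rfp"]] + gain_r * traj$tetR * traj$N * (1 + eps[, 3L]),
    replicate = as.integer(replicate)
  )
  class(out) <- c("plate_reader_table", "data.frame")
  out
}

#' Generate replicate plate-reader tables
#'
#' Independent measurement-noise draws over a shared underlying trajectory,
#' emulating technical/biological replicates of one condition (the analyses
#' in this package use four replicates by convention).
#'
#' @inheritParams gen_plate_reader
#' @param n_reps Number of replicates (>= 1).
#' @return List of `plate_reader_table`s, one per replicate; replicate `i`
#'   is generated with seed `seed + i - 1`.
#' @export
gen_replicates <- function(traj, n_reps = 4, gain_g = 1000, gain_r = 1000,
                           od_scale = 1, noise_cv = 0.05,
                           background = c(od = 0, gfp = 0, rfp = 0),
                           seed = 1L) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  lapply(seq_len(n_reps), function(i)
    gen_plate_reader(traj, gain_g, gain_r, od_scale, noise_cv, background,
                     replicate = i, seed = seed + i - 1L))
}

#' Generate flow-cytometry-like per-cell fluorescence events
#'
#' Draws a population of cells whose initial AraC levels are lognormally
#' dispersed around a preconditioned state, propagates each through the
#' assay protocol, and applies lognormal measurement noise, yielding the
#' bimodal ON/OFF mixture structure characteristic of a bistable switch
#' near its transition dose: cells starting above the separatrix resolve to
#' the high mode, the rest to the low mode, and the density near the
#' separatrix-mapped intensity stays sparse.
#'
#' Cell-to-cell heterogeneity enters only through the initial AraC level;
#' the deterministic fate map from initial level to final output is
#' evaluated on a quantile grid of the initial distribution (`n_grid`
#' points) and interpolated, which is exact up to grid resolution because
#' the map is monotone away from the basin boundary.
#'
#' @param params A [circuit_params()] object.
#' @param growth A [growth_params()] object.
#' @param pre A [system_state()] around which initial AraC is dispersed
#'   (e.g. from [steady_precondition()]).
#' @param stg A [stage()]: the assay protocol applied to every cell.
#' @param n_events Number of events (default 20000).
#' @param init_cv Lognormal CV of initial AraC across cells (default 0.3).
#' @param meas_cv Lognormal CV of measurement noise (default 0.25).
#' @param gain Fluorescence gain (intensity units per concentration).
#' @param rfp_neg_frac Fraction of events emulating mutated/dysfunctional
#'   circuits (RFP-negative); they are flagged and excluded by gating.
#' @param n_grid Resolution of the initial-level fate map (default 256).
#' @param seed Integer seed.
#' @return A data frame (class `flow_event_set`) with columns `gfp`
#'   (intensity) and `gated` (logical, `TRUE` for events kept by RFP
#'   gating).
#' @export
gen_flow_events <- function(params, growth, pre, stg, n_events = 20000,
                            init_cv = 0.3, meas_cv = 0.25, gain = 1000,
                            rfp_neg_frac = 0, n_grid = 256, seed = 1L) {
  if (n_events <= 0) stop("n_events must be positive")
  if (init_cv < 0 || meas_cv < 0) stop("CVs must be >= 0")
  a0 <- pre[["araC"]]
  draws <- withr::with_seed(seed, {
    sdl <- sqrt(log(1 + init_cv^2))
    init <- if (init_cv > 0 && a0 > 0)
      a0 * stats::rlnorm(n_events, -sdl^2 / 2, sdl) else rep(a0, n_events)
    sdm <- sqrt(log(1 + meas_cv^2))
    meas <- if (meas_cv > 0)
      stats::rlnorm(n_events, -sdm^2 / 2, sdm) else rep(1, n_events)
    gneg <- stats::runif(n_events) < rfp_neg_frac
    list(init = init, meas = meas, gneg = gneg)
  })
  final_of <- function(a) {
    st <- system_state(araC = a, tetR = pre[["tetR"]], N = pre[["N"]])
    final_state(simulate_stage(st, stg, params, growth,
                               grid_step = stg$duration / 50))[["araC"]]
  }
  uin <- sort(unique(draws$init))
  if (length(uin) <= n_grid) {
    fmap <- vapply(uin, final_of, 0)
    fin <- fmap[match(draws$init, uin)]
  } else {
    grid <- stats::quantile(draws$init, probs = seq(0, 1, length.out = n_grid),
                            names = FALSE, type = 7)
    grid <- sort(unique(grid))
    fmap <- vapply(grid, final_of, 0)
    fin <- stats::approx(grid, fmap, xout = draws$init, rule = 2)$y
  }
  out <- data.frame(gfp = gain * fin * draws$meas, gated = !draws$gneg)
  class(out) <- c("flow_event_set", "data.frame")
  out
}

#' Write a synthetic table as delimited text with a provenance header
#'
#' @param x A data frame produced by one of the generators.
#' @param path Output path.
#' @param meta Named list recorded in `#`-prefixed header lines (generator
#'   parameters, seed, package version).
#' @return `path`, invisibly.
#' @export
write_synthetic <- function(x, path, meta = list()) {
  meta <- c(list(generator = class(x)[1L],
                 package = paste0("growthswitch ",
                                  as.character(utils::packageVersion("growthswitch")))),
            meta)
  hdr <- paste0("# ", names(meta), " = ", vapply(meta, function(v)
    paste(format(v), collapse = " "), ""))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a table written by [write_synthetic()]
#'
#' @param path Input path.
#' @return A data frame (header comments are skipped).
#' @export
read_synthetic <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
}
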