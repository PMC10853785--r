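base_traj <- simulate_stage(system_state(1, 1, 1 / 41),
                            stage(8, inducers(2.6e-3, 20)),
                            p_exp, growth_params(k_g = 0.75), grid_step = 0.25)

test_that("noise-free plate-reader channels are exactly proportional to the state", {
  tab <- gen_plate_reader(base_traj, gain_g = 500, gain_r = 200, od_scale = 2,
                          noise_cv = 0, seed = 9)
  expect_equal(tab$od, 2 * base_traj$N)
  expect_equal(tab$gfp, 500 * base_traj$araC * base_traj$N)
  expect_equal(tab$rfp, 200 * base_traj$tetR * base_traj$N)
})

test_that("generators are pure functions of inputs and seed (byte-identical files)", {
  t1 <- gen_plate_reader(base_traj, seed = 4)
  t2 <- gen_plate_reader(base_traj, seed = 4)
  expect_identical(t1, t2)
  expect_false(identical(t1$gfp, gen_plate_reader(base_traj, seed = 5)$gfp))
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_synthetic(t1, f1, meta = list(seed = 4))
  write_synthetic(t2, f2, meta = list(seed = 4))
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("per-OD-normalised fluorescence recovers the per-cell concentration", {
  tab <- gen_plate_reader(base_traj, gain_g = 1000, noise_cv = 0.05, seed = 21)
  est <- tab$gfp / tab$od / 1000
  rel <- (est - base_traj$araC) / base_traj$araC
  # ratio of two channels with 5% CV noise: sd about 7%; allow 4 sigma of
  # the mean over n points plus a generous per-point band
  expect_lt(abs(mean(rel)), 4 * 0.071 / sqrt(nrow(tab)) + 0.01)
  expect_lt(max(abs(rel)), 0.35)
})

test_that("metrics on noise-free tables equal metrics on the trajectory", {
  tab <- gen_plate_reader(base_traj, noise_cv = 0, seed = 1)
  per_cell <- tab$gfp / tab$od / 1000
  tr2 <- base_traj; tr2$araC <- per_cell
  expect_equal(percent_fall(tr2, window = 5), percent_fall(base_traj, window = 5),
               tolerance = 1e-12)
})

test_that("replicates share the trajectory but draw independent noise", {
  reps <- gen_replicates(base_traj, n_reps = 4, noise_cv = 0.05, seed = 100)
  expect_length(reps, 4L)
  expect_identical(reps[[1]],
                   gen_plate_reader(base_traj, noise_cv = 0.05, seed = 100,
                                    replicate = 1L))
  expect_false(identical(reps[[1]]$gfp, reps[[2]]$gfp))
  # the replicate mean approaches the true signal (CLT bound, fixed seed)
  truth <- 1000 * base_traj$araC * base_traj$N
  avg <- rowMeans(sapply(reps, `[[`, "gfp"))
  keep <- truth > max(truth) / 100
  rel <- (avg[keep] - truth[keep]) / truth[keep]
  expect_lt(max(abs(rel)), 3 * 0.05 / sqrt(4) * 3)
})

test_that("deterministic flow events collapse to a single class", {
  g <- growth_params(k_g = 0.3)
  pre <- system_state(2, 1, 1)
  ev <- gen_flow_events(p_exp, g, pre, stage(10, inducers(2.6e-3, 20), 41),
                        n_events = 200, init_cv = 0, meas_cv = 0, seed = 3)
  expect_equal(length(unique(ev$gfp)), 1L)
  expect_true(percent_on(ev$gfp, 1) %in% c(0, 100))
})

test_that("a dose far above the bistable range turns every event on", {
  g0 <- growth_params(k_g = 0)
  pre <- steady_precondition(inducers(0, 0), p_exp, g0)
  ev <- gen_flow_events(p_exp, g0, pre, stage(500, inducers(2.6e-3, 20)),
                        n_events = 500, init_cv = 0.3, meas_cv = 0.1,
                        n_grid = 64, seed = 8)
  fp <- fixed_points(p_exp, 2.6e-3, 20)
  gate <- 1000 * max(fp$araC) / 4
  expect_equal(percent_on(ev$gfp[ev$gated], gate), 100)
})

test_that("initial spread across the separatrix yields a bimodal event distribution", {
  d <- reference_dose(p_exp)
  sep <- separatrix(p_exp, d, 20)
  g0 <- growth_params(k_g = 0)
  pre <- system_state(sep, p_exp$k0_t / p_exp$db_t, 1)
  ev <- gen_flow_events(p_exp, g0, pre, stage(500, inducers(d, 20)),
                        n_events = 4000, init_cv = 0.3, meas_cv = 0.15,
                        n_grid = 128, seed = 12)
  lg <- log10(ev$gfp)
  fp <- fixed_points(p_exp, d, 20)
  lo_mode <- log10(1000 * fp$araC[1]); hi_mode <- log10(1000 * fp$araC[3])
  anti <- log10(1000 * sep)
  dens <- stats::density(lg, from = lo_mode - 1, to = hi_mode + 1)
  at <- function(x) dens$y[which.min(abs(dens$x - x))]
  # sparse density near the separatrix-mapped intensity relative to modes
  expect_lt(at(anti), 0.2 * at(lo_mode))
  expect_lt(at(anti), 0.2 * at(hi_mode))
  # percent-ON agrees with the deterministic classification of the draws
  pct <- percent_on(ev$gfp, 1000 * sep * 3)
  expect_gt(pct, 10); expect_lt(pct, 90)
})

test_that("percent-ON from events matches the deterministic fraction within binomial bounds", {
  d <- reference_dose(p_exp)
  sep <- separatrix(p_exp, d, 20)
  g0 <- growth_params(k_g = 0)
  pre <- system_state(sep * 1.02, p_exp$k0_t / p_exp$db_t, 1)
  n <- 20000
  ev <- gen_flow_events(p_exp, g0, pre, stage(500, inducers(d, 20)),
                        n_events = n, init_cv = 0.3, meas_cv = 0,
                        n_grid = 128, seed = 77)
  # with no measurement noise the fate is a step in the initial level:
  # deterministic fraction = share of initial draws above the separatrix
  p_det <- mean(ev$gfp > 1000 * sep)
  frac <- withr::with_seed(77, {
    sdl <- sqrt(log(1 + 0.3^2))
    init <- sep * 1.02 * stats::rlnorm(n, -sdl^2 / 2, sdl)
    mean(init > sep)
  })
  # identical draws under the same seed: binomial 99% bound is generous
  expect_lt(abs(p_det - frac), 2.58 * sqrt(frac * (1 - frac) / n) + 0.01)
})

test_that("RFP-negative gating flags the requested fraction", {
  g <- growth_params(k_g = 0.3)
  pre <- system_state(2, 1, 1)
  ev <- gen_flow_events(p_exp, g, pre, stage(5, inducers(1e-3, 20), 41),
                        n_events = 5000, init_cv = 0.1, meas_cv = 0.1,
                        rfp_neg_frac = 0.2, n_grid = 32, seed = 5)
  expect_lt(abs(mean(!ev$gated) - 0.2), 0.02)
})

test_that("synthetic tables round-trip through their text representation", {
  tab <- gen_plate_reader(base_traj, seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_synthetic(tab, path, meta = list(seed = 2, noise_cv = 0.05))
  hdr <- readLines(path, n = 2)
  expect_true(all(startsWith(hdr, "#")))
  back <- read_synthetic(path)
  expect_equal(back$gfp, tab$gfp, tolerance = 1e-9)
})
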