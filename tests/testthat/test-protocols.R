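test_that("a stage started at a zero-growth fixed point stays there", {
  g0 <- growth_params(k_g = 0)
  fp <- fixed_points(p_exp, 0, 20)
  st <- system_state(fp$araC[1], p_exp$k0_t / p_exp$db_t, 1)
  tr <- simulate_stage(st, stage(30, inducers(0, 20)), p_exp, g0)
  expect_lt(max(abs(tr$araC - st[["araC"]])) / st[["araC"]], 1e-6)
  expect_lt(max(abs(tr$tetR - st[["tetR"]])) / st[["tetR"]], 1e-6)
})

test_that("with the feedback silenced the relaxation matches the analytic exponential", {
  # k1_a = 0, lara = 0, N at carrying capacity: dA/dt = k0_a - db_a * A,
  # so A(t) = A_inf + (A0 - A_inf) * exp(-db_a * t)
  p <- circuit_params(k1_a = 0)
  g <- growth_params(k_g = 0.5)
  a0 <- 2; ainf <- p$k0_a / p$db_a
  st <- system_state(a0, p$k0_t / p$db_t, 1)
  tr <- simulate_stage(st, stage(20, inducers(0, 0)), p, g, grid_step = 0.5)
  expect_lt(max(abs(tr$araC - (ainf + (a0 - ainf) * exp(-p$db_a * tr$time_h)))),
            1e-7)
})

test_that("dilution events divide density, preserve concentrations, and compose", {
  st <- system_state(1.5, 0.8, 1)
  tr <- simulate_stage(st, stage(1e-4, inducers(0, 0), dilution_factor = 41),
                       p_exp, growth_params(k_g = 0.7), grid_step = 1e-4)
  expect_equal(tr$N[1], 1 / 41)
  expect_equal(tr$araC[1], 1.5)
  expect_equal(tr$tetR[1], 0.8)
  # two infinitesimal consecutive dilutions equal one combined dilution
  pr2 <- protocol(list(stage(1e-5, inducers(0, 0), dilution_factor = 4),
                       stage(1e-5, inducers(0, 0), dilution_factor = 10)), st)
  tr2 <- run_protocol(pr2, p_exp, growth_params(k_g = 0), grid_step = 1e-5)
  expect_equal(tr2$N[nrow(tr2)], 1 / 40, tolerance = 1e-6)
})

test_that("a one-stage protocol reproduces simulate_stage and stages concatenate", {
  st <- system_state(0.5, 1, 0.5)
  g <- growth_params(k_g = 0.6)
  stg <- stage(8, inducers(1e-3, 10), dilution_factor = 2)
  single <- simulate_stage(st, stg, p_exp, g, grid_step = 0.5)
  viaproto <- run_protocol(protocol(list(stg), st), p_exp, g, grid_step = 0.5)
  expect_equal(single$araC, viaproto$araC)
  two <- run_protocol(protocol(list(stg, stage(4, inducers(0, 0))), st),
                      p_exp, g, grid_step = 0.5)
  expect_equal(two$araC[two$stage_index == 1L], single$araC)
  expect_equal(max(two$time_h), 12)
  expect_true(all(diff(two$time_h) > 0))
})

test_that("population density is nondecreasing within a stage and bounded by N0", {
  g <- growth_params(k_g = 1.2)
  tr <- simulate_stage(system_state(2, 1, 1), stage(30, inducers(2.6e-3, 20), 41),
                       p_exp, g, grid_step = 0.25)
  expect_true(all(diff(tr$N) >= -1e-10))
  expect_true(all(tr$N <= g$N0 + 1e-7))
})

test_that("halving the output grid step leaves trajectory endpoints unchanged", {
  st <- system_state(2, 1, 1)
  g <- growth_params(k_g = 0.8)
  stg <- stage(12, inducers(1e-3, 20), 41)
  a <- final_state(simulate_stage(st, stg, p_exp, g, grid_step = 0.5))
  b <- final_state(simulate_stage(st, stg, p_exp, g, grid_step = 0.25))
  expect_lt(abs(a[["araC"]] - b[["araC"]]) / b[["araC"]], 1e-4)
  expect_lt(abs(a[["N"]] - b[["N"]]) / b[["N"]], 1e-4)
})

test_that("experimental and control trajectories coincide when lam = 0", {
  p0 <- p_ctrl
  p0b <- circuit_params(lam = 0, K_t = 3, K_aTc = 5, m = 3, n_t = 2)
  st <- system_state(1, 1, 1 / 41)
  g <- growth_params(k_g = 0.9)
  stg <- stage(15, inducers(2e-3, 33))
  ta <- simulate_stage(st, stg, p0, g, grid_step = 0.5)
  tb <- simulate_stage(st, stg, p0b, g, grid_step = 0.5)
  expect_equal(ta$araC, tb$araC, tolerance = 1e-10)
})

test_that("steady preconditioning lands on a fixed point of the dynamics", {
  g <- growth_params(k_g = 0.7)
  ind <- inducers(assay_defaults()$lara_high, assay_defaults()$atc_induction)
  st <- steady_precondition(ind, p_exp, g)
  expect_lt(max(abs(rhs(st, ind, p_exp, g))), 1e-8)
  expect_equal(st[["N"]], g$N0, tolerance = 1e-6)
  expect_equal(st[["tetR"]], p_exp$k0_t / p_exp$db_t, tolerance = 1e-6)
  # OFF precondition sits at the low attractor
  off <- steady_precondition(inducers(0, 0), p_exp, g)
  fp <- fixed_points(p_exp, 0, 0)
  expect_equal(off[["araC"]], min(fp$araC[fp$stability == "stable"]),
               tolerance = 1e-5)
})

test_that("a long final stage ends at a root-finder steady state", {
  g <- growth_params(k_g = 0.5)
  pre <- steady_precondition(inducers(assay_defaults()$lara_high,
                                      assay_defaults()$atc_induction), p_ctrl, g)
  tr <- simulate_stage(pre, stage(150, inducers(2.6e-3, 20), 41), p_ctrl, g,
                       grid_step = 1)
  fp <- fixed_points(p_ctrl, 2.6e-3, 20)
  on_root <- max(fp$araC[fp$stability == "stable"])
  expect_lt(abs(final_state(tr)[["araC"]] - on_root) / on_root, 1e-5)
})

test_that("trajectories export as tidy delimited text", {
  tr <- simulate_stage(system_state(1, 1, 0.5), stage(2, inducers(0, 0)),
                       p_exp, growth_params(k_g = 0.3), grid_step = 0.5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory(tr, path)
  back <- utils::read.table(path, header = TRUE, sep = "\t")
  expect_equal(names(back), c("time_h", "araC", "tetR", "N", "growth_rate",
                              "dilution_rate", "stage_index"))
  expect_equal(back$araC, tr$araC, tolerance = 1e-12)
})
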