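test_that("self-activation Hill function matches its closed form and limits", {
  expect_equal(f_A(0, 3), 0)
  expect_equal(f_A(1, 1), 0.5)
  # direct closed-form evaluation at an arbitrary point
  expect_equal(f_A(10, 0.04), 0.04 * 100 / (1 + 0.04 * 100))
  expect_error(f_A(-1, 1), "nonnegative")
  # monotone nondecreasing in both arguments
  a <- seq(0, 10, length.out = 50)
  expect_true(all(diff(f_A(a, 2)) >= 0))
  expect_true(all(diff(f_A(3, a)) >= 0))
})

test_that("repression function is inert for the control circuit and guarded at zero TetR", {
  expect_equal(f_T(runif(5, 0, 10), 37, p_ctrl), rep(1, 5))
  expect_equal(f_T(0, 50, p_exp), 1)
  p1 <- circuit_params(lam = 1, m = 1, n_t = 1, K_t = 0.7)
  expect_equal(f_T(p1$K_t, 0, p1), 0.5)
  # continuity at tetR -> 0 with atc > 0 (naive evaluation is singular there)
  small <- f_T(c(1e-13, 1e-11, 1e-9, 1e-6), 40, p_exp)
  expect_true(all(abs(small - 1) < 1e-6))
  # monotone: nonincreasing in tetR, nondecreasing in atc
  tt <- seq(0.01, 5, length.out = 60)
  expect_true(all(diff(f_T(tt, 10, p_exp)) <= 1e-12))
  av <- seq(0, 200, length.out = 60)
  expect_true(all(diff(vapply(av, function(a) f_T(1.5, a, p_exp), 0)) >= -1e-12))
})

test_that("binding activity interpolates between C_min and C_max", {
  expect_equal(s_A(0, p_exp), p_exp$C_min)
  expect_equal(s_A(p_exp$K_a, p_exp), (p_exp$C_min + p_exp$C_max) / 2)
  big <- s_A(c(1, 10, 100), p_exp)
  expect_true(all(diff(big) > 0))
  expect_true(all(big < p_exp$C_max))
  expect_gt(big[3], 0.999 * p_exp$C_max)
})

test_that("burden function is unity iff the circuit is silent and decreases with load", {
  expect_equal(f_G(0, 0, p_exp), 1)
  expect_equal(f_G(p_exp$J_a, p_exp$J_t, p_exp), 1 / 3)
  expect_lt(f_G(2, 1, p_exp), f_G(1, 1, p_exp))
  expect_lt(f_G(1, 2, p_exp), f_G(1, 1, p_exp))
})

test_that("regulation and burden functions stay in [0, 1] over random inputs", {
  set.seed(11)
  for (i in 1:200) {
    a <- runif(1, 0, 50); t <- runif(1, 0, 20); atc <- runif(1, 0, 300)
    sa <- runif(1, 0, 200)
    vals <- c(f_A(a, sa), f_T(t, atc, p_exp), f_G(a, t, p_exp))
    expect_true(all(vals >= 0 & vals <= 1))
  }
})

test_that("growth law is logistic with burden and vanishes at the boundaries", {
  g <- growth_params(k_g = 0.8)
  expect_equal(growth_rate(system_state(1, 1, 0), p_exp, g), 0)
  expect_equal(growth_rate(system_state(1, 1, g$N0), p_exp, g), 0)
  # silent circuit at half capacity: the logistic maximum k_g * N0 / 4
  expect_equal(growth_rate(system_state(0, 0, 0.5), p_exp, g), 0.8 / 4)
})

test_that("dilution augments degradation and is nonnegative up to carrying capacity", {
  g <- growth_params(k_g = 0.5)
  expect_equal(dilution_rate(system_state(0, 0, 0.5), p_exp, growth_params(k_g = 0)), 0)
  expect_equal(dilution_rate(system_state(1, 1, g$N0), p_exp, g), 0)
  expect_equal(dilution_rate(system_state(0, 0, 0.5), p_exp, g), 0.25)
  set.seed(7)
  for (i in 1:100) {
    st <- random_state()
    expect_gte(dilution_rate(st, p_exp, g), 0)
  }
})

test_that("rhs reduces to basal production at the origin and respects fixed points", {
  g <- growth_params(k_g = 0.4)
  d0 <- rhs(system_state(0, 0, 0), inducers(0, 0), p_exp, g)
  expect_equal(unname(d0), c(p_exp$k0_a, p_exp$k0_t, 0))
  # analytic fixed point at carrying capacity: tetR = k0_t/db_t, araC from
  # the one-dimensional balance found by the equilibria module
  fp <- fixed_points(p_exp, 0, 20)
  st <- system_state(fp$araC[1], p_exp$k0_t / p_exp$db_t, g$N0)
  expect_lt(max(abs(rhs(st, inducers(0, 20), p_exp, g))), 1e-8)
})

test_that("with lam = 0 the full rhs equals a repression-free model elementwise", {
  p_free <- p_ctrl
  set.seed(23)
  for (i in 1:50) {
    st <- random_state()
    ind <- inducers(runif(1, 0, 3e-3), runif(1, 0, 100))
    g <- growth_params(k_g = runif(1, 0, 2))
    lhs_d <- rhs(st, ind, p_ctrl, g)
    # manual repression-free right-hand side
    dil <- dilution_rate(st, p_free, g)
    da <- p_free$k0_a + p_free$k1_a * f_A(st[["araC"]], s_A(ind$lara, p_free)) -
      (p_free$db_a + dil) * st[["araC"]]
    expect_equal(unname(lhs_d[["araC"]]), da, tolerance = 1e-12)
  }
})

test_that("rhs is continuous across the tetR guard threshold", {
  g <- growth_params(k_g = 0.3)
  below <- rhs(system_state(0.5, 1e-13, 0.5), inducers(1e-3, 30), p_exp, g)
  above <- rhs(system_state(0.5, 1e-11, 0.5), inducers(1e-3, 30), p_exp, g)
  expect_lt(max(abs(below - above)), 1e-8)
})

test_that("parameter validation rejects invalid inputs", {
  expect_error(circuit_params(K_a = 0), "strictly positive")
  expect_error(circuit_params(k1_a = -1), "nonnegative")
  expect_error(circuit_params(C_min = 5, C_max = 2), "C_max")
  expect_error(growth_params(k_g = -0.1))
  expect_error(inducers(lara = -1))
  expect_error(system_state(araC = -1))
})

test_that("config round-trips through YAML with unknown keys rejected", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(p_exp, growth_params(k_g = 0.42), path)
  cfg <- read_config(path)
  expect_equal(unclass(cfg$params), unclass(p_exp))
  expect_equal(cfg$growth$k_g, 0.42)
  yaml::write_yaml(list(k0_a = 1, bogus = 2), path)
  expect_error(read_config(path), "unknown config keys")
  yaml::write_yaml(list(k0_a = 0.01), path)
  expect_warning(cfg2 <- read_config(path), "missing")
  expect_equal(cfg2$params$k0_a, 0.01)
  expect_equal(cfg2$params$K_t, p_exp$K_t)
})
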