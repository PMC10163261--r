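test_that("class I extension gap vanishes at rest and respects the phase rules", {
  cc <- fx_const()
  sp <- structural_params_c1(32, 10, 4.4, 3.2, cc$segments)
  expect_equal(extension_gap_c1(0, sp, cc$pc), 0)
  # untilted or fully folded geometries never produce a catch branch
  f <- seq(0.05, 60, length.out = 800)
  sp0 <- structural_params_c1(0, 7, 5.2, 2, cc$segments)
  expect_true(all(extension_gap_c1(f, sp0, cc$pc) > 0))
  spn <- structural_params_c1(30, 0, 8, 2, cc$segments)
  dz <- extension_gap_c1(f, spn, cc$pc)
  expect_true(all(dz > 0) || all(dz < 0))   # monotone deformation only
})

test_that("catch-slip parameter sets change sign exactly once", {
  m <- fx_class1()
  f <- seq(0.05, 60, length.out = 1200)
  dz <- extension_gap_c1(f, m$sp, m$pc)
  sgn <- sign(dz)
  expect_identical(sgn[1], -1)
  expect_identical(sgn[length(sgn)], 1)
  expect_identical(sum(diff(sgn) != 0), 1L)
})

test_that("parameter validation rejects invalid class I geometries", {
  seg <- fx_const()$segments
  expect_error(structural_params_c1(95, 5, 4, 2, seg), "theta")
  expect_error(structural_params_c1(30, -1, 4, 2, seg), "n_star")
  expect_error(structural_params_c1(30, 5, -4, 2, seg), "d_alpha3")
})

test_that("accumulated deformation integrates the gap exactly", {
  cc <- fx_const()
  m <- fx_class1()
  # empty integral
  expect_identical(energy_shift_c1(0, m$sp, cc$pc)$dl_gamma, 0)
  # constant-gap stub integrates to delta_z * F exactly
  stub <- gamma_functional(function(f) rep(0.7, length(f)))
  expect_equal(stub$dl_gamma(c(3, 11, 27)), 0.7 * c(3, 11, 27),
               tolerance = 1e-12)
  # adaptive quadrature against a dense trapezoid oracle
  F <- 24
  fgrid <- seq(0, F, length.out = 1e5 + 1)
  dz <- extension_gap_c1(fgrid, m$sp, cc$pc)
  trap <- sum((dz[-1] + dz[-length(dz)]) / 2) * (F / 1e5)
  es <- energy_shift_c1(F, m$sp, cc$pc)
  expect_equal(es$dl_gamma, trap, tolerance = 1e-6)
  expect_equal(es$gamma, es$dl_gamma / m$sp$delta0)
  # the fast Gauss-Legendre path agrees with the adaptive quadrature
  expect_equal(m$g$dl_gamma(F), es$dl_gamma, tolerance = 1e-8)
})

test_that("deformation derivative round-trips to the extension gap", {
  cc <- fx_const()
  m <- fx_class1()
  F <- c(2, 8, 15, 28)
  h <- 1e-4
  num <- (m$g$dl_gamma(F + h) - m$g$dl_gamma(F - h)) / (2 * h)
  expect_equal(num, extension_gap_c1(F, m$sp, cc$pc), tolerance = 1e-6)
})

test_that("contour criterion is linear in n* and satisfied after fitting", {
  cc <- fx_const()
  # constructed to satisfy the criterion exactly
  m <- fx_class1(delta0 = 2.8, n_star = 9)
  expect_equal(contour_consistency(m$sp, cc$pc), 0, tolerance = 1e-12)
  # increasing n* by dn changes the residual by dn * l_c
  sp2 <- structural_params_c1(m$sp$theta_deg, m$sp$n_star + 3, m$sp$d_alpha3,
                              m$sp$delta0, cc$segments)
  expect_equal(contour_consistency(sp2, cc$pc) -
                 contour_consistency(m$sp, cc$pc), 3 * cc$pc$l_c,
               tolerance = 1e-12)
  # the fit penalty drives the residual to ~0
  m0 <- fx_class1()
  ds <- bond_lifetime_dataset(seq(2, 30, length.out = 8),
                              1 / m0$rate(seq(2, 30, length.out = 8)),
                              rep(0.01, 8), rep(50, 8))
  fit <- fit_bond_model(ds, "classI", cc$pc, cc$segments, n_restarts = 3)
  expect_lt(abs(fit$contour_residual), 1e-3)
})

test_that("catch-slip occurrence matches the existence conditions across sweeps", {
  set.seed(77)
  cc <- fx_const()
  lp <- landscape_params(1, 2, kBT = cc$pc$kBT)
  for (i in 1:40) {
    theta <- runif(1, 0, 55)
    n_star <- runif(1, 0, 15)
    da3 <- runif(1, 3, 7)
    sp <- structural_params_c1(theta, n_star, da3, lp$delta0, cc$segments)
    g <- gamma_class1(sp, cc$pc)
    lab <- classify_bond_type(lp, g)
    if (lab == "catch-slip") {
      expect_gt(n_star, 0)
      expect_gt(theta, 0)
      expect_gt(g$dl_gamma(60), 0)
    }
    if (n_star == 0 || theta == 0) expect_false(lab == "catch-slip")
  }
})

test_that("stronger tilt strengthens and shifts the catch bond upward in force", {
  # exploring theta freely at the reference constants
  cc <- fx_const()
  m1 <- fx_class1(delta0 = 3.2, n_star = 10, theta = 30)
  m2 <- fx_class1(delta0 = 3.2, n_star = 10, theta = 40)
  met1 <- extract_metrics(m1$rate)
  met2 <- extract_metrics(m2$rate)
  expect_gt(met2$F_opt, met1$F_opt)
  expect_gt(met2$t_peak, met1$t_peak)
})
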