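test_that("noise-free structural fits recover their generating parameters", {
  cc <- fx_const()
  F <- seq(2, 30, length.out = 8)
  m1 <- fx_class1()
  ds1 <- bond_lifetime_dataset(F, 1 / m1$rate(F), rep(0.01, 8), rep(50, 8))
  fit1 <- fit_bond_model(ds1, "classI", cc$pc, cc$segments)
  expect_true(all(abs(fit1$par - m1$truth) / m1$truth < 1e-3))
  expect_gt(fit1$r_squared, 1 - 1e-8)
  expect_equal(fit1$DeltaG0, log(fit1$k_w / fit1$par[["k0"]]),
               tolerance = 1e-12)

  m2 <- fx_class2()
  ds2 <- bond_lifetime_dataset(F, 1 / m2$rate(F), rep(0.01, 8), rep(50, 8))
  fit2 <- fit_bond_model(ds2, "classII", cc$pc, cc$segments)
  expect_true(all(abs(fit2$par - m2$truth) / m2$truth < 1e-3))
})

test_that("fitting is deterministic for a fixed dataset and grid", {
  cc <- fx_const()
  ds <- make_dataset(simulation_spec(fx_class1()$rate, seed = 31))
  f1 <- fit_bond_model(ds, "classI", cc$pc, cc$segments, n_restarts = 3)
  f2 <- fit_bond_model(ds, "classI", cc$pc, cc$segments, n_restarts = 3)
  expect_identical(f1$par, f2$par)
})

test_that("SEM-refit uncertainty is zero without noise and grows with it", {
  cc <- fx_const()
  F <- seq(2, 30, length.out = 8)
  m <- fx_class1()
  y <- 1 / m$rate(F)
  ds0 <- suppressWarnings(bond_lifetime_dataset(F, y, rep(0, 8), rep(50, 8)))
  fit0 <- fit_bond_model(ds0, "classI", cc$pc, cc$segments,
                         init = as.list(m$truth))
  se0 <- fit_uncertainty(ds0, fit0)
  expect_true(all(se0 < 1e-4))
  # scalar inflation of all SEMs inflates every refit half-spread
  ds1 <- bond_lifetime_dataset(F, y, 0.05 * y, rep(50, 8))
  ds2 <- bond_lifetime_dataset(F, y, 0.15 * y, rep(50, 8))
  h1 <- attr(fit_uncertainty(ds1, fit_bond_model(
    ds1, "classI", cc$pc, cc$segments, init = as.list(m$truth))),
    "refit_half_spread")
  h2 <- attr(fit_uncertainty(ds2, fit_bond_model(
    ds2, "classI", cc$pc, cc$segments, init = as.list(m$truth))),
    "refit_half_spread")
  expect_true(all(h2 >= h1 - 1e-10))
  expect_gt(sum(h2), sum(h1))
})

test_that("goodness of fit follows the coefficient-of-determination conventions", {
  F <- c(2, 8, 16, 30)
  y <- c(1.4, 2.0, 1.1, 0.6)
  ds <- bond_lifetime_dataset(F, y, rep(0.1, 4), rep(50, 4))
  # perfect prediction
  expect_equal(goodness_of_fit(ds, function(f) y)$r_squared, 1)
  # constant prediction different from the mean scores below zero
  expect_lt(goodness_of_fit(ds, function(f) rep(2, 4))$r_squared, 0)
  # hand-computed textbook value
  pred <- c(1.5, 1.8, 1.2, 0.5)
  sse <- sum((y - pred)^2)
  sst <- sum((y - mean(y))^2)
  expect_equal(goodness_of_fit(ds, function(f) pred)$r_squared, 1 - sse / sst,
               tolerance = 1e-12)
})

test_that("the generic two-pathway model fits structural catch data comparably", {
  cc <- fx_const()
  ds <- make_dataset(simulation_spec(fx_class1()$rate, seed = 404))
  f_struct <- fit_bond_model(ds, "classI", cc$pc, cc$segments, n_restarts = 3)
  f_two <- fit_bond_model(ds, "two_pathway", cc$pc, cc$segments,
                          n_restarts = 4)
  expect_lt(f_two$sse, f_struct$sse * 1.25)
  expect_lt(f_two$par[["delta_p1"]], 0)   # catch pathway has negative distance
})

test_that("parameters pinned at a box edge are flagged", {
  cc <- fx_const()
  F <- seq(2, 30, length.out = 8)
  # data from an extreme catch bond pushes delta0 to its physical cap
  y <- 1 / fx_class1(delta0 = 4.9, n_star = 13)$rate(F)
  ds <- bond_lifetime_dataset(F, y * exp(0.3 * sin(1:8)), 0.1 * y, rep(50, 8))
  fit <- fit_bond_model(ds, "classI", cc$pc, cc$segments, n_restarts = 3)
  expect_type(fit$at_bound, "logical")
  expect_named(fit$at_bound, names(fit$par))
})
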