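test_that("prefactor constraint fixes the barrier height", {
  lp <- landscape_params(k0 = 0.8, delta0 = 2)
  expect_equal(lp$DeltaG0, log(1e6 / 0.8), tolerance = 1e-9)
  expect_error(landscape_params(k0 = -1, delta0 = 2), "k0")
  expect_error(landscape_params(k0 = 1, delta0 = 2, k_w = 0.5), "k_w")
})

test_that("undeformed landscape has the right barrier and cubic symmetry", {
  lp <- landscape_params(1, 2, kBT = 4.11)
  g0 <- gamma_linear(0)
  expect_equal(energy_profile(lp$delta0, 0, lp, g0) -
                 energy_profile(0, 0, lp, g0), lp$DeltaG0, tolerance = 1e-12)
  # antisymmetry of the linear-cubic form about delta0/2
  d <- seq(0, lp$delta0, length.out = 21)
  lhs <- energy_profile(d, 0, lp, g0) - energy_profile(lp$delta0 / 2, 0, lp, g0)
  rhs <- -(energy_profile(lp$delta0 - d, 0, lp, g0) -
             energy_profile(lp$delta0 / 2, 0, lp, g0))
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("profile stationary points match the closed-form well and barrier", {
  lp <- landscape_params(1, 2, kBT = 4.11)
  g <- gamma_linear(0.8)        # constant positive extension gap
  F <- 12
  eps <- 2 * g$dl_gamma(F) / (3 * lp$DeltaG0 * lp$kBT)
  well <- lp$delta0 / 2 * (1 - sqrt(1 - eps))
  barrier <- lp$delta0 / 2 * (1 + sqrt(1 - eps))
  grid <- seq(-0.5, lp$delta0 + 0.5, length.out = 40001)
  prof <- energy_profile(grid, F, lp, g)
  inner <- grid > -0.2 & grid < lp$delta0 + 0.2
  expect_equal(grid[inner][which.min(prof[inner] + 1e9 * (grid[inner] > lp$delta0 / 2))],
               well, tolerance = 1e-3)
  expect_equal(grid[which.max(prof - 1e9 * (grid < lp$delta0 / 2))],
               barrier, tolerance = 1e-3)
})

test_that("off-rate recovers k0 at rest and the Bell model at small deformation", {
  lp <- landscape_params(1.3, 1.5, kBT = 4.11)
  g <- gamma_linear(lp$delta0)   # gamma(F) = F
  expect_equal(as.numeric(off_rate(0, lp, g)), lp$k0, tolerance = 1e-14)
  # forces where the deformation is within 1% of the barrier scale
  Fmax <- 0.01 * 3 * lp$DeltaG0 * lp$kBT / (2 * lp$delta0^2)
  F <- seq(0, Fmax, length.out = 20)
  bell <- bell_rate(F, lp$k0, lp$delta0, lp$kBT)
  expect_true(all(abs(as.numeric(off_rate(F, lp, g)) / bell - 1) < 0.02))
})

test_that("linear gamma reproduces an independent DHS transcription to 1e-12", {
  lp <- landscape_params(0.6, 2.2, kBT = 4.11)
  g <- gamma_linear(lp$delta0)
  # literal transcription of the linear-cubic escape-rate formula
  dhs <- function(F) {
    x <- 1 - 2 * lp$delta0 * F / (3 * lp$DeltaG0 * lp$kBT)
    lp$k0 * sqrt(x) * exp(lp$DeltaG0 * (1 - x^(3 / 2)))
  }
  F <- seq(0, 25, length.out = 40)
  expect_equal(as.numeric(off_rate(F, lp, g)), dhs(F), tolerance = 1e-12)
})

test_that("barrier geometry obeys the cubic identity and the vanishing point", {
  lp <- landscape_params(1, 2, kBT = 4.11)
  g <- gamma_linear(0.9)
  bs <- barrier_state(0, lp, g)
  expect_equal(bs$delta_star, lp$delta0)
  expect_equal(bs$DeltaG_star, lp$DeltaG0)
  F <- seq(0, 40, length.out = 200)
  bs <- barrier_state(F, lp, g)
  ok <- !bs$barrierless
  expect_equal(bs$DeltaG_star[ok] / lp$DeltaG0,
               (bs$delta_star[ok] / lp$delta0)^3, tolerance = 1e-9)
  # gamma at the vanishing point kills the barrier
  Fv <- 3 * lp$DeltaG0 * lp$kBT / 2 / 0.9
  bv <- barrier_state(Fv, lp, g)
  expect_equal(bv$DeltaG_star, 0, tolerance = 1e-6)
  expect_equal(bv$delta_star, 0, tolerance = 1e-3)
})

test_that("barrierless regime is capped at the prefactor and flagged", {
  lp <- landscape_params(1, 2, kBT = 4.11)
  g <- gamma_linear(2)
  Fbig <- 3 * lp$DeltaG0 * lp$kBT / (2 * 2) * 1.2
  k <- off_rate(Fbig, lp, g)
  expect_equal(as.numeric(k), lp$k_w)
  expect_true(attr(k, "barrierless"))
  expect_error(energy_profile(1, Fbig, lp, g), class = "catchbond_barrierless")
})

test_that("critical force identifies the analytic condition that produced it", {
  # monotone Bell-type gamma with a huge barrier: no stationary rate
  lp_big <- landscape_params(1, 2, DeltaG0 = 50, k_w = 1e30, kBT = 4.11)
  cf <- critical_force(lp_big, gamma_linear(0.01))
  expect_identical(cf$criterion, "monotonic")
  # monotone gamma whose barrier crosses kBT/3 at finite force
  lp <- landscape_params(1, 2, kBT = 4.11)
  g <- gamma_linear(lp$delta0)
  cf <- critical_force(lp, g)
  expect_identical(cf$criterion, "barrier")
  eps <- 2 * g$dl_gamma(cf$F0) / (3 * lp$DeltaG0 * lp$kBT)
  expect_equal(lp$DeltaG0 * (1 - eps)^1.5, 1 / 3, tolerance = 1e-6)
  # biphasic gamma: stationary deformation point, against a grid argmin
  m <- fx_class1()
  cf <- critical_force(m$lp, m$g)
  expect_identical(cf$criterion, "gamma_prime")
  grid <- seq(0.05, 60, length.out = 6000)
  kk <- as.numeric(off_rate(grid, m$lp, m$g))
  expect_equal(cf$F0, grid[which.min(kk)], tolerance = 0.02)
})

test_that("classification agrees with the lifetime-shape oracle on random draws", {
  set.seed(202)
  cc <- fx_const()
  n_agree <- 0; n_tot <- 120
  for (i in seq_len(n_tot)) {
    cls <- sample(c("I", "II"), 1)
    n_star <- runif(1, 0, 15)
    theta <- if (cls == "I") runif(1, 0, 55) else runif(1, 0, 12)
    delta0 <- runif(1, 0.5, 4.5)
    k0 <- exp(runif(1, log(0.2), log(5)))
    lp <- landscape_params(k0, delta0, kBT = cc$pc$kBT)
    g <- if (cls == "I") {
      da3 <- runif(1, 2.5, 7.5)
      gamma_class1(structural_params_c1(theta, n_star, da3, delta0,
                                        cc$segments), cc$pc)
    } else {
      gamma_class2(structural_params_c2(theta, n_star, delta0, cc$segments),
                   cc$pc)
    }
    if (classify_bond_type(lp, g) == fx_shape_oracle(lp, g))
      n_agree <- n_agree + 1
  }
  expect_identical(n_agree, n_tot)
})

test_that("phase diagram has a slip-only theta=0 row and stable, contiguous domains", {
  cc <- fx_const()
  lp <- landscape_params(1, 2, kBT = cc$pc$kBT)
  ns <- seq(0, 15, length.out = 9)
  th <- seq(0, 60, length.out = 9)
  pd <- phase_diagram(ns, th, lp, cc$pc, cc$segments, mhc_class = "I")
  expect_true(all(pd$label[pd$theta_deg == 0] == "slip-only"))
  expect_true(all(pd$label[pd$n_star == 0] != "catch-slip"))
  # refinement stability on coincident nodes
  pd2 <- phase_diagram(seq(0, 15, length.out = 17), seq(0, 60, length.out = 17),
                       lp, cc$pc, cc$segments, mhc_class = "I")
  merged <- merge(pd, pd2, by = c("n_star", "theta_deg"))
  expect_identical(merged$label.x, merged$label.y)
  # contiguity: each observed label forms one connected component (4-neighbour)
  lab <- matrix(pd$label, nrow = length(ns))
  n_comp <- function(mask) {
    seen <- matrix(FALSE, nrow(mask), ncol(mask)); comps <- 0
    for (s in which(mask)) {
      if (seen[s]) next
      comps <- comps + 1
      queue <- s
      while (length(queue)) {
        idx <- queue[1]; queue <- queue[-1]
        if (seen[idx]) next
        seen[idx] <- TRUE
        i <- (idx - 1) %% nrow(mask) + 1; j <- (idx - 1) %/% nrow(mask) + 1
        for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
          ii <- i + d[1]; jj <- j + d[2]
          if (ii >= 1 && ii <= nrow(mask) && jj >= 1 && jj <= ncol(mask) &&
              mask[ii, jj] && !seen[ii + (jj - 1) * nrow(mask)])
            queue <- c(queue, ii + (jj - 1) * nrow(mask))
        }
      }
    }
    comps
  }
  for (l in unique(pd$label)) expect_lte(n_comp(lab == l), 1)
})
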