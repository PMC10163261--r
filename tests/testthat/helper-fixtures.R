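# Shared fixtures: model constants and reference parameter sets built in code.

fx_const <- function() default_constants()

# Class I system obeying the contour criterion and (by default) the
# pulling-constraint tilt relation; returns landscape params, gamma
# functional and the rate-law closure.
fx_class1 <- function(k0 = 1, delta0 = 3.2, n_star = 10, theta = NULL,
                      cc = fx_const()) {
  pc <- cc$pc; seg <- cc$segments
  if (is.null(theta)) theta <- tilt_from_unfolding(n_star, pc, seg, "I")
  d_alpha3 <- seg$N$d_c + delta0 - seg$BI$d_c - seg$Calphabeta$d_c -
    n_star * pc$l_c
  sp <- structural_params_c1(theta, n_star, d_alpha3, delta0, seg)
  lp <- landscape_params(k0, delta0, kBT = pc$kBT)
  g <- gamma_class1(sp, pc)
  list(sp = sp, lp = lp, g = g, pc = pc, seg = seg,
       rate = function(F) as.numeric(off_rate(F, lp, g)),
       truth = c(k0 = k0, delta0 = delta0, theta = theta, n_star = n_star,
                 d_alpha3 = d_alpha3))
}

fx_class2 <- function(k0 = 1, delta0 = 2, n_star = 9, theta = NULL,
                      cc = fx_const()) {
  pc <- cc$pc; seg <- cc$segments
  if (is.null(theta)) theta <- tilt_from_unfolding(n_star, pc, seg, "II")
  sp <- structural_params_c2(theta, n_star, delta0, seg)
  lp <- landscape_params(k0, delta0, kBT = pc$kBT)
  g <- gamma_class2(sp, pc)
  list(sp = sp, lp = lp, g = g, pc = pc, seg = seg,
       rate = function(F) as.numeric(off_rate(F, lp, g)),
       truth = c(k0 = k0, delta0 = delta0, theta = theta, n_star = n_star))
}

# brute-force bond-type oracle: shape analysis of the lifetime curve on the
# force range where the Kramers barrier stays above kBT/3
fx_shape_oracle <- function(lp, g, f_max = 60, n_grid = 1500) {
  grid <- seq(f_max / n_grid, f_max, length.out = n_grid)
  eps <- 2 * g$dl_gamma(grid) / (3 * lp$DeltaG0 * lp$kBT)
  ok <- lp$DeltaG0 * (1 - pmin(eps, 1))^1.5 > 1 / 3
  if (!all(ok)) {
    last <- which(!ok)[1] - 1L
    if (last < 10L) return("slip-only")
    grid <- grid[seq_len(last)]
  }
  tl <- 1 / as.numeric(off_rate(grid, lp, g))
  t0 <- 1 / lp$k0
  i <- which.max(tl)
  if (tl[i] <= t0 * (1 + 1e-9)) return("slip-only")
  if (i == length(tl)) return("catch-only")
  "catch-slip"
}
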