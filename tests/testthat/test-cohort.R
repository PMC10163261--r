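test_that("k-means recovers well-separated parameter groups exactly", {
  set.seed(41)
  blob <- function(cx, cy, n) cbind(rnorm(n, cx, 0.05), rnorm(n, cy, 0.05))
  X <- rbind(blob(0, 0, 6), blob(5, 0, 6), blob(0, 5, 6))
  tab <- data.frame(delta0 = X[, 1], theta = X[, 2],
                    n_star = 0, d_alpha3 = 0,
                    I = rep(c(0, 0.2, 0.4), each = 6))
  cl <- cluster_bond_types(tab, seed = 2)
  expect_identical(cl$labels, rep(c("SO", "WC", "SC"), each = 6))
  # affine rescaling of a feature does not change memberships
  tab2 <- tab
  tab2$theta <- tab2$theta * 40 + 7
  cl2 <- cluster_bond_types(tab2, seed = 2)
  expect_identical(cl2$labels, cl$labels)
})

test_that("k-means objective matches an exhaustive partition search on a toy set", {
  set.seed(6)
  X <- matrix(rnorm(18), ncol = 2)
  tab <- data.frame(delta0 = X[, 1], theta = X[, 2], n_star = 0,
                    d_alpha3 = 0, I = seq_len(9))
  cl <- cluster_bond_types(tab, features = c("delta0", "theta"), k = 3,
                           restarts = 100, seed = 4, standardize = FALSE)
  Xs <- as.matrix(tab[, c("delta0", "theta")])
  withinss <- function(assign) {
    sum(vapply(unique(assign), function(a) {
      pts <- Xs[assign == a, , drop = FALSE]
      sum(scale(pts, scale = FALSE)^2)
    }, numeric(1)))
  }
  best <- Inf
  grid <- expand.grid(rep(list(1:3), 8))   # first point fixed to cluster 1
  for (i in seq_len(nrow(grid))) {
    assign <- c(1L, as.integer(grid[i, ]))
    if (length(unique(assign)) == 3L) best <- min(best, withinss(assign))
  }
  expect_equal(cl$tot_withinss, best, tolerance = 1e-9)
})

test_that("Mahalanobis distances are zero at centroids and match the direct formula", {
  set.seed(12)
  # cluster "a": symmetric pair plus its own centroid (row 3)
  a <- rbind(c(1, 5, 1, 4), c(3, 7, 3, 5), c(2, 6, 2, 4.5))
  b <- matrix(rep(c(11, 31, 10, 6.5), each = 6), ncol = 4) +
    matrix(rnorm(24, sd = 0.8), ncol = 4)
  tab <- as.data.frame(rbind(a, b))
  names(tab) <- c("delta0", "theta", "n_star", "d_alpha3")
  labels <- rep(c("a", "b"), c(3, 6))
  mh <- pca_mahalanobis(tab, labels)
  expect_true(all(mh$mahalanobis >= 0))
  expect_equal(mh$mahalanobis[3], 0, tolerance = 1e-8)   # centroid of "a"
  # direct covariance-inverse computation on the common principal axes
  pca <- attr(mh, "pca")
  keep <- pca$sdev > 1e-8 * pca$sdev[1]
  S <- pca$x[, keep, drop = FALSE]
  idx <- which(labels == "b")
  Sc <- S[idx, , drop = FALSE]
  d_direct <- sqrt(stats::mahalanobis(Sc, colMeans(Sc), stats::cov(Sc)))
  expect_equal(mh$mahalanobis[idx], unname(d_direct), tolerance = 1e-9)
})

test_that("potency correlations reproduce exact linear relations", {
  x <- c(1, 2, 3, 4)
  pc_ <- potency_correlation(0.4 * x, x, log_transform = FALSE)
  expect_equal(pc_$slope, 0.4, tolerance = 1e-12)
  expect_equal(pc_$r_squared, 1, tolerance = 1e-12)
  # closed-form normal equations on a printed toy
  xs <- c(0.5, 1.1, 2.0, 3.2); ys <- c(0.9, 1.4, 2.1, 3.4)
  pc2 <- potency_correlation(ys, xs, log_transform = FALSE)
  b <- (sum(xs * ys) - length(xs) * mean(xs) * mean(ys)) /
    (sum(xs^2) - length(xs) * mean(xs)^2)
  expect_equal(pc2$slope, b, tolerance = 1e-12)
  expect_equal(pc2$intercept, mean(ys) - b * mean(xs), tolerance = 1e-12)
  # log transform applied to the potency axis
  pot <- 10^xs
  expect_equal(potency_correlation(ys, pot)$slope, b, tolerance = 1e-9)
})

test_that("cross-examination refuses single-system cohorts", {
  cc <- fx_const()
  ds <- make_dataset(simulation_spec(fx_class1()$rate, seed = 2))
  expect_error(cross_examine(list(a = ds), cc$pc, cc$segments),
               "at least two")
})

test_that("York regression undoes attenuation from noisy abscissae", {
  set.seed(13)
  n <- 40
  x_true <- runif(n, 5, 15)
  sx <- rep(1.2, n)
  x_obs <- x_true + rnorm(n, 0, 1.2)
  y <- 0.35 * x_true - 0.3 + rnorm(n, 0, 0.05)
  naive <- unname(stats::coef(stats::lm(y ~ x_obs))[2])
  yk <- catchbond:::.york(x_obs, y, sx, rep(0.05, n))
  expect_lt(abs(yk$slope - 0.35), abs(naive - 0.35))
  expect_lt(abs(yk$slope - 0.35), 2.5 * yk$se_slope)
})
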