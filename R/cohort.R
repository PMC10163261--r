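#' Build a cohort table from fits
#'
#' One row per fitted system: model parameters, bond-profile metrics and
#' optional potency, ready for clustering and correlation analyses.
#'
#' @param fits named list of \code{bond_fit} objects.
#' @param potency optional named/numeric potency values (e.g. 1/EC50).
#' @param f_max metric-extraction force limit (pN).
#' @return Data frame (CohortTable) with one row per system.
#' @export
cohort_table <- function(fits, potency = NULL, f_max = 60) {
  rows <- lapply(seq_along(fits), function(i) {
    fit <- fits[[i]]
    met <- extract_metrics(fit, f_max = f_max)
    p <- fit$par
    data.frame(
      system = names(fits)[i] %||% sprintf("sys%02d", i),
      model = fit$model,
      k0 = p[["k0"]],
      delta0 = if ("delta0" %in% names(p)) p[["delta0"]] else NA_real_,
      theta = if ("theta" %in% names(p)) p[["theta"]] else NA_real_,
      n_star = if ("n_star" %in% names(p)) p[["n_star"]] else NA_real_,
      d_alpha3 = if ("d_alpha3" %in% names(p)) p[["d_alpha3"]] else NA_real_,
      I = met$I, L = met$L, B = met$B, t_peak = met$t_peak,
      Delta_t = met$Delta_t, F_opt = met$F_opt, F_range = met$F_range,
      bond_type = met$bond_type, r_squared = fit$r_squared,
      potency = if (is.null(potency)) NA_real_ else potency[i])
  })
  tab <- do.call(rbind, rows)
  if (anyDuplicated(paste(tab$system, tab$model)))
    stop("duplicated system+model rows in cohort table", call. = FALSE)
  tab
}

# mean silhouette width for a clustering (small-n helper)
.mean_silhouette <- function(X, labels) {
  n <- nrow(X)
  if (length(unique(labels)) < 2 || n < 3) return(NA_real_)
  D <- as.matrix(stats::dist(X))
  s <- vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    a <- if (sum(own) > 1) mean(D[i, own & seq_len(n) != i]) else 0
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(D[i, labels == l]), numeric(1)))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

#' Cluster fitted bond parameters into bond-type groups
#'
#' Lloyd's k-means on standardized parameter features. With k = 3 the
#' clusters are relabelled SO / WC / SC in increasing order of their mean
#' catch-bond intensity.
#'
#' @param table cohort data frame (see \code{\link{cohort_table}}); must
#'   contain the feature columns and, for canonical ordering, column \code{I}.
#' @param features feature columns; default \code{c("delta0", "theta",
#'   "n_star", "d_alpha3", "I")} (k0 is excluded: it does not correlate with
#'   catch-bond intensity; the fitted intensity I is included because, with
#'   the pulling-constraint tie, the structural parameters span essentially
#'   one noisy direction and I is the most precisely estimated discriminant
#'   of weak versus strong catch bonds).
#' @param k number of clusters (default 3).
#' @param restarts random restarts of Lloyd's algorithm (default 50).
#' @param seed integer seed making the restarts deterministic.
#' @param standardize scale features to zero mean, unit variance (default).
#' @return List with \code{labels} (character vector, SO/WC/SC when k = 3),
#'   \code{cluster} (integer ids), \code{centroids} (original feature scale),
#'   \code{tot_withinss}, and \code{silhouette} (mean width).
#' @export
cluster_bond_types <- function(table,
                               features = c("delta0", "theta", "n_star",
                                            "d_alpha3", "I"),
                               k = 3, restarts = 50, seed = 1,
                               standardize = TRUE) {
  features <- intersect(features, names(table))
  X <- as.matrix(table[, features, drop = FALSE])
  if (nrow(X) < k) stop("need at least k rows to form k clusters",
                        call. = FALSE)
  Xs <- if (standardize) scale(X) else X
  Xs[, apply(Xs, 2, function(c) any(!is.finite(c)))] <- 0  # constant feature
  set.seed(seed)
  # Lloyd restarts occasionally propose empty clusters; kmeans keeps the
  # best non-degenerate solution across restarts
  km <- suppressWarnings(stats::kmeans(Xs, centers = k, nstart = restarts,
                                       algorithm = "Lloyd", iter.max = 200))
  ord <- if (!is.null(table$I)) {
    meanI <- tapply(table$I, km$cluster, mean)
    order(meanI)
  } else order(km$centers[, 1])
  rank_of <- match(km$cluster, ord)
  lab_names <- if (k == 3) c("SO", "WC", "SC")
               else paste0("C", seq_len(k))
  centroids <- do.call(rbind, lapply(ord, function(cl)
    colMeans(X[km$cluster == cl, , drop = FALSE])))
  rownames(centroids) <- lab_names
  list(labels = lab_names[rank_of], cluster = rank_of,
       centroids = centroids, tot_withinss = km$tot.withinss,
       silhouette = .mean_silhouette(Xs, km$cluster), km = km,
       features = features, seed = seed)
}

#' PCA scores and per-cluster Mahalanobis distances
#'
#' Principal component analysis of the pooled standardized features gives
#' common axes; each row's Mahalanobis distance is computed to its own
#' cluster's centroid using the cluster covariance on those common axes
#' (pooled covariance is substituted when a cluster is too small for a
#' stable inverse).
#'
#' @param table cohort data frame.
#' @param labels cluster labels, one per row.
#' @param features feature columns.
#' @return Data frame with \code{system} (when present), \code{label} and
#'   \code{mahalanobis}; the PCA object is attached as attribute
#'   \code{"pca"}.
#' @export
pca_mahalanobis <- function(table, labels,
                            features = c("delta0", "theta", "n_star",
                                         "d_alpha3")) {
  features <- intersect(features, names(table))
  X <- scale(as.matrix(table[, features, drop = FALSE]))
  X[, apply(X, 2, function(c) any(!is.finite(c)))] <- 0
  pca <- stats::prcomp(X, center = FALSE, scale. = FALSE)
  # drop numerically null axes so covariance inverses stay stable
  keep <- pca$sdev > 1e-8 * pca$sdev[1]
  S <- pca$x[, keep, drop = FALSE]
  pooled <- stats::cov(S)
  if (rcond(pooled) < 1e-12)
    pooled <- pooled + diag(1e-8 * mean(diag(pooled)), ncol(pooled))
  d <- numeric(nrow(S))
  for (l in unique(labels)) {
    idx <- which(labels == l)
    Sc <- S[idx, , drop = FALSE]
    ctr <- colMeans(Sc)
    cv <- if (length(idx) > ncol(S) + 1) stats::cov(Sc) else pooled
    if (rcond(cv) < 1e-12) cv <- pooled
    d[idx] <- sqrt(stats::mahalanobis(Sc, ctr, cv))
  }
  out <- data.frame(label = labels, mahalanobis = d)
  if (!is.null(table$system)) out <- cbind(system = table$system, out)
  attr(out, "pca") <- pca
  out
}

#' Linear correlation of a bond metric with ligand potency
#'
#' Ordinary least squares of the metric against log10 potency (the potency
#' proxy, e.g. 1/EC50, is log-transformed by default).
#'
#' @param metric numeric response (metric or model parameter values).
#' @param potency numeric potency proxy, same length.
#' @param log_transform log10-transform potency first (default TRUE).
#' @return List with \code{slope}, \code{intercept}, \code{se_slope},
#'   \code{se_intercept}, \code{r_squared}, \code{n}.
#' @export
potency_correlation <- function(metric, potency, log_transform = TRUE) {
  ok <- is.finite(metric) & is.finite(potency)
  x <- if (log_transform) log10(potency[ok]) else potency[ok]
  y <- metric[ok]
  if (length(y) < 3) stop("need at least 3 points for a slope with SE",
                          call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))   # exact relations trip lm's warning
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       se_slope = sm$coefficients[2, 2],
       se_intercept = sm$coefficients[1, 2],
       r_squared = sm$r.squared, n = length(y))
}

# OLS summary used by cross_examine; when per-point SEs are supplied the
# slope comes from York errors-in-variables regression, which corrects the
# attenuation caused by noise in the fitted n* and down-weights points whose
# x is poorly determined
.ols <- function(x, y, se_x = NULL, se_y = NULL, r_xy = NULL) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 2) stop("slope undefined: need at least two systems",
                        call. = FALSE)
  fit <- stats::lm(y[ok] ~ x[ok])
  sm <- suppressWarnings(summary(fit))
  slope <- unname(stats::coef(fit)[2])
  se_slope <- if (sum(ok) > 2) sm$coefficients[2, 2] else NA_real_
  r2 <- sm$r.squared
  if (!is.null(se_x) && sum(ok) > 3) {
    yk <- .york(x[ok], y[ok], se_x[ok],
                if (is.null(se_y)) rep(stats::sd(y[ok]) * 0.1, sum(ok))
                else se_y[ok],
                r = if (is.null(r_xy)) NULL else r_xy[ok])
    slope <- yk$slope
    se_slope <- yk$se_slope
  }
  list(slope = slope, se_slope = se_slope, r_squared = r2, n = sum(ok))
}

# York (2004) bivariate errors-in-variables straight-line fit, with optional
# per-point error correlation r
.york <- function(x, y, sx, sy, r = NULL, iter = 200, tol = 1e-10) {
  sx <- pmax(sx, 1e-6)
  sy <- pmax(sy, 1e-6)
  if (is.null(r)) r <- rep(0, length(x))
  r <- pmin(pmax(r, -0.99), 0.99)
  wx <- 1 / sx^2
  wy <- 1 / sy^2
  alpha <- sqrt(wx * wy)
  b <- stats::coef(stats::lm(y ~ x))[2]
  step <- function(b) {
    W <- wx * wy / (wx + b^2 * wy - 2 * b * r * alpha)
    xb <- sum(W * x) / sum(W)
    yb <- sum(W * y) / sum(W)
    U <- x - xb
    V <- y - yb
    beta <- W * (U / wy + b * V / wx - (b * U + V) * r / alpha)
    list(b = sum(W * beta * V) / sum(W * beta * U), W = W, xb = xb, yb = yb,
         beta = beta)
  }
  for (i in seq_len(iter)) {
    s <- step(b)
    if (!is.finite(s$b)) break
    if (abs(s$b - b) < tol) { b <- s$b; break }
    b <- s$b
  }
  s <- step(b)
  a <- s$yb - b * s$xb
  xadj <- s$xb + s$beta
  u <- xadj - sum(s$W * xadj) / sum(s$W)
  se_b <- sqrt(1 / sum(s$W * u^2))
  list(slope = unname(b), intercept = unname(a), se_slope = se_b)
}

#' Cross-examination of the class I and class II models
#'
#' Fits every dataset with both structural models, then summarises, per
#' model, the linear dependence of the fitted well width delta0 on the
#' catch-bond intensity I and on the unfolded amino-acid count n*. The
#' delta0-vs-n* slope estimates the average unfolding extension per amino
#' acid and must not exceed the ~0.4 nm/aa contour-length limit.
#'
#' @param datasets named list of \code{\link{bond_lifetime_dataset}}s.
#' @param pc,segments model constants.
#' @param f_max metric-extraction force limit (pN).
#' @param uncertainty compute per-fit SEs (via \code{\link{fit_uncertainty}})
#'   and use them to correct the delta0-vs-n* slope for attenuation by
#'   measurement error in the fitted n* (default TRUE).
#' @param ... passed to \code{\link{fit_bond_model}}.
#' @return List with \code{tables} (per-model cohort tables) and
#'   \code{summary} (data frame: model, slope/SE/R2 of delta0 vs I and
#'   delta0 vs n*).
#' @export
cross_examine <- function(datasets, pc = default_constants()$pc,
                          segments = default_constants()$segments,
                          f_max = 60, uncertainty = TRUE, ...) {
  if (length(datasets) < 2)
    stop("slope undefined: need at least two datasets", call. = FALSE)
  tables <- list()
  for (model in c("classI", "classII")) {
    fits <- lapply(datasets, fit_bond_model, model = model, pc = pc,
                   segments = segments, ...)
    tab <- cohort_table(fits, f_max = f_max)
    if (uncertainty) {
      ses <- lapply(seq_along(fits), function(i)
        fit_uncertainty(datasets[[i]], fits[[i]]))
      tab$se_n_star <- vapply(ses, function(s) s[["n_star"]], numeric(1))
      tab$se_delta0 <- vapply(ses, function(s) s[["delta0"]], numeric(1))
      tab$r_d0_n <- vapply(fits, function(f) {
        V <- f$vcov_curvature
        if (is.null(V) || !all(c("delta0", "n_star") %in% rownames(V)))
          return(0)
        d <- sqrt(V["delta0", "delta0"] * V["n_star", "n_star"])
        if (d <= 0) 0 else V["delta0", "n_star"] / d
      }, numeric(1))
    } else {
      tab$se_n_star <- tab$se_delta0 <- NA_real_
      tab$r_d0_n <- NA_real_
    }
    tables[[model]] <- tab
  }
  summ <- do.call(rbind, lapply(names(tables), function(model) {
    tab <- tables[[model]]
    a <- .ols(tab$I, tab$delta0)
    b <- .ols(tab$n_star, tab$delta0,
              se_x = if (uncertainty) tab$se_n_star else NULL,
              se_y = if (uncertainty) tab$se_delta0 else NULL,
              r_xy = if (uncertainty) tab$r_d0_n else NULL)
    data.frame(model = model,
               slope_delta0_I = a$slope, se_delta0_I = a$se_slope,
               r2_delta0_I = a$r_squared,
               slope_delta0_n = b$slope, se_delta0_n = b$se_slope,
               r2_delta0_n = b$r_squared)
  }))
  list(tables = tables, summary = summ)
}
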