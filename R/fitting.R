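# Fast fixed-order Gauss-Legendre accumulation of the extension gap:
# dl_gamma(F_j) for all F_j with a single vectorised delta_z call.
.dlgamma_gl <- function(delta_z, F, n = 24) {
  gl <- .gl_nodes(n)
  half <- as.numeric(F) / 2
  nodes <- as.vector(outer(gl$x + 1, half))
  vals <- matrix(delta_z(nodes), nrow = n)
  half * colSums(vals * gl$w)
}

# model metadata: parameter names, box bounds
.model_info <- function(model) {
  switch(model,
    classI = list(
      # physically admissible region: an Ig-fold alpha3 spans 2-8 nm, the
      # interdomain joints hold at most ~16 unfoldable residues, and the
      # force-free well width cannot exceed a few nm
      par_names = c("k0", "delta0", "theta", "n_star", "d_alpha3"),
      lower = c(1e-3, 0.3, 0, 0, 2),
      upper = c(100, 5, 60, 16, 8)),
    classII = list(
      par_names = c("k0", "delta0", "theta", "n_star"),
      lower = c(1e-3, 0.3, 0, 0),
      upper = c(100, 5, 15, 16)),
    two_pathway = list(
      par_names = c("k0_p1", "k0_p2", "delta_p1", "delta_p2"),
      lower = c(1e-6, 1e-6, -5, 1e-3),
      upper = c(1e3, 1e3, 0, 5)),
    bell = list(
      par_names = c("k0", "delta0"),
      lower = c(1e-6, 0),
      upper = c(1e3, 10)),
    stop("unknown model: ", model, call. = FALSE))
}

# Predicted mean lifetime at forces F for a named parameter vector.
.predict_lifetime <- function(model, par, F, pc, segments, k_w = 1e6) {
  kBT <- pc$kBT
  if (model %in% c("classI", "classII")) {
    k0 <- par[["k0"]]
    DeltaG0 <- log(k_w / k0)
    sp <- if (model == "classI")
      structural_params_c1(par[["theta"]], par[["n_star"]], par[["d_alpha3"]],
                           par[["delta0"]], segments)
    else
      structural_params_c2(par[["theta"]], par[["n_star"]], par[["delta0"]],
                           segments)
    dz <- if (model == "classI") function(f) extension_gap_c1(f, sp, pc)
          else function(f) extension_gap_c2(f, sp, pc)
    dlg <- .dlgamma_gl(dz, F)
    eps <- 2 * dlg / (3 * DeltaG0 * kBT)
    bl <- eps >= 1
    epsc <- pmin(eps, 1)
    k <- k0 * sqrt(1 - epsc) * exp(DeltaG0 * (1 - (1 - epsc)^1.5))
    k[bl] <- k_w
    1 / pmin(k, k_w)
  } else if (model == "two_pathway") {
    1 / (par[["k0_p1"]] * exp(par[["delta_p1"]] * F / kBT) +
           par[["k0_p2"]] * exp(par[["delta_p2"]] * F / kBT))
  } else {
    1 / (par[["k0"]] * exp(par[["delta0"]] * F / kBT))
  }
}

# deterministic initial-value grid per model
.init_grid <- function(model, ds, pc, segments) {
  k0_init <- 1 / ds$mean_lifetime[1]
  if (model == "bell")
    return(expand.grid(k0 = k0_init * c(0.5, 1, 2),
                       delta0 = c(0.1, 0.5, 1, 2), KEEP.OUT.ATTRS = FALSE))
  if (model == "two_pathway")
    return(expand.grid(k0_p1 = k0_init * c(0.5, 1, 2),
                       k0_p2 = c(0.001, 0.01, 0.1) * k0_init,
                       delta_p1 = c(-0.3, -1, -2.5),
                       delta_p2 = c(0.5, 1, 2.5), KEEP.OUT.ATTRS = FALSE))
  theta_init <- if (model == "classI") c(0, 15, 30, 45) else c(0, 2, 5, 8)
  g <- expand.grid(k0 = k0_init, delta0 = c(0.5, 1, 2, 4),
                   theta = theta_init, n_star = c(0, 3, 6, 9, 12),
                   KEEP.OUT.ATTRS = FALSE)
  if (model == "classI") {
    dN <- segments$N$d_c
    g$d_alpha3 <- pmin(pmax(
      dN + g$delta0 - segments$BI$d_c - segments$Calphabeta$d_c -
        g$n_star * pc$l_c, 0.3), 12)
  }
  g
}

#' Fit a rate law to a bond-lifetime dataset
#'
#' Levenberg-Marquardt least squares on mean lifetime versus force, with a
#' deterministic multi-start initial grid. Structural models carry the
#' prefactor constraint \code{DeltaG0 = log(k_w / k0)}; the class I model adds
#' the contour-length consistency penalty tying \code{d_alpha3} to the other
#' parameters.
#'
#' @param ds a \code{\link{bond_lifetime_dataset}}.
#' @param model one of "classI", "classII", "two_pathway", "bell".
#' @param pc a \code{\link{polymer_constants}}.
#' @param segments named segment list (class I/II models).
#' @param init optional named list/vector of start values (replaces the grid).
#' @param weights "none" (paper default: unweighted fit of mean lifetimes) or
#'   "sem" for 1/SEM^2 weighting.
#' @param n_restarts number of grid starts refined with LM (best by initial
#'   objective), default 6.
#' @param k_w prefactor (1/s).
#' @param penalty_weight weight (per nm) of the class I contour penalty.
#' @param so_threshold relative lifetime-peak gain below which a fitted
#'   curve is treated as slip-only and reported as the slip-region solution
#'   (no unfolded residues); default 0.02, far below the per-bin SEM at the
#'   experimental 50 dwells per bin.
#' @param tie_theta apply the pulling-constraint relation
#'   \code{\link{tilt_from_unfolding}} so the tilt angle is derived from
#'   \code{n_star} rather than fitted freely (default TRUE; structural models
#'   only). The reported parameter vector always includes \code{theta}.
#' @return An object of class \code{bond_fit}: best-fit parameters, fitted
#'   values, residuals, R-squared, convergence diagnostics, the implied
#'   \code{DeltaG0}, the contour-consistency residual (class I), and
#'   bound-hit flags.
#' @export
fit_bond_model <- function(ds, model = c("classI", "classII", "two_pathway",
                                         "bell"),
                           pc = default_constants()$pc,
                           segments = default_constants()$segments,
                           init = NULL, weights = c("none", "sem"),
                           n_restarts = 6, k_w = 1e6, penalty_weight = 1e3,
                           tie_theta = TRUE, so_threshold = 0.02) {
  stopifnot(inherits(ds, "bond_lifetime_dataset"))
  model <- match.arg(model)
  weights <- match.arg(weights)
  info <- .model_info(model)
  structural <- model %in% c("classI", "classII")
  tied <- tie_theta && structural
  free_names <- if (tied) setdiff(info$par_names, "theta") else info$par_names
  fidx <- match(free_names, info$par_names)
  F <- ds$force
  y <- ds$mean_lifetime
  w <- if (weights == "sem") 1 / pmax(ds$sem, 1e-6 * mean(y))^2
       else rep(1, length(y))
  sw <- sqrt(w)

  full_par <- function(p) {
    par <- stats::setNames(numeric(length(info$par_names)), info$par_names)
    # numeric-jacobian probes may step marginally outside the box
    par[free_names] <- pmin(pmax(as.numeric(p), info$lower[fidx]),
                            info$upper[fidx])
    if (tied)
      par[["theta"]] <- tilt_from_unfolding(
        par[["n_star"]], pc, segments,
        mhc_class = if (model == "classI") "I" else "II")
    par
  }

  resid_fn <- function(p) {
    par <- full_par(p)
    pred <- .predict_lifetime(model, par, F, pc, segments, k_w)
    r <- sw * (y - pred)
    if (model == "classI") {
      sp <- structural_params_c1(par[["theta"]], par[["n_star"]],
                                 par[["d_alpha3"]], par[["delta0"]], segments)
      r <- c(r, penalty_weight * contour_consistency(sp, pc))
    }
    r
  }

  starts <- if (!is.null(init)) {
    v <- unlist(init)
    if (tied && !all(free_names %in% names(v)))
      stop("init must name parameters ", paste(free_names, collapse = ", "),
           call. = FALSE)
    as.data.frame(as.list(v[free_names]))
  } else {
    g <- unique(.init_grid(model, ds, pc, segments)[, free_names,
                                                    drop = FALSE])
    sse <- vapply(seq_len(nrow(g)), function(i)
      sum(resid_fn(as.numeric(g[i, ]))^2), numeric(1))
    g[order(sse)[seq_len(min(n_restarts, nrow(g)))], , drop = FALSE]
  }

  lower <- info$lower[fidx]
  upper <- info$upper[fidx]
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    p0 <- pmin(pmax(as.numeric(starts[i, ]), lower), upper)
    res <- tryCatch(
      minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-10)),
      error = function(e) NULL)
    if (is.null(res)) next
    sse <- res$deviance
    if (is.null(best) || sse < best$deviance) best <- res
  }
  if (is.null(best))
    stop("fitting failed from every start", call. = FALSE)

  # Slip-only shaped solutions are reported in the slip-only region of the
  # parameter space (no unfolded residues): a monotone curve carries no
  # information about n*, so the unconstrained optimum is an arbitrary point
  # on the catch-cancelling ridge. A fitted peak below the detection floor
  # (2% lifetime gain, far under the per-bin SEM at 50 dwells/bin) is not
  # evidence of catch and is treated the same way.
  so_region <- FALSE
  if (structural) {
    par0 <- full_par(best$par)
    fgrid <- seq(0, 60, length.out = 601)
    tl0 <- .predict_lifetime(model, par0, fgrid, pc, segments, k_w)
    if (max(tl0) <= tl0[1] * (1 + so_threshold) && par0[["n_star"]] > 1e-6) {
      upper_so <- upper
      upper_so[match("n_star", free_names)] <- 1e-9
      k0_init <- 1 / y[1]
      best_so <- NULL
      for (d0 in c(0.3, 0.6, 1, 2)) {
        st <- stats::setNames(as.numeric(best$par), free_names)
        st[["k0"]] <- k0_init
        st[["delta0"]] <- d0
        st[["n_star"]] <- 0
        if ("d_alpha3" %in% free_names)
          st[["d_alpha3"]] <- min(max(
            segments$N$d_c + d0 - segments$BI$d_c - segments$Calphabeta$d_c,
            lower[match("d_alpha3", free_names)]),
            upper[match("d_alpha3", free_names)])
        p0 <- pmin(pmax(as.numeric(st), lower), upper_so)
        res <- tryCatch(
          minpack.lm::nls.lm(par = p0, lower = lower, upper = upper_so,
                             fn = resid_fn,
                             control = minpack.lm::nls.lm.control(
                               maxiter = 200, ftol = 1e-12, ptol = 1e-10)),
          error = function(e) NULL)
        if (!is.null(res) &&
            (is.null(best_so) || res$deviance < best_so$deviance))
          best_so <- res
      }
      if (!is.null(best_so)) {
        best <- best_so
        so_region <- TRUE
      }
    }
  }

  par <- full_par(best$par)
  fitted <- .predict_lifetime(model, par, F, pc, segments, k_w)
  residuals <- y - fitted
  sst <- sum((y - mean(y))^2)
  r2 <- 1 - sum(residuals^2) / sst

  # curvature standard errors: sandwich covariance using the known per-bin
  # SEMs (the noise is heteroscedastic, sigma_bin = SEM), with the contour
  # penalty row regularising the constrained direction; a tied tilt angle
  # inherits its SE from n_star
  se_curv <- stats::setNames(rep(NA_real_, length(par)), names(par))
  p_hat <- par[free_names]
  r0 <- resid_fn(p_hat)
  J <- vapply(seq_along(p_hat), function(j) {
    h <- max(1e-6, 1e-6 * abs(p_hat[j]))
    (resid_fn(replace(p_hat, j, p_hat[j] + h)) -
       resid_fn(replace(p_hat, j, p_hat[j] - h))) / (2 * h)
  }, numeric(length(r0)))
  ndata <- length(F)
  sigma <- ds$sem * sw[seq_len(ndata)]
  A <- tryCatch(solve(crossprod(J)), error = function(e) NULL)
  vcov_curv <- NULL
  if (!is.null(A)) {
    Jd <- J[seq_len(ndata), , drop = FALSE]
    # HC1-style finite-sample correction for the sandwich estimator
    B <- crossprod(Jd * sigma) * ndata / max(1, ndata - length(p_hat))
    V <- A %*% B %*% A
    dimnames(V) <- list(free_names, free_names)
    vcov_curv <- V
    se_curv[free_names] <- sqrt(pmax(diag(V), 0))
    if (tied) {
      mhc <- if (model == "classI") "I" else "II"
      se_curv[["theta"]] <- abs(
        tilt_from_unfolding(par[["n_star"]] + se_curv[["n_star"]], pc,
                            segments, mhc) -
        tilt_from_unfolding(par[["n_star"]], pc, segments, mhc))
    }
  }
  at_bound <- stats::setNames(rep(FALSE, length(par)), names(par))
  at_bound[free_names] <- par[free_names] <= lower + 1e-8 |
    par[free_names] >= upper - 1e-8
  contour_res <- if (model == "classI") {
    sp <- structural_params_c1(par[["theta"]], par[["n_star"]],
                               par[["d_alpha3"]], par[["delta0"]], segments)
    contour_consistency(sp, pc)
  } else NA_real_
  DeltaG0 <- if (model %in% c("classI", "classII")) log(k_w / par[["k0"]])
             else NA_real_

  structure(list(
    model = model, par = par, se = NULL, se_curvature = se_curv,
    vcov_curvature = vcov_curv,
    fitted = fitted, residuals = residuals, r_squared = r2,
    sse = sum(residuals^2), DeltaG0 = DeltaG0, k_w = k_w,
    contour_residual = contour_res, at_bound = at_bound,
    convergence = list(info = best$info, message = best$message,
                       niter = best$niter, converged = best$info %in% 1:4),
    so_region = so_region, tie_theta = tied, free_names = free_names,
    data = ds, pc = pc, segments = segments, weights = weights),
    class = "bond_fit")
}

#' @export
print.bond_fit <- function(x, ...) {
  cat("bond_fit [", x$model, "]  R^2 =", format(x$r_squared, digits = 4), "\n")
  print(round(x$par, 4))
  if (!is.null(x$se)) {
    cat("SE:\n")
    print(round(stats::setNames(as.numeric(x$se), names(x$se)), 4))
  }
  if (any(x$at_bound))
    cat("note: parameter(s) at bound:",
        paste(names(x$par)[x$at_bound], collapse = ", "), "\n")
  invisible(x)
}

#' Predicted mean lifetime from a fit
#'
#' @param object a \code{\link{fit_bond_model}} result.
#' @param F forces (pN); defaults to the fitted data forces.
#' @param ... unused.
#' @return Predicted mean lifetimes (s).
#' @export
predict.bond_fit <- function(object, F = object$data$force, ...) {
  .predict_lifetime(object$model, object$par, F, object$pc, object$segments,
                    object$k_w)
}

#' Off-rate function implied by a fit
#'
#' @param fit a \code{bond_fit}.
#' @return Vectorised function of force (pN) returning the rate (1/s).
#' @export
rate_function <- function(fit) {
  stopifnot(inherits(fit, "bond_fit"))
  function(F) 1 / predict(fit, F)
}

#' Parameter standard errors by mean +/- SEM refitting
#'
#' Refits the model to the (mean + SEM) and (mean - SEM) lifetime curves,
#' starting from the best-fit parameters; the refit half-spread per parameter
#' measures the fit's sensitivity to a coherent level shift of the data. That
#' spread is blind to uncertainty directions orthogonal to a level shift, so
#' by default it is combined in quadrature with the curvature (asymptotic
#' Levenberg-Marquardt) standard error, which captures shape-parameter
#' uncertainty; \code{method = "refit"} returns the bare half-spread.
#'
#' @param ds the fitted \code{\link{bond_lifetime_dataset}}.
#' @param fit the \code{bond_fit} from \code{\link{fit_bond_model}}.
#' @param method "combined" (default) or "refit".
#' @return Named numeric vector of per-parameter SEs, with attributes
#'   \code{par_plus} and \code{par_minus} holding the two refits and
#'   \code{refit_half_spread} the bare refit component.
#' @export
fit_uncertainty <- function(ds, fit, method = c("combined", "refit")) {
  stopifnot(inherits(ds, "bond_lifetime_dataset"), inherits(fit, "bond_fit"))
  method <- match.arg(method)
  refit <- function(shift) {
    y <- pmax(ds$mean_lifetime + shift * ds$sem, 1e-4 * ds$mean_lifetime)
    ds2 <- bond_lifetime_dataset(ds$force, y, ds$sem, ds$n,
                                 system = attr(ds, "system"))
    fit_bond_model(ds2, model = fit$model, pc = fit$pc,
                   segments = fit$segments, init = as.list(fit$par),
                   weights = fit$weights, k_w = fit$k_w,
                   tie_theta = fit$tie_theta)$par
  }
  p_plus <- refit(+1)
  p_minus <- refit(-1)
  half <- abs(p_plus - p_minus) / 2
  se <- if (method == "refit") half else {
    cv <- fit$se_curvature
    cv[!is.finite(cv)] <- 0
    sqrt(half^2 + cv^2)
  }
  attr(se, "par_plus") <- p_plus
  attr(se, "par_minus") <- p_minus
  attr(se, "refit_half_spread") <- half
  se
}

#' Goodness of fit
#'
#' Coefficient of determination against the binned mean lifetimes, with
#' residual diagnostics. A fit no better than the constant mean gives
#' R-squared <= 0 by this convention.
#'
#' @param ds a \code{\link{bond_lifetime_dataset}}.
#' @param fit a \code{bond_fit} (or any object usable by \code{predict} at
#'   \code{ds$force}).
#' @return List with \code{r_squared}, \code{sse}, \code{rmse},
#'   \code{residuals}.
#' @export
goodness_of_fit <- function(ds, fit) {
  pred <- if (inherits(fit, "bond_fit")) predict(fit, ds$force)
          else fit(ds$force)
  res <- ds$mean_lifetime - pred
  sse <- sum(res^2)
  sst <- sum((ds$mean_lifetime - mean(ds$mean_lifetime))^2)
  list(r_squared = 1 - sse / sst, sse = sse,
       rmse = sqrt(mean(res^2)), residuals = res)
}
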