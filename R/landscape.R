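#' Kinetic landscape parameters
#'
#' Parameters of the force-free linear-cubic energy landscape: zero-force
#' off-rate \code{k0} (1/s), well-to-barrier distance \code{delta0} (nm),
#' barrier height \code{DeltaG0} (kBT units) and the attempt-frequency
#' prefactor \code{k_w} (1/s). When \code{DeltaG0} is not supplied the
#' prefactor constraint \code{DeltaG0 = log(k_w / k0)} is applied.
#'
#' @param k0 zero-force off-rate (1/s).
#' @param delta0 force-free well-to-barrier distance (nm).
#' @param DeltaG0 force-free barrier height (kBT); default \code{log(k_w/k0)}.
#' @param k_w prefactor (1/s), default 1e6.
#' @param kBT thermal energy (pN nm).
#' @return An object of class \code{landscape_params}.
#' @export
landscape_params <- function(k0, delta0, DeltaG0 = NULL, k_w = 1e6,
                             kBT = 4.11) {
  if (k0 <= 0 || delta0 <= 0 || k_w < k0 || kBT <= 0)
    stop("require k0 > 0, delta0 > 0, k_w >= k0, kBT > 0", call. = FALSE)
  constrained <- is.null(DeltaG0)
  if (constrained) DeltaG0 <- log(k_w / k0)
  if (DeltaG0 <= 0) stop("DeltaG0 must be positive", call. = FALSE)
  structure(list(k0 = k0, delta0 = delta0, DeltaG0 = DeltaG0, k_w = k_w,
                 kBT = kBT, prefactor_constrained = constrained),
            class = "landscape_params")
}

#' @export
print.landscape_params <- function(x, ...) {
  cat(sprintf(
    "landscape: k0 = %.4g /s, delta0* = %.3g nm, DeltaG0* = %.3g kBT, k_w = %.3g /s\n",
    x$k0, x$delta0, x$DeltaG0, x$k_w))
  invisible(x)
}

# -- Gauss-Legendre nodes (Golub-Welsch), cached per order ------------------
.gl_cache <- new.env(parent = emptyenv())
.gl_nodes <- function(n) {
  key <- as.character(n)
  if (!is.null(.gl_cache[[key]])) return(.gl_cache[[key]])
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  out <- list(x = e$values, w = 2 * e$vectors[1, ]^2)
  .gl_cache[[key]] <- out
  out
}

#' Construct a gamma functional
#'
#' A gamma functional packages the extension gap \code{delta_z(f)} (nm) between
#' the transition-state and bound-state conformations and its accumulated
#' energy \code{dl_gamma(F) = integral of delta_z from 0 to F} (pN nm), which
#' deforms the landscape by \code{-delta_l * gamma(F)}.
#'
#' @param delta_z vectorised function of force (pN) returning nm.
#' @param dl_gamma optional vectorised integral function (pN nm); when omitted
#'   it is built from \code{delta_z} by fixed-order Gauss-Legendre quadrature.
#' @param class model label: "I", "II", "bell", "dhs" or "custom".
#' @return An object of class \code{gamma_functional}.
#' @export
gamma_functional <- function(delta_z, dl_gamma = NULL, class = "custom") {
  stopifnot(is.function(delta_z))
  if (is.null(dl_gamma)) {
    dl_gamma <- function(F) {
      gl <- .gl_nodes(32)
      half <- as.numeric(F) / 2
      nodes <- as.vector(outer(gl$x + 1, half))
      vals <- matrix(delta_z(nodes), nrow = 32)
      half * colSums(vals * gl$w)
    }
  }
  structure(list(delta_z = delta_z, dl_gamma = dl_gamma, class = class),
            class = "gamma_functional")
}

#' Linear (Bell/DHS-type) gamma functional
#'
#' Constant extension gap \code{delta_z0}, so \code{dl_gamma(F) = delta_z0 * F}.
#' With \code{delta_z0 = delta0} this reproduces the
#' Dudko-Hummer-Szabo linear-cubic rate, and in the small-deformation limit the
#' Bell model.
#'
#' @param delta_z0 constant extension gap (nm).
#' @return A \code{\link{gamma_functional}} with class label "dhs".
#' @export
gamma_linear <- function(delta_z0) {
  force(delta_z0)
  gamma_functional(function(f) rep(delta_z0, length(f)),
                   function(F) delta_z0 * F, class = "dhs")
}

# Dimensionless landscape deformation 2*delta0*gamma(F) / (3*DeltaG0*kBT).
.epsilon <- function(F, lp, g) {
  2 * g$dl_gamma(F) / (3 * lp$DeltaG0 * lp$kBT)
}

#' Deformed linear-cubic energy profile
#'
#' Evaluates the landscape at dissociation coordinate \code{delta_l} under
#' force \code{F}, reported relative to the instantaneous well level (wells
#' aligned at zero energy).
#'
#' @param delta_l dissociation coordinate (nm), vectorised.
#' @param F clamped force (pN), scalar.
#' @param lp a \code{\link{landscape_params}}.
#' @param g a \code{\link{gamma_functional}}.
#' @return Energy (kBT) relative to the well at force \code{F}.
#' @export
energy_profile <- function(delta_l, F, lp, g) {
  eps <- .epsilon(F, lp, g)
  if (eps > 1)
    stop(structure(class = c("catchbond_barrierless", "error", "condition"),
                   list(message = sprintf(
                     "barrier vanished at F = %g pN (deformation %.3f > 1)",
                     F, eps), call = NULL)))
  gam <- g$dl_gamma(F) / lp$delta0            # pN
  raw <- function(dl) {
    u <- dl / lp$delta0 - 0.5
    1.5 * lp$DeltaG0 * u - 2 * lp$DeltaG0 * u^3 - dl * gam / lp$kBT
  }
  well <- lp$delta0 / 2 * (1 - sqrt(1 - eps))
  raw(delta_l) - raw(well)
}

#' Force-dependent off-rate
#'
#' Kramers off-rate of the deformed linear-cubic landscape. In the barrierless
#' regime (deformation beyond barrier vanishing) the rate is capped at the
#' prefactor \code{k_w} and flagged via the \code{"barrierless"} attribute
#' rather than extrapolated to complex values.
#'
#' @param F force (pN), vectorised, non-negative.
#' @param lp a \code{\link{landscape_params}}.
#' @param g a \code{\link{gamma_functional}}.
#' @return Rate (1/s) with logical attribute \code{barrierless}. Mean bond
#'   lifetime is \code{1 / off_rate(F, ...)}.
#' @export
off_rate <- function(F, lp, g) {
  if (any(F < 0)) stop("force must be non-negative", call. = FALSE)
  eps <- .epsilon(F, lp, g)
  bl <- eps >= 1
  epsc <- pmin(eps, 1)
  k <- lp$k0 * sqrt(1 - epsc) *
    exp(lp$DeltaG0 * (1 - (1 - epsc)^1.5))
  k[bl] <- lp$k_w
  k <- pmin(k, lp$k_w)
  attr(k, "barrierless") <- bl
  k
}

#' Mean bond lifetime
#'
#' Reciprocal of \code{\link{off_rate}}.
#' @inheritParams off_rate
#' @return Mean lifetime (s).
#' @export
bond_lifetime <- function(F, lp, g) {
  k <- off_rate(F, lp, g)
  out <- 1 / as.numeric(k)
  attr(out, "barrierless") <- attr(k, "barrierless")
  out
}

#' Barrier geometry at force F
#'
#' Closed-form transition-state distance \code{delta_star = delta0 *
#' sqrt(1 - eps)} and barrier height \code{DeltaG_star = DeltaG0 *
#' (1 - eps)^(3/2)}, where \code{eps} is the dimensionless deformation.
#'
#' @inheritParams off_rate
#' @return List with \code{delta_star} (nm), \code{DeltaG_star} (kBT),
#'   \code{F} (pN) and \code{barrierless} flag(s); geometry is \code{NA} where
#'   the barrier has vanished.
#' @export
barrier_state <- function(F, lp, g) {
  eps <- .epsilon(F, lp, g)
  bl <- eps > 1
  s <- sqrt(pmax(1 - eps, 0))
  ds <- lp$delta0 * s
  dg <- lp$DeltaG0 * s^3
  ds[bl] <- NA_real_
  dg[bl] <- NA_real_
  list(delta_star = ds, DeltaG_star = dg, F = F, barrierless = bl)
}

# sign-change refinement helper: roots of fn on grid by uniroot
.grid_roots <- function(fn, grid, tol = 1e-8) {
  v <- fn(grid)
  ok <- is.finite(v)
  grid <- grid[ok]; v <- v[ok]
  sgn <- sign(v)
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  vapply(idx, function(i)
    stats::uniroot(fn, c(grid[i], grid[i + 1]), tol = tol)$root, numeric(1))
}

#' Critical force of the lifetime-force curve
#'
#' Finds the smallest positive force where \code{dk/dF = 0}, and reports which
#' analytic condition produced it: the barrier height crossing \code{kBT/3}
#' ("barrier"), or a stationary point of the deformation functional,
#' \code{gamma'(F0) = 0}, equivalently \code{delta_z(F0) = 0} ("gamma_prime").
#'
#' @param lp a \code{\link{landscape_params}}.
#' @param g a \code{\link{gamma_functional}}.
#' @param f_max bracket upper limit (pN), default 200.
#' @return List with \code{F0} (pN, or \code{NA}) and \code{criterion}
#'   ("barrier", "gamma_prime" or "monotonic").
#' @export
critical_force <- function(lp, g, f_max = 200) {
  grid <- seq(1e-6, f_max, length.out = 4001)
  eps <- .epsilon(grid, lp, g)
  valid <- eps < 1
  if (!all(valid)) {
    last <- which(!valid)[1] - 1L
    if (last < 2L) return(list(F0 = NA_real_, criterion = "monotonic"))
    grid <- grid[seq_len(last)]
  }
  barrier_fn <- function(F) lp$DeltaG0 * (1 - .epsilon(F, lp, g))^1.5 - 1 / 3
  r1 <- .grid_roots(barrier_fn, grid)
  r2 <- .grid_roots(g$delta_z, grid)
  cand <- c(r1, r2)
  lab <- c(rep("barrier", length(r1)), rep("gamma_prime", length(r2)))
  keep <- cand > 1e-5
  cand <- cand[keep]; lab <- lab[keep]
  if (length(cand) == 0) return(list(F0 = NA_real_, criterion = "monotonic"))
  i <- which.min(cand)
  list(F0 = cand[i], criterion = lab[i])
}

#' Classify the bond type of a rate law
#'
#' Sign analysis of the extension gap \code{delta_z(f)} over the force range
#' where the Kramers description is valid (barrier above kBT/3): everywhere
#' positive means force only lowers the barrier (slip-only); everywhere
#' negative means force only raises it (catch-only); a single sign change from
#' negative to positive is a catch-slip bond.
#'
#' @inheritParams critical_force
#' @param f_max scan limit (pN), default 60.
#' @return One of "slip-only", "catch-slip", "catch-only".
#' @export
classify_bond_type <- function(lp, g, f_max = 60) {
  grid <- seq(f_max / 2000, f_max, length.out = 2000)
  eps <- .epsilon(grid, lp, g)
  barrier_ok <- lp$DeltaG0 * (1 - pmin(eps, 1))^1.5 > 1 / 3
  if (!all(barrier_ok)) {
    last <- which(!barrier_ok)[1] - 1L
    if (last < 10L) return("slip-only")  # barrier collapses immediately
    grid <- grid[seq_len(last)]
  }
  dz <- g$delta_z(grid)
  if (all(dz >= 0)) return("slip-only")
  if (all(dz <= 0)) return("catch-only")
  if (dz[1] < 0 && dz[length(dz)] > 0) return("catch-slip")
  # fall back to lifetime-curve shape for irregular sign patterns
  tl <- 1 / as.numeric(off_rate(grid, lp, g))
  i <- which.max(tl)
  if (i == 1L) "slip-only" else if (i == length(tl)) "catch-only"
  else "catch-slip"
}

#' Bond-type phase diagram over (n*, theta)
#'
#' Classifies the bond type on a grid of unfolded amino-acid counts and
#' interface tilt angles for the class I or class II extension-gap geometry.
#'
#' @param n_star_grid numeric vector of n* values (aa).
#' @param theta_grid numeric vector of tilt angles (degrees).
#' @param lp a \code{\link{landscape_params}}.
#' @param pc a \code{\link{polymer_constants}}.
#' @param segments named segment list as from \code{\link{default_constants}}.
#' @param mhc_class "I" or "II".
#' @param f_max classification scan limit (pN).
#' @return Data frame with columns \code{n_star}, \code{theta_deg},
#'   \code{label}, one row per grid cell.
#' @export
phase_diagram <- function(n_star_grid, theta_grid, lp,
                          pc = default_constants()$pc,
                          segments = default_constants()$segments,
                          mhc_class = c("I", "II"), f_max = 60) {
  mhc_class <- match.arg(mhc_class)
  grid <- expand.grid(n_star = n_star_grid, theta_deg = theta_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid$label <- vapply(seq_len(nrow(grid)), function(i) {
    if (mhc_class == "I") {
      sp <- structural_params_c1(theta_deg = grid$theta_deg[i],
                                 n_star = grid$n_star[i],
                                 d_alpha3 = segments$alpha3$d_c,
                                 delta0 = lp$delta0, segments = segments)
      g <- gamma_class1(sp, pc)
    } else {
      sp <- structural_params_c2(theta_deg = grid$theta_deg[i],
                                 n_star = grid$n_star[i],
                                 delta0 = lp$delta0, segments = segments)
      g <- gamma_class2(sp, pc)
    }
    classify_bond_type(lp, g, f_max = f_max)
  }, character(1))
  grid
}
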