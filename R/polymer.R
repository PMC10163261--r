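#' Polymer-mechanics constants
#'
#' Bundles the elastic constants used by every force-extension law in the
#' package: the contour and persistence lengths per unfolded amino acid, the
#' enthalpic (stretch) moduli of unfolded polypeptide and folded globular
#' domains, the shared Kuhn segment length of the semi-rigid bodies, and the
#' thermal energy.
#'
#' All rigid bodies share one Kuhn length \code{kuhn_b}: their fractional
#' force-extension response then collapses onto a single Langevin shape, which
#' is what keeps the sign structure of the extension gap controlled purely by
#' projected contour lengths (see the methods vignette).
#'
#' @param l_c contour length per unfolded amino acid (nm/aa).
#' @param l_p persistence length of unfolded polypeptide (nm).
#' @param E_p elastic (stretch) modulus of unfolded polypeptide (pN).
#' @param E_c elastic modulus of folded globular domains (pN).
#' @param kuhn_b Kuhn/segment length shared by the semi-rigid bodies (nm).
#' @param kBT thermal energy (pN nm); 4.11 pN nm at 298 K.
#' @return An object of class \code{polymer_constants}.
#' @export
polymer_constants <- function(l_c = 0.4, l_p = 0.36, E_p = 1000, E_c = 1000,
                              kuhn_b = 3.0, kBT = 4.11) {
  vals <- c(l_c = l_c, l_p = l_p, E_p = E_p, E_c = E_c,
            kuhn_b = kuhn_b, kBT = kBT)
  if (any(!is.finite(vals) & !is.infinite(vals)) || any(vals <= 0))
    stop("all polymer constants must be strictly positive", call. = FALSE)
  structure(as.list(vals), class = "polymer_constants")
}

#' @export
print.polymer_constants <- function(x, ...) {
  cat("polymer constants: l_c =", x$l_c, "nm/aa, l_p =", x$l_p,
      "nm, E_p =", x$E_p, "pN, E_c =", x$E_c, "pN, b =", x$kuhn_b,
      "nm, kBT =", x$kBT, "pN nm\n")
  invisible(x)
}

#' Semi-rigid body segment
#'
#' A folded, globular region of the force-transmission path treated as a
#' freely-jointed chain of contour length \code{d_c}.
#'
#' @param name segment label (e.g. "N", "alpha3", "BI", "Calphabeta").
#' @param d_c force-free contour length (nm), strictly positive.
#' @return An object of class \code{rigid_segment}.
#' @export
rigid_segment <- function(name, d_c) {
  if (!is.character(name) || length(name) != 1L)
    stop("'name' must be a single string", call. = FALSE)
  if (!is.numeric(d_c) || length(d_c) != 1L || !is.finite(d_c) || d_c <= 0)
    stop("segment contour length d_c must be a single positive number",
         call. = FALSE)
  structure(list(name = name, d_c = d_c), class = "rigid_segment")
}

# Langevin function coth(x) - 1/x with a series branch near zero.
.langevin <- function(x) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-4
  out[small] <- x[small] / 3 - x[small]^3 / 45
  xs <- x[!small]
  out[!small] <- 1 / tanh(xs) - 1 / xs
  out
}

#' Freely-jointed-chain extension of a rigid segment
#'
#' Mean projection on the force axis of a 3D freely-jointed chain of contour
#' length \code{d_c} under tension \code{f}, with an enthalpic stretch factor
#' \code{(1 + f / E_c)}. Set \code{E_c = Inf} in the constants to disable the
#' enthalpic term.
#'
#' @param f tensile force (pN), vectorised, non-negative.
#' @param seg a \code{\link{rigid_segment}}.
#' @param pc a \code{\link{polymer_constants}}.
#' @return Extension along the force axis (nm), same length as \code{f}.
#' @export
fjc_extension <- function(f, seg, pc) {
  stopifnot(inherits(seg, "rigid_segment"), inherits(pc, "polymer_constants"))
  if (any(f < 0)) stop("force must be non-negative", call. = FALSE)
  xi <- f * pc$kuhn_b / pc$kBT
  seg$d_c * .langevin(xi) * (1 + f / pc$E_c)
}

# Fractional Marko-Siggia WLC extension x = z/L at force f, solved by a
# bracket-guarded Newton iteration (bisection fallback), tol 1e-12 on x.
.wlc_fraction <- function(f, pc) {
  phi <- f * pc$l_p / pc$kBT              # dimensionless force
  n <- length(phi)
  x <- pmin(0.9, 2 * phi / 3)             # small-force linearisation start
  lo <- numeric(n)
  hi <- rep(1 - 1e-12, n)
  g  <- function(x) 1 / (4 * (1 - x)^2) - 0.25 + x - phi
  gp <- function(x) 1 / (2 * (1 - x)^3) + 1
  for (it in seq_len(120)) {
    gx <- g(x)
    pos <- gx > 0
    hi[pos] <- x[pos]
    lo[!pos] <- x[!pos]
    step <- gx / gp(x)
    xn <- x - step
    bad <- xn <= lo | xn >= hi | !is.finite(xn)
    xn[bad] <- (lo[bad] + hi[bad]) / 2    # bisection fallback
    done <- abs(xn - x) < 1e-12
    x <- xn
    if (all(done) && it > 3) break
  }
  x[phi == 0] <- 0
  x
}

#' Extensible worm-like-chain extension per unfolded amino acid
#'
#' Marko-Siggia interpolation solved for the fractional extension at force
#' \code{f}, plus the enthalpic term \code{f / E_p}, scaled by the contour
#' length per amino acid. Zero at zero force, strictly increasing, bounded by
#' \code{l_c * (1 + f / E_p)}.
#'
#' @param f tensile force (pN), vectorised, non-negative.
#' @param pc a \code{\link{polymer_constants}}.
#' @return Extension per amino acid (nm/aa).
#' @export
ewlc_extension_per_residue <- function(f, pc) {
  stopifnot(inherits(pc, "polymer_constants"))
  if (any(f < 0)) stop("force must be non-negative", call. = FALSE)
  pc$l_c * (.wlc_fraction(f, pc) + f / pc$E_p)
}

#' Marko-Siggia force at a given fractional extension
#'
#' Forward worm-like-chain relation; mainly used to round-trip the inverse
#' solver.
#'
#' @param x fractional extension in [0, 1).
#' @param pc a \code{\link{polymer_constants}}.
#' @return Force (pN).
#' @export
wlc_force <- function(x, pc) {
  stopifnot(inherits(pc, "polymer_constants"))
  if (any(x < 0 | x >= 1)) stop("fractional extension must be in [0, 1)",
                                call. = FALSE)
  pc$kBT / pc$l_p * (1 / (4 * (1 - x)^2) - 0.25 + x)
}
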