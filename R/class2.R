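#' Structural parameters, class II pMHC
#'
#' Class II (pMHC-II) extension-gap parameters. The MHC-II molecule anchors to
#' the membrane through both chains and has no beta2m/alpha3 stalk, so its
#' catch mechanism is dominated by partial unfolding of the MHC alpha1-alpha2
#' and beta1-beta2 joints and the TCR Valpha-Calpha joint; the interface tilt
#' is small and the unfolded joints carry load even without tilt.
#'
#' @param theta_deg tilt angle in degrees, in [0, 90); typically < 10.
#' @param n_star total unfolded amino acids (aa), >= 0; the MHC share is the
#'   average over the alpha1-alpha2 and beta1-beta2 joints.
#' @param delta0 force-free well-to-barrier distance (nm), > 0.
#' @param segments named list of \code{\link{rigid_segment}}s (\code{BI},
#'   \code{Calphabeta}, \code{N} used).
#' @param mhc_fraction fraction of \code{n_star} assigned to the MHC joints.
#' @return An object of class \code{structural_params_c2}.
#' @export
structural_params_c2 <- function(theta_deg, n_star, delta0,
                                 segments = default_constants()$segments,
                                 mhc_fraction = 0.5) {
  if (theta_deg < 0 || theta_deg >= 90)
    stop("theta must lie in [0, 90) degrees", call. = FALSE)
  if (n_star < 0) stop("n_star must be non-negative", call. = FALSE)
  if (delta0 <= 0) stop("delta0 must be positive", call. = FALSE)
  structure(list(theta_deg = theta_deg, n_star = n_star, delta0 = delta0,
                 segments = segments, mhc_fraction = mhc_fraction),
            class = "structural_params_c2")
}

.dN_eff_c2 <- function(sp, pc) {
  dN <- sp$segments$BI$d_c + sp$segments$Calphabeta$d_c +
    sp$n_star * pc$l_c - sp$delta0
  if (dN <= 0)
    stop("invalid geometry: bound-state span non-positive; delta0 too large ",
         "for the configured domain lengths", call. = FALSE)
  dN
}

#' Extension gap of the class II complex
#'
#' Composition for the class II geometry: aligned FJC stretching of the
#' Calpha-Cbeta module, eWLC extension of the unfolded TCR and MHC joints
#' (load-bearing at any tilt, including theta = 0), the bonding interface
#' projected through cos(theta), minus the bound-state whole-complex term.
#'
#' @param f force (pN), vectorised, non-negative.
#' @param sp a \code{\link{structural_params_c2}}.
#' @param pc a \code{\link{polymer_constants}}.
#' @return Extension gap delta_z(f) in nm.
#' @export
extension_gap_c2 <- function(f, sp, pc) {
  stopifnot(inherits(sp, "structural_params_c2"))
  if (any(f < 0)) stop("force must be non-negative", call. = FALSE)
  th <- sp$theta_deg * pi / 180
  # dual membrane anchoring: tilting concentrates load asymmetrically on the
  # unfolded joints, coarse-grained as an enhanced axial force f*(1 + sin th)
  per_aa <- ewlc_extension_per_residue(f * (1 + sin(th)), pc)
  n_mhc <- sp$mhc_fraction * sp$n_star
  n_tcr <- sp$n_star - n_mhc
  z_cab   <- fjc_extension(f, sp$segments$Calphabeta, pc)
  z_p_tcr <- n_tcr * per_aa
  z_p_mhc <- n_mhc * per_aa
  z_bi    <- cos(th) * fjc_extension(f * cos(th), sp$segments$BI, pc)
  # bound state with the transition path's composite compliance shape (see
  # class I): catch behaviour can only come from the unfolded-joint terms
  rigid_ts <- z_bi + z_cab
  rigid_contour <- cos(th) * sp$segments$BI$d_c + sp$segments$Calphabeta$d_c
  z_n <- .dN_eff_c2(sp, pc) * rigid_ts / rigid_contour
  rigid_ts + z_p_tcr + z_p_mhc - z_n
}

#' Accumulated landscape deformation, class II
#'
#' Same contract as \code{\link{energy_shift_c1}} with the class II extension
#' gap.
#'
#' @inheritParams energy_shift_c1
#' @param sp a \code{\link{structural_params_c2}}.
#' @return List with \code{dl_gamma} (pN nm) and \code{gamma} (pN).
#' @export
energy_shift_c2 <- function(F, sp, pc, abs_tol = 1e-6) {
  if (any(F < 0)) stop("force must be non-negative", call. = FALSE)
  dz <- function(f) extension_gap_c2(f, sp, pc)
  dlg <- vapply(F, function(Fi) {
    if (Fi == 0) return(0)
    stats::integrate(dz, 0, Fi, abs.tol = abs_tol, rel.tol = 1e-9,
                     subdivisions = 200L)$value
  }, numeric(1))
  list(dl_gamma = dlg, gamma = dlg / sp$delta0)
}

#' Gamma functional for the class II model
#'
#' @param sp a \code{\link{structural_params_c2}}.
#' @param pc a \code{\link{polymer_constants}}.
#' @return A \code{\link{gamma_functional}} with class label "II".
#' @export
gamma_class2 <- function(sp, pc) {
  force(sp); force(pc)
  gamma_functional(function(f) extension_gap_c2(f, sp, pc), class = "II")
}
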