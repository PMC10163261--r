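#' Structural parameters, class I pMHC
#'
#' Conformational-change parameters of the class I (pMHC-I) extension gap:
#' bonding-interface tilt angle \code{theta_deg}, total number of force-
#' unfolded amino acids \code{n_star} (MHC alpha1alpha2-alpha3 joint plus TCR
#' Valpha-Calpha joint), end-to-end span of the dissociated alpha3 domain
#' \code{d_alpha3}, and the force-free well-to-barrier distance \code{delta0}
#' that closes the bound-state geometry.
#'
#' Only the total \code{n_star} enters the extension gap; the MHC/TCR split is
#' retained for bookkeeping and defaults to half and half.
#'
#' @param theta_deg tilt angle in degrees, in [0, 90).
#' @param n_star total unfolded amino acids (aa), >= 0.
#' @param d_alpha3 dissociated alpha3 end-to-end span (nm), > 0.
#' @param delta0 force-free well-to-barrier distance (nm), > 0.
#' @param segments named list of \code{\link{rigid_segment}}s with entries
#'   \code{N}, \code{alpha3}, \code{BI}, \code{Calphabeta}; \code{alpha3} is
#'   superseded by \code{d_alpha3}.
#' @param mhc_fraction fraction of \code{n_star} assigned to the MHC joint.
#' @return An object of class \code{structural_params_c1}.
#' @export
structural_params_c1 <- function(theta_deg, n_star, d_alpha3, delta0,
                                 segments = default_constants()$segments,
                                 mhc_fraction = 0.5) {
  if (theta_deg < 0 || theta_deg >= 90)
    stop("theta must lie in [0, 90) degrees", call. = FALSE)
  if (n_star < 0) stop("n_star must be non-negative", call. = FALSE)
  if (d_alpha3 <= 0) stop("d_alpha3 must be positive", call. = FALSE)
  if (delta0 <= 0) stop("delta0 must be positive", call. = FALSE)
  if (mhc_fraction < 0 || mhc_fraction > 1)
    stop("mhc_fraction must be in [0, 1]", call. = FALSE)
  structure(list(theta_deg = theta_deg, n_star = n_star,
                 d_alpha3 = d_alpha3, delta0 = delta0,
                 segments = segments, mhc_fraction = mhc_fraction),
            class = "structural_params_c1")
}

# Tilt-recruitment factor: the fraction of the unfolded-joint contour
# mobilised along the force axis grows with interface tilt and vanishes in
# the untilted geometry, where the load path is unchanged.
.recruit_c1 <- function(theta_rad) sin(theta_rad)

#' Pulling-constraint tilt angle
#'
#' The interface tilt is generated by the same conformational change that
#' releases the unfolded joint contour: the bonding interface pivots on the
#' lever formed by its own span, so the tilt angle is tied to the slack
#' released, \code{tan(theta) = n_star * l_c / lever}. The class I lever is
#' the bonding-interface span; the dual-anchored class II platform resists
#' tilting, modelled as a six-fold longer effective lever, which keeps class
#' II tilts below ~10 degrees at realistic n*.
#'
#' This relation is used as a model constraint during fitting (the tilt is
#' not a free parameter there); the landscape and classification machinery
#' accept arbitrary (n*, theta) combinations for exploration.
#'
#' @param n_star unfolded amino-acid count (aa), vectorised.
#' @param pc a \code{\link{polymer_constants}}.
#' @param segments segment list (uses \code{BI}).
#' @param mhc_class "I" or "II".
#' @return Tilt angle in degrees.
#' @export
tilt_from_unfolding <- function(n_star, pc = default_constants()$pc,
                                segments = default_constants()$segments,
                                mhc_class = c("I", "II")) {
  mhc_class <- match.arg(mhc_class)
  lever <- segments$BI$d_c * if (mhc_class == "I") 1 else 6
  atan(n_star * pc$l_c / lever) * 180 / pi
}

# Effective bound-state span closing the transition-state path so the
# force-free coordinate gap equals delta0 (see methods vignette).
.dN_eff_c1 <- function(sp, pc) {
  u <- .recruit_c1(sp$theta_deg * pi / 180)
  dN <- sp$d_alpha3 + sp$segments$BI$d_c + sp$segments$Calphabeta$d_c +
    u * sp$n_star * pc$l_c - sp$delta0
  if (dN <= 0)
    stop("invalid geometry: bound-state span non-positive; delta0 too large ",
         "for the configured domain lengths", call. = FALSE)
  dN
}

#' Extension gap of the class I complex
#'
#' The projection on the force axis of the transition-state extension minus
#' the bound-state extension: FJC terms for the dissociated alpha3 and the
#' tilted bonding interface (both projected through cos(theta)), an aligned
#' FJC term for the Calpha-Cbeta module, eWLC terms for the tilt-recruited
#' unfolded MHC and TCR joints, minus the whole-complex bound-state FJC term.
#'
#' @param f force (pN), vectorised, non-negative.
#' @param sp a \code{\link{structural_params_c1}}.
#' @param pc a \code{\link{polymer_constants}}.
#' @return Extension gap delta_z(f) in nm.
#' @export
extension_gap_c1 <- function(f, sp, pc) {
  stopifnot(inherits(sp, "structural_params_c1"))
  if (any(f < 0)) stop("force must be non-negative", call. = FALSE)
  th <- sp$theta_deg * pi / 180
  u <- .recruit_c1(th)
  # tilted bodies feel the axial force component f*cos(theta) and project
  # back through cos(theta); the unfolded joints are loaded by the
  # tilt-transverse component and project through sin(theta)
  per_aa <- ewlc_extension_per_residue(f * u, pc)
  n_mhc <- sp$mhc_fraction * sp$n_star
  n_tcr <- sp$n_star - n_mhc
  z_alpha3 <- cos(th) *
    fjc_extension(f * cos(th), rigid_segment("alpha3", sp$d_alpha3), pc)
  z_p_mhc  <- u * n_mhc * per_aa
  z_bi     <- cos(th) * fjc_extension(f * cos(th), sp$segments$BI, pc)
  z_p_tcr  <- u * n_tcr * per_aa
  z_cab    <- fjc_extension(f, sp$segments$Calphabeta, pc)
  # bound state: same contour bookkeeping, same composite compliance shape as
  # the transition-state rigid path, so the sign of the rigid contribution is
  # set by contour lengths alone and catch behaviour can only arise from the
  # modelled conformational changes
  rigid_ts <- z_alpha3 + z_bi + z_cab
  rigid_contour <- cos(th) * (sp$d_alpha3 + sp$segments$BI$d_c) +
    sp$segments$Calphabeta$d_c
  z_n <- .dN_eff_c1(sp, pc) * rigid_ts / rigid_contour
  rigid_ts + z_p_mhc + z_p_tcr - z_n
}

#' Accumulated landscape deformation, class I
#'
#' Adaptive quadrature of \code{\link{extension_gap_c1}} from 0 to each force,
#' giving \code{delta_l * gamma(F)} (pN nm), and \code{gamma(F)} (pN) via the
#' contour-length criterion \code{delta_l = delta0}.
#'
#' @param F force (pN), vectorised.
#' @param sp a \code{\link{structural_params_c1}}.
#' @param pc a \code{\link{polymer_constants}}.
#' @param abs_tol absolute quadrature tolerance (pN nm).
#' @return List with \code{dl_gamma} (pN nm) and \code{gamma} (pN).
#' @export
energy_shift_c1 <- function(F, sp, pc, abs_tol = 1e-6) {
  if (any(F < 0)) stop("force must be non-negative", call. = FALSE)
  dz <- function(f) extension_gap_c1(f, sp, pc)
  dlg <- vapply(F, function(Fi) {
    if (Fi == 0) return(0)
    stats::integrate(dz, 0, Fi, abs.tol = abs_tol, rel.tol = 1e-9,
                     subdivisions = 200L)$value
  }, numeric(1))
  list(dl_gamma = dlg, gamma = dlg / sp$delta0)
}

#' Gamma functional for the class I model
#'
#' Wraps the class I extension gap as a \code{\link{gamma_functional}} for use
#' with \code{\link{off_rate}} and friends; the integral uses fast fixed-order
#' Gauss-Legendre quadrature (cross-checked against the adaptive
#' \code{\link{energy_shift_c1}}).
#'
#' @param sp a \code{\link{structural_params_c1}}.
#' @param pc a \code{\link{polymer_constants}}.
#' @return A \code{\link{gamma_functional}} with class label "I".
#' @export
gamma_class1 <- function(sp, pc) {
  force(sp); force(pc)
  gamma_functional(function(f) extension_gap_c1(f, sp, pc), class = "I")
}

#' Contour-length consistency residual, class I
#'
#' The force-free dissociation-coordinate gap is the contour difference
#' between the transition-state path (dissociated alpha3 + unfolded joints +
#' bonding interface + Calpha-Cbeta) and the bound-state whole-complex span;
#' best-fit parameters are required to make this difference equal
#' \code{delta0}. Used as an equality penalty during fitting.
#'
#' @param sp a \code{\link{structural_params_c1}}.
#' @param pc a \code{\link{polymer_constants}}.
#' @param delta0 target well-to-barrier distance (nm); defaults to
#'   \code{sp$delta0}.
#' @return Residual (nm): transition contour minus bound contour minus delta0.
#' @export
contour_consistency <- function(sp, pc, delta0 = sp$delta0) {
  stopifnot(inherits(sp, "structural_params_c1"))
  (sp$d_alpha3 + sp$segments$BI$d_c + sp$segments$Calphabeta$d_c +
     sp$n_star * pc$l_c) - sp$segments$N$d_c - delta0
}
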