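#' Bell off-rate
#'
#' Single-pathway exponential rate \code{k0 * exp(delta0 * F / kBT)}.
#'
#' @param F force (pN), vectorised.
#' @param k0 zero-force off-rate (1/s).
#' @param delta0 transition-state distance (nm).
#' @param kBT thermal energy (pN nm).
#' @return Rate (1/s).
#' @export
bell_rate <- function(F, k0, delta0, kBT = 4.11) {
  if (k0 <= 0) stop("k0 must be positive", call. = FALSE)
  k0 * exp(delta0 * F / kBT)
}

#' Two-pathway parameters
#'
#' Parameters of the generic two-pathway comparator: each pathway is a Bell
#' term; the catch pathway has a negative transition-state distance.
#'
#' @param k0_p1,k0_p2 zero-force off-rates (1/s), positive.
#' @param delta_p1 catch-pathway distance (nm), typically negative.
#' @param delta_p2 slip-pathway distance (nm), positive.
#' @return Object of class \code{two_pathway_params}.
#' @export
two_pathway_params <- function(k0_p1, k0_p2, delta_p1, delta_p2) {
  if (k0_p1 <= 0 || k0_p2 <= 0)
    stop("pathway rates must be positive", call. = FALSE)
  if (delta_p2 <= 0)
    stop("slip-pathway distance delta_p2 must be positive", call. = FALSE)
  structure(list(k0_p1 = k0_p1, k0_p2 = k0_p2,
                 delta_p1 = delta_p1, delta_p2 = delta_p2),
            class = "two_pathway_params")
}

#' Two-pathway off-rate
#'
#' Sum of two Bell terms:
#' \code{k0_p1 * exp(delta_p1 F / kBT) + k0_p2 * exp(delta_p2 F / kBT)}.
#'
#' @param F force (pN), vectorised, non-negative.
#' @param tp a \code{\link{two_pathway_params}}.
#' @param kBT thermal energy (pN nm).
#' @return Rate (1/s); mean lifetime is its reciprocal.
#' @export
two_pathway_rate <- function(F, tp, kBT = 4.11) {
  stopifnot(inherits(tp, "two_pathway_params"))
  if (any(F < 0)) stop("force must be non-negative", call. = FALSE)
  tp$k0_p1 * exp(tp$delta_p1 * F / kBT) + tp$k0_p2 * exp(tp$delta_p2 * F / kBT)
}

#' Closed-form optimal force of the two-pathway model
#'
#' With a negative catch-pathway distance the lifetime peaks at
#' \code{F_opt = kBT * log(-k0_p1 delta_p1 / (k0_p2 delta_p2)) /
#' (delta_p2 - delta_p1)}; returns 0 when no interior peak exists.
#'
#' @param tp a \code{\link{two_pathway_params}}.
#' @param kBT thermal energy (pN nm).
#' @return Optimal force (pN).
#' @export
two_pathway_fopt <- function(tp, kBT = 4.11) {
  stopifnot(inherits(tp, "two_pathway_params"))
  if (tp$delta_p1 >= 0) return(0)
  arg <- -tp$k0_p1 * tp$delta_p1 / (tp$k0_p2 * tp$delta_p2)
  if (arg <= 1) return(0)
  kBT * log(arg) / (tp$delta_p2 - tp$delta_p1)
}
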