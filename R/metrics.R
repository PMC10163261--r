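#' Bond-profile metrics
#'
#' Characterises a lifetime-versus-force curve: the zero-force lifetime
#' \code{t0 = 1/k(0)}, peak lifetime \code{t_peak} at the optimal force
#' \code{F_opt}, lifetime gain \code{Delta_t = t_peak - t0}, the force span
#' \code{F_range} over which force amplifies lifetime beyond \code{t0}, the
#' relative length \code{L = Delta_t / t_peak}, relative breadth
#' \code{B = (F_range - F_opt) / F_opt}, and the catch-bond intensity
#' \code{I = L / (1 + B)} — the area ratio of the rectangles
#' \code{Delta_t x F_opt} and \code{t_peak x F_range}.
#'
#' Slip-only curves are reported with the convention \code{F_opt = 0},
#' \code{Delta_t = 0}, \code{L = 0}, \code{I = 0}. When the fitted curve has
#' not returned to \code{t0} by \code{f_max} the range is right-censored at
#' \code{f_max} and flagged.
#'
#' @param x a \code{bond_fit} or a vectorised rate-law function of force
#'   (pN) returning 1/s.
#' @param f_max upper force limit for the search (pN), default 60.
#' @param grid_n grid resolution for locating the peak.
#' @return An object of class \code{bond_metrics}.
#' @export
extract_metrics <- function(x, f_max = 60, grid_n = 2001) {
  ratefun <- if (inherits(x, "bond_fit")) rate_function(x)
             else if (is.function(x)) x
             else stop("x must be a bond_fit or a rate function",
                       call. = FALSE)
  tl <- function(F) 1 / as.numeric(ratefun(F))
  t0 <- tl(0)
  grid <- seq(0, f_max, length.out = grid_n)
  tg <- tl(grid)
  i <- which.max(tg)
  censored <- FALSE

  if (tg[i] <= t0 * (1 + 1e-9) || i == 1L) {
    # monotone decay: slip-only convention
    out <- list(bond_type = "slip-only", t0 = t0, t_peak = t0, F_opt = 0,
                Delta_t = 0, F_range = 0, L = 0, B = NA_real_, I = 0,
                censored = FALSE, f_max = f_max)
    return(structure(out, class = "bond_metrics"))
  }

  if (i == grid_n) {
    # still rising at the limit: catch-only, right-censored peak
    F_opt <- f_max
    t_peak <- tg[i]
    censored <- TRUE
    bond_type <- "catch-only"
  } else {
    opt <- stats::optimize(tl, lower = grid[max(1, i - 1)],
                           upper = grid[min(grid_n, i + 1)],
                           maximum = TRUE, tol = 1e-8)
    F_opt <- opt$maximum
    t_peak <- opt$objective
    bond_type <- "catch-slip"
  }

  Delta_t <- t_peak - t0
  # force span where lifetime returns to t0, right of the peak
  if (bond_type == "catch-only" || tl(f_max) > t0) {
    F_range <- f_max
    censored <- TRUE
  } else {
    F_range <- stats::uniroot(function(F) tl(F) - t0, c(F_opt, f_max),
                              tol = 1e-8)$root
  }
  L <- Delta_t / t_peak
  B <- (F_range - F_opt) / F_opt
  I <- L / (1 + B)
  structure(list(bond_type = bond_type, t0 = t0, t_peak = t_peak,
                 F_opt = F_opt, Delta_t = Delta_t, F_range = F_range,
                 L = L, B = B, I = I, censored = censored, f_max = f_max),
            class = "bond_metrics")
}

#' @export
print.bond_metrics <- function(x, ...) {
  cat(sprintf(
    "bond_metrics [%s]%s\n  t0 = %.3g s, t_peak = %.3g s, F_opt = %.3g pN\n",
    x$bond_type, if (x$censored) " (right-censored)" else "",
    x$t0, x$t_peak, x$F_opt))
  cat(sprintf("  Delta_t = %.3g s, F_range = %.3g pN, L = %.3g, B = %s, I = %.3g\n",
              x$Delta_t, x$F_range, x$L, format(x$B, digits = 3), x$I))
  invisible(x)
}
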