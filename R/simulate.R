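#' Sample single-bond dwell times at a clamped force
#'
#' For single-state, single-pathway dissociation the dwell time at a clamped
#' force is exponential with rate \code{k(F)}; the mean lifetime is the
#' reciprocal rate.
#'
#' @param F clamped force (pN), scalar.
#' @param rate vectorised rate-law function of force (1/s).
#' @param n number of dwell times.
#' @param seed optional integer seed (set for reproducibility).
#' @return \code{n} dwell times (s).
#' @export
sample_lifetimes <- function(F, rate, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k <- as.numeric(rate(F))
  if (k <= 0 || !is.finite(k)) stop("rate must be positive and finite",
                                    call. = FALSE)
  stats::rexp(n, rate = k)
}

#' Simulation specification for a force-clamp experiment
#'
#' Emulates biomembrane-force-probe output: per clamped force bin, i.i.d.
#' exponential dwell times summarised as mean +/- SEM with a count.
#'
#' @param rate vectorised rate-law function of force (1/s).
#' @param forces clamped forces (pN); default 8 bins spanning 2-30 pN.
#' @param per_bin lifetimes per bin (default 50, the experimental floor).
#' @param seed integer seed (mandatory for reproducibility).
#' @param floor optional minimum detectable lifetime (s); shorter dwells are
#'   discarded, which biases bin means upward (documented, off by default).
#' @param system system label.
#' @return Object of class \code{simulation_spec}.
#' @export
simulation_spec <- function(rate, forces = seq(2, 30, length.out = 8),
                            per_bin = 50, seed, floor = 0,
                            system = "synthetic") {
  stopifnot(is.function(rate))
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  if (any(forces <= 0) || any(diff(forces) <= 0))
    stop("forces must be positive and strictly increasing", call. = FALSE)
  if (per_bin < 1) stop("per_bin must be >= 1", call. = FALSE)
  structure(list(rate = rate, forces = forces, per_bin = per_bin,
                 seed = as.integer(seed), floor = floor, system = system),
            class = "simulation_spec")
}

#' Simulate a binned bond-lifetime dataset
#'
#' @param spec a \code{\link{simulation_spec}}.
#' @param sampler dwell-time sampler, \code{function(F, rate, n)}; defaults to
#'   exponential sampling via \code{\link{sample_lifetimes}}. Replaceable for
#'   testing (e.g. a degenerate sampler).
#' @return A \code{\link{bond_lifetime_dataset}} with per-bin mean, SEM
#'   (sd/sqrt(n)) and count.
#' @export
make_dataset <- function(spec, sampler = sample_lifetimes) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  rows <- lapply(spec$forces, function(F) {
    x <- sampler(F, spec$rate, spec$per_bin)
    if (spec$floor > 0) x <- x[x >= spec$floor]
    if (length(x) == 0) x <- spec$floor   # degenerate bin: keep the floor
    c(mean = mean(x), sem = stats::sd(x) / sqrt(length(x)), n = length(x))
  })
  m <- do.call(rbind, rows)
  m[is.na(m[, "sem"]), "sem"] <- 0
  bond_lifetime_dataset(spec$forces, m[, "mean"], m[, "sem"], m[, "n"],
                        system = spec$system)
}

# per-type parameter draws for the synthetic class I cohort; the three
# regimes mirror slip-only, weak catch-slip and strong catch-slip bonds.
# delta0 follows the planted linear relation in n_star, the tilt follows the
# pulling-constraint relation, and d_alpha3 the contour-length criterion.
.cohort_draw <- function(type, slope, intercept, delta0_sd, pc, segments) {
  rng <- switch(type,
    SO = c(2, 5),
    WC = c(8.5, 9.5),
    SC = c(12, 13),
    stop("unknown cohort type: ", type, call. = FALSE))
  n_star <- stats::runif(1, rng[1], rng[2])
  delta0 <- max(0.4, slope * n_star + intercept + stats::rnorm(1, 0, delta0_sd))
  theta <- tilt_from_unfolding(n_star, pc, segments, "I")
  k0 <- exp(stats::runif(1, log(0.3), log(2)))
  d_alpha3 <- segments$N$d_c + delta0 - segments$BI$d_c -
    segments$Calphabeta$d_c - n_star * pc$l_c
  list(k0 = k0, delta0 = delta0, theta = theta, n_star = n_star,
       d_alpha3 = d_alpha3)
}

#' Simulate a cohort of class I systems with planted structure
#'
#' Draws per-system class I parameters in three regimes (slip-only SO, weak
#' catch-slip WC, strong catch-slip SC) with a planted linear relation
#' \code{delta0 = slope * n_star + intercept} (slope below the 0.4 nm/aa
#' contour-length limit) and a planted log-linear relation between ligand
#' potency and the true catch-bond intensity, then simulates a lifetime
#' dataset for each system.
#'
#' @param n_per_type named counts for SO, WC, SC systems.
#' @param slope planted delta0-vs-n* slope (nm/aa), default 0.35.
#' @param intercept planted intercept (nm), default -0.3 (keeps low-n*
#'   systems in the slip-only regime and high-n* systems in the catch
#'   window).
#' @param delta0_sd Gaussian jitter of the planted relation (nm); 0 plants it
#'   exactly.
#' @param seed integer seed.
#' @param forces,per_bin passed to \code{\link{simulation_spec}}.
#' @param potency_noise_sd sd of the log10-potency jitter.
#' @param pc,segments model constants.
#' @param k_w prefactor (1/s).
#' @return List with \code{truth} (data frame of system labels, regime, true
#'   parameters, true metrics, potency) and \code{datasets} (list of
#'   \code{\link{bond_lifetime_dataset}}s).
#' @export
make_cohort <- function(n_per_type = c(SO = 4, WC = 4, SC = 4),
                        slope = 0.35, intercept = -0.3, delta0_sd = 0.05,
                        seed = 1, forces = seq(2, 30, length.out = 8),
                        per_bin = 50, potency_noise_sd = 0.1,
                        pc = default_constants()$pc,
                        segments = default_constants()$segments,
                        k_w = 1e6) {
  set.seed(seed)
  types <- rep(names(n_per_type), times = n_per_type)
  truth <- list()
  datasets <- list()
  for (i in seq_along(types)) {
    p <- .cohort_draw(types[i], slope, intercept, delta0_sd, pc, segments)
    sp <- structural_params_c1(p$theta, p$n_star, p$d_alpha3, p$delta0,
                               segments)
    lp <- landscape_params(p$k0, p$delta0, k_w = k_w, kBT = pc$kBT)
    g <- gamma_class1(sp, pc)
    ratefun <- function(F) as.numeric(off_rate(F, lp, g))
    met <- extract_metrics(ratefun)
    log_pot <- -1 + 3 * met$I + stats::rnorm(1, 0, potency_noise_sd)
    sys <- sprintf("%s-%02d", types[i], i)
    spec <- simulation_spec(ratefun, forces = forces, per_bin = per_bin,
                            seed = sample.int(.Machine$integer.max / 2, 1),
                            system = sys)
    datasets[[sys]] <- make_dataset(spec)
    attr(datasets[[sys]], "potency") <- 10^log_pot
    truth[[sys]] <- data.frame(
      system = sys, type = types[i], k0 = p$k0, delta0 = p$delta0,
      theta = p$theta, n_star = p$n_star, d_alpha3 = p$d_alpha3,
      I = met$I, t_peak = met$t_peak, F_opt = met$F_opt,
      bond_type = met$bond_type, potency = 10^log_pot)
  }
  list(truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
       datasets = datasets)
}
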