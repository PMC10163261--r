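#' Write a JSON fit report
#'
#' Serialises a fit (parameters, SEs, goodness of fit, contour residual),
#' its bond-profile metrics and provenance (package version, seed, time) to
#' JSON alongside a short human-readable summary printed to the console.
#'
#' @param fit a \code{bond_fit}.
#' @param metrics optional \code{bond_metrics}; computed from the fit when
#'   omitted.
#' @param path output JSON path.
#' @param seed seed to record, if the run was stochastic.
#' @param quiet suppress the console summary.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(fit, metrics = NULL, path, seed = NA_integer_,
                         quiet = FALSE) {
  stopifnot(inherits(fit, "bond_fit"))
  if (is.null(metrics)) metrics <- extract_metrics(fit)
  report <- list(
    model = fit$model,
    parameters = as.list(fit$par),
    se = if (is.null(fit$se)) NULL else as.list(fit$se),
    DeltaG0_kBT = fit$DeltaG0,
    k_w = fit$k_w,
    r_squared = fit$r_squared,
    sse = fit$sse,
    contour_residual_nm = fit$contour_residual,
    converged = fit$convergence$converged,
    metrics = metrics[c("bond_type", "t0", "t_peak", "F_opt", "Delta_t",
                        "F_range", "L", "B", "I", "censored")],
    provenance = list(
      package = "catchbond",
      version = as.character(utils::packageVersion("catchbond")),
      seed = seed,
      system = attr(fit$data, "system"),
      timestamp = format(Sys.time(), tz = "UTC"))
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  if (!quiet) {
    cat("model:", fit$model, " R^2:", format(fit$r_squared, digits = 4),
        " bond type:", metrics$bond_type, "\n")
  }
  invisible(path)
}

#' Read a JSON fit report
#'
#' @param path report path written by \code{\link{write_report}}.
#' @return The report as a nested list.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
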