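#' Bond-lifetime dataset
#'
#' Force-clamp lifetime data binned by force: per bin the clamped force, mean
#' bond lifetime, standard error of the mean and measurement count, as
#' produced by biomembrane-force-probe experiments (typically >7 bins over
#' 2-30 pN with >50 lifetimes per bin).
#'
#' @param force forces (pN), strictly increasing, non-negative.
#' @param mean_lifetime mean bond lifetimes (s), positive.
#' @param sem per-bin standard errors of the mean (s), non-negative.
#' @param n per-bin measurement counts, >= 1.
#' @param system system label.
#' @param mhc_class optional "I" or "II".
#' @param potency optional ligand-potency value (e.g. 1/EC50).
#' @return Object of class \code{bond_lifetime_dataset} (a data frame with
#'   attributes).
#' @export
bond_lifetime_dataset <- function(force, mean_lifetime, sem, n,
                                  system = "unnamed", mhc_class = NA_character_,
                                  potency = NA_real_) {
  m <- length(force)
  if (length(mean_lifetime) != m || length(sem) != m || length(n) != m)
    stop("force, mean_lifetime, sem and n must have equal length",
         call. = FALSE)
  if (any(force < 0)) stop("forces must be non-negative", call. = FALSE)
  if (any(diff(force) <= 0))
    stop("forces must be strictly increasing", call. = FALSE)
  if (any(mean_lifetime <= 0))
    stop("mean lifetimes must be positive", call. = FALSE)
  if (any(sem < 0)) stop("sem must be non-negative", call. = FALSE)
  if (any(n < 1)) stop("counts must be >= 1", call. = FALSE)
  if (m < 4)
    warning("fewer than 4 force bins: a 5-parameter fit is under-determined",
            call. = FALSE)
  structure(data.frame(force = force, mean_lifetime = mean_lifetime,
                       sem = sem, n = n),
            system = system, mhc_class = mhc_class, potency = potency,
            class = c("bond_lifetime_dataset", "data.frame"))
}

#' Read a lifetime CSV file
#'
#' Expects columns \code{force_pN}, \code{mean_lifetime_s}, \code{sem_s},
#' \code{n}; validates the schema and reports offending rows.
#'
#' @param path CSV file path.
#' @param system system label; defaults to the file name.
#' @param mhc_class,potency passed to \code{\link{bond_lifetime_dataset}}.
#' @return A \code{\link{bond_lifetime_dataset}}.
#' @export
read_lifetime_csv <- function(path, system = NULL, mhc_class = NA_character_,
                              potency = NA_real_) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("force_pN", "mean_lifetime_s", "sem_s", "n")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  for (col in need) {
    bad <- which(!is.finite(df[[col]]))
    if (length(bad) > 0)
      stop("non-numeric or missing values in '", col, "' at row(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  dup <- which(duplicated(df$force_pN))
  if (length(dup) > 0)
    stop("duplicated force value at row(s) ", paste(dup, collapse = ", "),
         call. = FALSE)
  ord <- order(df$force_pN)
  df <- df[ord, , drop = FALSE]
  bond_lifetime_dataset(df$force_pN, df$mean_lifetime_s, df$sem_s, df$n,
                        system = system %||% basename(path),
                        mhc_class = mhc_class, potency = potency)
}

#' Write a lifetime CSV file
#'
#' @param ds a \code{\link{bond_lifetime_dataset}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_lifetime_csv <- function(ds, path) {
  stopifnot(inherits(ds, "bond_lifetime_dataset"))
  out <- data.frame(force_pN = ds$force, mean_lifetime_s = ds$mean_lifetime,
                    sem_s = ds$sem, n = ds$n)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
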