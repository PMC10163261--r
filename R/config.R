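#' Default model constants
#'
#' Returns the shipped constants block: polymer constants plus the default
#' force-free contour lengths of the semi-rigid bodies (whole complex N,
#' MHC alpha3, bonding interface B.I., TCR Calpha-Cbeta).
#'
#' @return A list with elements \code{pc} (a \code{\link{polymer_constants}})
#'   and \code{segments} (named list of \code{\link{rigid_segment}}s).
#' @export
default_constants <- function() {
  read_constants(system.file("extdata", "constants_default.yaml",
                             package = "catchbond", mustWork = TRUE))
}

#' Read a constants configuration file
#'
#' Accepts YAML or JSON with keys \code{l_c_nm}, \code{l_p_nm}, \code{E_p_pN},
#' \code{E_c_pN}, \code{kuhn_nm}, \code{temperature_K} and a
#' \code{domain_lengths_nm} block with entries \code{N}, \code{alpha3},
#' \code{BI}, \code{Calphabeta}.
#'
#' @param path file path.
#' @return As \code{\link{default_constants}}.
#' @export
read_constants <- function(path) {
  if (!file.exists(path)) stop("constants file not found: ", path,
                               call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  need <- c("l_c_nm", "l_p_nm", "E_p_pN", "E_c_pN", "kuhn_nm",
            "temperature_K", "domain_lengths_nm")
  miss <- setdiff(need, names(cfg))
  if (length(miss) > 0)
    stop("constants file missing keys: ", paste(miss, collapse = ", "),
         call. = FALSE)
  kBT <- 0.0138065 * cfg$temperature_K   # pN nm per kelvin
  pc <- polymer_constants(l_c = cfg$l_c_nm, l_p = cfg$l_p_nm,
                          E_p = cfg$E_p_pN, E_c = cfg$E_c_pN,
                          kuhn_b = cfg$kuhn_nm, kBT = kBT)
  dl <- cfg$domain_lengths_nm
  for (nm in c("N", "alpha3", "BI", "Calphabeta"))
    if (is.null(dl[[nm]]))
      stop("domain_lengths_nm must name segment ", nm, call. = FALSE)
  segments <- list(
    N          = rigid_segment("N", dl$N),
    alpha3     = rigid_segment("alpha3", dl$alpha3),
    BI         = rigid_segment("BI", dl$BI),
    Calphabeta = rigid_segment("Calphabeta", dl$Calphabeta)
  )
  list(pc = pc, segments = segments)
}
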