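#' Physical constants for electrodiffusion calculations
#'
#' Bundles the Faraday constant, the molar gas constant and an absolute
#' temperature into the object consumed by all GHK-based computations.
#' The temperature defaults to 293.15 K (room temperature, the usual
#' condition for Xenopus oocyte recordings) and is configurable because
#' bath temperature is rarely reported precisely.
#'
#' @param T_K absolute temperature in kelvin; must be positive.
#' @return A list of class \code{"phys_constants"} with elements
#'   \code{F} (C/mol), \code{R} (J/(mol K)), \code{T} (K) and the derived
#'   thermal voltage \code{RT_F} in millivolts.
#' @examples
#' pc <- phys_constants()
#' pc$RT_F  # ~25.26 mV at 293.15 K
#' @export
phys_constants <- function(T_K = 293.15) {
  stopifnot(is.numeric(T_K), length(T_K) == 1L, is.finite(T_K))
  if (T_K <= 0) stop("temperature must be positive (kelvin), got ", T_K)
  structure(list(
    F = 96485.332,          # C/mol
    R = 8.31446,            # J/(mol K)
    T = T_K,
    RT_F = 1000 * 8.31446 * T_K / 96485.332  # mV
  ), class = "phys_constants")
}

#' Dehydrated alkali-cation radii
#'
#' Default crystal (dehydrated) ionic radii in angstroms for the five
#' alkali cations used in bi-ionic substitution experiments.  Sodium is
#' the reference ion of the excluded-volume regression; the table is
#' user-overridable since published radius sets differ at the 0.1 A level.
#'
#' @param overrides optional named numeric vector of radii (A) that
#'   replaces or extends the defaults, e.g. \code{c(K = 1.38)}.
#' @return Named numeric vector of radii in angstroms, always containing
#'   a \code{"Na"} entry.
#' @examples
#' ion_radii()
#' ion_radii(c(Cs = 1.67))
#' @export
ion_radii <- function(overrides = NULL) {
  r <- c(Li = 0.60, Na = 0.98, K = 1.33, Rb = 1.48, Cs = 1.69)
  if (!is.null(overrides)) {
    stopifnot(is.numeric(overrides), !is.null(names(overrides)),
              all(nzchar(names(overrides))))
    r[names(overrides)] <- overrides
  }
  if (any(r <= 0)) stop("ionic radii must be positive")
  if (!"Na" %in% names(r)) stop("radius table must contain the reference ion Na")
  r
}
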