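#' Goldman-Hodgkin-Katz constant-field current for a single ion
#'
#' Evaluates the constant-field current density carried by one ionic
#' species at membrane potential \code{V_mV}.  The removable singularity
#' at V = 0 is handled analytically: the limit is
#' P z F (c_in - c_out).  Units follow the physical convention with P in
#' m/s and concentrations in mM (= mol/m^3), giving A/m^2; in this
#' package the permeabilities are relative, so the output is used as an
#' arbitrary current scale.
#'
#' @param V_mV membrane potential(s), mV; vectorized.
#' @param P permeability (relative units).
#' @param z ion valence (signed integer).
#' @param c_in,c_out internal / external concentration, mM.
#' @param consts a [phys_constants()] object.
#' @return Numeric vector of current densities, same length as \code{V_mV};
#'   positive = outward.
#' @examples
#' pc <- phys_constants()
#' ghk_current(0, P = 1, z = 1, c_in = 10, c_out = 115, pc)
#' @export
ghk_current <- function(V_mV, P, z = 1, c_in, c_out, consts = phys_constants()) {
  stopifnot(inherits(consts, "phys_constants"), is.finite(V_mV))
  if (c_in < 0 || c_out < 0) stop("concentrations must be non-negative")
  u <- z * V_mV / consts$RT_F              # dimensionless zFV/RT
  zF <- z * consts$F
  out <- numeric(length(u))
  small <- abs(u) < 1e-8
  # series limit at u -> 0: P z F (c_in - c_out)
  out[small] <- P * zF * (c_in - c_out)
  ub <- u[!small]
  out[!small] <- P * zF * ub * (c_in - c_out * exp(-ub)) / (1 - exp(-ub))
  out
}

#' Multi-ion GHK reversal potential for monovalent cations
#'
#' Solves the GHK voltage equation for a set of monovalent cations:
#' E_rev = (RT/F) ln( sum P_x [X]_out / sum P_x [X]_in ).  Divalent bath
#' ions (Ba2+, Mg2+) are treated as non-permeant blockers and must not be
#' passed in.  For a single permeant ion this reduces to the Nernst
#' potential.
#'
#' @param perms named numeric vector of relative permeabilities (ion
#'   species names, e.g. \code{c(Na = 1, K = 0.5)}).
#' @param inside,outside [solution_spec()] objects giving internal and
#'   external monovalent-cation concentrations (mM).
#' @param consts a [phys_constants()] object.
#' @return Reversal potential in mV.
#' @examples
#' pc <- phys_constants()
#' out <- solution_spec("Na", c(Na = 115))
#' inn <- solution_spec("in", c(Na = 10))
#' ghk_reversal(c(Na = 1), inn, out, pc)  # (RT/F) ln(11.5) ~ 61.7 mV
#' @export
ghk_reversal <- function(perms, inside, outside, consts = phys_constants()) {
  stopifnot(is.numeric(perms), !is.null(names(perms)),
            inherits(inside, "solution_spec"), inherits(outside, "solution_spec"))
  if (any(perms < 0)) stop("permeabilities must be non-negative")
  if (all(perms == 0)) stop("at least one permeability must be nonzero")
  num <- sum(perms * conc_of(outside, names(perms)))
  den <- sum(perms * conc_of(inside, names(perms)))
  if (num <= 0 || den <= 0)
    stop("zero total permeability-weighted concentration on one side; ",
         "cannot form the GHK reversal potential")
  consts$RT_F * log(num / den)
}

#' Permeability ratio from a reversal-potential shift
#'
#' Converts a bi-ionic reversal-potential shift into the relative
#' permeability P_x/P_Na via the GHK relation
#' P_x/P_Na = exp(z F dErev / (R T)), valid when the test cation replaces
#' sodium at equal external concentration.  Values below 1 indicate
#' reduced permeability for the test cation.
#'
#' @param delta a [delta_erev()] result, or a bare numeric shift in mV
#'   (E_rev,X - E_rev,Na).
#' @param consts a [phys_constants()] object.
#' @param z valence of the substituted cation (default 1).
#' @param conc_x,conc_na external test-ion and sodium concentrations (mM);
#'   if both supplied they are checked for equality, since the simple
#'   exponential form assumes an equal-concentration substitution.
#' @return A list of class \code{"permeability_ratio"} with elements
#'   \code{ion}, \code{ratio}, \code{source_delta_mV}, \code{T}, and
#'   (when the input carries them) \code{sem} and \code{n}.
#' @examples
#' ghk_ratio(-29.2)$ratio  # ~0.315 at 293.15 K
#' @export
ghk_ratio <- function(delta, consts = phys_constants(), z = 1,
                      conc_x = NULL, conc_na = NULL) {
  if (!is.null(conc_x) && !is.null(conc_na) &&
      abs(conc_x - conc_na) > 1e-9 * max(conc_x, conc_na, 1))
    stop("test-ion and sodium concentrations differ (", conc_x, " vs ", conc_na,
         " mM); use the full GHK voltage equation instead of ghk_ratio")
  if (inherits(delta, "delta_erev")) {
    d <- delta$value; ion <- delta$ion
    sem_mV <- delta$sem; n <- delta$n
  } else {
    stopifnot(is.numeric(delta), length(delta) == 1L, is.finite(delta))
    d <- delta; ion <- NA_character_; sem_mV <- NA_real_; n <- NA_integer_
  }
  ratio <- exp(z * d / consts$RT_F)
  # delta-method propagation of the SEM on dErev to the ratio scale
  sem_ratio <- if (is.finite(sem_mV)) ratio * z * sem_mV / consts$RT_F else NA_real_
  structure(list(ion = ion, ratio = ratio, source_delta_mV = d,
                 T = consts$T, sem = sem_ratio, n = n),
            class = "permeability_ratio")
}
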