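#' Recording-solution specification
#'
#' Describes the monovalent-cation composition of a bath or internal
#' solution.  The standard external alkali solutions of the TEVC protocol
#' are 115 mM XCl with 2 mM BaCl2 and 1 mM MgCl2 (Tris, pH 9); the
#' divalents act as blockers and are excluded from all GHK sums, so only
#' monovalent cations are listed here.
#'
#' @param label short name, conventionally the substituted cation
#'   (\code{"Na"}, \code{"K"}, ...).
#' @param cations named numeric vector of monovalent-cation
#'   concentrations in mM.
#' @param pH bath pH (recordings are done at pH 9 so that proton current
#'   is negligible); metadata only.
#' @return A list of class \code{"solution_spec"}.
#' @examples
#' solution_spec("K", c(K = 115))
#' @export
solution_spec <- function(label, cations, pH = 9) {
  stopifnot(is.character(label), length(label) == 1L,
            is.numeric(cations), !is.null(names(cations)))
  if (any(cations < 0)) stop("concentrations must be non-negative")
  if (length(cations) == 0L) stop("solution needs at least one cation entry")
  structure(list(label = label, cations = cations, pH = pH),
            class = "solution_spec")
}

# concentration lookup with 0 for absent species
conc_of <- function(sol, species) {
  out <- sol$cations[species]
  out[is.na(out)] <- 0
  unname(out)
}

#' Standard 115 mM alkali bath solutions
#'
#' @param ions character vector of substituted cations.
#' @param conc_mM substituted-cation concentration (default 115 mM).
#' @return Named list of [solution_spec()] objects.
#' @export
alkali_solutions <- function(ions = c("Li", "Na", "K", "Rb", "Cs"),
                             conc_mM = 115) {
  stats::setNames(lapply(ions, function(x) {
    solution_spec(x, stats::setNames(conc_mM, x))
  }), ions)
}

#' Nominal oocyte internal solution
#'
#' The cytosol is modelled as 10 mM Na+ plus 110 mM K+, the textbook
#' Xenopus oocyte composition; it keeps the simulated reversal
#' potentials near 0 mV, inside the -120..+60 mV protocol.  Because the
#' internal term of the GHK voltage equation is identical across bath
#' substitutions, the bi-ionic shift between an X+ and a Na+ bath is
#' exactly (RT/F) ln(P_x/P_Na) regardless of the internal composition.
#'
#' @param na_mM internal sodium concentration, mM.
#' @param k_mM internal potassium concentration, mM.
#' @return A [solution_spec()].
#' @export
oocyte_internal <- function(na_mM = 10, k_mM = 110) {
  cat_in <- c(Na = na_mM, K = k_mM)
  solution_spec("internal", cat_in[cat_in > 0], pH = 7.4)
}

#' Voltage-clamp stimulation protocol
#'
#' Defines the sweep layout shared by the simulator and the analysis
#' stages: the holding-potential family (default -120 to +60 mV in 20 mV
#' steps), the light window, sweep duration, sampling rate and additive
#' current-noise SD.
#'
#' @param holding_mV holding potentials, mV.
#' @param light_on,light_off light window, s.
#' @param sweep_s total sweep duration, s.
#' @param sample_rate_Hz sampling rate, Hz.
#' @param noise_sd SD of additive Gaussian current noise, uA.
#' @return A list of class \code{"protocol_spec"}.
#' @export
protocol_spec <- function(holding_mV = seq(-120, 60, by = 20),
                          light_on = 0.1, light_off = 0.6,
                          sweep_s = 1.0, sample_rate_Hz = 5000,
                          noise_sd = 0.02) {
  stopifnot(is.numeric(holding_mV), length(holding_mV) >= 1L,
            light_on >= 0, sample_rate_Hz > 0, noise_sd >= 0)
  if (!(light_on < light_off && light_off < sweep_s))
    stop("need light_on < light_off < sweep_s, got ",
         light_on, ", ", light_off, ", ", sweep_s)
  structure(list(holding_mV = holding_mV, light_on = light_on,
                 light_off = light_off, sweep_s = sweep_s,
                 sample_rate_Hz = sample_rate_Hz, noise_sd = noise_sd),
            class = "protocol_spec")
}

protocol_times <- function(protocol) {
  seq(0, protocol$sweep_s, by = 1 / protocol$sample_rate_Hz)
}
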