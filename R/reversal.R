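#' Assemble a current-voltage relation from sweep summaries
#'
#' Collects one current per holding potential from a set of sweeps
#' sharing construct, solution and day.  Replicate sweeps at the same
#' potential are averaged.  The current basis is either the stationary
#' current (default: reversal shifts are measured under continuous
#' illumination) or the peak current.
#'
#' @param summaries list of [summarize_sweep()] results.
#' @param basis \code{"stationary"} or \code{"peak"}.
#' @return A list of class \code{"iv_curve"}: data.frame \code{points}
#'   (V_mV, I_uA, sorted by voltage), labels, \code{current_basis}.
#' @export
build_iv <- function(summaries, basis = c("stationary", "peak")) {
  basis <- match.arg(basis)
  stopifnot(length(summaries) >= 2L,
            all(vapply(summaries, inherits, TRUE, "sweep_summary")))
  lab <- function(f) unique(vapply(summaries, `[[`, "", f))
  for (f in c("construct", "solution")) {
    if (length(lab(f)) != 1L)
      stop("sweeps mix ", f, " labels: ", paste(lab(f), collapse = ", "))
  }
  V <- vapply(summaries, `[[`, 0, "holding_mV")
  I <- vapply(summaries, `[[`, 0, if (basis == "stationary") "I_ss" else "I_p")
  agg <- stats::aggregate(list(I_uA = I), list(V_mV = V), mean)
  agg <- agg[order(agg$V_mV), ]
  if (nrow(agg) < 2L) stop("need >= 2 distinct holding potentials")
  structure(list(points = agg,
                 construct = lab("construct")[1],
                 solution = lab("solution")[1],
                 day = paste(sort(unique(vapply(summaries, `[[`, "", "day"))),
                             collapse = "+"),
                 current_basis = basis),
            class = "iv_curve")
}

# direct construction from (V, I) pairs, used by the simulator round trip
iv_curve <- function(V_mV, I_uA, construct = "WT", solution = "Na",
                     day = "day1", basis = "stationary") {
  ord <- order(V_mV)
  if (anyDuplicated(V_mV)) stop("voltages must be unique")
  structure(list(points = data.frame(V_mV = V_mV[ord], I_uA = I_uA[ord]),
                 construct = construct, solution = solution, day = day,
                 current_basis = basis),
            class = "iv_curve")
}

#' Reversal potential from an I-V relation
#'
#' E_rev is the zero crossing of the piecewise-linear interpolation
#' through the I-V points — assumption-free and robust at 20 mV spacing.
#' With exactly one sign change the crossing is interpolated inside its
#' bracket; with none, the line through the two points nearest zero
#' current is extrapolated and the estimate flagged.  Multiple sign
#' changes (a non-monotone I-V) are an error reporting every crossing.
#'
#' @param iv an \code{"iv_curve"}.
#' @return A list of class \code{"reversal_estimate"}: \code{E_rev_mV},
#'   \code{method} ("interpolated"/"extrapolated"),
#'   \code{bracketing_mV}, \code{flag_extrapolated}, plus the curve labels.
#' @export
estimate_erev <- function(iv) {
  stopifnot(inherits(iv, "iv_curve"))
  V <- iv$points$V_mV; I <- iv$points$I_uA
  if (length(V) < 2L) stop("need >= 2 I-V points")

  exact <- which(I == 0)
  s <- sign(I)
  flips <- which(s[-1] * s[-length(s)] < 0)
  cross <- function(i) V[i] - I[i] * (V[i + 1] - V[i]) / (I[i + 1] - I[i])

  if (length(exact) + length(flips) > 1L) {
    xs <- c(V[exact], vapply(flips, cross, 0))
    stop("non-monotone I-V: multiple zero crossings at ",
         paste(sprintf("%.2f", sort(xs)), collapse = ", "), " mV")
  }
  if (length(exact) == 1L) {
    est <- V[exact]; br <- c(V[exact], V[exact]); method <- "interpolated"
  } else if (length(flips) == 1L) {
    i <- flips
    est <- cross(i); br <- c(V[i], V[i + 1]); method <- "interpolated"
  } else {
    near <- order(abs(I))[1:2]
    near <- sort(near)
    i <- near[1]; j <- near[2]
    est <- V[i] - I[i] * (V[j] - V[i]) / (I[j] - I[i])
    br <- c(V[i], V[j]); method <- "extrapolated"
  }
  structure(list(E_rev_mV = est, method = method, bracketing_mV = br,
                 flag_extrapolated = method == "extrapolated",
                 construct = iv$construct, solution = iv$solution,
                 current_basis = iv$current_basis),
            class = "reversal_estimate")
}

#' Reversal-potential shift of a test cation relative to sodium
#'
#' dErev = E_rev,X - E_rev,Na.  With this sign convention a cation less
#' permeant than sodium gives a negative shift, matching the reported
#' direction of alkali-substitution experiments; it is antisymmetric
#' under swapping the two solutions.
#'
#' @param erev_x,erev_na [estimate_erev()] results for the test-cation
#'   and sodium solutions of the same construct.
#' @param sem optional SEM of the shift, mV.
#' @param n optional number of cells.
#' @return A list of class \code{"delta_erev"}: \code{ion}, \code{value}
#'   (mV), \code{sem}, \code{n}.
#' @export
delta_erev <- function(erev_x, erev_na, sem = NA_real_, n = NA_integer_) {
  stopifnot(inherits(erev_x, "reversal_estimate"),
            inherits(erev_na, "reversal_estimate"))
  if (!identical(erev_x$construct, erev_na$construct))
    stop("reversal estimates come from different constructs: ",
         erev_x$construct, " vs ", erev_na$construct)
  structure(list(ion = erev_x$solution,
                 value = erev_x$E_rev_mV - erev_na$E_rev_mV,
                 sem = sem, n = n, construct = erev_x$construct),
            class = "delta_erev")
}
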