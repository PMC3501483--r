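#' Segment a photocurrent sweep around its light window
#'
#' Splits a sweep into the four contiguous analysis windows: baseline
#' (pre-light samples), rise (light onset to peak), decay (peak to
#' light-off) and off (light-off to sweep end).  The peak is the signed
#' extremum of the baseline-subtracted current inside the light window,
#' matching the driving-force sign (a minimum for inward photocurrents),
#' detected after a ~0.5 ms running-median prefilter so single-sample
#' noise spikes cannot claim the peak.
#'
#' @param trace a [tevc_trace()].
#' @return A list of class \code{"trace_segments"} with integer index
#'   vectors \code{baseline}, \code{rise}, \code{decay}, \code{off} and
#'   the scalar \code{peak_index}.
#' @export
segment_trace <- function(trace) {
  stopifnot(inherits(trace, "tevc_trace"))
  t <- trace$times
  base_idx <- which(t < trace$light_on)
  light_idx <- which(t >= trace$light_on & t < trace$light_off)
  off_idx <- which(t >= trace$light_off)
  if (length(light_idx) < 3L)
    stop("sweep ", trace$construct, "/", trace$cell_id,
         ": too few samples in the light window")
  baseline <- if (length(base_idx)) mean(trace$currents[base_idx]) else 0
  y <- trace$currents[light_idx] - baseline

  k <- max(3L, 2L * floor(0.00025 * trace$sample_rate_Hz) + 1L)  # ~0.5 ms, odd
  ys <- if (length(y) > k) stats::runmed(y, k) else y
  sgn <- sign(mean(ys))
  if (sgn == 0) sgn <- -1  # inward by convention for a null window
  peak_rel <- which.max(sgn * ys)
  if (sgn * ys[peak_rel] <= 0)
    stop("sweep ", trace$construct, "/", trace$cell_id,
         ": no photocurrent peak found between light-on and light-off")
  peak <- light_idx[peak_rel]
  structure(list(
    baseline = base_idx,
    rise = light_idx[light_idx <= peak],
    decay = light_idx[light_idx >= peak],
    off = off_idx,
    peak_index = peak
  ), class = "trace_segments")
}

#' Peak / stationary currents and the inactivation ratio of a sweep
#'
#' Computes the baseline, the baseline-subtracted peak current I_p, the
#' stationary current I_ss (mean over the final \code{steady_window_ms}
#' before light-off) and the inactivation ratio I_ss/I_p.  The ratio is
#' sign-free and invariant under current rescaling, so normalizing
#' traces (e.g. to -1 uA at -120 mV) leaves it unchanged.  Ratios above
#' 1 (growing photocurrent) are flagged, not rejected.
#'
#' @param trace a [tevc_trace()].
#' @param steady_window_ms averaging window for I_ss, ms; must fit
#'   inside the light window.
#' @return A list of class \code{"sweep_summary"} with \code{baseline},
#'   \code{I_p}, \code{I_ss}, \code{Iss_over_Ip}, \code{flag_ratio_gt1}
#'   and the sweep metadata.
#' @export
summarize_sweep <- function(trace, steady_window_ms = 50) {
  stopifnot(inherits(trace, "tevc_trace"), steady_window_ms > 0)
  light_dur <- trace$light_off - trace$light_on
  if (steady_window_ms / 1000 >= light_dur)
    stop("steady_window_ms (", steady_window_ms,
         ") must be shorter than the light window (", 1000 * light_dur, " ms)")
  seg <- segment_trace(trace)
  baseline <- if (length(seg$baseline)) mean(trace$currents[seg$baseline]) else 0
  I_p <- trace$currents[seg$peak_index] - baseline
  ss_idx <- which(trace$times >= trace$light_off - steady_window_ms / 1000 &
                  trace$times < trace$light_off)
  I_ss <- mean(trace$currents[ss_idx]) - baseline
  ratio <- I_ss / I_p
  structure(list(
    baseline = baseline, I_p = I_p, I_ss = I_ss,
    Iss_over_Ip = ratio, flag_ratio_gt1 = is.finite(ratio) && ratio > 1,
    construct = trace$construct, cell_id = trace$cell_id, day = trace$day,
    solution = trace$solution, holding_mV = trace$holding_mV
  ), class = "sweep_summary")
}

# fixed initial-guess policy (deterministic fits):
# offset = tail mean, amplitude = first-sample residual,
# tau = duration/5 and duration/50 for the second component
.exp_start <- function(tt, yy, n_components) {
  dur <- tt[length(tt)] - tt[1]
  C0 <- mean(utils::tail(yy, max(3L, length(yy) %/% 20L)))
  A0 <- yy[1] - C0
  if (n_components == 1L) {
    list(A1 = A0, tau1 = dur / 5, C = C0)
  } else {
    list(A1 = A0 / 2, tau1 = dur / 5, A2 = A0 / 2, tau2 = dur / 50, C = C0)
  }
}

#' Fit a sum of exponentials to a sampled time series
#'
#' Least-squares fit of sum_i A_i exp(-t/tau_i) + C, with t re-zeroed at
#' the first sample.  Components are returned ordered by descending
#' |amplitude| and summarized by the amplitude-weighted time constant
#' tau_w = sum |A_i| tau_i / sum |A_i|, the single "apparent tau"
#' reported for each kinetic phase.  Initial guesses follow a fixed
#' policy so fits are deterministic; non-convergence (including a
#' constant series) is reported via \code{converged = FALSE}, never
#' silently.
#'
#' @param times sample times, s.
#' @param values sampled signal (current), uA.
#' @param n_components 1 or 2 exponential components.
#' @param segment optional label stored on the result.
#' @return A list of class \code{"kinetic_fit"}: \code{segment},
#'   \code{components} (data.frame amplitude/tau_ms, sorted), \code{offset},
#'   \code{tau_weighted_ms}, \code{r2}, \code{converged}.
#' @export
fit_exp_series <- function(times, values, n_components = 2L,
                           segment = NA_character_) {
  stopifnot(is.numeric(times), is.numeric(values),
            length(times) == length(values))
  n_components <- as.integer(n_components)
  if (!n_components %in% 1:2) stop("n_components must be 1 or 2")
  if (length(times) < 10L)
    stop("segment has ", length(times), " samples; need >= 10")
  tt <- times - times[1]
  yy <- values

  if (stats::sd(yy) < 1e-12 * (1 + abs(mean(yy)))) {
    comp <- data.frame(amplitude = rep(0, n_components),
                       tau_ms = rep(NA_real_, n_components))
    return(structure(list(segment = segment, components = comp,
                          offset = mean(yy), tau_weighted_ms = NA_real_,
                          r2 = NA_real_, converged = FALSE),
                     class = "kinetic_fit"))
  }

  start <- .exp_start(tt, yy, n_components)
  form <- if (n_components == 1L) {
    yy ~ A1 * exp(-tt / tau1) + C
  } else {
    yy ~ A1 * exp(-tt / tau1) + A2 * exp(-tt / tau2) + C
  }
  lower <- if (n_components == 1L) c(-Inf, 1e-9, -Inf)
           else c(-Inf, 1e-9, -Inf, 1e-9, -Inf)
  fit <- tryCatch(
    minpack.lm::nlsLM(form, start = start, lower = lower,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    comp <- data.frame(amplitude = rep(NA_real_, n_components),
                       tau_ms = rep(NA_real_, n_components))
    return(structure(list(segment = segment, components = comp,
                          offset = mean(yy), tau_weighted_ms = NA_real_,
                          r2 = NA_real_, converged = FALSE),
                     class = "kinetic_fit"))
  }
  cf <- stats::coef(fit)
  A <- cf[grep("^A", names(cf))]
  tau <- cf[grep("^tau", names(cf))]
  ord <- order(abs(A), decreasing = TRUE)
  comp <- data.frame(amplitude = unname(A[ord]),
                     tau_ms = unname(tau[ord]) * 1000)
  tau_w <- sum(abs(comp$amplitude) * comp$tau_ms) / sum(abs(comp$amplitude))
  r2 <- 1 - sum(stats::resid(fit)^2) / sum((yy - mean(yy))^2)
  structure(list(segment = segment, components = comp,
                 offset = unname(cf["C"]), tau_weighted_ms = tau_w,
                 r2 = r2, converged = TRUE),
            class = "kinetic_fit")
}

#' Fit a mono- or biexponential to one trace segment
#'
#' Segments the sweep with [segment_trace()] and applies
#' [fit_exp_series()] to the chosen window (\code{"on"} = light onset to
#' peak, \code{"decay"} = peak to light-off, \code{"off"} = light-off to
#' sweep end).
#'
#' @param trace a [tevc_trace()].
#' @param segment which window to fit.
#' @param n_components 1 or 2 exponential components.
#' @return A \code{"kinetic_fit"}, see [fit_exp_series()].
#' @export
fit_exponential <- function(trace, segment = c("off", "on", "decay"),
                            n_components = 2L) {
  stopifnot(inherits(trace, "tevc_trace"))
  segment <- match.arg(segment)
  seg <- segment_trace(trace)
  idx <- switch(segment, on = seg$rise, decay = seg$decay, off = seg$off)
  if (length(idx) < 10L)
    stop(segment, " segment has ", length(idx), " samples; need >= 10")
  fit_exp_series(trace$times[idx], trace$currents[idx],
                 n_components = n_components, segment = segment)
}

#' Apparent kinetic constants of one sweep
#'
#' Convenience wrapper reproducing the standard analysis: the off
#' segment is fit with two components (the off-decay is biphasic), the
#' rise and light-decay segments with one component, falling back to two
#' components when the single-exponential fit leaves r2 below
#' \code{r2_fallback}.  Each phase is summarized by its
#' amplitude-weighted tau.
#'
#' @param trace a [tevc_trace()].
#' @param r2_fallback r2 threshold below which on/decay refit with two
#'   components.
#' @return A one-row data.frame: tau_on_ms, tau_decay_ms, tau_off_ms,
#'   r2_on, r2_decay, r2_off, plus sweep metadata.
#' @export
sweep_kinetics <- function(trace, r2_fallback = 0.95) {
  fit1 <- function(segment) {
    f <- fit_exponential(trace, segment, n_components = 1L)
    if (!isTRUE(f$converged) || !is.finite(f$r2) || f$r2 < r2_fallback) {
      f2 <- fit_exponential(trace, segment, n_components = 2L)
      if (isTRUE(f2$converged) && is.finite(f2$r2) &&
          (!is.finite(f$r2) || f2$r2 > f$r2)) return(f2)
    }
    f
  }
  on <- fit1("on"); dec <- fit1("decay")
  off <- fit_exponential(trace, "off", n_components = 2L)
  data.frame(construct = trace$construct, cell_id = trace$cell_id,
             day = trace$day, solution = trace$solution,
             holding_mV = trace$holding_mV,
             tau_on_ms = on$tau_weighted_ms,
             tau_decay_ms = dec$tau_weighted_ms,
             tau_off_ms = off$tau_weighted_ms,
             r2_on = on$r2, r2_decay = dec$r2, r2_off = off$r2)
}

#' Normalize a photocurrent to the same-day wild-type reference
#'
#' Mutant photocurrents are expressed as a fraction of the WT peak
#' current recorded on the same day (same oocyte batch), cancelling
#' day-to-day expression variability.  Day matching is enforced through
#' the metadata.
#'
#' @param I_construct peak current of the construct, uA.
#' @param I_wt_same_day peak current of same-day WT, uA; must be nonzero.
#' @param day,wt_day day labels of the two measurements; checked for
#'   equality when both given.
#' @return Scalar fraction I_construct / I_wt_same_day.
#' @export
normalize_to_reference <- function(I_construct, I_wt_same_day,
                                   day = NULL, wt_day = NULL) {
  if (!is.null(day) && !is.null(wt_day) && !identical(day, wt_day))
    stop("no same-day WT reference: construct day '", day,
         "' but WT day '", wt_day, "'")
  if (!is.finite(I_wt_same_day) || abs(I_wt_same_day) <= 0)
    stop("WT reference current must be nonzero")
  I_construct / I_wt_same_day
}
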