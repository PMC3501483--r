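#' Forward excluded-volume permeability model
#'
#' In excluded-volume theory the permeability of an ion through a
#' cylindrical pore is proportional to the cross-sectional area it
#' leaves unoccupied, so relative to sodium
#' P_x/P_Na = ((R_c - R_x) / (R_c - R_Na))^2, clipped at 0 once the ion
#' reaches the pore radius R_c.  This is the generative model whose
#' linearization underlies [fit_excluded_volume()], and the oracle for
#' inversion tests.
#'
#' @param R_c pore (channel) radius, A.
#' @param R_x test-ion radius (A); vectorized.
#' @param R_Na reference sodium radius, A; must be smaller than R_c.
#' @return Relative permeability ratio(s), dimensionless.
#' @examples
#' predict_ratio(3.11, c(Na = 0.98, Rb = 1.48), R_Na = 0.98)
#' @export
predict_ratio <- function(R_c, R_x, R_Na) {
  stopifnot(is.finite(R_c), is.finite(R_Na), all(is.finite(R_x)))
  if (any(R_x <= 0)) stop("ion radii must be positive")
  if (R_Na >= R_c) stop("sodium radius (", R_Na,
                        ") must be smaller than the pore radius (", R_c, ")")
  out <- pmax(0, (R_c - R_x) / (R_c - R_Na))^2
  names(out) <- names(R_x)
  out
}

#' Excluded-volume regression of permeability ratios on ionic radius
#'
#' Ordinary least squares of sqrt(P_x/P_Na) on the dehydrated ionic
#' radius R_x.  Under the excluded-volume model the points are collinear
#' with intercept a = R_c/(R_c - R_Na) and slope b = -1/(R_c - R_Na), so
#' the fitted line yields the minimum pore diameter d_min = 2 a/|b| and
#' the apparent radius of a permeating sodium ion (1 - a)/b.  Sodium
#' itself anchors the regression at ratio exactly 1.  A non-negative
#' slope (permeability not decreasing with radius) leaves d_min
#' undefined with an explicit diagnostic rather than an error.
#'
#' @param ratios named numeric vector of P_x/P_Na (names = ion species),
#'   or a list of \code{"permeability_ratio"} objects.  A Na entry at
#'   ratio 1 is added when absent.
#' @param radii radius table from [ion_radii()]; every ion in
#'   \code{ratios} must appear.
#' @param weights optional OLS weights (default unweighted, the
#'   conventional plain linear regression).
#' @return A list of class \code{"pore_fit"}: \code{a}, \code{b},
#'   \code{r2}, \code{ions_used}, \code{sqrt_ratios}, \code{radii_used},
#'   \code{d_min_A}, \code{R_Na_est_A}, \code{R_c_A}, \code{diagnostic}.
#' @export
fit_excluded_volume <- function(ratios, radii = ion_radii(), weights = NULL) {
  if (is.list(ratios) && all(vapply(ratios, inherits, TRUE, "permeability_ratio")))
    ratios <- stats::setNames(vapply(ratios, `[[`, 0, "ratio"),
                              vapply(ratios, `[[`, "", "ion"))
  stopifnot(is.numeric(ratios), !is.null(names(ratios)))
  if (!"Na" %in% names(ratios)) ratios <- c(ratios, Na = 1)
  if (any(ratios <= 0))
    stop("permeability ratios must be positive; got ",
         paste(names(ratios)[ratios <= 0], collapse = ", "))
  if (length(ratios) < 3L)
    stop("need >= 3 ions (including Na) for the excluded-volume regression")
  missing <- setdiff(names(ratios), names(radii))
  if (length(missing))
    stop("no radius for ion(s): ", paste(missing, collapse = ", "))

  ions <- names(ratios)
  x <- unname(radii[ions])
  y <- sqrt(unname(ratios))
  df <- data.frame(x = x, y = y)
  fit <- if (is.null(weights)) stats::lm(y ~ x, data = df)
         else stats::lm(y ~ x, data = df, weights = weights)
  a <- unname(stats::coef(fit)[1])
  b <- unname(stats::coef(fit)[2])
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::resid(fit)^2) / ss_tot else NA_real_

  if (b < 0 && a > 0) {
    R_c <- a / abs(b)
    out <- list(a = a, b = b, r2 = r2, ions_used = ions,
                sqrt_ratios = y, radii_used = x,
                d_min_A = 2 * R_c, R_Na_est_A = (1 - a) / b, R_c_A = R_c,
                diagnostic = NA_character_)
  } else {
    out <- list(a = a, b = b, r2 = r2, ions_used = ions,
                sqrt_ratios = y, radii_used = x,
                d_min_A = NA_real_,
                R_Na_est_A = if (b != 0) (1 - a) / b else NA_real_,
                R_c_A = NA_real_,
                diagnostic = paste0(
                  "slope b = ", format(b, digits = 4),
                  " >= 0: permeability does not decrease with ionic radius, ",
                  "no size cutoff is observable and d_min is undefined"))
  }
  structure(out, class = "pore_fit")
}

#' @export
print.pore_fit <- function(x, ...) {
  cat(sprintf("Excluded-volume pore fit over {%s}\n",
              paste(x$ions_used, collapse = ", ")))
  cat(sprintf("  sqrt(Px/PNa) = %.4f %+.4f * R_x   (r2 = %.3f)\n",
              x$a, x$b, x$r2))
  if (is.finite(x$d_min_A)) {
    cat(sprintf("  minimum pore diameter 2a/|b| = %.2f A, permeant Na radius (1-a)/b = %.2f A\n",
                x$d_min_A, x$R_Na_est_A))
  } else cat("  ", x$diagnostic, "\n")
  invisible(x)
}

#' Minimum pore diameter from an excluded-volume fit
#'
#' d_min = 2 a / |b|: twice the radius at which the fitted line
#' sqrt(P/P_Na) = a + b R_x reaches zero.  The regression slope must be
#' negative (permeability falling with radius) and the intercept
#' positive for a physically meaningful diameter; the magnitude of b is
#' used so the diameter is reported as a positive length.
#'
#' @param fit a [fit_excluded_volume()] result, or a list/vector with
#'   elements \code{a} and \code{b} (e.g. published coefficients).
#' @return Minimum pore diameter in angstroms.
#' @examples
#' pore_diameter(list(a = 1.37, b = -0.44))  # 6.23 A
#' @export
pore_diameter <- function(fit) {
  a <- fit$a; b <- fit$b
  stopifnot(is.finite(a), is.finite(b))
  if (b >= 0)
    stop("slope b = ", format(b, digits = 4),
         " >= 0: no size cutoff observable, pore diameter undefined")
  if (a <= 0)
    stop("intercept a = ", format(a, digits = 4),
         " <= 0: pore diameter undefined")
  2 * a / abs(b)
}

#' Apparent permeating sodium radius from an excluded-volume fit
#'
#' (1 - a)/b: the radius at which the fitted line crosses
#' sqrt(P/P_Na) = 1, i.e. the effective radius of a sodium ion moving
#' through the channel.  Comparing it with the crystal radius (~0.98 A)
#' gauges the internal consistency of the fit.
#'
#' @param fit a [fit_excluded_volume()] result or a list with \code{a},
#'   \code{b}.
#' @return Estimated sodium radius in angstroms.
#' @examples
#' sodium_radius(list(a = 1.37, b = -0.44))  # 0.84 A
#' @export
sodium_radius <- function(fit) {
  a <- fit$a; b <- fit$b
  stopifnot(is.finite(a), is.finite(b))
  if (b == 0) stop("slope b = 0: sodium radius undefined")
  (1 - a) / b
}
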