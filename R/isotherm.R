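#' Langmuir binding isotherm
#'
#' Evaluates the Langmuir law `y = alpha * x / (x + k_eq)`: the steady-state
#' percent of molecules driven into the scored population (unfolded, or
#' protein-bound, depending on the titration) at effector concentration `x`.
#' `alpha` is the saturating population in percent and `k_eq` the effector
#' concentration at half-saturation, in the same units as `x`.
#'
#' The law is monotonically non-decreasing in `x`, bounded above by `alpha`,
#' and `y(k_eq) = alpha / 2`.
#'
#' @param x Effector concentration(s), >= 0 (nM for protein, uM for
#'   nucleotide titrations; units are never converted implicitly).
#' @param alpha Saturation amplitude in percent, in (0, 100].
#' @param k_eq Half-saturation constant, > 0, same units as `x`.
#' @return Percent values, same length as `x`.
#' @examples
#' langmuir(c(0, 305, 1000), alpha = 49, k_eq = 305)
#' @export
langmuir <- function(x, alpha, k_eq) {
  p <- isotherm_params(alpha, k_eq)
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("effector concentration `x` must be finite and >= 0", call. = FALSE)
  }
  p$alpha * x / (x + p$k_eq)
}

#' Langmuir isotherm parameters
#'
#' Bundles `(alpha, k_eq)` with their 1-sigma uncertainties. `alpha` is a
#' percent in \[0, 100\]; `k_eq` carries the units of the titrated effector.
#'
#' @param alpha Saturation amplitude, percent, in \[0, 100\].
#' @param k_eq Half-saturation constant, > 0.
#' @param alpha_err,k_eq_err Non-negative 1-sigma uncertainties.
#' @param units Concentration unit label carried for reporting ("nM" or "uM").
#' @return A list of class `"isotherm_params"`.
#' @export
isotherm_params <- function(alpha, k_eq, alpha_err = 0, k_eq_err = 0,
                            units = "nM") {
  stopifnot(is.numeric(alpha), is.numeric(k_eq),
            length(alpha) == 1L, length(k_eq) == 1L)
  if (!is.finite(alpha) || alpha < 0 || alpha > 100) {
    stop("`alpha` must lie in [0, 100] percent", call. = FALSE)
  }
  if (!is.finite(k_eq) || k_eq <= 0) stop("`k_eq` must be > 0", call. = FALSE)
  if (alpha_err < 0 || k_eq_err < 0) {
    stop("uncertainties must be >= 0", call. = FALSE)
  }
  structure(list(alpha = alpha, k_eq = k_eq,
                 alpha_err = alpha_err, k_eq_err = k_eq_err,
                 units = units),
            class = "isotherm_params")
}

#' @export
print.isotherm_params <- function(x, ...) {
  cat(sprintf("<isotherm_params> alpha = %g +/- %g %%, K_eq = %g +/- %g %s\n",
              x$alpha, x$alpha_err, x$k_eq, x$k_eq_err, x$units))
  invisible(x)
}

#' Relative change between two population percentages
#'
#' `100 * (b - a) / a`: the percent change of `b` relative to `a`. Used for
#' statements of the form "47% unfolding versus 40% is an 18% increase".
#' Reported values are conventionally rounded half-away-from-zero to the
#' nearest integer percent; `relative_change()` returns the exact value and
#' [format_relative_change()] applies the rounding.
#'
#' @param a Baseline percentage (> 0).
#' @param b Comparison percentage.
#' @return Exact relative change, percent.
#' @examples
#' relative_change(40, 47)  # +17.5, formats as +18%
#' relative_change(40, 30)  # -25
#' @export
relative_change <- function(a, b) {
  if (any(a <= 0)) stop("baseline `a` must be > 0", call. = FALSE)
  100 * (b - a) / a
}

#' @rdname relative_change
#' @export
format_relative_change <- function(a, b) {
  round_half_away(relative_change(a, b), 0)
}

#' Fold change between two equilibrium constants
#'
#' Plain ratio `k_a / k_b`, used for statements such as "K_eq is 6-fold
#' lower". [format_fold_change()] rounds to one decimal, the convention used
#' when reporting such ratios.
#'
#' @param k_a,k_b Positive constants in the same units.
#' @return The ratio (exact, or one-decimal for the `format_` variant).
#' @examples
#' fold_change(4.2, 0.7)          # 6
#' format_fold_change(10.8, 4.7)  # 2.3
#' @export
fold_change <- function(k_a, k_b) {
  if (any(k_b <= 0)) stop("denominator `k_b` must be > 0", call. = FALSE)
  k_a / k_b
}

#' @rdname fold_change
#' @export
format_fold_change <- function(k_a, k_b) {
  round_half_away(fold_change(k_a, k_b), 1)
}

#' Round half away from zero
#'
#' Commercial rounding (0.5 always rounds away from zero), as opposed to the
#' IEEE round-half-even used by [base::round()]. 17.5 -> 18, -24.5 -> -25.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits.
#' @return Rounded values.
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
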