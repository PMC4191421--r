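#' Build a titration series
#'
#' A titration series is the table the isotherm fit consumes: effector
#' concentration `x`, scored population `y` in percent (cumulative positive
#' area relative to the stated reference state), and its 1-sigma uncertainty
#' `y_err`. Units of `x` are carried explicitly (nM for protein, uM for
#' nucleotide) and never converted implicitly.
#'
#' @param x Non-negative effector concentrations (at least 3 distinct).
#' @param y Percent population relative to the reference state.
#' @param y_err Positive 1-sigma uncertainties in percent. With replicate
#'   datasets use their standard deviation; for a single synthetic replicate
#'   the pipeline uses the binomial standard error of the histogram areas
#'   (see [analyze_titration()]).
#' @param units Unit label for `x`.
#' @param response `"unfolding"` (positive lobe = unfolded population, the
#'   default) or `"folding"` (positive lobe = refolded population, used when
#'   an effector suppresses unfolding, e.g. an ADP titration at fixed
#'   protein).
#' @param reference_description Free-text description of the reference
#'   state.
#' @return A tibble of class `"titration_series"`, sorted by `x`.
#' @export
titration_series <- function(x, y, y_err,
                             units = "nM",
                             response = c("unfolding", "folding"),
                             reference_description = "zero-effector reference") {
  response <- match.arg(response)
  if (length(x) != length(y) || length(y) != length(y_err)) {
    stop("`x`, `y`, `y_err` must have equal length", call. = FALSE)
  }
  if (any(x < 0)) stop("concentrations must be >= 0", call. = FALSE)
  if (any(duplicated(x))) stop("concentrations must be distinct", call. = FALSE)
  if (any(y_err <= 0)) stop("`y_err` must be > 0", call. = FALSE)
  ord <- order(x)
  structure(
    tibble::tibble(x = x[ord], y = y[ord], y_err = y_err[ord]),
    units = units, response = response,
    reference_description = reference_description,
    class = c("titration_series", class(tibble::tibble()))
  )
}

#' Weighted Langmuir isotherm fit
#'
#' Fits `y = alpha * x / (x + k_eq)` to a titration series by weighted
#' nonlinear least squares, minimizing `sum(((y - model) / y_err)^2)` over
#' `alpha` in (0, 100\] and `k_eq > 0` (Levenberg-Marquardt). Parameter
#' 1-sigma uncertainties come from the curvature (inverse weighted
#' Gauss-Newton Hessian) at the optimum, i.e. they propagate the supplied
#' `y_err` without rescaling by the residual variance; the chi-square of the
#' fit is reported so over/under-dispersion stays visible.
#'
#' The zero-concentration point is the subtraction reference, not an
#' independent observation (its y is 0 by construction), so it is excluded
#' from the residuals by default and kept for plotting; set
#' `include_zero = TRUE` to keep it in the fit.
#'
#' Starting values default to `alpha0 = max(y)` and `k0 = ` the first
#' concentration whose response exceeds `max(y) / 2` — robust for both
#' saturating and non-saturating series.
#'
#' @param series A [titration_series()] (or a data frame with columns `x`,
#'   `y`, `y_err`).
#' @param init Optional [isotherm_params()] with starting values.
#' @param include_zero Keep the x = 0 point in the residuals?
#' @return An object of class `"langmuir_fit"`; see [tidy.langmuir_fit()],
#'   [glance.langmuir_fit()], [autoplot.langmuir_fit()]. The recovered
#'   parameters are in `$params`, an [isotherm_params()].
#' @examples
#' s <- titration_series(x = c(50, 108, 300, 1000, 2000),
#'                       y = langmuir(c(50, 108, 300, 1000, 2000), 53, 108),
#'                       y_err = rep(2, 5))
#' fit_langmuir(s)
#' @export
fit_langmuir <- function(series, init = NULL, include_zero = FALSE) {
  stopifnot(is.data.frame(series),
            all(c("x", "y", "y_err") %in% names(series)))
  dat <- tibble::as_tibble(series)[c("x", "y", "y_err")]
  if (!include_zero) dat <- dat[dat$x > 0, ]
  if (nrow(dat) < 3) {
    stop("need at least 3 titration points to fit the isotherm", call. = FALSE)
  }
  if (any(dat$y_err <= 0)) stop("`y_err` must be > 0", call. = FALSE)
  if (max(abs(dat$y)) < 1e-6) {
    stop("no signal to fit: all responses are ~0", call. = FALSE)
  }
  if (is.null(init)) {
    a0 <- min(max(dat$y), 100)
    above <- dat$x[dat$y >= a0 / 2]
    k0 <- if (length(above) > 0) max(min(above), min(dat$x[dat$x > 0]) / 2)
          else max(dat$x)
    init <- isotherm_params(max(a0, 1), max(k0, 1e-6))
  } else {
    stopifnot(inherits(init, "isotherm_params"))
  }
  wres <- function(p) {
    (dat$y - p[[1]] * dat$x / (dat$x + p[[2]])) / dat$y_err
  }
  fit <- minpack.lm::nls.lm(
    par = c(alpha = init$alpha, k_eq = init$k_eq),
    lower = c(1e-9, 1e-12), upper = c(100, Inf),
    fn = wres,
    control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-12)
  )
  # info codes 1-4 signal convergence of the Levenberg-Marquardt iteration
  if (!fit$info %in% 1:4 || !is.finite(fit$deviance)) {
    stop("Langmuir fit did not converge: ", fit$message,
         " (last iterate: alpha = ", signif(fit$par[["alpha"]], 4),
         ", k_eq = ", signif(fit$par[["k_eq"]], 4),
         "; weighted SS = ", signif(fit$deviance, 4), ")", call. = FALSE)
  }
  alpha <- fit$par[["alpha"]]
  k_eq <- fit$par[["k_eq"]]
  if (k_eq <= 2e-12 || alpha >= 100 - 1e-9) {
    warning("Langmuir fit converged on a parameter bound (alpha = ",
            signif(alpha, 4), ", k_eq = ", signif(k_eq, 4),
            "); the titration may not constrain the isotherm", call. = FALSE)
  }
  # curvature (Gauss-Newton) covariance at the optimum, using the supplied
  # per-point uncertainties as absolute weights
  jac <- cbind(alpha = dat$x / (dat$x + k_eq),
               k_eq = -alpha * dat$x / (dat$x + k_eq)^2)
  wjac <- jac / dat$y_err
  cov <- tryCatch(solve(crossprod(wjac)), error = function(e) {
    matrix(NA_real_, 2, 2)
  })
  se <- unname(sqrt(pmax(diag(cov), 0)))
  resid <- (dat$y - alpha * dat$x / (dat$x + k_eq)) / dat$y_err
  units <- attr(series, "units", exact = TRUE) %||% "nM"
  params <- isotherm_params(alpha, k_eq,
                            alpha_err = se[1], k_eq_err = se[2],
                            units = units)
  structure(
    list(params = params,
         chi2 = sum(resid^2),
         n_points = nrow(dat),
         data = tibble::as_tibble(series),
         include_zero = include_zero,
         response = attr(series, "response", exact = TRUE) %||% "unfolding",
         reference_description =
           attr(series, "reference_description", exact = TRUE) %||% "",
         cov = cov,
         saturation_reached = max(dat$x) >= 3 * k_eq),
    class = "langmuir_fit"
  )
}

#' @export
print.langmuir_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf(paste0(
    "Langmuir isotherm fit  y = alpha * x / (x + K_eq)   [%s response]\n",
    "  alpha = %.3g +/- %.2g %%\n  K_eq  = %.4g +/- %.2g %s\n",
    "  chi^2 = %.3g on %d points\n"),
    x$response, p$alpha, p$alpha_err, p$k_eq, p$k_eq_err, p$units,
    x$chi2, x$n_points))
  if (!x$saturation_reached) {
    cat("  note: max concentration < 3 * K_eq; saturation not reached\n")
  }
  invisible(x)
}

#' Tidy / summarize a Langmuir fit
#'
#' `tidy()` returns one row per parameter (`term`, `estimate`, `std.error`);
#' `glance()` a one-row model summary; `augment()` the titration points with
#' fitted values and residuals.
#'
#' @param x A `langmuir_fit`.
#' @param ... Unused.
#' @export
tidy.langmuir_fit <- function(x, ...) {
  p <- x$params
  tibble::tibble(
    term = c("alpha", "k_eq"),
    estimate = c(p$alpha, p$k_eq),
    std.error = c(p$alpha_err, p$k_eq_err),
    units = c("percent", p$units)
  )
}

#' @rdname tidy.langmuir_fit
#' @export
glance.langmuir_fit <- function(x, ...) {
  tibble::tibble(
    alpha = x$params$alpha, alpha_err = x$params$alpha_err,
    k_eq = x$params$k_eq, k_eq_err = x$params$k_eq_err,
    units = x$params$units, chi2 = x$chi2, n_points = x$n_points,
    saturation_reached = x$saturation_reached
  )
}

#' @rdname tidy.langmuir_fit
#' @export
augment.langmuir_fit <- function(x, ...) {
  d <- x$data
  d$.fitted <- langmuir(d$x, x$params$alpha, x$params$k_eq)
  d$.resid <- d$y - d$.fitted
  d
}

#' @export
predict.langmuir_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x else newdata$x
  langmuir(x, object$params$alpha, object$params$k_eq)
}

#' Export a Langmuir fit as JSON plus a text report
#'
#' @param fit A `langmuir_fit`.
#' @param json_path Output JSON path (`alpha`, `alpha_err`, `k_eq`,
#'   `k_eq_err`, `units`, `chi2`, `n_points`, `reference_description`).
#' @param report_path Optional one-page text report path.
#' @return `json_path`, invisibly.
#' @export
write_langmuir_fit <- function(fit, json_path, report_path = NULL) {
  stopifnot(inherits(fit, "langmuir_fit"))
  p <- fit$params
  out <- list(alpha = p$alpha, alpha_err = p$alpha_err,
              k_eq = p$k_eq, k_eq_err = p$k_eq_err, units = p$units,
              chi2 = fit$chi2, n_points = fit$n_points,
              response = fit$response,
              reference_description = fit$reference_description)
  jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (!is.null(report_path)) {
    lines <- c(
      "Langmuir binding isotherm fit: y = alpha * x / (x + K_eq)",
      sprintf("response:  %s", fit$response),
      sprintf("reference: %s", fit$reference_description),
      sprintf("alpha = %.4g +/- %.3g percent", p$alpha, p$alpha_err),
      sprintf("K_eq  = %.5g +/- %.3g %s", p$k_eq, p$k_eq_err, p$units),
      sprintf("chi^2 = %.4g on %d points", fit$chi2, fit$n_points),
      if (!fit$saturation_reached)
        "warning: max concentration < 3 * K_eq; saturation not reached",
      "", "data:",
      utils::capture.output(print.data.frame(as.data.frame(fit$data)))
    )
    writeLines(lines[!vapply(lines, is.null, logical(1))], report_path)
  }
  invisible(json_path)
}
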