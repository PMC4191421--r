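#' Build a percent-normalized FRET population histogram
#'
#' Pools the first `min(frames_per_molecule, usable_frames)` FRET values of
#' each molecule — emulating short steady-state movies so that long-lived
#' bright molecules do not dominate — and bins them on a uniform grid over
#' `range`. Counts are normalized to a percentage scale: the pooled samples
#' in the histogram total 100%, which is what makes histograms from
#' different conditions directly subtractable.
#'
#' The default range \[-0.2, 1.2\] deliberately exceeds \[0, 1\] because
#' proximity-ratio noise produces values slightly outside the unit interval;
#' the default bin width 0.025 resolves levels separated by ~0.1 given
#' level widths of 0.05-0.08.
#'
#' @param fret A FRET tibble from [compute_fret()] (`molecule_id`, `frame`,
#'   `e`, `usable`).
#' @param frames_per_molecule Frames pooled per molecule (default 20).
#' @param bin_width Uniform bin width (default 0.025).
#' @param range Histogram range (default `c(-0.2, 1.2)`).
#' @return A tibble of class `"fret_histogram"` with columns `bin_left`,
#'   `bin_right`, `percent` (summing to 100); attributes `n_molecules`,
#'   `n_samples`, `bin_width` and `condition`.
#' @export
fret_histogram <- function(fret, frames_per_molecule = 20,
                           bin_width = 0.025, range = c(-0.2, 1.2)) {
  stopifnot(is.data.frame(fret), all(c("molecule_id", "e") %in% names(fret)))
  if (!"usable" %in% names(fret)) fret$usable <- TRUE
  pooled <- fret |>
    dplyr::filter(.data$usable, !is.na(.data$e)) |>
    dplyr::group_by(.data$molecule_id) |>
    dplyr::slice_head(n = frames_per_molecule) |>
    dplyr::ungroup()
  if (nrow(pooled) == 0) {
    stop("no usable frames: cannot build a histogram", call. = FALSE)
  }
  edges <- .histogram_edges(bin_width, range)
  e <- pooled$e[pooled$e >= range[1] & pooled$e <= range[2]]
  if (length(e) == 0) {
    stop("no FRET values inside the histogram range", call. = FALSE)
  }
  idx <- pmin(findInterval(e, edges, left.open = FALSE), length(edges) - 1L)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  out <- tibble::tibble(
    bin_left = edges[-length(edges)],
    bin_right = edges[-1],
    percent = 100 * counts / sum(counts)
  )
  structure(out,
            n_molecules = dplyr::n_distinct(pooled$molecule_id),
            n_samples = length(e),
            bin_width = bin_width,
            condition = attr(fret, "condition", exact = TRUE),
            class = c("fret_histogram", class(tibble::tibble())))
}

.histogram_edges <- function(bin_width, range) {
  n_bins <- round((range[2] - range[1]) / bin_width)
  if (abs(n_bins * bin_width - (range[2] - range[1])) > 1e-9) {
    stop("`bin_width` must tile `range` exactly", call. = FALSE)
  }
  seq(range[1], range[2], length.out = n_bins + 1L)
}

#' Subtract a reference histogram
#'
#' The subtraction analysis: a percent-normalized reference histogram (the
#' state without the titrated effector) is subtracted bin-by-bin from a
#' condition histogram on the *same* binning (no silent rebinning). Because
#' both inputs total 100%, the difference has equal positive and negative
#' populations; the positive lobe is the population that entered new FRET
#' levels under the condition (unfolded / protein-bound DNA at low E_FRET),
#' the negative lobe what it left.
#'
#' @param sample,reference `fret_histogram` objects with identical bin
#'   edges.
#' @return A tibble of class `"fret_difference"` with `bin_left`,
#'   `bin_right`, `delta_percent` (summing to 0); attributes `n_sample`,
#'   `n_reference` record molecule counts for error models.
#' @export
subtract_reference <- function(sample, reference) {
  stopifnot(inherits(sample, "fret_histogram"),
            inherits(reference, "fret_histogram"))
  if (nrow(sample) != nrow(reference) ||
      max(abs(sample$bin_left - reference$bin_left)) > 1e-12 ||
      max(abs(sample$bin_right - reference$bin_right)) > 1e-12) {
    stop("sample and reference histograms must share identical bin edges; ",
         "rebuild them with the same `bin_width` and `range`", call. = FALSE)
  }
  out <- tibble::tibble(
    bin_left = sample$bin_left,
    bin_right = sample$bin_right,
    delta_percent = sample$percent - reference$percent
  )
  structure(out,
            n_sample = attr(sample, "n_molecules", exact = TRUE),
            n_reference = attr(reference, "n_molecules", exact = TRUE),
            bin_width = attr(sample, "bin_width", exact = TRUE),
            condition = attr(sample, "condition", exact = TRUE),
            class = c("fret_difference", class(tibble::tibble())))
}

#' Cumulative positive area of a difference histogram
#'
#' Sums all positive bins of a subtraction result — the percent of molecules
#' that moved into new FRET levels relative to the reference. By
#' conservation (both histograms total 100%) this equals the magnitude of
#' the negative lobe. The whole positive lobe is summed, with no FRET
#' cutoff, unless `e_cut` is given, in which case only positive bins whose
#' upper edge lies at or below `e_cut` contribute (a sensitivity-analysis
#' variant: it excludes, e.g., mass entering the protein-bound folded level).
#'
#' @param diff A `fret_difference` from [subtract_reference()].
#' @param e_cut Optional FRET cutoff for the positive lobe.
#' @return Percent (scalar, in \[0, 100\]).
#' @export
positive_area <- function(diff, e_cut = NULL) {
  stopifnot(inherits(diff, "fret_difference"))
  d <- diff$delta_percent
  if (!is.null(e_cut)) d[diff$bin_right > e_cut + 1e-12] <- 0
  sum(d[d > 0])
}

#' @rdname positive_area
#' @export
negative_area <- function(diff) {
  stopifnot(inherits(diff, "fret_difference"))
  d <- diff$delta_percent
  abs(sum(d[d < 0]))
}

#' Integrate the population below a FRET threshold
#'
#' Sums `percent` over all bins whose upper edge lies at or below `e_max`;
#' a bin straddling `e_max` contributes pro-rata (the fraction of its width
#' below the threshold), which removes bin-edge aliasing. Used, e.g., to
#' score the unfolded population as the area at E_FRET <= 0.40.
#'
#' @param hist A `fret_histogram`.
#' @param e_max Threshold within the histogram range.
#' @return Percent (scalar).
#' @export
threshold_population <- function(hist, e_max) {
  stopifnot(inherits(hist, "fret_histogram"))
  lo <- hist$bin_left[1]
  hi <- hist$bin_right[nrow(hist)]
  if (e_max < lo || e_max > hi) {
    stop("`e_max` must lie within the histogram range [", lo, ", ", hi, "]",
         call. = FALSE)
  }
  frac <- pmin(pmax((e_max - hist$bin_left) /
                      (hist$bin_right - hist$bin_left), 0), 1)
  sum(hist$percent * frac)
}

#' Fit Gaussian components to a FRET histogram
#'
#' Least-squares fit of a sum of one or two Gaussians to bin centers versus
#' percent, the standard way of identifying FRET levels from steady-state
#' histograms (e.g. resolving the two folded GQ conformers in K+, or
#' verifying a single conformation in Na+). Initialization splits the
#' occupied bins at their weighted median for two components; sigma is
#' bounded to \[0.01, 0.3\].
#'
#' @param hist A `fret_histogram` with at least `5 * n_components` occupied
#'   bins.
#' @param n_components 1 or 2.
#' @return An object of class `"fret_gaussian_fit"`: tibble of components
#'   (`center`, `sigma`, `area_percent`, sorted by center) plus fit
#'   diagnostics; see [tidy.fret_gaussian_fit()]. Errors on non-convergence,
#'   carrying the last iterate and residual in the condition message.
#' @export
fit_fret_gaussians <- function(hist, n_components = 1) {
  stopifnot(inherits(hist, "fret_histogram"))
  if (!n_components %in% c(1, 2)) {
    stop("`n_components` must be 1 or 2", call. = FALSE)
  }
  occupied <- hist$percent > 0
  if (sum(occupied) < 5 * n_components) {
    stop("need at least ", 5 * n_components, " occupied bins to fit ",
         n_components, " component(s)", call. = FALSE)
  }
  x <- (hist$bin_left + hist$bin_right) / 2
  y <- hist$percent
  w <- y / sum(y)
  mu0 <- sum(w * x)
  sd0 <- sqrt(max(sum(w * (x - mu0)^2), 1e-4))
  gauss <- function(x, a, c, s) a * exp(-(x - c)^2 / (2 * s^2))
  clamp_s <- function(s) min(max(s, 0.011), 0.29)
  if (n_components == 1) {
    start <- list(a1 = max(y), c1 = mu0, s1 = clamp_s(sd0))
    formula <- y ~ gauss(x, a1, c1, s1)
    lower <- c(0, min(x), 0.01)
    upper <- c(Inf, max(x), 0.3)
  } else {
    # k-means-style split of occupied mass at the weighted median
    cum <- cumsum(w)
    split <- x[which(cum >= 0.5)[1]]
    left <- x <= split
    m1 <- sum(w[left] * x[left]) / max(sum(w[left]), 1e-12)
    m2 <- sum(w[!left] * x[!left]) / max(sum(w[!left]), 1e-12)
    start <- list(a1 = max(y[left]), c1 = m1, s1 = clamp_s(sd0 / 2),
                  a2 = max(y[!left]), c2 = m2, s2 = clamp_s(sd0 / 2))
    formula <- y ~ gauss(x, a1, c1, s1) + gauss(x, a2, c2, s2)
    lower <- c(0, min(x), 0.01, 0, min(x), 0.01)
    upper <- c(Inf, max(x), 0.3, Inf, max(x), 0.3)
  }
  dat <- data.frame(x = x, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(formula, data = dat, start = start,
                      lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) {
      stop("Gaussian fit did not converge: ", conditionMessage(e),
           "; last start = ", paste(signif(unlist(start), 4), collapse = ", "),
           call. = FALSE)
    }
  )
  cf <- stats::coef(fit)
  bw <- attr(hist, "bin_width", exact = TRUE)
  comp <- tibble::tibble(
    component = seq_len(n_components),
    amplitude = unname(cf[paste0("a", seq_len(n_components))]),
    center = unname(cf[paste0("c", seq_len(n_components))]),
    sigma = unname(cf[paste0("s", seq_len(n_components))])
  )
  comp$area_percent <- comp$amplitude * comp$sigma * sqrt(2 * pi) / bw
  comp <- comp[order(comp$center), ]
  comp$component <- seq_len(n_components)
  structure(
    list(components = comp,
         residual_ss = sum(stats::residuals(fit)^2),
         converged = fit$convInfo$isConv %||% TRUE,
         n_components = n_components,
         hist = hist, fit = fit),
    class = "fret_gaussian_fit"
  )
}

#' @export
print.fret_gaussian_fit <- function(x, ...) {
  cat(sprintf("<fret_gaussian_fit> %d component(s), residual SS %.3g\n",
              x$n_components, x$residual_ss))
  print(x$components[c("component", "center", "sigma", "area_percent")])
  invisible(x)
}

#' Tidy a Gaussian FRET-level fit
#'
#' @param x A `fret_gaussian_fit`.
#' @param ... Unused.
#' @return One row per component: `component`, `center`, `sigma`,
#'   `area_percent`, `amplitude`.
#' @export
tidy.fret_gaussian_fit <- function(x, ...) {
  x$components[c("component", "center", "sigma", "area_percent", "amplitude")]
}

#' @rdname tidy.fret_gaussian_fit
#' @export
glance.fret_gaussian_fit <- function(x, ...) {
  tibble::tibble(n_components = x$n_components,
                 residual_ss = x$residual_ss,
                 converged = x$converged)
}

#' Export / import histograms as CSV
#'
#' Writes `bin_left, bin_right, percent` (or `delta_percent`) plus a JSON
#' sidecar with the condition metadata and sample sizes; `read_histogram()`
#' restores the object.
#'
#' @param hist A `fret_histogram` or `fret_difference`.
#' @param path CSV file path; the sidecar is `<path>.json`.
#' @return `path`, invisibly (write); the restored object (read).
#' @export
write_histogram <- function(hist, path) {
  stopifnot(inherits(hist, "fret_histogram") || inherits(hist, "fret_difference"))
  readr::write_csv(tibble::as_tibble(hist), path, progress = FALSE)
  meta <- list(
    class = class(hist)[1],
    bin_width = attr(hist, "bin_width", exact = TRUE),
    n_molecules = attr(hist, "n_molecules", exact = TRUE),
    n_sample = attr(hist, "n_sample", exact = TRUE),
    n_reference = attr(hist, "n_reference", exact = TRUE),
    n_samples = attr(hist, "n_samples", exact = TRUE),
    condition = {
      cond <- attr(hist, "condition", exact = TRUE)
      if (!is.null(cond)) unclass(cond)
    }
  )
  jsonlite::write_json(meta[!vapply(meta, is.null, logical(1))],
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_histogram
#' @export
read_histogram <- function(path) {
  tab <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()),
                         progress = FALSE)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else list(class = if ("delta_percent" %in% names(tab)) "fret_difference"
              else "fret_histogram")
  cond <- if (!is.null(meta$condition)) .validate_condition_list(meta$condition)
  structure(tab,
            bin_width = meta$bin_width %||% (tab$bin_right[1] - tab$bin_left[1]),
            n_molecules = meta$n_molecules,
            n_sample = meta$n_sample,
            n_reference = meta$n_reference,
            n_samples = meta$n_samples,
            condition = cond,
            class = c(meta$class, class(tibble::tibble())))
}
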