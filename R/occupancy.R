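#' Occupancy specification: from an isotherm to per-state probabilities
#'
#' An occupancy spec is the forward model that turns a Langmuir isotherm into
#' a full probability vector over spectroscopic states at any effector
#' concentration. The low-FRET class (unfolded + protein-bound unfolded)
#' receives total probability `(baseline_low_percent + langmuir(x)) / 100`,
#' split across the low states by their within-class weights; the folded
#' class keeps the remainder, split across the folded conformers, with an
#' optional fraction diverted to the protein-bound folded level.
#'
#' `baseline_low_percent` supports titrations measured *relative to* a
#' reference state that already contains unfolded molecules (e.g. nucleotide
#' titrated at fixed protein concentration): the isotherm then describes the
#' additional unfolding on top of the baseline.
#'
#' `bound_folded_fraction` controls how much of the residual folded class is
#' shown at the protein-bound folded level (~0.55): a fixed number in
#' \[0, 1\], or `"saturation"` for the binding-first model `x / (x + k_eq)`.
#' The default is 0: titration isotherm parameters describe the unfolded
#' population only, and a growing bound-folded shoulder would otherwise leak
#' into the cumulative-positive-area score (see the methods vignette).
#'
#' @param isotherm An [isotherm_params()] object.
#' @param states A state table as from [default_states()]; within-class
#'   weights of `"folded"` and `"low"` states must each sum to 1.
#' @param bound_folded_fraction Number in \[0, 1\] or `"saturation"`.
#' @param baseline_low_percent Low-class percent already present at `x = 0`.
#' @return A list of class `"occupancy_spec"`.
#' @examples
#' spec <- occupancy_spec(isotherm_params(49, 305))
#' occupancy_vector(305, spec)
#' @export
occupancy_spec <- function(isotherm,
                           states = default_states(),
                           bound_folded_fraction = 0,
                           baseline_low_percent = 0) {
  stopifnot(inherits(isotherm, "isotherm_params"))
  for (cls in c("folded", "low")) {
    active <- states[states$class == cls & states$weight > 0, ]
    if (nrow(active) == 0) {
      stop("state table has no weighted states of class \"", cls, "\"",
           call. = FALSE)
    }
    if (abs(sum(active$weight) - 1) > 1e-9) {
      stop("weights of class \"", cls, "\" states must sum to 1 (got ",
           sum(active$weight), ")", call. = FALSE)
    }
  }
  if (is.character(bound_folded_fraction)) {
    bound_folded_fraction <- match.arg(bound_folded_fraction, "saturation")
  } else if (!is.numeric(bound_folded_fraction) ||
             bound_folded_fraction < 0 || bound_folded_fraction > 1) {
    stop("`bound_folded_fraction` must be in [0, 1] or \"saturation\"",
         call. = FALSE)
  }
  if (baseline_low_percent < 0 || baseline_low_percent > 100) {
    stop("`baseline_low_percent` must lie in [0, 100]", call. = FALSE)
  }
  if (!"blm_bound_folded" %in% states$state &&
      !identical(bound_folded_fraction, 0)) {
    stop("non-zero `bound_folded_fraction` requires a blm_bound_folded state",
         call. = FALSE)
  }
  structure(
    list(isotherm = isotherm, states = states,
         bound_folded_fraction = bound_folded_fraction,
         baseline_low_percent = baseline_low_percent),
    class = "occupancy_spec"
  )
}

#' Per-state occupancy probabilities at an effector concentration
#'
#' @param x Effector concentration (scalar, >= 0), in the units of the
#'   spec's isotherm.
#' @param spec An [occupancy_spec()].
#' @return A tibble with columns `state`, `e_mean`, `e_sigma`, `prob`;
#'   `prob` sums to 1.
#' @export
occupancy_vector <- function(x, spec) {
  stopifnot(inherits(spec, "occupancy_spec"), length(x) == 1L)
  p_low <- min((spec$baseline_low_percent +
                  langmuir(x, spec$isotherm$alpha, spec$isotherm$k_eq)) / 100, 1)
  p_folded_class <- 1 - p_low

  bf <- spec$bound_folded_fraction
  if (identical(bf, "saturation")) {
    bf <- x / (x + spec$isotherm$k_eq)
  }

  st <- spec$states
  prob <- numeric(nrow(st))
  low_idx <- st$class == "low"
  prob[low_idx] <- p_low * st$weight[low_idx]
  folded_idx <- st$class == "folded" & st$state != "blm_bound_folded"
  prob[folded_idx] <- p_folded_class * (1 - bf) * st$weight[folded_idx]
  bound_idx <- st$state == "blm_bound_folded"
  prob[bound_idx] <- p_folded_class * bf

  out <- tibble::tibble(state = st$state, e_mean = st$e_mean,
                        e_sigma = st$e_sigma, prob = prob)
  out <- out[out$prob > 0 | out$state %in% st$state[st$weight > 0], ]
  stopifnot(abs(sum(out$prob) - 1) < 1e-12)
  out
}
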