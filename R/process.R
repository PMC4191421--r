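#' Background subtraction
#'
#' Removes the camera/solution background from both channels of every trace.
#' Two methods:
#'
#' * `"constant"` — subtract fixed per-channel values (typically the imaging
#'   backgrounds recorded with the movie);
#' * `"post_bleach"` — estimate the background per molecule and channel as
#'   the mean over the frames after the last detected bleach step (a
#'   single-frame drop in total intensity larger than `step_frac` of the
#'   running pre-drop mean). Molecules with no detectable bleach fall back
#'   to the constant method with a warning.
#'
#' Corrected intensities may go slightly negative; they are not clipped.
#'
#' @param traces Trace tibble (`molecule_id`, `frame`, `i_donor`,
#'   `i_acceptor`), e.g. a `trace_dataset`.
#' @param method `"constant"` or `"post_bleach"`.
#' @param background_d,background_a Constant backgrounds (used by
#'   `"constant"` and as the fallback).
#' @param step_frac Bleach-step detection threshold as a fraction of the
#'   pre-drop mean total intensity.
#' @return The input tibble with corrected `i_donor` / `i_acceptor`
#'   (attributes preserved).
#' @export
subtract_background <- function(traces,
                                method = c("constant", "post_bleach"),
                                background_d = 0, background_a = 0,
                                step_frac = 0.5) {
  method <- match.arg(method)
  stopifnot(is.data.frame(traces))
  out <- traces
  if (method == "constant") {
    out$i_donor <- traces$i_donor - background_d
    out$i_acceptor <- traces$i_acceptor - background_a
    return(out)
  }
  fallback <- 0L
  corrected <- traces |>
    dplyr::group_by(.data$molecule_id) |>
    dplyr::group_map(function(tr, key) {
      steps <- .bleach_steps(tr$i_donor + tr$i_acceptor, step_frac)
      if (length(steps) == 0) {
        fallback <<- fallback + 1L
        bd <- background_d
        ba <- background_a
      } else {
        post <- seq_len(nrow(tr)) > max(steps)
        bd <- mean(tr$i_donor[post])
        ba <- mean(tr$i_acceptor[post])
      }
      tr$i_donor <- tr$i_donor - bd
      tr$i_acceptor <- tr$i_acceptor - ba
      tr$molecule_id <- key$molecule_id
      tr
    }) |>
    purrr::list_rbind()
  if (fallback > 0) {
    warning(fallback, " molecule(s) had no detectable bleach step; ",
            "fell back to constant background subtraction", call. = FALSE)
  }
  corrected <- corrected[names(traces)]
  for (a in c("condition", "ground_truth", "sim_info")) {
    attr(corrected, a) <- attr(traces, a, exact = TRUE)
  }
  class(corrected) <- class(traces)
  corrected
}

# Indices (into the frame sequence) of single-frame drops in total intensity
# exceeding `step_frac` of the running mean before the drop.
.bleach_steps <- function(total, step_frac) {
  n <- length(total)
  if (n < 3) return(integer(0))
  pre_mean <- cumsum(total)[-n] / seq_len(n - 1)
  drop <- total[-n] - total[-1]
  which(drop > step_frac * pmax(pre_mean, .Machine$double.eps))
}

#' Compute FRET efficiency time traces
#'
#' The apparent FRET efficiency (proximity ratio) per frame is
#' `E = i_acceptor / (i_acceptor + i_donor)` on background-subtracted
#' intensities; no gamma or crosstalk correction is applied (generator and
#' analyzer share this convention, so FRET levels are self-consistent).
#' Frames whose total intensity falls below `intensity_floor` — donor
#' bleached, or both fluorophores dark — are marked unusable rather than
#' propagating unstable ratios; `usable` is the prefix of frames before the
#' first such event, so a molecule's usable window ends at its donor bleach.
#'
#' @param traces Background-subtracted trace tibble.
#' @param intensity_floor Minimum total intensity (counts) for a frame to
#'   count as fluorescent.
#' @return A tibble `molecule_id`, `frame`, `e`, `usable`. `e` is `NA` for
#'   frames with non-positive total intensity. Invariant to rescaling both
#'   channels by a common positive factor larger than the floor allows.
#' @export
compute_fret <- function(traces, intensity_floor = 100) {
  stopifnot(is.data.frame(traces))
  total <- traces$i_donor + traces$i_acceptor
  e <- ifelse(total > 0, traces$i_acceptor / total, NA_real_)
  out <- tibble::tibble(
    molecule_id = traces$molecule_id,
    frame = traces$frame,
    e = e,
    bright = total > intensity_floor
  )
  out <- out |>
    dplyr::group_by(.data$molecule_id) |>
    dplyr::mutate(usable = cumall(.data$bright)) |>
    dplyr::ungroup() |>
    dplyr::select(-"bright")
  attr(out, "condition") <- attr(traces, "condition", exact = TRUE)
  attr(out, "ground_truth") <- attr(traces, "ground_truth", exact = TRUE)
  out
}

# running all() along a logical vector (TRUE prefix)
cumall <- function(x) cumsum(!x) == 0

#' Filter traces to single molecules
#'
#' Screens out non-single-molecule traces before histogram building. A trace
#' is accepted iff, in order:
#'
#' 1. `intensity_band` — its mean total intensity over usable frames lies
#'    within `median * (1 +/- intensity_band_frac)` of the per-dataset
#'    median (rejects aggregates and dim spots);
#' 2. `multi_step` — it shows at most one bleach step (single-frame drop in
#'    total intensity exceeding `step_frac` of the running pre-drop mean;
#'    a single molecule can lose each dye at most once, and the donor step
#'    kills both channels together);
#' 3. `no_acceptor` — its mean FRET efficiency over usable frames exceeds
#'    `e_min` (rejects donor-only molecules).
#'
#' @param traces Background-subtracted trace tibble.
#' @param intensity_band_frac Half-width of the intensity acceptance band as
#'   a fraction of the median (default 0.5).
#' @param step_frac Bleach-step detection threshold (default 0.5).
#' @param e_min Minimum mean FRET efficiency (default 0.1).
#' @param intensity_floor Passed to [compute_fret()].
#' @return A list with `accepted` (the filtered `trace_dataset`), `report`
#'   (per-molecule tibble: `molecule_id`, `accepted`, `reason`,
#'   `mean_total`, `mean_e`, `n_steps`) and `summary` (counts per reason).
#'   Accepted and rejected molecules partition the input.
#' @export
filter_single_molecules <- function(traces,
                                    intensity_band_frac = 0.5,
                                    step_frac = 0.5,
                                    e_min = 0.1,
                                    intensity_floor = 100) {
  stopifnot(is.data.frame(traces))
  if (nrow(traces) == 0) {
    warning("empty dataset: nothing to filter", call. = FALSE)
    return(list(accepted = traces,
                report = tibble::tibble(molecule_id = integer(),
                                        accepted = logical(),
                                        reason = character()),
                summary = tibble::tibble(reason = character(), n = integer())))
  }
  fret <- compute_fret(traces, intensity_floor = intensity_floor)
  per_mol <- traces |>
    dplyr::mutate(total = .data$i_donor + .data$i_acceptor) |>
    dplyr::left_join(fret[c("molecule_id", "frame", "e", "usable")],
                     by = c("molecule_id", "frame")) |>
    dplyr::group_by(.data$molecule_id) |>
    dplyr::summarise(
      mean_total = if (any(.data$usable)) mean(.data$total[.data$usable])
                   else mean(.data$total),
      mean_e = if (any(.data$usable)) mean(.data$e[.data$usable], na.rm = TRUE)
               else NA_real_,
      n_steps = length(.bleach_steps(.data$total, step_frac)),
      .groups = "drop"
    )
  med <- stats::median(per_mol$mean_total)
  lo <- med * (1 - intensity_band_frac)
  hi <- med * (1 + intensity_band_frac)
  report <- per_mol |>
    dplyr::mutate(
      reason = dplyr::case_when(
        .data$mean_total < lo | .data$mean_total > hi ~ "intensity_band",
        .data$n_steps > 1 ~ "multi_step",
        is.na(.data$mean_e) | .data$mean_e <= e_min ~ "no_acceptor",
        TRUE ~ NA_character_
      ),
      accepted = is.na(.data$reason)
    ) |>
    dplyr::relocate("molecule_id", "accepted", "reason")
  keep <- report$molecule_id[report$accepted]
  accepted <- traces[traces$molecule_id %in% keep, ]
  truth <- attr(traces, "ground_truth", exact = TRUE)
  if (!is.null(truth)) truth <- truth[truth$molecule_id %in% keep, ]
  accepted <- new_trace_dataset(accepted,
                                condition = attr(traces, "condition", exact = TRUE),
                                ground_truth = truth,
                                sim_info = attr(traces, "sim_info", exact = TRUE))
  summary <- report |>
    dplyr::filter(!.data$accepted) |>
    dplyr::count(.data$reason, name = "n")
  list(accepted = accepted, report = report, summary = summary)
}
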