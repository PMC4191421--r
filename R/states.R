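#' Spectroscopic FRET states of the G-quadruplex assay
#'
#' A named spectroscopic state is a Gaussian FRET-efficiency (E_FRET) level:
#' the apparent proximity ratio of a molecule dwelling in that conformation
#' fluctuates around `e_mean` with standard deviation `e_sigma`. States belong
#' to one of three classes used by the occupancy model: `"folded"` (high
#' E_FRET: folded GQ conformers, the protein-bound folded GQ, or the coiled
#' conformation of non-GQ constructs), `"low"` (unfolded and protein-bound
#' unfolded DNA) and `"artifact"` (donor-only molecules).
#'
#' Samples drawn from a state Gaussian are deliberately *not* clipped to
#' \[0, 1\]: proximity-ratio noise legitimately produces values slightly
#' outside the unit interval, and histograms span a wider range instead.
#'
#' @param name State name, one of `"folded_conf1"`, `"folded_conf2"`,
#'   `"blm_bound_folded"`, `"unfolded"`, `"blm_bound_unfolded"`, `"coiled"`,
#'   `"donor_only"`.
#' @param e_mean Mean FRET efficiency, in \[0, 1\].
#' @param e_sigma Standard deviation of the apparent FRET efficiency (> 0).
#' @param class State class: `"folded"`, `"low"` or `"artifact"`.
#' @param weight Relative weight of the state within its class (weights of
#'   the states sharing a class must sum to 1).
#' @return A one-row tibble with columns `state`, `e_mean`, `e_sigma`,
#'   `class`, `weight`.
#' @seealso [default_states()] for the calibrated level table.
#' @export
fret_state <- function(name, e_mean, e_sigma,
                       class = c("folded", "low", "artifact"),
                       weight = 1) {
  class <- match.arg(class)
  stopifnot(is.character(name), length(name) == 1L)
  if (!name %in% .state_names) {
    stop("unknown state name: ", name, call. = FALSE)
  }
  if (!is.numeric(e_mean) || e_mean < 0 || e_mean > 1) {
    stop("`e_mean` must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(e_sigma) || e_sigma <= 0) {
    stop("`e_sigma` must be > 0", call. = FALSE)
  }
  if (!is.numeric(weight) || weight < 0 || weight > 1) {
    stop("`weight` must lie in [0, 1]", call. = FALSE)
  }
  tibble::tibble(state = name, e_mean = e_mean, e_sigma = e_sigma,
                 class = class, weight = weight)
}

.state_names <- c("folded_conf1", "folded_conf2", "blm_bound_folded",
                  "unfolded", "blm_bound_unfolded", "coiled", "donor_only")

#' Default calibrated FRET levels
#'
#' The level table used throughout the package, calibrated for partial-duplex
#' human-telomeric GQ constructs with a ~12-15 nt single-stranded overhang:
#'
#' * folded GQ in K+ is a broad distribution resolved as two conformers,
#'   0.64 +/- 0.07 and 0.78 +/- 0.05 (relative abundance unresolved
#'   experimentally; the table defaults to 50/50);
#' * in Na+ the GQ folds into a single conformation and a single Gaussian
#'   (0.68 +/- 0.06) is used;
#' * unfolded DNA sits at 0.40 +/- 0.06 and protein-bound unfolded DNA at
#'   0.20 +/- 0.08 (a steady-state mixture of the two appears as the merged
#'   peak near 0.30);
#' * protein-bound *folded* GQ is intermediate, ~0.55;
#' * the coiled conformation of GQ-free poly-dT constructs sits near 0.85.
#'
#' @param cation `"K"` or `"Na"` — selects one or two folded conformers.
#' @return A tibble of [fret_state()] rows.
#' @examples
#' default_states()
#' @export
default_states <- function(cation = c("K", "Na")) {
  cation <- match.arg(cation)
  folded <- if (cation == "K") {
    dplyr::bind_rows(
      fret_state("folded_conf1", 0.64, 0.07, "folded", 0.5),
      fret_state("folded_conf2", 0.78, 0.05, "folded", 0.5)
    )
  } else {
    fret_state("folded_conf1", 0.68, 0.06, "folded", 1)
  }
  dplyr::bind_rows(
    folded,
    fret_state("blm_bound_folded", 0.55, 0.07, "folded", 0),
    fret_state("unfolded", 0.40, 0.06, "low", 0.5),
    fret_state("blm_bound_unfolded", 0.20, 0.08, "low", 0.5),
    fret_state("coiled", 0.85, 0.05, "folded", 0),
    fret_state("donor_only", 0.02, 0.02, "artifact", 0)
  )
}

#' FRET levels for a protein-binding (non-GQ) construct
#'
#' State table for binding assays on GQ-free poly-dT partial-duplex
#' constructs: the unbound DNA is in the coiled conformation near
#' E_FRET = 0.85 and the protein-bound DNA drops to ~0.60. With this table
#' the occupancy isotherm describes the *bound* population, and the
#' subtraction analysis against a zero-protein coiled reference scores the
#' percent of DNA molecules bound by the protein.
#'
#' @param e_bound Mean FRET efficiency of the bound state (default 0.60).
#' @param sigma_bound Width of the bound-state level (default 0.07, in line
#'   with the other protein-bound levels).
#' @return A tibble of [fret_state()] rows.
#' @export
binding_states <- function(e_bound = 0.60, sigma_bound = 0.07) {
  dplyr::bind_rows(
    fret_state("coiled", 0.85, 0.05, "folded", 1),
    fret_state("blm_bound_unfolded", e_bound, sigma_bound, "low", 1)
  )
}

#' Experimental condition metadata
#'
#' Describes one smFRET measurement condition: the DNA construct, the protein
#' and its concentration, the nucleotide cofactor state, the monovalent
#' cation, and the camera frame time. Conditions travel with datasets and
#' histograms so that titrations stay self-describing.
#'
#' @param construct Construct identifier (e.g. `"pd-hGQ12T"`).
#' @param protein One of `"BLM"`, `"BLM_K695M"`, `"WRN"`, `"RecQ"`,
#'   `"RECQ5"`, `"none"`.
#' @param protein_conc Protein concentration in nM (>= 0).
#' @param nucleotide One of `"nt_free"`, `"ATP"`, `"ATPgammaS"`, `"ADP"`,
#'   `"AMP_PNP"`.
#' @param nucleotide_conc Nucleotide concentration in uM; must be 0 iff
#'   `nucleotide == "nt_free"`.
#' @param cation `"K"` or `"Na"`.
#' @param cation_conc Cation concentration in mM (> 0).
#' @param frame_time Camera frame time in seconds (> 0).
#' @return A named list of class `"fret_condition"`.
#' @examples
#' condition("pd-hGQ12T", protein = "BLM", protein_conc = 300)
#' @export
condition <- function(construct = "pd-hGQ12T",
                      protein = c("none", "BLM", "BLM_K695M", "WRN", "RecQ", "RECQ5"),
                      protein_conc = 0,
                      nucleotide = c("nt_free", "ATP", "ATPgammaS", "ADP", "AMP_PNP"),
                      nucleotide_conc = 0,
                      cation = c("K", "Na"),
                      cation_conc = 150,
                      frame_time = 0.04) {
  protein <- match.arg(protein)
  nucleotide <- match.arg(nucleotide)
  cation <- match.arg(cation)
  stopifnot(is.character(construct), length(construct) == 1L)
  if (protein_conc < 0) stop("`protein_conc` must be >= 0", call. = FALSE)
  if (nucleotide_conc < 0) stop("`nucleotide_conc` must be >= 0", call. = FALSE)
  if ((nucleotide == "nt_free") != (nucleotide_conc == 0)) {
    stop("`nucleotide_conc` must be 0 if and only if `nucleotide` is \"nt_free\"",
         call. = FALSE)
  }
  if (cation_conc <= 0) stop("`cation_conc` must be > 0", call. = FALSE)
  if (frame_time <= 0) stop("`frame_time` must be > 0", call. = FALSE)
  structure(
    list(construct = construct, protein = protein,
         protein_conc_nM = protein_conc,
         nucleotide = nucleotide, nucleotide_conc_uM = nucleotide_conc,
         cation = cation, cation_conc_mM = cation_conc,
         frame_time_s = frame_time),
    class = "fret_condition"
  )
}

#' @export
print.fret_condition <- function(x, ...) {
  cat(sprintf("<fret_condition> %s | %s %g nM | %s %g uM | %g mM %s+ | %g s/frame\n",
              x$construct, x$protein, x$protein_conc_nM,
              x$nucleotide, x$nucleotide_conc_uM,
              x$cation_conc_mM, x$cation, x$frame_time_s))
  invisible(x)
}

.validate_condition_list <- function(cond) {
  required <- c("construct", "protein", "protein_conc_nM", "nucleotide",
                "nucleotide_conc_uM", "cation", "cation_conc_mM", "frame_time_s")
  missing <- setdiff(required, names(cond))
  if (length(missing) > 0) {
    stop("manifest `condition` block is missing required keys: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  do.call(condition, list(
    construct = cond$construct, protein = cond$protein,
    protein_conc = cond$protein_conc_nM, nucleotide = cond$nucleotide,
    nucleotide_conc = cond$nucleotide_conc_uM, cation = cond$cation,
    cation_conc = cond$cation_conc_mM, frame_time = cond$frame_time_s
  ))
}
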