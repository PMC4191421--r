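# Shared builders for synthetic fixtures. Everything is generated in code;
# no data files.

# nt-free BLM titration parameters (saturating amplitude %, K_eq nM)
NTFREE_ALPHA <- 49
NTFREE_KEQ <- 305

fixture_occupancy <- function(alpha = NTFREE_ALPHA, k_eq = NTFREE_KEQ,
                              units = "nM", ...) {
  occupancy_spec(isotherm_params(alpha, k_eq, units = units), ...)
}

fixture_config <- function(occupancy = fixture_occupancy(),
                           n_molecules = 100, n_frames = 30, seed = 1, ...) {
  simulation_config(occupancy = occupancy, n_molecules = n_molecules,
                    n_frames = n_frames, seed = seed, ...)
}

# single-state occupancy: all probability in one spectroscopic level
single_state_occupancy <- function(name = "unfolded", e_mean = 0.40,
                                   e_sigma = 0.06,
                                   class = if (name %in% c("unfolded", "blm_bound_unfolded")) "low" else "folded") {
  other <- if (class == "low") {
    fret_state("folded_conf1", 0.64, 0.07, "folded", 1)
  } else {
    fret_state("unfolded", 0.40, 0.06, "low", 1)
  }
  states <- dplyr::bind_rows(fret_state(name, e_mean, e_sigma, class, 1), other)
  # saturate the isotherm so the low class holds everything, or starve it
  if (class == "low") {
    occupancy_spec(isotherm_params(100, 1e-6), states = states)
  } else {
    occupancy_spec(isotherm_params(0, 1), states = states)
  }
}

single_state_config <- function(name = "unfolded", e_mean = 0.40,
                                e_sigma = 0.06, n_molecules = 50,
                                n_frames = 30, seed = 1, ...) {
  occ <- single_state_occupancy(name, e_mean, e_sigma)
  x <- if (occ$isotherm$alpha == 100) 1 else 0
  simulation_config(occupancy = occ, effector_conc = x,
                    n_molecules = n_molecules, n_frames = n_frames,
                    seed = seed, ...)
}

# full chain: dataset -> percent histogram (uses recorded backgrounds)
fixture_histogram <- function(dataset, ...) dataset_histogram(dataset, ...)

LOW_STATES <- c("unfolded", "blm_bound_unfolded")
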