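#' Simulation configuration for synthetic smFRET trace datasets
#'
#' Bundles everything the stochastic trace generator needs: the experimental
#' condition, the occupancy model, dataset geometry (molecules x frames),
#' photophysics (brightness, per-channel noise, backgrounds, bleach rates),
#' the contaminant fraction and the master seed. Defaults emulate a typical
#' TIRF field: ~250 molecules per imaging area, short 30-frame movies at
#' 40 ms per frame for steady-state histograms (long 1000-4000 frame movies
#' are used for time-trace inspection), per-molecule brightness around 500
#' counts/frame with a lognormal 20% spread, and additive Gaussian camera
#' noise of 30 counts per channel.
#'
#' Bleaching is geometric per frame; the default rates are chosen so that
#' most 30-frame movies survive unbleached while most 1000+-frame movies
#' bleach, which exercises both histogram building and bleach-based
#' filtering. In `dynamic_mode` a molecule alternates between the folded and
#' low classes with exponential dwell times instead of holding one state —
#' a qualitative mode for inspecting unfolding/refolding dynamics; all
#' steady-state analyses use the static default.
#'
#' @param condition A [condition()] object.
#' @param occupancy An [occupancy_spec()].
#' @param effector_conc Effector concentration at which occupancies are
#'   evaluated (units of the occupancy isotherm).
#' @param n_molecules Number of molecules (default 250).
#' @param n_frames Frames per movie (default 30; use 1000-4000 for long
#'   movies).
#' @param total_intensity Mean per-molecule total brightness, counts/frame.
#' @param intensity_cv Lognormal coefficient of variation of the
#'   molecule-to-molecule brightness.
#' @param noise_sigma Additive Gaussian read noise per channel, counts.
#'   Kept small by default because the configured state widths `e_sigma`
#'   are *apparent* level widths — they already contain the photon-noise
#'   broadening seen in measured histograms.
#' @param background_d,background_a Constant background counts added to the
#'   donor / acceptor channel.
#' @param donor_bleach_rate,acceptor_bleach_rate Per-frame bleaching
#'   probabilities.
#' @param contaminant_fraction Fraction of molecules that are not single
#'   molecules (aggregates or donor-only), in \[0, 1).
#' @param dynamic_mode Logical; see Details.
#' @param dwell_folded,dwell_unfolded Mean dwell times in seconds
#'   (dynamic mode only).
#' @param seed Master integer seed; per-molecule streams are derived from
#'   `(seed, dataset_index, molecule_id)` so each molecule is independently
#'   reproducible.
#' @return A list of class `"simulation_config"`.
#' @export
simulation_config <- function(condition = gquadfret::condition(),
                              occupancy = occupancy_spec(isotherm_params(49, 305)),
                              effector_conc = 0,
                              n_molecules = 250,
                              n_frames = 30,
                              total_intensity = 500,
                              intensity_cv = 0.2,
                              noise_sigma = 10,
                              background_d = 20,
                              background_a = 15,
                              donor_bleach_rate = 5e-4,
                              acceptor_bleach_rate = 1e-3,
                              contaminant_fraction = 0,
                              dynamic_mode = FALSE,
                              dwell_folded = 2,
                              dwell_unfolded = 3,
                              seed = 1L) {
  stopifnot(inherits(condition, "fret_condition"),
            inherits(occupancy, "occupancy_spec"))
  if (n_molecules < 1 || n_frames < 1) {
    stop("`n_molecules` and `n_frames` must be positive integers", call. = FALSE)
  }
  if (total_intensity <= 0) stop("`total_intensity` must be > 0", call. = FALSE)
  if (intensity_cv < 0) stop("`intensity_cv` must be >= 0", call. = FALSE)
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0", call. = FALSE)
  if (background_d < 0 || background_a < 0) {
    stop("backgrounds must be >= 0", call. = FALSE)
  }
  if (donor_bleach_rate < 0 || donor_bleach_rate >= 1 ||
      acceptor_bleach_rate < 0 || acceptor_bleach_rate >= 1) {
    stop("bleach rates must lie in [0, 1)", call. = FALSE)
  }
  if (contaminant_fraction < 0 || contaminant_fraction >= 1) {
    stop("`contaminant_fraction` must lie in [0, 1)", call. = FALSE)
  }
  if (effector_conc < 0) stop("`effector_conc` must be >= 0", call. = FALSE)
  if (dwell_folded <= 0 || dwell_unfolded <= 0) {
    stop("dwell times must be > 0", call. = FALSE)
  }
  structure(
    list(condition = condition, occupancy = occupancy,
         effector_conc = effector_conc,
         n_molecules = as.integer(n_molecules),
         n_frames = as.integer(n_frames),
         total_intensity = total_intensity, intensity_cv = intensity_cv,
         noise_sigma = noise_sigma,
         background_d = background_d, background_a = background_a,
         donor_bleach_rate = donor_bleach_rate,
         acceptor_bleach_rate = acceptor_bleach_rate,
         contaminant_fraction = contaminant_fraction,
         dynamic_mode = dynamic_mode,
         dwell_folded = dwell_folded, dwell_unfolded = dwell_unfolded,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# Deterministic per-molecule stream: a 32-bit mix of (seed, dataset, molecule)
# so that the same (seed, molecule_id) always reproduces the same trace and
# molecules are independent of dataset size and simulation order.
.molecule_seed <- function(seed, dataset_index, molecule_id) {
  m <- 2147483629 # largest prime < 2^31
  s <- (as.numeric(seed) %% m)
  s <- (s * 69069 + as.numeric(dataset_index) * 40503 +
          as.numeric(molecule_id) * 10007 + 12345) %% m
  s <- (s * 48271) %% m # Lehmer step; stays below 2^53 before reduction
  as.integer(s)
}

# Frame-wise state path for one molecule (state-table row indices).
.state_path <- function(config, occ) {
  n <- config$n_frames
  if (!config$dynamic_mode) {
    idx <- sample.int(nrow(occ), 1, prob = occ$prob)
    return(rep.int(idx, n))
  }
  # dynamic mode: alternate folded-class / low-class with exponential dwells,
  # drawing a state within the class at each entry
  st <- config$occupancy$states
  low_rows <- which(occ$state %in% st$state[st$class == "low"])
  high_rows <- setdiff(seq_len(nrow(occ)), low_rows)
  if (length(low_rows) == 0 || sum(occ$prob[low_rows]) == 0) {
    return(rep.int(sample.int(nrow(occ), 1, prob = occ$prob), n))
  }
  dt <- config$condition$frame_time_s
  path <- integer(n)
  p_low <- sum(occ$prob[low_rows])
  in_low <- stats::runif(1) < p_low
  t <- 1L
  while (t <= n) {
    rows <- if (in_low) low_rows else high_rows
    idx <- if (length(rows) == 1) rows else
      sample(rows, 1, prob = occ$prob[rows])
    dwell <- stats::rexp(1, rate = dt /
                           (if (in_low) config$dwell_unfolded else config$dwell_folded))
    len <- max(1L, min(n - t + 1L, as.integer(ceiling(dwell))))
    path[t:(t + len - 1L)] <- idx
    t <- t + len
    in_low <- !in_low
  }
  path
}

# Render donor/acceptor intensities for a per-frame E path with brightness b.
# RNG draw order (fixed contract): bleach frames, per-frame E, donor noise,
# acceptor noise.
.render_channels <- function(config, e_path, b) {
  n <- config$n_frames
  bleach_d <- .draw_bleach(config$donor_bleach_rate, n)
  bleach_a <- .draw_bleach(config$acceptor_bleach_rate, n)
  e_eff <- e_path
  if (!is.na(bleach_a)) e_eff[seq_len(n) >= bleach_a + 1L] <- 0
  alive <- if (is.na(bleach_d)) rep(TRUE, n) else seq_len(n) < bleach_d + 1L
  i_d <- ifelse(alive, b * (1 - e_eff), 0) + config$background_d +
    stats::rnorm(n, 0, config$noise_sigma)
  i_a <- ifelse(alive, b * e_eff, 0) + config$background_a +
    stats::rnorm(n, 0, config$noise_sigma)
  list(i_donor = i_d, i_acceptor = i_a,
       bleach_frame_d = bleach_d, bleach_frame_a = bleach_a)
}

# First bleached frame (0-indexed), or NA if the fluorophore survives.
.draw_bleach <- function(rate, n) {
  if (rate <= 0) return(NA_integer_)
  f <- stats::rgeom(1, rate) # frames survived before bleaching
  if (f >= n) NA_integer_ else as.integer(f)
}

.draw_brightness <- function(config) {
  cv <- config$intensity_cv
  if (cv == 0) return(config$total_intensity)
  sdlog <- sqrt(log(1 + cv^2))
  config$total_intensity * stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a single smFRET trace
#'
#' Generates one molecule's donor/acceptor intensity time series under the
#' configured state model. In static mode one spectroscopic state is drawn
#' from the occupancy vector and held for the whole movie; per frame, the
#' apparent FRET efficiency is drawn from the state Gaussian (not clipped to
#' \[0, 1\]) and split into channels as `i_acceptor = B*E + background +
#' noise`, `i_donor = B*(1-E) + background + noise` with per-molecule
#' brightness `B`. Acceptor bleaching sends E to 0 (signal moves to the
#' donor channel); donor bleaching sends both channels to background.
#' Bit-identical under a fixed `(seed, dataset_index, molecule_id)`.
#'
#' @param config A [simulation_config()].
#' @param molecule_id Positive integer molecule index.
#' @param dataset_index Dataset index within a titration (default 1).
#' @return A list with `trace` (tibble: `molecule_id`, `frame` (0-indexed),
#'   `i_donor`, `i_acceptor`) and `truth` (one-row tibble of ground-truth
#'   metadata, including the per-frame state path as a list column).
#' @export
simulate_trace <- function(config, molecule_id, dataset_index = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  occ <- occupancy_vector(config$effector_conc, config$occupancy)
  raw <- .simulate_molecule(config, molecule_id, dataset_index, occ)
  .assemble_trace(config, molecule_id, raw, raw$state_path, raw$brightness,
                  contaminant = NA_character_)
}

# Workhorse used by simulate_trace() and simulate_dataset(): seeds the
# molecule's stream and returns plain vectors (no tibble overhead).
.simulate_molecule <- function(config, molecule_id, dataset_index, occ) {
  set.seed(.molecule_seed(config$seed, dataset_index, molecule_id))
  b <- .draw_brightness(config)
  path <- .state_path(config, occ)
  e_path <- stats::rnorm(config$n_frames, occ$e_mean[path], occ$e_sigma[path])
  ch <- .render_channels(config, e_path, b)
  c(ch, list(state_path = occ$state[path], brightness = b))
}

#' Simulate a contaminant (non-single-molecule) trace
#'
#' Returns either an *aggregate* — two independent molecules summed, hence
#' roughly double brightness — or a *donor-only* molecule whose acceptor is
#' dark from frame 0 (apparent E near 0). Used to exercise the
#' single-molecule filter; ground truth flags the contaminant kind.
#'
#' @inheritParams simulate_trace
#' @param kind `"aggregate"` or `"donor_only"`; by default drawn 50/50 from
#'   the molecule's stream.
#' @return Same shape as [simulate_trace()].
#' @export
simulate_contaminant <- function(config, molecule_id, dataset_index = 1L,
                                 kind = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  occ <- occupancy_vector(config$effector_conc, config$occupancy)
  raw <- .simulate_contaminant_raw(config, molecule_id, dataset_index, occ, kind)
  .assemble_trace(config, molecule_id, raw, raw$state_path, raw$brightness,
                  contaminant = raw$kind)
}

.simulate_contaminant_raw <- function(config, molecule_id, dataset_index, occ,
                                      kind = NULL) {
  set.seed(.molecule_seed(config$seed, dataset_index, molecule_id))
  if (is.null(kind)) {
    kind <- if (stats::runif(1) < 0.5) "aggregate" else "donor_only"
  }
  kind <- match.arg(kind, c("aggregate", "donor_only"))
  n <- config$n_frames
  if (kind == "aggregate") {
    b1 <- .draw_brightness(config)
    b2 <- .draw_brightness(config)
    p1 <- .state_path(config, occ)
    p2 <- .state_path(config, occ)
    e1 <- stats::rnorm(n, occ$e_mean[p1], occ$e_sigma[p1])
    e2 <- stats::rnorm(n, occ$e_mean[p2], occ$e_sigma[p2])
    ch1 <- .render_channels(config, e1, b1)
    ch2 <- .render_channels(config, e2, b2)
    ch <- list(
      i_donor = ch1$i_donor + ch2$i_donor - config$background_d,
      i_acceptor = ch1$i_acceptor + ch2$i_acceptor - config$background_a,
      bleach_frame_d = suppressWarnings(
        min(ch1$bleach_frame_d, ch2$bleach_frame_d, na.rm = TRUE)),
      bleach_frame_a = suppressWarnings(
        min(ch1$bleach_frame_a, ch2$bleach_frame_a, na.rm = TRUE))
    )
    if (!is.finite(ch$bleach_frame_d)) ch$bleach_frame_d <- NA_integer_
    if (!is.finite(ch$bleach_frame_a)) ch$bleach_frame_a <- NA_integer_
    c(ch, list(state_path = occ$state[p1], brightness = b1 + b2,
               kind = "aggregate"))
  } else {
    b <- .draw_brightness(config)
    e_path <- rep(0, n) + stats::rnorm(n, 0.02, 0.02) # residual leakage
    ch <- .render_channels(config, e_path, b)
    c(ch, list(state_path = rep("donor_only", n), brightness = b,
               kind = "donor_only"))
  }
}

.assemble_trace <- function(config, molecule_id, ch, state_path, brightness,
                            contaminant) {
  trace <- tibble::tibble(
    molecule_id = as.integer(molecule_id),
    frame = 0:(config$n_frames - 1L),
    i_donor = ch$i_donor,
    i_acceptor = ch$i_acceptor
  )
  truth <- tibble::tibble(
    molecule_id = as.integer(molecule_id),
    state = state_path[1],
    brightness = brightness,
    bleach_frame_d = ch$bleach_frame_d,
    bleach_frame_a = ch$bleach_frame_a,
    contaminant = contaminant,
    state_path = list(state_path)
  )
  list(trace = trace, truth = truth)
}

#' Simulate a full dataset of traces
#'
#' Generates `n_molecules` traces at one experimental condition. The last
#' `round(contaminant_fraction * n_molecules)` molecule ids are contaminants.
#' The result is a tidy trace table (one row per molecule x frame) carrying
#' the condition and per-molecule ground truth as attributes.
#'
#' @param config A [simulation_config()].
#' @param dataset_index Dataset index within a titration (default 1);
#'   part of the per-molecule seed derivation.
#' @return A tibble of class `"trace_dataset"` with columns `molecule_id`,
#'   `frame`, `i_donor`, `i_acceptor`; attributes `condition`,
#'   `ground_truth` (per-molecule tibble) and `sim_info`.
#' @examples
#' cfg <- simulation_config(n_molecules = 20, seed = 7)
#' ds <- simulate_dataset(cfg)
#' dplyr::count(ds, molecule_id)
#' @export
simulate_dataset <- function(config, dataset_index = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_molecules
  n_cont <- as.integer(round(config$contaminant_fraction * n))
  is_cont <- seq_len(n) > (n - n_cont)
  occ <- occupancy_vector(config$effector_conc, config$occupancy)
  sims <- purrr::map(seq_len(n), function(i) {
    if (is_cont[i]) .simulate_contaminant_raw(config, i, dataset_index, occ)
    else .simulate_molecule(config, i, dataset_index, occ)
  })
  nf <- config$n_frames
  traces <- tibble::tibble(
    molecule_id = rep(seq_len(n), each = nf),
    frame = rep.int(0:(nf - 1L), n),
    i_donor = unlist(purrr::map(sims, "i_donor"), use.names = FALSE),
    i_acceptor = unlist(purrr::map(sims, "i_acceptor"), use.names = FALSE)
  )
  truth <- tibble::tibble(
    molecule_id = seq_len(n),
    state = vapply(sims, function(s) s$state_path[1], character(1)),
    brightness = vapply(sims, function(s) s$brightness, numeric(1)),
    bleach_frame_d = vapply(sims, function(s)
      as.integer(s$bleach_frame_d), integer(1)),
    bleach_frame_a = vapply(sims, function(s)
      as.integer(s$bleach_frame_a), integer(1)),
    contaminant = vapply(sims, function(s)
      if (is.null(s$kind)) NA_character_ else s$kind, character(1)),
    state_path = purrr::map(sims, "state_path")
  )
  new_trace_dataset(
    traces,
    condition = config$condition,
    ground_truth = truth,
    sim_info = list(seed = config$seed, dataset_index = dataset_index,
                    effector_conc = config$effector_conc,
                    n_molecules = n, n_frames = config$n_frames,
                    background_d = config$background_d,
                    background_a = config$background_a,
                    isotherm = unclass(config$occupancy$isotherm),
                    baseline_low_percent = config$occupancy$baseline_low_percent)
  )
}

new_trace_dataset <- function(traces, condition, ground_truth = NULL,
                              sim_info = NULL) {
  structure(
    tibble::as_tibble(traces),
    condition = condition,
    ground_truth = ground_truth,
    sim_info = sim_info,
    class = c("trace_dataset", class(tibble::tibble()))
  )
}

#' Dataset metadata accessors
#'
#' @param dataset A `trace_dataset` tibble.
#' @return `dataset_condition()` returns the [condition()] object;
#'   `dataset_truth()` the per-molecule ground-truth tibble (or `NULL` for
#'   real data); `dataset_sim_info()` the generator parameters recorded in
#'   the manifest.
#' @export
dataset_condition <- function(dataset) attr(dataset, "condition", exact = TRUE)

#' @rdname dataset_condition
#' @export
dataset_truth <- function(dataset) attr(dataset, "ground_truth", exact = TRUE)

#' @rdname dataset_condition
#' @export
dataset_sim_info <- function(dataset) attr(dataset, "sim_info", exact = TRUE)

#' Simulate a titration series of datasets
#'
#' One dataset per effector concentration, with state occupancies evaluated
#' from the shared occupancy spec at each concentration. The zero
#' concentration point is the subtraction reference; omitting it triggers a
#' warning because downstream subtraction analysis will need an explicit
#' reference. Dataset indices follow the order of `concentrations`, so every
#' dataset is independently reproducible from `(seed, dataset_index)`.
#'
#' @param config A [simulation_config()]; its `effector_conc` is overridden
#'   per dataset.
#' @param concentrations Non-negative effector concentrations (units of the
#'   occupancy isotherm); should include 0.
#' @param n_fields Replicate imaging fields simulated per concentration
#'   (default 1). Fields are independent `n_molecules`-sized datasets whose
#'   molecules are pooled into one dataset per concentration — mirroring
#'   steady-state histograms built from several movies of the same chamber.
#' @param dir Optional directory: when given, each dataset is written via
#'   [write_trace_dataset()] under `dir/conc_<value>` together with a
#'   top-level `manifest.json`.
#' @return A named list of `trace_dataset` objects (names are the
#'   concentrations).
#' @export
simulate_titration <- function(config, concentrations, n_fields = 1,
                               dir = NULL) {
  stopifnot(inherits(config, "simulation_config"), n_fields >= 1)
  if (any(concentrations < 0)) {
    stop("concentrations must be >= 0", call. = FALSE)
  }
  if (!0 %in% concentrations) {
    warning("titration has no zero-concentration dataset; ",
            "subtraction analysis will need an explicit reference",
            call. = FALSE)
  }
  datasets <- purrr::imap(as.list(concentrations), function(x, i) {
    cfg_x <- config
    cfg_x$effector_conc <- x
    fields <- purrr::map(seq_len(n_fields), function(f) {
      ds <- simulate_dataset(cfg_x, dataset_index = (i - 1L) * n_fields + f)
      offset <- (f - 1L) * cfg_x$n_molecules
      ds$molecule_id <- ds$molecule_id + offset
      tr <- dataset_truth(ds)
      tr$molecule_id <- tr$molecule_id + offset
      attr(ds, "ground_truth") <- tr
      ds
    })
    pooled <- purrr::list_rbind(purrr::map(fields, tibble::as_tibble))
    new_trace_dataset(
      pooled,
      condition = dataset_condition(fields[[1]]),
      ground_truth = purrr::list_rbind(purrr::map(fields, dataset_truth)),
      sim_info = utils::modifyList(dataset_sim_info(fields[[1]]),
                                   list(n_fields = n_fields,
                                        n_molecules = n_fields * cfg_x$n_molecules))
    )
  })
  names(datasets) <- format_conc(concentrations)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    purrr::iwalk(datasets, function(ds, nm) {
      write_trace_dataset(ds, file.path(dir, paste0("conc_", nm)))
    })
    manifest <- list(
      kind = "titration",
      seed = config$seed,
      concentrations = as.numeric(concentrations),
      datasets = as.list(file.path(".", paste0("conc_", names(datasets)))),
      ground_truth = list(
        isotherm = unclass(config$occupancy$isotherm),
        baseline_low_percent = config$occupancy$baseline_low_percent,
        states = as.data.frame(config$occupancy$states)
      )
    )
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  datasets
}

format_conc <- function(x) {
  vapply(x, function(v) format(v, scientific = FALSE, trim = TRUE),
         character(1))
}
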