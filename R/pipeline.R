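#' Subtraction analysis of a titration: datasets to unfolded-percent table
#'
#' Runs the quantification chain on a list of trace datasets sharing one
#' titration: background subtraction, single-molecule filtering, FRET
#' computation, percent-normalized histograms, subtraction of the
#' zero-effector reference histogram, and cumulative-positive-area scoring.
#' Returns one row per concentration, ready for [fit_langmuir()].
#'
#' The per-point uncertainty is the binomial standard error of a difference
#' of two independent histogram areas,
#' `sigma^2 = 100^2 * (p_s (1 - p_s) / n_s + p_r (1 - p_r) / n_r)`,
#' where `p_s`, `p_r` are the low-FRET fractions of sample and reference
#' (measured by [threshold_population()] at `e_split`) and `n_s`, `n_r`
#' their molecule counts. When the reference holds no low-FRET mass this
#' reduces to the binomial error of the sample's unfolded fraction.
#'
#' @param datasets Named list of trace datasets (names = concentrations),
#'   as from [simulate_titration()] or [read_titration()].
#' @param reference Name (concentration) of the reference dataset; default
#'   `"0"`, the zero-effector dataset.
#' @param background_d,background_a Constant backgrounds; defaults are
#'   looked up from each dataset's recorded `sim_info` when present.
#' @param background_method Passed to [subtract_background()].
#' @param frames_per_molecule,bin_width,range Passed to [fret_histogram()].
#' @param e_split FRET threshold separating the low class from the folded
#'   class for the error model (default 0.45, between the unfolded level at
#'   0.40 and the bound-folded level at 0.55).
#' @param e_cut Optional positive-lobe cutoff for [positive_area()].
#' @param response `"unfolding"` or `"folding"` (see [titration_series()]).
#' @param units Concentration unit label.
#' @param filter_args List of arguments for [filter_single_molecules()].
#' @param keep Return histograms and differences alongside the series?
#' @return A [titration_series()] (x = 0 included with y = 0, for
#'   plotting; the fit excludes it by default). With `keep = TRUE`, a list
#'   `series`, `histograms`, `differences`, `filter_reports`.
#' @export
analyze_titration <- function(datasets,
                              reference = "0",
                              background_d = NULL, background_a = NULL,
                              background_method = "constant",
                              frames_per_molecule = 20,
                              bin_width = 0.025, range = c(-0.2, 1.2),
                              e_split = 0.45, e_cut = NULL,
                              response = c("unfolding", "folding"),
                              units = "nM",
                              filter_args = list(),
                              keep = FALSE) {
  response <- match.arg(response)
  stopifnot(is.list(datasets), length(datasets) >= 2)
  if (is.null(names(datasets))) {
    stop("`datasets` must be named by concentration", call. = FALSE)
  }
  if (!reference %in% names(datasets)) {
    stop("no reference dataset \"", reference, "\" in the titration; ",
         "a zero-effector dataset (or an explicit `reference`) is required",
         call. = FALSE)
  }
  filter_reports <- list()
  histograms <- purrr::imap(datasets, function(ds, nm) {
    info <- dataset_sim_info(ds)
    bd <- background_d %||% info$background_d %||% 0
    ba <- background_a %||% info$background_a %||% 0
    corrected <- subtract_background(ds, method = background_method,
                                     background_d = bd, background_a = ba)
    filt <- do.call(filter_single_molecules, c(list(corrected), filter_args))
    filter_reports[[nm]] <<- filt$report
    fret <- compute_fret(filt$accepted)
    fret_histogram(fret, frames_per_molecule = frames_per_molecule,
                   bin_width = bin_width, range = range)
  })
  ref_hist <- histograms[[reference]]
  p_r <- threshold_population(ref_hist, e_split) / 100
  n_r <- attr(ref_hist, "n_molecules", exact = TRUE)
  concs <- as.numeric(names(datasets))
  rows <- purrr::imap(histograms, function(h, nm) {
    diff <- subtract_reference(h, ref_hist)
    p_s <- threshold_population(h, e_split) / 100
    n_s <- attr(h, "n_molecules", exact = TRUE)
    var_pct <- 1e4 * (p_s * (1 - p_s) / n_s + p_r * (1 - p_r) / n_r)
    tibble::tibble(
      x = as.numeric(nm),
      y = if (nm == reference) 0 else positive_area(diff, e_cut = e_cut),
      y_err = max(sqrt(var_pct), 100 * sqrt(0.25 / (n_s + n_r))),
      n_molecules = n_s
    )
  })
  tab <- dplyr::arrange(purrr::list_rbind(rows), .data$x)
  series <- titration_series(
    tab$x, tab$y, tab$y_err, units = units, response = response,
    reference_description = paste0("dataset at concentration ", reference)
  )
  series$n_molecules <- tab$n_molecules
  if (!keep) return(series)
  diffs <- purrr::map(histograms, subtract_reference, reference = ref_hist)
  list(series = series, histograms = histograms, differences = diffs,
       filter_reports = filter_reports)
}

#' Process one dataset into a population histogram
#'
#' Convenience chain for a single condition: background subtraction,
#' single-molecule filtering, FRET computation, percent-normalized
#' histogram. [analyze_titration()] applies the same chain across a
#' titration.
#'
#' @inheritParams analyze_titration
#' @param dataset A trace dataset.
#' @return A [fret_histogram()].
#' @export
dataset_histogram <- function(dataset,
                              background_d = NULL, background_a = NULL,
                              background_method = "constant",
                              frames_per_molecule = 20,
                              bin_width = 0.025, range = c(-0.2, 1.2),
                              filter_args = list()) {
  info <- dataset_sim_info(dataset)
  bd <- background_d %||% info$background_d %||% 0
  ba <- background_a %||% info$background_a %||% 0
  corrected <- subtract_background(dataset, method = background_method,
                                   background_d = bd, background_a = ba)
  filt <- do.call(filter_single_molecules, c(list(corrected), filter_args))
  fret_histogram(compute_fret(filt$accepted),
                 frames_per_molecule = frames_per_molecule,
                 bin_width = bin_width, range = range)
}

#' Run configuration
#'
#' A run config is a flat, human-editable YAML document with namespaced
#' blocks: `condition` (construct, protein, cation, ...), `isotherm`
#' (`alpha`, `k_eq`, optional `baseline_low_percent`,
#' `bound_folded_fraction`), `generator` ([simulation_config()] fields plus
#' `concentrations`), `processing` (filter criteria, background method),
#' `histogram` (`bin_width`, `frames_per_molecule`, `e_split`, optional
#' `e_cut`), `fit` (`response`, `include_zero`, `units`) and a top-level
#' `seed`. A run is reproducible from config + seed alone; every output
#' carries the config hash.
#'
#' @param path YAML file path.
#' @return A named list of class `"run_config"`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no config file at ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param config A named list with the blocks above.
#' @export
validate_run_config <- function(config) {
  stopifnot(is.list(config))
  gen <- config$generator %||% list()
  if (is.null(gen$concentrations)) {
    stop("config key `generator.concentrations` is required", call. = FALSE)
  }
  iso <- config$isotherm %||% list()
  if (is.null(iso$alpha) || is.null(iso$k_eq)) {
    stop("config keys `isotherm.alpha` and `isotherm.k_eq` are required",
         call. = FALSE)
  }
  cond_args <- config$condition %||% list()
  cond <- tryCatch(do.call(condition, cond_args), error = function(e) {
    stop("invalid `condition` block: ", conditionMessage(e), call. = FALSE)
  })
  config$condition_obj <- cond
  config$seed <- as.integer(config$seed %||% 1L)
  structure(config, class = c("run_config", "list"))
}

.config_hash <- function(config) {
  x <- unclass(config)
  x$condition_obj <- NULL
  rlang::hash(x)
}

.sim_config_from_run <- function(config) {
  iso <- config$isotherm
  gen <- config$generator %||% list()
  cation <- config$condition_obj$cation
  states <- if (!is.null(gen$states)) {
    tibble::as_tibble(gen$states)
  } else {
    default_states(cation)
  }
  occ <- occupancy_spec(
    isotherm_params(iso$alpha, iso$k_eq,
                    units = config$fit$units %||% "nM"),
    states = states,
    bound_folded_fraction = iso$bound_folded_fraction %||% 0,
    baseline_low_percent = iso$baseline_low_percent %||% 0
  )
  args <- gen[setdiff(names(gen), c("concentrations", "states"))]
  do.call(simulation_config,
          c(list(condition = config$condition_obj, occupancy = occ,
                 seed = config$seed), args))
}

#' Pipeline runners: simulate, analyze, fit
#'
#' Thin orchestration over the package's functions, writing a reproducible
#' run directory:
#'
#' * `run_simulate()` writes `datasets/conc_*/` trace tables and a
#'   `manifest.json` (including the generator ground truth);
#' * `run_analyze()` writes `histograms/*.csv`, `differences/*.csv` and
#'   `unfolded_table.csv` (per-concentration positive areas with binomial
#'   errors);
#' * `run_fit()` writes `fits/fit.json` and `fits/report.txt`, warning when
#'   the titration does not reach saturation (max x < 3 K_eq).
#'
#' Every stage appends to `run.log` (counts per filtering stage, config
#' hash, seed); re-running with an identical config reproduces all numeric
#' outputs exactly.
#'
#' @param config A validated run config ([read_run_config()]).
#' @param run_dir Run directory.
#' @return `run_simulate()`: the dataset list, invisibly. `run_analyze()`:
#'   the [titration_series()]. `run_fit()`: the `langmuir_fit`.
#' @export
run_simulate <- function(config, run_dir) {
  config <- validate_run_config(config)
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- .sim_config_from_run(config)
  concs <- as.numeric(config$generator$concentrations)
  datasets <- simulate_titration(sim, concs, dir = file.path(run_dir, "datasets"))
  .log_run(run_dir, config,
           sprintf("simulate: %d datasets x %d molecules x %d frames",
                   length(datasets), sim$n_molecules, sim$n_frames))
  invisible(datasets)
}

#' @rdname run_simulate
#' @export
run_analyze <- function(config, run_dir) {
  config <- validate_run_config(config)
  datasets <- read_titration(file.path(run_dir, "datasets"))
  h <- config$histogram %||% list()
  p <- config$processing %||% list()
  res <- analyze_titration(
    datasets,
    reference = as.character(p$reference %||% "0"),
    background_method = p$background_method %||% "constant",
    frames_per_molecule = h$frames_per_molecule %||% 20,
    bin_width = h$bin_width %||% 0.025,
    e_split = h$e_split %||% 0.45,
    e_cut = h$e_cut,
    response = config$fit$response %||% "unfolding",
    units = config$fit$units %||% "nM",
    filter_args = p$filter %||% list(),
    keep = TRUE
  )
  hist_dir <- file.path(run_dir, "histograms")
  diff_dir <- file.path(run_dir, "differences")
  dir.create(hist_dir, showWarnings = FALSE)
  dir.create(diff_dir, showWarnings = FALSE)
  purrr::iwalk(res$histograms, function(hh, nm) {
    write_histogram(hh, file.path(hist_dir, paste0("conc_", nm, ".csv")))
  })
  purrr::iwalk(res$differences, function(dd, nm) {
    write_histogram(dd, file.path(diff_dir, paste0("conc_", nm, ".csv")))
  })
  readr::write_csv(tibble::as_tibble(res$series),
                   file.path(run_dir, "unfolded_table.csv"), progress = FALSE)
  counts <- purrr::imap_chr(res$filter_reports, function(r, nm) {
    sprintf("conc %s: read %d, accepted %d, rejected %s", nm, nrow(r),
            sum(r$accepted),
            paste(utils::capture.output(
              cat(table(r$reason[!r$accepted]))), collapse = " "))
  })
  .log_run(run_dir, config, c("analyze:", counts))
  res$series
}

#' @rdname run_simulate
#' @export
run_fit <- function(config, run_dir) {
  config <- validate_run_config(config)
  tab_path <- file.path(run_dir, "unfolded_table.csv")
  if (!file.exists(tab_path)) {
    stop("no unfolded_table.csv under ", run_dir, "; run run_analyze() first",
         call. = FALSE)
  }
  tab <- readr::read_csv(tab_path, col_types = readr::cols(), progress = FALSE)
  series <- titration_series(tab$x, tab$y, tab$y_err,
                             units = config$fit$units %||% "nM",
                             response = config$fit$response %||% "unfolding")
  fit <- fit_langmuir(series,
                      include_zero = isTRUE(config$fit$include_zero))
  if (!fit$saturation_reached) {
    warning("titration does not reach saturation (max x < 3 * K_eq); ",
            "K_eq is poorly constrained", call. = FALSE)
  }
  fit_dir <- file.path(run_dir, "fits")
  dir.create(fit_dir, showWarnings = FALSE)
  write_langmuir_fit(fit, file.path(fit_dir, "fit.json"),
                     file.path(fit_dir, "report.txt"))
  .log_run(run_dir, config,
           sprintf("fit: alpha = %.4g +/- %.3g, K_eq = %.5g +/- %.3g %s",
                   fit$params$alpha, fit$params$alpha_err,
                   fit$params$k_eq, fit$params$k_eq_err, fit$params$units))
  fit
}

.log_run <- function(run_dir, config, lines) {
  con <- file(file.path(run_dir, "run.log"), open = "a")
  on.exit(close(con))
  writeLines(sprintf("[%s] config %s seed %d",
                     format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                     .config_hash(config), config$seed), con)
  writeLines(paste0("  ", lines), con)
}
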