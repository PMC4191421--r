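#' Read and write trace datasets
#'
#' A dataset on disk is a directory holding `traces.csv` — a UTF-8,
#' comma-separated table with header `molecule_id, frame, i_donor,
#' i_acceptor` ('.' decimal separator, frames 0-indexed) — and
#' `manifest.json` with a required `condition` block (`construct`,
#' `protein`, `protein_conc_nM`, `nucleotide`, `nucleotide_conc_uM`,
#' `cation`, `cation_conc_mM`, `frame_time_s`) plus optional `ground_truth`
#' and `sim_info` blocks. Unknown manifest keys are preserved on round-trip.
#'
#' @param dataset A `trace_dataset` tibble (see [simulate_dataset()]).
#' @param path Dataset directory (created if missing on write).
#' @return `write_trace_dataset()` returns `path` invisibly;
#'   `read_trace_dataset()` returns a `trace_dataset` tibble.
#' @export
write_trace_dataset <- function(dataset, path) {
  stopifnot(is.data.frame(dataset))
  required <- c("molecule_id", "frame", "i_donor", "i_acceptor")
  if (!all(required %in% names(dataset))) {
    stop("dataset must have columns ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  cond <- dataset_condition(dataset)
  if (is.null(cond)) {
    stop("dataset carries no condition metadata; cannot write a manifest",
         call. = FALSE)
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(dataset[required], file.path(path, "traces.csv"),
                   progress = FALSE)
  manifest <- list(condition = unclass(cond))
  truth <- dataset_truth(dataset)
  if (!is.null(truth)) {
    gt <- truth[setdiff(names(truth), "state_path")]
    manifest$ground_truth <- gt
  }
  info <- dataset_sim_info(dataset)
  if (!is.null(info)) manifest$sim_info <- info
  extra <- attr(dataset, "manifest_extra", exact = TRUE)
  if (!is.null(extra)) manifest <- utils::modifyList(manifest, extra)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns",
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_trace_dataset
#' @export
read_trace_dataset <- function(path) {
  csv <- file.path(path, "traces.csv")
  mf <- file.path(path, "manifest.json")
  if (!file.exists(csv)) stop("no traces.csv under ", path, call. = FALSE)
  if (!file.exists(mf)) stop("no manifest.json under ", path, call. = FALSE)
  if (file.size(csv) == 0) {
    stop("traces.csv is empty: ", csv, call. = FALSE)
  }
  traces <- suppressWarnings(readr::read_csv(
    csv,
    col_types = readr::cols(
      molecule_id = readr::col_integer(),
      frame = readr::col_integer(),
      i_donor = readr::col_double(),
      i_acceptor = readr::col_double()
    ),
    progress = FALSE
  ))
  prob <- readr::problems(traces)
  if (nrow(prob) > 0) {
    bad <- prob[1, ]
    # vroom reports the physical line (header included); the data row is one up
    mol <- tryCatch(traces$molecule_id[bad$row - 1L], error = function(e) NA)
    stop(sprintf(
      "malformed trace table %s: line %d (molecule %s): expected %s, got %s",
      csv, bad$row, as.character(mol), bad$expected, bad$actual),
      call. = FALSE)
  }
  required <- c("molecule_id", "frame", "i_donor", "i_acceptor")
  if (!all(required %in% names(traces)) || nrow(traces) == 0) {
    stop("trace table ", csv, " must be a non-empty table with columns ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (is.null(manifest$condition)) {
    stop("manifest ", mf, " has no `condition` block; required keys: ",
         "construct, protein, protein_conc_nM, nucleotide, ",
         "nucleotide_conc_uM, cation, cation_conc_mM, frame_time_s",
         call. = FALSE)
  }
  cond <- .validate_condition_list(manifest$condition)
  truth <- if (!is.null(manifest$ground_truth)) {
    tibble::as_tibble(manifest$ground_truth)
  }
  known <- c("condition", "ground_truth", "sim_info")
  extra <- manifest[setdiff(names(manifest), known)]
  ds <- new_trace_dataset(traces, condition = cond, ground_truth = truth,
                          sim_info = manifest$sim_info)
  if (length(extra) > 0) attr(ds, "manifest_extra") <- extra
  ds
}

#' Read all datasets of a titration run
#'
#' @param dir Directory written by [simulate_titration()] (or laid out the
#'   same way): a `manifest.json` listing dataset subdirectories with their
#'   concentrations.
#' @return A named list of `trace_dataset` objects, names = concentrations.
#' @export
read_titration <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json under ", dir, call. = FALSE)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (is.null(manifest$datasets) || is.null(manifest$concentrations)) {
    stop("titration manifest must list `datasets` and `concentrations`",
         call. = FALSE)
  }
  paths <- file.path(dir, sub("^\\./", "", unlist(manifest$datasets)))
  datasets <- purrr::map(paths, read_trace_dataset)
  names(datasets) <- format_conc(as.numeric(manifest$concentrations))
  attr(datasets, "manifest") <- manifest
  datasets
}
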