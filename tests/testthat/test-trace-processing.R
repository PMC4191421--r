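test_that("trace datasets round-trip losslessly through CSV + manifest", {
  cfg <- fixture_config(n_molecules = 8, seed = 21)
  ds <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  write_trace_dataset(ds, dir)
  back <- read_trace_dataset(dir)
  expect_identical(back$molecule_id, ds$molecule_id)
  expect_identical(back$frame, ds$frame)
  # intensities survive to within one ulp of the serialized magnitude
  expect_equal(back$i_donor, ds$i_donor, tolerance = 1e-12)
  expect_equal(back$i_acceptor, ds$i_acceptor, tolerance = 1e-12)
  expect_equal(unclass(dataset_condition(back)),
               unclass(dataset_condition(ds)))
  tr <- dataset_truth(back)
  expect_equal(tr$state, dataset_truth(ds)$state)
  # unknown manifest keys survive the round trip
  attr(ds, "manifest_extra") <- list(operator = "test-bench")
  write_trace_dataset(ds, dir)
  expect_equal(attr(read_trace_dataset(dir), "manifest_extra")$operator,
               "test-bench")
})

test_that("malformed or incomplete dataset files raise informative errors", {
  dir <- withr::local_tempdir()
  expect_error(read_trace_dataset(dir), "no traces.csv")
  # empty file is a parse error, not an empty dataset
  file.create(file.path(dir, "traces.csv"))
  writeLines("{}", file.path(dir, "manifest.json"))
  expect_error(read_trace_dataset(dir), "empty")
  # non-numeric cell is reported with its physical line and molecule
  cond <- condition()
  writeLines(jsonlite::toJSON(list(condition = unclass(cond)),
                              auto_unbox = TRUE),
             file.path(dir, "manifest.json"))
  writeLines(c("molecule_id,frame,i_donor,i_acceptor",
               "1,0,100,50", "1,1,oops,60"),
             file.path(dir, "traces.csv"))
  expect_error(read_trace_dataset(dir), "line 3 \\(molecule 1\\)")
  # manifest without the full condition block names the missing keys
  writeLines(c("molecule_id,frame,i_donor,i_acceptor", "1,0,100,50"),
             file.path(dir, "traces.csv"))
  writeLines('{"condition": {"construct": "x"}}',
             file.path(dir, "manifest.json"))
  expect_error(read_trace_dataset(dir), "missing required keys")
})

test_that("constant background subtraction is exact and invertible", {
  cfg <- fixture_config(n_molecules = 4, seed = 8)
  ds <- simulate_dataset(cfg)
  # zero background: identity
  expect_equal(subtract_background(ds, "constant", 0, 0)$i_donor, ds$i_donor)
  corr <- subtract_background(ds, "constant", cfg$background_d,
                              cfg$background_a)
  expect_equal(corr$i_donor, ds$i_donor - cfg$background_d)
  # corrected totals match the per-molecule brightness expectation
  truth <- dataset_truth(ds)
  fr <- compute_fret(corr)
  tot <- corr |>
    dplyr::left_join(fr[c("molecule_id", "frame", "usable")],
                     by = c("molecule_id", "frame")) |>
    dplyr::filter(.data$usable) |>
    dplyr::group_by(.data$molecule_id) |>
    dplyr::summarise(m = mean(.data$i_donor + .data$i_acceptor),
                     .groups = "drop")
  expect_equal(tot$m, truth$brightness, tolerance = 0.05)
})

test_that("post-bleach background estimation recovers the true offsets", {
  cfg <- single_state_config("folded_conf1", 0.64, 0.05,
                             n_molecules = 1, n_frames = 1000, seed = 13,
                             background_d = 20, background_a = 15,
                             donor_bleach_rate = 0, acceptor_bleach_rate = 0)
  tr <- simulate_trace(cfg, 1)$trace
  # impose a donor bleach at frame 500: both channels drop to background
  post <- tr$frame >= 500
  tr$i_donor[post] <- 20 + stats::rnorm(sum(post), 0, cfg$noise_sigma)
  tr$i_acceptor[post] <- 15 + stats::rnorm(sum(post), 0, cfg$noise_sigma)
  corr <- subtract_background(tr, "post_bleach")
  est_d <- 20 - mean(corr$i_donor[post])
  est_a <- 15 - mean(corr$i_acceptor[post])
  tol <- 3 * cfg$noise_sigma / sqrt(500)
  expect_lt(abs(est_d - 20), tol)
  expect_lt(abs(est_a - 15), tol)
  # no detectable bleach: falls back to the constant method with a warning
  flat <- simulate_trace(cfg, 2)$trace
  expect_warning(out <- subtract_background(flat, "post_bleach",
                                            background_d = 20,
                                            background_a = 15),
                 "no detectable bleach")
  expect_equal(out$i_donor, flat$i_donor - 20)
})

test_that("FRET computation has the ratio symmetries", {
  tr <- tibble::tibble(molecule_id = 1L, frame = 0:3,
                       i_donor = c(100, 200, 0, 300),
                       i_acceptor = c(100, 0, 150, 300))
  fr <- compute_fret(tr, intensity_floor = 50)
  expect_equal(fr$e[1], 0.5)
  expect_equal(fr$e[2], 0)
  expect_equal(fr$e[3], 1)
  # invariance under common positive rescaling of both channels
  tr2 <- dplyr::mutate(tr, i_donor = i_donor * 7, i_acceptor = i_acceptor * 7)
  expect_equal(compute_fret(tr2, intensity_floor = 50)$e, fr$e)
  # a dead frame is marked unusable and ends the usable prefix
  tr3 <- tibble::tibble(molecule_id = 1L, frame = 0:2,
                        i_donor = c(200, 10, 200),
                        i_acceptor = c(200, 5, 200))
  fr3 <- compute_fret(tr3, intensity_floor = 100)
  expect_equal(fr3$usable, c(TRUE, FALSE, FALSE))
  # non-positive total does not propagate NaN
  tr4 <- tibble::tibble(molecule_id = 1L, frame = 0L,
                        i_donor = -5, i_acceptor = 2)
  expect_true(is.na(compute_fret(tr4)$e))
})

test_that("single-molecule filter separates singles from contaminants", {
  cfg <- fixture_config(n_molecules = 500, n_frames = 30, seed = 31,
                        contaminant_fraction = 0.2)
  ds <- simulate_dataset(cfg)
  corr <- subtract_background(ds, "constant", cfg$background_d,
                              cfg$background_a)
  res <- filter_single_molecules(corr)
  truth <- dataset_truth(ds)
  joined <- dplyr::left_join(res$report,
                             truth[c("molecule_id", "contaminant")],
                             by = "molecule_id")
  singles <- is.na(joined$contaminant)
  # recover >= 95% of true singles; let through <= 5% contaminants
  expect_gte(mean(joined$accepted[singles]), 0.95)
  expect_lte(mean(joined$accepted[!singles]), 0.05)
  # rejection reasons match the contaminant signatures
  expect_equal(unname(joined$reason[joined$contaminant %in% "donor_only" &
                                      !joined$accepted][1]), "no_acceptor")
  agg_reasons <- joined$reason[joined$contaminant %in% "aggregate" &
                                 !joined$accepted]
  expect_true(all(agg_reasons %in% c("intensity_band", "multi_step")))
  # accepted and rejected partition the input
  expect_equal(sort(res$report$molecule_id), sort(unique(ds$molecule_id)))
  expect_equal(dplyr::n_distinct(res$accepted$molecule_id),
               sum(res$report$accepted))
})

test_that("filter accepts everything on clean, bleach-free data", {
  cfg <- fixture_config(n_molecules = 80, seed = 15,
                        donor_bleach_rate = 0, acceptor_bleach_rate = 0,
                        contaminant_fraction = 0)
  corr <- subtract_background(simulate_dataset(cfg), "constant",
                              cfg$background_d, cfg$background_a)
  res <- filter_single_molecules(corr)
  # brightness is stochastic, so a few honest singles graze the intensity
  # band; essentially all clean traces must survive, none for other reasons
  expect_gte(mean(res$report$accepted), 0.95)
  expect_true(all(res$summary$reason %in% "intensity_band"))
  expect_warning(filter_single_molecules(corr[0, ]), "empty dataset")
})
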