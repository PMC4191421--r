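fret_tbl <- function(e, id = NULL) {
  if (is.null(id)) id <- rep(1L, length(e))
  tibble::tibble(molecule_id = as.integer(id),
                 frame = stats::ave(seq_along(e), id, FUN = seq_along) - 1L,
                 e = e, usable = TRUE)
}

manual_histogram <- function(percent_by_bin) {
  # build a fret_histogram directly from per-bin percentages (tests only)
  edges <- seq(-0.2, 1.2, by = 0.025)
  stopifnot(length(percent_by_bin) == length(edges) - 1)
  structure(tibble::tibble(bin_left = edges[-length(edges)],
                           bin_right = edges[-1],
                           percent = percent_by_bin),
            n_molecules = 100L, n_samples = 1000L, bin_width = 0.025,
            class = c("fret_histogram", class(tibble::tibble())))
}

test_that("histograms are percent normalized with exact bookkeeping", {
  # a single molecule at one level occupies one bin with 100%
  h <- fret_histogram(fret_tbl(rep(0.5124, 30)))
  expect_equal(sum(h$percent), 100, tolerance = 1e-9)
  expect_equal(max(h$percent), 100)
  expect_equal(h$bin_left[which.max(h$percent)], 0.5)
  # two molecules at distinct levels with equal frames: 50/50
  h2 <- fret_histogram(fret_tbl(c(rep(0.2, 10), rep(0.8, 10)),
                                id = rep(1:2, each = 10)))
  expect_equal(sort(h2$percent[h2$percent > 0]), c(50, 50))
  expect_equal(attr(h2, "n_molecules"), 2)
  # random data still sums to exactly 100
  set.seed(1)
  h3 <- fret_histogram(fret_tbl(runif(5000), id = rep(1:250, each = 20)))
  expect_equal(sum(h3$percent), 100, tolerance = 1e-9)
})

test_that("histogram pooling respects usable windows and frame caps", {
  e <- c(rep(0.3, 25), rep(0.9, 5))
  tbl <- fret_tbl(e)
  tbl$usable <- c(rep(TRUE, 25), rep(FALSE, 5))
  h <- fret_histogram(tbl, frames_per_molecule = 20)
  # only the first 20 usable frames pooled; the unusable 0.9 frames excluded
  expect_equal(attr(h, "n_samples"), 20)
  expect_equal(sum(h$percent[h$bin_left >= 0.85]), 0)
  expect_error(fret_histogram(dplyr::mutate(tbl, usable = FALSE)),
               "no usable frames")
})

test_that("subtraction conserves population and rejects mismatched bins", {
  set.seed(7)
  mk <- function(seed, n = 200) {
    set.seed(seed)
    fret_histogram(fret_tbl(rnorm(n * 10, 0.5, 0.2),
                            id = rep(seq_len(n), each = 10)))
  }
  a <- mk(1); b <- mk(2)
  d <- subtract_reference(a, b)
  expect_equal(sum(d$delta_percent), 0, tolerance = 1e-9)
  expect_equal(sum(d$delta_percent[d$delta_percent > 0]),
               abs(sum(d$delta_percent[d$delta_percent < 0])),
               tolerance = 1e-9)
  expect_equal(positive_area(d), negative_area(d), tolerance = 1e-9)
  # self-subtraction is identically zero
  expect_equal(positive_area(subtract_reference(a, a)), 0)
  # different binning is an error, not a silent rebin
  coarse <- fret_histogram(fret_tbl(rnorm(500, 0.5, 0.2),
                                    id = rep(1:50, each = 10)),
                           bin_width = 0.05)
  expect_error(subtract_reference(a, coarse), "identical bin edges")
})

test_that("positive area matches an independent per-bin loop oracle", {
  set.seed(42)
  for (rep in 1:5) {
    h1 <- manual_histogram({p <- runif(56); 100 * p / sum(p)})
    h2 <- manual_histogram({p <- runif(56); 100 * p / sum(p)})
    d <- subtract_reference(h1, h2)
    # brute force: loop over bins, accumulate positive entries
    acc <- 0
    for (i in seq_len(nrow(d))) {
      if (d$delta_percent[i] > 0) acc <- acc + d$delta_percent[i]
    }
    expect_equal(positive_area(d), acc, tolerance = 1e-12)
    expect_lte(positive_area(d), 100)
  }
})

test_that("a constructed 30% population shift scores exactly 30", {
  p <- numeric(56)
  edges <- seq(-0.2, 1.2, by = 0.025)
  hi_bin <- which(abs(edges - 0.70) < 1e-9)  # reference mass at E = 0.70
  lo_bin <- which(abs(edges - 0.30) < 1e-9)  # shifted mass lands at E = 0.30
  ref <- p; ref[hi_bin] <- 100
  smp <- p; smp[hi_bin] <- 70; smp[lo_bin] <- 30
  d <- subtract_reference(manual_histogram(smp), manual_histogram(ref))
  expect_equal(positive_area(d), 30)
  expect_equal(negative_area(d), 30)
  # the e_cut variant only counts the low-FRET part of the positive lobe
  expect_equal(positive_area(d, e_cut = 0.45), 30)
  expect_equal(positive_area(d, e_cut = 0.25), 0)
})

test_that("threshold integration is pro-rata at bin boundaries", {
  p <- numeric(56); p[c(10, 20, 40)] <- c(25, 25, 50)
  h <- manual_histogram(p)
  expect_equal(threshold_population(h, -0.2), 0)
  expect_equal(threshold_population(h, 1.2), 100)
  # e_max below the first occupied bin
  expect_equal(threshold_population(h, 0.0), 0)
  # bin 10 spans [0.025, 0.05); a threshold 40% into it takes 40% of 25
  expect_equal(threshold_population(h, 0.035), 25 * 0.4)
  # on a bin edge: whole bins below count fully
  expect_equal(threshold_population(h, 0.3), 50)
})

test_that("Gaussian fitting is self-consistent and identifies known levels", {
  # an exactly rendered Gaussian is recovered to numerical precision
  edges <- seq(-0.2, 1.2, by = 0.025)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  y <- exp(-(mids - 0.4)^2 / (2 * 0.06^2))
  g <- fit_fret_gaussians(manual_histogram(100 * y / sum(y)), 1)
  expect_equal(tidy(g)$center, 0.40, tolerance = 1e-6)
  expect_equal(tidy(g)$sigma, 0.06, tolerance = 1e-6)
  expect_equal(tidy(g)$area_percent, 100, tolerance = 1e-4)
  # simulated unfolded-state dataset: single component near 0.40 +/- 0.06
  cfg <- single_state_config("unfolded", 0.40, 0.06,
                             n_molecules = 250, seed = 5)
  h <- fixture_histogram(simulate_dataset(cfg))
  g1 <- tidy(fit_fret_gaussians(h, 1))
  expect_equal(g1$center, 0.40, tolerance = 0.02)
  expect_equal(g1$sigma, 0.06, tolerance = 0.25)
  # simulated K+ folded dataset: two conformers near 0.64 and 0.78
  occ2 <- occupancy_spec(isotherm_params(0, 1))
  cfg2 <- simulation_config(occupancy = occ2, n_molecules = 500, seed = 6)
  h2 <- fixture_histogram(simulate_dataset(cfg2))
  g2 <- tidy(fit_fret_gaussians(h2, 2))
  expect_equal(g2$center[1], 0.64, tolerance = 0.03)
  expect_equal(g2$center[2], 0.78, tolerance = 0.03)
  # the blended folded distribution peaks between the two conformer centers
  mode_bin <- h2$bin_left[which.max(h2$percent)]
  expect_gte(mode_bin, 0.64 - 0.025)
  expect_lte(mode_bin, 0.78 + 0.025)
  # a well-separated single level peaks within a bin of its center
  cfg_u <- single_state_config("unfolded", 0.40, 0.06,
                               n_molecules = 200, seed = 14)
  hu <- fixture_histogram(simulate_dataset(cfg_u))
  expect_lt(abs(hu$bin_left[which.max(hu$percent)] + 0.0125 - 0.40), 0.05)
  expect_error(fit_fret_gaussians(manual_histogram(c(rep(0, 54), 60, 40)), 1),
               "occupied bins")
})

test_that("positive area is stable under bin-width refinement", {
  occ <- fixture_occupancy()
  cfg <- simulation_config(occupancy = occ, effector_conc = NTFREE_KEQ,
                           n_molecules = 400, seed = 12)
  cfg0 <- simulation_config(occupancy = occ, effector_conc = 0,
                            n_molecules = 400, seed = 12)
  areas <- sapply(c(0.025, 0.05), function(bw) {
    h1 <- fixture_histogram(simulate_dataset(cfg, dataset_index = 1),
                            bin_width = bw)
    h0 <- fixture_histogram(simulate_dataset(cfg0, dataset_index = 2),
                            bin_width = bw)
    positive_area(subtract_reference(h1, h0))
  })
  expect_equal(areas[1], areas[2], tolerance = 0.1)
})

test_that("histograms round-trip through CSV with their metadata", {
  cfg <- single_state_config(n_molecules = 30, seed = 3)
  h <- fixture_histogram(simulate_dataset(cfg))
  path <- withr::local_tempfile(fileext = ".csv")
  write_histogram(h, path)
  back <- read_histogram(path)
  expect_equal(back$percent, h$percent)
  expect_s3_class(back, "fret_histogram")
  expect_equal(attr(back, "n_molecules"), attr(h, "n_molecules"))
  d <- subtract_reference(h, h)
  write_histogram(d, path)
  expect_s3_class(read_histogram(path), "fret_difference")
})
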