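test_that("simulation is bit-identical under a fixed seed and stream", {
  cfg <- fixture_config(seed = 42)
  tr1 <- simulate_trace(cfg, 7)
  tr2 <- simulate_trace(cfg, 7)
  expect_identical(tr1$trace, tr2$trace)
  expect_identical(tr1$truth$brightness, tr2$truth$brightness)
  # changing the molecule index or the seed changes the trace
  tr3 <- simulate_trace(cfg, 8)
  expect_false(identical(tr1$trace$i_donor, tr3$trace$i_donor))
  cfg2 <- fixture_config(seed = 43)
  tr4 <- simulate_trace(cfg2, 7)
  expect_false(identical(tr1$trace$i_donor, tr4$trace$i_donor))
  # whole datasets reproduce exactly
  expect_identical(as.data.frame(simulate_dataset(cfg)),
                   as.data.frame(simulate_dataset(cfg)))
})

test_that("noiseless single-state traces reproduce the configured level", {
  cfg <- single_state_config("unfolded", 0.40, 1e-9,
                             noise_sigma = 0, intensity_cv = 0,
                             donor_bleach_rate = 0, acceptor_bleach_rate = 0,
                             background_d = 0, background_a = 0,
                             n_molecules = 3)
  ds <- simulate_dataset(cfg)
  fret <- compute_fret(ds)
  expect_true(all(abs(fret$e - 0.40) < 1e-6))
})

test_that("per-frame FRET samples follow the configured state Gaussian", {
  # law of large numbers on a long single-molecule trace
  cfg <- single_state_config("folded_conf2", 0.78, 0.05,
                             n_frames = 10000, noise_sigma = 0,
                             donor_bleach_rate = 0, acceptor_bleach_rate = 0,
                             background_d = 0, background_a = 0, seed = 9)
  tr <- simulate_trace(cfg, 1)
  e <- tr$trace$i_acceptor / (tr$trace$i_acceptor + tr$trace$i_donor)
  expect_gt(mean(e), 0.775)
  expect_lt(mean(e), 0.785)
  expect_equal(stats::sd(e), 0.05, tolerance = 0.05)
})

test_that("ground-truth state fractions converge to the occupancy vector", {
  cfg <- fixture_config(n_molecules = 2000, n_frames = 2, seed = 3,
                        effector_conc = NTFREE_KEQ)
  ds <- simulate_dataset(cfg)
  truth <- dataset_truth(ds)
  p_low <- mean(truth$state %in% LOW_STATES)
  se <- sqrt(0.245 * 0.755 / 2000)
  expect_lt(abs(p_low - 0.245), 3 * se)
  # per-state mean of drawn E values matches e_mean within 3 sigma / sqrt(n)
  fret <- compute_fret(subtract_background(ds, "constant",
                                           cfg$background_d, cfg$background_a))
  joined <- dplyr::left_join(fret, truth[c("molecule_id", "state")],
                             by = "molecule_id")
  by_state <- joined |>
    dplyr::filter(.data$usable) |>
    dplyr::group_by(.data$state) |>
    dplyr::summarise(m = mean(.data$e), n = dplyr::n(), .groups = "drop")
  levels <- default_states()
  for (i in seq_len(nrow(by_state))) {
    lev <- levels[levels$state == by_state$state[i], ]
    expect_lt(abs(by_state$m[i] - lev$e_mean),
              4 * lev$e_sigma / sqrt(by_state$n[i]) + 0.005)
  }
})

test_that("photobleaching truncates the usable window as configured", {
  cfg <- single_state_config("folded_conf1", 0.64, 0.05,
                             n_molecules = 300, n_frames = 200,
                             donor_bleach_rate = 0.02,
                             acceptor_bleach_rate = 0, seed = 10)
  ds <- simulate_dataset(cfg)
  truth <- dataset_truth(ds)
  expect_gt(mean(!is.na(truth$bleach_frame_d)), 0.9) # most bleach in 200 frames
  # after donor bleach both channels fall to background
  corr <- subtract_background(ds, "constant", cfg$background_d, cfg$background_a)
  bleached <- truth$molecule_id[!is.na(truth$bleach_frame_d)][1]
  bf <- truth$bleach_frame_d[truth$molecule_id == bleached]
  tail_frames <- corr[corr$molecule_id == bleached & corr$frame >= bf, ]
  expect_lt(mean(abs(tail_frames$i_donor + tail_frames$i_acceptor)), 50)
  # compute_fret marks the post-bleach frames unusable
  fr <- compute_fret(corr)
  expect_equal(sum(fr$usable[fr$molecule_id == bleached]), bf)
})

test_that("contaminants have the advertised signatures", {
  cfg <- fixture_config(seed = 5, n_molecules = 20)
  dn <- simulate_contaminant(cfg, 1, kind = "donor_only")
  e <- dn$trace$i_acceptor / (dn$trace$i_acceptor + dn$trace$i_donor)
  expect_true(all(e < 0.12))
  ag <- simulate_contaminant(cfg, 2, kind = "aggregate")
  expect_gt(ag$truth$brightness, 1.4 * cfg$total_intensity)
  expect_equal(mean(ag$trace$i_donor + ag$trace$i_acceptor),
               ag$truth$brightness, tolerance = 0.2)
  # zero contaminant fraction -> none generated
  ds <- simulate_dataset(fixture_config(contaminant_fraction = 0))
  expect_true(all(is.na(dataset_truth(ds)$contaminant)))
  # requested fraction is honored
  ds2 <- simulate_dataset(fixture_config(contaminant_fraction = 0.2,
                                         n_molecules = 50))
  expect_equal(sum(!is.na(dataset_truth(ds2)$contaminant)), 10)
})

test_that("dynamic mode alternates between folded and low classes", {
  occ <- fixture_occupancy(alpha = 50, k_eq = 100)
  cfg <- simulation_config(occupancy = occ, effector_conc = 100,
                           n_molecules = 5, n_frames = 3000,
                           dynamic_mode = TRUE,
                           dwell_folded = 1, dwell_unfolded = 1,
                           donor_bleach_rate = 0, acceptor_bleach_rate = 0,
                           seed = 11)
  tr <- simulate_trace(cfg, 1)
  path <- tr$truth$state_path[[1]]
  classes <- path %in% LOW_STATES
  expect_gt(mean(classes), 0.1)
  expect_lt(mean(classes), 0.9)
  expect_gt(sum(diff(classes) != 0), 5) # multiple unfolding/refolding cycles
})

test_that("titrations index datasets reproducibly and warn without reference", {
  cfg <- fixture_config(n_molecules = 10, seed = 2)
  expect_warning(simulate_titration(cfg, c(10, 100)), "zero-concentration")
  ds <- simulate_titration(cfg, c(0, NTFREE_KEQ))
  truth <- dataset_truth(ds[[2]])
  expect_equal(names(ds), c("0", "305"))
  expect_equal(sum(dataset_truth(ds[[1]])$state %in% LOW_STATES), 0)
  # pooled fields: molecule ids unique, count multiplies
  ds2 <- simulate_titration(cfg, c(0, 305), n_fields = 3)
  expect_equal(dplyr::n_distinct(ds2[[1]]$molecule_id), 30)
  expect_equal(nrow(dataset_truth(ds2[[1]])), 30)
})
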