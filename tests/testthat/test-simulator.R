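test_that("heart-rate walks stay in band, reflect and reproduce", {
  cfg <- sim_config(duration_s = 300, hr_drift = 0, seed = 14)
  expect_true(all(simulate_hr_trace(cfg) == cfg$hr_start_bpm))

  cfg2 <- sim_config(duration_s = 600, hr_drift = 8,
                     hr_band = c(70, 90), hr_start_bpm = 80, seed = 15)
  tr <- simulate_hr_trace(cfg2)
  expect_true(all(tr >= 70 & tr <= 90))
  expect_identical(tr, simulate_hr_trace(cfg2))
})

test_that("clean recordings put every window argmax on the true bin", {
  rec <- simulate_recording(sim_config(duration_s = 60, noise_sd = 0,
                                       seed = 16))
  cfg <- pp_config()
  wins <- slide_windows(rec, cfg)
  for (i in seq_along(wins)) {
    spec <- periodogram_spectrum(wins[[i]]$ppg, cfg$fs, cfg$N)
    hb <- 2:(cfg$N / 2)
    amax <- hb[which.max(spec$amp[hb])]
    expect_lte(abs(amax - bpm_to_loc(rec$truth_bpm[i], cfg$fs, cfg$N)), 1)
  }
})

test_that("strong coupling makes the cadence dominate the raw spectrum", {
  rec <- simulate_recording(sim_config(duration_s = 60, hr_start_bpm = 90,
                                       cadence_hz = 2.4,
                                       ma_gain_linear = 5, ma_rampup_s = 0,
                                       seed = 17))
  cfg <- pp_config()
  wins <- slide_windows(rec, cfg)
  cad_bin <- hz_to_bin(2.4, cfg$fs, cfg$N)
  hits <- vapply(wins, function(w) {
    spec <- periodogram_spectrum(w$ppg, cfg$fs, cfg$N)
    hb <- 2:(cfg$N / 2)
    abs(hb[which.max(spec$amp[hb])] - cad_bin) <= 2
  }, logical(1))
  expect_gt(mean(hits), 0.9)
  expect_true(all(colSums(rec$accel^2) > 0))
})

test_that("recordings carry consistent channels, truth and windows", {
  rec <- simulate_recording(sim_config(duration_s = 30, seed = 18))
  expect_s3_class(rec, "pp_recording")
  expect_equal(nrow(rec$ppg), 30 * 125)
  expect_length(rec$truth_bpm, 12)  # floor((3750 - 1000)/250) + 1
  expect_true(all(rec$truth_bpm >= 60 & rec$truth_bpm <= 160))
})

test_that("dataset grids enumerate cells and differ across replicates", {
  three <- list(clean = c(0, 0), moderate = c(0.8, 0.3),
                strong = c(3, 1.2, 0.5, 3))
  ds <- simulate_dataset(sim_config(duration_s = 10), gain_levels = three,
                         n_per_cell = 2, seed = 19)
  expect_length(ds, 6)
  expect_equal(as.integer(table(vapply(ds, attr, "", "level"))),
               c(2L, 2L, 2L))
  expect_false(identical(ds[[1]]$ppg, ds[[2]]$ppg))
  ds2 <- simulate_dataset(sim_config(duration_s = 10), gain_levels = three,
                          n_per_cell = 2, seed = 19)
  expect_identical(ds[[1]]$ppg, ds2[[1]]$ppg)
  # default grid spans all four artifact levels
  ds4 <- simulate_dataset(sim_config(duration_s = 10), n_per_cell = 1,
                          seed = 20)
  expect_length(ds4, 4)
})
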