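test_that("search ranges follow the harmonic geometry and clip", {
  cfg <- pp_config()
  r <- compute_ranges(60L, cfg, N = 4096)
  expect_equal(r$r1, c(58L, 62L))
  expect_equal(r$r2, c(115L, 123L))

  cfg0 <- pp_config(delta_s = 0)
  r0 <- compute_ranges(60L, cfg0, N = 4096)
  expect_equal(r0$r1, c(60L, 60L))
  expect_equal(r0$r2, c(119L, 119L))

  rhi <- compute_ranges(2047L, cfg, N = 4096)
  expect_equal(rhi$r2[2], 4096L)
  expect_error(compute_ranges(0L, cfg), "state error")
})

test_that("bin-to-BPM conversion matches the spectral definition", {
  fs <- 125; N <- 4096
  expect_equal(loc_to_bpm(1, fs, N), 0)
  expect_equal(loc_to_bpm(56, fs, N), 55 * 7500 / 4096)
  expect_equal(loc_to_bpm(56, fs, N), 100.708, tolerance = 1e-4)
  expect_error(loc_to_bpm(0, fs, N), "parameter error")
  expect_error(bpm_to_loc(-1, fs, N), "parameter error")
  # strictly increasing with resolution fs*60/N
  bpm <- loc_to_bpm(1:100, fs, N)
  expect_equal(unique(round(diff(bpm), 10)), fs * 60 / N)
})

test_that("range peaks and harmonic pairs are detected as specified", {
  cfg <- pp_config()
  amp <- rep(0, 4096)
  amp[60] <- 1.0
  spec <- make_spectrum(amp)
  ranges <- compute_ranges(58L, cfg, 4096L)
  pk <- range_peaks(spec, ranges, cfg)
  expect_equal(pk$Li0, 60L)
  expect_equal(pk$n2, 0L)
  expect_null(detect_harmonic_pair(pk, cfg))

  amp[119] <- 0.6  # harmonic image of bin 60: 2*59 + 1
  pk2 <- range_peaks(make_spectrum(amp), ranges, cfg)
  pair <- detect_harmonic_pair(pk2, cfg)
  expect_equal(pair, c(60L, 119L))

  amp[119] <- 0; amp[123] <- 0.6  # 4 bins off the harmonic image
  pk3 <- range_peaks(make_spectrum(amp), ranges, cfg)
  expect_null(detect_harmonic_pair(pk3, cfg))

  # two in-range tones above half maximum are both returned, strongest first
  amp2 <- rep(0, 4096); amp2[c(57, 60)] <- c(0.8, 1.0)
  pk4 <- range_peaks(make_spectrum(amp2), ranges, cfg)
  expect_equal(pk4$Li0, c(60L, 57L))

  flat <- make_spectrum(rep(0, 4096))
  pk5 <- range_peaks(flat, ranges, cfg)
  expect_length(pk5$Li0, 0)
})

test_that("candidate construction follows the three selection rules", {
  cfg <- pp_config()
  # harmonic pair present: candidate 1 is its fundamental
  pk <- list(Li0 = c(60L), Li1 = c(119L), n1 = 1L, n2 = 1L)
  pair <- c(60L, 119L)
  cand <- build_candidates(58L, pk, pair, cfg)
  expect_equal(cand$L1, 60L)
  expect_equal(cand$L3, 58L)

  # no pair: step sigma1 toward the strongest in-range peak
  pk2 <- list(Li0 = c(65L), Li1 = integer(0), n1 = 1L, n2 = 0L)
  cand2 <- build_candidates(60L, pk2, NULL, cfg)
  expect_equal(cand2$L1, 62L)
  # candidate 2 steps sigma2 toward the closest candidate (65 too far)
  expect_equal(cand2$L2, 62L)

  # close peak is adopted directly as candidate 2
  pk3 <- list(Li0 = c(61L), Li1 = integer(0), n1 = 1L, n2 = 0L)
  cand3 <- build_candidates(60L, pk3, NULL, cfg)
  expect_equal(cand3$L2, 61L)

  # no peaks anywhere: everything stays at Lprev
  pk4 <- list(Li0 = integer(0), Li1 = integer(0), n1 = 0L, n2 = 0L)
  cand4 <- build_candidates(60L, pk4, NULL, cfg)
  expect_equal(c(cand4$L1, cand4$L2, cand4$L3), rep(60L, 3))

  # harmonic peaks map back through the inverse harmonic relation
  pk5 <- list(Li0 = integer(0), Li1 = c(121L), n1 = 0L, n2 = 1L)
  cand5 <- build_candidates(60L, pk5, NULL, cfg)
  expect_equal(cand5$L2, 61L)  # (121 - 1)/2 + 1
})

test_that("stage-2 labels pick the candidate closest to the true bin", {
  cand <- list(L1 = 60L, L2 = 59L, L3 = 58L)
  expect_equal(label_stage2(cand, 61L), 1L)
  expect_equal(label_stage2(cand, 58L), 3L)
  expect_equal(label_stage2(list(L1 = 60L, L2 = 60L, L3 = 60L), 60L), 1L)
})

test_that("stage-2 features have the documented layout and degeneracies", {
  cfg <- pp_config()
  s <- make_tone(1.7, n = 1000)
  a <- make_tone(2.2, n = 1000)
  spec <- periodogram_spectrum(s, cfg$fs, cfg$N)
  a_spec <- periodogram_spectrum(a, cfg$fs, cfg$N)
  pk <- list(Li0 = 56L, Li1 = 111L, n1 = 1L, n2 = 1L)
  f <- extract_stage2_features(s, a, spec, a_spec, pk, c(56L, 111L))
  expect_named(f, c("n_peaks_r1", "n_peaks_r2", "accel_energy", "cc_time",
                    "cc_spec", "mean", "skewness", "kurtosis", "pair_flag"))
  expect_equal(unname(f["pair_flag"]), 1)

  fz <- extract_stage2_features(rep(1, 1000), rep(0, 1000), spec, a_spec,
                                pk, NULL)
  expect_equal(unname(fz[c("skewness", "kurtosis", "cc_time",
                           "accel_energy", "pair_flag")]),
               c(0, 0, 0, 0, 0))
})

test_that("the stage-2 classifier recovers separable states and seeds", {
  cfg <- pp_config()
  clouds <- make_clouds(70, centers = c(0, 3, 6), dim = 9, seed = 12)
  fit <- train_stage2(clouds$features, clouds$labels, cfg, seed = 5)
  expect_gte(fit$cv$accuracy, 0.9)
  fit2 <- train_stage2(clouds$features, clouds$labels, cfg, seed = 5)
  expect_identical(fit$cv, fit2$cv)

  set.seed(13)
  null_fit <- train_stage2(clouds$features, sample(clouds$labels), cfg,
                           seed = 5)
  expect_lt(abs(null_fit$cv$accuracy - 1 / 3), 0.1)

  cands <- list(L1 = 70L, L2 = 65L, L3 = 60L)
  sel <- select_loc(fit, unlist(clouds$features[200, ]), cands)
  expect_equal(sel$class, 3L)
  expect_equal(sel$loc, 60L)  # class 3 repeats the previous bin
  sel1 <- select_loc(fit, unlist(clouds$features[1, ]), cands)
  expect_equal(sel1$loc, 70L)
  expect_error(select_loc(NULL, unlist(clouds$features[1, ]), cands),
               "state error")
})

test_that("tracker initialisation uses the band argmax or a supplied rate", {
  cfg <- pp_config()
  spec <- periodogram_spectrum(make_tone(90 / 60, n = 1000), cfg$fs, cfg$N)
  init <- initialize_tracker(spec, cfg)
  expect_lte(abs(init - bpm_to_loc(90, cfg$fs, cfg$N)), 1)

  expect_equal(initialize_tracker(spec, cfg, init_bpm = 75),
               bpm_to_loc(75, cfg$fs, cfg$N))

  flat <- make_spectrum(rep(0, 4096))
  expect_warning(lo <- initialize_tracker(flat, cfg), "flat spectrum")
  expect_equal(lo, bpm_to_loc(cfg$hr_band[1], cfg$fs, cfg$N))

  # excluded cadence bins cannot capture the start-up argmax
  two <- periodogram_spectrum(make_tone(90 / 60, n = 1000) +
                                2 * make_tone(120 / 60, n = 1000),
                              cfg$fs, cfg$N)
  cad_bin <- bpm_to_loc(120, cfg$fs, cfg$N)
  init2 <- initialize_tracker(two, cfg, exclude = cad_bin)
  expect_lte(abs(init2 - bpm_to_loc(90, cfg$fs, cfg$N)), 1)
})
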