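test_that("SSA components always sum back to the input series", {
  set.seed(7)
  for (i in 1:5) {
    s <- rnorm(400)
    dec <- ssa_decompose(s, L = 100, k = 10)
    expect_lt(max(abs(rowSums(dec$components) - s)), 1e-8 * max(abs(s)))
    expect_true(all(diff(dec$eigenvalues) <= 1e-9))
  }
  expect_error(ssa_decompose(rnorm(50), L = 50), "parameter error")
  expect_error(ssa_decompose(rnorm(50), L = 10, k = 11), "parameter error")
})

test_that("a pure sinusoid concentrates in the two leading components", {
  s <- make_tone(1.9, n = 500)
  dec <- ssa_decompose(s, L = 100, k = 5)
  # the leading quadrature pair jointly reconstructs the tone
  pair <- rowSums(dec$components[, 1:2])
  expect_gt(sum(pair^2) / sum(s^2), 0.95)
  expect_lt(sum((pair - s)^2) / sum(s^2), 0.05)

  const <- ssa_decompose(rep(3, 200), L = 50, k = 3)
  expect_equal(const$components[, 1], rep(3, 200), tolerance = 1e-6)
})

test_that("dominant acceleration bins follow the 50% peak rule", {
  fs <- 125; N <- 4096
  tone <- periodogram_spectrum(make_tone(2.1), fs, N)
  lacc <- accel_dominant_bins(tone, 0.5)
  expect_true(any(abs(lacc - hz_to_bin(2.1, fs, N)) <= 1))

  expect_length(accel_dominant_bins(periodogram_spectrum(rep(0, 1000),
                                                         fs, N), 0.5), 0)

  two <- periodogram_spectrum(make_tone(1.5) + 0.4 * make_tone(2.8),
                              fs, N)
  lacc2 <- accel_dominant_bins(two, 0.5)
  expect_true(all(abs(lacc2 - hz_to_bin(1.5, fs, N)) <= 1))
})

test_that("SSA removal suppresses the cadence tone and keeps the pulse", {
  fs <- 125; N <- 4096
  pulse <- make_tone(1.7, n = 1000)
  cad <- make_tone(2.5, n = 1000, amp = 1.5, phase = 1)  # MA above pulse
  s_hat <- pulse + cad
  a_spec <- periodogram_spectrum(make_tone(2.5, n = 1000, phase = 0.3),
                                 fs, N)
  out <- ssa_remove_ma(s_hat, a_spec, pp_config())
  amp_at <- function(sig, f) {
    sp <- periodogram_spectrum(sig, fs, N)
    b <- hz_to_bin(f, fs, N)
    max(sp$amp[(b - 2):(b + 2)])
  }
  expect_lt(amp_at(out$s_recon, 2.5), 0.2 * amp_at(s_hat, 2.5))
  expect_gt(amp_at(out$s_recon, 1.7), 0.8 * amp_at(pulse, 1.7))
  expect_true(length(out$dropped) >= 1)
})

test_that("removal is a no-op without dominant acceleration frequencies", {
  s_hat <- make_tone(1.7, n = 1000) + 0.01 * rnorm(1000)
  silent <- periodogram_spectrum(rep(0, 1000), 125, 4096)
  out <- ssa_remove_ma(s_hat, silent, pp_config())
  expect_identical(out$s_recon, s_hat)
  expect_length(out$lacc, 0)
})

test_that("removal refuses to annihilate a signal that is all cadence", {
  tone <- make_tone(2.5, n = 1000)
  a_spec <- periodogram_spectrum(tone, 125, 4096)
  expect_warning(out <- ssa_remove_ma(tone, a_spec, pp_config()),
                 "whole signal")
  expect_equal(out$s_recon, tone)
})
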