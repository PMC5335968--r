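# Shared fixtures, built once per test run and memoised.
.fix <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (is.null(.fix[[name]])) .fix[[name]] <- builder()
  .fix[[name]]
}

# Default training grid (clean / moderate / strong-with-bursts) and the
# two fitted classifiers.
fixture_models <- function() {
  memo("models", function() {
    recs <- simulate_dataset(sim_config(duration_s = 120),
                             n_per_cell = 2L, seed = 42)
    pp_train(recs, pp_config(), seed = 7)
  })
}

# Class-balanced clean + severe grid for classifier sanity checks: severe
# recordings have dense bursts and fully modulated coupling with no
# low-motion lead-in, so roughly half of all windows carry strong
# residual artifacts.
fixture_balanced_tables <- function() {
  memo("balanced_tables", function() {
    base <- sim_config(duration_s = 120, ma_rampup_s = 0,
                       burst_rate = 15, burst_dur_s = c(3, 8))
    grid <- simulate_dataset(base,
                             gain_levels = list(clean = c(0, 0, 0, 0),
                                                severe = c(4, 1.5, 1, 4)),
                             n_per_cell = 3L, seed = 11)
    pp_training_tables(grid, pp_config(), seed = 3)
  })
}

# Strong-artifact evaluation regime: cadence within 0.2 Hz of the pulse
# fundamental, coupling strong enough that the raw argmax is wrong in
# most windows, plus contact bursts.
strong_sim_config <- function(seed) {
  sim_config(duration_s = 120, hr_start_bpm = 110, cadence_hz = 2.0,
             ma_gain_linear = 3, ma_gain_quadratic = 1.2, ma_mod = 0.5,
             burst_gain = 3, seed = seed)
}

clean_sim_config <- function(seed, duration_s = 180) {
  sim_config(duration_s = duration_s, ma_gain_linear = 0,
             ma_gain_quadratic = 0, burst_gain = 0, noise_sd = 0.02,
             seed = seed)
}

# A single-tone recording helper for spectral unit tests.
make_tone <- function(freq_hz, n = 1000, fs = 125, amp = 1, phase = 0) {
  amp * sin(2 * pi * freq_hz * (seq_len(n) - 1) / fs + phase)
}

# A pp_spectrum built directly from an amplitude vector.
make_spectrum <- function(amp, fs = 125) {
  structure(list(amp = amp, fs = fs, N = length(amp)),
            class = "pp_spectrum")
}

# Separable Gaussian feature clouds for classifier mechanics tests.
make_clouds <- function(n_per_class, centers, sd = 0.5, dim = 9,
                        seed = 1) {
  set.seed(seed)
  feats <- do.call(rbind, lapply(seq_along(centers), function(k) {
    matrix(rnorm(n_per_class * dim, mean = centers[k], sd = sd),
           nrow = n_per_class)
  }))
  colnames(feats) <- paste0("f", seq_len(dim))
  list(features = as.data.frame(feats),
       labels = rep(seq_along(centers), each = n_per_class))
}
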