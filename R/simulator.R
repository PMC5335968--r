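#' Simulation configuration
#'
#' Describes one synthetic wrist recording: a quasi-periodic pulse whose
#' fundamental follows a bounded random-walk BPM trajectory, with decaying
#' harmonics; cadence-locked tri-axial acceleration (gravity offset +
#' cadence fundamental + first harmonic + sensor noise); and motion
#' artifacts coupled into both PPG channels as a delayed linear +
#' quadratic transform of the cadence motion signal, plus white noise.
#'
#' Defaults emulate a treadmill session: three minutes at 125 Hz, heart
#' rate starting at 80 BPM and drifting by up to 1 BPM per 2-s step within
#' 60-160 BPM, a 2 Hz step cadence, three pulse harmonics decaying by half
#' each, and additive noise at 5% of the pulse amplitude.
#'
#' @param duration_s Recording length in seconds.
#' @param fs Sampling rate in Hz.
#' @param hr_start_bpm Initial heart rate in BPM.
#' @param hr_drift Half-width of the uniform per-window random-walk step
#'   (BPM per window step).
#' @param hr_band Reflecting bounds of the heart-rate walk, in BPM.
#' @param n_harmonics Number of pulse harmonics (including the
#'   fundamental).
#' @param harmonic_decay Amplitude ratio between consecutive harmonics.
#' @param cadence_hz Step cadence of the simulated exercise, in Hz.
#' @param ma_gain_linear,ma_gain_quadratic Coupling gains of the delayed
#'   motion signal (and its square) into the PPG channels.
#' @param ma_mod Depth of a slow sinusoidal amplitude modulation of the
#'   coupling gains, in `[0, 1]`. At 0 (default) the coupling is
#'   time-invariant and lies exactly in the model family of the Volterra
#'   canceller; at 1 the coupling strength swings between 0 and twice its
#'   nominal value, emulating the grip/pressure drift that makes real
#'   artifacts non-stationary within an analysis window.
#' @param ma_mod_hz Frequency of the coupling modulation, in Hz.
#' @param accel_harmonic Relative amplitude of the first cadence harmonic
#'   in the motion signal and accelerometer axes.
#' @param burst_gain Amplitude of transient contact-pressure artifacts:
#'   short tone bursts at random frequencies inside the pulse band that
#'   corrupt the optical channel only, with no counterpart in the
#'   accelerometer. 0 (default) disables them.
#' @param burst_rate Expected number of bursts per minute.
#' @param burst_dur_s Range `c(min, max)` of burst durations in seconds.
#' @param ma_rampup_s Lead-in during which all artifact amplitudes ramp
#'   linearly from zero, emulating the low-motion start (slow walking
#'   before the exercise proper) of treadmill protocols. The tracker
#'   initialises during this phase.
#' @param noise_sd Standard deviation of the white noise added to every
#'   channel (pulse fundamental has amplitude 1).
#' @param delay_s Transport delay between acceleration and the PPG
#'   artifact, in seconds.
#' @param T_s,M0_s Window length and step used to define the per-window
#'   ground-truth heart rate.
#' @param seed Optional RNG seed; a seeded configuration reproduces the
#'   identical recording.
#' @param id Recording label.
#' @return A named list of class `sim_config`.
#' @export
sim_config <- function(duration_s = 180, fs = 125, hr_start_bpm = 80,
                       hr_drift = 1, hr_band = c(60, 160),
                       n_harmonics = 3L, harmonic_decay = 0.5,
                       cadence_hz = 2.0, ma_gain_linear = 0,
                       ma_gain_quadratic = 0, ma_mod = 0,
                       ma_mod_hz = 0.06, accel_harmonic = 0.4,
                       burst_gain = 0, burst_rate = 6, burst_dur_s = c(2, 6),
                       ma_rampup_s = 15,
                       noise_sd = 0.05, delay_s = 0.08, T_s = 8, M0_s = 2,
                       seed = NULL, id = "sim") {
  stopifnot(duration_s >= T_s, fs > 0,
            hr_band[1] < hr_band[2], hr_band[2] < fs * 30,
            hr_start_bpm >= hr_band[1], hr_start_bpm <= hr_band[2],
            ma_gain_linear >= 0, ma_gain_quadratic >= 0, noise_sd >= 0,
            ma_mod >= 0, ma_mod <= 1, accel_harmonic >= 0,
            burst_gain >= 0, burst_rate >= 0,
            n_harmonics >= 1)
  structure(list(duration_s = duration_s, fs = fs,
                 hr_start_bpm = hr_start_bpm, hr_drift = hr_drift,
                 hr_band = hr_band, n_harmonics = as.integer(n_harmonics),
                 harmonic_decay = harmonic_decay, cadence_hz = cadence_hz,
                 ma_gain_linear = ma_gain_linear,
                 ma_gain_quadratic = ma_gain_quadratic,
                 ma_mod = ma_mod, ma_mod_hz = ma_mod_hz,
                 accel_harmonic = accel_harmonic,
                 burst_gain = burst_gain, burst_rate = burst_rate,
                 burst_dur_s = burst_dur_s, ma_rampup_s = ma_rampup_s,
                 noise_sd = noise_sd, delay_s = delay_s,
                 T_s = T_s, M0_s = M0_s, seed = seed, id = id),
            class = "sim_config")
}

#' Simulate a per-window heart-rate trajectory
#'
#' Bounded random walk: starting at `hr_start_bpm`, each window step adds
#' a uniform perturbation in `[-hr_drift, hr_drift]` and reflects at the
#' edges of `hr_band`.
#'
#' @param cfg A [sim_config()].
#' @return Numeric vector of one BPM value per analysis window.
#' @export
simulate_hr_trace <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- as.integer(round(cfg$duration_s * cfg$fs))
  W <- count_windows(n, cfg$T_s, cfg$M0_s, cfg$fs)
  reflect <- function(v) {
    lo <- cfg$hr_band[1]; hi <- cfg$hr_band[2]
    while (v < lo || v > hi) {
      if (v < lo) v <- 2 * lo - v
      if (v > hi) v <- 2 * hi - v
    }
    v
  }
  trace <- numeric(W)
  trace[1] <- cfg$hr_start_bpm
  if (W > 1) {
    steps <- runif(W - 1L, -cfg$hr_drift, cfg$hr_drift)
    for (i in 2:W) trace[i] <- reflect(trace[i - 1] + steps[i - 1])
  }
  trace
}

#' Simulate one synthetic wrist recording
#'
#' Builds the channels described in [sim_config()]: a phase-continuous
#' pulse following the simulated heart-rate trajectory, tri-axial
#' acceleration with a gravity offset so that the vector norm preserves
#' the cadence fundamental, and PPG channels corrupted by a delayed linear
#' + quadratic transform of the cadence motion signal. The per-window
#' ground truth is the mean instantaneous heart rate over each window.
#'
#' @param cfg A [sim_config()].
#' @return A [pp_recording()] with `truth_bpm` attached.
#' @export
simulate_recording <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  fs <- cfg$fs
  n <- as.integer(round(cfg$duration_s * fs))
  M <- as.integer(round(cfg$T_s * fs))
  step <- as.integer(round(cfg$M0_s * fs))
  W <- count_windows(n, cfg$T_s, cfg$M0_s, cfg$fs)

  # Heart-rate trajectory, interpolated to per-sample instantaneous BPM
  # through the window centres, then integrated into a continuous phase.
  trace <- {
    saved <- cfg$seed; cfg2 <- cfg; cfg2$seed <- NULL
    if (!is.null(saved)) set.seed(saved)
    simulate_hr_trace(cfg2)
  }
  centers <- (seq_len(W) - 1L) * step + (M + 1) / 2
  inst_bpm <- approx(centers, trace, xout = seq_len(n), rule = 2)$y
  phase <- 2 * pi * cumsum(inst_bpm / 60) / fs
  ph_off <- runif(cfg$n_harmonics, 0, 2 * pi)
  pulse <- numeric(n)
  for (h in seq_len(cfg$n_harmonics))
    pulse <- pulse + cfg$harmonic_decay^(h - 1) * sin(h * phase + ph_off[h])

  # Cadence motion signal and its delayed copy (exact phase shift).
  t <- (seq_len(n) - 1) / fs
  cad_ph <- runif(2, 0, 2 * pi)
  motion_at <- function(tt)
    cos(2 * pi * cfg$cadence_hz * tt + cad_ph[1]) +
      cfg$accel_harmonic * cos(4 * pi * cfg$cadence_hz * tt + cad_ph[2])
  m <- motion_at(t)
  m_del <- motion_at(t - cfg$delay_s)

  # Tri-axial acceleration: gravity projection keeps the norm linearised
  # around the offset so the cadence fundamental survives consolidation.
  grav <- c(3.0, 8.5, 4.0)
  w1 <- c(0.8, 0.3, 0.5); w2 <- c(0.3, 0.15, 0.2)
  m2 <- cfg$accel_harmonic * cos(4 * pi * cfg$cadence_hz * t + cad_ph[2])
  ramp <- if (cfg$ma_rampup_s > 0) pmin(t / cfg$ma_rampup_s, 1) else 1
  accel <- sapply(1:3, function(ax)
    grav[ax] + ramp * (w1[ax] * m + w2[ax] * m2) +
      rnorm(n, sd = cfg$noise_sd))

  gain_mod <- 1 + cfg$ma_mod * sin(2 * pi * cfg$ma_mod_hz * t +
                                     runif(1, 0, 2 * pi))
  ma <- gain_mod * (cfg$ma_gain_linear * m_del +
                      cfg$ma_gain_quadratic * m_del^2)

  # Contact-pressure bursts: Hann-windowed tones at random in-band
  # frequencies, present in the optical channel only (no inertial
  # counterpart), so neither the canceller nor SSA can explain them.
  bursts <- numeric(n)
  if (cfg$burst_gain > 0 && cfg$burst_rate > 0) {
    n_bursts <- max(0L, stats::rpois(1, cfg$burst_rate * cfg$duration_s / 60))
    for (b in seq_len(n_bursts)) {
      dur <- runif(1, cfg$burst_dur_s[1], cfg$burst_dur_s[2])
      start <- runif(1, 0, max(cfg$duration_s - dur, 0))
      f_b <- runif(1, 0.9, 3.0)
      amp <- cfg$burst_gain * runif(1, 0.7, 1.3)
      idx <- which(t >= start & t < start + dur)
      if (!length(idx)) next
      env <- 0.5 * (1 - cos(2 * pi * seq_along(idx) / length(idx)))
      bursts[idx] <- bursts[idx] +
        amp * env * sin(2 * pi * f_b * t[idx] + runif(1, 0, 2 * pi))
    }
  }
  ppg <- sapply(1:2, function(ch)
    pulse + ramp * (ma + bursts) + rnorm(n, sd = cfg$noise_sd))

  truth <- vapply(seq_len(W) - 1L, function(i)
    mean(inst_bpm[(i * step + 1L):(i * step + M)]), numeric(1))

  pp_recording(ppg = ppg, accel = accel, fs = fs, truth_bpm = truth,
               id = cfg$id)
}

#' Simulate a labelled dataset over artifact-strength levels
#'
#' Factorial grid over motion-artifact levels (by default `clean`,
#' `moderate` and `strong` cadence coupling plus a `severe` level with
#' fully modulated coupling and stronger contact bursts, so the training
#' material contains windows where artifact removal genuinely fails and
#' the spectrum state must be held), with `n_per_cell` replicates per
#' level. Each
#' replicate draws its own starting heart rate and cadence so that the
#' two classifiers see varied, reproducible training material.
#'
#' @param base_cfg A [sim_config()] used as the template.
#' @param gain_levels Named list of numeric settings
#'   `c(linear, quadratic[, modulation[, burst]])` — the cadence coupling
#'   gains, the coupling modulation depth, and the contact-burst
#'   amplitude.
#' @param n_per_cell Replicates per gain level.
#' @param seed RNG seed for the whole grid.
#' @return List of [pp_recording()] objects with a `level` attribute each.
#' @export
simulate_dataset <- function(base_cfg = sim_config(),
                             gain_levels = list(clean = c(0, 0, 0, 0),
                                                moderate = c(0.8, 0.3, 0, 0),
                                                strong = c(3, 1.2, 0.5, 3),
                                                severe = c(4, 1.5, 1, 4)),
                             n_per_cell = 2L, seed = 1L) {
  set.seed(seed)
  out <- list()
  idx <- 0L
  for (lv in names(gain_levels)) {
    for (r in seq_len(n_per_cell)) {
      idx <- idx + 1L
      cfg <- base_cfg
      lvset <- gain_levels[[lv]]
      cfg$ma_gain_linear <- lvset[1]
      cfg$ma_gain_quadratic <- lvset[2]
      cfg$ma_mod <- if (length(lvset) > 2) lvset[3] else 0
      cfg$burst_gain <- if (length(lvset) > 3) lvset[4] else 0
      cfg$hr_start_bpm <- runif(1, cfg$hr_band[1] + 15, cfg$hr_band[2] - 15)
      cfg$cadence_hz <- runif(1, 1.5, 2.3)
      cfg$seed <- seed * 1000L + idx
      cfg$id <- sprintf("sim_%s_%02d", lv, r)
      rec <- simulate_recording(cfg)
      attr(rec, "level") <- lv
      out[[cfg$id]] <- rec
    }
  }
  out
}
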