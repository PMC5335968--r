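# ppgpulse

Heart-rate estimation from wrist photoplethysmography (PPG) recorded
during physical exercise, when motion artifacts (MA) can bury the pulse.
Wrist-worn optical sensors are attractive for fitness tracking because
they are cheap and unobtrusive, but arm movement couples into the optical
signal at amplitudes well above the pulse, and a running cadence
(~2 Hz ≈ 120 steps/min) sits squarely inside the physiological
heart-rate band. `ppgpulse` implements a two-stage estimator for this
setting, together with a synthetic-recording simulator, evaluation
metrics, recording I/O, and a command-line interface.

## Method

Each recording (2 PPG channels, 3 accelerometer axes, 125 Hz) is
band-pass filtered to 0.4–5 Hz and cut into 8-s windows advanced by 2 s.
Per window, with spectra computed as zero-padded periodograms on
N = 4096 bins:

**Stage 1 — hybrid MA removal.**

1. *Volterra adaptive noise cancellation.* The acceleration norm
   `a(k)` (delayed 0.08 s to align with the artifact it produces) is
   expanded into a second-order Volterra regressor
   `â(k) = [a(k), …, a(k−N), a²(k), a(k)a(k−1), …, a²(k−N)]ᵀ` and filter
   weights are adapted by exponentially weighted recursive least squares
   (forgetting factor λ), so the artifact estimate `n̂(k) = w(k)ᵀ â(k)`
   captures both linear and quadratic motion coupling:
   `ŝ(k) = x(k) − w(k)ᵀ â(k)`.
2. *Random-forest gate.* 24 features of `ŝ` (energy; significant-peak
   count above δ₁ = 30% of the spectral maximum; spectral mean and
   kurtosis; correlations of its spectrum with the raw-PPG and
   acceleration spectra; energy/mean/SD of the six sub-bands of a
   5-level db4 wavelet decomposition) feed a random forest that declares
   residual MA `Strong` or `NotStrong`.
3. *Singular spectrum analysis.* Only gated (`Strong`) windows are
   decomposed via the trajectory-matrix SVD; elementary components whose
   dominant frequency matches a dominant acceleration frequency
   (≥ δ₂ = 50% of the acceleration spectral maximum) are removed and the
   rest re-summed.

**Stage 2 — spectral peak tracking as classification.** Around the
previous heart-rate bin `Lprev`, a fundamental range
`[Lprev−Δs, Lprev+Δs]` and its first-harmonic image
`[2(Lprev−Δs−1)+1, 2(Lprev+Δs−1)+1]` are searched for dominant peaks.
Three candidate bins are built: the fundamental of a detected
harmonic peak-pair (else a σ₁ step toward the strongest in-range peak);
the in-range peak closest to `Lprev` (else a σ₂ step toward it); and
`Lprev` itself. A second random forest classifies the window's spectrum
state (harmonic pair present / peak found / peak not found) from 9
features, the candidate of the predicted class becomes `Loc`, and

    HR = (Loc − 1) / N · fs · 60   [BPM].

Both forests are trained on simulated recordings with ECG-style
per-window ground truth; window labels derive from the truth
(`NotStrong` iff the spectral argmax is within 3 BPM of truth; the
stage-2 class is the candidate closest to the true bin).

## Worked example

```r
library(ppgpulse)
cfg <- pp_config()

# training material: simulated grid over artifact severities
train  <- simulate_dataset(sim_config(duration_s = 120), n_per_cell = 2, seed = 42)
models <- pp_train(train, cfg, seed = 1)

# a hard test case: running cadence 2 Hz (120 steps/min) next to a
# ~110 BPM heart rate, with strong modulated coupling and contact bursts
rec <- simulate_recording(
  sim_config(duration_s = 120, hr_start_bpm = 110, cadence_hz = 2,
             ma_gain_linear = 3, ma_gain_quadratic = 1.2, ma_mod = 0.5,
             burst_gain = 3, seed = 99))
est <- pp_estimate(rec, models)
head(est[, c("window", "bpm", "truth_bpm", "gate", "class", "bpm_raw_argmax")])
#>   window      bpm truth_bpm      gate class bpm_raw_argmax
#> 1      0 109.8633  109.9670 NotStrong    NA       109.8633
#> 2      1 109.8633  109.8623 NotStrong     2       109.8633
#> 3      2 113.5254  109.9268 NotStrong     1       120.8496
#> 4      3 113.5254  110.1020    Strong     1       119.0186
#> 5      4 109.8633  110.4780 NotStrong     1       120.8496
#> 6      5 111.6943  111.0640 NotStrong     1       120.8496

trace    <- hr_trace(est$bpm, est$truth_bpm, id = rec$id)
baseline <- hr_trace(est$bpm_raw_argmax, est$truth_bpm)
c(aae = aae(trace), aae_no_tracking = aae(baseline))
#>             aae aae_no_tracking
#>        2.726742       10.781524
pearson_cor(trace)
#> [1] 0.6510519
```

From window 2 on, the raw spectral argmax locks onto the cadence
(120.8 BPM) while the tracker stays near the true rate: the tracked
average absolute error is 2.7 BPM against 10.8 BPM for the no-tracking
argmax baseline. `gate` shows which windows the stage-1 decision sent
through SSA, `class` the spectrum state chosen by stage 2.

The same pipeline is available from the shell via `exec/ppgpulse`
(`simulate`, `train`, `estimate`, `evaluate` subcommands).

## Scope

The estimator, simulator and metrics are self-contained: every number
above is computed on synthetic recordings with known ground truth.
Recordings in the wrist-PPG benchmark MAT layout (channel-matrix `sig`,
per-window `BPM0`) or the package's CSV dialect can be processed with
the same functions via `read_recording()`.
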