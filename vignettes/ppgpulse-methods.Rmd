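---
title: "Motion-robust heart-rate estimation from wrist PPG: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motion-robust heart-rate estimation from wrist PPG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
signal model, the two-stage estimator, every tunable constant with its
default and rationale, what the synthetic-recording generator does and
does not emulate, and the design decisions that were genuinely open.

## Signal model and assumptions

A wrist recording carries two PPG channels and three accelerometer axes
sampled at a common rate (`fs = 125` Hz by default). The measured PPG in
a window is modelled additively, `x(k) = s(k) + n(k)`: a quasi-periodic
pulse `s` whose spectral fundamental is the heart rate, plus motion
artifacts `n` that share their mechanical source with the accelerometer.
Three assumptions do the work:

1. *Artifacts are (approximately) a short-memory polynomial transform of
   acceleration.* The canceller models `n(k)` as a second-order Volterra
   expansion of the delayed acceleration norm — all linear lags plus all
   pairwise lag products. Purely linear coupling is a special case;
   amplitude rectification and harmonic distortion land in the quadratic
   terms.
2. *The pulse is spectrally compact and harmonically structured.* In a
   clean window the spectrum shows a dominant fundamental and a first
   harmonic at `2(b - 1) + 1` in 1-based bin coordinates — the evidence
   the tracker's "harmonic pair" state exploits.
3. *Heart rate moves slowly relative to the window step.* With 8-s
   windows advanced by 2 s, the true bin rarely moves more than ±2 bins
   (±3.7 BPM) between windows, which justifies searching only a small
   neighbourhood of the previous estimate.

## Pipeline constants

| constant | default | units | role |
|---|---|---|---|
| `T_s`, `M0_s` | 8, 2 | s | window length and step |
| `fs` | 125 | Hz | sampling rate |
| `N` | 4096 | bins | zero-padded periodogram size; resolution `fs·60/N ≈ 1.83` BPM |
| `band` | 0.4–5 | Hz | analysis passband (24–300 BPM plus harmonics) |
| `delta1` | 0.30 | — | significant-peak threshold (stage-1 feature) |
| `delta2` | 0.50 | — | dominant-peak threshold (SSA matching, stage-2 ranges) |
| `delta_s`, `sigma1`, `sigma2` | 2 | bins | search half-width and fallback step sizes |
| `delay_s` | 0.08 | s | acceleration-to-artifact transport delay |
| `memory` | 10 | samples | Volterra memory; regressor dimension D = 77 |
| `lambda` | 0.999 | — | RLS forgetting factor |
| `init_diag` | 100 | — | initial inverse-correlation scale (ridge-like start) |
| `ssa_L` | 500 | samples | SSA embedding length (M/2) |
| `ssa_k` | 20 | — | elementary components examined |
| `match_tol` | 2 | bins | component-to-acceleration frequency match tolerance |
| `tol_bpm` | 3 | BPM | "very close" threshold for Strong/NotStrong labels |
| `pair_tol` | 1 | bin | harmonic-pair acceptance distance |
| `hr_band` | 50–180 | BPM | tracker initialisation band |
| `ntree` | 100 | — | trees per random forest |

Notes on the less obvious defaults:

* **`memory = 10`.** The window length (1000 samples) cannot be the
  filter memory: the quadratic expansion would have ~500k terms. Ten
  samples (80 ms) cover the configured transport delay and typical
  coupling dynamics while keeping D = 77 regressors, a standard
  operating point for Volterra cancellers.
* **`lambda = 0.999`** gives an effective averaging memory of about
  1000 samples — the whole window — which is the right choice when the
  coupling is quasi-stationary within a window; the gate plus SSA handle
  windows where it is not. `init_diag` only matters for the first few
  dozen samples; tests that compare against the exact least-squares
  solution raise it to 10⁸ to make the start-up bias negligible.
* **`ssa_L = M/2`** follows standard SSA guidance (maximally mixing
  embedding); `ssa_k = 20` suffices because a pulse plus a handful of
  artifact tones occupy well under 20 elementary components, and
  everything beyond `k` is lumped into a remainder that is never
  removed, so the decomposition always reconstructs the input exactly.
* **`tol_bpm = 3`** is about 1.6 bins at the default resolution: one
  bin of quantisation plus one of leakage.

## Numerical choices

* *Filtering.* Zero-phase 4th-order Butterworth applied
  forward-backward. Zero phase matters because stage-2 features
  correlate the PPG window with the acceleration window in time.
* *Consolidation order.* The acceleration norm is taken on the raw axes
  and band-passed afterwards. Filtering first would remove the gravity
  offset, and the norm of zero-mean oscillating axes rectifies the
  cadence into its second harmonic; with the offset in place the norm is
  locally linear in the motion and keeps the fundamental. The two PPG
  channels are filtered and then averaged (configurable to either single
  channel); averaging is symmetric and halves uncorrelated noise.
* *Periodogram scaling.* Amplitudes are `|FFT|/sqrt(N)` so summed
  squared amplitude equals signal energy (Parseval), making energy
  fractions across bins well defined.
* *Peak definition.* Strict local maximum (`amp[i-1] < amp[i] >=
  amp[i+1]`), ties broken toward the lower bin.
* *Peak dominance reference.* Inside the stage-2 search ranges,
  dominance is measured against the maximum of the whole
  positive-frequency spectrum, not the in-range maximum. A range that
  contains only noise would otherwise always yield "dominant" peaks —
  and those spurious peaks form spurious harmonic pairs that drag the
  tracker. (For `find_peaks_above()` called with an explicit range and
  no reference, the in-range maximum remains the default, which is what
  the stage-1 significant-peak count uses on the full band.)
* *RLS output.* The residual uses a-posteriori coefficients (updated
  through the current sample), so the final weight vector equals the
  closed-form exponentially weighted least-squares solution up to the
  `init_diag` regularisation; the equivalence is asserted to 1e-6 in the
  tests.
* *Degenerate inputs.* Correlation features on zero-variance inputs are
  defined as 0; skewness/kurtosis of constant windows are 0; a flat
  first-window spectrum initialises the tracker at the band edge with a
  warning; if SSA removal would annihilate the signal (retained energy
  below 1e-6 of the input) the input is returned unchanged with a
  warning.
* *Tracker state.* The tracked bin is clamped to
  `[delta_s + 1, N/2]` so the search ranges always exist. Class-3
  decisions repeat the previous bin exactly.

## Training the two classifiers

Labels come from per-window ground truth. Stage 1: `NotStrong` iff the
argmax-implied rate of the denoised window is within `tol_bpm` of truth.
Stage 2: windows are processed with the *true* gate labels (so stage 2
sees what a perfect gate would produce) and with the previous window's
*true* bin as `Lprev` (teacher forcing); the class label is the
candidate closest to the true bin, ties toward the lower class.

`pp_training_tables()` exposes an optional jitter of the teacher-forced
`Lprev`. It is off by default: experiments during development showed
that jitter biases labels toward class 1 (the jittered state makes the
true peak the "harmonic pair" answer more often) and that covering
displaced tracker states is better achieved by including severe-artifact
recordings in the training grid, where such states arise naturally with
honest features.

Both forests use 100 trees and default splitting; reported performance
is stratified 10-fold cross-validation (accuracy, plus
sensitivity/specificity for the binary gate, treating `Strong` as the
positive class).

## What the simulator emulates — and what it does not

`simulate_recording()` generates: a pulse with `n_harmonics = 3`
harmonics decaying by `harmonic_decay = 0.5`, phase-continuously
following a bounded random-walk BPM trajectory (`hr_drift = 1` BPM per
2-s step, reflected inside `hr_band = 60–160`); tri-axial acceleration
as gravity projections plus a cadence fundamental and first harmonic
with sensor noise; and PPG channels corrupted by

* a delayed linear + quadratic transform of the cadence motion signal
  (`ma_gain_linear`, `ma_gain_quadratic`, delay 0.08 s) — deliberately
  the same functional family the Volterra canceller models, so
  cancellation is well posed;
* a slow sinusoidal amplitude modulation of those coupling gains
  (`ma_mod`, `ma_mod_hz = 0.06` Hz). Real grip and posture drift make
  coupling non-stationary; a whole-window RLS cannot track it, which is
  precisely what produces windows with genuinely `Strong` residual
  artifacts. The modulation is slow compared with the 8-s window so its
  spectral sidebands stay within `match_tol` of the cadence bins and
  SSA can still identify the residual as motion-locked;
* optional contact-pressure bursts (`burst_gain`, ~6 per minute, 2–6 s):
  Hann-windowed tones at random in-band frequencies present only in the
  optical channel. These emulate artifact sources an accelerometer
  cannot see; neither ANC nor SSA can remove them, and the tracker must
  ride them out by holding its state — the situation the third spectrum
  class exists for;
* a 15-s lead-in during which all artifacts ramp up from zero,
  mirroring exercise protocols that start with slow walking; the
  tracker initialises during this low-motion phase. Initialisation
  takes the in-band spectral argmax, excluding bins near dominant
  acceleration frequencies so a cadence peak cannot capture the tracker
  at start-up.

The default artifact grid (`clean`, `moderate`, `strong`, `severe`)
spans no coupling to fully modulated coupling with dense bursts; each
replicate draws its own starting heart rate and cadence.

Not emulated: realistic PPG pulse morphology (dicrotic notch,
respiratory amplitude modulation), sensor saturation and quantisation,
cadence drift within a recording, heart-rate jumps (intervals,
arrhythmia), and cross-subject variability of coupling. Passing tests on
this generator therefore demonstrate that the pipeline's mechanisms work
under the stated model — artifact families it was designed for, at
realistic frequencies and amplitudes — not that field accuracy on any
particular device would match.

## Problem sizes used by the test suite

The suite and the acceptance script size their simulations to run in a
few minutes on one core while keeping every window count in the
hundreds: training grids of 8 recordings × 2 min, clean-regime
evaluation on 10 recordings × 3 min (870 windows), strong-regime
evaluation on 4 recordings × 2 min (228 windows), 50 SSA
reconstructions at full window scale (M = 1000, L = 500), and 20
small-instance RLS oracle comparisons.

## Known limitations

* Ungrouped SSA: elementary components are removed singly; when pulse
  and artifact amplitudes are nearly equal their singular subspaces can
  mix, leaving partial residuals (the removal tests use artifacts ≥1.2×
  the pulse, where separation is clean).
* The tracker cannot recover from displacements larger than the search
  ranges except by chance encounters with in-range peaks; the gate and
  SSA exist to keep such displacements rare, and the severe-level
  training material teaches the classifier to hold rather than chase.
* The stage-2 feature set cannot distinguish *which* peak a harmonic
  pair points at; a periodic artifact with a genuine harmonic (a steady
  cadence) inside the search range looks like a pulse. Keeping the
  cadence out of the ranges is again the job of stage 1.
* Per-window class labels are intrinsically noisy near ties (two
  candidates equidistant from truth), which caps the stage-2
  cross-validated accuracy on realistic material well below 1.
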