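# Keep a tracked bin where the search ranges stay valid.
clamp_loc <- function(loc, cfg) {
  lo <- cfg$delta_s + 1L
  hi <- as.integer(cfg$N %/% 2L)
  max(lo, min(hi, as.integer(loc)))
}

# Argmax-in-band heart rate of a spectrum, used as the no-tracking
# baseline and by the tracker initialiser.
argmax_bpm <- function(spec, cfg) {
  lo <- bpm_to_loc(cfg$hr_band[1], cfg$fs, cfg$N)
  hi <- bpm_to_loc(cfg$hr_band[2], cfg$fs, cfg$N)
  loc <- lo + which.max(spec$amp[lo:hi]) - 1L
  loc_to_bpm(loc, cfg$fs, cfg$N)
}

# Shared per-window stage-1 processing: ANC, gate, optional SSA.
stage1_window <- function(w, cfg, model = NULL, truth = NULL) {
  x <- w$ppg
  a <- w$accel_norm
  a_sh <- shift_reference(a, cfg$delay_s, cfg$fs)
  s_hat <- rls_denoise(x, a_sh, cfg)$s_hat
  a_spec <- periodogram_spectrum(a, cfg$fs, cfg$N)
  f1 <- extract_stage1_features(s_hat, x, a, cfg)
  gate <- if (!is.null(truth)) label_stage1(s_hat, truth, cfg)
          else decide_ma(model, f1)
  s_recon <- if (gate == "Strong")
    suppressWarnings(ssa_remove_ma(s_hat, a_spec, cfg)$s_recon)
  else s_hat
  list(x = x, a = a, s_hat = s_hat, s_recon = s_recon,
       a_spec = a_spec, f1 = f1, gate = gate)
}

# Shared stage-2 geometry for one window given the previous bin.
stage2_window <- function(st1, Lprev, cfg) {
  spec <- periodogram_spectrum(st1$s_recon, cfg$fs, cfg$N)
  ranges <- compute_ranges(Lprev, cfg, cfg$N)
  peaks <- range_peaks(spec, ranges, cfg)
  pair <- detect_harmonic_pair(peaks, cfg)
  cands <- build_candidates(Lprev, peaks, pair, cfg)
  f2 <- extract_stage2_features(st1$s_recon, st1$a, spec, st1$a_spec,
                                peaks, pair)
  list(spec = spec, cands = cands, f2 = f2)
}

#' Build classifier training tables from labelled recordings
#'
#' Runs stage 1 over every window of every recording, deriving
#' Strong/NotStrong labels from the ground truth, and runs the stage-2
#' geometry with the previous window's true bin as `Lprev` (teacher
#' forcing) to derive the three-class labels. The stage-1 gate uses the
#' true labels during training so that stage 2 sees windows processed the
#' way a perfect gate would process them.
#'
#' At estimation time `Lprev` is the tracker's own previous output, which
#' is rarely exactly on the true bin, so the teacher-forced `Lprev` is
#' jittered: with probability one half the offset is zero, otherwise it
#' is a uniform non-zero integer up to `lprev_jitter` bins. The
#' classifier then learns which candidate steers back toward the true bin
#' from displaced states instead of only ever seeing perfectly centred
#' ranges.
#'
#' @param recordings List of [pp_recording()] objects with `truth_bpm`.
#' @param cfg A [pp_config()].
#' @param lprev_jitter Maximum magnitude (bins) of the training-time
#'   jitter on the teacher-forced previous bin; 0 disables it.
#' @param seed RNG seed for the jitter.
#' @return List with data frames `features1`, `features2` and label
#'   vectors `labels1` (character), `labels2` (integer).
#' @export
pp_training_tables <- function(recordings, cfg = pp_config(),
                               lprev_jitter = 2L, seed = 1L) {
  set.seed(seed)
  if (inherits(recordings, "pp_recording")) recordings <- list(recordings)
  F1 <- list(); L1 <- character(0)
  F2 <- list(); L2 <- integer(0)
  for (rec in recordings) {
    if (is.null(rec$truth_bpm))
      stop("training requires recordings with truth_bpm")
    windows <- slide_windows(rec, cfg)
    truth <- rec$truth_bpm
    for (i in seq_along(windows)) {
      st1 <- stage1_window(windows[[i]], cfg, truth = truth[i])
      F1[[length(F1) + 1L]] <- st1$f1
      L1 <- c(L1, st1$gate)
      if (i == 1L) next
      jit <- 0L
      if (lprev_jitter > 0 && runif(1) < 0.5)
        jit <- sample(c(-(1:lprev_jitter), 1:lprev_jitter), 1L)
      Lprev <- clamp_loc(bpm_to_loc(truth[i - 1L], cfg$fs, cfg$N) + jit,
                         cfg)
      st2 <- stage2_window(st1, Lprev, cfg)
      F2[[length(F2) + 1L]] <- st2$f2
      L2 <- c(L2, label_stage2(st2$cands,
                               bpm_to_loc(truth[i], cfg$fs, cfg$N)))
    }
  }
  list(features1 = as.data.frame(do.call(rbind, F1)), labels1 = L1,
       features2 = as.data.frame(do.call(rbind, F2)), labels2 = L2)
}

#' Train both pipeline classifiers
#'
#' Builds the training tables with [pp_training_tables()] and fits the
#' stage-1 gate and the stage-2 spectrum-state classifier, each with
#' stratified 10-fold cross-validation reports.
#'
#' @inheritParams pp_training_tables
#' @param seed RNG seed for cross-validation folds and forest growth.
#' @return A `pp_models` object: list with `stage1`, `stage2` (each
#'   `model` + `cv`) and the `cfg` used.
#' @export
pp_train <- function(recordings, cfg = pp_config(), seed = 1L) {
  tabs <- pp_training_tables(recordings, cfg, seed = seed)
  s1 <- train_stage1(tabs$features1, tabs$labels1, cfg, seed = seed)
  s2 <- train_stage2(tabs$features2, tabs$labels2, cfg, seed = seed)
  structure(list(stage1 = s1, stage2 = s2, cfg = cfg), class = "pp_models")
}

#' @export
print.pp_models <- function(x, ...) {
  cat("<pp_models>\n")
  cat(sprintf("  stage 1 gate: CV accuracy %.3f (sens %.3f, spec %.3f)\n",
              x$stage1$cv$accuracy, x$stage1$cv$sensitivity,
              x$stage1$cv$specificity))
  cat(sprintf("  stage 2 tracker: CV accuracy %.3f\n",
              x$stage2$cv$accuracy))
  invisible(x)
}

#' Estimate the heart-rate trace of a recording
#'
#' Runs the full two-stage pipeline window by window: band-pass and
#' consolidation, Volterra-RLS noise cancellation, the Strong/NotStrong
#' gate (applying SSA to gated windows), candidate-peak construction
#' around the previous heart-rate bin, stage-2 classification, and
#' bin-to-BPM conversion. The first window is initialised from the
#' in-band spectral argmax unless `init_bpm` is given.
#'
#' @param rec A [pp_recording()].
#' @param models A `pp_models` object from [pp_train()].
#' @param cfg A [pp_config()]; defaults to the configuration the models
#'   were trained with.
#' @param init_bpm Optional known starting heart rate in BPM.
#' @return Data frame with one row per window: `window` (0-based), `loc`,
#'   `bpm`, `class`, `gate`, `bpm_raw_argmax` (no-tracking baseline on the
#'   raw window spectrum) and `truth_bpm` (NA when absent).
#' @export
pp_estimate <- function(rec, models, cfg = NULL, init_bpm = NULL) {
  stopifnot(inherits(models, "pp_models"))
  if (is.null(cfg)) cfg <- models$cfg
  windows <- slide_windows(rec, cfg)
  truth <- rec$truth_bpm
  n <- length(windows)
  out <- data.frame(window = seq_len(n) - 1L, loc = NA_integer_,
                    bpm = NA_real_, class = NA_integer_,
                    gate = NA_character_, bpm_raw_argmax = NA_real_,
                    truth_bpm = if (is.null(truth)) NA_real_ else truth)
  Lprev <- NA_integer_
  for (i in seq_len(n)) {
    st1 <- stage1_window(windows[[i]], cfg, model = models$stage1)
    out$gate[i] <- st1$gate
    out$bpm_raw_argmax[i] <-
      argmax_bpm(periodogram_spectrum(st1$x, cfg$fs, cfg$N), cfg)
    if (i == 1L) {
      spec <- periodogram_spectrum(st1$s_recon, cfg$fs, cfg$N)
      lacc <- accel_dominant_bins(st1$a_spec, cfg$delta2)
      Lprev <- clamp_loc(initialize_tracker(spec, cfg, init_bpm,
                                            exclude = lacc), cfg)
      out$loc[i] <- Lprev
    } else {
      st2 <- stage2_window(st1, Lprev, cfg)
      sel <- select_loc(models$stage2, st2$f2, st2$cands)
      out$class[i] <- sel$class
      Lprev <- clamp_loc(sel$loc, cfg)
      out$loc[i] <- Lprev
    }
    out$bpm[i] <- loc_to_bpm(out$loc[i], cfg$fs, cfg$N)
  }
  out
}
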