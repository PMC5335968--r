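# Harmonic bin map and its inverse (1-based bins; bin 1 = DC, so the
# first harmonic of bin b sits at 2*(b-1)+1).
harmonic_bin <- function(b) 2L * (as.integer(b) - 1L) + 1L
inv_harmonic_bin <- function(b) as.integer(round((b - 1) / 2)) + 1L

#' Convert a spectral bin to BPM and back
#'
#' `loc_to_bpm()` maps the 1-based frequency bin `Loc` to heart rate:
#' `HR = (Loc - 1) / N * fs * 60`. `bpm_to_loc()` is its inverse, rounded
#' to the nearest integer bin.
#'
#' @param loc 1-based bin index in `[1, N]` (vectorised).
#' @param bpm Heart rate in BPM, `>= 0` (vectorised).
#' @param fs Sampling rate in Hz.
#' @param N Number of frequency bins.
#' @return Heart rate in BPM, or an integer bin index.
#' @export
loc_to_bpm <- function(loc, fs, N) {
  if (any(loc < 1 | loc > N)) stop("parameter error: loc outside [1, N]")
  (loc - 1) / N * fs * 60
}

#' @rdname loc_to_bpm
#' @export
bpm_to_loc <- function(bpm, fs, N) {
  if (any(bpm < 0)) stop("parameter error: bpm must be non-negative")
  loc <- as.integer(round(bpm / 60 * N / fs)) + 1L
  if (any(loc > N)) stop("parameter error: bpm beyond spectrum range")
  loc
}

#' Search ranges around the previous heart-rate bin
#'
#' The fundamental range `LRange1 = [Lprev - ds, Lprev + ds]` and its
#' first-harmonic image `LRange2 = [2(Lprev - ds - 1) + 1,
#' 2(Lprev + ds - 1) + 1]`, both clipped to the spectrum.
#'
#' @param Lprev Previous window's heart-rate bin (1-based).
#' @param cfg A [pp_config()] (supplies `delta_s`).
#' @param N Number of frequency bins.
#' @return List with integer intervals `r1` and `r2` (`c(lo, hi)`).
#' @export
compute_ranges <- function(Lprev, cfg = pp_config(), N = cfg$N) {
  if (Lprev < 1 || Lprev > N) stop("state error: Lprev outside [1, N]")
  ds <- cfg$delta_s
  r1 <- c(max(1L, Lprev - ds), min(N, Lprev + ds))
  r2 <- c(harmonic_bin(Lprev - ds), harmonic_bin(Lprev + ds))
  r2 <- pmin(pmax(r2, 1L), N)
  list(r1 = as.integer(r1), r2 = as.integer(r2))
}

#' Dominant peaks inside the tracking ranges
#'
#' Up to two dominant peaks in each of the fundamental and harmonic
#' search ranges, sorted by descending amplitude. Dominance is measured
#' against the maximum amplitude of the positive-frequency spectrum (the
#' same `delta2` reference the SSA step uses), so a search range that
#' contains only noise yields no peaks rather than noise maxima. The
#' total dominant-peak counts per range are kept for the stage-2
#' features.
#'
#' @param spec `pp_spectrum` of the cleansed window.
#' @param ranges Output of [compute_ranges()].
#' @param cfg A [pp_config()] (supplies `delta2`).
#' @return List with `Li0`, `Li1` (bins, length 0-2), `amp0`, `amp1`, and
#'   counts `n1`, `n2`.
#' @export
range_peaks <- function(spec, ranges, cfg = pp_config()) {
  ref <- max(spec$amp[half_bins(spec$N)])
  p1 <- find_peaks_above(spec, cfg$delta2, range = ranges$r1,
                         ref_max = ref)
  p2 <- find_peaks_above(spec, cfg$delta2, range = ranges$r2,
                         ref_max = ref)
  list(Li0 = head(p1$locations, 2L), amp0 = head(p1$amplitudes, 2L),
       Li1 = head(p2$locations, 2L), amp1 = head(p2$amplitudes, 2L),
       n1 = length(p1$locations), n2 = length(p2$locations))
}

#' Detect a fundamental/first-harmonic peak pair
#'
#' Searches the cross product of fundamental-range and harmonic-range
#' peaks for the pair whose harmonic image `2(Li0 - 1) + 1` is closest to
#' `Lj1`, and accepts it when that distance is at most `pair_tol` bins.
#'
#' @param peaks Output of [range_peaks()].
#' @param cfg A [pp_config()] (supplies `pair_tol`).
#' @return `c(Li0, Lj1)` or `NULL` when no pair qualifies.
#' @export
detect_harmonic_pair <- function(peaks, cfg = pp_config()) {
  if (length(peaks$Li0) == 0L || length(peaks$Li1) == 0L) return(NULL)
  best <- NULL; best_d <- Inf
  for (f in peaks$Li0) {
    for (h in peaks$Li1) {
      d <- abs(h - harmonic_bin(f))
      if (d < best_d) { best_d <- d; best <- c(f, h) }
    }
  }
  if (best_d <= cfg$pair_tol) best else NULL
}

#' Build the three candidate heart-rate bins
#'
#' Candidate 1 is the fundamental of the harmonic pair when one exists,
#' otherwise `Lprev` stepped by `sigma1` toward the strongest
#' fundamental-range peak (unchanged when there is none). Candidate 2 is
#' the member of the peak set (harmonic peaks mapped back to the
#' fundamental) closest to `Lprev`, kept when within `sigma2` bins and
#' otherwise replaced by a `sigma2` step toward it. Candidate 3 is always
#' `Lprev`.
#'
#' @param Lprev Previous heart-rate bin.
#' @param peaks Output of [range_peaks()].
#' @param pair Output of [detect_harmonic_pair()] (or `NULL`).
#' @param cfg A [pp_config()].
#' @return List with integer candidates `L1`, `L2`, `L3` and `pair`.
#' @export
build_candidates <- function(Lprev, peaks, pair, cfg = pp_config()) {
  Lprev <- as.integer(Lprev)
  step_toward <- function(target, sigma) {
    if (target > Lprev) Lprev + sigma
    else if (target < Lprev) Lprev - sigma
    else Lprev
  }
  L1 <- if (!is.null(pair)) as.integer(pair[1])
        else if (length(peaks$Li0)) step_toward(peaks$Li0[1], cfg$sigma1)
        else Lprev
  cand_set <- c(peaks$Li0, inv_harmonic_bin(peaks$Li1))
  if (length(cand_set)) {
    d <- abs(cand_set - Lprev)
    closest <- cand_set[order(d, cand_set)][1]
    L2 <- if (abs(closest - Lprev) <= cfg$sigma2) as.integer(closest)
          else step_toward(closest, cfg$sigma2)
  } else {
    L2 <- Lprev
  }
  list(L1 = as.integer(L1), L2 = as.integer(L2), L3 = Lprev, pair = pair)
}

#' Stage-2 tracking features
#'
#' Nine features describing the spectrum state of one cleansed window: the
#' dominant-peak counts in the fundamental and harmonic ranges, the energy
#' of the acceleration window, the time-domain correlation between the
#' cleansed window and the acceleration, the correlation between their
#' amplitude spectra, the mean, skewness and kurtosis of the cleansed
#' window, and a 0/1 flag for the presence of a harmonic peak pair.
#'
#' @param s_recon Cleansed PPG window.
#' @param accel_norm Consolidated acceleration window.
#' @param spec `pp_spectrum` of `s_recon`.
#' @param a_spec `pp_spectrum` of `accel_norm`.
#' @param peaks Output of [range_peaks()].
#' @param pair Output of [detect_harmonic_pair()].
#' @return Named numeric vector of length 9.
#' @export
extract_stage2_features <- function(s_recon, accel_norm, spec, a_spec,
                                    peaks, pair) {
  hb <- half_bins(spec$N)
  c(n_peaks_r1 = peaks$n1,
    n_peaks_r2 = peaks$n2,
    accel_energy = sum(accel_norm^2),
    cc_time = safe_cor(s_recon, accel_norm),
    cc_spec = safe_cor(spec$amp[hb], a_spec$amp[hb]),
    mean = mean(s_recon),
    skewness = moment_skewness(s_recon),
    kurtosis = moment_kurtosis(s_recon),
    pair_flag = as.numeric(!is.null(pair)))
}

#' Stage-2 training label from ground truth
#'
#' The class of a training window is the index of the candidate bin
#' closest to the ground-truth bin `Lreal`, ties broken toward the lower
#' class.
#'
#' @param candidates Output of [build_candidates()].
#' @param Lreal Ground-truth heart-rate bin ([bpm_to_loc()] of the ECG
#'   value).
#' @return Integer class in `{1, 2, 3}`.
#' @export
label_stage2 <- function(candidates, Lreal) {
  d <- abs(c(candidates$L1, candidates$L2, candidates$L3) - Lreal)
  which.min(d)
}

#' Train the stage-2 spectrum-state classifier
#'
#' Fits a three-class random forest on stage-2 features and reports
#' stratified 10-fold cross-validation accuracy and per-class recall.
#'
#' @param features Data frame or matrix of stage-2 features.
#' @param labels Integer classes in `{1, 2, 3}`.
#' @param cfg A [pp_config()].
#' @param seed RNG seed.
#' @return List with `model` and `cv` (accuracy, per-class recall,
#'   confusion matrix).
#' @export
train_stage2 <- function(features, labels, cfg = pp_config(), seed = 1L) {
  features <- as.data.frame(features)
  labels <- factor(labels, levels = c("1", "2", "3"))
  cv <- rf_crossval(features, droplevels(labels), cfg$ntree, seed = seed)
  set.seed(seed)
  model <- randomForest::randomForest(x = features, y = droplevels(labels),
                                      ntree = cfg$ntree)
  list(model = model,
       cv = list(accuracy = cv$accuracy, recall = cv$recall,
                 confusion = cv$confusion))
}

#' Select the heart-rate bin for one window
#'
#' Classifies the window's stage-2 features and returns the candidate bin
#' of the predicted class; a prediction of class 3 therefore repeats the
#' previous window's bin.
#'
#' @param model Fitted stage-2 forest from [train_stage2()].
#' @param features Stage-2 feature vector.
#' @param candidates Output of [build_candidates()].
#' @return List with `loc` (selected bin) and `class` (1, 2 or 3).
#' @export
select_loc <- function(model, features, candidates) {
  if (inherits(model, "list") && !is.null(model$model)) model <- model$model
  if (!inherits(model, "randomForest"))
    stop("state error: model is not a trained random forest")
  cl <- as.integer(as.character(predict(model, as.data.frame(t(features)))))
  loc <- switch(cl, candidates$L1, candidates$L2, candidates$L3)
  list(loc = as.integer(loc), class = cl)
}

#' Initialise the tracker from the first window
#'
#' `Lprev` for the first window is either supplied directly as a BPM value
#' or taken as the maximum-amplitude bin of the first window's spectrum
#' inside the heart-rate band. Bins listed in `exclude` (with a
#' `match_tol` neighbourhood) are skipped in the argmax — the pipeline
#' passes the dominant acceleration bins here so that a cadence peak
#' inside the heart-rate band cannot capture the tracker at start-up —
#' unless excluding them would empty the band.
#'
#' @param spec `pp_spectrum` of the first cleansed window.
#' @param cfg A [pp_config()] (supplies `hr_band`, `fs`, `N`,
#'   `match_tol`).
#' @param init_bpm Optional user-supplied initial heart rate in BPM.
#' @param exclude Optional integer bins to avoid (e.g. cadence bins).
#' @return Integer starting bin `Lprev`.
#' @export
initialize_tracker <- function(spec, cfg = pp_config(), init_bpm = NULL,
                               exclude = NULL) {
  if (!is.null(init_bpm)) return(bpm_to_loc(init_bpm, cfg$fs, cfg$N))
  lo <- bpm_to_loc(cfg$hr_band[1], cfg$fs, cfg$N)
  hi <- bpm_to_loc(cfg$hr_band[2], cfg$fs, cfg$N)
  if (lo > hi) stop("parameter error: empty heart-rate band")
  bins <- lo:hi
  if (!is.null(exclude) && length(exclude)) {
    near_acc <- vapply(bins, function(b)
      any(abs(b - exclude) <= cfg$match_tol), logical(1))
    if (!all(near_acc)) bins <- bins[!near_acc]
  }
  seg <- spec$amp[bins]
  if (max(seg) <= 0) {
    warning("flat spectrum in heart-rate band; starting at the band edge")
    return(lo)
  }
  as.integer(bins[which.max(seg)])
}
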