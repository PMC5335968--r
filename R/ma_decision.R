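# Central moments with degenerate inputs mapped to 0.
moment_skewness <- function(x) {
  m2 <- mean((x - mean(x))^2)
  if (m2 <= 0) return(0)
  mean((x - mean(x))^3) / m2^1.5
}
moment_kurtosis <- function(x) {
  m2 <- mean((x - mean(x))^2)
  if (m2 <= 0) return(0)
  mean((x - mean(x))^4) / m2^2
}
safe_cor <- function(x, y) {
  if (sd(x) == 0 || sd(y) == 0) return(0)
  cor(x, y)
}

# Positive-frequency bins, DC excluded.
half_bins <- function(N) 2:(N %/% 2L + 1L)

#' Stage-1 artifact-strength features
#'
#' The 24 features used by the Strong/NotStrong gate, computed from one
#' ANC-denoised window: signal energy in time; the number of significant
#' spectral peaks (above `delta1` of the maximum), the mean and kurtosis of
#' the amplitude spectrum; the correlation of the denoised spectrum with
#' the raw-PPG spectrum and with the acceleration spectrum; and, from a
#' five-level db4 wavelet decomposition, the energy, mean and standard
#' deviation of each of the six sub-bands.
#'
#' @param s_hat Denoised PPG window.
#' @param raw_ppg Raw (band-passed, consolidated) PPG window.
#' @param accel_norm Consolidated acceleration window.
#' @param cfg A [pp_config()] supplying `fs`, `N`, `delta1`.
#' @return Named numeric vector of length 24.
#' @export
extract_stage1_features <- function(s_hat, raw_ppg, accel_norm,
                                    cfg = pp_config()) {
  stopifnot(length(s_hat) == length(raw_ppg),
            length(s_hat) == length(accel_norm))
  N <- cfg$N
  spec <- periodogram_spectrum(s_hat, cfg$fs, N)
  raw_spec <- periodogram_spectrum(raw_ppg, cfg$fs, N)
  acc_spec <- periodogram_spectrum(accel_norm, cfg$fs, N)
  hb <- half_bins(N)
  amp <- spec$amp[hb]
  feats <- c(
    energy_time = sum(s_hat^2),
    n_sig_peaks = length(find_peaks_above(spec, cfg$delta1,
                                          range = range(hb))$locations),
    spec_mean = mean(amp),
    spec_kurtosis = moment_kurtosis(amp),
    cc_spec_raw = safe_cor(amp, raw_spec$amp[hb]),
    cc_spec_accel = safe_cor(amp, acc_spec$amp[hb]))
  bands <- dwt_db4(s_hat, 5L)
  en <- vapply(bands, function(b) sum(b^2), numeric(1))
  mu <- vapply(bands, mean, numeric(1))
  sdv <- vapply(bands, function(b) if (length(b) > 1) sd(b) else 0,
                numeric(1))
  names(en) <- paste0("wv_energy_", names(bands))
  names(mu) <- paste0("wv_mean_", names(bands))
  names(sdv) <- paste0("wv_sd_", names(bands))
  c(feats, en, mu, sdv)
}

#' Derive the Strong/NotStrong training label
#'
#' A window is labelled `NotStrong` when the heart rate implied by the
#' maximum-amplitude spectral peak of the denoised window lies within
#' `tol_bpm` of the ECG-derived ground truth, and `Strong` otherwise.
#'
#' @param s_hat Denoised PPG window.
#' @param truth_bpm Ground-truth heart rate for this window (BPM).
#' @param cfg A [pp_config()].
#' @return `"Strong"` or `"NotStrong"`.
#' @export
label_stage1 <- function(s_hat, truth_bpm, cfg = pp_config()) {
  spec <- periodogram_spectrum(s_hat, cfg$fs, cfg$N)
  hb <- half_bins(cfg$N)
  loc <- hb[which.max(spec$amp[hb])]
  est <- loc_to_bpm(loc, cfg$fs, cfg$N)
  if (abs(est - truth_bpm) <= cfg$tol_bpm) "NotStrong" else "Strong"
}

# Stratified k-fold cross-validation of a random forest; returns per-fold
# out-of-sample predictions pooled into one confusion matrix.
rf_crossval <- function(features, labels, ntree, folds = 10L, seed = 1L) {
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("training error: single-class training set")
  if (min(table(labels)) < 2)
    stop("training error: need at least 2 examples per class")
  set.seed(seed)
  fold_id <- integer(length(labels))
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  pred <- factor(rep(levels(labels)[1], length(labels)),
                 levels = levels(labels))
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    if (all(tr) || !any(tr)) next
    if (length(unique(labels[tr])) < 2) next
    fit <- randomForest::randomForest(x = features[tr, , drop = FALSE],
                                      y = droplevels(labels[tr]),
                                      ntree = ntree)
    p <- predict(fit, features[!tr, , drop = FALSE])
    pred[!tr] <- factor(as.character(p), levels = levels(labels))
  }
  confusion <- table(truth = labels, predicted = pred)
  acc <- sum(diag(confusion)) / sum(confusion)
  recall <- diag(confusion) / rowSums(confusion)
  list(accuracy = acc, recall = recall, confusion = confusion)
}

#' Train the stage-1 Strong/NotStrong gate
#'
#' Fits a random forest on stage-1 feature vectors and reports stratified
#' 10-fold cross-validation accuracy, sensitivity (recall of `Strong`) and
#' specificity (recall of `NotStrong`).
#'
#' @param features Data frame or matrix of stage-1 features (one row per
#'   window).
#' @param labels Vector of `"Strong"` / `"NotStrong"` labels.
#' @param cfg A [pp_config()] (supplies `ntree`).
#' @param seed RNG seed for fold assignment and forest growth.
#' @return List with `model` (the fitted forest) and `cv` (accuracy,
#'   sensitivity, specificity, confusion matrix).
#' @export
train_stage1 <- function(features, labels, cfg = pp_config(), seed = 1L) {
  features <- as.data.frame(features)
  labels <- factor(labels, levels = c("NotStrong", "Strong"))
  cv <- rf_crossval(features, labels, cfg$ntree, seed = seed)
  set.seed(seed)
  model <- randomForest::randomForest(x = features, y = labels,
                                      ntree = cfg$ntree)
  list(model = model,
       cv = list(accuracy = cv$accuracy,
                 sensitivity = unname(cv$recall["Strong"]),
                 specificity = unname(cv$recall["NotStrong"]),
                 confusion = cv$confusion))
}

#' Gate decision for one window
#'
#' Classifies a stage-1 feature vector as `Strong` (residual motion
#' artifacts remain; SSA will be applied) or `NotStrong` (the ANC output
#' is passed through unchanged).
#'
#' @param model A fitted stage-1 forest from [train_stage1()].
#' @param features Stage-1 feature vector from
#'   [extract_stage1_features()].
#' @return `"Strong"` or `"NotStrong"`.
#' @export
decide_ma <- function(model, features) {
  if (inherits(model, "list") && !is.null(model$model)) model <- model$model
  if (!inherits(model, "randomForest"))
    stop("state error: model is not a trained random forest")
  as.character(predict(model, as.data.frame(t(features))))
}
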