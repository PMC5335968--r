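#' Paired heart-rate trace
#'
#' Aligns per-window heart-rate estimates with their ground truth for
#' metric computation.
#'
#' @param est_bpm Estimated BPM per window.
#' @param true_bpm Ground-truth BPM per window (same length).
#' @param id Recording label.
#' @return An object of class `pp_hrtrace`.
#' @export
hr_trace <- function(est_bpm, true_bpm, id = "trace") {
  if (length(est_bpm) != length(true_bpm))
    stop("est_bpm and true_bpm must have equal length")
  if (length(est_bpm) < 1) stop("parameter error: empty trace")
  if (any(est_bpm < 0) || any(true_bpm < 0))
    stop("BPM values must be non-negative")
  structure(list(est_bpm = as.numeric(est_bpm),
                 true_bpm = as.numeric(true_bpm), id = id),
            class = "pp_hrtrace")
}

#' Average absolute error
#'
#' Mean absolute difference between estimated and true heart rate over
#' all windows, in BPM.
#'
#' @param trace A [hr_trace()].
#' @return AAE in BPM.
#' @export
aae <- function(trace) {
  stopifnot(inherits(trace, "pp_hrtrace"))
  mean(abs(trace$est_bpm - trace$true_bpm))
}

#' Bland-Altman agreement statistics
#'
#' Mean and sample standard deviation of the estimate-minus-truth
#' differences and the limits of agreement `mu -/+ 1.96 sigma`.
#'
#' @param trace A [hr_trace()] with at least two windows.
#' @return List with `mu`, `sigma`, `loa_low`, `loa_high`.
#' @export
bland_altman <- function(trace) {
  stopifnot(inherits(trace, "pp_hrtrace"))
  d <- trace$est_bpm - trace$true_bpm
  if (length(d) < 2) stop("parameter error: need at least 2 windows")
  mu <- mean(d)
  sigma <- sd(d)
  list(mu = mu, sigma = sigma,
       loa_low = mu - 1.96 * sigma, loa_high = mu + 1.96 * sigma)
}

#' Pearson correlation between estimates and truth
#'
#' @param trace A [hr_trace()]; both series must be non-constant.
#' @return Correlation coefficient in `[-1, 1]`, or `NA` when either
#'   series is constant.
#' @export
pearson_cor <- function(trace) {
  stopifnot(inherits(trace, "pp_hrtrace"))
  if (sd(trace$est_bpm) == 0 || sd(trace$true_bpm) == 0) return(NA_real_)
  cor(trace$est_bpm, trace$true_bpm)
}

#' Per-recording evaluation report
#'
#' One row per trace with its window count, AAE, Bland-Altman statistics
#' and Pearson correlation, plus pooled mean and sample SD of the AAEs as
#' attributes `aae_mean` / `aae_sd`.
#'
#' @param traces A [hr_trace()] or list of them.
#' @return Data frame with columns `id`, `W`, `aae`, `mu`, `loa_low`,
#'   `loa_high`, `pearson`.
#' @export
hr_report <- function(traces) {
  if (inherits(traces, "pp_hrtrace")) traces <- list(traces)
  stopifnot(length(traces) >= 1)
  rows <- lapply(traces, function(tr) {
    ba <- if (length(tr$est_bpm) >= 2) bland_altman(tr)
          else list(mu = mean(tr$est_bpm - tr$true_bpm),
                    loa_low = NA_real_, loa_high = NA_real_)
    data.frame(id = tr$id, W = length(tr$est_bpm), aae = aae(tr),
               mu = ba$mu, loa_low = ba$loa_low, loa_high = ba$loa_high,
               pearson = pearson_cor(tr))
  })
  rep <- do.call(rbind, rows)
  attr(rep, "aae_mean") <- mean(rep$aae)
  attr(rep, "aae_sd") <- if (nrow(rep) > 1) sd(rep$aae) else NA_real_
  rep
}
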