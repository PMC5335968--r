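#' Pipeline configuration
#'
#' Collects every tunable constant of the two-stage estimator in one list.
#' Defaults follow the operating point used throughout the package: 8-s
#' analysis windows advanced by 2 s over signals sampled at 125 Hz, spectra
#' on 4096 zero-padded bins, and a 0.4-5 Hz passband that brackets the
#' physiological heart-rate range (24-300 BPM).
#'
#' @param T_s Window length in seconds.
#' @param M0_s Window step in seconds (generally `M0_s <= T_s / 2`).
#' @param fs Sampling rate in Hz.
#' @param N Number of frequency bins of the zero-padded periodogram.
#' @param band Passband of the zero-phase band-pass filter, in Hz.
#' @param delta1 Significant-peak threshold (fraction of maximum amplitude)
#'   used by the stage-1 peak-count feature.
#' @param delta2 Dominant-peak threshold (fraction of maximum amplitude)
#'   used by SSA artifact matching and stage-2 range peaks.
#' @param delta_s Half-width, in bins, of the fundamental search range
#'   around the previous heart-rate bin.
#' @param sigma1,sigma2 Step bounds, in bins, for the first and second
#'   candidate peak when no direct spectral evidence is found.
#' @param delay_s Time shift applied to the acceleration reference before
#'   Volterra expansion, in seconds; acceleration leads the artifact.
#' @param memory Volterra filter memory in samples (order of the reference
#'   history); the expansion has `(memory+1) + (memory+1)*(memory+2)/2`
#'   coefficients.
#' @param lambda RLS forgetting factor in (0, 1].
#' @param init_diag Scale of the initial RLS inverse-correlation matrix.
#' @param ssa_L SSA embedding window length in samples (capped at `M/2`).
#' @param ssa_k Number of leading SSA elementary components examined for
#'   artifact content.
#' @param match_tol Bin tolerance when matching a component's dominant
#'   frequency against the acceleration dominant set.
#' @param tol_bpm "Very close" threshold in BPM for deriving Strong /
#'   NotStrong training labels from ground truth.
#' @param pair_tol Bin tolerance for the fundamental/first-harmonic
#'   peak-pair relation.
#' @param hr_band Heart-rate search band in BPM used to initialise the
#'   tracker and for argmax baselines.
#' @param ppg_channel How the two PPG channels are consolidated:
#'   `"mean"`, `"channel1"` or `"channel2"`.
#' @param ntree Number of trees in each random forest.
#'
#' @return A named list of class `pp_config`.
#' @export
pp_config <- function(T_s = 8, M0_s = 2, fs = 125, N = 4096,
                      band = c(0.4, 5), delta1 = 0.30, delta2 = 0.50,
                      delta_s = 2L, sigma1 = 2L, sigma2 = 2L,
                      delay_s = 0.08, memory = 10L, lambda = 0.999,
                      init_diag = 100, ssa_L = 500L, ssa_k = 20L,
                      match_tol = 2L, tol_bpm = 3, pair_tol = 1L,
                      hr_band = c(50, 180), ppg_channel = "mean",
                      ntree = 100L) {
  cfg <- list(T_s = T_s, M0_s = M0_s, fs = fs, N = as.integer(N),
              band = band, delta1 = delta1, delta2 = delta2,
              delta_s = as.integer(delta_s), sigma1 = as.integer(sigma1),
              sigma2 = as.integer(sigma2), delay_s = delay_s,
              memory = as.integer(memory), lambda = lambda,
              init_diag = init_diag, ssa_L = as.integer(ssa_L),
              ssa_k = as.integer(ssa_k), match_tol = as.integer(match_tol),
              tol_bpm = tol_bpm, pair_tol = as.integer(pair_tol),
              hr_band = hr_band,
              ppg_channel = match.arg(ppg_channel,
                                      c("mean", "channel1", "channel2")),
              ntree = as.integer(ntree))
  validate_config(cfg)
  class(cfg) <- "pp_config"
  cfg
}

validate_config <- function(cfg) {
  stopifnot(cfg$fs > 0, cfg$T_s > 0, cfg$M0_s > 0,
            cfg$N >= cfg$T_s * cfg$fs,
            length(cfg$band) == 2, cfg$band[1] > 0,
            cfg$band[2] > cfg$band[1], cfg$band[2] < cfg$fs / 2,
            cfg$delta1 > 0, cfg$delta1 <= 1,
            cfg$delta2 > 0, cfg$delta2 <= 1,
            cfg$lambda > 0, cfg$lambda <= 1,
            cfg$memory >= 0, cfg$delay_s >= 0,
            cfg$delta_s >= 0, cfg$sigma1 >= 0, cfg$sigma2 >= 0,
            length(cfg$hr_band) == 2, cfg$hr_band[1] < cfg$hr_band[2])
  m_window <- cfg$T_s * cfg$fs
  m_step <- cfg$M0_s * cfg$fs
  if (abs(m_window - round(m_window)) > 1e-9 ||
      abs(m_step - round(m_step)) > 1e-9)
    stop("T_s * fs and M0_s * fs must be whole numbers of samples")
  if (cfg$M0_s > cfg$T_s / 2)
    warning("window step M0_s exceeds T_s/2; windows may under-overlap")
  invisible(cfg)
}

#' @export
print.pp_config <- function(x, ...) {
  cat("<pp_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-10s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}
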