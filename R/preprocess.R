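#' Zero-phase band-pass filter
#'
#' Fourth-order Butterworth band-pass applied forward and backward
#' (`signal::filtfilt`), giving zero phase distortion so spectral peak
#' locations are preserved across channels.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param lo,hi Passband edges in Hz; `0 < lo < hi < fs/2`.
#' @return Filtered signal, same length as `x`.
#' @export
bandpass <- function(x, fs, lo = 0.4, hi = 5) {
  if (!(lo > 0 && hi > lo && hi < fs / 2))
    stop("parameter error: need 0 < lo < hi < fs/2")
  bf <- signal::butter(4, c(lo, hi) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Amplitude spectrum by zero-padded periodogram
#'
#' Computes the plain (rectangular-taper) periodogram of a window on `N`
#' zero-padded DFT bins. Amplitudes are scaled by `1/sqrt(N)` so that the
#' summed squared amplitude equals the signal energy `sum(x^2)` (Parseval).
#' Bin `b` (1-based) maps to frequency `(b-1)/N * fs` Hz; bin 1 is DC.
#'
#' @param x Numeric window of `M` samples, `M <= N`.
#' @param fs Sampling rate in Hz.
#' @param N Number of frequency bins.
#' @return A `pp_spectrum`: list with `amp` (length `N`), `fs`, `N`.
#' @export
periodogram_spectrum <- function(x, fs, N = 4096) {
  M <- length(x)
  if (N < M) stop("parameter error: N must be at least the window length")
  padded <- c(x, numeric(N - M))
  amp <- Mod(fft(padded)) / sqrt(N)
  structure(list(amp = amp, fs = fs, N = as.integer(N)),
            class = "pp_spectrum")
}

#' @export
print.pp_spectrum <- function(x, ...) {
  cat(sprintf("<pp_spectrum> %d bins at %g Hz (resolution %.4f Hz)\n",
              x$N, x$fs, x$fs / x$N))
  invisible(x)
}

#' Map spectrum bins to frequency and back
#'
#' `bin_to_hz()` converts 1-based bin indices to Hz; `hz_to_bin()` rounds a
#' frequency to the nearest bin. These are the inverse pair used everywhere
#' a bin index is interpreted as a frequency.
#'
#' @param bin 1-based bin index (vectorised).
#' @param hz Frequency in Hz (vectorised).
#' @param fs Sampling rate in Hz.
#' @param N Number of frequency bins.
#' @return Frequencies in Hz, or integer bin indices.
#' @export
bin_to_hz <- function(bin, fs, N) (bin - 1) / N * fs

#' @rdname bin_to_hz
#' @export
hz_to_bin <- function(hz, fs, N) as.integer(round(hz * N / fs) + 1L)

# Strict local maxima of a vector: v[i-1] < v[i] >= v[i+1], endpoints
# allowed. Ties on the right shoulder break toward the lower bin.
local_maxima <- function(v) {
  n <- length(v)
  if (n == 1L) return(1L)
  left <- c(-Inf, v[-n])
  right <- c(v[-1], -Inf)
  which(v > left & v >= right)
}

#' Find spectral peaks above a fractional threshold
#'
#' Locates the strict local maxima of the amplitude spectrum whose height
#' is at least `frac` times the maximum amplitude. When `range` is given,
#' both the candidate peaks and the reference maximum are restricted to
#' that bin interval.
#'
#' @param spec A `pp_spectrum` from [periodogram_spectrum()].
#' @param frac Fraction of the maximum amplitude, in (0, 1].
#' @param range Optional inclusive bin interval `c(lo, hi)` (1-based).
#' @param ref_max Optional reference maximum for the threshold; defaults
#'   to the maximum amplitude inside `range`. The peak tracker passes the
#'   whole-spectrum maximum here so that noise-level fluctuations inside
#'   an otherwise quiet search range are never promoted to peaks.
#' @return A `pp_peakset`: list with `locations` (1-based bins, sorted by
#'   descending amplitude), `amplitudes`, and `threshold_frac`.
#' @export
find_peaks_above <- function(spec, frac, range = NULL, ref_max = NULL) {
  stopifnot(inherits(spec, "pp_spectrum"))
  if (!(frac > 0 && frac <= 1))
    stop("parameter error: frac must be in (0, 1]")
  N <- spec$N
  if (is.null(range)) range <- c(1L, N)
  lo <- max(1L, as.integer(range[1])); hi <- min(N, as.integer(range[2]))
  if (lo > hi) stop("parameter error: empty bin range")
  seg <- spec$amp[lo:hi]
  peaks <- integer(0); amps <- numeric(0)
  mx <- if (is.null(ref_max)) max(seg) else ref_max
  if (mx > 0) {
    cand <- local_maxima(seg)
    keep <- cand[seg[cand] >= frac * mx]
    if (length(keep)) {
      ord <- order(-seg[keep], keep)  # amplitude desc, lower bin on ties
      peaks <- (keep + lo - 1L)[ord]
      amps <- seg[keep][ord]
    }
  }
  structure(list(locations = peaks, amplitudes = amps,
                 threshold_frac = frac),
            class = "pp_peakset")
}

#' @export
print.pp_peakset <- function(x, ...) {
  cat(sprintf("<pp_peakset> %d peak(s) above %.0f%% of max\n",
              length(x$locations), 100 * x$threshold_frac))
  if (length(x$locations))
    print(data.frame(bin = x$locations, amplitude = x$amplitudes))
  invisible(x)
}
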