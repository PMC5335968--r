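#' Second-order Volterra expansion of a reference sample
#'
#' Expands the reference history at sample `i` into the regressor vector of
#' the second-order Volterra filter: the `memory + 1` lagged linear terms
#' `a(i), a(i-1), ..., a(i-memory)` followed by all distinct pairwise
#' products `a(i-p) * a(i-q)` with `p <= q`, in row-major order over
#' `(p, q)`. History before the first sample is zero-padded. The expansion
#' dimension is `D = (memory+1) + (memory+1)*(memory+2)/2`.
#'
#' @param a Numeric reference signal.
#' @param i 1-based sample index.
#' @param memory Filter memory in samples (number of past lags).
#' @return Numeric vector of length `D`.
#' @export
volterra_expand <- function(a, i, memory) {
  stopifnot(i >= 1, i <= length(a), memory >= 0)
  lags <- i - (0:memory)
  h <- ifelse(lags >= 1, a[pmax(lags, 1)], 0)
  prods <- numeric(0)
  for (p in seq_len(memory + 1)) {
    prods <- c(prods, h[p] * h[p:(memory + 1)])
  }
  c(h, prods)
}

#' Time-shift the acceleration reference
#'
#' Motion couples into the PPG with a short transport delay, so the
#' acceleration reference leads the artifact it explains. Delaying the
#' reference by `delay_s` seconds (zero-padding the start) aligns its
#' history with the artifact before Volterra expansion.
#'
#' @param a Numeric reference signal.
#' @param delay_s Delay in seconds (default 0.08 s).
#' @param fs Sampling rate in Hz.
#' @param lead If `TRUE` (default) the reference is assumed to lead the
#'   artifact and is delayed; `FALSE` advances it instead.
#' @return Shifted signal, same length as `a`.
#' @export
shift_reference <- function(a, delay_s, fs, lead = TRUE) {
  d <- as.integer(round(delay_s * fs))
  n <- length(a)
  if (d == 0L || d >= n) return(a)
  if (lead) c(numeric(d), a[seq_len(n - d)])
  else c(a[(d + 1L):n], numeric(d))
}

#' Adaptive noise cancellation by Volterra RLS
#'
#' Estimates the motion artifact in a PPG window as a second-order
#' Volterra transform of the (already time-aligned) acceleration reference
#' and subtracts it. Filter coefficients are updated per sample by
#' exponentially-weighted recursive least squares with forgetting factor
#' `lambda`; the returned residual uses the a-posteriori coefficients, so
#' at every sample it equals the window's weighted least-squares solution
#' up to the `init_diag` regularisation of the inverse-correlation matrix.
#' Filter state is reset at every window, keeping windows reproducible in
#' isolation.
#'
#' @param x PPG window (band-passed, consolidated).
#' @param a Acceleration reference window, already shifted by
#'   [shift_reference()].
#' @param cfg A [pp_config()] supplying `memory`, `lambda`, `init_diag`.
#' @param order `2` (default) for the full linear + quadratic expansion,
#'   `1` for a linear-only ablation.
#' @return List with `s_hat` (denoised window), `w` (final coefficients)
#'   and `D` (expansion dimension).
#' @export
rls_denoise <- function(x, a, cfg = pp_config(), order = 2) {
  if (length(x) != length(a))
    stop("x and a must have equal length")
  if (!all(is.finite(x)) || !all(is.finite(a)))
    stop("numeric error: non-finite input")
  res <- rls_core(as.numeric(x), as.numeric(a), cfg$memory, cfg$lambda,
                  cfg$init_diag, order == 2)
  list(s_hat = as.numeric(res$s_hat), w = as.numeric(res$w),
       D = as.integer(res$D))
}
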