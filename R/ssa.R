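#' Singular spectrum analysis decomposition
#'
#' Embeds the series in an `L x (M - L + 1)` trajectory matrix, takes its
#' SVD, and reconstructs the first `k` rank-1 terms as elementary series by
#' diagonal (Hankel) averaging. The tail of the expansion is lumped into a
#' single remainder component so that the components always sum exactly to
#' the input series.
#'
#' @param s Numeric series of length `M`.
#' @param L Embedding window length, `1 < L < M`.
#' @param k Number of elementary components to extract, `1 <= k <= L`.
#' @return A `pp_ssa`: list with `components` (an `M x (k+1)` matrix, the
#'   last column being the remainder), `eigenvalues` (the `k` leading
#'   singular values, non-increasing) and `L`.
#' @export
ssa_decompose <- function(s, L, k = min(20L, L)) {
  M <- length(s)
  if (!(L > 1 && L < M)) stop("parameter error: need 1 < L < M")
  if (!(k >= 1 && k <= L)) stop("parameter error: need 1 <= k <= L")
  K <- M - L + 1L
  X <- t(stats::embed(s, L)[, L:1, drop = FALSE])  # X[i, j] = s[i + j - 1]
  sv <- svd(X, nu = k, nv = k)
  counts <- stats::convolve(rep(1, L), rep(1, K), type = "open")
  comps <- matrix(0, nrow = M, ncol = k + 1L)
  for (m in seq_len(k)) {
    comps[, m] <- sv$d[m] *
      stats::convolve(sv$u[, m], rev(sv$v[, m]), type = "open") / counts
  }
  comps[, k + 1L] <- s - rowSums(comps[, seq_len(k), drop = FALSE])
  colnames(comps) <- c(sprintf("elem%02d", seq_len(k)), "remainder")
  structure(list(components = comps, eigenvalues = sv$d[seq_len(k)], L = L),
            class = "pp_ssa")
}

#' @export
print.pp_ssa <- function(x, ...) {
  k <- ncol(x$components) - 1L
  cat(sprintf("<pp_ssa> %d elementary components + remainder (L = %d)\n",
              k, x$L))
  cat("  leading singular values:",
      paste(signif(head(x$eigenvalues, 5), 4), collapse = ", "), "\n")
  invisible(x)
}

# Dominant spectral bin of a series: argmax of the periodogram amplitude
# over the positive-frequency half, DC excluded.
dominant_bin <- function(x, fs, N) {
  spec <- periodogram_spectrum(x, fs, N)
  half <- 2:(N %/% 2 + 1L)
  half[which.max(spec$amp[half])]
}

#' Dominant acceleration frequency bins
#'
#' Bin locations of the acceleration spectrum peaks whose amplitude is at
#' least `frac` of the maximum (positive-frequency half, DC excluded).
#' These are the frequencies attributed to motion.
#'
#' @param a_spec Acceleration `pp_spectrum`.
#' @param frac Dominance threshold as a fraction of the maximum amplitude.
#' @return Integer vector of 1-based bin indices (possibly empty).
#' @export
accel_dominant_bins <- function(a_spec, frac = 0.5) {
  stopifnot(inherits(a_spec, "pp_spectrum"))
  half <- c(2L, a_spec$N %/% 2L + 1L)
  find_peaks_above(a_spec, frac, range = half)$locations
}

#' Remove motion-locked SSA components
#'
#' Decomposes the ANC output and drops every elementary component whose own
#' dominant frequency bin lies within `match_tol` bins of a dominant
#' acceleration frequency; the remaining components (always including the
#' remainder) are summed back into the cleansed window. If removal would
#' annihilate the signal — no acceleration-free component carries
#' appreciable energy — the input is returned unchanged with a warning.
#'
#' @param s_hat Denoised PPG window from [rls_denoise()].
#' @param a_spec Acceleration `pp_spectrum` for the same window.
#' @param cfg A [pp_config()] supplying `ssa_L`, `ssa_k`, `delta2`,
#'   `match_tol`.
#' @return List with `s_recon` (cleansed window), `dropped` (indices of
#'   removed components) and `lacc` (the acceleration bin set).
#' @export
ssa_remove_ma <- function(s_hat, a_spec, cfg = pp_config()) {
  stopifnot(inherits(a_spec, "pp_spectrum"))
  M <- length(s_hat)
  lacc <- accel_dominant_bins(a_spec, cfg$delta2)
  if (length(lacc) == 0L)
    return(list(s_recon = s_hat, dropped = integer(0), lacc = lacc))
  L <- min(cfg$ssa_L, M %/% 2L)
  k <- min(cfg$ssa_k, L)
  dec <- ssa_decompose(s_hat, L = L, k = k)
  drop <- logical(k)
  for (m in seq_len(k)) {
    db <- dominant_bin(dec$components[, m], a_spec$fs, a_spec$N)
    drop[m] <- any(abs(db - lacc) <= cfg$match_tol)
  }
  keep <- c(!drop, TRUE)  # remainder is never dropped
  s_recon <- rowSums(dec$components[, keep, drop = FALSE])
  if (sum(s_recon^2) < 1e-6 * sum(s_hat^2)) {
    warning("SSA would remove the whole signal; returning input unchanged")
    return(list(s_recon = s_hat, dropped = integer(0), lacc = lacc))
  }
  list(s_recon = s_recon, dropped = which(drop), lacc = lacc)
}
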