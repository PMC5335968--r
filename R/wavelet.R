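# Daubechies-4 (8-tap, four vanishing moments) analysis filters.
# Low-pass taps in convolution order; high-pass by quadrature mirror.
DB4_LO <- c(-0.010597401784997278, 0.032883011666982945,
            0.030841381835986965, -0.187034811718881140,
            -0.027983769416983850, 0.630880767929590400,
            0.714846570552541500, 0.230377813308855230)
DB4_HI <- rev(DB4_LO) * c(-1, 1, -1, 1, -1, 1, -1, 1)

# One analysis step: symmetric (half-point) boundary extension, valid
# convolution, dyadic downsampling.
dwt_step <- function(x, filt) {
  nf <- length(filt)
  ext <- c(x[(nf - 1L):1L], x, x[length(x):(length(x) - nf + 2L)])
  full <- stats::convolve(ext, rev(filt), type = "open")
  valid <- full[nf:(length(ext))]
  valid[seq(2L, length(valid), by = 2L)]
}

#' Discrete wavelet decomposition with db4
#'
#' Five-level (by default) pyramid decomposition of a window using the
#' Daubechies wavelet with four vanishing moments and symmetric boundary
#' extension. Returns the coefficient vectors of each sub-band, finest
#' detail first.
#'
#' @param x Numeric signal.
#' @param levels Number of decomposition levels.
#' @return Named list `d1, ..., d<levels>, a<levels>` of coefficient
#'   vectors.
#' @export
dwt_db4 <- function(x, levels = 5L) {
  stopifnot(levels >= 1, length(x) >= 2^levels)
  out <- list()
  approx_c <- x
  for (lev in seq_len(levels)) {
    out[[sprintf("d%d", lev)]] <- dwt_step(approx_c, DB4_HI)
    approx_c <- dwt_step(approx_c, DB4_LO)
  }
  out[[sprintf("a%d", levels)]] <- approx_c
  out
}
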