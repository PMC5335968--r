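#' Construct a multi-channel wrist recording
#'
#' A `pp_recording` bundles the synchronized channels of one recording
#' session: two PPG channels from the wrist oximeter, three accelerometer
#' axes, the sampling rate, and (for training or evaluation) the per-window
#' ground-truth heart rate derived from a simultaneous ECG.
#'
#' @param ppg Numeric matrix with two columns (`ppg1`, `ppg2`) or a single
#'   vector (duplicated into two identical channels).
#' @param accel Numeric matrix with three columns (`ax`, `ay`, `az`).
#' @param fs Sampling rate in Hz; shared by all channels.
#' @param truth_bpm Optional numeric vector of per-window ground-truth BPM.
#' @param id Recording label.
#'
#' @return An object of class `pp_recording`.
#' @export
pp_recording <- function(ppg, accel, fs, truth_bpm = NULL, id = "recording") {
  if (is.null(dim(ppg))) ppg <- cbind(ppg1 = ppg, ppg2 = ppg)
  ppg <- as.matrix(ppg)
  accel <- as.matrix(accel)
  if (ncol(ppg) != 2) stop("ppg must have exactly 2 channels")
  if (ncol(accel) != 3) stop("accel must have exactly 3 channels")
  if (nrow(ppg) != nrow(accel))
    stop("integrity error: ppg and accel channel lengths differ")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop("fs must be a single positive number")
  if (!all(is.finite(ppg)) || !all(is.finite(accel)))
    stop("non-finite samples in recording channels")
  structure(list(ppg = unname(ppg), accel = unname(accel), fs = fs,
                 truth_bpm = truth_bpm, id = id),
            class = "pp_recording")
}

#' @export
print.pp_recording <- function(x, ...) {
  cat(sprintf("<pp_recording> '%s': %d samples (%.1f s) at %g Hz%s\n",
              x$id, nrow(x$ppg), nrow(x$ppg) / x$fs, x$fs,
              if (!is.null(x$truth_bpm))
                sprintf(", truth for %d windows", length(x$truth_bpm))
              else ""))
  invisible(x)
}

#' Consolidate tri-axial acceleration into one channel
#'
#' Reduces the three accelerometer axes to a single reference channel by
#' taking the Euclidean norm of the axis vector at every sampling point.
#'
#' @param accel Numeric matrix with three equal-length columns.
#' @return Numeric vector of per-sample norms (non-negative).
#' @export
consolidate_accel <- function(accel) {
  accel <- as.matrix(accel)
  if (ncol(accel) != 3)
    stop("integrity error: expected three acceleration channels")
  sqrt(rowSums(accel^2))
}

# Number of analysis windows for a recording of n samples.
count_windows <- function(n_samples, T_s, M0_s, fs) {
  M <- as.integer(round(T_s * fs))
  step <- as.integer(round(M0_s * fs))
  if (n_samples < M) return(0L)
  as.integer((n_samples - M) %/% step + 1L)
}

#' Slide analysis windows over a recording
#'
#' Consolidates the PPG and acceleration channels (see
#' [prepare_recording()]) and cuts the result into overlapping analysis
#' windows of `T_s` seconds advanced by `M0_s` seconds.
#'
#' @param rec A `pp_recording`.
#' @param cfg A [pp_config()]; supplies `T_s`, `M0_s`, the passband and the
#'   PPG consolidation rule.
#' @return A list of window views, each a list with `index` (0-based),
#'   `start_sample` (1-based), `ppg` and `accel_norm` (both of length
#'   `T_s * fs`).
#' @export
slide_windows <- function(rec, cfg = pp_config()) {
  stopifnot(inherits(rec, "pp_recording"))
  if (cfg$M0_s > cfg$T_s / 2)
    warning("window step exceeds half the window length")
  prep <- prepare_recording(rec, cfg)
  M <- as.integer(round(cfg$T_s * cfg$fs))
  step <- as.integer(round(cfg$M0_s * cfg$fs))
  n <- length(prep$ppg)
  if (n < M)
    stop("empty-sequence error: recording shorter than one window")
  W <- count_windows(n, cfg$T_s, cfg$M0_s, cfg$fs)
  if (!is.null(rec$truth_bpm) && length(rec$truth_bpm) != W)
    warning(sprintf("truth_bpm has %d entries but %d windows are produced",
                    length(rec$truth_bpm), W))
  lapply(seq_len(W) - 1L, function(i) {
    s <- i * step + 1L
    list(index = i, start_sample = s,
         ppg = prep$ppg[s:(s + M - 1L)],
         accel_norm = prep$accel_norm[s:(s + M - 1L)])
  })
}

#' Consolidate and band-pass filter a recording's channels
#'
#' The two PPG channels are band-pass filtered and then combined according
#' to `cfg$ppg_channel` (averaged by default). The acceleration axes are
#' consolidated to their Euclidean norm first and band-pass filtered after:
#' taking the norm before filtering keeps the gravity offset in place while
#' the norm is formed, so the cadence fundamental is preserved instead of
#' being rectified to its second harmonic.
#'
#' @inheritParams slide_windows
#' @return List with elements `ppg`, `accel_norm`, `fs`, `n`.
#' @export
prepare_recording <- function(rec, cfg = pp_config()) {
  stopifnot(inherits(rec, "pp_recording"))
  f1 <- bandpass(rec$ppg[, 1], rec$fs, cfg$band[1], cfg$band[2])
  f2 <- bandpass(rec$ppg[, 2], rec$fs, cfg$band[1], cfg$band[2])
  ppg <- switch(cfg$ppg_channel,
                mean = (f1 + f2) / 2,
                channel1 = f1,
                channel2 = f2)
  an <- bandpass(consolidate_accel(rec$accel), rec$fs,
                 cfg$band[1], cfg$band[2])
  list(ppg = ppg, accel_norm = an, fs = rec$fs, n = length(ppg))
}

#' Read a recording from disk
#'
#' Two dialects are supported. `"csv"` is a plain-text table with columns
#' `ppg1,ppg2,ax,ay,az` and the sampling rate in a leading `# fs=` comment;
#' per-window ground truth, when present, lives in a `<stem>_bpm.csv`
#' sidecar with a single `truth_bpm` column. `"mat"` is the Level-4 MAT
#' binary layout used by the wrist-PPG benchmark recordings: a `sig` matrix
#' whose rows are channels (an optional leading ECG row, two PPG rows,
#' three acceleration rows), an optional scalar `fs`, and an optional
#' `BPM0` vector of per-window ground truth.
#'
#' @param path Path to the recording file.
#' @param dialect `"csv"` or `"mat"`; inferred from the file extension by
#'   default.
#' @param fs Sampling rate fallback when the file does not carry one.
#' @return A [pp_recording()].
#' @export
read_recording <- function(path, dialect = c("auto", "csv", "mat"),
                           fs = 125) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.mat$", path, ignore.case = TRUE)) "mat" else "csv"
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "csv") read_recording_csv(path, fs) else
    read_recording_mat(path, fs)
}

#' Write a recording to disk
#'
#' Inverse of [read_recording()]; see that help page for the dialects.
#'
#' @param rec A [pp_recording()].
#' @inheritParams read_recording
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, dialect = c("auto", "csv", "mat")) {
  stopifnot(inherits(rec, "pp_recording"))
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.mat$", path, ignore.case = TRUE)) "mat" else "csv"
  if (dialect == "csv") write_recording_csv(rec, path) else
    write_recording_mat(rec, path)
  invisible(path)
}

read_recording_csv <- function(path, fs_default) {
  first <- readLines(path, n = 1L)
  fs <- fs_default
  if (grepl("^#\\s*fs\\s*=", first))
    fs <- as.numeric(sub("^#\\s*fs\\s*=\\s*", "", first))
  tab <- read.csv(path, comment.char = "#")
  need <- c("ppg1", "ppg2", "ax", "ay", "az")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("schema error: missing channel column(s) ",
         paste(missing, collapse = ", "))
  truth <- NULL
  sidecar <- sub("\\.csv$", "_bpm.csv", path)
  if (sidecar != path && file.exists(sidecar)) {
    st <- read.csv(sidecar, comment.char = "#")
    if (!"truth_bpm" %in% names(st))
      stop("schema error: sidecar lacks truth_bpm column")
    truth <- st$truth_bpm
  }
  pp_recording(ppg = as.matrix(tab[, c("ppg1", "ppg2")]),
               accel = as.matrix(tab[, c("ax", "ay", "az")]),
               fs = fs, truth_bpm = truth,
               id = sub("\\.[^.]*$", "", basename(path)))
}

write_recording_csv <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.10g", rec$fs), con)
  tab <- data.frame(ppg1 = rec$ppg[, 1], ppg2 = rec$ppg[, 2],
                    ax = rec$accel[, 1], ay = rec$accel[, 2],
                    az = rec$accel[, 3])
  write.csv(format(tab, digits = 17, trim = TRUE, scientific = FALSE),
            con, row.names = FALSE, quote = FALSE)
  if (!is.null(rec$truth_bpm)) {
    sidecar <- sub("\\.csv$", "_bpm.csv", path)
    write.csv(data.frame(truth_bpm = rec$truth_bpm), sidecar,
              row.names = FALSE)
  }
  invisible(path)
}

# --- Level-4 MAT container ------------------------------------------------
# Each element is [type, mrows, ncols, imagf, namlen] as int32, a
# null-terminated name, then column-major doubles. type 0 encodes
# little-endian IEEE doubles in a full numeric matrix, which is all this
# dialect uses. No installed R package reads this container, so the 20-byte
# header format is handled here directly.

read_mat4 <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  out <- list()
  repeat {
    hdr <- readBin(con, "integer", n = 5L, size = 4L, endian = "little")
    if (length(hdr) < 5L) break
    type <- hdr[1]; mrows <- hdr[2]; ncols <- hdr[3]
    imagf <- hdr[4]; namlen <- hdr[5]
    if (type != 0L)
      stop("unsupported MAT element type ", type,
           " (only little-endian double full matrices are handled)")
    nm <- readBin(con, "raw", n = namlen)
    name <- rawToChar(nm[nm != as.raw(0)])
    vals <- readBin(con, "numeric", n = mrows * ncols, size = 8L,
                    endian = "little")
    if (imagf) readBin(con, "numeric", n = mrows * ncols, size = 8L,
                       endian = "little")
    out[[name]] <- matrix(vals, nrow = mrows, ncol = ncols)
  }
  out
}

write_mat4 <- function(mats, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  for (name in names(mats)) {
    m <- as.matrix(mats[[name]])
    storage.mode(m) <- "double"
    nm <- c(charToRaw(name), as.raw(0))
    writeBin(as.integer(c(0L, nrow(m), ncol(m), 0L, length(nm))), con,
             size = 4L, endian = "little")
    writeBin(nm, con)
    writeBin(as.vector(m), con, size = 8L, endian = "little")
  }
  invisible(path)
}

read_recording_mat <- function(path, fs_default) {
  mats <- read_mat4(path)
  if (!"sig" %in% names(mats))
    stop("schema error: missing 'sig' matrix")
  sig <- mats$sig
  if (nrow(sig) > ncol(sig)) sig <- t(sig)
  if (nrow(sig) == 6L) sig <- sig[-1L, , drop = FALSE]  # leading ECG row
  if (nrow(sig) != 5L)
    stop("schema error: 'sig' must have 5 channel rows ",
         "(ppg1, ppg2, ax, ay, az) or 6 with a leading ECG row")
  fs <- if ("fs" %in% names(mats)) as.numeric(mats$fs[1]) else fs_default
  truth <- if ("BPM0" %in% names(mats)) as.numeric(mats$BPM0) else NULL
  pp_recording(ppg = t(sig[1:2, , drop = FALSE]),
               accel = t(sig[3:5, , drop = FALSE]),
               fs = fs, truth_bpm = truth,
               id = sub("\\.[^.]*$", "", basename(path)))
}

write_recording_mat <- function(rec, path) {
  mats <- list(sig = rbind(t(rec$ppg), t(rec$accel)),
               fs = matrix(rec$fs))
  if (!is.null(rec$truth_bpm))
    mats$BPM0 <- matrix(rec$truth_bpm, ncol = 1L)
  write_mat4(mats, path)
}
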