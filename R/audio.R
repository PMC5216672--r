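# Audio container and PCM WAV I/O. No audio package ships with the target
# environment, so RIFF parsing is done directly with readBin/writeBin.

#' Construct an audio clip
#'
#' Lightweight container for a mono or multi-channel signal with an explicit
#' units flag. All analysis functions track whether samples are dimensionless
#' digital full-scale units in \[-1, 1\] or calibrated pressure in pascal;
#' the flag may only transition digital -> Pa (via [pressure_from_digital()]).
#'
#' @param samples Numeric vector (mono) or matrix with one column per channel.
#' @param sample_rate Sampling rate in Hz (> 0).
#' @param units `"digital"` or `"Pa"`.
#' @return An object of class `audio_clip`.
#' @export
audio_clip <- function(samples, sample_rate, units = c("digital", "Pa")) {
  units <- match.arg(units)
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0)
    stop("sample_rate must be a single positive number")
  if (is.matrix(samples) && ncol(samples) == 1) samples <- samples[, 1]
  stopifnot(is.numeric(samples))
  structure(list(samples = samples, sample_rate = sample_rate, units = units),
            class = "audio_clip")
}

#' @export
print.audio_clip <- function(x, ...) {
  n <- if (is.matrix(x$samples)) nrow(x$samples) else length(x$samples)
  ch <- if (is.matrix(x$samples)) ncol(x$samples) else 1L
  cat(sprintf("<audio_clip> %d samples, %d channel(s), %g Hz, %.3f s, units=%s\n",
              n, ch, x$sample_rate, n / x$sample_rate, x$units))
  invisible(x)
}

#' Number of samples per channel
#' @param clip An `audio_clip`.
#' @return Integer sample count.
#' @export
clip_length <- function(clip) {
  if (is.matrix(clip$samples)) nrow(clip$samples) else length(clip$samples)
}

#' Clip duration in seconds
#' @param clip An `audio_clip`.
#' @return Duration in s.
#' @export
clip_duration <- function(clip) clip_length(clip) / clip$sample_rate

#' Collapse a stereo clip to mono
#'
#' @param clip An `audio_clip`.
#' @param method `"mix"` (average channels) or `"left"` / `"right"`.
#' @return Mono `audio_clip`.
#' @export
to_mono <- function(clip, method = c("mix", "left", "right")) {
  method <- match.arg(method)
  if (!is.matrix(clip$samples)) return(clip)
  s <- switch(method,
              mix = rowMeans(clip$samples),
              left = clip$samples[, 1],
              right = clip$samples[, min(2L, ncol(clip$samples))])
  audio_clip(s, clip$sample_rate, clip$units)
}

#' Read a PCM WAV file
#'
#' Supports uncompressed 16- and 24-bit integer PCM, mono or stereo. Samples
#' are returned as digital full-scale units in \[-1, 1).
#'
#' @param path Path to a `.wav` file.
#' @return An `audio_clip` with `units = "digital"`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE"))
    stop("not a WAVE file: ", path)
  fmt <- NULL; dat <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        audio_format = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        channels     = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        sample_rate  = readBin(con, "integer", 1, 4, endian = "little"),
        byte_rate    = readBin(con, "integer", 1, 4, endian = "little"),
        block_align  = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        bits         = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE))
      if (sz > 16) invisible(readBin(con, "raw", sz - 16))
    } else if (identical(id, "data")) {
      dat <- readBin(con, "raw", sz)
      break
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2))
    }
  }
  if (is.null(fmt) || is.null(dat)) stop("malformed WAV: missing fmt/data chunk")
  if (fmt$audio_format != 1) stop("only uncompressed PCM WAV is supported")
  if (!fmt$bits %in% c(16L, 24L)) stop("only 16- or 24-bit PCM is supported")
  if (fmt$bits == 16L) {
    v <- readBin(dat, "integer", length(dat) / 2, 2, endian = "little") / 32768
  } else {
    m <- matrix(as.integer(dat), nrow = 3)
    v <- m[1, ] + 256L * m[2, ] + 65536L * m[3, ]
    v <- ifelse(v >= 8388608, v - 16777216, v) / 8388608
  }
  if (fmt$channels > 1)
    v <- matrix(v, ncol = fmt$channels, byrow = TRUE)
  audio_clip(v, fmt$sample_rate, "digital")
}

#' Write a clip as 16-bit PCM WAV
#'
#' Digital full-scale samples are quantized to 16 bits; values outside
#' \[-1, 1\] are hard-clipped with a warning (the count of clipped samples is
#' attached as attribute `clipped`).
#'
#' @param clip An `audio_clip` in digital units.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_wav <- function(clip, path) {
  if (clip$units != "digital")
    stop("write_wav expects digital full-scale units; convert first")
  s <- clip$samples
  ch <- if (is.matrix(s)) ncol(s) else 1L
  x <- if (is.matrix(s)) as.numeric(t(s)) else s
  nclip <- sum(x > 1 | x < -1)
  if (nclip > 0) {
    warning(sprintf("%d sample(s) clipped at full scale", nclip))
    x <- pmin(pmax(x, -1), 1)
  }
  q <- as.integer(pmin(pmax(round(x * 32768), -32768), 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  nbytes <- length(q) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + nbytes), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(1L, con, 2, endian = "little")                 # PCM
  writeBin(ch, con, 2, endian = "little")
  writeBin(as.integer(clip$sample_rate), con, 4, endian = "little")
  writeBin(as.integer(clip$sample_rate * ch * 2L), con, 4, endian = "little")
  writeBin(as.integer(ch * 2L), con, 2, endian = "little")
  writeBin(16L, con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(nbytes, con, 4, endian = "little")
  writeBin(q, con, 2, endian = "little")
  invisible(structure(path, clipped = nclip))
}

#' Extract a time segment from a clip
#'
#' @param clip An `audio_clip`.
#' @param from,to Segment bounds in seconds (clamped to the clip).
#' @return An `audio_clip` holding the segment.
#' @export
clip_segment <- function(clip, from, to) {
  stopifnot(to > from)
  n <- clip_length(clip)
  i0 <- max(1L, as.integer(floor(from * clip$sample_rate)) + 1L)
  i1 <- min(n, as.integer(ceiling(to * clip$sample_rate)))
  if (i1 < i0) stop("segment outside clip")
  s <- if (is.matrix(clip$samples)) clip$samples[i0:i1, , drop = FALSE]
       else clip$samples[i0:i1]
  audio_clip(s, clip$sample_rate, clip$units)
}

#' Decimate a clip by an integer factor
#'
#' Polyphase-style decimation: linear-phase windowed-sinc (Blackman, 301
#' taps) anti-alias low-pass with cutoff just below the new Nyquist,
#' delay-compensated, then sample picking. The FIR passband is flat to
#' within ~0.01 dB up to ~85% of the new Nyquist, so decimation does not
#' tilt spectral-centroid measurements. Used to mirror field workflows that
#' analyse calls at 11,025 Hz from 44.1 kHz recordings.
#'
#' @param clip Mono `audio_clip`.
#' @param factor Integer decimation factor (e.g. 4 for 44100 -> 11025).
#' @return An `audio_clip` at `sample_rate / factor`.
#' @export
decimate <- function(clip, factor) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1)
  if (factor == 1L) return(clip)
  if (is.matrix(clip$samples)) clip <- to_mono(clip)
  new_rate <- clip$sample_rate / factor
  ntap <- 301L
  m <- (ntap - 1) / 2
  fc <- 0.94 * new_rate / 2           # cutoff, leaves a guard before Nyquist
  k <- seq_len(ntap) - 1 - m
  h <- 2 * fc / clip$sample_rate * sinc_fn(2 * fc * k / clip$sample_rate)
  w <- 0.42 - 0.5 * cos(2 * pi * (0:(ntap - 1)) / (ntap - 1)) +
    0.08 * cos(4 * pi * (0:(ntap - 1)) / (ntap - 1))
  h <- h * w
  h <- h / sum(h)
  x <- clip$samples
  y <- stats::convolve(c(x, numeric(ntap - 1)), rev(h), type = "open")
  y <- y[(m + ntap):(m + ntap + length(x) - 1)]
  audio_clip(y[seq(1, length(y), by = factor)], new_rate, clip$units)
}

sinc_fn <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))
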