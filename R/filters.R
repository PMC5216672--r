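# Minimal IIR filtering toolkit: Butterworth band-pass design (biquad cascade,
# bilinear transform) and zero-phase forward-backward application. The heavy
# recursion runs through stats::filter (C code), so long recordings stay fast.

#' Design a Butterworth band-pass filter as second-order sections
#'
#' Designs a digital Butterworth band-pass filter of the given prototype order
#' (final filter has `2 * order` poles) via the analog low-pass prototype,
#' low-pass-to-band-pass transform and bilinear transform. Returned as a
#' cascade of biquad sections for numerical stability at extreme band edges
#' (e.g. a 10 Hz lower corner at 44.1 kHz).
#'
#' @param f_lo,f_hi Band edges in Hz, `0 < f_lo < f_hi < sample_rate / 2`.
#' @param sample_rate Sampling rate in Hz.
#' @param order Prototype low-pass order; default 4.
#' @return Object of class `sos_filter`: a list with a `sections` matrix
#'   (columns `b0 b1 b2 a1 a2`, one row per biquad) and the design parameters.
#' @examples
#' f <- butter_bandpass(1000, 4500, 44100)
#' nrow(f$sections)  # 4 biquads = 8 poles
#' @export
butter_bandpass <- function(f_lo, f_hi, sample_rate, order = 4L) {
  stopifnot(is.numeric(f_lo), is.numeric(f_hi), is.numeric(sample_rate))
  if (f_lo <= 0 || f_hi <= f_lo)
    stop("band edges must satisfy 0 < f_lo < f_hi")
  if (f_hi >= sample_rate / 2)
    stop("upper band edge must be below the Nyquist frequency (",
         sample_rate / 2, " Hz)")
  n <- as.integer(order)
  fs2 <- 2 * sample_rate
  # pre-warped analog edges
  w1 <- fs2 * tan(pi * f_lo / sample_rate)
  w2 <- fs2 * tan(pi * f_hi / sample_rate)
  w0 <- sqrt(w1 * w2)
  bw <- w2 - w1
  # analog Butterworth low-pass prototype poles (unit cutoff)
  k <- seq_len(n)
  p_lp <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  # low-pass -> band-pass: each prototype pole maps to two poles
  s <- p_lp * bw / 2
  p_bp <- c(s + sqrt(s^2 - w0^2), s - sqrt(s^2 - w0^2))
  # bilinear transform; n analog zeros at s = 0 map to z = +1, and the n
  # excess poles contribute zeros at z = -1
  z_p <- (fs2 + p_bp) / (fs2 - p_bp)
  gain <- Re(bw^n * fs2^n / prod(fs2 - p_bp))
  sections <- .pair_sections(z_p, gain)
  structure(list(sections = sections, f_lo = f_lo, f_hi = f_hi,
                 sample_rate = sample_rate, order = n),
            class = "sos_filter")
}

#' Design a Butterworth low-pass filter as second-order sections
#'
#' Used for anti-alias filtering before decimation and as the band-pass
#' fallback when the lower edge is effectively DC.
#'
#' @inheritParams butter_bandpass
#' @param f_c Cutoff frequency in Hz.
#' @return An `sos_filter` object.
#' @export
butter_lowpass <- function(f_c, sample_rate, order = 4L) {
  stopifnot(f_c > 0, f_c < sample_rate / 2)
  n <- as.integer(order)
  fs2 <- 2 * sample_rate
  wc <- fs2 * tan(pi * f_c / sample_rate)
  k <- seq_len(n)
  p_a <- wc * exp(1i * pi * (2 * k + n - 1) / (2 * n))
  z_p <- (fs2 + p_a) / (fs2 - p_a)
  # n zeros at z = -1
  gain <- Re(wc^n / prod(fs2 - p_a))
  sections <- .pair_sections(z_p, gain, zero_type = "lowpass")
  structure(list(sections = sections, f_lo = 0, f_hi = f_c,
                 sample_rate = sample_rate, order = n),
            class = "sos_filter")
}

# Pair digital poles into conjugate biquads and distribute zeros/gain.
# zero_type "bandpass": each biquad gets zeros at z = +1 and z = -1;
# "lowpass": each biquad gets a double zero at z = -1.
.pair_sections <- function(z_p, gain, zero_type = c("bandpass", "lowpass")) {
  zero_type <- match.arg(zero_type)
  tol <- 1e-9
  cplx <- z_p[Im(z_p) > tol]
  reals <- sort(Re(z_p[abs(Im(z_p)) <= tol]))
  secs <- list()
  for (p in cplx)
    secs[[length(secs) + 1L]] <- c(-2 * Re(p), abs(p)^2)      # a1, a2
  while (length(reals) >= 2) {
    r <- reals[1:2]; reals <- reals[-(1:2)]
    secs[[length(secs) + 1L]] <- c(-(r[1] + r[2]), r[1] * r[2])
  }
  if (length(reals) == 1)  # odd leftover: first-order section as biquad
    secs[[length(secs) + 1L]] <- c(-reals[1], 0)
  nsec <- length(secs)
  g <- abs(gain)^(1 / nsec)
  bz <- switch(zero_type,
               bandpass = c(1, 0, -1),
               lowpass  = c(1, 2, 1))
  m <- t(vapply(secs, function(a) c(g * bz, a), numeric(5)))
  # keep the overall sign in the first section
  if (gain < 0) m[1, 1:3] <- -m[1, 1:3]
  colnames(m) <- c("b0", "b1", "b2", "a1", "a2")
  m
}

# Single-pass filtering through one biquad, zero initial state.
.biquad <- function(x, sec) {
  n <- length(x)
  m <- sec[["b0"]] * x +
    sec[["b1"]] * c(0, x[-n]) +
    sec[["b2"]] * c(0, 0, x[-c(n - 1, n)])
  as.numeric(stats::filter(m, filter = -sec[c("a1", "a2")],
                           method = "recursive"))
}

#' Apply a second-order-section filter (single pass)
#'
#' @param x Numeric signal.
#' @param filt An `sos_filter` from [butter_bandpass()] or [butter_lowpass()].
#' @return Filtered signal, same length as `x`.
#' @export
sos_filter_apply <- function(x, filt) {
  stopifnot(inherits(filt, "sos_filter"))
  for (i in seq_len(nrow(filt$sections)))
    x <- .biquad(x, filt$sections[i, ])
  x
}

#' Zero-phase (forward-backward) filtering
#'
#' Applies the filter forward and backward so the net response is zero-phase
#' with squared magnitude. Edge transients are absorbed by odd-symmetric
#' signal extension before filtering, as in standard `filtfilt`
#' implementations.
#'
#' @inheritParams sos_filter_apply
#' @param pad Extension length in samples; default scales with the filter's
#'   slowest time constant (3 periods of the lower band edge), capped at
#'   `length(x) - 1`.
#' @return Filtered signal, same length as `x`.
#' @export
filtfilt_sos <- function(x, filt, pad = NULL) {
  n <- length(x)
  if (n < 4) return(sos_filter_apply(rev(sos_filter_apply(rev(x), filt)), filt))
  if (is.null(pad)) {
    f_ref <- if (filt$f_lo > 0) filt$f_lo else filt$f_hi
    pad <- round(3 * filt$sample_rate / f_ref)
  }
  pad <- max(6L, min(as.integer(pad), n - 1L))
  ext <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- sos_filter_apply(ext, filt)
  y <- rev(sos_filter_apply(rev(y), filt))
  y[(pad + 1):(pad + n)]
}
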