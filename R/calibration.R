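# Calibration chain: digital full-scale units -> pascal -> dB re 20 uPa,
# and band-limited windowed RMS SPL extraction.

#' Microphone/recorder calibration specification
#'
#' Maps digital sample amplitude to absolute pressure. A full-scale digital
#' sample corresponds to `adc_full_scale` volts at the converter; dividing by
#' the system sensitivity `10^((mic_sensitivity + gain) / 20)` V/Pa yields
#' pressure. Typical autonomous-recorder values: sensitivity around -35 dB
#' re 1 V/Pa, gain 36-51 dB.
#'
#' @param mic_sensitivity Microphone sensitivity in dB re 1 V/Pa (usually
#'   negative).
#' @param gain Recorder gain in dB.
#' @param adc_full_scale ADC full-scale voltage (V); recorders rarely publish
#'   it, so it is an explicit, configurable constant (default 1.0 V).
#' @param reference_pressure Reference pressure in Pa; default the airborne
#'   standard 20 uPa.
#' @return Object of class `calibration_spec`.
#' @examples
#' calibration_spec(mic_sensitivity = -36, gain = 36)
#' @export
calibration_spec <- function(mic_sensitivity, gain, adc_full_scale = 1.0,
                             reference_pressure = 20e-6) {
  stopifnot(is.numeric(mic_sensitivity), is.numeric(gain))
  if (adc_full_scale <= 0) stop("adc_full_scale must be > 0")
  if (reference_pressure <= 0) stop("reference_pressure must be > 0")
  structure(list(mic_sensitivity = mic_sensitivity, gain = gain,
                 adc_full_scale = adc_full_scale,
                 reference_pressure = reference_pressure),
            class = "calibration_spec")
}

# linear conversion factor: pascal per digital full-scale unit
.pa_per_fs <- function(calib) {
  calib$adc_full_scale / 10^((calib$mic_sensitivity + calib$gain) / 20)
}

#' Convert digital samples to pressure (Pa)
#'
#' `p = x * adc_full_scale / 10^((sensitivity + gain) / 20)`. The conversion
#' is linear and invertible; applying it to an already-converted clip is an
#' error (the units flag only transitions digital -> Pa).
#'
#' @param clip `audio_clip` in digital units.
#' @param calib A [calibration_spec()].
#' @return `audio_clip` with `units = "Pa"`.
#' @export
pressure_from_digital <- function(clip, calib) {
  stopifnot(inherits(clip, "audio_clip"), inherits(calib, "calibration_spec"))
  if (clip$units != "digital")
    stop("clip is already in pressure units; conversion is digital -> Pa only")
  audio_clip(clip$samples * .pa_per_fs(calib), clip$sample_rate, "Pa")
}

#' Convert a pressure clip back to digital units
#'
#' Exact inverse of [pressure_from_digital()]; used when rendering synthetic
#' pressure scenes to recorder output.
#'
#' @inheritParams pressure_from_digital
#' @param clip `audio_clip` in Pa.
#' @return `audio_clip` with `units = "digital"`.
#' @export
digital_from_pressure <- function(clip, calib) {
  stopifnot(inherits(clip, "audio_clip"), inherits(calib, "calibration_spec"))
  if (clip$units != "Pa") stop("clip is not in pressure units")
  audio_clip(clip$samples / .pa_per_fs(calib), clip$sample_rate, "digital")
}

#' Sound-pressure level from RMS pressure
#'
#' `SPL = 20 log10(p_rms / p_ref)` in dB re 20 uPa (or the supplied
#' reference). Zero pressure returns `-Inf` as an explicit silence sentinel.
#'
#' @param p_rms RMS pressure in Pa (vectorized, must be >= 0).
#' @param reference_pressure Reference pressure in Pa.
#' @return SPL in dB re `reference_pressure`.
#' @examples
#' spl(20e-6)         # 0 dB
#' spl(1)             # 93.98 dB
#' @export
spl <- function(p_rms, reference_pressure = 20e-6) {
  if (any(p_rms < 0, na.rm = TRUE)) stop("RMS pressure must be >= 0")
  ifelse(p_rms == 0, -Inf, 20 * log10(p_rms / reference_pressure))
}

#' Inverse of [spl()]: RMS pressure from a level in dB
#' @param level_db SPL in dB re `reference_pressure`.
#' @param reference_pressure Reference pressure in Pa.
#' @return RMS pressure in Pa.
#' @export
pressure_from_spl <- function(level_db, reference_pressure = 20e-6)
  reference_pressure * 10^(level_db / 20)

#' Band-pass filter a clip (zero phase)
#'
#' 4th-order Butterworth applied forward-backward. A lower edge at or below
#' 10 Hz is treated as DC and the filter degrades to a low-pass (the nominal
#' "0-1000 Hz" traffic band is realized as 10-1000 Hz for filter stability;
#' synthetic and field scenes carry negligible energy below 10 Hz).
#'
#' @param clip Mono `audio_clip` (stereo is mixed down).
#' @param f_lo,f_hi Band edges in Hz; `f_hi` must not exceed Nyquist.
#' @param order Butterworth prototype order, default 4.
#' @return Filtered `audio_clip` (same units).
#' @export
bandpass <- function(clip, f_lo, f_hi, order = 4L) {
  stopifnot(inherits(clip, "audio_clip"))
  if (f_hi > clip$sample_rate / 2)
    stop("f_hi exceeds the Nyquist frequency")
  if (f_lo >= f_hi) stop("need f_lo < f_hi")
  if (is.matrix(clip$samples)) clip <- to_mono(clip)
  f_lo_eff <- max(f_lo, 10)
  filt <- if (f_lo_eff >= f_hi || f_lo <= 0 && f_hi <= 20)
    stop("degenerate band") else butter_bandpass(f_lo_eff, f_hi,
                                                 clip$sample_rate, order)
  audio_clip(filtfilt_sos(clip$samples, filt), clip$sample_rate, clip$units)
}

#' Windowed band-limited RMS SPL series
#'
#' The clip is band-pass filtered, converted to pressure if needed, cut into
#' non-overlapping windows aligned to the clip start (trailing partial window
#' dropped), and each window's RMS pressure is expressed as SPL in dB re
#' 20 uPa. This reproduces the classic "band-limited RMS amplitude per
#' 15-minute period" extraction used in passive road-noise monitoring.
#'
#' @param clip `audio_clip` (digital or Pa units).
#' @param calib A [calibration_spec()] (ignored if clip already in Pa).
#' @param band Numeric length-2, band edges in Hz (default the 1-4.5 kHz
#'   frog-call masking band).
#' @param window_s Window length in seconds (> 0); default 900 s (15 min).
#' @return `data.frame` with columns `window_start_s` and `spl_db`. Silent
#'   windows yield `-Inf`.
#' @export
band_rms_spl <- function(clip, calib = NULL, band = c(1000, 4500),
                         window_s = 900) {
  stopifnot(window_s > 0)
  if (clip$units == "digital") {
    if (is.null(calib)) stop("digital clip requires a calibration_spec")
    clip <- pressure_from_digital(if (is.matrix(clip$samples)) to_mono(clip)
                                  else clip, calib)
  }
  filtered <- bandpass(clip, band[1], band[2])
  nwin <- as.integer(window_s * clip$sample_rate)
  n <- clip_length(filtered)
  k <- n %/% nwin
  if (k == 0) {
    warning("window longer than clip; empty SPL series")
    return(data.frame(window_start_s = numeric(0), spl_db = numeric(0)))
  }
  x <- filtered$samples[seq_len(k * nwin)]
  rms <- sqrt(colMeans(matrix(x^2, nrow = nwin)))
  data.frame(window_start_s = (seq_len(k) - 1) * window_s,
             spl_db = spl(rms))
}
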