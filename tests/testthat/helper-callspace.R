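# Shared fixtures and independent oracles.

default_calib <- function() calibration_spec(mic_sensitivity = -36, gain = 36)

# pure tone clip at a given RMS pressure (Pa)
tone_clip <- function(freq, duration = 1, sample_rate = 44100,
                      rms_pa = NULL, amp = 1, units = "Pa") {
  t <- seq(0, duration - 1 / sample_rate, by = 1 / sample_rate)
  x <- amp * sin(2 * pi * freq * t)
  if (!is.null(rms_pa)) x <- x * rms_pa / sqrt(mean(x^2))
  audio_clip(x, sample_rate, units)
}

# independent masking-radius oracle: plain bisection on the level balance
bisect_radius <- function(s, n, ae, tol = 1e-13) {
  f <- function(r) s - 20 * log10(r) - ae * r - n
  lo <- 1e-12
  hi <- 1
  while (f(hi) > 0) hi <- hi * 2
  while ((hi - lo) > tol * hi) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# standard test scene: three frogs over road noise, SNR >= 25 dB
test_scene <- function(noise_db = 40, duration_s = 20, seed = 5) {
  frogs <- data.frame(
    frog_id = c("A", "B", "C"), distance_m = c(3, 6, 10),
    source_level_db = c(90, 92, 88),
    centroid_frequency_hz = c(2300, 2600, 2450),
    duration_s = c(0.25, 0.30, 0.20), call_rate_cpm = c(20, 15, 25))
  scene <- synthesize_scene(frogs, noise_db, duration_s,
                            calib = default_calib(), seed = seed)
  ann <- scene$truth[, c("begin_s", "end_s", "frog_id", "overlapped")]
  names(ann) <- c("begin", "end", "frog_id", "overlapped")
  list(frogs = frogs, scene = scene, ann = ann,
       distances = list(A = 3, B = 6, C = 10))
}
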