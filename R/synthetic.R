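# Forward simulation of sites, frog populations and calibrated audio scenes.
# Ground truth is carried alongside every synthetic artefact so the full
# measurement pipeline can be validated without field recordings.

# run expr with a locally-seeded RNG, restoring global state afterwards
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' Configuration for the synthetic frog/noise world
#'
#' Defaults encode the study system the package emulates: 8 wetland sites
#' along a road-noise gradient, 89 recorded male frogs, ambient noise
#' declining with the inverse square of road distance, and per-frog call
#' parameters governed by linear models in nightly temperature and site
#' noise. Default fixed-effect slopes are the field estimates for Pacific
#' chorus frogs (per 1 degC: +1.566 calls/min, +16.676 Hz, -0.048
#' log-duration, -0.179 dB source level; per 1 dB noise: -0.438 calls/min,
#' -4.422 Hz, +0.002 log-duration, +0.039 dB). Intercepts, variance
#' components and the source-level distribution are not published and are
#' set to realistic values for the species (see the package vignette).
#'
#' @param n_sites Number of sites.
#' @param site_distances_m Distance of each site to the nearest busy road, m.
#' @param noise_intercept,noise_slope,noise_residual_sd Ambient-noise model
#'   `n = intercept + slope / d_km^2 + eps` with distance in km; intercept
#'   and SD in dB re 20 uPa, slope in dB km^2.
#' @param n_frogs Total frogs across sites (round-robin allocation).
#' @param n_dates_per_site Recording nights per site.
#' @param temperature_range_c Nightly temperature range, degC (uniform draw
#'   per site-night; the field seasons average 9.59 degC).
#' @param fixed_effects Named list per response (`call_rate`,
#'   `centroid_frequency`, `log_duration`, `source_level`), each
#'   `c(intercept, temperature, noise)`.
#' @param random_effect_sds Named list per response of `c(site, date)` SDs.
#' @param residual_sds Named vector of per-response residual SDs.
#' @param source_level_mean,source_level_sd Population distribution of call
#'   source level at 1 m, dB re 20 uPa (placeholder Normal(90, 4); not
#'   published for this species, keep configurable).
#' @param seed Integer master seed; per-stage streams are derived from it.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(
    n_sites = 8L,
    site_distances_m = c(90, 100, 110, 120, 1200, 2000, 3000, 4000),
    noise_intercept = 37.44,
    noise_slope = 0.158,
    noise_residual_sd = 1,
    n_frogs = 89L,
    n_dates_per_site = 3L,
    temperature_range_c = c(4, 15),
    fixed_effects = list(
      call_rate          = c(intercept = 35,   temperature = 1.566,  noise = -0.438),
      centroid_frequency = c(intercept = 2440, temperature = 16.676, noise = -4.422),
      log_duration       = c(intercept = -1.0, temperature = -0.048, noise = 0.002),
      source_level       = c(intercept = 90,   temperature = -0.179, noise = 0.039)),
    random_effect_sds = list(
      call_rate          = c(site = 2,    date = 1.5),
      centroid_frequency = c(site = 40,   date = 25),
      log_duration       = c(site = 0.06, date = 0.04),
      source_level       = c(site = 1.5,  date = 1)),
    residual_sds = c(call_rate = 8, centroid_frequency = 120,
                     log_duration = 0.15, source_level = 4),
    source_level_mean = 90,
    source_level_sd = 4,
    seed = 1L) {
  if (length(site_distances_m) != n_sites)
    site_distances_m <- rep_len(site_distances_m, n_sites)
  if (any(site_distances_m <= 0)) stop("site distances must be > 0")
  if (n_frogs < 1) stop("n_frogs must be >= 1")
  sds <- c(noise_residual_sd, residual_sds, source_level_sd,
           unlist(random_effect_sds))
  if (any(sds < 0)) stop("all standard deviations must be >= 0")
  responses <- c("call_rate", "centroid_frequency", "log_duration",
                 "source_level")
  stopifnot(all(responses %in% names(fixed_effects)),
            all(responses %in% names(random_effect_sds)),
            all(responses %in% names(residual_sds)))
  structure(list(
    n_sites = as.integer(n_sites), site_distances_m = site_distances_m,
    noise_intercept = noise_intercept, noise_slope = noise_slope,
    noise_residual_sd = noise_residual_sd, n_frogs = as.integer(n_frogs),
    n_dates_per_site = as.integer(n_dates_per_site),
    temperature_range_c = temperature_range_c, fixed_effects = fixed_effects,
    random_effect_sds = random_effect_sds, residual_sds = residual_sds,
    source_level_mean = source_level_mean, source_level_sd = source_level_sd,
    seed = as.integer(seed)), class = "synthetic_config")
}

#' Mean evaluation temperature for communication-space summaries (degC)
#' @export
MEAN_EVAL_TEMPERATURE_C <- 9.59

#' Generate synthetic sites with ambient noise levels
#'
#' Median ambient noise follows the inverse-square law in road distance:
#' `n_i = intercept + slope / d_km_i^2 + eps_i`, `eps ~ N(0, residual_sd)`.
#'
#' @param config A [synthetic_config()].
#' @return `data.frame` with `site_id`, `distance_m`, `noise_db`.
#' @export
generate_sites <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  d_km <- config$site_distances_m / 1000
  with_local_seed(config$seed * 13L + 1L, {
    eps <- stats::rnorm(config$n_sites, 0, config$noise_residual_sd)
    data.frame(
      site_id = sprintf("S%02d", seq_len(config$n_sites)),
      distance_m = config$site_distances_m,
      noise_db = config$noise_intercept + config$noise_slope / d_km^2 + eps)
  })
}

#' Generate a synthetic frog population with known ground truth
#'
#' Each frog is allocated round-robin to a site and to a recording night
#' within it. Every response follows
#' `y = b0 + b_T * T + b_n * n + u_site + u_date(site) + eps`, with duration
#' generated on the natural-log scale and exponentiated. Call rates are
#' truncated at zero (draws below zero are rare under the defaults).
#'
#' @param sites Site table from [generate_sites()].
#' @param config A [synthetic_config()].
#' @return Truth table `data.frame`: `frog_id, site_id, date, temperature_c,
#'   noise_db, call_rate_cpm, centroid_frequency_hz, duration_s,
#'   source_level_db`.
#' @export
generate_frog_population <- function(sites, config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"), nrow(sites) >= 1)
  responses <- names(config$fixed_effects)
  with_local_seed(config$seed * 13L + 2L, {
    nf <- config$n_frogs
    site_idx <- rep_len(seq_len(nrow(sites)), nf)
    date_idx <- unlist(lapply(split(seq_len(nf), site_idx), function(i)
      rep_len(seq_len(config$n_dates_per_site), length(i))), use.names = FALSE)
    # put frogs back in original order after split
    ord <- order(unlist(split(seq_len(nf), site_idx), use.names = FALSE))
    date_idx <- date_idx[ord]
    key_site <- sites$site_id[site_idx]
    # season runs Feb-May; nights are spaced through it
    date0 <- as.Date("2015-02-15")
    key_date <- format(date0 + (site_idx - 1) + 7 * (date_idx - 1), "%Y-%m-%d")
    sd_keys <- paste(key_site, key_date, sep = "|")
    usd <- unique(sd_keys)
    temp_night <- stats::runif(length(usd), config$temperature_range_c[1],
                               config$temperature_range_c[2])
    names(temp_night) <- usd
    out <- data.frame(frog_id = sprintf("F%03d", seq_len(nf)),
                      site_id = key_site, date = key_date,
                      temperature_c = as.numeric(temp_night[sd_keys]),
                      noise_db = sites$noise_db[site_idx])
    for (resp in responses) {
      fe <- config$fixed_effects[[resp]]
      re <- config$random_effect_sds[[resp]]
      u_site <- stats::rnorm(nrow(sites), 0, re[["site"]])
      u_date <- stats::rnorm(length(usd), 0, re[["date"]])
      names(u_date) <- usd
      eps <- stats::rnorm(nf, 0, config$residual_sds[[resp]])
      y <- fe[["intercept"]] + fe[["temperature"]] * out$temperature_c +
        fe[["noise"]] * out$noise_db + u_site[site_idx] +
        as.numeric(u_date[sd_keys]) + eps
      out[[resp]] <- y
    }
    out$call_rate_cpm <- pmax(out$call_rate, 0)
    out$centroid_frequency_hz <- out$centroid_frequency
    out$duration_s <- exp(out$log_duration)
    out$source_level_db <- out$source_level
    out$call_rate <- out$centroid_frequency <- out$log_duration <-
      out$source_level <- NULL
    out
  })
}

#' Synthesize a single two-syllable frog call at 1 m
#'
#' The call is a three-component harmonic stack with the dominant component
#' at the requested centroid frequency and symmetric side components at 0.5x
#' and 1.5x (relative amplitude 0.3 each), so the energy-weighted centroid
#' equals `freq` exactly. Two raised-cosine-enveloped syllables occupy 35%
#' of the duration each, separated by a 30% gap. The waveform is scaled so
#' its RMS pressure over the call equals the requested source level.
#'
#' @param freq Target centroid frequency, Hz. For all components to stay in
#'   the 1-4.5 kHz analysis band, keep `freq` in roughly 2000-3000 Hz.
#' @param duration Call duration, s.
#' @param source_level Band-limited RMS SPL at 1 m, dB re 20 uPa.
#' @param sample_rate Sampling rate, Hz.
#' @return `audio_clip` in Pa units, length `round(duration * sample_rate)`.
#' @export
synthesize_call_clip <- function(freq, duration, source_level,
                                 sample_rate = 44100) {
  stopifnot(duration > 0)
  if (freq <= 0 || 1.5 * freq >= sample_rate / 2)
    stop("freq (and its 1.5x component) must lie below Nyquist")
  n <- max(8L, round(duration * sample_rate))
  t <- (seq_len(n) - 1) / sample_rate
  env <- numeric(n)
  syl_len <- max(4L, round(0.35 * n))
  hann <- function(m) 0.5 - 0.5 * cos(2 * pi * (seq_len(m) - 1) / (m - 1))
  env[seq_len(syl_len)] <- hann(syl_len)
  env[(n - syl_len + 1):n] <- hann(syl_len)
  x <- env * (0.3 * sin(2 * pi * 0.5 * freq * t) +
                1.0 * sin(2 * pi * freq * t) +
                0.3 * sin(2 * pi * 1.5 * freq * t))
  target <- pressure_from_spl(source_level)
  x <- x * target / sqrt(mean(x^2))
  audio_clip(x, sample_rate, "Pa")
}

# shaped road noise in Pa: first-order low-pass (corner f_c) white noise
# plus a -34 dB flat floor, scaled so the 1-4.5 kHz band SPL hits target_db
.road_noise <- function(n, sample_rate, target_db, band = c(1000, 4500),
                        corner_hz = 500) {
  w <- stats::rnorm(n)
  alpha <- exp(-2 * pi * corner_hz / sample_rate)
  lp <- as.numeric(stats::filter((1 - alpha) * w, alpha, method = "recursive"))
  shaped <- lp + 0.02 * stats::rnorm(n)
  clip <- audio_clip(shaped, sample_rate, "Pa")
  meas <- band_rms_spl(clip, band = band, window_s = n / sample_rate)
  gain <- pressure_from_spl(target_db) / pressure_from_spl(meas$spl_db[1])
  shaped * gain
}

#' Synthesize a calibrated recording scene: frogs over road noise
#'
#' Each frog calls periodically at its call rate; every call is attenuated
#' to its received level `RL = s - 20 log10(r) - A_e r` before mixing over
#' shaped road noise whose 1-4.5 kHz band SPL equals `noise_db`. The pressure
#' scene is rendered to digital units through the inverse calibration so the
#' measurement chain can reconstruct absolute levels.
#'
#' @param frogs `data.frame` with columns `frog_id, distance_m,
#'   source_level_db, centroid_frequency_hz, duration_s, call_rate_cpm`.
#'   May have zero rows (noise-only scene).
#' @param noise_db Road-noise band SPL (1-4.5 kHz), dB re 20 uPa.
#' @param duration_s Scene length, s.
#' @param params A [propagation_params()].
#' @param calib A [calibration_spec()].
#' @param sample_rate Sampling rate, Hz.
#' @param seed Integer seed; identical seed and arguments give bit-identical
#'   scenes.
#' @return List: `clip` (digital `audio_clip`), `truth` (selection table with
#'   `begin_s, end_s, low_freq_hz, high_freq_hz, frog_id, received_level_db`),
#'   `clipped` (count of digitally clipped samples, with a warning if > 0).
#' @export
synthesize_scene <- function(frogs, noise_db, duration_s,
                             params = propagation_params(),
                             calib = calibration_spec(-36, 36),
                             sample_rate = 44100, seed = 1L) {
  stopifnot(duration_s > 0)
  if (nrow(frogs) > 0 && any(frogs$distance_m <= 0))
    stop("frog distances must be > 0")
  n <- round(duration_s * sample_rate)
  with_local_seed(seed * 13L + 3L, {
    scene <- .road_noise(n, sample_rate, noise_db)
    truth <- list()
    if (nrow(frogs) > 0) {
      for (i in seq_len(nrow(frogs))) {
        f <- frogs[i, ]
        rl <- received_level(f$source_level_db, f$distance_m, params)
        call <- synthesize_call_clip(f$centroid_frequency_hz, f$duration_s,
                                     rl, sample_rate)
        period <- 60 / max(f$call_rate_cpm, 1e-6)
        t0 <- stats::runif(1, 0.1, min(period, duration_s / 4))
        starts <- seq(t0, duration_s - f$duration_s - 0.1, by = period)
        if (f$call_rate_cpm <= 0) starts <- numeric(0)
        for (st in starts) {
          i0 <- round(st * sample_rate) + 1
          idx <- i0:(i0 + clip_length(call) - 1)
          scene[idx] <- scene[idx] + call$samples
          truth[[length(truth) + 1L]] <- data.frame(
            begin_s = st, end_s = st + f$duration_s,
            low_freq_hz = max(1000, 0.5 * f$centroid_frequency_hz - 200),
            high_freq_hz = min(4500, 1.5 * f$centroid_frequency_hz + 200),
            frog_id = f$frog_id, received_level_db = rl)
        }
      }
    }
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(begin_s = numeric(0), end_s = numeric(0),
                 low_freq_hz = numeric(0), high_freq_hz = numeric(0),
                 frog_id = character(0), received_level_db = numeric(0))
    # flag calls that overlap (within a 0.05 s guard) a call from another frog
    truth$overlapped <- vapply(seq_len(nrow(truth)), function(i) {
      any(truth$frog_id != truth$frog_id[i] &
            truth$begin_s < truth$end_s[i] + 0.05 &
            truth$end_s > truth$begin_s[i] - 0.05)
    }, logical(1))
    digital <- digital_from_pressure(audio_clip(scene, sample_rate, "Pa"),
                                     calib)
    nclip <- sum(abs(digital$samples) > 1)
    if (nclip > 0) {
      warning(sprintf("%d sample(s) exceed digital full scale", nclip))
      digital$samples <- pmin(pmax(digital$samples, -1), 1)
    }
    list(clip = digital, truth = truth, clipped = nclip)
  })
}

#' Write a synthetic scenario to disk
#'
#' Renders the scene WAV (16-bit PCM), its truth selection table
#' (tab-separated, Raven dialect) and the site/frog tables as CSV.
#'
#' @param scene Result of [synthesize_scene()].
#' @param dir Output directory (created if needed).
#' @param stem File-name stem.
#' @return Invisibly, the paths written.
#' @export
write_scene <- function(scene, dir, stem = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wav <- file.path(dir, paste0(stem, ".wav"))
  sel <- file.path(dir, paste0(stem, "_selections.txt"))
  write_wav(scene$clip, wav)
  write_selection_table(
    data.frame(begin = scene$truth$begin_s, end = scene$truth$end_s,
               low_freq = scene$truth$low_freq_hz,
               high_freq = scene$truth$high_freq_hz,
               frog_id = scene$truth$frog_id), sel)
  invisible(c(wav = wav, selections = sel))
}
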