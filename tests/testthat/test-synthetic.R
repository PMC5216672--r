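test_that("generate_sites follows the inverse-square noise model", {
  # zero residual: pure arithmetic (intercept 37, slope 15, 1 km -> 52 dB)
  cfg <- synthetic_config(n_sites = 1, site_distances_m = 1000,
                          noise_intercept = 37, noise_slope = 15,
                          noise_residual_sd = 0)
  expect_equal(generate_sites(cfg)$noise_db, 52)
  # distance -> infinity: noise -> intercept
  cfg2 <- synthetic_config(n_sites = 1, site_distances_m = 1e9,
                           noise_intercept = 37, noise_slope = 15,
                           noise_residual_sd = 0)
  expect_equal(generate_sites(cfg2)$noise_db, 37, tolerance = 1e-9)
  # determinism under a fixed seed
  cfg3 <- synthetic_config(seed = 1)
  expect_identical(generate_sites(cfg3), generate_sites(cfg3))
  # validation
  expect_error(synthetic_config(site_distances_m = c(-1, rep(100, 7))),
               "> 0")
})

test_that("generate_frog_population reproduces the linear model exactly at zero variance", {
  zero_sds <- list(call_rate = c(site = 0, date = 0),
                   centroid_frequency = c(site = 0, date = 0),
                   log_duration = c(site = 0, date = 0),
                   source_level = c(site = 0, date = 0))
  cfg <- synthetic_config(
    n_sites = 2, site_distances_m = c(100, 2000), n_frogs = 10,
    noise_residual_sd = 0, temperature_range_c = c(10, 10),
    fixed_effects = list(
      call_rate = c(intercept = 30, temperature = 1.566, noise = 0),
      centroid_frequency = c(intercept = 2000, temperature = 16.676, noise = 0),
      log_duration = c(intercept = log(0.25), temperature = 0, noise = 0),
      source_level = c(intercept = 90, temperature = 0, noise = 0)),
    random_effect_sds = zero_sds,
    residual_sds = c(call_rate = 0, centroid_frequency = 0,
                     log_duration = 0, source_level = 0))
  frogs <- generate_frog_population(generate_sites(cfg), cfg)
  expect_equal(nrow(frogs), 10)
  # centroid = 2000 + 16.676 * 10 (noise slope zeroed)
  expect_equal(unique(frogs$centroid_frequency_hz), 2166.76)
  # log-duration intercept log(0.25), zero slopes -> duration 0.25 s
  expect_equal(unique(frogs$duration_s), 0.25)
  expect_equal(unique(frogs$source_level_db), 90)
  # frogs per site differ by at most 1
  expect_lte(diff(range(table(frogs$site_id))), 1)
})

test_that("population sample moments recover configured means (89 frogs, seed 7)", {
  cfg <- synthetic_config(seed = 7)
  sites <- generate_sites(cfg)
  frogs <- generate_frog_population(sites, cfg)
  expect_equal(nrow(frogs), 89)
  expect_true(all(is.finite(frogs$centroid_frequency_hz)))
  expect_true(all(frogs$duration_s > 0))
  expect_true(all(frogs$call_rate_cpm >= 0))
  # expected response means given realized covariates; SE from configured SDs
  t_bar <- mean(frogs$temperature_c)
  n_bar <- mean(frogs$noise_db)
  for (resp in c("call_rate", "centroid_frequency", "source_level")) {
    fe <- cfg$fixed_effects[[resp]]
    mu <- fe[["intercept"]] + fe[["temperature"]] * t_bar +
      fe[["noise"]] * n_bar
    re <- cfg$random_effect_sds[[resp]]
    se <- sqrt(re[["site"]]^2 / cfg$n_sites +
                 re[["date"]]^2 / (cfg$n_sites * cfg$n_dates_per_site) +
                 cfg$residual_sds[[resp]]^2 / cfg$n_frogs)
    col <- c(call_rate = "call_rate_cpm",
             centroid_frequency = "centroid_frequency_hz",
             source_level = "source_level_db")[[resp]]
    expect_lt(abs(mean(frogs[[col]]) - mu), 3 * se)
  }
  # determinism
  expect_identical(frogs, generate_frog_population(sites, cfg))
})

test_that("synthesized calls hit their level, length and centroid targets", {
  clip <- synthesize_call_clip(2400, 0.30, 90)
  expect_equal(clip_length(clip), 13230)
  meas <- band_rms_spl(clip, band = c(1000, 4500),
                       window_s = clip_duration(clip))
  expect_lt(abs(meas$spl_db - 90), 0.1)
  bin <- 44100 / 4096
  expect_lt(abs(centroid_frequency(clip) - 2400), bin)
  # amplitude scaling leaves the centroid unchanged
  scaled <- audio_clip(clip$samples * 37, clip$sample_rate, "Pa")
  expect_equal(centroid_frequency(scaled), centroid_frequency(clip))
  expect_error(synthesize_call_clip(20000, 0.3, 90, 44100), "Nyquist")
})

test_that("scenes follow the propagation model and are reproducible", {
  calib <- default_calib()
  one <- data.frame(frog_id = "A", distance_m = 10, source_level_db = 90,
                    centroid_frequency_hz = 2400, duration_s = 0.3,
                    call_rate_cpm = 10)
  sc <- synthesize_scene(one, noise_db = 30, duration_s = 8, calib = calib,
                         seed = 11)
  # received band SPL of a call: 90 - 20 log10(10) - 0.2*10 = 68 dB
  tr <- sc$truth[1, ]
  expect_equal(tr$received_level_db, 68)
  seg <- clip_segment(sc$clip, tr$begin_s, tr$end_s)
  m <- band_rms_spl(seg, calib, window_s = clip_duration(seg))
  expect_lt(abs(m$spl_db - 68), 0.2 + 0.05)  # noise floor 38 dB below
  # noise-only scene measures at the requested level
  sc0 <- synthesize_scene(one[0, ], noise_db = 52, duration_s = 5,
                          calib = calib, seed = 2)
  m0 <- band_rms_spl(sc0$clip, calib, window_s = 5)
  expect_lt(abs(m0$spl_db - 52), 0.2)
  expect_equal(nrow(sc0$truth), 0)
  # bit-identical under the same seed, including written WAV bytes
  sc2 <- synthesize_scene(one, noise_db = 30, duration_s = 8, calib = calib,
                          seed = 11)
  expect_identical(sc$clip$samples, sc2$clip$samples)
  d <- withr::local_tempdir()
  write_scene(sc, d, "a"); write_scene(sc2, d, "b")
  expect_identical(readBin(file.path(d, "a.wav"), "raw", 1e7),
                   readBin(file.path(d, "b.wav"), "raw", 1e7))
  # clipping is reported
  loud <- data.frame(frog_id = "A", distance_m = 1, source_level_db = 140,
                     centroid_frequency_hz = 2400, duration_s = 0.3,
                     call_rate_cpm = 30)
  expect_warning(sc3 <- synthesize_scene(loud, 40, 3, calib = calib,
                                         seed = 1), "full scale")
  expect_gt(sc3$clipped, 0)
})
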