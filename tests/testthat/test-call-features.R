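test_that("select_calls screens overlap flags and SNR thresholds", {
  ann <- data.frame(begin = c(1, 2, 3), end = c(1.3, 2.3, 3.3),
                    low_freq = 1000, high_freq = 4500,
                    overlapped = c(FALSE, TRUE, FALSE),
                    spl_db = c(70, 72, 55))
  kept <- select_calls(ann, min_snr = 10, ambient_db = 50)
  expect_equal(kept$begin, c(1))       # row 2 overlapped, row 3 SNR 5 < 10
  # threshold edge: SPL 55, ambient 50, min_snr 10 -> rejected
  expect_false(3 %in% kept$begin)
  # order preserved
  ann2 <- ann; ann2$overlapped <- FALSE; ann2$spl_db <- c(70, 71, 72)
  expect_equal(select_calls(ann2, 10, 50)$begin, c(1, 2, 3))
  # empty input passes through
  expect_equal(nrow(select_calls(ann[0, ], 10, 50)), 0)
})

test_that("call_duration applies the analysis buffer without changing duration", {
  cd <- call_duration(10.00, 10.30)
  expect_equal(cd$duration, 0.30)
  expect_equal(cd$window, c(9.95, 10.35))
  expect_equal(call_duration(10, 10.3, buffer_s = 0)$window, c(10, 10.3))
  expect_error(call_duration(5, 5), "end > begin")
  expect_warning(cd2 <- call_duration(0.02, 0.30, clip_duration_s = 0.32),
                 "clamped")
  expect_equal(cd2$window, c(0, 0.32))
  expect_equal(cd2$duration, 0.28)  # buffer never affects duration
})

test_that("centroid_frequency localizes tones within one FFT bin", {
  bin <- 44100 / 4096
  pure <- tone_clip(2000, 0.5)
  expect_lt(abs(centroid_frequency(pure) - 2000), bin)
  # equal-power tones at 1500/2500 -> symmetric centroid at 2000
  t <- seq(0, 0.5, by = 1 / 44100)
  two <- audio_clip(sin(2 * pi * 1500 * t) + sin(2 * pi * 2500 * t),
                    44100, "Pa")
  expect_lt(abs(centroid_frequency(two) - 2000), bin)
  # out-of-band tone is excluded from the weighting
  mix <- audio_clip(sin(2 * pi * 500 * t) + sin(2 * pi * 3000 * t),
                    44100, "Pa")
  expect_lt(abs(centroid_frequency(mix) - 3000), bin)
  # zero in-band energy -> NA
  silent <- audio_clip(numeric(22050), 44100, "Pa")
  expect_true(is.na(centroid_frequency(silent)))
})

test_that("source_level_1m inverts the propagation model", {
  p0 <- propagation_params(excess_attenuation = 0)
  p2 <- propagation_params(excess_attenuation = 0.2)
  expect_equal(source_level_1m(60, 2, p0), 66.0206, tolerance = 1e-4)
  expect_equal(source_level_1m(60, 1, p2), 60.2)
  expect_equal(source_level_1m(60, 10, p2), 82.0, tolerance = 1e-12)
  expect_error(source_level_1m(60, 0, p2), "> 0")
  # composition with the forward model is the identity
  for (r in c(0.5, 1, 7, 60)) {
    rl <- received_level(88, r, p2)
    expect_equal(source_level_1m(rl, r, p2), 88, tolerance = 1e-12)
  }
})

test_that("call_rate is calls per minute of recording", {
  expect_equal(call_rate(45, 90), 30)
  expect_equal(call_rate(0, 90), 0)
  expect_equal(call_rate(17, 210), 4.857143, tolerance = 1e-6)
  expect_error(call_rate(5, 0), "> 0")
})

test_that("aggregate_frog averages calls and flags empty frogs", {
  m <- data.frame(duration_s = c(0.2, 0.4),
                  centroid_frequency_hz = c(2300, 2500),
                  received_spl_db = c(70, 71), source_level_db = c(89, 91))
  rec <- aggregate_frog(m, rate = 12, "F1", "S1", "2015-03-01", 9)
  expect_equal(rec$duration_s, 0.3)
  expect_equal(rec$source_level_db, 90)
  expect_false(rec$excluded)
  single <- aggregate_frog(m[1, ], 12, "F1", "S1", "2015-03-01", 9)
  expect_equal(single$centroid_frequency_hz, 2300)
  empty <- aggregate_frog(m[0, ], 12, "F2", "S1", "2015-03-01", 9)
  expect_true(empty$excluded)
  expect_match(empty$reason, "no accepted calls")
})

test_that("full pipeline on a synthesized scene recovers ground truth", {
  fx <- test_scene(noise_db = 40, duration_s = 20, seed = 5)
  recs <- measure_scene(fx$scene$clip, fx$ann, default_calib(),
                        fx$distances, ambient_db = 40)
  recs <- recs[match(fx$frogs$frog_id, recs$frog_id), ]
  # source level within +-1 dB of truth
  expect_true(all(abs(recs$source_level_db - fx$frogs$source_level_db) < 1))
  # centroid within +-2 bins of the 11,025 Hz / 4096-pt analysis
  bin <- 11025 / 4096
  expect_true(all(abs(recs$centroid_frequency_hz -
                        fx$frogs$centroid_frequency_hz) < 2 * bin))
  # call rate equals the truth-annotation rate exactly
  counts <- table(fx$ann$frog_id)[fx$frogs$frog_id]
  expect_equal(recs$call_rate_cpm,
               as.numeric(counts) * 60 / clip_duration(fx$scene$clip))
  # duration is annotation-bounded, hence exact
  expect_equal(recs$duration_s, fx$frogs$duration_s, tolerance = 1e-9)
})

test_that("selection tables round-trip through the Raven dialect", {
  d <- withr::local_tempdir()
  path <- file.path(d, "sel.txt")
  ann <- data.frame(begin = c(1.5, 3.25), end = c(1.8, 3.6),
                    low_freq = c(1000, 1100), high_freq = c(4000, 4200),
                    frog_id = c("F1", "F2"), overlapped = c(FALSE, TRUE))
  write_selection_table(ann, path)
  hdr <- readLines(path, n = 1)
  expect_match(hdr, "Begin Time \\(s\\)\tEnd Time \\(s\\)")
  back <- read_selection_table(path)
  expect_equal(back$begin, ann$begin)
  expect_equal(back$high_freq, ann$high_freq)
  expect_identical(back$overlapped, ann$overlapped)
  expect_identical(back$frog_id, ann$frog_id)
  # packaged example parses too
  ex <- system.file("extdata", "example_selections.txt",
                    package = "callspace")
  expect_gt(nrow(read_selection_table(ex)), 0)
})
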