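zero_variance_config <- function(seed = 3) {
  synthetic_config(
    noise_residual_sd = 0,
    random_effect_sds = list(call_rate = c(site = 0, date = 0),
                             centroid_frequency = c(site = 0, date = 0),
                             log_duration = c(site = 0, date = 0),
                             source_level = c(site = 0, date = 0)),
    residual_sds = c(call_rate = 0, centroid_frequency = 0,
                     log_duration = 0, source_level = 0),
    seed = seed)
}

test_that("fit_lmm recovers generator truth exactly on noiseless data", {
  cfg <- zero_variance_config()
  frogs <- generate_frog_population(generate_sites(cfg), cfg)
  for (resp in c("call_rate", "centroid_frequency", "log_duration",
                 "source_level")) {
    f <- fit_lmm(frogs, resp)
    fe <- cfg$fixed_effects[[resp]]
    expect_lt(abs(lmm_effect(f, "noise")["estimate"] - fe[["noise"]]), 1e-6)
    expect_lt(abs(lmm_effect(f, "temperature")["estimate"] -
                    fe[["temperature"]]), 1e-6)
    expect_equal(f$n, nrow(frogs))
    expect_true(all(f$varcomp >= 0 | is.na(f$varcomp)))
  }
})

test_that("fit_lmm validates its design", {
  cfg <- synthetic_config(seed = 4)
  frogs <- generate_frog_population(generate_sites(cfg), cfg)
  one_site <- frogs[frogs$site_id == "S01", ]
  expect_error(fit_lmm(one_site, "call_rate"), "site")
  frogs2 <- frogs
  frogs2$temperature_c[3] <- NA
  expect_error(fit_lmm(frogs2, "call_rate"), "covariates")
  expect_error(fit_lmm(frogs[, setdiff(names(frogs), "duration_s")],
                       "log_duration"), "missing response")
})

test_that("duration is modeled on the log scale and only there", {
  cfg <- synthetic_config(seed = 6)
  frogs <- generate_frog_population(generate_sites(cfg), cfg)
  fd <- fit_lmm(frogs, "log_duration")
  expect_identical(fd$transform, "log")
  # changing durations leaves every other response's fit bit-identical
  frogs2 <- frogs
  frogs2$duration_s <- frogs2$duration_s * 3
  for (resp in c("call_rate", "centroid_frequency", "source_level")) {
    expect_identical(fit_lmm(frogs, resp)$coefficients,
                     fit_lmm(frogs2, resp)$coefficients)
  }
  # and the log fit shifts only its intercept
  fd2 <- fit_lmm(frogs2, "log_duration")
  expect_equal(fd2$coefficients$estimate[2:3], fd$coefficients$estimate[2:3],
               tolerance = 1e-9)
})

test_that("percent_change_per_unit back-transforms log-scale coefficients", {
  cfg <- zero_variance_config()
  frogs <- generate_frog_population(generate_sites(cfg), cfg)
  fd <- fit_lmm(frogs, "log_duration")
  # generator slope -0.048/degC -> 100 (1 - e^-0.048) = 4.6866% decrease
  expect_equal(percent_change_per_unit(fd, "temperature"), 4.686621,
               tolerance = 1e-4)
  # beta = 0 -> 0%; beta = ln(0.5) -> 50% (closed forms via a stub fit)
  stub <- fd
  stub$coefficients$estimate[3] <- 0
  expect_equal(percent_change_per_unit(stub, "temperature"), 0)
  stub$coefficients$estimate[3] <- log(0.5)
  expect_equal(percent_change_per_unit(stub, "temperature"), 50)
  fr <- fit_lmm(frogs, "call_rate")
  expect_error(percent_change_per_unit(fr, "temperature"), "log")
})

test_that("the masking-radius model inherits monotone noise dependence", {
  cfg <- synthetic_config(seed = 12)
  frogs <- generate_frog_population(generate_sites(cfg), cfg)
  fits <- fit_all_lmms(frogs)
  expect_named(fits, c("call_rate", "centroid_frequency", "log_duration",
                       "source_level", "radius"))
  # source level barely responds to noise, so radius must fall with noise
  expect_lt(lmm_effect(fits$radius, "noise")["estimate"], 0)
})

test_that("time_volume_comparison reproduces the quiet-gain/loud-loss pattern", {
  cfg <- synthetic_config(seed = 8)
  frogs <- generate_frog_population(generate_sites(cfg), cfg)
  fits <- fit_all_lmms(frogs)
  tv <- time_volume_comparison(fits, noise_db = c(26.82, 58.48))
  # with a negative rate-noise coefficient, adding the rate response raises
  # the time-volume at the quiet end and lowers it at the loud end
  expect_gt(tv$pct_change[1], 0)
  expect_lt(tv$pct_change[2], 0)
  # time-volume with fixed behaviour declines monotonically across noise
  grid <- time_volume_comparison(fits, noise_db = seq(26.82, 58.48,
                                                      length.out = 15))
  expect_true(all(diff(grid$tv_fixed_rate) < 0))
})
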