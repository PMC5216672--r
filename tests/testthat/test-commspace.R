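test_that("received_level follows spreading plus excess attenuation", {
  p0 <- propagation_params(excess_attenuation = 0)
  p2 <- propagation_params(excess_attenuation = 0.2)
  expect_equal(received_level(90, 1, p0), 90)
  expect_equal(received_level(90, 10, p2), 68)
  expect_equal(received_level(90, 100, p0), 50)  # 20 dB per decade
  expect_error(received_level(90, 0, p0), "> 0")
  r <- seq(0.5, 200, length.out = 50)
  expect_true(all(diff(received_level(85, r, p2)) < 0))
})

test_that("masking_radius matches closed forms and the bisection oracle", {
  p0 <- propagation_params(excess_attenuation = 0)
  expect_equal(as.numeric(masking_radius(90, 50, p0)), 100)
  expect_equal(as.numeric(masking_radius(70, 70, p0)), 1)
  r <- as.numeric(masking_radius(90, 50, propagation_params(0.2)))
  expect_equal(r, 39.9013, tolerance = 1e-4)
  # solver-oracle equivalence: <= 1e-9 relative error across the model range
  for (delta in c(-20, -10, 0, 10, 20, 40, 60, 80)) {
    for (ae in c(0, 0.01, 0.05, 0.2, 0.5, 1)) {
      pp <- propagation_params(excess_attenuation = ae)
      mine <- as.numeric(masking_radius(50 + delta, 50, pp))
      oracle <- bisect_radius(50 + delta, 50, ae)
      expect_lt(abs(mine - oracle) / oracle, 1e-9)
      # composition: RL(r*) returns the noise floor to 1e-6 dB
      expect_lt(abs(received_level(50 + delta, mine, pp) - 50), 1e-6)
    }
  }
  # detection threshold shifts the effective floor
  pt <- propagation_params(0, detection_threshold = 20)
  expect_equal(as.numeric(masking_radius(90, 50, pt)), 10)
  # sub-reference radii are flagged, not clamped
  rr <- masking_radius(60, 80, p0)
  expect_lt(as.numeric(rr), 1)
  expect_true(attr(rr, "sub_reference"))
})

test_that("masking_radius is monotone and approaches the spreading-only limit", {
  p <- propagation_params(0.2)
  s_grid <- seq(70, 100, by = 5)
  r_s <- as.numeric(masking_radius(s_grid, 50, p))
  expect_true(all(diff(r_s) > 0))            # increasing in s
  n_grid <- seq(30, 60, by = 5)
  r_n <- as.numeric(masking_radius(90, n_grid, p))
  expect_true(all(diff(r_n) < 0))            # decreasing in n
  ae_grid <- c(0.01, 0.05, 0.1, 0.3, 0.6, 1)
  r_a <- vapply(ae_grid, function(a)
    as.numeric(masking_radius(90, 50, propagation_params(a))), numeric(1))
  expect_true(all(diff(r_a) < 0))            # decreasing in A_e
  lim <- vapply(c(1e-3, 1e-5, 1e-7), function(a)
    as.numeric(masking_radius(90, 50, propagation_params(a))), numeric(1))
  expect_equal(lim[3], 100, tolerance = 1e-4)  # A_e -> 0 limit 10^((s-n)/20)
  expect_true(all(diff(abs(lim - 100)) < 0))
})

test_that("hemisphere_volume and time_volume match geometry and scale linearly", {
  expect_equal(hemisphere_volume(1), 2 * pi / 3, tolerance = 1e-12)
  expect_equal(hemisphere_volume(0), 0)
  expect_equal(hemisphere_volume(3), 18 * pi, tolerance = 1e-12)
  expect_error(hemisphere_volume(-1), ">= 0")
  # numeric shell integration oracle: V = int_0^r 2 pi rho^2 drho
  r <- 2.7
  rho <- seq(0, r, length.out = 20001)
  v_num <- sum(2 * pi * rho^2) * (rho[2] - rho[1]) -
    pi * r^2 * (rho[2] - rho[1])  # trapezoid end correction
  expect_lt(abs(v_num - hemisphere_volume(r)) / hemisphere_volume(r), 1e-3)
  expect_equal(time_volume(0.2, 30, 1), 12.56637, tolerance = 1e-5)
  expect_equal(time_volume(0.2, 0, 5), 0)
  expect_equal(time_volume(0.4, 30, 2), 2 * time_volume(0.2, 30, 2))
  expect_equal(time_volume(0.2, 60, 2), 2 * time_volume(0.2, 30, 2))
  expect_error(time_volume(-0.1, 30, 1), ">= 0")
})

test_that("barrier scenarios enlarge the radius by the insertion loss", {
  p <- propagation_params(0.2)
  sc <- barrier_scenario(90, 50, barrier_spec(5), p)
  expect_equal(sc$radius_before_m, 39.9013, tolerance = 1e-4)
  expect_equal(sc$radius_after_m,
               bisect_radius(90, 45, 0.2), tolerance = 1e-6)
  expect_gt(sc$delta_m, 0)
  expect_equal(sc$radius_after_m - sc$radius_before_m, sc$delta_m)
  # zero loss: no change
  expect_equal(barrier_scenario(90, 50, barrier_spec(0), p)$delta_m, 0)
  # pure spreading: 6.0206 dB of relief doubles the radius exactly
  p0 <- propagation_params(0)
  sc2 <- barrier_scenario(90, 50, barrier_spec(20 * log10(2)), p0)
  expect_equal(sc2$radius_after_m / sc2$radius_before_m, 2,
               tolerance = 1e-12)
  expect_error(barrier_spec(-1), ">= 0")
})
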