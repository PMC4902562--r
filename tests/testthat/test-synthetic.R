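test_that("make_bee_profile fills defaults and validates fields", {
  b <- make_bee_profile(seed = 1)
  expect_s3_class(b, "bee_profile")
  expect_equal(b$baseline_iaa, 96)
  expect_equal(b$sigmoid_amplitude, 35)
  expect_equal(b$of_threshold, 10)
  expect_equal(b$noise_sd, 0.8)

  # identical config + seed -> identical profile
  expect_identical(make_bee_profile(list(of_gain = 2), seed = 7),
                   make_bee_profile(list(of_gain = 2), seed = 7))

  expect_error(make_bee_profile(list(noise_sd = -1)), "noise_sd")
  expect_error(make_bee_profile(list(baseline_iaa = 200)), "baseline_iaa")
  expect_error(make_bee_profile(list(bogus = 1)), "bogus")

  # amplitude 0: flat airflow response
  b0 <- quiet_bee(sigmoid_amplitude = 0)
  tr <- simulate_iaa_trace(b0, build_protocol("linear_ramp_air"), seed = 1)
  expect_lt(diff(range(tr$iaa_deg)), 1e-9)
})

test_that("build_protocol reproduces the published protocol structure", {
  p1 <- build_protocol("linear_ramp_of")
  expect_equal(nrow(p1), 26)                       # 0-25 cps, 1 cps steps
  expect_equal(protocol_duration(p1), 26)          # 26 s total
  expect_equal(p1$tf_cps, 0:25)

  p2 <- build_protocol("low_range_of")
  expect_equal(protocol_duration(p2), 54)          # 54 s total
  expect_setequal(unique(p2$tf_cps[p2$role == "stim"]),
                  c(1.8, 1.5, 1.2, 0.9, 0.3, 0))

  p3 <- build_protocol("random_of", list(seed = 7))
  p4 <- build_protocol("random_of", list(seed = 7))
  expect_identical(p3$tf_cps, p4$tf_cps)           # seeded determinism
  expect_setequal(p3$tf_cps, 1:25)

  pa <- build_protocol("linear_ramp_air")
  expect_equal(pa$windspeed_mps, seq(0, 5.5, 0.5))
  expect_equal(attr(pa, "fps"), 500)

  pr <- build_protocol("regime", list(from = "B", to = "C", vary = "air"))
  expect_equal(pr$windspeed_mps, c(2.5, 4))
  expect_equal(pr$tf_cps, c(0, 0))                 # static grating

  expect_error(build_protocol("nope"), "unknown protocol kind")
  expect_error(build_protocol("linear_ramp_of", list(step = 0)),
               "non-positive step")
})

test_that("simulate_iaa_trace matches the set-point model", {
  # constant 0.5 m/s, no optic flow: mean ~ baseline, sd ~ sigma
  b <- make_bee_profile(seed = 1)
  p <- build_protocol("linear_ramp_air", list(levels = 0.5, epoch_s = 1))
  tr <- simulate_iaa_trace(b, p, seed = 3)
  expect_equal(nrow(tr), 500)
  st <- circ_mean_sd(tr$iaa_deg)
  expect_equal(st$mean, 96, tolerance = 0.2)
  expect_equal(st$sd, 0.8, tolerance = 0.2)

  # determinism: identical inputs -> bit-identical traces
  expect_identical(tr$iaa_deg, simulate_iaa_trace(b, p, seed = 3)$iaa_deg)

  # impulse-decay closed form: step 0 -> 5 cps then static
  bq <- quiet_bee()
  ps <- build_protocol("linear_ramp_of", list(levels = c(0, 5, 5, 5)))
  trs <- simulate_iaa_trace(bq, ps, seed = 1)
  tstep <- trs$time_s - 1  # impulse lands on the first 5-cps frame (t = 1 s)
  expected <- 96 + ifelse(tstep < 0, 0, 5 * exp(-tstep / 4))
  expect_equal(trs$iaa_deg, expected, tolerance = 1e-9)

  # steps entirely above threshold produce no set-point change (clip makes
  # the transition impulses zero; huge tau freezes the initial transient)
  ph <- build_protocol("linear_ramp_of", list(levels = c(15, 20, 15, 20)))
  trh <- simulate_iaa_trace(quiet_bee(adaptation_tau = 1e9), ph, seed = 1)
  expect_lt(diff(range(trh$iaa_deg)), 1e-6)
  expect_equal(trh$iaa_deg[1], 96 + 10, tolerance = 1e-9)  # clipped onset
})

test_that("set-point antagonism and saturation invariants hold", {
  bq <- quiet_bee()
  sp <- function(v, tf_impulse) {
    96 - 35 * plogis((v - 2.25) / 0.09) + 1 * tf_impulse
  }
  # increasing v alone lowers the set point
  expect_lt(sp(2.5, 0), sp(2.0, 0))
  # increasing tf below threshold alone raises it (impulse +)
  expect_gt(sp(2.25, 3), sp(2.25, 0))
  # v changes with both levels below 1.5 or above 3 m/s: < 0.5 deg
  expect_lt(abs(sp(1.0, 0) - sp(0.0, 0)), 0.5)
  expect_lt(abs(sp(5.5, 0) - sp(3.0, 0)), 0.5)
})

test_that("simulate_bin_means realizes the stated bin-mean models", {
  b <- quiet_bee()
  lv <- seq(0, 5.5, 0.5)
  air <- simulate_bin_means(b, lv, 5, mode = "air", seed = 1)
  # noise-free: samples equal bin mean exactly
  expect_equal(air$angles[[1]], rep(air$circ_mean[1], 5))
  # slow vs fast plateau difference ~ amplitude
  expect_equal(mean(air$circ_mean[lv <= 1.5]) -
                 mean(air$circ_mean[lv >= 3]), 35, tolerance = 0.01)

  ofr <- simulate_bin_means(b, c(5, 10, 15), 5, mode = "of_ramp", seed = 1)
  expect_equal(ofr$circ_mean[2], ofr$circ_mean[3])  # saturation at threshold
  expect_equal(ofr$circ_mean[2] - ofr$circ_mean[1], 5)

  lowr <- simulate_bin_means(b, c(0.3, 0.9), 5, mode = "of_low_range",
                             seed = 1)
  expect_equal(diff(lowr$circ_mean), 0.6, tolerance = 1e-9)

  expect_error(simulate_bin_means(b, numeric(0), 5), "non-empty")
  expect_error(simulate_bin_means(b, 1:3, 1), "n_per_bin")
})

test_that("simulate_geometry round-trips IAA and calibrates pixel noise", {
  bq <- quiet_bee()
  p <- build_protocol("linear_ramp_air", list(levels = c(0, 3), epoch_s = 0.05))
  tr <- simulate_iaa_trace(bq, p, seed = 1)
  g <- simulate_geometry(tr, pixel_noise = 0, seed = 1)
  rec <- reconstruct_antennae(g$landmarks, g$cameras)
  expect_equal(unname(rec$iaa_deg), tr$iaa_deg, tolerance = 1e-6)

  # fixed antennal length: zero variation at zero noise
  expect_equal(unname(digitization_error(rec$frames)), c(0, 0),
               tolerance = 1e-6)

  # tethered-level pixel noise gives 0.5-1.5% length variation;
  # free-flight-level noise gives 3-5%
  p2 <- build_protocol("linear_ramp_air", list(levels = 2, epoch_s = 0.6))
  tr2 <- simulate_iaa_trace(bq, p2, seed = 1)
  g_teth <- simulate_geometry(tr2, pixel_noise = 0.12, seed = 2)
  cv_teth <- digitization_error(reconstruct_antennae(g_teth$landmarks,
                                                     g_teth$cameras)$frames)
  expect_true(all(cv_teth >= 0.5 & cv_teth <= 1.5))
  g_free <- simulate_geometry(tr2, pixel_noise = 0.5, seed = 2)
  cv_free <- digitization_error(reconstruct_antennae(g_free$landmarks,
                                                     g_free$cameras)$frames)
  expect_true(all(cv_free >= 3 & cv_free <= 5))

  cam <- default_camera_rig()[[1]]
  expect_error(simulate_geometry(tr, cameras = list(cam, cam)),
               "parallel optical axes")
})

test_that("simulate_free_flight holds groundspeed against wind", {
  # zero noise: recovered groundspeed is exactly the target
  ff0 <- simulate_free_flight(2, groundspeed_target = 0.4,
                              noise = list(speed_sd = 0, pos_sd_mm = 0),
                              seed = 1)
  fs0 <- flight_speeds(as.matrix(ff0[, c("x_mm", "y_mm", "z_mm")]), 500,
                       windspeed_vector = 2)
  expect_equal(fs0$mean_groundspeed, 0.4, tolerance = 1e-9)
  expect_equal(fs0$mean_airspeed, 2.4, tolerance = 1e-9)  # collinear

  # default noise: mean groundspeed ~ target at every windspeed
  ff <- simulate_free_flight(seq(0, 3.5, 0.5), seed = 5)
  gs <- vapply(split(ff, ff$windspeed_mps), function(d)
    flight_speeds(as.matrix(d[, c("x_mm", "y_mm", "z_mm")]), 500,
                  windspeed_vector = d$windspeed_mps[1])$mean_groundspeed, 1)
  expect_true(all(abs(gs - 0.43) < 0.03))
  expect_identical(ff, simulate_free_flight(seq(0, 3.5, 0.5), seed = 5))
  expect_error(simulate_free_flight(1, groundspeed_target = 0))
})
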