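ramp_of_bins <- function(gain = 1.5, theta = 10, noise = 1, n = 50,
                         seed = 1) {
  bee <- make_bee_profile(list(of_gain = gain, of_threshold = theta,
                               noise_sd = noise), seed = seed)
  simulate_bin_means(bee, 1:25, n, mode = "of_ramp", seed = seed)
}

test_that("detect_threshold recovers the generator saturation point", {
  thr <- detect_threshold(ramp_of_bins(seed = 2), seed = 2)
  expect_equal(thr$threshold, 10)
  expect_equal(thr$flag, "ok")
  expect_equal(dim(thr$p_matrix), c(24, 24))  # first-stimulus bin excluded

  thr14 <- detect_threshold(ramp_of_bins(theta = 14, seed = 3), seed = 3)
  expect_equal(thr14$threshold, 14)

  # flat bins: minimum tf returned with flag
  flat <- ramp_of_bins(gain = 0, seed = 4)
  thr0 <- detect_threshold(flat, seed = 4)
  expect_equal(thr0$threshold, 2)  # smallest level after first-bin exclusion
  expect_equal(thr0$flag, "all_saturated")

  expect_error(detect_threshold(ramp_of_bins(seed = 1)[1:4, ]), "at least 5")
})

test_that("predict_transitions enumerates and classifies steps correctly", {
  set.seed(5)
  for (i in 1:5) {
    perm <- sample(1:25)
    pred <- predict_transitions(perm, 10)
    expect_equal(nrow(pred), 23)  # 25 stimuli -> 23 scored transitions
    # direction nonzero exactly when change is predicted
    expect_true(all((pred$predicted_direction != 0) == pred$predicted_change))
  }

  # hand cases at threshold 10
  pred <- predict_transitions(c(1, 15, 20, 12, 6, 9, 10, 14), 10)
  expect_false(pred$predicted_change[pred$tf_from == 15])   # 15 -> 20
  row <- pred[pred$tf_from == 12 & pred$tf_to == 6, ]
  expect_true(row$predicted_change)                         # 12 -> 6
  expect_equal(row$predicted_direction, -1L)
  # exactly-at-threshold upward: clip difference zero, no change predicted
  row2 <- pred[pred$tf_from == 10, ]
  expect_false(row2$predicted_change)

  expect_error(predict_transitions(c(1, 2), 10), "length >= 3")
})

test_that("predictions depend on the sequence only through clipped values", {
  set.seed(6)
  for (i in 1:20) {
    perm <- sample(1:25)
    capped <- ifelse(perm > 10, 11, perm)
    expect_identical(predict_transitions(perm, 10)[, 4:5],
                     predict_transitions(capped, 10)[, 4:5])
  }
})

test_that("noise-free model bins give perfect scores for any permutation", {
  # 16 samples/bin: a change call at alpha 0.005 needs the attainable p
  # (about 2/2^n for a consistent difference) below 0.005, so n >= 10
  bee <- quiet_bee(of_gain = 1.5)
  set.seed(8)
  for (i in 1:100) {
    perm <- sample(1:25)
    bins <- simulate_bin_means(bee, perm, 16, mode = "of_ramp", seed = i)
    ev <- evaluate_predictions(bins, perm, 10, n_perm = 999, seed = i)
    expect_equal(ev$scores$motion_score, 1)
    expect_equal(ev$scores$direction_score, 1)
    expect_equal(ev$scores$n_scored, 23)
  }
})

test_that("classify_observed_transitions is calibrated on null generators", {
  # gamma = 0: no real changes; at alpha 0.005 false alarms are rare
  bee0 <- make_bee_profile(list(of_gain = 0, noise_sd = 1), seed = 1)
  seq1 <- build_protocol("random_of", list(seed = 2))$tf_cps
  bins <- simulate_bin_means(bee0, seq1, 50, mode = "of_ramp", seed = 2)
  obs <- classify_observed_transitions(bins, seed = 2)
  expect_lte(sum(obs$observed_change), 2)
  expect_true(all(obs$observed_direction[!obs$observed_change] == 0))

  # identical bins: p = 1, no change
  same <- bins
  same$angles <- lapply(seq_len(nrow(same)), function(i) same$angles[[1]])
  same$circ_mean <- rep(same$circ_mean[1], nrow(same))
  obs2 <- classify_observed_transitions(same, seed = 1)
  expect_true(all(obs2$p == 1))
  expect_false(any(obs2$observed_change))
  expect_error(classify_observed_transitions(bins[1, ]), "at least 2")
})

test_that("score_predictions computes fraction-correct scores", {
  rec <- data.frame(predicted_change = c(TRUE, TRUE, FALSE, FALSE),
                    predicted_direction = c(1L, -1L, 0L, 0L),
                    observed_change = c(TRUE, FALSE, FALSE, TRUE),
                    observed_direction = c(1L, 0L, 0L, -1L))
  sc <- score_predictions(rec)
  expect_equal(sc$motion_score, 0.5)
  expect_equal(sc$direction_score, 0.5)
  expect_equal(sc$n_scored, 4)
  # 19 of 23 correct -> 0.83 at 2 d.p.
  expect_equal(round(19 / 23, 2), 0.83)
  expect_error(score_predictions(rec[0, ]), "no records")
})

test_that("scramble_significance separates signal from scrambled null", {
  bee <- make_bee_profile(list(noise_sd = 0.1), seed = 1)
  seqs <- build_protocol("random_of", list(seed = 3))$tf_cps
  bins <- simulate_bin_means(bee, seqs, 30, mode = "of_ramp", seed = 3)
  scr <- scramble_significance(bins, seqs, 10, n_scrambles = 150, seed = 3,
                               n_perm = 399)
  expect_lt(scr$p_motion, 0.01)
  expect_lt(scr$p_direction, 0.01)
  expect_equal(scr$observed$motion_score, 1, tolerance = 0.05)
  # scrambled scores sit well below the observed score
  expect_lt(mean(scr$scramble_scores$motion), 0.8)

  # null calibration: scrambled input is itself exchangeable, p not small
  set.seed(99)
  null_bins <- bins[sample.int(nrow(bins)), ]
  scr0 <- scramble_significance(null_bins, seqs, 10, n_scrambles = 150,
                                seed = 4, n_perm = 399)
  expect_gt(scr0$p_motion, 0.05)
  expect_error(scramble_significance(bins, seqs, 10, n_scrambles = 50),
               ">= 100")
})

test_that("low_range_response shows a graded increase; flat for gamma 0", {
  bees <- make_bee_population(9, seed = 15)
  proto <- build_protocol("low_range_of")
  traces <- lapply(seq_along(bees), function(i)
    simulate_iaa_trace(bees[[i]], proto, seed = 150 + i))
  lr <- low_range_response(traces, seed = 15)
  expect_equal(lr$levels, c(0, 0.3, 0.9, 1.2, 1.5, 1.8))
  expect_gt(lr$slope, 0)
  # graded increasing response (tight correlation; adjacent deltas at the
  # bottom of the range sit near the noise floor, so no strict ordering)
  expect_gt(stats::cor(lr$levels, lr$mean_response), 0.7)
  expect_gt(lr$mean_response[6], lr$mean_response[1])
  expect_true(all(lr$normalized >= 0 & lr$normalized <= 1))

  # gamma = 0 bees: flat response
  b0 <- quiet_bee(of_gain = 0)
  lr0 <- low_range_response(simulate_iaa_trace(b0, proto, seed = 1))
  expect_lt(diff(range(lr0$mean_response)), 0.5)  # only onset residue
})

test_that("sinusoid_tracking matches the first-order filter closed form", {
  proto <- build_protocol("sinusoid_of", list(dt = 0.02))
  bee <- quiet_bee()
  tr <- simulate_iaa_trace(bee, proto, seed = 1)
  st <- sinusoid_tracking(tr, period = 10)
  w <- 2 * pi / 10; tau <- 4
  expect_equal(st$gain, w * tau / sqrt(1 + (w * tau)^2), tolerance = 0.02)
  # first-order change detector *leads* the stimulus by atan-complement
  expect_equal(st$phase_lag_s, -(pi / 2 - atan(w * tau)) / w,
               tolerance = 0.02)
  expect_gt(st$correlation, 0.75)

  # gamma = 0: no tracking
  tr0 <- simulate_iaa_trace(quiet_bee(of_gain = 0, noise_sd = 0.1), proto,
                            seed = 2)
  expect_lt(abs(sinusoid_tracking(tr0, 10)$correlation), 0.1)
  expect_error(sinusoid_tracking(tr[tr$time_s < 5, ], 10), "shorter")
})
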