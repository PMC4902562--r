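# Optic-flow response analysis: per-bee saturation threshold, transition
# prediction and scoring with a scrambled-data null, low-range graded
# response, and sinusoid tracking.
#
# The behavioural model under test: the antennae track *changes* in grating
# temporal frequency, not its absolute value, and only while at least one of
# the two levels lies below a per-bee saturation threshold.

#' Detect the optic-flow saturation threshold of one bee
#'
#' Finds the smallest temporal frequency tf* such that the IAA bins at and
#' above tf* are mutually indistinguishable: all pairwise Moore's paired
#' tests within that set are non-significant, judged family-wise with a Holm
#' correction (the all-pairs family grows quadratically, so per-comparison
#' testing at alpha would reject a true saturation set almost surely). The
#' first-stimulus bin is excluded: the response to the first value reflects
#' onset positioning and is always distinguishable.
#'
#' @param bins a `bin_summary` ordered by tf (ascending levels).
#' @param alpha family-wise significance level (default 0.05).
#' @param n_perm Moore permutations per pair (default 9999: the smallest
#'   attainable p, 1/(n_perm+1), must stay below alpha divided by the
#'   largest family size, 276 pairs for a 25-level ramp, for Holm-adjusted
#'   decisions to resolve).
#' @param seed integer seed for the permutation draws and bin pairing.
#' @param exclude_first drop the first-stimulus bin (default TRUE).
#' @return list with `threshold` (cps), `flag` ("ok", "none_qualify" when
#'   even the top set differs, or "all_saturated" when the full set already
#'   qualifies), `p_matrix` (all-pairs Moore p-values for audit) and
#'   `levels` (the levels tested).
#' @export
detect_threshold <- function(bins, alpha = 0.05, n_perm = 9999, seed = 1,
                             exclude_first = TRUE) {
  if (nrow(bins) < 5L) stop("need at least 5 bins", call. = FALSE)
  if (is.unsorted(bins$level))
    stop("bins must be ordered by ascending tf", call. = FALSE)
  if (exclude_first) bins <- bins[-1L, ]
  m <- nrow(bins)
  pm <- matrix(NA_real_, m, m, dimnames = list(bins$level, bins$level))
  for (i in seq_len(m - 1)) {
    for (j in seq.int(i + 1, m)) {
      pr <- pair_bins(bins$angles[[i]], bins$angles[[j]],
                      seed = seed + 1000L * i + j)
      mt <- moore_paired_test(pr$alpha, pr$beta, n_perm = n_perm,
                              seed = seed + 1000L * i + j)
      pm[i, j] <- pm[j, i] <- mt$p
    }
  }
  for (k in seq_len(m - 1)) {
    idx <- k:m
    ps <- pm[idx, idx][upper.tri(diag(length(idx)))]
    if (all(stats::p.adjust(ps, method = "holm") >= alpha)) {
      flag <- if (k == 1L) "all_saturated" else "ok"
      return(list(threshold = bins$level[k], flag = flag, p_matrix = pm,
                  levels = bins$level))
    }
  }
  list(threshold = bins$level[m], flag = "none_qualify", p_matrix = pm,
       levels = bins$level)
}

clip01 <- function(tf, threshold) pmin(pmax(tf, 0), threshold)

#' Predict IAA changes across a stimulus sequence
#'
#' For a sequence of temporal frequencies and a saturation threshold, the
#' IAA is predicted to change at a transition when the stimulus change
#' occurs below or across threshold, i.e. when `min(tf_from, tf_to) <
#' threshold`; the predicted direction is the sign of the change in
#' threshold-clipped tf (+1 = IAA increase for low-to-high). The transition
#' out of the first stimulus is excluded from scoring (the first response
#' reflects onset positioning), so a sequence of length L yields L - 2
#' scored transitions (23 for the 25-value protocols).
#'
#' @param sequence ordered tf values (cps), length >= 3.
#' @param threshold saturation threshold (cps).
#' @return data.frame of class `prediction_record`: `transition` (index of
#'   the step k -> k+1), `tf_from`, `tf_to`, `predicted_change`,
#'   `predicted_direction` (0 when no change is predicted).
#' @export
predict_transitions <- function(sequence, threshold) {
  L <- length(sequence)
  if (L < 3L) stop("sequence must have length >= 3", call. = FALSE)
  check_num(threshold, "threshold", 0, open_lower = TRUE)
  k <- 2:(L - 1)
  from <- sequence[k]; to <- sequence[k + 1]
  change <- pmin(from, to) < threshold
  dirn <- sign(clip01(to, threshold) - clip01(from, threshold))
  dirn[!change] <- 0
  structure(data.frame(transition = k, tf_from = from, tf_to = to,
                       predicted_change = change,
                       predicted_direction = as.integer(dirn)),
            class = c("prediction_record", "data.frame"))
}

#' Classify observed IAA transitions
#'
#' For each consecutive pair of sequence-ordered bins, tests whether the IAA
#' changed using Moore's paired test (equal-index frame pairing, larger bin
#' subsampled) at `alpha` (default 0.005, the level used for observed-change
#' calls). The observed direction is the sign of the wrapped circular-mean
#' difference when a change is observed, else 0.
#'
#' @param bins a `bin_summary` in sequence order (one bin per stimulus
#'   epoch; `sort_levels = FALSE` in [bin_by_level()]).
#' @param alpha per-transition significance level (default 0.005).
#' @param n_perm Moore permutations (default 999).
#' @param seed integer seed.
#' @param transitions which steps k -> k+1 to classify (default all).
#' @return data.frame: `transition`, `observed_change`,
#'   `observed_direction`, `p`.
#' @export
classify_observed_transitions <- function(bins, alpha = 0.005, n_perm = 999,
                                          seed = 1, transitions = NULL) {
  L <- nrow(bins)
  if (L < 2L) stop("need at least 2 bins", call. = FALSE)
  if (any(bins$n < 4L)) stop("bins must hold at least 4 samples", call. = FALSE)
  if (is.null(transitions)) transitions <- seq_len(L - 1)
  out <- data.frame(transition = transitions, observed_change = NA,
                    observed_direction = 0L, p = NA_real_)
  for (r in seq_along(transitions)) {
    k <- transitions[r]
    pr <- pair_bins(bins$angles[[k]], bins$angles[[k + 1]], seed = seed + k)
    mt <- moore_paired_test(pr$alpha, pr$beta, n_perm = n_perm,
                            seed = seed + k)
    chg <- mt$p < alpha
    out$observed_change[r] <- chg
    out$p[r] <- mt$p
    if (chg) {
      d <- wrap_diff_deg(bins$circ_mean[k + 1] - bins$circ_mean[k])
      out$observed_direction[r] <- as.integer(sign(d))
    }
  }
  out
}

#' Score predictions against observed transitions
#'
#' The motion score is the fraction of scored transitions whose
#' predicted-change call matches the observed-change call; the direction
#' score is the fraction whose predicted direction matches the observed
#' direction, counted over all scored transitions (a no-change prediction
#' matched by no observed change counts correct), so both scores share one
#' denominator.
#'
#' @param records a `prediction_record` data.frame carrying
#'   `observed_change` and `observed_direction` columns (see
#'   [evaluate_predictions()]).
#' @return list with `motion_score`, `direction_score`, `n_scored`.
#' @export
score_predictions <- function(records) {
  if (nrow(records) < 1L) stop("no records to score", call. = FALSE)
  needed <- c("predicted_change", "predicted_direction",
              "observed_change", "observed_direction")
  if (!all(needed %in% names(records)))
    stop("records lack observed columns; run evaluate_predictions()",
         call. = FALSE)
  list(motion_score = mean(records$predicted_change == records$observed_change),
       direction_score = mean(records$predicted_direction ==
                                records$observed_direction),
       n_scored = nrow(records))
}

#' Predict, classify and score a full transition series
#'
#' Convenience composition: predictions from the sequence and threshold,
#' observed calls from the sequence-ordered bins, joined into one audit
#' table with correctness flags.
#'
#' @inheritParams predict_transitions
#' @param bins sequence-ordered `bin_summary` (one bin per stimulus).
#' @inheritParams classify_observed_transitions
#' @return list with `records` (audit data.frame, one row per scored
#'   transition with `motion_correct`/`direction_correct`) and `scores`
#'   (from [score_predictions()]).
#' @export
evaluate_predictions <- function(bins, sequence = bins$level, threshold,
                                 alpha = 0.005, n_perm = 999, seed = 1) {
  if (nrow(bins) != length(sequence))
    stop("one bin per sequence element required", call. = FALSE)
  pred <- predict_transitions(sequence, threshold)
  obs <- classify_observed_transitions(bins, alpha = alpha, n_perm = n_perm,
                                       seed = seed,
                                       transitions = pred$transition)
  rec <- cbind(pred, obs[, c("observed_change", "observed_direction", "p")])
  rec$motion_correct <- as.integer(rec$predicted_change == rec$observed_change)
  rec$direction_correct <-
    as.integer(rec$predicted_direction == rec$observed_direction)
  list(records = rec, scores = score_predictions(rec))
}

#' Scrambled-data significance of prediction scores
#'
#' Re-scores the same per-bin responses after randomly permuting their
#' assignment to stimulus positions (whole-bin blocks, preserving within-bin
#' correlation), `n_scrambles` times. Reports the empirical permutation
#' p-value `(count of scramble scores >= observed + 1)/(n_scrambles + 1)`
#' for both scores, and (for comparison with the originally reported
#' analysis) a one-sample Student's t test of the scrambled score
#' distribution against the observed value.
#'
#' @inheritParams evaluate_predictions
#' @param n_scrambles number of scrambles (>= 100; default 1000).
#' @param seed integer seed.
#' @param n_perm Moore permutations inside each scramble (default 399; the
#'   classification alpha of 0.005 stays resolvable).
#' @return list with `p_motion`, `p_direction`, `t_test_motion`,
#'   `t_test_direction`, `observed` (scores), `scramble_scores`
#'   (data.frame), `n_scrambles`, `seed`.
#' @export
scramble_significance <- function(bins, sequence = bins$level, threshold,
                                  n_scrambles = 1000, seed = 1,
                                  alpha = 0.005, n_perm = 399) {
  if (n_scrambles < 100L) stop("n_scrambles must be >= 100", call. = FALSE)
  obs <- evaluate_predictions(bins, sequence, threshold, alpha = alpha,
                              n_perm = n_perm, seed = seed)
  L <- nrow(bins)
  perms <- local_seed(seed, replicate(n_scrambles, sample.int(L),
                                      simplify = FALSE))
  sc <- vapply(seq_len(n_scrambles), function(s) {
    b <- bins[perms[[s]], ]
    b$circ_mean <- bins$circ_mean[perms[[s]]]
    b$angles <- bins$angles[perms[[s]]]
    ev <- evaluate_predictions(b, sequence, threshold, alpha = alpha,
                               n_perm = n_perm, seed = seed + s)
    c(ev$scores$motion_score, ev$scores$direction_score)
  }, numeric(2))
  p_emp <- function(x, o) (sum(x >= o - 1e-12) + 1) / (n_scrambles + 1)
  tt <- function(x, o) {
    if (sd(x) < 1e-12) return(NA_real_)
    stats::t.test(x, mu = o)$p.value
  }
  list(p_motion = p_emp(sc[1, ], obs$scores$motion_score),
       p_direction = p_emp(sc[2, ], obs$scores$direction_score),
       t_test_motion = tt(sc[1, ], obs$scores$motion_score),
       t_test_direction = tt(sc[2, ], obs$scores$direction_score),
       observed = obs$scores,
       scramble_scores = data.frame(motion = sc[1, ], direction = sc[2, ]),
       n_scrambles = n_scrambles, seed = seed)
}

#' Low-range graded optic-flow response
#'
#' Analyzes the 0-1.8 cps protocol (6 s moving gratings interleaved with 3 s
#' static screens): bins the IAA per temporal frequency (moving epochs
#' only), tests each 0.3 cps step with Moore's paired test, and reports a
#' per-bee min/max-normalized response. With a list of traces (one per bee)
#' the step tests pair per-bee bin means across bees; with a single trace
#' they pair frames within the bee.
#'
#' @param traces an `iaa_trace` or list of them.
#' @param frames_per_bin steady-state frames per epoch (default 50, the
#'   count digitized per temporal frequency in the low-range recordings).
#' @param alpha step significance level (default 0.05).
#' @param n_perm Moore permutations (default 1024).
#' @param seed integer seed.
#' @return list with `levels`, `mean_response` (per-level grand mean, deg),
#'   `normalized` (bees x levels matrix in \[0, 1\]), `steps` (data.frame
#'   with p-values), `slope` (deg per cps, least squares on per-bee means),
#'   `per_bee_bins`.
#' @export
low_range_response <- function(traces, frames_per_bin = 50, alpha = 0.05,
                               n_perm = 1024, seed = 1) {
  if (inherits(traces, "iaa_trace")) traces <- list(traces)
  per_bee <- lapply(traces, function(tr) {
    if (!"role" %in% names(tr)) {
      # moving epochs are those whose tf matches a stim epoch; static
      # screens share tf = 0 with the 0-cps level, so use epoch parity of
      # the generating protocol: stim epochs are the odd ones.
      stim_epochs <- unique(tr$epoch)[seq(1, length(unique(tr$epoch)), by = 2)]
    } else stim_epochs <- unique(tr$epoch[tr$role == "stim"])
    bin_by_level(tr, by = "tf", frames_per_bin = frames_per_bin,
                 sort_levels = TRUE, epochs = stim_epochs)
  })
  lv <- per_bee[[1]]$level
  means <- t(vapply(per_bee, function(b) b$circ_mean, numeric(length(lv))))
  n_bee <- nrow(means)
  steps <- data.frame(from = lv[-length(lv)], to = lv[-1], p = NA_real_)
  for (j in seq_len(length(lv) - 1)) {
    if (n_bee >= 4L) {
      mt <- moore_paired_test(means[, j], means[, j + 1], n_perm = n_perm,
                              seed = seed + j)
    } else {
      pr <- pair_bins(per_bee[[1]]$angles[[j]], per_bee[[1]]$angles[[j + 1]],
                      seed = seed + j)
      mt <- moore_paired_test(pr$alpha, pr$beta, n_perm = n_perm,
                              seed = seed + j)
    }
    steps$p[j] <- mt$p
  }
  steps$significant <- steps$p < alpha
  norm <- t(apply(means, 1, function(m) (m - min(m)) / (max(m) - min(m))))
  slope <- as.numeric(coef(lm(c(means) ~ rep(lv, each = n_bee)))[2])
  list(levels = lv, mean_response = colMeans(means), normalized = norm,
       steps = steps, slope = slope, per_bee_bins = per_bee)
}

#' Track a sinusoidal optic-flow stimulus
#'
#' Fits sinusoids at the stimulus period to both the (signed) temporal
#' frequency and the IAA by least squares, and reports the response gain
#' (IAA amplitude per tf amplitude, deg per cps), the phase lag (s, positive
#' when the response trails the stimulus) and the stimulus-response
#' correlation.
#'
#' @param trace an `iaa_trace` from a sinusoidal protocol.
#' @param period stimulus period in s (default: the protocol's period,
#'   carried on the trace, else 10).
#' @return list with `gain`, `phase_lag_s`, `correlation`,
#'   `stim_amplitude`, `iaa_amplitude`.
#' @export
sinusoid_tracking <- function(trace, period = NULL) {
  if (is.null(period)) {
    period <- attr(trace, "period")
    if (is.null(period)) period <- 10
  }
  tmax <- max(trace$time_s)
  if (tmax < period)
    stop("trace shorter than one stimulus period", call. = FALSE)
  w <- 2 * pi / period
  s <- sin(w * trace$time_s); c_ <- cos(w * trace$time_s)
  fit_wave <- function(y) {
    cf <- coef(lm(y ~ s + c_))
    list(amplitude = as.numeric(sqrt(cf[2]^2 + cf[3]^2)),
         phase = atan2(cf[[3]], cf[[2]]))  # y ~ amp * sin(wt + phase)
  }
  stim <- fit_wave(trace$tf_cps)
  resp <- fit_wave(trace$iaa_deg)
  if (stim$amplitude < 1e-9) stop("stimulus is not sinusoidal", call. = FALSE)
  dphi <- (resp$phase - stim$phase + pi) %% (2 * pi) - pi
  list(gain = resp$amplitude / stim$amplitude,
       phase_lag_s = -dphi / w,
       correlation = stats::cor(trace$tf_cps, trace$iaa_deg),
       stim_amplitude = stim$amplitude, iaa_amplitude = resp$amplitude)
}
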