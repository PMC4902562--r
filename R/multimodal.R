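# Combined-cue analyses: regime antagonism, constant-cue offset
# classification, crossmodal speedometer calibration.

#' Regime transition ΔIAA analysis
#'
#' Quantifies antennal responses to step changes between bimodal stimulus
#' regimes (A = 0.5 m/s + 0.3 cps, B = 2.5 m/s + 0.9 cps, C = 4 m/s +
#' 1.8 cps) under three manipulations: airflow only, optic flow only, or
#' both cues co-varied. ΔIAA is the wrapped circular difference of the
#' post-transition and regime-B bin means per bee. Per condition, a Moore's
#' paired test compares the before/after per-bee means across bees; all
#' conditions then enter [delta_vs_zero_tests()] (ANOVA + Tukey HSD
#' including the hypothetical zero mean). Airflow and optic flow act
#' antagonistically, so co-varied steps should leave ΔIAA near zero while
#' single-cue steps shift it.
#'
#' @param trials data.frame with columns `bee`, `condition` (e.g. "air",
#'   "of", "both"), `phase` ("B" or "post") and `iaa_deg` (frame samples).
#' @param alpha significance level (default 0.05).
#' @param n_perm Moore permutations (default 1024).
#' @param seed integer seed.
#' @return list with `delta` (data.frame: bee, condition, delta_iaa),
#'   `moore` (per-condition test results), `anova_tukey` (from
#'   [delta_vs_zero_tests()]).
#' @export
regime_delta_analysis <- function(trials, alpha = 0.05, n_perm = 1024,
                                  seed = 1) {
  needed <- c("bee", "condition", "phase", "iaa_deg")
  if (!all(needed %in% names(trials)))
    stop("trials must have columns bee, condition, phase, iaa_deg",
         call. = FALSE)
  if (!all(c("B", "post") %in% unique(trials$phase)))
    stop("missing phase: need both 'B' and 'post' samples", call. = FALSE)
  conds <- unique(trials$condition)
  delta <- NULL
  moore <- list()
  for (cn in conds) {
    sub <- trials[trials$condition == cn, ]
    bees <- unique(sub$bee)
    if (!length(bees)) stop(sprintf("missing condition '%s'", cn), call. = FALSE)
    mb <- vapply(bees, function(b)
      circ_mean(sub$iaa_deg[sub$bee == b & sub$phase == "B"]), 1)
    mp <- vapply(bees, function(b)
      circ_mean(sub$iaa_deg[sub$bee == b & sub$phase == "post"]), 1)
    delta <- rbind(delta, data.frame(bee = bees, condition = cn,
                                     delta_iaa = wrap_diff_deg(mp - mb)))
    moore[[cn]] <- if (length(bees) >= 2L)
      moore_paired_test(mb, mp, n_perm = n_perm, seed = seed) else NULL
  }
  groups <- split(delta$delta_iaa, delta$condition)
  at <- if (length(groups) >= 2L && all(lengths(groups) >= 2L))
    delta_vs_zero_tests(groups, alpha = alpha) else NULL
  list(delta = delta, moore = moore, anova_tukey = at, alpha = alpha)
}

#' Classify the effect of a constant second cue on a response curve
#'
#' Compares a response curve measured alone with the same curve measured in
#' the presence of a constant second cue. Per matching level, the paired
#' difference Δ(level) is tested against zero (Moore's paired test at
#' `alpha`); a one-way ANOVA across levels tests constancy of Δ; the pooled
#' Δ is tested against zero with a one-sample t test. Verdicts:
#' `adaptation` when no level differs from zero; `uniform_offset` when the
#' differences are level-independent (constancy ANOVA non-significant) and
#' the pooled offset is nonzero — the signature of linear cue summation;
#' otherwise `nonuniform`.
#'
#' @param curve_alone,curve_with `bin_summary` objects over identical
#'   levels (>= 3 levels).
#' @param alpha significance level (default 0.05).
#' @param n_perm Moore permutations (default 999).
#' @param seed integer seed.
#' @return object of class `offset_classification`: list with `verdict`,
#'   `per_level` (level, delta, p, significant), `constancy_p`,
#'   `zero_mean_p`, `pooled_delta`.
#' @export
offset_classification <- function(curve_alone, curve_with, alpha = 0.05,
                                  n_perm = 999, seed = 1) {
  if (nrow(curve_alone) < 3L)
    stop("need at least 3 levels", call. = FALSE)
  if (!isTRUE(all.equal(curve_alone$level, curve_with$level)))
    stop("level mismatch between curves", call. = FALSE)
  L <- nrow(curve_alone)
  per <- data.frame(level = curve_alone$level, delta = NA_real_, p = NA_real_)
  diffs <- vector("list", L)
  for (i in seq_len(L)) {
    pr <- pair_bins(curve_with$angles[[i]], curve_alone$angles[[i]],
                    seed = seed + i)
    mt <- moore_paired_test(pr$alpha, pr$beta, n_perm = n_perm,
                            seed = seed + i)
    per$p[i] <- mt$p
    per$delta[i] <- wrap_diff_deg(curve_with$circ_mean[i] -
                                    curve_alone$circ_mean[i])
    diffs[[i]] <- wrap_diff_deg(pr$alpha - pr$beta)
  }
  per$significant <- per$p < alpha
  ddf <- data.frame(d = unlist(diffs),
                    level = factor(rep(per$level, lengths(diffs))))
  constancy_p <- as.data.frame(summary(aov(d ~ level, data = ddf))[[1]])[
    1, "Pr(>F)"]
  zero_mean_p <- stats::t.test(ddf$d, mu = 0)$p.value
  verdict <- if (!any(per$significant)) "adaptation"
  else if (constancy_p >= alpha && zero_mean_p < alpha) "uniform_offset"
  else "nonuniform"
  structure(list(verdict = verdict, per_level = per,
                 constancy_p = constancy_p, zero_mean_p = zero_mean_p,
                 pooled_delta = mean(ddf$d), alpha = alpha),
            class = "offset_classification")
}

#' Calibrate an optic-flow speedometer against airspeed
#'
#' Within the dynamic range of the airspeed sense (default 1.5-3 m/s), the
#' observed grating temporal frequency is regressed on airspeed through the
#' origin (zero optic flow at zero airspeed in steady flight): `tf = k * v`.
#' The returned estimator `v_hat(tf) = tf / k` extrapolates speed from optic
#' flow beyond the calibration range. An intercept-including variant is
#' available.
#'
#' @param airspeed,tf paired samples (m/s, cps).
#' @param range calibration range in m/s (default c(1.5, 3)).
#' @param through_origin regression through the origin (default TRUE).
#' @return list with `gain` (cps per m/s), `intercept`, `estimator`
#'   (function of tf returning m/s), `n_used`, `flag` ("ok" or
#'   "nonpositive_gain").
#' @export
crossmodal_calibrate <- function(airspeed, tf, range = c(1.5, 3),
                                 through_origin = TRUE) {
  if (length(airspeed) != length(tf))
    stop("`airspeed` and `tf` must be paired", call. = FALSE)
  keep <- airspeed >= range[1] & airspeed <= range[2]
  if (sum(keep) < 3L)
    stop("need at least 3 samples inside the calibration range",
         call. = FALSE)
  v <- airspeed[keep]; y <- tf[keep]
  if (through_origin) {
    k <- as.numeric(coef(lm(y ~ 0 + v))[1]); b <- 0
  } else {
    cf <- coef(lm(y ~ v)); b <- as.numeric(cf[1]); k <- as.numeric(cf[2])
  }
  flag <- if (k <= 0) "nonpositive_gain" else "ok"
  estimator <- function(tf_obs) (tf_obs - b) / k
  list(gain = k, intercept = b, estimator = estimator, n_used = sum(keep),
       flag = flag, through_origin = through_origin)
}
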