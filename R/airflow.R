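# Airspeed-response characterization: steady-state binning, plateau
# normalization, 4-parameter logistic fitting, dynamic-region detection.

new_bin_summary <- function(levels, samples) {
  stats <- lapply(samples, circ_mean_sd)
  out <- data.frame(level = levels,
                    circ_mean = vapply(stats, `[[`, 1, "mean"),
                    circ_sd = vapply(stats, `[[`, 1, "sd"),
                    n = vapply(samples, length, 1L))
  out$angles <- samples
  structure(out, class = c("bin_summary", "data.frame"))
}

#' Bin an IAA trace by stimulus level
#'
#' Extracts the steady-state portion (the last `frames_per_bin` frames) of
#' each stimulus epoch and summarizes the IAA samples per stimulus level
#' with circular statistics. Epochs sharing a level are pooled when
#' `sort_levels = TRUE`; with `sort_levels = FALSE` bins stay in epoch order
#' (one bin per epoch), as needed for transition analyses.
#'
#' @param trace an `iaa_trace` (or data.frame with `iaa_deg`, `epoch` and
#'   the stimulus column).
#' @param by stimulus dimension: "windspeed" or "tf".
#' @param frames_per_bin steady-state frames per epoch (default 500, the
#'   count digitized per airspeed in the tethered recordings). Epochs
#'   shorter than this are used in full, with a warning.
#' @param sort_levels pool and sort by level (default TRUE).
#' @param epochs restrict to these epoch indices (default all).
#' @return a `bin_summary` data.frame: `level`, `circ_mean`, `circ_sd`, `n`
#'   and a list column `angles` holding the samples.
#' @export
bin_by_level <- function(trace, by = c("windspeed", "tf"),
                         frames_per_bin = 500, sort_levels = TRUE,
                         epochs = NULL) {
  by <- match.arg(by)
  col <- if (by == "windspeed") "windspeed_mps" else "tf_cps"
  if (!all(c("iaa_deg", "epoch", col) %in% names(trace)))
    stop("trace lacks required columns", call. = FALSE)
  eps <- unique(trace$epoch)
  if (!is.null(epochs)) eps <- intersect(eps, epochs)
  short <- FALSE
  per_epoch <- lapply(eps, function(e) {
    x <- trace$iaa_deg[trace$epoch == e]
    if (length(x) < frames_per_bin) short <<- TRUE
    list(level = trace[[col]][trace$epoch == e][1],
         angles = tail(x, frames_per_bin))
  })
  if (short)
    warning("some epochs are shorter than `frames_per_bin`; used all frames")
  lv <- vapply(per_epoch, `[[`, 1, "level")
  ang <- lapply(per_epoch, `[[`, "angles")
  if (sort_levels) {
    ulv <- sort(unique(lv))
    ang <- lapply(ulv, function(l) unlist(ang[lv == l], use.names = FALSE))
    lv <- ulv
  }
  new_bin_summary(lv, ang)
}

#' Normalize an airspeed response curve between its plateaus
#'
#' Maps each bin's circular mean onto \[~0, ~1\] using the slow and fast
#' plateau means: `norm = (IAA - mu_fast) / (mu_slow - mu_fast)`. The
#' slow-plateau mean (0-1.5 m/s) maps to 1 and the fast-plateau mean
#' (3-5.5 m/s) to 0, so the normalized response decreases with airspeed as
#' the antennae move forward. Affine-invariant: adding a constant to all bin
#' means leaves normalized values unchanged.
#'
#' @param bins a `bin_summary`.
#' @param slow_range,fast_range inclusive level ranges defining the plateaus
#'   (defaults c(0, 1.5) and c(3, 5.5) m/s).
#' @return `bins` with a `normalized` column (plus attributes `mu_slow`,
#'   `mu_fast`).
#' @export
normalize_response <- function(bins, slow_range = c(0, 1.5),
                               fast_range = c(3, 5.5)) {
  in_rng <- function(r) bins$level >= r[1] & bins$level <= r[2]
  if (!any(in_rng(slow_range)) || !any(in_rng(fast_range)))
    stop("each plateau range must contain at least one bin", call. = FALSE)
  mu_slow <- circ_mean(unlist(bins$angles[in_rng(slow_range)]))
  mu_fast <- circ_mean(unlist(bins$angles[in_rng(fast_range)]))
  if (abs(wrap_diff_deg(mu_slow - mu_fast)) < 1e-9)
    stop("degenerate normalization: plateau means are equal", call. = FALSE)
  bins$normalized <- wrap_diff_deg(bins$circ_mean - mu_fast) /
    wrap_diff_deg(mu_slow - mu_fast)
  attr(bins, "mu_slow") <- mu_slow
  attr(bins, "mu_fast") <- mu_fast
  bins
}

#' Fit a four-parameter logistic to an airspeed response
#'
#' Least-squares fit of `IAA(v) = lower + A * logistic(-(v - v50)/k)` to the
#' bin circular means (a decreasing sigmoid: amplitude `A` is the plateau
#' difference, `v50` the midpoint, `k` the slope scale). Initialization uses
#' a small multistart grid over `v50` and `k`; `nls` (port algorithm, with
#' box constraints) is tried first and a Nelder-Mead fallback is used if it
#' fails to converge.
#'
#' @param bins a `bin_summary` with at least 5 bins spanning both plateaus.
#' @return object of class `sigmoid_fit`: list with `lower_plateau`,
#'   `amplitude`, `midpoint`, `slope`, `rms_residual`, `fitted`.
#' @export
fit_airspeed_sigmoid <- function(bins) {
  v <- bins$level; y <- bins$circ_mean
  if (length(v) < 5L) stop("need at least 5 bins", call. = FALSE)
  lo0 <- min(y); a0 <- max(y) - min(y)
  model <- function(p, v) p[1] + p[2] * plogis(-(v - p[3]) / p[4])
  sse <- function(p) {
    if (p[2] < 0 || p[4] <= 0) return(Inf)
    sum((y - model(p, v))^2)
  }
  starts <- expand.grid(v50 = quantile(v, c(0.3, 0.5, 0.7)),
                        k = c(0.05, 0.1, 0.25, 0.5))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      nls(y ~ lower + A * plogis(-(v - v50) / k),
          start = list(lower = lo0, A = max(a0, 1e-6),
                       v50 = starts$v50[i], k = starts$k[i]),
          algorithm = "port",
          lower = c(lower = -Inf, A = 0, v50 = min(v), k = 1e-4),
          upper = c(lower = Inf, A = Inf, v50 = max(v), k = diff(range(v))),
          control = nls.control(maxiter = 200, warnOnly = FALSE)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (!is.null(best)) {
    p <- coef(best$fit)
    pars <- c(p[["lower"]], p[["A"]], p[["v50"]], p[["k"]])
  } else {
    opt <- NULL
    for (i in seq_len(nrow(starts))) {
      o <- stats::optim(c(lo0, max(a0, 1e-6), starts$v50[i], starts$k[i]),
                        sse, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
      if (is.null(opt) || o$value < opt$value) opt <- o
    }
    if (is.null(opt) || !is.finite(opt$value))
      stop("sigmoid fit failed to converge (flat or degenerate data?)",
           call. = FALSE)
    pars <- opt$par
  }
  fitted_y <- model(pars, v)
  structure(list(lower_plateau = pars[1], amplitude = pars[2],
                 midpoint = pars[3], slope = pars[4],
                 rms_residual = sqrt(mean((y - fitted_y)^2)),
                 fitted = fitted_y),
            class = "sigmoid_fit")
}

#' Locate the dynamic region of the airspeed response across bees
#'
#' Tests each consecutive pair of airspeed levels with Moore's paired
#' circular test, pairing per-bee bin circular means across bees (N pairs =
#' N bees). Step decisions are family-wise (Holm-corrected across the
#' consecutive-step family): with ~11 steps tested at a raw per-step alpha a
#' flat response would show a spurious region almost half the time. The
#' dynamic region runs from the lowest level whose step up is significant to
#' the highest level reached by a significant step; steps outside the region
#' are expected non-significant.
#'
#' @param per_bee_bins list (one per bee, >= 4 bees) of `bin_summary`
#'   objects over a common set of levels.
#' @param alpha significance level (default 0.05).
#' @param n_perm Moore permutations (default 1024: exact for <= 10 bees).
#' @param seed seed for the (non-exhaustive) permutation draws.
#' @return list with `lower`, `upper` (m/s; NA and `empty = TRUE` when no
#'   step is significant) and `steps` (data.frame: from, to, statistic, p,
#'   significant).
#' @export
locate_dynamic_region <- function(per_bee_bins, alpha = 0.05, n_perm = 1024,
                                  seed = NULL) {
  if (length(per_bee_bins) < 4L)
    stop("need at least 4 bees for cross-bee pairing", call. = FALSE)
  lv <- per_bee_bins[[1]]$level
  if (length(lv) < 2L) stop("need at least 2 levels", call. = FALSE)
  ok <- vapply(per_bee_bins, function(b) identical(b$level, lv), TRUE)
  if (!all(ok)) stop("bees must share a common level set", call. = FALSE)
  means <- vapply(per_bee_bins, function(b) b$circ_mean, numeric(length(lv)))
  means <- t(means)  # bees x levels
  steps <- data.frame(from = lv[-length(lv)], to = lv[-1],
                      statistic = NA_real_, p = NA_real_)
  for (j in seq_len(ncol(means) - 1)) {
    mt <- moore_paired_test(means[, j], means[, j + 1], n_perm = n_perm,
                            seed = if (is.null(seed)) NULL else seed + j)
    steps$statistic[j] <- mt$statistic
    steps$p[j] <- mt$p
  }
  steps$p_adj <- stats::p.adjust(steps$p, method = "holm")
  steps$significant <- steps$p_adj < alpha
  sig <- which(steps$significant)
  if (!length(sig)) {
    return(list(lower = NA_real_, upper = NA_real_, empty = TRUE,
                steps = steps))
  }
  list(lower = steps$from[min(sig)], upper = steps$to[max(sig)],
       empty = FALSE, steps = steps)
}
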