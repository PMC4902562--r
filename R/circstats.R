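# Circular descriptive statistics and Moore's paired circular test.
#
# Moore's test is the workhorse statistic for every within-bee IAA
# comparison: it is a nonparametric paired test on the circle, based on
# ranked rectangular differences between angle pairs. P-values are obtained
# by permutation (random within-pair order swaps, i.e. sign reversal of each
# difference vector), exhaustively when feasible.

#' Circular mean, standard deviation and resultant length
#'
#' Computes the standard vector-resultant circular mean of a sample of
#' angles, the circular standard deviation \eqn{\sqrt{-2\ln R}} (in degrees),
#' and the mean resultant length \eqn{R \in [0,1]}.
#'
#' @param angles numeric vector of angles in degrees (any range; wrapped
#'   internally).
#' @return list with elements `mean` (degrees in \[0, 360); `NA` and flagged
#'   when the resultant length is numerically zero), `sd` (degrees), `r`
#'   (resultant length) and `n`.
#' @examples
#' circ_mean_sd(c(95, 96, 97))
#' circ_mean_sd(c(0, 180))  # antipodal: mean undefined
#' @export
circ_mean_sd <- function(angles) {
  if (length(angles) < 1L || !is.numeric(angles))
    stop("`angles` must be a non-empty numeric vector", call. = FALSE)
  if (anyNA(angles) || any(!is.finite(angles)))
    stop("`angles` must be finite", call. = FALSE)
  th <- deg2rad(angles)
  C <- mean(cos(th)); S <- mean(sin(th))
  r <- sqrt(C^2 + S^2)
  if (r < 1e-12) {
    return(list(mean = NA_real_, sd = Inf, r = 0, n = length(angles),
                undefined_mean = TRUE))
  }
  m <- wrap_deg(rad2deg(atan2(S, C)))
  list(mean = m, sd = rad2deg(sqrt(-2 * log(min(r, 1)))), r = r,
       n = length(angles), undefined_mean = FALSE)
}

# circular mean only, as a plain number (internal convenience)
circ_mean <- function(angles) circ_mean_sd(angles)$mean

#' Moore's paired circular test
#'
#' Nonparametric paired test for a common change in direction between two
#' sets of matched angles. For each pair the rectangular difference
#' \eqn{(\cos\alpha_i-\cos\beta_i,\ \sin\alpha_i-\sin\beta_i)} is formed;
#' its magnitudes are ranked ascending (ties get average ranks) and
#' \deqn{R^* = \sqrt{(\sum_i \mathrm{rank}_i\cos\theta_i)^2 +
#'   (\sum_i \mathrm{rank}_i\sin\theta_i)^2} / n^{3/2}}
#' where \eqn{\theta_i} is the direction of the i-th difference. The null
#' distribution is generated by randomly swapping the within-pair order
#' (equivalently, reversing the sign of each difference vector). When
#' `n_perm >= 2^n` all \eqn{2^n} swap patterns are enumerated and the
#' p-value is exact; otherwise `n_perm` random patterns are drawn and
#' \eqn{p = (\#\{R^*_{perm} \ge R^*\} + 1)/(n_{perm} + 1)}.
#'
#' @param alpha,beta numeric vectors of paired angles in degrees.
#' @param n_perm number of permutations (default 1000). Values at or above
#'   `2^n` trigger exact enumeration.
#' @param seed optional integer seed for the random permutations; the
#'   caller's RNG state is untouched.
#' @return list with `statistic` (R*), `p`, `n`, `n_perm` (actual number of
#'   null patterns used), `exhaustive` (logical).
#' @examples
#' a <- c(10, 20, 30, 40, 50, 60, 70, 80)
#' moore_paired_test(a, a + 12, n_perm = 255)  # exhaustive at n = 8
#' @export
moore_paired_test <- function(alpha, beta, n_perm = 1000, seed = NULL) {
  if (length(alpha) != length(beta))
    stop("`alpha` and `beta` must have equal length", call. = FALSE)
  n <- length(alpha)
  if (n < 2L) stop("need at least 2 pairs", call. = FALSE)
  if (anyNA(alpha) || anyNA(beta) || any(!is.finite(c(alpha, beta))))
    stop("angles must be finite", call. = FALSE)
  a <- deg2rad(alpha); b <- deg2rad(beta)
  dx <- cos(a) - cos(b)
  dy <- sin(a) - sin(b)
  r <- sqrt(dx^2 + dy^2)
  if (all(r < 1e-12)) {
    return(list(statistic = 0, p = 1, n = n, n_perm = 0L, exhaustive = TRUE))
  }
  rk <- rank(r)                       # average ranks for ties
  # unit direction of each difference, weighted by rank
  nz <- r > 1e-12
  x <- numeric(n); y <- numeric(n)
  x[nz] <- rk[nz] * dx[nz] / r[nz]
  y[nz] <- rk[nz] * dy[nz] / r[nz]
  scale <- n^(3 / 2)
  stat <- sqrt(sum(x)^2 + sum(y)^2) / scale

  exhaustive <- n <= 20L && n_perm >= 2^n
  if (exhaustive) {
    m <- 2^n
    # enumerate all sign patterns via bit expansion
    signs <- matrix(1, nrow = m, ncol = n)
    idx <- 0:(m - 1)
    for (j in seq_len(n)) signs[, j] <- ifelse(bitwAnd(idx, bitwShiftL(1L, j - 1L)) > 0, -1, 1)
    perm_stat <- sqrt((signs %*% x)^2 + (signs %*% y)^2) / scale
    p <- sum(perm_stat >= stat - 1e-12) / m
    n_used <- m
  } else {
    perm_stat <- local_seed(seed, {
      signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                      nrow = n_perm, ncol = n)
      sqrt((signs %*% x)^2 + (signs %*% y)^2) / scale
    })
    p <- (sum(perm_stat >= stat - 1e-12) + 1) / (n_perm + 1)
    n_used <- as.integer(n_perm)
  }
  list(statistic = as.numeric(stat), p = as.numeric(p), n = n,
       n_perm = n_used, exhaustive = exhaustive)
}

#' Pair two IAA bins for Moore's test
#'
#' Within-bee comparisons pair equal-index frames of two equal-size bins;
#' when sizes differ the larger bin is subsampled (seeded) to match.
#'
#' @param a,b numeric vectors of angles (degrees).
#' @param seed integer seed controlling the subsample.
#' @return list with `alpha`, `beta` (equal length) and `pairing` metadata.
#' @export
pair_bins <- function(a, b, seed = NULL) {
  n <- min(length(a), length(b))
  if (n < 2L) stop("bins must hold at least 2 samples each", call. = FALSE)
  sub <- function(x) {
    if (length(x) == n) x
    else local_seed(seed, x[sort(sample.int(length(x), n))])
  }
  list(alpha = sub(a), beta = sub(b),
       pairing = list(mode = "equal_index_frames", n = n,
                      subsampled = length(a) != length(b), seed = seed))
}

#' ANOVA with Tukey HSD against group means and a hypothetical zero mean
#'
#' Compares labelled samples of IAA changes with each other and with a
#' hypothetical mean of zero. The zero hypothesis enters as a degenerate
#' all-zero group in a one-way ANOVA; pairwise decisions come from Tukey's
#' Honest Significant Difference contrasts at the given alpha.
#'
#' @param groups named list of numeric vectors (degrees), each of length >= 2.
#' @param alpha significance level (default 0.05).
#' @param zero_group_n size of the synthetic zero group (default: rounded
#'   mean group size).
#' @return list with `anova` (the aov fit summary data.frame), `tukey`
#'   (data.frame of contrasts with `p_adj` and `significant`), and
#'   `zero_mean` (per-group decision vs the zero group).
#' @export
delta_vs_zero_tests <- function(groups, alpha = 0.05, zero_group_n = NULL) {
  if (!is.list(groups) || length(groups) < 2L || is.null(names(groups)))
    stop("`groups` must be a named list of >= 2 numeric vectors", call. = FALSE)
  if (any(vapply(groups, length, 1L) < 2L))
    stop("each group needs n >= 2", call. = FALSE)
  if ("zero" %in% names(groups))
    stop("group name 'zero' is reserved", call. = FALSE)
  if (is.null(zero_group_n))
    zero_group_n <- max(2L, round(mean(vapply(groups, length, 1L))))
  groups <- c(groups, list(zero = rep(0, zero_group_n)))
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), vapply(groups, length, 1L)),
                   levels = names(groups)))
  fit <- aov(value ~ group, data = df)
  tk <- TukeyHSD(fit, conf.level = 1 - alpha)$group
  tk_df <- data.frame(contrast = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"],
                      significant = !is.na(tk[, "p adj"]) & tk[, "p adj"] < alpha,
                      row.names = NULL)
  is_zero <- grepl("(^zero-)|(-zero$)", tk_df$contrast)
  zm <- tk_df[is_zero, ]
  zm$group <- sub("-?zero-?", "", zm$contrast)
  list(anova = as.data.frame(summary(fit)[[1]]),
       tukey = tk_df[!is_zero, ],
       zero_mean = zm[, c("group", "diff", "p_adj", "significant")],
       alpha = alpha, zero_group_n = zero_group_n)
}
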