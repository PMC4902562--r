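# Shared fixtures: quiet bees, tiny protocols, reference cameras.

quiet_bee <- function(...) {
  make_bee_profile(modifyList(list(noise_sd = 0, onset_jump = 0), list(...)),
                   seed = 1)
}

# independent brute-force Moore statistic + exhaustive p, computed from
# first principles (no shared code with the package implementation)
oracle_moore <- function(alpha, beta) {
  n <- length(alpha)
  a <- alpha * pi / 180; b <- beta * pi / 180
  dx <- cos(a) - cos(b); dy <- sin(a) - sin(b)
  r <- sqrt(dx^2 + dy^2)
  th <- atan2(dy, dx)
  rk <- rank(r)
  stat_for <- function(s) {
    X <- sum(s * rk * cos(th)); Y <- sum(s * rk * sin(th))
    sqrt(X^2 + Y^2) / n^1.5
  }
  obs <- stat_for(rep(1, n))
  cnt <- 0L
  for (code in 0:(2^n - 1)) {
    s <- ifelse(bitwAnd(code, bitwShiftL(1L, seq_len(n) - 1L)) > 0, -1, 1)
    if (stat_for(s) >= obs - 1e-12) cnt <- cnt + 1L
  }
  list(statistic = obs, p = cnt / 2^n)
}

ref_cube_points <- function() {
  as.matrix(expand.grid(X = c(-20, 0, 20), Y = c(-20, 0, 20),
                        Z = c(-20, 0, 20)))
}
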