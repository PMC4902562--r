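# Internal helpers: angle conversions, seeded RNG scoping, validation.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# wrap angles (degrees) into [0, 360)
wrap_deg <- function(x) x %% 360

# wrap a difference into (-180, 180]
wrap_diff_deg <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All package-level randomness flows through this so identical seeds give
# bit-identical output regardless of surrounding RNG use.
local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_num <- function(x, field, lower = -Inf, upper = Inf,
                      open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_field(field, "must be a single finite number")
  lo_ok <- if (open_lower) x > lower else x >= lower
  hi_ok <- if (open_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop_field(field, sprintf("must be in %s%g, %g%s (got %g)",
                              if (open_lower) "(" else "[", lower, upper,
                              if (open_upper) ")" else "]", x))
  x
}
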