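# Two-camera DLT calibration/reconstruction, IAA computation, digitization
# error, and flight-speed vector algebra.
#
# Conventions: right-handed world coordinates in mm, tunnel axis = +x,
# upwind flight = +x; angles in degrees; image coordinates in pixels.

#' Calibrate a camera by direct linear transformation (DLT)
#'
#' Solves the standard 11-parameter DLT model
#' \deqn{u = \frac{L_1 X + L_2 Y + L_3 Z + L_4}{L_9 X + L_{10} Y + L_{11} Z + 1},
#'       \quad
#'       v = \frac{L_5 X + L_6 Y + L_7 Z + L_8}{L_9 X + L_{10} Y + L_{11} Z + 1}}
#' by linear least squares from matched 3D calibration points and their
#' image coordinates.
#'
#' @param world_points numeric matrix (n x 3) of 3D points in mm, n >= 6,
#'   not all coplanar.
#' @param pixel_points numeric matrix (n x 2) of matching pixel coordinates.
#' @return object of class `camera_calibration`: list with `coefficients`
#'   (length 11) and `residual` (RMS reprojection error, px).
#' @export
dlt_calibrate <- function(world_points, pixel_points) {
  world_points <- as.matrix(world_points)
  pixel_points <- as.matrix(pixel_points)
  n <- nrow(world_points)
  if (n < 6L) stop("DLT calibration needs at least 6 points", call. = FALSE)
  if (nrow(pixel_points) != n || ncol(world_points) != 3L ||
      ncol(pixel_points) != 2L)
    stop("world_points must be n x 3 and pixel_points n x 2", call. = FALSE)
  X <- world_points[, 1]; Y <- world_points[, 2]; Z <- world_points[, 3]
  u <- pixel_points[, 1]; v <- pixel_points[, 2]
  zero <- numeric(n); one <- rep(1, n)
  A <- rbind(
    cbind(X, Y, Z, one, zero, zero, zero, zero, -u * X, -u * Y, -u * Z),
    cbind(zero, zero, zero, zero, X, Y, Z, one, -v * X, -v * Y, -v * Z))
  b <- c(u, v)
  qrA <- qr(A)
  if (qrA$rank < 11L)
    stop("calibration points are rank-deficient (coplanar or degenerate)",
         call. = FALSE)
  L <- qr.coef(qrA, b)
  proj <- dlt_project(L, world_points)
  resid <- sqrt(mean((proj - pixel_points)^2))
  structure(list(coefficients = as.numeric(L), residual = resid, n_points = n),
            class = "camera_calibration")
}

#' Project 3D points through a DLT camera
#'
#' @param L either a `camera_calibration` or a numeric vector of 11 DLT
#'   coefficients.
#' @param points numeric matrix (n x 3) in mm.
#' @return numeric matrix (n x 2) of pixel coordinates.
#' @export
dlt_project <- function(L, points) {
  if (inherits(L, "camera_calibration")) L <- L$coefficients
  stopifnot(length(L) == 11L)
  points <- matrix(as.numeric(points), ncol = 3)
  den <- points %*% L[9:11] + 1
  u <- (points %*% L[1:3] + L[4]) / den
  v <- (points %*% L[5:7] + L[8]) / den
  cbind(u = as.numeric(u), v = as.numeric(v))
}

#' Triangulate a 3D point from two (or more) calibrated views
#'
#' Stacks the two DLT ray equations per camera and solves the linear least
#' squares system; no iterative refinement (standard DLT practice, adequate
#' for a two-camera rig).
#'
#' @param calibrations list of >= 2 `camera_calibration` objects.
#' @param pixels numeric matrix (one row per camera) of pixel coordinates,
#'   or a list of length-2 vectors.
#' @param cond_tol condition-number threshold above which near-parallel rays
#'   are reported as an error (default 1e8).
#' @return numeric length-3 vector (mm).
#' @export
dlt_reconstruct <- function(calibrations, pixels, cond_tol = 1e8) {
  if (!is.list(calibrations) || length(calibrations) < 2L)
    stop("need at least 2 camera calibrations", call. = FALSE)
  if (is.list(pixels) && !is.matrix(pixels)) pixels <- do.call(rbind, pixels)
  pixels <- matrix(as.numeric(pixels), ncol = 2)
  if (nrow(pixels) != length(calibrations))
    stop("one pixel pair per camera required", call. = FALSE)
  rows <- lapply(seq_along(calibrations), function(i) {
    L <- calibrations[[i]]
    if (inherits(L, "camera_calibration")) L <- L$coefficients
    u <- pixels[i, 1]; v <- pixels[i, 2]
    rbind(c(L[1] - u * L[9], L[2] - u * L[10], L[3] - u * L[11]),
          c(L[5] - v * L[9], L[6] - v * L[10], L[7] - v * L[11]))
  })
  A <- do.call(rbind, rows)
  b <- unlist(lapply(seq_along(calibrations), function(i) {
    L <- calibrations[[i]]
    if (inherits(L, "camera_calibration")) L <- L$coefficients
    c(pixels[i, 1] - L[4], pixels[i, 2] - L[8])
  }))
  sv <- svd(A, nu = 0, nv = 0)$d
  if (sv[1] / max(sv[3], .Machine$double.xmin) > cond_tol)
    stop("near-parallel rays: reconstruction is ill-conditioned",
         call. = FALSE)
  as.numeric(qr.coef(qr(A), b))
}

#' Inter-antennal angle from four digitized 3D points
#'
#' The IAA is the angle between the base-to-tip vector of the left antenna
#' and that of the right antenna, in \[0, 180\] degrees. It is invariant
#' under rigid motion and uniform scaling of the four points.
#'
#' @param left_base,left_tip,right_base,right_tip numeric length-3 vectors
#'   (mm); alternatively pass a single list/frame with those named elements
#'   as `left_base`.
#' @return angle in degrees.
#' @examples
#' compute_iaa(c(0, 1, 0), c(1, 2, 0), c(0, -1, 0), c(1, -2, 0))
#' @export
compute_iaa <- function(left_base, left_tip = NULL, right_base = NULL,
                        right_tip = NULL) {
  if (is.list(left_base) && is.null(left_tip)) {
    f <- left_base
    left_tip <- f$left_tip; right_base <- f$right_base
    right_tip <- f$right_tip; left_base <- f$left_base
  }
  vl <- as.numeric(left_tip) - as.numeric(left_base)
  vr <- as.numeric(right_tip) - as.numeric(right_base)
  nl <- sqrt(sum(vl^2)); nr <- sqrt(sum(vr^2))
  if (nl < 1e-12 || nr < 1e-12)
    stop("zero-length antenna vector", call. = FALSE)
  cosang <- sum(vl * vr) / (nl * nr)
  rad2deg(acos(pmin(1, pmax(-1, cosang))))
}

#' Digitization error from antennal-length variation
#'
#' The antennal segments are rigid, so any frame-to-frame variation in the
#' reconstructed base-to-tip length reflects digitization error. Reported as
#' the per-side coefficient of variation (100 * SD / mean, percent).
#'
#' @param frames list of frames, each with `left_base`, `left_tip`,
#'   `right_base`, `right_tip` (length-3 numeric, mm).
#' @return named numeric vector `c(left = %, right = %)`.
#' @export
digitization_error <- function(frames) {
  if (length(frames) < 2L) stop("need at least 2 frames", call. = FALSE)
  seglen <- function(a, b) sqrt(sum((as.numeric(b) - as.numeric(a))^2))
  L <- vapply(frames, function(f) seglen(f$left_base, f$left_tip), 1)
  R <- vapply(frames, function(f) seglen(f$right_base, f$right_tip), 1)
  cv <- function(x) 100 * sd(x) / mean(x)
  c(left = cv(L), right = cv(R))
}

#' Groundspeed and airspeed from a tracked head landmark
#'
#' Groundspeed is the smoothed finite difference of the tracked position of
#' a head-fixed landmark; airspeed is its vector difference with the
#' (experimenter-set) windspeed: airspeed = groundspeed - windspeed. For a
#' stationary (tethered) bee, airspeed therefore equals windspeed in
#' magnitude and opposes it in direction. Wind blows along -x when the bee
#' faces upwind (+x).
#'
#' @param positions numeric matrix (n x 3) of positions in mm at uniform
#'   frame intervals.
#' @param fps frames per second.
#' @param windspeed_vector numeric length-3 wind velocity in m/s (ground
#'   frame). A scalar `w` is taken as wind blowing downwind at `c(-w, 0, 0)`.
#' @param smooth_window centered moving-average window (frames, odd;
#'   default 5) applied to positions before differencing.
#' @return list with matrices `groundspeed` and `airspeed` (n x 3, m/s;
#'   central differences, one-sided at the ends) and scalar summaries
#'   `mean_groundspeed`, `mean_airspeed` (mean vector magnitudes, edge
#'   frames trimmed by half the smoothing window).
#' @export
flight_speeds <- function(positions, fps, windspeed_vector = c(0, 0, 0),
                          smooth_window = 5L) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (n < 2L) stop("need at least 2 frames", call. = FALSE)
  check_num(fps, "fps", lower = 0, open_lower = TRUE)
  if (length(windspeed_vector) == 1L)
    windspeed_vector <- c(-windspeed_vector, 0, 0)
  w <- as.integer(smooth_window)
  if (w < 1L || w %% 2L == 0L)
    stop("`smooth_window` must be a positive odd integer", call. = FALSE)
  sm <- if (w > 1L && n > w) {
    apply(positions, 2, function(x) {
      k <- stats::filter(x, rep(1 / w, w), sides = 2)
      k <- as.numeric(k)
      k[is.na(k)] <- x[is.na(k)]  # keep raw values at the edges
      k
    })
  } else positions
  vel <- matrix(NA_real_, n, 3)
  if (n >= 3L)
    vel[2:(n - 1), ] <- (sm[3:n, , drop = FALSE] -
                           sm[1:(n - 2), , drop = FALSE]) * fps / 2
  vel[1, ] <- (sm[2, ] - sm[1, ]) * fps
  vel[n, ] <- (sm[n, ] - sm[n - 1, ]) * fps
  vel <- vel / 1000  # mm/s -> m/s
  air <- sweep(vel, 2, windspeed_vector)
  trim <- max(1L, (w + 1L) %/% 2L)
  keep <- seq.int(trim + 1L, n - trim)
  if (length(keep) < 1L) keep <- seq_len(n)
  mag <- function(m) sqrt(rowSums(m^2))
  list(groundspeed = vel, airspeed = air,
       mean_groundspeed = mean(mag(vel[keep, , drop = FALSE])),
       mean_airspeed = mean(mag(air[keep, , drop = FALSE])))
}

#' Angular image speed of a moving grating
#'
#' Converts grating temporal frequency to the angular speed seen at the eye:
#' linear grating speed (tf / spatial frequency) per unit distance from the
#' eye, in degrees per second.
#'
#' @param tf temporal frequency, cycles/s (>= 0).
#' @param spatial_frequency grating spatial frequency, cycles/cm (> 0).
#' @param distance distance from eye to grating, cm (> 0).
#' @return angular speed, deg/s.
#' @examples
#' angular_speed(25, 0.44, 10)  # ~325.6 deg/s
#' @export
angular_speed <- function(tf, spatial_frequency, distance) {
  if (!is.numeric(tf) || any(tf < 0))
    stop_field("tf", "must be non-negative")
  check_num(spatial_frequency, "spatial_frequency", 0, open_lower = TRUE)
  check_num(distance, "distance", 0, open_lower = TRUE)
  rad2deg((tf / spatial_frequency) / distance)
}
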