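# Synthetic-data generator.
#
# Emulates the statistical structure of tethered and free-flight high-speed
# recordings of honeybee antennae: per-bee IAA set points, wrapped-Gaussian
# frame noise, a negative sigmoid airspeed response, an adapting
# change-detection response to optic flow saturating at a per-bee threshold,
# and free-flight trajectories holding groundspeed against varying wind.
#
# Set-point model (degrees):
#   S(t) = baseline - A * logistic((v(t) - v50)/k) + G(t) + O(t)
#   dG/dt = -G/tau + gamma * d/dt[ clip(phi(t), -theta, +theta) ]
# i.e. G receives an impulse gamma * d(clip phi) at each stimulus transition
# and decays exponentially otherwise; O is a one-time onset jump applied at
# the first moving-grating stimulus, decaying with the same tau. Measured
# IAA = S + wrapped-Gaussian(sigma).

default_profile_values <- function() {
  list(baseline_iaa = 96, sigmoid_amplitude = 35, sigmoid_midpoint = 2.25,
       sigmoid_slope = 0.09, of_gain = 1, of_threshold = 10,
       adaptation_tau = 4, noise_sd = 0.8, onset_jump = 5,
       of_mode = "change")
}

# Piecewise-linear map from low-range optic flow (cps) onto airspeed (m/s)
# through the bimodal regime pairs A (0.3, 0.5), B (0.9, 2.5), C (1.8, 4),
# linearly extended beyond the ends. Used by the "matched" optic-flow mode:
# the crossmodally calibrated bee whose low-range optic-flow response mirrors
# its airspeed sigmoid at the paired stimulus values.
regime_of_to_air <- function(tf) {
  ifelse(tf <= 0.9, 0.5 + (tf - 0.3) * (2.5 - 0.5) / (0.9 - 0.3),
         2.5 + (tf - 0.9) * (4 - 2.5) / (1.8 - 0.9))
}

#' Create a synthetic bee profile
#'
#' Builds the generative parameter set of one synthetic bee. Missing entries
#' are filled with defaults matching the tethered recordings: set point 96
#' degrees, airspeed-response amplitude 35 degrees with midpoint 2.25 m/s,
#' optic-flow saturation threshold 10 cps, frame noise SD 0.8 degrees.
#'
#' @param config named list overriding any of `baseline_iaa` (deg),
#'   `sigmoid_amplitude` (deg), `sigmoid_midpoint` (m/s), `sigmoid_slope`
#'   (m/s), `of_gain` (deg per cps), `of_threshold` (cps), `adaptation_tau`
#'   (s), `noise_sd` (deg), `onset_jump` (deg), `of_mode` ("change": the
#'   optic-flow response tracks changes in threshold-clipped tf with gain
#'   `of_gain`; "matched": the low-range optic-flow response mirrors the
#'   bee's airspeed sigmoid through the regime stimulus pairing, as a
#'   crossmodally calibrated bee would — used for combined-cue trials).
#' @param seed integer recorded in the profile (generation itself is
#'   deterministic given `config`).
#' @return object of class `bee_profile`.
#' @examples
#' make_bee_profile(list(noise_sd = 0.1), seed = 1)
#' @export
make_bee_profile <- function(config = list(), seed = NULL) {
  p <- modifyList(default_profile_values(), config[lengths(config) > 0])
  unknown <- setdiff(names(config), names(default_profile_values()))
  if (length(unknown))
    stop_field(unknown[1], "unknown profile field")
  check_num(p$baseline_iaa, "baseline_iaa", 0, 180, TRUE, TRUE)
  check_num(p$sigmoid_amplitude, "sigmoid_amplitude", 0)
  check_num(p$sigmoid_midpoint, "sigmoid_midpoint", 0, open_lower = TRUE)
  check_num(p$sigmoid_slope, "sigmoid_slope", 0, open_lower = TRUE)
  check_num(p$of_gain, "of_gain")
  check_num(p$of_threshold, "of_threshold", 0, open_lower = TRUE)
  check_num(p$adaptation_tau, "adaptation_tau", 0, open_lower = TRUE)
  check_num(p$noise_sd, "noise_sd", 0)  # 0 = noise-free mode
  check_num(p$onset_jump, "onset_jump")
  if (!p$of_mode %in% c("change", "matched"))
    stop_field("of_mode", "must be 'change' or 'matched'")
  p$seed <- seed
  structure(p, class = "bee_profile")
}

#' Draw a population of synthetic bees
#'
#' Individual bees differ mainly in their set point (spread over roughly
#' 85-100 degrees in the recordings) with milder variation in response
#' amplitude and midpoint. Fields fixed in `config` are not jittered.
#'
#' @param n number of bees.
#' @param seed integer seed.
#' @param config overrides applied to every bee (see [make_bee_profile()]).
#' @return list of `bee_profile` objects.
#' @export
make_bee_population <- function(n, seed = 1, config = list()) {
  stopifnot(n >= 1)
  local_seed(seed, {
    lapply(seq_len(n), function(i) {
      jit <- list(
        baseline_iaa = runif(1, 85, 100),
        sigmoid_amplitude = max(1, rnorm(1, 35, 1.5)),
        sigmoid_midpoint = rnorm(1, 2.25, 0.05),
        of_gain = max(0.2, rnorm(1, 1, 0.1)))
      jit[names(config)] <- NULL  # explicit overrides win, unjittered
      make_bee_profile(modifyList(jit, config), seed = seed + i)
    })
  })
}

protocol_df <- function(duration_s, windspeed_mps, tf_cps,
                        spatial_freq_per_cm = 0.44,
                        role = "stim") {
  data.frame(duration_s = duration_s, windspeed_mps = windspeed_mps,
             tf_cps = tf_cps, spatial_freq_per_cm = spatial_freq_per_cm,
             role = role, stringsAsFactors = FALSE)
}

#' Build a stimulus protocol
#'
#' Constructs the epoch sequences used in the wind-tunnel and visual-arena
#' experiments:
#' \describe{
#'   \item{linear_ramp_air}{airspeeds 0-5.5 m/s in 0.5 m/s steps, 1 s each,
#'     500 fps (params: `levels`, `epoch_s`, `descending`).}
#'   \item{random_air}{seeded random order of the same airspeed levels.}
#'   \item{linear_ramp_of}{temporal frequencies 0-25 cps in 1 cps steps of
#'     1 s (26 epochs, 26 s total), 250 fps.}
#'   \item{random_of}{a seeded permutation of 1-25 cps, 1 s each.}
#'   \item{sinusoid_of}{sinusoidal tf, amplitude 1.8 cps, period 10 s,
#'     6 periods, discretized at `dt` (default 0.1 s).}
#'   \item{low_range_of}{each of 1.8, 1.5, 1.2, 0.9, 0.3 and 0 cps shown
#'     moving for 6 s followed by a 3 s static screen (54 s total).}
#'   \item{regime}{two 6 s bimodal epochs stepping between regimes
#'     A (0.5 m/s, 0.3 cps), B (2.5 m/s, 0.9 cps) and C (4 m/s, 1.8 cps);
#'     params `from`, `to`, `vary` in \{"air", "of", "both"\}.}
#' }
#'
#' @param kind protocol kind (see above).
#' @param params named list of kind-specific parameters, including `seed`
#'   for the random orders.
#' @return object of class `stimulus_protocol`: a data.frame of epochs with
#'   columns `duration_s`, `windspeed_mps`, `tf_cps`, `spatial_freq_per_cm`,
#'   `role`, plus attributes `fps` and `kind`.
#' @export
build_protocol <- function(kind, params = list()) {
  g <- function(name, default) if (!is.null(params[[name]])) params[[name]] else default
  fps <- g("fps", switch(kind, linear_ramp_air = 500, random_air = 500, 250))
  check_num(fps, "fps", 0, open_lower = TRUE)
  epochs <- switch(
    kind,
    linear_ramp_air = {
      lv <- g("levels", seq(0, 5.5, by = 0.5))
      if (isTRUE(g("descending", FALSE))) lv <- rev(lv)
      protocol_df(rep(g("epoch_s", 1), length(lv)), lv, 0)
    },
    random_air = {
      lv <- g("levels", seq(0, 5.5, by = 0.5))
      lv <- local_seed(g("seed", 1), sample(lv))
      protocol_df(rep(g("epoch_s", 1), length(lv)), lv, 0)
    },
    linear_ramp_of = {
      lv <- g("levels", 0:25)
      if (isTRUE(g("descending", FALSE))) lv <- rev(lv)
      if (g("step", 1) <= 0) stop("non-positive step", call. = FALSE)
      protocol_df(rep(g("epoch_s", 1), length(lv)), 0, lv)
    },
    random_of = {
      lv <- local_seed(g("seed", 1), sample(g("levels", 1:25)))
      protocol_df(rep(g("epoch_s", 1), length(lv)), 0, lv)
    },
    sinusoid_of = {
      amp <- g("amplitude", 1.8); period <- g("period", 10)
      np <- g("n_periods", 6); dt <- g("dt", 0.1)
      tt <- seq(0, np * period - dt, by = dt)
      protocol_df(rep(dt, length(tt)), 0, amp * sin(2 * pi * tt / period))
    },
    low_range_of = {
      lv <- g("levels", c(1.8, 1.5, 1.2, 0.9, 0.3, 0))
      do.call(rbind, lapply(lv, function(l) rbind(
        protocol_df(g("stim_s", 6), 0, l, role = "stim"),
        protocol_df(g("static_s", 3), 0, 0, role = "static"))))
    },
    regime = {
      reg <- list(A = c(air = 0.5, of = 0.3), B = c(air = 2.5, of = 0.9),
                  C = c(air = 4, of = 1.8))
      from <- reg[[g("from", "B")]]; to <- reg[[g("to", "A")]]
      if (is.null(from) || is.null(to)) stop("unknown regime label", call. = FALSE)
      vary <- match.arg(g("vary", "both"), c("air", "of", "both"))
      air <- if (vary %in% c("air", "both")) c(from["air"], to["air"]) else c(0, 0)
      of <- if (vary %in% c("of", "both")) c(from["of"], to["of"]) else c(0, 0)
      protocol_df(rep(g("epoch_s", 6), 2), air, of)
    },
    stop(sprintf("unknown protocol kind '%s'", kind), call. = FALSE))
  if (any(epochs$duration_s <= 0)) stop("durations must be > 0", call. = FALSE)
  if (any(epochs$spatial_freq_per_cm <= 0))
    stop("spatial_frequency must be > 0", call. = FALSE)
  structure(epochs, fps = fps, kind = kind,
            period = if (kind == "sinusoid_of") g("period", 10) else NULL,
            class = c("stimulus_protocol", "data.frame"))
}

#' Total duration of a protocol in seconds
#' @param protocol a `stimulus_protocol`.
#' @return seconds.
#' @export
protocol_duration <- function(protocol) sum(protocol$duration_s)

# expand a protocol into per-frame stimulus values
expand_protocol <- function(protocol) {
  fps <- attr(protocol, "fps")
  nf <- round(protocol$duration_s * fps)
  idx <- rep(seq_len(nrow(protocol)), nf)
  n <- length(idx)
  data.frame(time_s = (seq_len(n) - 1) / fps, epoch = idx,
             windspeed_mps = protocol$windspeed_mps[idx],
             tf_cps = protocol$tf_cps[idx])
}

#' Simulate an IAA trace for one bee and one protocol
#'
#' Integrates the set-point model frame by frame: the airflow term follows
#' the bee's negative sigmoid of instantaneous airspeed (tethered bees:
#' airspeed = windspeed); the optic-flow term is an adapting
#' change-integrator that receives an impulse `of_gain * d(clip(tf))` at
#' each stimulus transition (tf clipped to the bee's saturation threshold)
#' and decays with `adaptation_tau`; an onset jump is added at the first
#' moving-grating frame. Wrapped-Gaussian frame noise of SD `noise_sd` is
#' then applied (`noise_sd` may be overridden to 0 via the profile for
#' noise-free traces).
#'
#' @param bee a `bee_profile`.
#' @param protocol a `stimulus_protocol`.
#' @param seed integer seed for the frame noise.
#' @return object of class `iaa_trace`: data.frame with `time_s`, `iaa_deg`,
#'   `epoch`, `windspeed_mps`, `tf_cps` and attributes `fps`, `bee`, `seed`,
#'   `set_point` (the noise-free set-point series).
#' @export
simulate_iaa_trace <- function(bee, protocol, seed = 1) {
  stopifnot(inherits(bee, "bee_profile"), inherits(protocol, "stimulus_protocol"))
  fr <- expand_protocol(protocol)
  fps <- attr(protocol, "fps")
  dt <- 1 / fps
  n <- nrow(fr)
  u <- if (bee$of_mode == "matched") {
    # crossmodally calibrated low-range response: mirror of the airspeed
    # sigmoid through the regime pairing (static screen maps below 0 m/s)
    m <- ifelse(fr$tf_cps == 0, -1, regime_of_to_air(fr$tf_cps))
    bee$sigmoid_amplitude *
      plogis((m - bee$sigmoid_midpoint) / bee$sigmoid_slope)
  } else {
    bee$of_gain * pmin(pmax(fr$tf_cps, -bee$of_threshold), bee$of_threshold)
  }
  decay <- exp(-dt / bee$adaptation_tau)
  impulses <- c(u[1] - 0, diff(u))
  # G_t = sum_j impulses_j * decay^(t-j): first-order recursive filter
  G <- as.numeric(stats::filter(impulses, decay, method = "recursive"))
  onset <- numeric(n)
  first_move <- which(fr$tf_cps != 0)[1]
  if (!is.na(first_move)) {
    tt <- fr$time_s[first_move:n] - fr$time_s[first_move]
    onset[first_move:n] <- bee$onset_jump * exp(-tt / bee$adaptation_tau)
  }
  setp <- bee$baseline_iaa -
    bee$sigmoid_amplitude *
      plogis((fr$windspeed_mps - bee$sigmoid_midpoint) / bee$sigmoid_slope) +
    G + onset
  noise <- if (bee$noise_sd > 0)
    local_seed(seed, rnorm(n, 0, bee$noise_sd)) else numeric(n)
  out <- data.frame(time_s = fr$time_s, iaa_deg = wrap_deg(setp + noise),
                    epoch = fr$epoch, windspeed_mps = fr$windspeed_mps,
                    tf_cps = fr$tf_cps)
  structure(out, fps = fps, bee = bee, seed = seed, set_point = setp,
            protocol_kind = attr(protocol, "kind"),
            class = c("iaa_trace", "data.frame"))
}

#' Simulate per-level IAA bins directly (statistical shortcut)
#'
#' Generates steady-state bin samples without integrating a trace. Bin means
#' follow the generative model: `air` mode, `baseline - A * logistic((v -
#' v50)/k)`; `of_ramp` mode, `baseline + of_gain * min(tf, threshold)`;
#' `of_low_range` mode, `baseline + of_gain * tf` (valid for tf at or below
#' threshold). Each bin holds `n_per_bin` wrapped-Gaussian samples.
#'
#' @param bee a `bee_profile`.
#' @param levels stimulus levels (m/s or cps).
#' @param n_per_bin samples per bin (>= 2).
#' @param mode one of "air", "of_ramp", "of_low_range".
#' @param seed integer seed.
#' @return a `bin_summary` data.frame (see [bin_by_level()]).
#' @export
simulate_bin_means <- function(bee, levels, n_per_bin, mode = "air", seed = 1) {
  stopifnot(inherits(bee, "bee_profile"))
  if (length(levels) < 1L) stop("`levels` must be non-empty", call. = FALSE)
  if (n_per_bin < 2L) stop("`n_per_bin` must be >= 2", call. = FALSE)
  mode <- match.arg(mode, c("air", "of_ramp", "of_low_range"))
  mu <- switch(mode,
    air = bee$baseline_iaa - bee$sigmoid_amplitude *
      plogis((levels - bee$sigmoid_midpoint) / bee$sigmoid_slope),
    of_ramp = bee$baseline_iaa + bee$of_gain * pmin(levels, bee$of_threshold),
    of_low_range = bee$baseline_iaa + bee$of_gain * levels)
  samples <- local_seed(seed, lapply(seq_along(levels), function(i) {
    wrap_deg(mu[i] + if (bee$noise_sd > 0) rnorm(n_per_bin, 0, bee$noise_sd)
             else numeric(n_per_bin))
  }))
  new_bin_summary(levels, samples)
}

#' Synthesize two-camera landmark projections from an IAA trace
#'
#' Realizes each frame's IAA as four 3D landmarks (left/right antennal base
#' and tip) placed symmetrically about the head midline in the horizontal
#' plane at fixed antennal length, then projects them through two calibrated
#' cameras with additive pixel noise. Ground truth is retained for oracle
#' tests.
#'
#' @param trace an `iaa_trace`.
#' @param geometry list with `antenna_len_mm` (default 3), `base_sep_mm`
#'   (distance between antennal bases, default 2).
#' @param cameras list of two `camera_calibration` objects (default
#'   [default_camera_rig()]); optical axes must not be parallel.
#' @param pixel_noise SD of additive Gaussian pixel noise (px). About
#'   0.12 px reproduces the 0.5-1.5% tethered digitization error; about
#'   0.5 px the 3-5% free-flight error.
#' @param seed integer seed.
#' @return list with `landmarks` (data.frame: frame, camera, landmark in
#'   \{LB, LT, RB, RT\}, x_px, y_px), `truth` (frame, landmark, X_mm, Y_mm,
#'   Z_mm) and `cameras`.
#' @export
simulate_geometry <- function(trace, geometry = list(), cameras = default_camera_rig(),
                              pixel_noise = 0, seed = 1) {
  stopifnot(inherits(trace, "iaa_trace"))
  if (length(cameras) != 2L)
    stop("exactly two cameras required", call. = FALSE)
  check_camera_pair(cameras)
  alen <- if (!is.null(geometry$antenna_len_mm)) geometry$antenna_len_mm else 3
  bsep <- if (!is.null(geometry$base_sep_mm)) geometry$base_sep_mm else 2
  n <- nrow(trace)
  half <- deg2rad(trace$iaa_deg / 2)
  lb <- cbind(0, rep(bsep / 2, n), 0)
  rb <- cbind(0, rep(-bsep / 2, n), 0)
  lt <- lb + alen * cbind(cos(half), sin(half), 0)
  rt <- rb + alen * cbind(cos(half), -sin(half), 0)
  pts <- list(LB = lb, LT = lt, RB = rb, RT = rt)
  truth <- do.call(rbind, lapply(names(pts), function(lm)
    data.frame(frame = seq_len(n), landmark = lm, X_mm = pts[[lm]][, 1],
               Y_mm = pts[[lm]][, 2], Z_mm = pts[[lm]][, 3])))
  truth <- truth[order(truth$frame, truth$landmark), ]
  rownames(truth) <- NULL
  landmarks <- local_seed(seed, {
    do.call(rbind, lapply(seq_along(cameras), function(ci) {
      do.call(rbind, lapply(names(pts), function(lm) {
        px <- dlt_project(cameras[[ci]], pts[[lm]])
        if (pixel_noise > 0)
          px <- px + matrix(rnorm(2 * n, 0, pixel_noise), ncol = 2)
        data.frame(frame = seq_len(n), camera = ci, landmark = lm,
                   x_px = px[, 1], y_px = px[, 2])
      }))
    }))
  })
  landmarks <- landmarks[order(landmarks$frame, landmarks$camera,
                               landmarks$landmark), ]
  rownames(landmarks) <- NULL
  list(landmarks = landmarks, truth = truth, cameras = cameras)
}

#' Default two-camera rig (overhead + lateral view)
#'
#' Two synthetic pinhole cameras 500 mm from the head, one overhead and one
#' lateral, expressed as 11-coefficient DLT calibrations. Their optical axes
#' are orthogonal, so triangulation is well conditioned.
#'
#' @param focal_px focal length in pixels (default 2000).
#' @return list of two `camera_calibration` objects.
#' @export
default_camera_rig <- function(focal_px = 2000) {
  list(pinhole_camera(center = c(0, 0, 500), target = c(0, 0, 0),
                      up = c(0, 1, 0), focal_px = focal_px),
       pinhole_camera(center = c(0, -500, 0), target = c(0, 0, 0),
                      up = c(0, 0, 1), focal_px = focal_px))
}

#' Construct a pinhole camera as DLT coefficients
#'
#' @param center camera center (mm).
#' @param target point the optical axis looks at (mm).
#' @param up approximate up direction.
#' @param focal_px focal length (px).
#' @param principal_point image center (px), default c(512, 512).
#' @return a `camera_calibration` (residual 0: exact model).
#' @export
pinhole_camera <- function(center, target, up = c(0, 0, 1), focal_px = 2000,
                           principal_point = c(512, 512)) {
  zc <- target - center
  zc <- zc / sqrt(sum(zc^2))
  xc <- c(zc[2] * up[3] - zc[3] * up[2],
          zc[3] * up[1] - zc[1] * up[3],
          zc[1] * up[2] - zc[2] * up[1])
  if (sqrt(sum(xc^2)) < 1e-9)
    stop("`up` is parallel to the optical axis", call. = FALSE)
  xc <- xc / sqrt(sum(xc^2))
  yc <- c(zc[2] * xc[3] - zc[3] * xc[2],
          zc[3] * xc[1] - zc[1] * xc[3],
          zc[1] * xc[2] - zc[2] * xc[1])
  R <- rbind(xc, yc, zc)
  K <- rbind(c(focal_px, 0, principal_point[1]),
             c(0, focal_px, principal_point[2]),
             c(0, 0, 1))
  P <- K %*% cbind(R, -R %*% center)
  if (abs(P[3, 4]) < 1e-9)
    stop("degenerate camera: principal plane passes through the origin",
         call. = FALSE)
  L <- as.numeric(t(P))[1:11] / P[3, 4]
  structure(list(coefficients = L, residual = 0, n_points = NA_integer_,
                 center = center),
            class = "camera_calibration")
}

check_camera_pair <- function(cameras) {
  # optical-axis direction from DLT row 3 (L9, L10, L11)
  ax <- lapply(cameras, function(cc) {
    L <- if (inherits(cc, "camera_calibration")) cc$coefficients else cc
    a <- L[9:11]
    a / sqrt(sum(a^2))
  })
  if (abs(sum(ax[[1]] * ax[[2]])) > 1 - 1e-6)
    stop("degenerate camera pair: parallel optical axes", call. = FALSE)
  invisible(TRUE)
}

#' Simulate free-flight trajectories against varying wind
#'
#' Generates straight upwind trajectories (+x = upwind tunnel axis) whose
#' ground-frame speed fluctuates around a fixed target independent of
#' windspeed, mimicking the constant-groundspeed behaviour of freely flying
#' bees. Positional digitization noise is added on top.
#'
#' @param windspeeds windspeed levels (m/s), one trajectory each.
#' @param groundspeed_target target groundspeed (m/s, > 0; default 0.43).
#' @param duration trajectory duration (s, default 1).
#' @param fps frames per second (default 500).
#' @param noise list with `speed_sd` (AR(1) groundspeed fluctuation SD, m/s,
#'   default 0.03) and `pos_sd_mm` (positional noise SD, default 0.05).
#' @param seed integer seed.
#' @return data.frame: `windspeed_mps`, `time_s`, `x_mm`, `y_mm`, `z_mm`.
#' @export
simulate_free_flight <- function(windspeeds, groundspeed_target = 0.43,
                                 duration = 1, fps = 500,
                                 noise = list(speed_sd = 0.03, pos_sd_mm = 0.05),
                                 seed = 1) {
  check_num(groundspeed_target, "groundspeed_target", 0, open_lower = TRUE)
  speed_sd <- if (!is.null(noise$speed_sd)) noise$speed_sd else 0.03
  pos_sd <- if (!is.null(noise$pos_sd_mm)) noise$pos_sd_mm else 0.05
  n <- round(duration * fps)
  local_seed(seed, {
    do.call(rbind, lapply(windspeeds, function(w) {
      vx <- if (speed_sd > 0) {
        groundspeed_target +
          as.numeric(stats::filter(rnorm(n, 0, speed_sd * sqrt(1 - 0.9^2)),
                                   0.9, method = "recursive"))
      } else rep(groundspeed_target, n)
      x <- cumsum(vx / fps) * 1000  # m -> mm
      pn <- function() if (pos_sd > 0) rnorm(n, 0, pos_sd) else numeric(n)
      data.frame(windspeed_mps = w, time_s = (seq_len(n) - 1) / fps,
                 x_mm = x + pn(), y_mm = pn(), z_mm = pn())
    }))
  })
}
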