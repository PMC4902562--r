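# File formats: protocol JSON, trace CSV, landmark CSV, calibration JSON.
# CSV dialect: comma-separated, dot decimal, mandatory header; units are
# embedded in column names (deg, m/s via "_mps", cps, mm, px).

#' Write / read a stimulus protocol as JSON
#'
#' @param protocol a `stimulus_protocol`.
#' @param path file path.
#' @return `read_protocol` returns a `stimulus_protocol`.
#' @export
write_protocol <- function(protocol, path) {
  obj <- list(fps = attr(protocol, "fps"), kind = attr(protocol, "kind"),
              period = attr(protocol, "period"),
              epochs = as.data.frame(protocol))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ep <- as.data.frame(obj$epochs)
  needed <- c("duration_s", "windspeed_mps", "tf_cps", "spatial_freq_per_cm")
  if (!all(needed %in% names(ep)))
    stop("protocol JSON lacks required epoch fields", call. = FALSE)
  if (is.null(ep$role)) ep$role <- "stim"
  structure(ep, fps = obj$fps, kind = obj$kind,
            period = if (is.null(obj$period)) NULL else obj$period,
            class = c("stimulus_protocol", "data.frame"))
}

#' Write / read an IAA trace as CSV
#'
#' Columns: `time_s`, `iaa_deg`, `epoch`, `windspeed_mps`, `tf_cps`.
#'
#' @param trace an `iaa_trace`.
#' @param path file path.
#' @param fps frame rate to attach on read (default: inferred from the time
#'   column).
#' @return `read_trace` returns an `iaa_trace`.
#' @export
write_trace <- function(trace, path) {
  write.csv(as.data.frame(trace)[, c("time_s", "iaa_deg", "epoch",
                                     "windspeed_mps", "tf_cps")],
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path, fps = NULL) {
  df <- read.csv(path)
  needed <- c("time_s", "iaa_deg", "epoch", "windspeed_mps", "tf_cps")
  if (!all(needed %in% names(df)))
    stop("trace CSV lacks required columns", call. = FALSE)
  if (is.null(fps)) {
    dt <- diff(df$time_s[1:2])
    fps <- if (is.finite(dt) && dt > 0) 1 / dt else NA_real_
  }
  structure(df, fps = fps, class = c("iaa_trace", "data.frame"))
}

#' Read and validate a digitized-landmark CSV
#'
#' Expects columns `frame`, `camera`, `landmark` (LB, LT, RB, RT), `x_px`,
#' `y_px`. Malformed rows are reported with their line numbers; duplicate
#' (frame, camera, landmark) keys are an error; frames missing any of the
#' four landmarks in any camera are flagged, excluded and logged in the
#' return value.
#'
#' @param path CSV path.
#' @return list with `landmarks` (validated data.frame of complete frames),
#'   `excluded_frames`, `messages`.
#' @export
read_landmarks <- function(path) {
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop(sprintf(
                   "cannot parse landmark CSV '%s': %s", path,
                   conditionMessage(e)), call. = FALSE))
  needed <- c("frame", "camera", "landmark", "x_px", "y_px")
  miss <- setdiff(needed, names(df))
  if (length(miss))
    stop(sprintf("landmark CSV missing columns: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  if (nrow(df) == 0L) stop("landmark CSV has no data rows", call. = FALSE)
  msgs <- character()
  bad_num <- !is.finite(suppressWarnings(as.numeric(df$x_px))) |
    !is.finite(suppressWarnings(as.numeric(df$y_px))) |
    !is.finite(suppressWarnings(as.numeric(df$frame)))
  if (any(bad_num)) {
    lines <- which(bad_num) + 1L  # +1 for header
    msgs <- c(msgs, sprintf("non-numeric cells on line(s): %s",
                            paste(lines, collapse = ", ")))
    df <- df[!bad_num, ]
  }
  df$x_px <- as.numeric(df$x_px); df$y_px <- as.numeric(df$y_px)
  df$frame <- as.integer(df$frame)
  bad_lm <- !df$landmark %in% c("LB", "LT", "RB", "RT")
  if (any(bad_lm)) {
    msgs <- c(msgs, sprintf("unknown landmark label on line(s): %s",
                            paste(which(bad_lm) + 1L, collapse = ", ")))
    df <- df[!bad_lm, ]
  }
  key <- paste(df$frame, df$camera, df$landmark)
  if (anyDuplicated(key))
    stop(sprintf("duplicate (frame, camera, landmark) keys, e.g. %s",
                 key[duplicated(key)][1]), call. = FALSE)
  n_cam <- length(unique(df$camera))
  cnt <- table(df$frame)
  complete <- as.integer(names(cnt))[cnt == 4L * n_cam]
  excluded <- setdiff(unique(df$frame), complete)
  if (length(excluded))
    msgs <- c(msgs, sprintf("frame(s) missing landmarks, excluded: %s",
                            paste(excluded, collapse = ", ")))
  list(landmarks = df[df$frame %in% complete, ],
       excluded_frames = excluded, messages = msgs)
}

#' Reconstruct 3D antenna frames from landmark tables
#'
#' Triangulates the four antennal landmarks per frame through two calibrated
#' cameras and computes the IAA per frame.
#'
#' @param landmarks landmark data.frame (see [read_landmarks()]).
#' @param cameras list of two `camera_calibration` objects, in the order of
#'   the `camera` codes in `landmarks`.
#' @return list with `frames` (list of antenna frames: `left_base`,
#'   `left_tip`, `right_base`, `right_tip`) and `iaa_deg` (numeric per
#'   frame), named by frame index.
#' @export
reconstruct_antennae <- function(landmarks, cameras) {
  cams <- sort(unique(landmarks$camera))
  if (length(cams) != 2L)
    stop("exactly two cameras required", call. = FALSE)
  lm_names <- c(LB = "left_base", LT = "left_tip",
                RB = "right_base", RT = "right_tip")
  frames <- sort(unique(landmarks$frame))
  out <- lapply(frames, function(fr) {
    sub <- landmarks[landmarks$frame == fr, ]
    pts <- lapply(names(lm_names), function(lm) {
      px <- t(vapply(cams, function(cm) {
        r <- sub[sub$camera == cm & sub$landmark == lm, ]
        c(r$x_px, r$y_px)
      }, numeric(2)))
      dlt_reconstruct(cameras, px)
    })
    setNames(pts, lm_names)
  })
  names(out) <- frames
  list(frames = out, iaa_deg = vapply(out, compute_iaa, 1))
}

#' Write landmark tables produced by [simulate_geometry()]
#'
#' @param geom result of [simulate_geometry()].
#' @param landmarks_path,truth_path CSV paths (truth optional).
#' @export
write_landmarks <- function(geom, landmarks_path, truth_path = NULL) {
  write.csv(geom$landmarks, landmarks_path, row.names = FALSE)
  if (!is.null(truth_path))
    write.csv(geom$truth, truth_path, row.names = FALSE)
  invisible(landmarks_path)
}

#' Write / read camera calibrations as JSON
#'
#' @param cameras list of `camera_calibration` objects.
#' @param path file path.
#' @export
write_calibration <- function(cameras, path) {
  obj <- lapply(cameras, function(cc)
    list(coefficients = cc$coefficients, residual = cc$residual))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(obj, function(cc)
    structure(list(coefficients = as.numeric(unlist(cc$coefficients)),
                   residual = as.numeric(cc$residual)),
              class = "camera_calibration"))
}
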