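# Configuration-driven orchestration: composes generator + analyses into
# reproducible experiment runs with machine-readable summaries.

config_defaults <- function() {
  list(kind = "fig1_tethered_ramp", n_bees = 10, seed = 1,
       profile = list(), alpha = 0.05, alpha_change = 0.005,
       frames_per_bin = 500, n_scrambles = 200, outdir = NULL,
       log_level = "info")
}

# stable hash of a config: md5 of its canonical JSON. Output location and
# verbosity do not define the run, so they are excluded.
config_hash <- function(config) {
  config <- config[setdiff(names(config), c("outdir", "log_level"))]
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config[order(names(config))], tf, auto_unbox = TRUE,
                       digits = NA, null = "null")
  unname(tools::md5sum(tf))
}

log_msg <- function(level, config, fmt, ...) {
  levels <- c(debug = 1, info = 2, warn = 3, quiet = 4)
  if (levels[[level]] >= levels[[config$log_level %||% "info"]])
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a named experiment end to end
#'
#' Executes generate -> bin -> analyze for one of the canned experiment
#' kinds and returns (optionally writes) a reproducible result bundle.
#' All randomness flows from `config$seed`; identical configs give
#' identical bundles.
#'
#' Kinds:
#' \describe{
#'   \item{fig1_tethered_ramp}{airspeed ramp over `n_bees` tethered bees:
#'     per-bee bins, normalized response, sigmoid fit on the grand-mean
#'     curve, dynamic-region detection.}
#'   \item{fig2_random}{per-bee optic-flow threshold from a linear ramp,
#'     then change-prediction scoring on a randomized 1-25 cps sequence
#'     with scrambled-data significance.}
#'   \item{fig2_low_range}{low-range (0-1.8 cps) graded-response analysis
#'     over `n_bees` bees.}
#'   \item{fig3_regimes}{regime B->A and B->C transitions under air-only,
#'     optic-flow-only and co-varied manipulations.}
#'   \item{fig4_offset}{low-range optic-flow curve with and without a
#'     constant airflow (2.5 m/s, inside the dynamic range) and offset
#'     classification.}
#' }
#'
#' @param config named list; unset fields take defaults (see
#'   `iaakit:::config_defaults()`). `profile` overrides bee parameters.
#' @return list (the bundle) with `config`, `config_hash` and
#'   kind-specific `summary` plus intermediate objects; written to
#'   `config$outdir` as JSON/CSV when set.
#' @export
run_experiment <- function(config = list()) {
  config <- modifyList(config_defaults(), config)
  hash <- config_hash(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  log_msg("info", config, "run_experiment kind=%s seed=%d hash=%s",
          config$kind, config$seed, hash)
  bundle <- switch(
    config$kind,
    fig1_tethered_ramp = stage("airflow", run_fig1(config)),
    fig2_random = stage("opticflow", run_fig2(config)),
    fig2_low_range = stage("opticflow_low", run_fig2_low(config)),
    fig3_regimes = stage("multimodal", run_fig3(config)),
    fig4_offset = stage("multimodal", run_fig4(config)),
    stop(sprintf("unknown experiment kind '%s'", config$kind),
         call. = FALSE))
  bundle$config <- config
  bundle$config_hash <- hash
  if (!is.null(config$outdir)) stage("write", write_summary(bundle, config$outdir))
  bundle
}

run_fig1 <- function(config) {
  bees <- make_bee_population(config$n_bees, seed = config$seed,
                              config = config$profile)
  proto <- build_protocol("linear_ramp_air")
  per_bee <- lapply(seq_along(bees), function(i) {
    tr <- simulate_iaa_trace(bees[[i]], proto, seed = config$seed * 1000 + i)
    bin_by_level(tr, by = "windspeed", frames_per_bin = config$frames_per_bin)
  })
  grand <- per_bee[[1]]
  grand$circ_mean <- colMeans(t(vapply(per_bee, function(b) b$circ_mean,
                                       numeric(nrow(grand)))))
  fit <- fit_airspeed_sigmoid(grand)
  region <- locate_dynamic_region(per_bee, alpha = config$alpha,
                                  seed = config$seed)
  norm <- normalize_response(grand)
  list(per_bee_bins = per_bee, fit = fit, region = region,
       normalized = norm,
       summary = list(amplitude = fit$amplitude, midpoint = fit$midpoint,
                      region_lower = region$lower,
                      region_upper = region$upper))
}

run_fig2 <- function(config) {
  bee <- make_bee_profile(config$profile, seed = config$seed)
  ramp_bins <- simulate_bin_means(bee, 1:25, n_per_bin = 50,
                                  mode = "of_ramp", seed = config$seed)
  thr <- detect_threshold(ramp_bins, alpha = config$alpha,
                          seed = config$seed)
  seq_proto <- build_protocol("random_of", list(seed = config$seed))
  sequence <- seq_proto$tf_cps
  seq_bins <- simulate_bin_means(bee, sequence, n_per_bin = 50,
                                 mode = "of_ramp", seed = config$seed + 1)
  ev <- evaluate_predictions(seq_bins, sequence, thr$threshold,
                             alpha = config$alpha_change,
                             seed = config$seed)
  scr <- scramble_significance(seq_bins, sequence, thr$threshold,
                               n_scrambles = max(100, config$n_scrambles),
                               seed = config$seed,
                               alpha = config$alpha_change)
  list(threshold = thr, records = ev$records, scores = ev$scores,
       scramble = scr[c("p_motion", "p_direction", "t_test_motion",
                        "t_test_direction", "n_scrambles")],
       summary = list(threshold = thr$threshold,
                      motion_score = ev$scores$motion_score,
                      direction_score = ev$scores$direction_score,
                      n_scored = ev$scores$n_scored,
                      p_motion = scr$p_motion,
                      p_direction = scr$p_direction))
}

run_fig2_low <- function(config) {
  bees <- make_bee_population(config$n_bees, seed = config$seed,
                              config = config$profile)
  proto <- build_protocol("low_range_of")
  traces <- lapply(seq_along(bees), function(i)
    simulate_iaa_trace(bees[[i]], proto, seed = config$seed * 1000 + i))
  res <- low_range_response(traces, alpha = config$alpha, seed = config$seed)
  res$summary <- list(slope = res$slope,
                      n_significant_steps = sum(res$steps$significant))
  res
}

#' Simulate regime-transition trials for a population of bees
#'
#' Generates the trial table consumed by [regime_delta_analysis()]: for
#' each bee, each transition (B->A, B->C) and each manipulation (air, of,
#' both), an IAA trace over the two 6 s regime epochs. The regime-B sample
#' is the last `frames_per_bin` frames before the step and the post sample
#' the first `frames_per_bin` frames after it (50 frames = 0.2 s at
#' 250 fps), so ΔIAA quantifies the step response before adaptation returns
#' the optic-flow component to baseline. Bees are run in the "matched"
#' optic-flow mode (see [make_bee_profile()]) unless their profile says
#' otherwise: the regime pairs are defined on matched points of the two
#' response curves, which is exactly what a crossmodally calibrated bee
#' realizes.
#'
#' @param bees list of `bee_profile`s.
#' @param seed integer seed.
#' @param frames_per_bin frames per phase sample (default 50).
#' @param of_mode optic-flow response mode for the trials (default
#'   "matched").
#' @return data.frame: `bee`, `transition`, `condition`, `phase`, `iaa_deg`.
#' @export
simulate_regime_trials <- function(bees, seed = 1, frames_per_bin = 50,
                                   of_mode = "matched") {
  grid <- expand.grid(to = c("A", "C"), vary = c("air", "of", "both"),
                      stringsAsFactors = FALSE)
  out <- NULL
  for (i in seq_along(bees)) {
    bee <- bees[[i]]
    if (!is.null(of_mode)) {
      cfg <- unclass(bee)
      cfg$seed <- NULL
      cfg$of_mode <- of_mode
      bee <- make_bee_profile(cfg, seed = bee$seed)
    }
    for (g in seq_len(nrow(grid))) {
      proto <- build_protocol("regime", list(from = "B", to = grid$to[g],
                                             vary = grid$vary[g]))
      tr <- simulate_iaa_trace(bee, proto, seed = seed + 97L * i + g)
      xB <- tail(tr$iaa_deg[tr$epoch == 1], frames_per_bin)
      xP <- head(tr$iaa_deg[tr$epoch == 2], frames_per_bin)
      out <- rbind(out,
                   data.frame(bee = i, transition = paste0("B", grid$to[g]),
                              condition = grid$vary[g], phase = "B",
                              iaa_deg = xB),
                   data.frame(bee = i, transition = paste0("B", grid$to[g]),
                              condition = grid$vary[g], phase = "post",
                              iaa_deg = xP))
    }
  }
  out
}

run_fig3 <- function(config) {
  bees <- make_bee_population(config$n_bees, seed = config$seed,
                              config = config$profile)
  trials <- simulate_regime_trials(bees, seed = config$seed)
  res <- lapply(split(trials, trials$transition), regime_delta_analysis,
                alpha = config$alpha, seed = config$seed)
  means <- lapply(res, function(r)
    vapply(split(r$delta$delta_iaa, r$delta$condition), mean, 1))
  list(trials = trials, analyses = res,
       summary = list(mean_delta = means))
}

run_fig4 <- function(config) {
  bee <- make_bee_profile(config$profile, seed = config$seed)
  levels <- c(0, 0.3, 0.6, 0.9, 1.2, 1.5, 1.8)
  alone <- simulate_bin_means(bee, levels, n_per_bin = 50,
                              mode = "of_low_range", seed = config$seed)
  # constant airflow inside the dynamic range shifts the whole curve down
  shift <- -bee$sigmoid_amplitude *
    plogis((2.5 - bee$sigmoid_midpoint) / bee$sigmoid_slope)
  bee2 <- make_bee_profile(modifyList(
    config$profile, list(baseline_iaa = bee$baseline_iaa + shift)),
    seed = config$seed)
  with_air <- simulate_bin_means(bee2, levels, n_per_bin = 50,
                                 mode = "of_low_range",
                                 seed = config$seed + 1)
  cls <- offset_classification(alone, with_air, alpha = config$alpha,
                               seed = config$seed)
  list(curve_alone = alone, curve_with = with_air, classification = cls,
       summary = list(verdict = cls$verdict,
                      pooled_delta = cls$pooled_delta))
}

#' Write an experiment bundle to disk
#'
#' Writes `summary.json` (summary + config + config hash) and, when
#' present, a prediction-audit CSV and a region/steps CSV into `outdir`.
#' Every file records the config hash that produced it.
#'
#' @param bundle result of [run_experiment()].
#' @param outdir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_summary <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  sj <- file.path(outdir, "summary.json")
  cfg <- bundle$config
  cfg <- cfg[setdiff(names(cfg), c("outdir", "log_level"))]
  jsonlite::write_json(
    list(config_hash = bundle$config_hash, config = cfg,
         summary = bundle$summary),
    sj, auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)
  paths <- c(paths, sj)
  if (!is.null(bundle$records)) {
    p <- file.path(outdir, "prediction_audit.csv")
    rec <- bundle$records
    rec$config_hash <- bundle$config_hash
    write.csv(rec, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(bundle$region)) {
    p <- file.path(outdir, "dynamic_region_steps.csv")
    st <- bundle$region$steps
    st$config_hash <- bundle$config_hash
    write.csv(st, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `reconstruct`, `analyze-airflow`,
#' `analyze-opticflow`, `analyze-multimodal`, `report`. Global flags:
#' `--config` (JSON file of [run_experiment()] fields), `--seed`,
#' `--outdir`, `--log-level`. A copy of this entry point is installed at
#' `system.file("cli", "iaakit.R", package = "iaakit")`.
#'
#' @param args character vector (default: command-line arguments).
#' @return invisibly, the bundle produced (if any).
#' @export
iaa_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  sub <- if (length(args)) args[1] else "report"
  rest <- args[-1]
  parser <- optparse::OptionParser(option_list = list(
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--outdir", type = "character", default = "iaakit_out"),
    optparse::make_option("--log-level", type = "character", default = "info",
                          dest = "log_level")))
  opt <- optparse::parse_args(parser, args = rest)
  config <- if (!is.null(opt$config))
    jsonlite::read_json(opt$config, simplifyVector = TRUE) else list()
  config$seed <- config$seed %||% opt$seed
  config$outdir <- config$outdir %||% opt$outdir
  config$log_level <- config$log_level %||% opt$log_level
  kind_map <- c(simulate = "fig1_tethered_ramp",
                `analyze-airflow` = "fig1_tethered_ramp",
                `analyze-opticflow` = "fig2_random",
                `analyze-multimodal` = "fig3_regimes",
                report = "fig1_tethered_ramp")
  if (sub == "reconstruct") {
    if (is.null(config$landmarks) || is.null(config$calibration))
      stop("reconstruct needs `landmarks` and `calibration` paths in --config",
           call. = FALSE)
    lm <- read_landmarks(config$landmarks)
    cams <- read_calibration(config$calibration)
    rec <- reconstruct_antennae(lm$landmarks, cams)
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    out <- file.path(config$outdir, "iaa_reconstructed.csv")
    write.csv(data.frame(frame = as.integer(names(rec$iaa_deg)),
                         iaa_deg = rec$iaa_deg), out, row.names = FALSE)
    message("wrote ", out)
    return(invisible(rec))
  }
  if (!sub %in% names(kind_map))
    stop(sprintf("unknown subcommand '%s'", sub), call. = FALSE)
  config$kind <- config$kind %||% unname(kind_map[sub])
  bundle <- run_experiment(config)
  invisible(bundle)
}
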