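# Synthetic inpatient sessions: time-of-day posture schedules, rendered
# 25 Hz accelerations consistent with each posture, and fixture sets on
# disk. Everything is seed-deterministic with no global RNG state.

#' Time-of-day posture schedule for the synthetic generator
#'
#' The day is tiled by blocks, each with a posture distribution; labels
#' are drawn from a time-inhomogeneous Markov chain that keeps the
#' previous label with probability `persistence` and otherwise redraws
#' from the current block's distribution (persistence produces realistic
#' multi-minute posture bouts). The default schedule mimics a
#' rehabilitation-ward day: reclining-dominant nights (21:00-06:00),
#' upright peaks around the 08:00/12:00/18:00 meals, and walking of the
#' order of 1% of daytime epochs.
#'
#' @param grid an [epoch_grid()].
#' @param blocks data.frame with columns `start_hour`, `end_hour`,
#'   `reclining`, `sitting_or_standing`, `walking`; blocks must tile
#'   0-24 h and each row sum to 1.
#' @param persistence probability of carrying the previous epoch's label
#'   over, in \[0, 1\].
#' @param seed integer seed for [simulate_posture_days()].
#' @return object of class `schedule_config`.
#' @export
schedule_config <- function(grid = epoch_grid(), blocks = NULL,
                            persistence = 0.95, seed = 1) {
  if (is.null(blocks)) blocks <- default_schedule_blocks()
  stopifnot(inherits(grid, "epoch_grid"),
            is.data.frame(blocks),
            all(c("start_hour", "end_hour", posture_levels()) %in%
                  names(blocks)),
            persistence >= 0, persistence <= 1)
  blocks <- blocks[order(blocks$start_hour), ]
  if (blocks$start_hour[1] != 0 ||
      blocks$end_hour[nrow(blocks)] != 24 ||
      any(blocks$end_hour[-nrow(blocks)] != blocks$start_hour[-1]))
    stop("schedule blocks must tile 0-24 h without gaps", call. = FALSE)
  p <- as.matrix(blocks[posture_levels()])
  if (any(abs(rowSums(p) - 1) > 1e-8) || any(p < 0))
    stop("each block's posture distribution must be non-negative and sum to 1",
         call. = FALSE)
  structure(list(grid = grid, blocks = blocks, persistence = persistence,
                 seed = seed),
            class = "schedule_config")
}

#' @rdname schedule_config
#' @export
default_schedule_blocks <- function() {
  data.frame(
    start_hour = c(0, 6, 8, 9, 12, 13, 18, 19, 21),
    end_hour   = c(6, 8, 9, 12, 13, 18, 19, 21, 24),
    reclining           = c(0.97, 0.60, 0.35, 0.55, 0.35, 0.55, 0.35,
                            0.70, 0.97),
    sitting_or_standing = c(0.03, 0.40, 0.64, 0.44, 0.64, 0.44, 0.64,
                            0.30, 0.03),
    walking             = c(0.00, 0.00, 0.01, 0.01, 0.01, 0.01, 0.01,
                            0.00, 0.00))
}

#' Simulate per-epoch posture label days from a schedule
#'
#' @param config a [schedule_config()].
#' @param n_days number of measurement days to draw; days are independent
#'   draws from the same schedule (day-to-day variation).
#' @param day_ids identifiers; default `day1, day2, ...`.
#' @return list of [posture_day()] objects (no missing epochs; use
#'   [inject_losses()] to add losses).
#' @export
simulate_posture_days <- function(config, n_days = 2,
                                  day_ids = paste0("day", seq_len(n_days))) {
  stopifnot(inherits(config, "schedule_config"), n_days >= 1)
  grid <- config$grid
  E <- grid$epochs_per_day
  hours <- ((seq_len(E) - 1) * grid$epoch_length) / 3600
  block_of <- findInterval(hours, config$blocks$start_hour)
  probs <- as.matrix(config$blocks[posture_levels()])
  lv <- posture_levels()
  with_seed(config$seed, {
    lapply(seq_len(n_days), function(d) {
      labels <- character(E)
      for (e in seq_len(E)) {
        p <- probs[block_of[e], ]
        if (e > 1 && stats::runif(1) < config$persistence) {
          labels[e] <- labels[e - 1]
        } else {
          labels[e] <- sample(lv, 1, prob = p)
        }
      }
      posture_day(day_ids[d], labels, grid)
    })
  })
}

#' Rendering parameters for synthetic accelerations
#'
#' Each posture maps to a trunk-angle regime; walking epochs additionally
#' modulate the acceleration norm with a gait oscillation so the step
#' detector can find them. Defaults keep the regimes cleanly separated by
#' the default 35/143 deg thresholds: reclining centred at 10 deg (prone
#' side of the band) or 170 deg (supine), upright at 90 deg, angular
#' jitter 8 deg s.d., sensor noise 0.03 g.
#'
#' @param reclining_angle,supine_angle,upright_angle regime mean trunk
#'   angles, degrees.
#' @param supine_fraction probability that a reclining epoch uses the
#'   supine regime instead of `reclining_angle`.
#' @param angle_jitter_sd per-epoch angular jitter s.d., degrees.
#' @param gait_amplitude norm oscillation amplitude while walking, g.
#' @param cadence step frequency, Hz; must give an inter-step interval
#'   inside the [walking_rule()] band.
#' @param noise_sd per-axis sensor noise s.d., g.
#' @param sample_rate output sampling rate, Hz (default 25).
#' @return object of class `accel_render_config`.
#' @export
accel_render_config <- function(reclining_angle = 10, supine_angle = 170,
                                upright_angle = 90, supine_fraction = 0.4,
                                angle_jitter_sd = 8, gait_amplitude = 0.3,
                                cadence = 1.8, noise_sd = 0.03,
                                sample_rate = 25) {
  thr <- posture_thresholds()
  stopifnot(reclining_angle < thr$prone_upright,
            supine_angle > thr$upright_supine,
            upright_angle > thr$prone_upright,
            upright_angle < thr$upright_supine,
            supine_fraction >= 0, supine_fraction <= 1,
            angle_jitter_sd >= 0, gait_amplitude >= 0, cadence > 0,
            noise_sd >= 0, sample_rate > 0)
  structure(list(reclining_angle = reclining_angle,
                 supine_angle = supine_angle,
                 upright_angle = upright_angle,
                 supine_fraction = supine_fraction,
                 angle_jitter_sd = angle_jitter_sd,
                 gait_amplitude = gait_amplitude,
                 cadence = cadence, noise_sd = noise_sd,
                 sample_rate = sample_rate),
            class = "accel_render_config")
}

#' Render a 25 Hz acceleration series consistent with a posture day
#'
#' For each non-missing epoch draws a base trunk angle from the label's
#' regime (mean + Gaussian jitter) and emits evenly spaced samples of the
#' gravity vector at that inclination, `(0, sin(theta), cos(theta))` g,
#' plus per-axis sensor noise. Walking epochs scale the vector by
#' `1 + A sin(2 pi cadence t)` so the norm oscillates at step cadence.
#' Missing epochs emit no samples.
#'
#' @param day a [posture_day()].
#' @param config an [accel_render_config()].
#' @param date calendar date (`"YYYY-MM-DD"`) used for the timestamps.
#' @param seed integer seed; rendering is deterministic given it.
#' @return an [accel_series()].
#' @export
render_acceleration <- function(day, config = accel_render_config(),
                                date = "2000-01-01", seed = 1) {
  stopifnot(inherits(day, "posture_day"),
            inherits(config, "accel_render_config"))
  grid <- day$grid
  spe <- round(config$sample_rate * grid$epoch_length)  # samples per epoch
  day0 <- as.POSIXct(paste(date, "00:00:00"), tz = "")
  keep <- which(day$labels != "missing")
  if (!length(keep)) stop("day is entirely missing; nothing to render",
                          call. = FALSE)
  with_seed(seed, {
    parts <- lapply(keep, function(e) {
      lab <- day$labels[e]
      mu <- switch(lab,
                   reclining = if (stats::runif(1) < config$supine_fraction)
                     config$supine_angle else config$reclining_angle,
                   sitting_or_standing = config$upright_angle,
                   walking = config$upright_angle)
      theta <- stats::rnorm(1, mu, config$angle_jitter_sd)
      theta <- max(-179.5, min(179.5, theta))
      tloc <- (seq_len(spe) - 1) / config$sample_rate
      rad <- theta * pi / 180
      scale <- if (lab == "walking")
        1 + config$gait_amplitude * sin(2 * pi * config$cadence * tloc)
      else rep(1, spe)
      data.frame(
        t = (e - 1) * grid$epoch_length + tloc,
        ax = stats::rnorm(spe, 0, config$noise_sd),
        ay = scale * sin(rad) + stats::rnorm(spe, 0, config$noise_sd),
        az = scale * cos(rad) + stats::rnorm(spe, 0, config$noise_sd))
    })
    all <- do.call(rbind, parts)
    accel_series(day$day_id, day0 + all$t, all$ax, all$ay, all$az,
                 nominal_rate = config$sample_rate)
  })
}

#' Write a reproducible set of synthetic session fixtures to disk
#'
#' Generates `n_sessions` multi-day sessions, optionally injects block
#' losses, and writes per-day acceleration and posture CSVs plus a JSON
#' manifest recording ids, paths, seeds and the injected-loss epochs.
#' Regeneration with the same seed is byte-identical.
#'
#' @param dir output directory (created if needed).
#' @param n_sessions,days_per_session counts.
#' @param loss a [loss_spec()] applied independently per day, or `NULL`.
#' @param seed integer base seed.
#' @param schedule a [schedule_config()]; its own seed is overridden per
#'   session from `seed`.
#' @param render an [accel_render_config()], or `NULL` to skip the (bulky)
#'   acceleration files and write posture CSVs only.
#' @return the manifest, invisibly (also written as `manifest.json`).
#' @export
make_session_fixtures <- function(dir, n_sessions = 1, days_per_session = 2,
                                  loss = NULL, seed = 1,
                                  schedule = schedule_config(),
                                  render = accel_render_config()) {
  if (!dir.exists(dir))
    if (!dir.create(dir, recursive = TRUE))
      stop("cannot create fixture directory: ", dir, call. = FALSE)
  sessions <- list()
  for (s in seq_len(n_sessions)) {
    sid <- sprintf("session%02d", s)
    cfg <- schedule
    cfg$seed <- child_seed(seed, s)
    day_ids <- sprintf("%s_day%d", sid, seq_len(days_per_session))
    days <- simulate_posture_days(cfg, days_per_session, day_ids)
    files <- list()
    for (d in seq_along(days)) {
      day <- days[[d]]
      lost_epochs <- integer(0)
      if (!is.null(loss)) {
        spec <- loss
        spec$seed <- child_seed(seed, s, d, 7L)
        masked <- inject_losses(day, spec)
        lost_epochs <- which(masked$labels == "missing" &
                               day$labels != "missing")
        day <- masked
      }
      pfile <- file.path(dir, paste0(day$day_id, "_posture.csv"))
      write_posture_csv(day, pfile)
      entry <- list(day_id = day$day_id, posture = basename(pfile),
                    injected_loss_epochs = lost_epochs)
      if (!is.null(render)) {
        acc <- render_acceleration(day, render,
                                   date = as.character(
                                     as.Date("2000-01-01") + (d - 1)),
                                   seed = child_seed(seed, s, d, 11L))
        afile <- file.path(dir, paste0(day$day_id, "_accel.csv"))
        write_accel_csv(acc, afile)
        entry$accel <- basename(afile)
      }
      files[[d]] <- entry
    }
    sessions[[s]] <- list(session_id = sid, seed = cfg$seed, days = files)
  }
  manifest <- list(seed = seed, n_sessions = n_sessions,
                   days_per_session = days_per_session,
                   epoch_length = schedule$grid$epoch_length,
                   loss = if (is.null(loss)) NULL else
                     list(target_rate = loss$target_rate,
                          block_length = loss$block_length),
                   sessions = sessions)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Write an acceleration series as CSV
#'
#' Header `timestamp,ax,ay,az`, ISO 8601 timestamps with fractional
#' seconds, components in g.
#'
#' @param series an [accel_series()].
#' @param path file path.
#' @export
write_accel_csv <- function(series, path) {
  stopifnot(inherits(series, "accel_series"))
  s <- series$samples
  utils::write.csv(data.frame(
    timestamp = format(s$time, "%Y-%m-%dT%H:%M:%OS3"),
    ax = sprintf("%.5f", s$ax),
    ay = sprintf("%.5f", s$ay),
    az = sprintf("%.5f", s$az)),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Synthetic heart-rate day series (quantitative-ensemble exerciser)
#'
#' A deliberately simple circadian sinusoid plus noise, provided only to
#' exercise [ensemble_quantitative()]; it is not a physiological model.
#'
#' @param grid an [epoch_grid()].
#' @param base,amplitude mean level and circadian swing, beats/min.
#' @param noise_sd additive noise s.d., beats/min.
#' @param seed integer seed.
#' @return numeric vector, one value per epoch.
#' @export
simulate_heart_rate_day <- function(grid = epoch_grid(), base = 70,
                                    amplitude = 8, noise_sd = 3, seed = 1) {
  E <- grid$epochs_per_day
  h <- ((seq_len(E) - 1) * grid$epoch_length) / 3600
  with_seed(seed,
            base - amplitude * cos(2 * pi * (h - 4) / 24) +
              stats::rnorm(E, 0, noise_sd))
}
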