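# Closed-loop moon tracking: threshold segmentation of the bright disk,
# binary centroid, deadband-gated corrective motor pulses to a two-axis
# alt-azimuth mount, and loss-of-moon error policy.
#
# The control law is deliberately minimal: the mount stays motionless while
# the moon drifts inside a deadband around the reference point, then is
# re-centred with proportional-duration pulses.  This keeps the recorded
# video still for almost all of every correction interval.

#' Tracker configuration
#'
#' @param work_width_px,work_height_px working resolution at which tracking is
#'   evaluated (defaults 800 x 600)
#' @param threshold 8-bit segmentation level, strictly between 0 and 255;
#'   adjustable at runtime when clouds or fog change the disk brightness
#' @param deadband_radius_px no-correction radius around the reference point;
#'   default 12.5% of the working-frame height.  Re-centring, once triggered,
#'   continues until the error falls below half the deadband (hysteresis
#'   against boundary chatter)
#' @param reference_point_px target point for the moon centroid; default the
#'   frame centre
#' @param min_moon_area_px minimum segmented area for a valid moon fix
#' @param sample_interval_s seconds between tracking evaluations
#' @param pulse_gain seconds of motor pulse per pixel of error; `NULL` (the
#'   default) calibrates it at session start with a short probe pulse per axis
#' @param max_pulse_s cap on a single pulse duration
#' @param loss_patience number of consecutive invalid evaluations tolerated
#'   (transient cloud cover) before the session is terminated with an error
#' @return an object of class `tracker_config`
#' @export
tracker_config <- function(work_width_px = 800, work_height_px = 600,
                           threshold = 120,
                           deadband_radius_px = 0.125 * work_height_px,
                           reference_point_px = c(work_width_px / 2,
                                                  work_height_px / 2),
                           min_moon_area_px = 200,
                           sample_interval_s = 5,
                           pulse_gain = NULL,
                           max_pulse_s = 2,
                           loss_patience = 5) {
  if (threshold <= 0 || threshold >= 255)
    stop("threshold must satisfy 0 < threshold < 255", call. = FALSE)
  if (deadband_radius_px >= min(work_width_px, work_height_px) / 2)
    stop("deadband radius must be less than half the smaller working dimension",
         call. = FALSE)
  if (sample_interval_s <= 0) stop("sample_interval_s must be > 0", call. = FALSE)
  if (min_moon_area_px <= 0) stop("min_moon_area_px must be > 0", call. = FALSE)
  structure(list(
    work_width_px = as.integer(work_width_px),
    work_height_px = as.integer(work_height_px),
    threshold = threshold,
    deadband_radius_px = deadband_radius_px,
    reference_point_px = reference_point_px,
    min_moon_area_px = min_moon_area_px,
    sample_interval_s = sample_interval_s,
    pulse_gain = pulse_gain,
    max_pulse_s = max_pulse_s,
    loss_patience = as.integer(loss_patience)
  ), class = "tracker_config")
}

#' Extract the low-resolution tracking frame
#'
#' Nearest-neighbour resampling to the working resolution.  Each output pixel
#' copies one input pixel, so intensity order is preserved exactly and a
#' constant image stays constant; an input already at working resolution is
#' returned unchanged.
#'
#' @param frame numeric matrix (height x width)
#' @param cfg a [tracker_config()]
#' @return numeric matrix of dimensions `work_height_px` x `work_width_px`
#' @export
extract_tracking_frame <- function(frame, cfg) {
  h <- nrow(frame); w <- ncol(frame)
  if (h == 0 || w == 0) stop("frame must be nonempty", call. = FALSE)
  if (h == cfg$work_height_px && w == cfg$work_width_px) return(frame)
  ri <- pmin(h, pmax(1L, ceiling((seq_len(cfg$work_height_px) - 0.5) * h /
                                   cfg$work_height_px)))
  ci <- pmin(w, pmax(1L, ceiling((seq_len(cfg$work_width_px) - 0.5) * w /
                                   cfg$work_width_px)))
  frame[ri, ci, drop = FALSE]
}

#' Threshold segmentation of the moon
#'
#' @param gray numeric matrix on the 8-bit scale
#' @param threshold level in (0, 255); pixels strictly above it are moon
#' @return logical matrix; an empty mask is legal output (consumed by loss
#'   detection)
#' @export
threshold_moon <- function(gray, threshold) {
  if (threshold <= 0 || threshold >= 255)
    stop("threshold must satisfy 0 < threshold < 255", call. = FALSE)
  gray > threshold
}

#' Moon state from a binary mask
#'
#' Centroid (mean position of mask pixels, in continuous image coordinates),
#' pixel area, equivalent-disk radius `sqrt(area/pi)`, and a validity flag
#' requiring at least `min_moon_area_px` pixels.  The centroid is computed on
#' the binary mask, not intensity-weighted, so it is robust to exposure
#' changes above threshold.
#'
#' @param mask logical matrix at working resolution
#' @param cfg a [tracker_config()]
#' @return list of class `moon_state`: `centroid_px` c(x, y), `area_px`,
#'   `fitted_radius_px`, `valid`
#' @export
moon_centroid <- function(mask, cfg) {
  area <- sum(mask)
  if (area == 0) {
    return(structure(list(centroid_px = c(NA_real_, NA_real_), area_px = 0L,
                          fitted_radius_px = 0, valid = FALSE),
                     class = "moon_state"))
  }
  idx <- which(mask, arr.ind = TRUE)
  cx <- mean(idx[, 2]) - 0.5
  cy <- mean(idx[, 1]) - 0.5
  structure(list(centroid_px = c(cx, cy), area_px = as.integer(area),
                 fitted_radius_px = sqrt(area / pi),
                 valid = area >= cfg$min_moon_area_px),
            class = "moon_state")
}

#' Deadband-gated corrective motor commands
#'
#' No command is issued while the centroid sits within the deadband radius of
#' the reference point (or, once a correction episode has ended, until it
#' leaves the deadband again).  Outside it, one command per offending axis is
#' returned with pulse duration `min(pulse_gain * |error|, max_pulse_s)`,
#' signed to move the moon image toward the reference.
#'
#' @param state a valid `moon_state`
#' @param cfg a [tracker_config()]
#' @param gains per-axis seconds-per-pixel and sign, as calibrated by the
#'   tracking loop: list(x = c(gain, sign), y = c(gain, sign)); when `NULL`,
#'   `cfg$pulse_gain` with positive sign is used
#' @param engaged logical; `TRUE` while a correction episode is in progress,
#'   in which case the trigger radius is the hysteresis target
#'   `deadband_radius_px / 2` instead of the full deadband
#' @return list of commands, each `list(axis, direction, pulse_duration_s,
#'   duty_cycle)`; empty when inside the (hysteresis-adjusted) deadband
#' @export
compute_correction <- function(state, cfg, gains = NULL, engaged = FALSE) {
  if (!isTRUE(state$valid))
    stop("compute_correction requires a valid moon state; route invalid states to loss handling",
         call. = FALSE)
  err <- state$centroid_px - cfg$reference_point_px
  r <- sqrt(sum(err^2))
  trigger <- if (engaged) cfg$deadband_radius_px / 2 else cfg$deadband_radius_px
  if (r <= trigger) return(list())
  if (is.null(gains)) {
    g <- cfg$pulse_gain
    if (is.null(g)) g <- 0.02
    gains <- list(x = c(g, 1), y = c(g, 1))
  }
  cmds <- list()
  axes <- list(x = list(axis = "azimuth", e = err[1]),
               y = list(axis = "altitude", e = err[2]))
  for (nm in names(axes)) {
    e <- axes[[nm]]$e
    if (abs(e) < 1) next   # axis already on target contributes no pulse
    gn <- gains[[nm]]
    dur <- min(gn[1] * abs(e), cfg$max_pulse_s)
    if (dur <= 0) next
    cmds[[length(cmds) + 1L]] <- list(
      axis = axes[[nm]]$axis,
      direction = -sign(e) * gn[2],
      pulse_duration_s = dur,
      duty_cycle = 1)
  }
  cmds
}

#' Loss-of-moon policy
#'
#' Transient occlusions (clouds) make tracking fail until they pass; only a
#' sustained run of invalid evaluations counts as complete loss and
#' terminates the session with an error.
#'
#' @param state a `moon_state`
#' @param consecutive_invalid number of invalid evaluations immediately
#'   preceding this one (>= 0)
#' @param cfg a [tracker_config()]
#' @return list with `decision` (`"continue"` or `"error_and_close"`) and the
#'   updated `consecutive_invalid` counter
#' @export
detect_loss <- function(state, consecutive_invalid, cfg) {
  if (consecutive_invalid < 0) stop("consecutive_invalid must be >= 0", call. = FALSE)
  if (isTRUE(state$valid))
    return(list(decision = "continue", consecutive_invalid = 0L))
  n <- consecutive_invalid + 1L
  list(decision = if (n >= cfg$loss_patience) "error_and_close" else "continue",
       consecutive_invalid = n)
}

# one tracking evaluation; env carries controller state across calls:
#   engaged, consecutive_invalid, gains, last_eval_t, busy_until
.tracker_step <- function(env, frame, t, cfg) {
  work <- extract_tracking_frame(frame, cfg)
  state <- moon_centroid(threshold_moon(work, cfg$threshold), cfg)
  loss <- detect_loss(state, env$consecutive_invalid, cfg)
  env$consecutive_invalid <- loss$consecutive_invalid
  if (loss$decision == "error_and_close")
    return(list(status = "error_and_close", state = state, commands = list()))
  cmds <- list()
  if (state$valid && t >= env$busy_until) {
    cmds <- compute_correction(state, cfg, gains = env$gains,
                               engaged = env$engaged)
    err <- sqrt(sum((state$centroid_px - cfg$reference_point_px)^2))
    env$engaged <- if (env$engaged) err >= cfg$deadband_radius_px / 2
                   else err > cfg$deadband_radius_px
    if (length(cmds) > 0)
      env$busy_until <- t + max(vapply(cmds, `[[`, 0, "pulse_duration_s"))
  }
  list(status = "continue", state = state, commands = cmds)
}

# probe each axis with a short pulse against the plant and measure image
# motion, yielding seconds-per-pixel gain and sign per axis
.calibrate_axes <- function(source_fn, plant, cfg, probe_s = 0.3) {
  gains <- list(x = c(0.02, 1), y = c(0.02, 1))
  for (axis in c("azimuth", "altitude")) {
    f0 <- source_fn()
    if (is.null(f0)) return(gains)
    s0 <- moon_centroid(threshold_moon(extract_tracking_frame(f0$frame, cfg),
                                       cfg$threshold), cfg)
    mount_pulse(plant, axis, +1, probe_s)
    f1 <- source_fn()
    if (is.null(f1)) return(gains)
    s1 <- moon_centroid(threshold_moon(extract_tracking_frame(f1$frame, cfg),
                                       cfg$threshold), cfg)
    if (!s0$valid || !s1$valid) next
    d <- s1$centroid_px - s0$centroid_px
    comp <- if (axis == "azimuth") d[1] else d[2]
    key <- if (axis == "azimuth") "x" else "y"
    if (abs(comp) > 0.25) {
      # a +1 pulse of probe_s moved the image by comp px along this axis, so
      # a command (direction dir, duration p) moves it dir * comp/probe_s * p;
      # cancelling an error e needs dir = -sign(e)*sign(comp), p = |e|*probe_s/|comp|
      gains[[key]] <- c(probe_s / abs(comp), sign(comp))
    }
    # undo the probe displacement
    mount_pulse(plant, axis, -1, probe_s)
    source_fn()
  }
  gains
}

#' Run the closed-loop tracking controller over a frame stream
#'
#' Evaluates tracking every `sample_interval_s`, logging every moon state,
#' command and loss decision.  When a mount plant is supplied, commands are
#' applied to it (so a simulator source that renders from the plant pose is
#' driven closed-loop) and the per-axis pulse gain and sign are first
#' calibrated with a short probe pulse.  A command is never issued while the
#' previous pulse is still executing.
#'
#' @param source a closure returning `list(frame, t, index)` per call and
#'   `NULL` when exhausted (see [simulate_session()] and
#'   [frame_sequence_source()])
#' @param cfg a [tracker_config()]
#' @param plant optional mount plant from [mount_plant()]
#' @return list of class `tracking_session`: `log` (one row per evaluation:
#'   `t`, `frame_index`, `centroid_x/y`, `area`, `valid`, `n_commands`,
#'   `decision`), `commands` (one row per issued command), `terminated`
#'   (logical: ended by complete loss of the moon), `gains`
#' @export
run_tracking_loop <- function(source, cfg, plant = NULL) {
  env <- new.env(parent = emptyenv())
  env$engaged <- FALSE; env$consecutive_invalid <- 0L
  env$busy_until <- -Inf
  env$gains <- if (!is.null(plant)) .calibrate_axes(source, plant, cfg) else NULL
  log <- list(); cmdlog <- list()
  terminated <- FALSE
  next_eval <- -Inf
  repeat {
    item <- source()
    if (is.null(item)) break
    if (item$t < next_eval) next
    next_eval <- item$t + cfg$sample_interval_s
    res <- .tracker_step(env, item$frame, item$t, cfg)
    log[[length(log) + 1L]] <- data.frame(
      t = item$t, frame_index = item$index,
      centroid_x = res$state$centroid_px[1],
      centroid_y = res$state$centroid_px[2],
      area = res$state$area_px, valid = res$state$valid,
      n_commands = length(res$commands),
      decision = res$status)
    for (cmd in res$commands) {
      cmdlog[[length(cmdlog) + 1L]] <- data.frame(
        t = item$t, axis = cmd$axis, direction = cmd$direction,
        pulse_s = cmd$pulse_duration_s, duty = cmd$duty_cycle)
      if (!is.null(plant))
        mount_pulse(plant, cmd$axis, cmd$direction, cmd$pulse_duration_s,
                    cmd$duty_cycle)
    }
    if (res$status == "error_and_close") { terminated <- TRUE; break }
  }
  structure(list(
    log = if (length(log)) do.call(rbind, log) else NULL,
    commands = if (length(cmdlog)) do.call(rbind, cmdlog) else
      data.frame(t = numeric(0), axis = character(0), direction = numeric(0),
                 pulse_s = numeric(0), duty = numeric(0)),
    terminated = terminated,
    gains = env$gains
  ), class = "tracking_session")
}

#' Write a tracking session log to CSV
#' @param session a `tracking_session`
#' @param path output file
#' @param t0 POSIXct session start used to derive wall-clock timestamps
#' @return `path`, invisibly
#' @export
write_tracking_log <- function(session, path,
                               t0 = as.POSIXct("2018-04-28 21:00:00", tz = "UTC")) {
  log <- session$log
  out <- data.frame(
    wall_time_iso = format(t0 + log$t, "%Y-%m-%dT%H:%M:%OS3Z"),
    frame_index = log$frame_index,
    centroid_x = round(log$centroid_x, 2),
    centroid_y = round(log$centroid_y, 2),
    area = log$area, valid = log$valid,
    n_commands = log$n_commands, decision = log$decision)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
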