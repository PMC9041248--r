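# The simulated mount plant and the session simulator that ties rendering,
# drift, the mount, the controller and the truth/timestamp logs together.

#' Simulated two-axis alt-azimuth mount plant
#'
#' The plant the controller drives in place of real motors.  The motor scale
#' is set by gear motors of about 0.5 rotation/min at no load, geared down
#' further at the mount; `gear_reduction` expresses the combined reduction as
#' image-motion degrees of sky per motor-second at full duty.  Optional
#' backlash absorbs dead motion on direction reversal.  Axis polarity (which
#' image direction a positive pulse moves the moon) is a property of the
#' optical train; the tracker discovers it with its calibration probe.
#'
#' @param azimuth_deg,altitude_deg initial pose
#' @param no_load_rpm motor no-load speed, rotations/min
#' @param gear_reduction dimensionless reduction from motor rotation to mount
#'   motion; the effective slew rate is `no_load_rpm * 360 / 60 / gear_reduction`
#'   degrees of sky per second
#' @param backlash_deg dead motion absorbed when an axis reverses direction
#' @param polarity_az,polarity_alt +1 or -1; sign relating a positive pulse to
#'   image-plane +x / +y (downward) motion of the moon
#' @return a mutable environment of class `mount_plant`
#' @export
mount_plant <- function(azimuth_deg = 180, altitude_deg = 45,
                        no_load_rpm = 0.5, gear_reduction = 30,
                        backlash_deg = 0,
                        polarity_az = 1, polarity_alt = 1) {
  env <- new.env(parent = emptyenv())
  env$azimuth_deg <- azimuth_deg
  env$altitude_deg <- clamp(altitude_deg, 0, 90)
  env$slew_deg_s <- no_load_rpm * 360 / 60 / gear_reduction
  env$backlash_deg <- backlash_deg
  env$polarity <- c(azimuth = polarity_az, altitude = polarity_alt)
  env$last_dir <- c(azimuth = 0, altitude = 0)
  env$pending_backlash <- c(azimuth = 0, altitude = 0)
  class(env) <- "mount_plant"
  env
}

#' Apply one motor pulse to the plant
#'
#' @param plant a [mount_plant()]
#' @param axis `"azimuth"` or `"altitude"`
#' @param direction +1 or -1
#' @param pulse_duration_s pulse length in seconds
#' @param duty_cycle PWM duty fraction in (0, 1]
#' @return the moved distance in degrees (after backlash), invisibly
#' @export
mount_pulse <- function(plant, axis, direction, pulse_duration_s,
                        duty_cycle = 1) {
  axis <- match.arg(axis, c("azimuth", "altitude"))
  travel <- plant$slew_deg_s * duty_cycle * pulse_duration_s
  if (plant$backlash_deg > 0 && plant$last_dir[[axis]] != 0 &&
      direction != plant$last_dir[[axis]]) {
    absorbed <- min(travel, plant$backlash_deg)
    travel <- travel - absorbed
  }
  plant$last_dir[[axis]] <- direction
  if (axis == "azimuth") {
    plant$azimuth_deg <- plant$azimuth_deg + direction * travel
  } else {
    plant$altitude_deg <- clamp(plant$altitude_deg + direction * travel, 0, 90)
  }
  invisible(travel)
}

# image-plane displacement (px, y-down) of the moon due to the mount pose
# relative to a reference pose
.mount_image_offset_px <- function(plant, pose0, ppd) {
  c((plant$azimuth_deg - pose0[1]) * ppd * plant$polarity[["azimuth"]],
    (plant$altitude_deg - pose0[2]) * ppd * plant$polarity[["altitude"]])
}

#' Simulate an observation session
#'
#' Steps frames at the nominal rate (with optional per-frame timing jitter),
#' drifting the moon linearly across the image plane, rendering active
#' silhouette transits, and — when a tracker configuration is supplied —
#' running the closed-loop controller against the mount plant so corrective
#' pulses move the rendered moon.  Emits a per-frame ground-truth log and a
#' checkpointed timestamp log covering every frame.
#'
#' Frames are rendered lazily: pixels are produced only for frames the
#' tracker evaluates, frames passed to `on_frame`, frames kept in memory, or
#' frames written to disk, while truth and timing cover every frame.
#'
#' @param scene a [scene_config()]
#' @param schedule list of [transit_spec()]
#' @param duration_s session length in seconds (> 0)
#' @param tracker optional [tracker_config()]; enables closed-loop tracking
#' @param plant a [mount_plant()]; only used when `tracker` is given
#' @param moon_start_px starting moon centre, default the frame centre
#' @param out_dir optional directory; when given, frames are written as a
#'   numbered PNG sequence plus a timestamp log and a ground-truth JSONL file
#' @param keep_frames keep rendered frames in memory (lists of matrices);
#'   only sensible for short sessions
#' @param on_frame optional `function(frame, index, t)` called for every frame
#' @param checkpoint_interval_s cadence of timestamp-log checkpoints
#' @return list of class `session_result`: `truth` (per-transit per-frame
#'   data frame), `moon_truth` (per-frame moon centre), `timestamp_log`,
#'   `tracking` (a `tracking_session` or NULL), `frames` (or NULL),
#'   `n_frames`, `terminated`, `out_dir`
#' @export
simulate_session <- function(scene, schedule, duration_s,
                             tracker = NULL, plant = mount_plant(),
                             moon_start_px = c(scene$frame_width_px / 2,
                                               scene$frame_height_px / 2),
                             out_dir = NULL, keep_frames = FALSE,
                             on_frame = NULL,
                             checkpoint_interval_s = 1) {
  if (duration_s <= 0) stop("duration_s must be > 0", call. = FALSE)
  n_frames <- max(1L, round(duration_s * scene$fps_nominal))
  period <- 1 / scene$fps_nominal
  # frame clock with optional jitter (imprecise software-timed capture)
  times <- .with_seed(scene$rng_seed + 1L, {
    if (scene$timing_jitter > 0) {
      dt <- period * (1 + stats::runif(n_frames - 1, -scene$timing_jitter,
                                       scene$timing_jitter))
      cumsum(c(0, dt))
    } else (seq_len(n_frames) - 1) * period
  })
  ppd <- px_per_deg(scene)
  drift_dir <- deg2rad(scene$drift_direction_deg)
  drift_vec_px_s <- scene$drift_rate_deg_per_min / 60 * ppd *
    c(cos(drift_dir), -sin(drift_dir))
  pose0 <- c(plant$azimuth_deg, plant$altitude_deg)
  kins <- lapply(schedule, .transit_kinematics, scene = scene)
  durs <- vapply(kins, .transit_duration_s, 0)
  starts <- vapply(schedule, `[[`, 0, "start_time_s")
  R <- moon_radius_px(scene)

  moon_center_at <- function(t) {
    moon_start_px + t * drift_vec_px_s -
      .mount_image_offset_px(plant, pose0, ppd)
  }
  active_at <- function(t) {
    which(starts - 0.5 <= t & t <= starts + durs + 0.5)
  }

  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  frames <- if (keep_frames) vector("list", n_frames) else NULL
  truth_rows <- vector("list", n_frames)
  moon_x <- moon_y <- numeric(n_frames)
  i <- 0L

  render_needed_always <- keep_frames || !is.null(on_frame) || !is.null(out_dir)

  emit_frame <- function(need_pixels) {
    i <<- i + 1L
    if (i > n_frames) return(NULL)
    t <- times[i]
    mc <- moon_center_at(t)
    moon_x[i] <<- mc[1]; moon_y[i] <<- mc[2]
    act <- active_at(t)
    if (length(act) > 0) {
      pos <- vapply(act, function(k)
        .transit_position(schedule[[k]], kins[[k]], t), numeric(2))
      cx <- mc[1] + pos[1, ]; cy <- mc[2] + pos[2, ]
      rdist <- sqrt((cx - mc[1])^2 + (cy - mc[2])^2)
      # a silhouette is "on disk" when its body, not just its centroid,
      # reaches the rim: allow the ellipse's half-extent along the radial
      # direction (capped at half the body length), minus half a pixel so a
      # truth-visible frame always has rendered silhouette pixels on the disk
      ext <- vapply(seq_along(act), function(j) {
        k <- act[j]
        a <- max(schedule[[k]]$silhouette_length_px / 2, 0.5)
        b <- max(a / 3, 0.35)
        rad_ang <- atan2(pos[2, j], pos[1, j])          # y-down
        ax <- deg2rad(kins[[k]]$axis_angle_deg)
        gam <- rad_ang - (-ax)                          # axis angle in y-down
        sqrt((a * cos(gam))^2 + (b * sin(gam))^2)
      }, 0)
      truth_rows[[i]] <<- data.frame(
        transit_id = act, frame_index = i, t = t,
        x = cx, y = cy,
        in_frame = cx >= 0 & cx <= scene$frame_width_px &
          cy >= 0 & cy <= scene$frame_height_px,
        visible = rdist <= R + pmax(ext - 0.5, 0))
    }
    frame <- NULL
    if (need_pixels || render_needed_always) {
      frame <- render_frame(scene, mc, schedule[act], t)
      attr(frame, "index") <- i
      if (keep_frames) frames[[i]] <<- frame
      if (!is.null(on_frame)) on_frame(frame, i, t)
      if (!is.null(out_dir))
        png::writePNG(frame / 255,
                      file.path(out_dir, sprintf("frame_%06d.png", i)))
    }
    list(frame = frame, t = t, index = i)
  }

  tracking <- NULL
  terminated <- FALSE
  if (!is.null(tracker)) {
    # inline controller drive so frames between evaluations stay unrendered
    env <- new.env(parent = emptyenv())
    env$engaged <- FALSE; env$consecutive_invalid <- 0L; env$busy_until <- -Inf
    env$gains <- .calibrate_axes(function() emit_frame(need_pixels = TRUE),
                                 plant, tracker)
    log <- list(); cmdlog <- list()
    next_eval <- -Inf
    repeat {
      if (i >= n_frames) break
      need <- times[i + 1L] >= next_eval
      item <- emit_frame(need_pixels = need)
      if (is.null(item)) break
      if (!need) next
      next_eval <- item$t + tracker$sample_interval_s
      res <- .tracker_step(env, item$frame, item$t, tracker)
      log[[length(log) + 1L]] <- data.frame(
        t = item$t, frame_index = item$index,
        centroid_x = res$state$centroid_px[1],
        centroid_y = res$state$centroid_px[2],
        area = res$state$area_px, valid = res$state$valid,
        n_commands = length(res$commands), decision = res$status)
      for (cmd in res$commands) {
        cmdlog[[length(cmdlog) + 1L]] <- data.frame(
          t = item$t, axis = cmd$axis, direction = cmd$direction,
          pulse_s = cmd$pulse_duration_s, duty = cmd$duty_cycle)
        mount_pulse(plant, cmd$axis, cmd$direction, cmd$pulse_duration_s,
                    cmd$duty_cycle)
      }
      if (res$status == "error_and_close") { terminated <- TRUE; break }
    }
    tracking <- structure(list(
      log = if (length(log)) do.call(rbind, log) else NULL,
      commands = if (length(cmdlog)) do.call(rbind, cmdlog) else
        data.frame(t = numeric(0), axis = character(0),
                   direction = numeric(0), pulse_s = numeric(0),
                   duty = numeric(0)),
      terminated = terminated, gains = env$gains), class = "tracking_session")
  } else {
    while (!is.null(emit_frame(need_pixels = FALSE))) {}
  }
  n_emitted <- min(i, n_frames)

  # timestamp log: checkpoints at the first frame and then every interval
  tlog <- timestamp_log(camera_settings = list(
    fps_nominal = scene$fps_nominal, width = scene$frame_width_px,
    height = scene$frame_height_px))
  last_cp <- -Inf
  for (k in seq_len(n_emitted)) {
    if (k == 1L || times[k] - last_cp >= checkpoint_interval_s ||
        k == n_emitted) {
      tlog <- append_checkpoint(tlog, times[k], k - 1L)
      last_cp <- times[k]
    }
  }

  truth <- if (any(!vapply(truth_rows[seq_len(n_emitted)], is.null, TRUE)))
    do.call(rbind, truth_rows[seq_len(n_emitted)]) else
    data.frame(transit_id = integer(0), frame_index = integer(0),
               t = numeric(0), x = numeric(0), y = numeric(0),
               in_frame = logical(0), visible = logical(0))
  moon_truth <- data.frame(frame_index = seq_len(n_emitted),
                           t = times[seq_len(n_emitted)],
                           moon_x = moon_x[seq_len(n_emitted)],
                           moon_y = moon_y[seq_len(n_emitted)])

  if (!is.null(out_dir)) {
    write_timestamp_log(tlog, file.path(out_dir, "timestamps.log"))
    write_ground_truth(schedule, truth, file.path(out_dir, "truth.jsonl"))
    if (!is.null(tracking))
      write_tracking_log(tracking, file.path(out_dir, "tracking_log.csv"))
  }

  structure(list(truth = truth, moon_truth = moon_truth,
                 timestamp_log = tlog, tracking = tracking,
                 frames = frames, n_frames = n_emitted,
                 times = times[seq_len(n_emitted)],
                 terminated = terminated, out_dir = out_dir,
                 schedule = schedule),
            class = "session_result")
}

#' Realized entry/exit frames per transit from a session truth log
#' @param session a `session_result`
#' @return data frame: `transit_id`, `entry_frame`, `exit_frame`,
#'   `n_visible_frames`, `start_s`, `end_s`
#' @export
transit_truth_summary <- function(session) {
  tr <- session$truth[session$truth$visible & session$truth$in_frame, ,
                      drop = FALSE]
  if (nrow(tr) == 0)
    return(data.frame(transit_id = integer(0), entry_frame = integer(0),
                      exit_frame = integer(0), n_visible_frames = integer(0),
                      start_s = numeric(0), end_s = numeric(0)))
  sp <- split(tr, tr$transit_id)
  do.call(rbind, lapply(sp, function(d) data.frame(
    transit_id = d$transit_id[1],
    entry_frame = min(d$frame_index), exit_frame = max(d$frame_index),
    n_visible_frames = nrow(d),
    start_s = min(d$t), end_s = max(d$t))))
}

#' Write the ground-truth transit log as JSON lines
#'
#' One record per transit: the planned spec plus realized entry/exit frames
#' and the per-frame centroid path.
#'
#' @param schedule list of [transit_spec()]
#' @param truth per-frame truth data frame from [simulate_session()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_ground_truth <- function(schedule, truth, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(schedule)) {
    rows <- truth[truth$transit_id == k, , drop = FALSE]
    vis <- rows[rows$visible, , drop = FALSE]
    rec <- c(schedule[[k]][c("start_time_s", "ground_track_bearing_deg",
                             "body_orientation_deg", "angular_speed_deg_per_s",
                             "silhouette_length_px", "silhouette_darkness",
                             "entry_chord_offset")],
             list(transit_id = k,
                  entry_frame = if (nrow(vis)) min(vis$frame_index) else NA,
                  exit_frame = if (nrow(vis)) max(vis$frame_index) else NA,
                  frames = rows$frame_index, x = round(rows$x, 2),
                  y = round(rows$y, 2), visible = rows$visible))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
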