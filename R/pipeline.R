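# End-to-end wiring: simulate -> track -> detect -> analyze, with a run
# manifest, a plain-text config dialect, and detection scoring against
# simulator ground truth.

#' Score detected tracks against simulator ground truth
#'
#' A truth transit is recovered when some detected track shares at least one
#' frame on which the detection centroid lies within `tol_px` of the truth
#' centroid; matching is greedy one-to-one by shared-frame count.  Recall is
#' recovered truth transits over truth transits with at least `min_frames`
#' visible frames; precision is matched tracks over all tracks.
#'
#' @param session a `session_result` from [simulate_session()]
#' @param detections data frame from [detector_results()]
#' @param tracks data frame from [link_tracks()]
#' @param tol_px spatial match tolerance (default 4)
#' @param min_frames minimum visible truth frames for a transit to count
#'   (default 1: single-frame transits are scored too)
#' @return list: `recall`, `precision`, `n_truth`, `n_tracks`, `n_matched`,
#'   `matches` (data frame transit_id, track_id)
#' @export
detection_performance <- function(session, detections, tracks,
                                  tol_px = 4, min_frames = 1) {
  truth <- session$truth[session$truth$visible, , drop = FALSE]
  members <- attr(tracks, "members")
  tsum <- transit_truth_summary(session)
  tsum <- tsum[tsum$n_visible_frames >= min_frames, , drop = FALSE]
  n_truth <- nrow(tsum); n_tracks <- nrow(tracks)
  if (n_truth == 0 || n_tracks == 0) {
    return(list(recall = if (n_truth == 0) NA_real_ else 0,
                precision = if (n_tracks == 0) NA_real_ else 0,
                n_truth = n_truth, n_tracks = n_tracks, n_matched = 0L,
                matches = data.frame(transit_id = integer(0),
                                     track_id = integer(0))))
  }
  # overlap counts between truth transits and tracks
  overlap <- matrix(0L, n_truth, n_tracks)
  for (j in seq_len(n_tracks)) {
    d <- detections[members[[j]], , drop = FALSE]
    for (i in seq_len(n_truth)) {
      tid <- tsum$transit_id[i]
      tt <- truth[truth$transit_id == tid, , drop = FALSE]
      m <- merge(d[, c("frame_index", "x", "y")],
                 tt[, c("frame_index", "x", "y")],
                 by = "frame_index", suffixes = c("_d", "_t"))
      if (nrow(m) == 0) next
      hit <- sqrt((m$x_d - m$x_t)^2 + (m$y_d - m$y_t)^2) <= tol_px
      overlap[i, j] <- sum(hit)
    }
  }
  matches <- list()
  ov <- overlap
  repeat {
    if (max(ov) == 0) break
    best <- arrayInd(which.max(ov), dim(ov))
    matches[[length(matches) + 1L]] <- data.frame(
      transit_id = tsum$transit_id[best[1]],
      track_id = tracks$track_id[best[2]])
    ov[best[1], ] <- 0L; ov[, best[2]] <- 0L
  }
  mdf <- if (length(matches)) do.call(rbind, matches) else
    data.frame(transit_id = integer(0), track_id = integer(0))
  list(recall = nrow(mdf) / n_truth,
       precision = nrow(mdf) / n_tracks,
       n_truth = n_truth, n_tracks = n_tracks,
       n_matched = nrow(mdf), matches = mdf)
}

#' Run the full pipeline on a simulated scene
#'
#' One call reproduces simulate -> track -> detect -> analyze: a session is
#' simulated (optionally under closed-loop tracking), silhouettes are
#' detected online, linked into tracks, grouped into flocks, solved for
#' flight directions and distances, and summarised including the traffic
#' rate; detection precision/recall against the simulator truth is part of
#' the summary.
#'
#' @param scene a [scene_config()]
#' @param schedule list of [transit_spec()] (e.g. from
#'   [sample_transit_schedule()])
#' @param duration_s session length, seconds
#' @param tracker optional [tracker_config()]
#' @param detect_cfg a [detect_config()]
#' @param flight_altitude_m traffic-rate altitude assumption
#' @param out_dir optional output directory (frames, logs, tracks, summary,
#'   manifest)
#' @param seed integer seed recorded in the manifest; the scene's own
#'   `rng_seed` governs scene randomness
#' @return list of class `pipeline_result`: `session`, `detections`,
#'   `tracks`, `flocks`, `solutions`, `summary`, `performance`, `manifest`
#' @export
full_pipeline <- function(scene, schedule, duration_s,
                          tracker = NULL,
                          detect_cfg = detect_config(),
                          flight_altitude_m = 500,
                          out_dir = NULL, seed = scene$rng_seed) {
  det <- silhouette_detector(detect_cfg)
  session <- simulate_session(
    scene, schedule, duration_s, tracker = tracker,
    out_dir = out_dir,
    on_frame = function(frame, index, t) detector_step(det, frame, t, index))
  detections <- detector_results(det)
  disk_r <- if (!is.null(det$last_disk)) det$last_disk$radius_px
            else moon_radius_px(scene)
  tracks <- link_tracks(detections, session$timestamp_log, disk_r, detect_cfg)
  flocks <- group_flocks(tracks)
  solutions <- flight_solutions(tracks, detections, scene$geometry, disk_r)
  duration_h <- duration_s / 3600
  summary <- session_summary(solutions, scene$geometry, duration_h,
                             flight_altitude_m)
  perf <- detection_performance(session, detections, tracks)
  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    seed = seed,
    scene = Filter(is.atomic, scene[setdiff(names(scene), "geometry")]),
    geometry = unclass(scene$geometry),
    tracker = if (!is.null(tracker)) unclass(tracker),
    detect = unclass(detect_cfg),
    flight_altitude_m = flight_altitude_m,
    duration_s = duration_s,
    n_transits_scheduled = length(schedule),
    n_frames = session$n_frames,
    n_motor_commands = if (!is.null(session$tracking))
      nrow(session$tracking$commands) else NA,
    terminated_by_loss = session$terminated)
  if (!is.null(out_dir)) {
    write_tracks_csv(tracks, file.path(out_dir, "tracks.csv"), flocks)
    write_tracks_jsonl(tracks, detections, file.path(out_dir, "tracks.jsonl"))
    utils::write.csv(solutions, file.path(out_dir, "solutions.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(summary = list(
             n_tracks = summary$n_tracks,
             circular_mean_bearing_deg = summary$circular_mean_bearing_deg,
             circular_mean_north_of_east_deg =
               summary$circular_mean_north_of_east_deg,
             traffic_rate_km_h = summary$traffic_rate$birds_per_km_front_per_hour,
             traffic_rate_mile_h = summary$traffic_rate$birds_per_mile_front_per_hour),
           performance = perf[c("recall", "precision", "n_truth",
                                "n_tracks", "n_matched")],
           manifest = manifest),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA,
      null = "null", force = TRUE)
  }
  structure(list(session = session, detections = detections, tracks = tracks,
                 flocks = flocks, solutions = solutions, summary = summary,
                 performance = perf, manifest = manifest),
            class = "pipeline_result")
}

# ---- plain-text config dialect ---------------------------------------------

#' Read an INI-style run configuration
#'
#' Sections `[scene]`, `[geometry]`, `[tracker]`, `[detect]`, `[schedule]`,
#' `[run]` with `key = value` lines; values are parsed as numbers or logicals
#' where possible.  All [scene_config()] fields are addressable.
#'
#' @param path config file
#' @return nested named list by section
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("[;#].*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list(); sect <- "run"
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      sect <- gsub("^\\[|\\]$", "", ln)
      next
    }
    kv <- regmatches(ln, regexec("^([^=]+)=(.*)$", ln))[[1]]
    if (length(kv) != 3) stop("unparseable config line: ", ln, call. = FALSE)
    key <- trimws(kv[2]); val <- trimws(gsub('^"|"$', "", trimws(kv[3])))
    num <- suppressWarnings(as.numeric(val))
    parsed <- if (!is.na(num)) num
      else if (tolower(val) %in% c("true", "false")) as.logical(toupper(val))
      else val
    out[[sect]][[key]] <- parsed
  }
  out
}

# build package objects from a parsed config
.config_objects <- function(cfg) {
  geom <- do.call(session_geometry, cfg$geometry %||% list())
  scene_args <- cfg$scene %||% list()
  scene_args$geometry <- geom
  scene <- do.call(scene_config, scene_args)
  tracker <- if (!is.null(cfg$tracker)) do.call(tracker_config, cfg$tracker)
  detect <- do.call(detect_config, cfg$detect %||% list())
  list(scene = scene, tracker = tracker, detect = detect,
       schedule = cfg$schedule %||% list(), run = cfg$run %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Command-line entry point
#'
#' Subcommands `simulate`, `track`, `detect`, `analyze`, `run-all`; see the
#' `moonwatch` script in the package's `cli` directory for shell usage.
#' Exit codes: 0 success, 2 config error, 3 moon-loss termination, 4 stage
#' failure.
#'
#' @param args character vector, default `commandArgs(trailingOnly = TRUE)`
#' @return exit status, invisibly
#' @export
moonwatch_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    cat("usage: moonwatch <simulate|track|detect|analyze|run-all> [options]\n")
    return(invisible(2L))
  }
  sub <- args[1]
  opts <- optparse::OptionParser(option_list = list(
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--input", type = "character", default = NULL),
    optparse::make_option("--log", type = "character", default = NULL),
    optparse::make_option("--tracks", type = "character", default = NULL),
    optparse::make_option("--out", type = "character", default = "moonwatch_out"),
    optparse::make_option("--duration", type = "double", default = 30),
    optparse::make_option("--density", type = "double", default = 500),
    optparse::make_option("--altitude", type = "double", default = 500),
    optparse::make_option("--threshold", type = "double", default = 120),
    optparse::make_option("--deadband", type = "double", default = NA),
    optparse::make_option("--controller", type = "character", default = "on"),
    optparse::make_option("--seed", type = "integer", default = 1L)))
  parsed <- tryCatch(optparse::parse_args(opts, args = args[-1]),
                     error = function(e) e)
  if (inherits(parsed, "error")) {
    message("config error: ", conditionMessage(parsed)); return(invisible(2L))
  }
  res <- tryCatch({
    cfg <- if (!is.null(parsed$config))
      .config_objects(read_run_config(parsed$config))
    else {
      scene <- scene_config(rng_seed = parsed$seed)
      list(scene = scene,
           tracker = tracker_config(
             work_width_px = scene$frame_width_px,
             work_height_px = scene$frame_height_px,
             threshold = parsed$threshold,
             deadband_radius_px = if (is.na(parsed$deadband))
               0.125 * scene$frame_height_px else parsed$deadband,
             min_moon_area_px = 0.1 * pi * moon_radius_px(scene)^2),
           detect = detect_config(), schedule = list(), run = list())
    }
    scene <- cfg$scene
    switch(sub,
      "simulate" = , "run-all" = {
        sched <- sample_transit_schedule(
          parsed$density, parsed$altitude, direction_uniform(),
          parsed$duration, scene, seed = parsed$seed)
        use_tracker <- identical(parsed$controller, "on")
        if (sub == "simulate") {
          s <- simulate_session(scene, sched, parsed$duration,
                                tracker = if (use_tracker) cfg$tracker,
                                out_dir = parsed$out)
          jsonlite::write_json(list(
            n_frames = s$n_frames, terminated = s$terminated,
            n_motor_commands = if (!is.null(s$tracking))
              nrow(s$tracking$commands) else 0L,
            seed = parsed$seed),
            file.path(parsed$out, "manifest.json"), auto_unbox = TRUE)
          if (s$terminated) 3L else 0L
        } else {
          p <- full_pipeline(scene, sched, parsed$duration,
                             tracker = if (use_tracker) cfg$tracker,
                             detect_cfg = cfg$detect,
                             flight_altitude_m = parsed$altitude,
                             out_dir = parsed$out, seed = parsed$seed)
          if (p$session$terminated) 3L else 0L
        }
      },
      "track" = {
        if (is.null(parsed$input)) stop("track needs --input")
        log <- if (!is.null(parsed$log)) read_timestamp_log(parsed$log)
        src <- frame_sequence_source(parsed$input, log)
        tcfg <- cfg$tracker %||% tracker_config(threshold = parsed$threshold)
        sess <- run_tracking_loop(src, tcfg)
        dir.create(parsed$out, showWarnings = FALSE, recursive = TRUE)
        write_tracking_log(sess, file.path(parsed$out, "tracking_log.csv"))
        if (sess$terminated) 3L else 0L
      },
      "detect" = {
        if (is.null(parsed$input)) stop("detect needs --input")
        log <- if (!is.null(parsed$log)) read_timestamp_log(parsed$log)
        src <- frame_sequence_source(parsed$input, log)
        d <- detect_session(src, cfg$detect)
        disk_r <- if (!is.null(d$last_disk)) d$last_disk$radius_px
                  else moon_radius_px(scene)
        tracks <- link_tracks(d$detections, log, disk_r, cfg$detect)
        dir.create(parsed$out, showWarnings = FALSE, recursive = TRUE)
        write_tracks_csv(tracks, file.path(parsed$out, "tracks.csv"),
                         group_flocks(tracks))
        write_tracks_jsonl(tracks, d$detections,
                           file.path(parsed$out, "tracks.jsonl"))
        0L
      },
      "analyze" = {
        if (is.null(parsed$tracks)) stop("analyze needs --tracks")
        tracks <- utils::read.csv(parsed$tracks)
        geom <- scene$geometry
        bearings <- vapply(tracks$image_path_angle_deg, function(a)
          if (is.finite(a)) image_to_ground_track(a, geom)$bearing_deg
          else NA_real_, 0)
        rate <- lowery_traffic_rate(bearings, geom, parsed$altitude,
                                    parsed$duration / 3600)
        dir.create(parsed$out, showWarnings = FALSE, recursive = TRUE)
        rose <- direction_rose(bearings)
        jsonlite::write_json(list(
          n_tracks = nrow(tracks),
          circular_mean_bearing_deg = attr(rose, "circular_mean_deg"),
          traffic_rate_km_h = rate$birds_per_km_front_per_hour,
          traffic_rate_mile_h = rate$birds_per_mile_front_per_hour),
          file.path(parsed$out, "analysis.json"), auto_unbox = TRUE,
          digits = NA)
        0L
      },
      { message("unknown subcommand: ", sub); 2L })
  }, error = function(e) {
    message("stage failure in '", sub, "': ", conditionMessage(e))
    4L
  })
  invisible(res)
}
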