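# Automated silhouette annotation: moon-disk fitting at analysis resolution,
# a running background model that suppresses static lunar features, dark-blob
# detection inside the disk, frame-wise nearest-neighbour track linking, and
# flock grouping.

#' Detection configuration
#'
#' @param moon_threshold 8-bit level segmenting the disk at analysis
#'   resolution
#' @param min_moon_area_px minimum disk area for a usable frame
#' @param contrast_threshold minimum per-pixel darkening below the background
#'   model for silhouette pixels (8-bit levels)
#' @param min_detection_area minimum blob area in pixels (the smallest real
#'   silhouettes are only a few pixels)
#' @param rim_exclude_px width of the anti-aliased rim band excluded from
#'   pixel candidates; only there is the disk-brightness model unreliable, so
#'   edge-skirting transits are still caught on their on-disk pixels
#' @param bg_halflife_s half-life of the exponential moving-average
#'   background; static dark features (maria, craters) decay into the
#'   background at this rate while moving blobs do not
#' @param gating_radius_frac floor on the track-linking gate, as a fraction
#'   of disk radius
#' @param max_angular_speed_deg_s fastest plausible bird; together with the
#'   frame period and plate scale it sets the per-frame linking gate
#' @param gap_frames frames a track survives without a matched detection
#' @param min_linearity_r2 tracks with straight-line fit R-squared below this
#'   are flagged (not deleted) as possible non-birds
#' @param min_angular_speed_deg_s tracks slower than this are flagged
#' @return an object of class `detect_config`
#' @export
detect_config <- function(moon_threshold = 120, min_moon_area_px = 200,
                          contrast_threshold = 40, min_detection_area = 2,
                          rim_exclude_px = 1.5,
                          bg_halflife_s = 1,
                          gating_radius_frac = 0.35, gap_frames = 1,
                          max_angular_speed_deg_s = 2.5,
                          min_linearity_r2 = 0.8,
                          min_angular_speed_deg_s = 0.05) {
  structure(as.list(environment()), class = "detect_config")
}

#' Fit the moon disk in an analysis frame
#'
#' Threshold segmentation and binary centroid, as in the tracker; the radius
#' is the equivalent-disk radius `sqrt(area/pi)`.  A gibbous moon biases the
#' centre toward the lit limb; the fit records what is there rather than
#' correcting phase.
#'
#' @param frame numeric matrix on the 8-bit scale
#' @param threshold segmentation level
#' @param min_area minimum mask area; below it the frame is skipped
#' @return list of class `moon_disk_fit` (`center_px`, `radius_px`,
#'   `area_px`) or `NULL` when no moon is found (caller logs the skip)
#' @export
fit_moon_disk <- function(frame, threshold = 120, min_area = 200) {
  mask <- threshold_moon(frame, threshold)
  area <- sum(mask)
  if (area < min_area) return(NULL)
  idx <- which(mask, arr.ind = TRUE)
  structure(list(center_px = c(mean(idx[, 2]) - 0.5, mean(idx[, 1]) - 0.5),
                 radius_px = sqrt(area / pi), area_px = as.integer(area)),
            class = "moon_disk_fit")
}

#' Create a streaming silhouette detector
#'
#' Returns a mutable detector advanced one frame at a time with
#' [detector_step()]; this form plugs directly into the simulator's
#' `on_frame` hook so long sessions never need to hold frames in memory.
#'
#' @param cfg a [detect_config()]
#' @return an environment of class `silhouette_detector`
#' @export
silhouette_detector <- function(cfg = detect_config()) {
  env <- new.env(parent = emptyenv())
  env$cfg <- cfg
  env$bg <- NULL
  env$last_t <- NULL
  env$detections <- list()
  env$skipped_frames <- integer(0)
  class(env) <- "silhouette_detector"
  env
}

#' Advance the detector by one frame
#'
#' Fits the disk, estimates the local disk brightness (median of the disk
#' interior, so fog-attenuated sessions adapt automatically), and records
#' connected components of pixels darker than that estimate by at least the
#' contrast threshold.  Detection is restricted to the disk interior because
#' a silhouette is only visible against the lit disk — off-disk pixels are
#' night sky whatever crosses them.  A running background frame, re-registered
#' to the current disk centre, vetoes static dark features (maria, craters):
#' a pixel must also be darker than the background, which movers are and
#' learned static features are not.  The first usable frame only initialises
#' the background.
#'
#' @param det a [silhouette_detector()]
#' @param frame numeric matrix on the 8-bit scale
#' @param t frame capture time, seconds
#' @param index frame index
#' @return data frame of detections for this frame (possibly empty),
#'   invisibly; detections accumulate inside the detector
#' @export
detector_step <- function(det, frame, t, index) {
  cfg <- det$cfg
  disk <- fit_moon_disk(frame, cfg$moon_threshold, cfg$min_moon_area_px)
  empty <- data.frame(frame_index = integer(0), t = numeric(0),
                      x = numeric(0), y = numeric(0), area = integer(0),
                      mean_darkness = numeric(0), on_edge = logical(0),
                      length_px = numeric(0), axis_angle_deg = numeric(0),
                      elongation = numeric(0), disk_x = numeric(0),
                      disk_y = numeric(0), disk_r = numeric(0))
  if (is.null(disk)) {
    det$skipped_frames <- c(det$skipped_frames, index)
    return(invisible(empty))
  }
  if (is.null(det$bg)) {
    det$bg <- frame
    det$bg_center <- disk$center_px
    det$last_t <- t
    det$last_disk <- disk
    return(invisible(empty))
  }
  # re-register the background to the current disk centre (integer shift)
  shift <- round(disk$center_px - det$bg_center)
  bg <- det$bg
  if (any(shift != 0)) {
    bg <- .shift_matrix(bg, shift[2], shift[1], fill = NA)
    det$bg_center <- det$bg_center + shift
  }
  H <- nrow(frame); W <- ncol(frame)
  dx <- matrix((seq_len(W) - 0.5) - disk$center_px[1], H, W, byrow = TRUE)
  dy <- matrix((seq_len(H) - 0.5) - disk$center_px[2], H, W)
  rdist <- sqrt(dx^2 + dy^2)
  interior <- rdist <= disk$radius_px - cfg$rim_exclude_px
  bright_est <- stats::median(frame[rdist <= 0.8 * disk$radius_px])
  diff <- bright_est - frame          # darkness below local disk brightness
  bgdiff <- bg - frame                # darkness below the learned background
  bgdiff[is.na(bgdiff)] <- Inf
  mask <- interior & diff >= cfg$contrast_threshold &
    bgdiff >= cfg$contrast_threshold / 2
  out <- empty
  if (any(mask)) {
    labels <- EBImage::bwlabel(mask)
    n_lab <- max(labels)
    rows <- list()
    for (lb in seq_len(n_lab)) {
      idx <- which(labels == lb)
      if (length(idx) < cfg$min_detection_area) next
      # component-level veto: a genuine mover is darker than the learned
      # background across its whole body; residual misregistration fringes of
      # static features are not
      if (mean(bgdiff[idx]) < cfg$contrast_threshold) next
      ri <- ((idx - 1) %% H) + 1
      ci <- ((idx - 1) %/% H) + 1
      wgt <- diff[idx]
      xs <- ci - 0.5; ys <- ri - 0.5
      cx <- sum(xs * wgt) / sum(wgt); cy <- sum(ys * wgt) / sum(wgt)
      # weighted second moments; y negated so angles are y-up convention
      mu20 <- sum(wgt * (xs - cx)^2) / sum(wgt)
      mu02 <- sum(wgt * (ys - cy)^2) / sum(wgt)
      mu11 <- sum(wgt * (xs - cx) * (-(ys - cy))) / sum(wgt)
      ang <- 0.5 * atan2(2 * mu11, mu20 - mu02)
      tr <- mu20 + mu02
      dets <- sqrt(max((mu20 - mu02)^2 + 4 * mu11^2, 0))
      l1 <- (tr + dets) / 2; l2 <- (tr - dets) / 2
      len <- 4 * sqrt(max(l1, 1e-9))   # full length of an equivalent ellipse
      elong <- sqrt(max(l1, 1e-9) / max(l2, 1e-9))
      rd <- sqrt((cx - disk$center_px[1])^2 + (cy - disk$center_px[2])^2)
      rows[[length(rows) + 1L]] <- data.frame(
        frame_index = index, t = t, x = cx, y = cy,
        area = length(idx),
        mean_darkness = mean(wgt),
        on_edge = (disk$radius_px - rd) <= len,
        length_px = len,
        axis_angle_deg = wrap360(rad2deg(ang)),
        elongation = elong,
        disk_x = disk$center_px[1], disk_y = disk$center_px[2],
        disk_r = disk$radius_px)
    }
    if (length(rows)) out <- do.call(rbind, rows)
  }
  # update the background after detection, dropping this frame's movers in
  # slowly so brief transits never become background
  alpha <- 1 - 2^(-(t - det$last_t) / cfg$bg_halflife_s)
  alpha <- clamp(alpha, 0, 1)
  det$bg <- bg + alpha * (frame - bg)
  nab <- is.na(det$bg)
  if (any(nab)) det$bg[nab] <- frame[nab]
  det$bg_center <- det$bg_center  # registered above
  det$last_t <- t
  det$last_disk <- disk
  if (nrow(out) > 0) det$detections[[length(det$detections) + 1L]] <- out
  invisible(out)
}

# integer shift of a matrix by (dr, dc), filling vacated cells
.shift_matrix <- function(m, dr, dc, fill = NA) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(fill, H, W)
  sr <- seq_len(H) - dr; sc <- seq_len(W) - dc
  okr <- sr >= 1 & sr <= H; okc <- sc >= 1 & sc <= W
  out[okr, okc] <- m[sr[okr], sc[okc]]
  out
}

#' Collected detections from a detector
#' @param det a [silhouette_detector()]
#' @return one data frame of all detections (zero rows if none)
#' @export
detector_results <- function(det) {
  if (length(det$detections) == 0)
    return(data.frame(frame_index = integer(0), t = numeric(0), x = numeric(0),
                      y = numeric(0), area = integer(0),
                      mean_darkness = numeric(0), on_edge = logical(0),
                      length_px = numeric(0), axis_angle_deg = numeric(0),
                      elongation = numeric(0), disk_x = numeric(0),
                      disk_y = numeric(0), disk_r = numeric(0)))
  do.call(rbind, det$detections)
}

#' Run detection over a frame source
#'
#' @param source a frame source closure (see [frame_sequence_source()])
#' @param cfg a [detect_config()]
#' @return list: `detections` (data frame), `skipped_frames`,
#'   `last_disk` (final [fit_moon_disk()] result)
#' @export
detect_session <- function(source, cfg = detect_config()) {
  det <- silhouette_detector(cfg)
  repeat {
    item <- source()
    if (is.null(item)) break
    detector_step(det, item$frame, item$t, item$index)
  }
  list(detections = detector_results(det),
       skipped_frames = det$skipped_frames,
       last_disk = det$last_disk)
}

#' Link per-frame detections into transit tracks
#'
#' Greedy nearest-neighbour association frame by frame: each active track
#' predicts its next position (constant velocity once two points exist) and
#' claims the nearest unclaimed detection within the gating radius; unmatched
#' detections start new tracks; tracks end after `gap_frames` frames without
#' a match.  Durations come from the timestamp log: last time minus first
#' time plus one local frame period, so a single-frame blip lasts exactly one
#' frame period.
#'
#' @param detections data frame from [detector_results()]
#' @param log a [timestamp_log()] for durations (frame indices are matched
#'   against it 0-based); `NULL` falls back to detection times and the median
#'   inter-frame gap
#' @param disk_radius_px analysis disk radius (sets the gating radius)
#' @param cfg a [detect_config()]
#' @param moon_diam_deg lunar angular diameter anchoring the plate scale used
#'   by the angular-speed flag (default 0.52)
#' @return data frame of tracks: `track_id`, `start_s`, `end_s`,
#'   `duration_s`, `n_frames`, `mean_area_px`, `image_path_angle_deg` (y-up),
#'   `completeness`, `flagged`, `mean_elongation`, plus list-columns
#'   `det_rows` indexing `detections`
#' @export
link_tracks <- function(detections, log = NULL, disk_radius_px,
                        cfg = detect_config(), moon_diam_deg = 0.52) {
  gate <- cfg$gating_radius_frac * disk_radius_px
  # widen the gate so the fastest plausible bird still links frame to frame
  if (nrow(detections) > 1) {
    fi <- detections$frame_index
    per_med <- (max(detections$t) - min(detections$t)) /
      max(max(fi) - min(fi), 1L)
    if (is.finite(per_med) && per_med > 0) {
      ppd <- 2 * disk_radius_px / moon_diam_deg
      gate <- max(gate, cfg$max_angular_speed_deg_s * per_med * ppd)
    }
  }
  empty <- data.frame(track_id = integer(0), start_s = numeric(0),
                      end_s = numeric(0), duration_s = numeric(0),
                      n_frames = integer(0), mean_area_px = numeric(0),
                      image_path_angle_deg = numeric(0),
                      completeness = character(0), flagged = logical(0),
                      mean_elongation = numeric(0))
  if (nrow(detections) == 0) {
    attr(empty, "members") <- list()
    return(empty)
  }
  detections <- detections[order(detections$frame_index), , drop = FALSE]
  frames <- sort(unique(detections$frame_index))
  active <- list()   # each: rows (indices into detections), last_xy, vel, last_frame
  done <- list()
  for (f in frames) {
    rows <- which(detections$frame_index == f)
    # retire stale tracks, and tracks whose predicted position has left the
    # disk: an off-disk bird is invisible and cannot be the same object as a
    # newly entering one
    if (length(active)) {
      dx0 <- detections$disk_x[rows[1]]; dy0 <- detections$disk_y[rows[1]]
      dr0 <- detections$disk_r[rows[1]]
      stale <- vapply(active, function(tr) {
        if (f - tr$last_frame > cfg$gap_frames + 1L) return(TRUE)
        pred <- tr$last_xy + tr$vel * (f - tr$last_frame)
        sqrt((pred[1] - dx0)^2 + (pred[2] - dy0)^2) > dr0 + 3
      }, TRUE)
      done <- c(done, active[stale])
      active <- active[!stale]
    }
    taken <- rep(FALSE, length(rows))
    if (length(active)) {
      # greedy: process tracks in order of best available match
      preds <- lapply(active, function(tr)
        tr$last_xy + tr$vel * (f - tr$last_frame))
      cost <- matrix(Inf, length(active), length(rows))
      for (a in seq_along(active))
        cost[a, ] <- sqrt((detections$x[rows] - preds[[a]][1])^2 +
                          (detections$y[rows] - preds[[a]][2])^2)
      # the plausible displacement grows with the number of elapsed frames
      gaps <- vapply(active, function(tr) f - tr$last_frame, 0)
      cost[cost > gate * pmax(gaps, 1)] <- Inf
      repeat {
        if (all(!is.finite(cost))) break
        best <- arrayInd(which.min(cost), dim(cost))
        a <- best[1]; d <- best[2]
        r <- rows[d]
        tr <- active[[a]]
        dtf <- f - tr$last_frame
        newxy <- c(detections$x[r], detections$y[r])
        tr$vel <- if (dtf > 0) (newxy - tr$last_xy) / dtf else tr$vel
        tr$last_xy <- newxy; tr$last_frame <- f
        tr$rows <- c(tr$rows, r)
        active[[a]] <- tr
        taken[d] <- TRUE
        cost[a, ] <- Inf; cost[, d] <- Inf
      }
    }
    for (d in which(!taken)) {
      r <- rows[d]
      active[[length(active) + 1L]] <- list(
        rows = r, last_xy = c(detections$x[r], detections$y[r]),
        vel = c(0, 0), last_frame = f)
    }
  }
  done <- c(done, active)
  if (length(done) == 0) {
    attr(empty, "members") <- list()
    return(empty)
  }
  # order tracks by first frame
  done <- done[order(vapply(done, function(tr) min(detections$frame_index[tr$rows]), 0))]
  members <- list()
  out <- vector("list", length(done))
  for (k in seq_along(done)) {
    rws <- done[[k]]$rows
    d <- detections[rws, , drop = FALSE]
    d <- d[order(d$frame_index), , drop = FALSE]
    fi <- d$frame_index
    if (!is.null(log)) {
      t_first <- frame_time(log, fi[1] - 1L)
      t_last <- frame_time(log, fi[length(fi)] - 1L)
      per <- frame_period(log, fi[length(fi)] - 1L)
    } else {
      t_first <- d$t[1]; t_last <- d$t[nrow(d)]
      per <- if (nrow(detections) > 1)
        stats::median(diff(sort(unique(detections$t)))) else 1 / 30
    }
    duration <- t_last - t_first + per
    # image path angle from the displacement plus a total-least-squares line
    n <- nrow(d)
    if (n >= 2) {
      disp <- c(d$x[n] - d$x[1], -(d$y[n] - d$y[1]))  # y-up
      xc <- d$x - mean(d$x); yc <- -(d$y - mean(d$y))
      cv <- cbind(xc, yc)
      ev <- eigen(crossprod(cv), symmetric = TRUE)
      axis <- ev$vectors[, 1]
      if (sum(axis * disp) < 0) axis <- -axis
      ang <- wrap360(rad2deg(atan2(axis[2], axis[1])))
      r2 <- ev$values[1] / max(sum(ev$values), 1e-12)
    } else {
      ang <- NA_real_; r2 <- 1
    }
    completeness <- if (n == 1) "single_frame"
      else if (all(d$on_edge)) "edge_skirting" else "full_crossing"
    path_px <- if (n >= 2)
      sqrt((d$x[n] - d$x[1])^2 + (d$y[n] - d$y[1])^2) else 0
    speed_px_s <- if (n >= 2 && t_last > t_first)
      path_px / (t_last - t_first) else NA_real_
    # plate scale anchored on the fitted disk for the angular-speed floor
    ppd <- 2 * disk_radius_px / moon_diam_deg
    slow <- is.finite(speed_px_s) && speed_px_s / ppd < cfg$min_angular_speed_deg_s
    flagged <- (n >= 3 && r2 < cfg$min_linearity_r2) || (n >= 3 && slow)
    members[[k]] <- rws
    out[[k]] <- data.frame(
      track_id = k, start_s = t_first, end_s = t_last + per,
      duration_s = duration, n_frames = n,
      mean_area_px = mean(d$area),
      image_path_angle_deg = ang,
      completeness = completeness, flagged = flagged,
      mean_elongation = mean(d$elongation))
  }
  res <- do.call(rbind, out)
  attr(res, "members") <- members
  res
}

#' Group coincident tracks into flock events
#'
#' Single-linkage clustering on temporal overlap: tracks whose
#' `[start_s, end_s]` intervals come within `window_s` of each other are
#' linked; clusters with at least two members are flock events.
#'
#' @param tracks data frame from [link_tracks()]
#' @param window_s grouping window, seconds
#' @return data frame of events: `flock_id`, `n_members`, `start_s`,
#'   `end_s`, with attribute `members` (list of track ids); tracks gain no
#'   event when isolated
#' @export
group_flocks <- function(tracks, window_s = 2) {
  empty <- data.frame(flock_id = integer(0), n_members = integer(0),
                      start_s = numeric(0), end_s = numeric(0))
  if (nrow(tracks) < 2) { attr(empty, "members") <- list(); return(empty) }
  ord <- order(tracks$start_s)
  cl <- integer(nrow(tracks)); cur <- 0L; cl_end <- -Inf
  for (k in ord) {
    if (tracks$start_s[k] - window_s > cl_end) {
      cur <- cur + 1L
      cl_end <- tracks$end_s[k]
    } else {
      cl_end <- max(cl_end, tracks$end_s[k])
    }
    cl[k] <- cur
  }
  rows <- list(); members <- list()
  for (g in unique(cl)) {
    ids <- tracks$track_id[cl == g]
    if (length(ids) < 2) next
    rows[[length(rows) + 1L]] <- data.frame(
      flock_id = length(rows) + 1L, n_members = length(ids),
      start_s = min(tracks$start_s[cl == g]),
      end_s = max(tracks$end_s[cl == g]))
    members[[length(members) + 1L]] <- ids
  }
  res <- if (length(rows)) do.call(rbind, rows) else empty
  attr(res, "members") <- members
  res
}

#' Write tracks to CSV (one row per track)
#' @param tracks data frame from [link_tracks()]
#' @param path output file
#' @param flocks optional [group_flocks()] result; adds a `flock_id` column
#' @return `path`, invisibly
#' @export
write_tracks_csv <- function(tracks, path, flocks = NULL) {
  out <- tracks
  out$flock_id <- NA_integer_
  if (!is.null(flocks) && nrow(flocks) > 0) {
    mem <- attr(flocks, "members")
    for (g in seq_along(mem)) out$flock_id[out$track_id %in% mem[[g]]] <- g
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write per-frame track centroids as JSON lines
#' @param tracks data frame from [link_tracks()]
#' @param detections the detections the tracks were linked from
#' @param path output file
#' @return `path`, invisibly
#' @export
write_tracks_jsonl <- function(tracks, detections, path) {
  con <- file(path, "w"); on.exit(close(con))
  members <- attr(tracks, "members")
  for (k in seq_len(nrow(tracks))) {
    d <- detections[members[[k]], , drop = FALSE]
    d <- d[order(d$frame_index), , drop = FALSE]
    writeLines(jsonlite::toJSON(list(
      track_id = tracks$track_id[k],
      frames = d$frame_index, t = d$t,
      x = round(d$x, 2), y = round(d$y, 2), area = d$area),
      auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
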