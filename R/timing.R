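# Recording timestamp log and per-frame time reconstruction.
#
# Software-timed cameras deliver frames at an imprecise rate, so the nominal
# frame rate cannot be trusted: the recorder checkpoints wall-clock time and
# cumulative frame count, and per-frame times are reconstructed by
# piecewise-linear interpolation of time against frame count.
#
# On-disk dialect: line-oriented plain text.  `#`-prefixed header lines carry
# camera settings as `# key: value`; each checkpoint line is
# `<ISO-8601 wall time>\t<cumulative frame count>`.

#' Create an empty timestamp log
#'
#' @param camera_settings named list of opaque camera metadata stored in the
#'   log header
#' @param t0 POSIXct wall-clock time of session start (frame times are stored
#'   as seconds since `t0`)
#' @return an object of class `timestamp_log`
#' @export
timestamp_log <- function(camera_settings = list(),
                          t0 = as.POSIXct("2018-04-28 21:00:00", tz = "UTC")) {
  structure(list(t = numeric(0), frames = integer(0),
                 camera_settings = camera_settings, t0 = t0),
            class = "timestamp_log")
}

#' Append a checkpoint to a timestamp log
#'
#' Checkpoints must be strictly monotone in both time and frame count; the
#' first checkpoint must be at frame 0.
#'
#' @param log a [timestamp_log()]
#' @param t seconds since session start
#' @param frames cumulative frames captured so far
#' @return the updated log
#' @export
append_checkpoint <- function(log, t, frames) {
  n <- length(log$t)
  if (n == 0L && frames != 0L)
    stop("first checkpoint must be at cumulative frame count 0", call. = FALSE)
  if (n > 0L && (t <= log$t[n] || frames <= log$frames[n]))
    stop(sprintf(
      "non-monotone checkpoint (t=%.3f after %.3f, frames=%d after %d): %s",
      t, log$t[n], frames, log$frames[n],
      "wall time and frame count must both increase"), call. = FALSE)
  log$t <- c(log$t, t)
  log$frames <- c(log$frames, as.integer(frames))
  log
}

#' Reconstruct the capture time of a frame
#'
#' Piecewise-linear interpolation of time against cumulative frame count:
#' exact at checkpoints, strictly monotone in the frame index, and refusing
#' to extrapolate beyond the last checkpoint.
#'
#' @param log a [timestamp_log()] with at least two checkpoints
#' @param frame_index frame number(s), 0-based, up to the last checkpointed
#'   count
#' @return capture time(s), seconds since session start
#' @export
frame_time <- function(log, frame_index) {
  if (length(log$t) < 2L)
    stop("frame_time needs a log with at least two checkpoints", call. = FALSE)
  if (any(frame_index < 0) || any(frame_index > log$frames[length(log$frames)]))
    stop(sprintf("frame_index out of range [0, %d]; no extrapolation",
                 log$frames[length(log$frames)]), call. = FALSE)
  stats::approx(log$frames, log$t, xout = frame_index, method = "linear",
                ties = "ordered")$y
}

#' Effective frame period around a frame
#'
#' Local frame period from the enclosing checkpoint interval; used to assign
#' single-frame transits their one-frame duration.
#'
#' @param log a [timestamp_log()]
#' @param frame_index frame number(s), 0-based
#' @return seconds per frame at that point of the recording
#' @export
frame_period <- function(log, frame_index) {
  if (length(log$t) < 2L)
    stop("frame_period needs a log with at least two checkpoints", call. = FALSE)
  iv <- findInterval(frame_index, log$frames, rightmost.closed = TRUE,
                     all.inside = TRUE)
  (log$t[iv + 1] - log$t[iv]) / (log$frames[iv + 1] - log$frames[iv])
}

#' Write a timestamp log in the plain-text dialect
#' @param log a [timestamp_log()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_timestamp_log <- function(log, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# t0: %s",
                     format(log$t0, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")), con)
  for (nm in names(log$camera_settings))
    writeLines(sprintf("# %s: %s", nm, log$camera_settings[[nm]]), con)
  iso <- format(log$t0 + log$t, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")
  writeLines(paste(iso, log$frames, sep = "\t"), con)
  invisible(path)
}

#' Read a timestamp log from the plain-text dialect
#' @param path file written by [write_timestamp_log()]
#' @return a [timestamp_log()]
#' @export
read_timestamp_log <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  settings <- list(); t0 <- NULL
  for (h in lines[hdr]) {
    m <- regmatches(h, regexec("^#\\s*([^:]+):\\s*(.*)$", h))[[1]]
    if (length(m) == 3) {
      if (m[2] == "t0") t0 <- as.POSIXct(m[3], format = "%Y-%m-%dT%H:%M:%OS",
                                         tz = "UTC")
      else settings[[m[2]]] <- m[3]
    }
  }
  if (is.null(t0)) stop("timestamp log lacks a t0 header", call. = FALSE)
  body <- lines[!hdr & nzchar(lines)]
  parts <- strsplit(body, "\t")
  times <- as.POSIXct(vapply(parts, `[[`, "", 1),
                      format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
  frames <- as.integer(vapply(parts, `[[`, "", 2))
  log <- timestamp_log(camera_settings = settings, t0 = t0)
  for (k in seq_along(frames))
    log <- append_checkpoint(log, as.numeric(times[k]) - as.numeric(t0),
                             frames[k])
  log
}

#' Frame source over a numbered PNG sequence
#'
#' Yields `(frame, t, index)` per call, joining pixel data with reconstructed
#' capture times from a timestamp log; the contract expected by
#' [run_tracking_loop()] and [detect_session()].
#'
#' @param dir directory containing `frame_%06d.png` files
#' @param log a [timestamp_log()] covering the sequence (or `NULL` to fall
#'   back to a fixed `fps`)
#' @param fps fallback nominal rate when no log is given
#' @return a closure returning `list(frame, t, index)` or `NULL` at end
#' @export
frame_sequence_source <- function(dir, log = NULL, fps = 30) {
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.png$",
                           full.names = TRUE))
  if (length(files) == 0)
    stop(sprintf("no frame_NNNNNN.png files found in %s", dir), call. = FALSE)
  k <- 0L
  function(...) {
    k <<- k + 1L
    if (k > length(files)) return(NULL)
    px <- png::readPNG(files[k])
    if (length(dim(px)) == 3) px <- px[, , 1]
    frame <- px * 255
    t <- if (!is.null(log)) frame_time(log, k - 1L) else (k - 1L) / fps
    attr(frame, "time_s") <- t
    attr(frame, "index") <- k
    list(frame = frame, t = t, index = k)
  }
}
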