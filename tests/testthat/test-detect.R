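test_that("disk fitting recovers radius and flags gibbous bias without correcting", {
  sc <- test_scene()
  fr <- render_frame(sc, c(128, 96), list(), 0)
  fit <- fit_moon_disk(fr, 120)
  expect_equal(fit$radius_px, moon_radius_px(sc), tolerance = 1 / 66)
  expect_equal(fit$center_px, c(128, 96), tolerance = 0.5 / 96)
  # gibbous moon (~85% illuminated): clip a lune off one limb
  full <- fr
  xs <- matrix(seq_len(ncol(fr)) - 0.5, nrow(fr), ncol(fr), byrow = TRUE)
  ys <- matrix(seq_len(nrow(fr)) - 0.5, nrow(fr), ncol(fr))
  R <- moon_radius_px(sc)
  lune <- sqrt((xs - (128 + 1.5 * R))^2 + (ys - 96)^2) < R
  full[lune] <- sc$sky_brightness
  area_frac <- sum(threshold_moon(full, 120)) / sum(threshold_moon(fr, 120))
  expect_gt(area_frac, 0.8); expect_lt(area_frac, 0.9)
  fitg <- fit_moon_disk(full, 120)
  # the equivalent-area radius of a gibbous mask shrinks like sqrt(area frac)
  expect_equal(fitg$radius_px / R, sqrt(area_frac), tolerance = 0.02)
  expect_lt(fitg$center_px[1], 128)  # centre biased toward the lit limb
  # all-dark frame: skip signal
  expect_null(fit_moon_disk(matrix(5, 192, 256), 120))
})

test_that("a lone silhouette is detected within a pixel of truth", {
  sc <- test_scene(seed = 3)
  spec <- transit_spec(1, 70, angular_speed_deg_per_s = 0.4,
                       silhouette_length_px = 5, silhouette_darkness = 100)
  det <- silhouette_detector(detect_config(contrast_threshold = 40))
  s <- simulate_session(sc, list(spec), 5,
                        on_frame = function(f, i, t) detector_step(det, f, t, i))
  d <- detector_results(det)
  truth <- s$truth[s$truth$visible, ]
  # every fully-on-disk truth frame except the background-init frame detected
  expect_gt(nrow(d), 0.7 * nrow(truth))
  merged <- merge(d, truth, by = "frame_index", suffixes = c("_d", "_t"))
  expect_true(all(sqrt((merged$x_d - merged$x_t)^2 +
                       (merged$y_d - merged$y_t)^2) < 1.5))
  # one detection per frame, never more
  expect_true(all(table(d$frame_index) == 1))
})

test_that("static maria are suppressed while movers persist", {
  sc <- test_scene(seed = 4, n_maria = 4, maria_darkness = 60)
  spec <- transit_spec(2, 120, angular_speed_deg_per_s = 0.4,
                       silhouette_length_px = 7, silhouette_darkness = 60)
  det <- silhouette_detector(detect_config(contrast_threshold = 40))
  s <- simulate_session(sc, list(spec), 6,
                        on_frame = function(f, i, t) detector_step(det, f, t, i))
  d <- detector_results(det)
  expect_gt(nrow(d), 3)
  # detections only while the bird transits, none from the static blotches
  tr_sum <- transit_truth_summary(s)
  expect_true(all(d$frame_index >= tr_sum$entry_frame - 1 &
                    d$frame_index <= tr_sum$exit_frame + 1))
})

test_that("fourteen simultaneous silhouettes yield fourteen detections and one flock", {
  sc <- test_scene(seed = 5)
  offs <- seq(-0.8, 0.8, length.out = 14)
  sch <- lapply(offs, function(o) transit_spec(
    1, 330, angular_speed_deg_per_s = 0.35, silhouette_length_px = 5,
    silhouette_darkness = 40, entry_chord_offset = o))
  det <- silhouette_detector(detect_config())
  s <- simulate_session(sc, sch, 5,
                        on_frame = function(f, i, t) detector_step(det, f, t, i))
  d <- detector_results(det)
  # pick a frame in the middle of the crossing: all 14 on the disk
  mid <- round(stats::median(s$truth$frame_index[s$truth$visible]))
  counts <- table(d$frame_index)
  expect_equal(unname(counts[as.character(mid)]), 14)
  tracks <- link_tracks(d, s$timestamp_log, moon_radius_px(sc))
  expect_equal(nrow(tracks), 14)
  flocks <- group_flocks(tracks, window_s = 2)
  expect_equal(nrow(flocks), 1)
  expect_equal(flocks$n_members, 14)
})

test_that("parallel birds separated beyond the gate keep distinct identities", {
  sc <- test_scene(seed = 6)
  sch <- list(
    transit_spec(1, 200, angular_speed_deg_per_s = 0.4,
                 silhouette_length_px = 6, entry_chord_offset = -0.55),
    transit_spec(1, 200, angular_speed_deg_per_s = 0.4,
                 silhouette_length_px = 6, entry_chord_offset = 0.55))
  det <- silhouette_detector(detect_config())
  s <- simulate_session(sc, sch, 5,
                        on_frame = function(f, i, t) detector_step(det, f, t, i))
  tracks <- link_tracks(detector_results(det), s$timestamp_log,
                        moon_radius_px(sc))
  expect_equal(nrow(tracks), 2)
  # no identity swap: every detection of a track stays near one truth transit
  mem <- attr(tracks, "members")
  d <- detector_results(det)
  for (m in mem) {
    owner <- vapply(m, function(r) {
      tt <- s$truth[s$truth$frame_index == d$frame_index[r], ]
      tt$transit_id[which.min((tt$x - d$x[r])^2 + (tt$y - d$y[r])^2)]
    }, 0L)
    expect_length(unique(owner), 1)
  }
})

test_that("entry and exit frames match truth within one frame", {
  sc <- test_scene(seed = 7)
  spec <- transit_spec(1.5, 45, angular_speed_deg_per_s = 0.45,
                       silhouette_length_px = 8, silhouette_darkness = 50,
                       entry_chord_offset = 0.2)
  det <- silhouette_detector(detect_config())
  s <- simulate_session(sc, list(spec), 5,
                        on_frame = function(f, i, t) detector_step(det, f, t, i))
  tracks <- link_tracks(detector_results(det), s$timestamp_log,
                        moon_radius_px(sc))
  expect_equal(nrow(tracks), 1)
  tsum <- transit_truth_summary(s)
  d <- detector_results(det)
  mem <- attr(tracks, "members")[[1]]
  expect_lte(abs(min(d$frame_index[mem]) - tsum$entry_frame), 1)
  expect_lte(abs(max(d$frame_index[mem]) - tsum$exit_frame), 1)
  expect_identical(tracks$completeness, "full_crossing")
})

test_that("single-frame blips become single-frame tracks lasting one frame period", {
  d <- data.frame(frame_index = 10L, t = 10 / 15, x = 100, y = 90,
                  area = 4L, mean_darkness = 80, on_edge = TRUE,
                  length_px = 3, axis_angle_deg = 10, elongation = 2,
                  disk_x = 128, disk_y = 96, disk_r = 66)
  log <- append_checkpoint(append_checkpoint(timestamp_log(), 0, 0), 4, 100)
  tracks <- link_tracks(d, log, disk_radius_px = 66)
  expect_equal(nrow(tracks), 1)
  expect_identical(tracks$completeness, "single_frame")
  expect_equal(tracks$duration_s, 0.04)
  expect_true(is.na(tracks$image_path_angle_deg))
})

test_that("track durations equal last minus first time plus one frame period", {
  sc <- test_scene(seed = 8)
  sch <- make_schedule(5, 1, 10, seed = 8)
  det <- silhouette_detector(detect_config())
  s <- simulate_session(sc, sch, 12,
                        on_frame = function(f, i, t) detector_step(det, f, t, i))
  d <- detector_results(det)
  tracks <- link_tracks(d, s$timestamp_log, moon_radius_px(sc))
  per <- 1 / sc$fps_nominal
  expect_true(all(tracks$duration_s >= per - 1e-9))
  mem <- attr(tracks, "members")
  for (k in seq_len(nrow(tracks))) {
    fi <- sort(d$frame_index[mem[[k]]])
    expect_equal(tracks$duration_s[k],
                 frame_time(s$timestamp_log, max(fi) - 1) -
                   frame_time(s$timestamp_log, min(fi) - 1) + per,
                 tolerance = 1e-6)
  }
})

test_that("no detection is claimed by two tracks (counting conservation)", {
  sc <- test_scene(seed = 9)
  sch <- make_schedule(12, 0.5, 18, seed = 9)
  det <- silhouette_detector(detect_config())
  s <- simulate_session(sc, sch, 20,
                        on_frame = function(f, i, t) detector_step(det, f, t, i))
  d <- detector_results(det)
  tracks <- link_tracks(d, s$timestamp_log, moon_radius_px(sc))
  mem <- attr(tracks, "members")
  all_rows <- unlist(mem)
  expect_equal(length(all_rows), length(unique(all_rows)))
  expect_equal(sum(tracks$n_frames), length(all_rows))
  expect_equal(length(all_rows), nrow(d))
})

test_that("edge-skirting transits with two on-disk frames are recovered and labelled", {
  sc <- test_scene(seed = 10)
  # grazing chord: offset 0.985 of the radius, moderately fast
  spec <- transit_spec(1, 15, angular_speed_deg_per_s = 0.5,
                       silhouette_length_px = 8, silhouette_darkness = 40,
                       entry_chord_offset = 0.985)
  det <- silhouette_detector(detect_config())
  s <- simulate_session(sc, list(spec), 4,
                        on_frame = function(f, i, t) detector_step(det, f, t, i))
  tsum <- transit_truth_summary(s)
  expect_gte(tsum$n_visible_frames, 2)
  expect_lte(tsum$n_visible_frames, 6)
  tracks <- link_tracks(detector_results(det), s$timestamp_log,
                        moon_radius_px(sc))
  expect_gte(nrow(tracks), 1)
  expect_true(any(tracks$completeness %in% c("edge_skirting", "single_frame")))
})

test_that("an erratic slow blob is flagged as a possible non-bird", {
  sc <- test_scene(seed = 11)
  insect <- transit_spec(1, 90, angular_speed_deg_per_s = 0.04,
                         silhouette_length_px = 5, silhouette_darkness = 60,
                         entry_chord_offset = 0, erratic = TRUE)
  det <- silhouette_detector(detect_config())
  s <- simulate_session(sc, list(insect), 10,
                        on_frame = function(f, i, t) detector_step(det, f, t, i))
  tracks <- link_tracks(detector_results(det), s$timestamp_log,
                        moon_radius_px(sc))
  expect_gte(nrow(tracks), 1)
  expect_true(any(tracks$flagged))
})

test_that("flock grouping is single-linkage on temporal proximity", {
  mk <- function(id, s, e) data.frame(track_id = id, start_s = s, end_s = e,
                                      duration_s = e - s, n_frames = 3L,
                                      mean_area_px = 5,
                                      image_path_angle_deg = 0,
                                      completeness = "full_crossing",
                                      flagged = FALSE, mean_elongation = 2)
  # all separated by more than the window: no events
  tr <- rbind(mk(1, 0, 1), mk(2, 5, 6), mk(3, 10, 11))
  expect_equal(nrow(group_flocks(tr, window_s = 2)), 0)
  # chain A-B overlap, B-C overlap, A-C disjoint: one event of three
  tr2 <- rbind(mk(1, 0, 2), mk(2, 1.5, 4), mk(3, 3.8, 6))
  fl <- group_flocks(tr2, window_s = 0.5)
  expect_equal(nrow(fl), 1)
  expect_equal(fl$n_members, 3)
})

test_that("tracks CSV carries flock ids and the JSONL paths parse", {
  sc <- test_scene(seed = 12)
  sch <- make_schedule(6, 0.5, 6, seed = 12)
  det <- silhouette_detector(detect_config())
  s <- simulate_session(sc, sch, 8,
                        on_frame = function(f, i, t) detector_step(det, f, t, i))
  d <- detector_results(det)
  tracks <- link_tracks(d, s$timestamp_log, moon_radius_px(sc))
  flocks <- group_flocks(tracks)
  csv <- withr::local_tempfile(fileext = ".csv")
  jl <- withr::local_tempfile(fileext = ".jsonl")
  write_tracks_csv(tracks, csv, flocks)
  write_tracks_jsonl(tracks, d, jl)
  back <- utils::read.csv(csv)
  expect_equal(nrow(back), nrow(tracks))
  expect_true("flock_id" %in% names(back))
  recs <- lapply(readLines(jl), jsonlite::fromJSON)
  expect_length(recs, nrow(tracks))
  expect_true(all(vapply(recs, function(r) length(r$x) == length(r$frames),
                         TRUE)))
})
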