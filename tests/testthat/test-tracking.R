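test_that("tracking-frame extraction preserves dimensions, identity and constants", {
  cfg <- tracker_config()
  big <- matrix(runif(1920 * 1080, 0, 255), 1080, 1920)
  low <- extract_tracking_frame(big, cfg)
  expect_equal(dim(low), c(600, 800))
  # already at working resolution: unchanged
  small <- matrix(runif(800 * 600), 600, 800)
  expect_identical(extract_tracking_frame(small, cfg), small)
  # constant in, same constant out
  const <- matrix(42, 300, 400)
  expect_true(all(extract_tracking_frame(const, cfg) == 42))
  expect_error(extract_tracking_frame(matrix(numeric(0), 0, 0), cfg),
               "nonempty")
})

test_that("thresholding is exact on synthetic disks and monotone in threshold", {
  sc <- test_scene()
  fr <- render_frame(sc, c(128, 96), list(), 0)
  mask <- threshold_moon(fr, 127)
  # every anti-aliased pixel above 127 and nothing else
  expect_identical(mask, fr > 127)
  expect_true(all(!threshold_moon(matrix(0, 60, 80), 127)))
  expect_error(threshold_moon(fr, 0), "threshold")
  # monotonicity property over random images
  set.seed(8)
  for (k in 1:40) {
    img <- matrix(runif(40 * 30, 0, 255), 30, 40)
    ths <- sort(runif(3, 1, 254))
    areas <- vapply(ths, function(th) sum(threshold_moon(img, th)), 0)
    expect_true(all(diff(areas) <= 0))
  }
})

test_that("centroid hits symmetric, translated and half-disk closed forms", {
  cfg <- tracker_config(work_width_px = 256, work_height_px = 192,
                        min_moon_area_px = 50)
  mk_disk <- function(cx, cy, r, half = FALSE) {
    xs <- matrix(seq_len(256) - 0.5, 192, 256, byrow = TRUE)
    ys <- matrix(seq_len(192) - 0.5, 192, 256)
    m <- sqrt((xs - cx)^2 + (ys - cy)^2) < r
    if (half) m <- m & xs < cx
    m
  }
  st <- moon_centroid(mk_disk(120, 90, 50), cfg)
  expect_true(st$valid)
  expect_equal(st$centroid_px, c(120, 90), tolerance = 0.5 / 120)
  expect_equal(st$fitted_radius_px, 50, tolerance = 0.02)
  # translation equivariance
  st2 <- moon_centroid(mk_disk(120 + 37, 90 - 21, 50), cfg)
  expect_equal(st2$centroid_px - st$centroid_px, c(37, -21),
               tolerance = 0.5 / 37)
  # half-disk centroid sits 4r/(3*pi) toward the lit side
  sth <- moon_centroid(mk_disk(120, 90, 50, half = TRUE), cfg)
  expect_equal(120 - sth$centroid_px[1], 4 * 50 / (3 * pi), tolerance = 1 / 21)
  expect_equal(sth$centroid_px[2], 90, tolerance = 1 / 90)
  # empty and subminimal masks are invalid
  expect_false(moon_centroid(matrix(FALSE, 192, 256), cfg)$valid)
})

test_that("centroid is invariant to brightness rescaling above threshold", {
  sc <- test_scene()
  cfg <- tracker_config(work_width_px = 256, work_height_px = 192,
                        min_moon_area_px = 100)
  fr <- render_frame(sc, c(100, 120), list(), 0)
  c1 <- moon_centroid(threshold_moon(fr, 120), cfg)$centroid_px
  sc_dim <- test_scene(moon_brightness = 180)
  c2 <- moon_centroid(threshold_moon(
    render_frame(sc_dim, c(100, 120), list(), 0), 120), cfg)$centroid_px
  expect_equal(c1, c2, tolerance = 0.6 / 100)
})

test_that("deadband gates corrections and commands are axis-resolved", {
  cfg <- tracker_config(deadband_radius_px = 50, pulse_gain = 0.02,
                        max_pulse_s = 2)
  at <- function(x, y) structure(list(centroid_px = c(x, y), area_px = 5000,
                                      fitted_radius_px = 40, valid = TRUE),
                                 class = "moon_state")
  ref <- cfg$reference_point_px
  expect_length(compute_correction(at(ref[1], ref[2]), cfg), 0)
  expect_length(compute_correction(at(ref[1] + 49, ref[2]), cfg), 0)
  # +100 px x error: one azimuth command, proportional duration
  cmds <- compute_correction(at(ref[1] + 100, ref[2]), cfg)
  expect_length(cmds, 1)
  expect_identical(cmds[[1]]$axis, "azimuth")
  expect_equal(cmds[[1]]$pulse_duration_s, 2)  # capped at max_pulse_s
  cmds2 <- compute_correction(at(ref[1] + 60, ref[2]), cfg)
  expect_equal(cmds2[[1]]$pulse_duration_s, 0.02 * 60)
  # diagonal displacement beyond deadband: one command per axis
  cmds3 <- compute_correction(at(ref[1] + 60, ref[2] - 60), cfg)
  expect_length(cmds3, 2)
  expect_setequal(vapply(cmds3, `[[`, "", "axis"), c("azimuth", "altitude"))
  # invalid state is a precondition violation
  bad <- structure(list(centroid_px = c(NA, NA), area_px = 0,
                        fitted_radius_px = 0, valid = FALSE),
                   class = "moon_state")
  expect_error(compute_correction(bad, cfg), "valid")
})

test_that("corrective pulses move the simulated moon toward the reference", {
  sc <- test_scene()
  plant <- mount_plant()
  cfg <- test_tracker(sc)
  ppd <- px_per_deg(sc)
  pose0 <- c(plant$azimuth_deg, plant$altitude_deg)
  # a +40 px x displacement is cancelled by a pulse sized from the slew rate;
  # the mount offset is subtracted from the drift path, so +azimuth with
  # positive polarity pulls the image in -x
  start <- c(128 + 40, 96)
  err_before <- 40
  mount_pulse(plant, "azimuth", +1, 40 / (plant$slew_deg_s * ppd))
  off <- moonwatch:::.mount_image_offset_px(plant, pose0, ppd)
  err_after <- abs((start[1] - off[1]) - 128)
  expect_lt(err_after, err_before / 10)
})

test_that("loss policy tolerates short occlusions and terminates on long ones", {
  cfg <- tracker_config(loss_patience = 5)
  valid <- structure(list(centroid_px = c(1, 1), area_px = 1e4,
                          fitted_radius_px = 50, valid = TRUE),
                     class = "moon_state")
  invalid <- structure(list(centroid_px = c(NA, NA), area_px = 0,
                            fitted_radius_px = 0, valid = FALSE),
                       class = "moon_state")
  r <- detect_loss(valid, 3, cfg)
  expect_identical(r$decision, "continue")
  expect_identical(r$consecutive_invalid, 0L)
  for (n in 0:3)
    expect_identical(detect_loss(invalid, n, cfg)$decision, "continue")
  expect_identical(detect_loss(invalid, 4, cfg)$decision, "error_and_close")
  expect_error(detect_loss(valid, -1, cfg), ">= 0")
})

test_that("zero drift from the reference yields zero motor commands", {
  sc <- test_scene(drift_rate_deg_per_min = 0, fps_nominal = 1)
  s <- simulate_session(sc, list(), 120, tracker = test_tracker(sc),
                        plant = mount_plant())
  expect_equal(nrow(s$tracking$commands), 0)
  expect_false(s$terminated)
})

test_that("paper-like drift is corrected at roughly minute-scale intervals", {
  sc <- test_scene(fps_nominal = 1, drift_rate_deg_per_min = 0.25,
                   drift_direction_deg = 215)
  s <- simulate_session(sc, list(), 900, tracker = test_tracker(sc),
                        plant = mount_plant())
  ct <- sort(unique(s$tracking$commands$t))
  ct <- ct[ct > 30]   # drop the calibration settle
  intervals <- diff(ct)
  expect_gt(mean(intervals), 20)
  expect_lt(mean(intervals), 180)
  # liveness: evaluations (hence commands) at least a sample interval apart
  expect_true(all(intervals >= test_tracker(sc)$sample_interval_s - 1e-9))
  # retention
  mt <- s$moon_truth
  expect_true(all(mt$moon_x > 0 & mt$moon_x < 256 &
                    mt$moon_y > 0 & mt$moon_y < 192))
})

test_that("closed loop retains the moon from off-centre starts at double the paper-like drift", {
  for (start in list(c(80, 60), c(180, 130))) {
    sc <- test_scene(fps_nominal = 1, drift_rate_deg_per_min = 0.5,
                     drift_direction_deg = 30)
    s <- simulate_session(sc, list(), 3600, tracker = test_tracker(sc),
                          plant = mount_plant(), moon_start_px = start)
    mt <- s$moon_truth
    expect_true(all(mt$moon_x > 0 & mt$moon_x < 256 &
                      mt$moon_y > 0 & mt$moon_y < 192))
    expect_false(s$terminated)
  }
})

test_that("transient fog continues tracking; sustained loss closes the session", {
  mk <- function(fog) test_scene(fps_nominal = 1, fog_attenuation = fog)
  cfg_t <- function(sc) test_tracker(sc, sample_interval_s = 5)
  # 12 s of full occlusion: 2-3 invalid evaluations, below patience 5
  fog_short <- function(t) if (t >= 60 && t < 72) 0 else 1
  sc1 <- mk(fog_short)
  s1 <- simulate_session(sc1, list(), 180, tracker = cfg_t(sc1),
                         plant = mount_plant())
  expect_false(s1$terminated)
  expect_gt(sum(!s1$tracking$log$valid), 0)
  # the tracker recovers a valid fix afterwards
  post <- s1$tracking$log[s1$tracking$log$t > 80, ]
  expect_true(all(post$valid))
  # 60 s of occlusion: >= 5 consecutive invalid evaluations, error and close
  fog_long <- function(t) if (t >= 60 && t < 120) 0 else 1
  sc2 <- mk(fog_long)
  s2 <- simulate_session(sc2, list(), 180, tracker = cfg_t(sc2),
                         plant = mount_plant())
  expect_true(s2$terminated)
  expect_lt(s2$n_frames, 180)
  expect_identical(utils::tail(s2$tracking$log$decision, 1), "error_and_close")
})

test_that("tracking session log writes the CSV dialect", {
  sc <- test_scene(fps_nominal = 1)
  s <- simulate_session(sc, list(), 60, tracker = test_tracker(sc),
                        plant = mount_plant())
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracking_log(s$tracking, path)
  log <- utils::read.csv(path)
  expect_true(all(c("wall_time_iso", "frame_index", "centroid_x",
                    "centroid_y", "area", "valid", "decision")
                  %in% names(log)))
  expect_equal(nrow(log), nrow(s$tracking$log))
})
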