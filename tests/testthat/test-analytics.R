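test_that("plate-scale arithmetic for size and distance is exact", {
  # disk radius 300 px at 0.52 deg diameter: 8.67e-4 deg/px
  r <- angular_size_and_distance(1, 300, 0.52, 0.15)
  expect_equal(r$angular_size_rad * 180 / pi, 0.52 / 600, tolerance = 1e-12)
  # a 10 px silhouette at that scale and 0.15 m body: about 991 m away
  r10 <- angular_size_and_distance(10, 300, 0.52, 0.15)
  expect_equal(r10$angular_size_rad, 10 * (0.52 * pi / 180) / 600,
               tolerance = 1e-12)
  expect_equal(r10$distance_m, 0.15 / r10$angular_size_rad)
  expect_equal(r10$distance_m, 991.7, tolerance = 1e-3)  # ~1 km away
  # doubling the assumed length doubles the distance exactly
  r2 <- angular_size_and_distance(10, 300, 0.52, 0.20)
  expect_equal(r2$distance_m / r10$distance_m * 0.15 / 0.20, 1)
  # sub-resolution silhouettes carry only a lower bound
  expect_true(angular_size_and_distance(1.5, 300)$lower_bound_only)
  expect_error(angular_size_and_distance(10, 300, 0.52, 0.5), "passerine")
})

test_that("distance recovers the simulated flight altitude from apparent size", {
  # a bird of known length at known slant range subtends length/D radians;
  # rendering it and measuring its pixel length must invert to D within the
  # pixel-quantisation error
  sc <- test_scene(seed = 21)
  geom <- sc$geometry              # altitude 45 deg
  H <- 600; D <- H / sin(deg2rad(geom$moon_altitude_deg))
  body <- 0.16
  len_px_true <- body / D * px_per_deg(sc) * 180 / pi
  spec <- transit_spec(1, 100, angular_speed_deg_per_s = 0.4,
                       silhouette_length_px = len_px_true,
                       silhouette_darkness = 40)
  det <- silhouette_detector(detect_config())
  s <- simulate_session(sc, list(spec), 4,
                        on_frame = function(f, i, t) detector_step(det, f, t, i))
  d <- detector_results(det)
  fit_r <- moon_radius_px(sc)
  est <- angular_size_and_distance(stats::median(d$length_px), fit_r,
                                   geom$moon_angular_diameter_deg, body)
  expect_equal(est$distance_m, D, tolerance = 2 / len_px_true)
})

test_that("drift angles of compensating and drifting flyers are recovered", {
  sc <- test_scene(seed = 22, fps_nominal = 20)
  geom <- sc$geometry
  cases <- list(c(bear = 60, off = 0), c(bear = 200, off = 20),
                c(bear = 310, off = -20))
  for (cs in cases) {
    spec <- transit_spec(1, cs[["bear"]],
                         body_orientation_deg = cs[["bear"]] - cs[["off"]],
                         angular_speed_deg_per_s = 0.35,
                         silhouette_length_px = 15,
                         silhouette_darkness = 30)
    det <- silhouette_detector(detect_config())
    s <- simulate_session(sc, list(spec), 5,
                          on_frame = function(f, i, t)
                            detector_step(det, f, t, i))
    d <- detector_results(det)
    tracks <- link_tracks(d, s$timestamp_log, moon_radius_px(sc))
    sol <- flight_solutions(tracks, d, geom, moon_radius_px(sc))
    expect_equal(nrow(sol), 1)
    expect_lt(abs(wrap180(sol$ground_track_bearing_deg - cs[["bear"]])), 3)
    expect_lt(abs(wrap180(sol$drift_angle_deg - cs[["off"]])), 3)
  }
})

test_that("orientation is undefined for round blobs", {
  bo <- body_orientation(axis_angles_deg = c(10, 40, 80),
                         elongations = c(1.1, 1.2, 1.05),
                         image_path_angle_deg = 30, track_bearing_deg = 100,
                         geometry = session_geometry())
  expect_true(is.na(bo$orientation_bearing_deg))
  expect_true(is.na(bo$drift_angle_deg))
})

test_that("the zenith worked case matches the closed-form gate arithmetic", {
  geom <- session_geometry(moon_azimuth_deg = 0, moon_altitude_deg = 90,
                           moon_angular_diameter_deg = 0.52)
  # 45 birds in one hour through a circular gate delta_rad * 1000 m wide
  bearings <- runif(45, 0, 360)
  est <- lowery_traffic_rate(bearings, geom, flight_altitude_m = 1000,
                             duration_h = 1)
  gate_m <- 0.52 * pi / 180 * 1000
  expect_equal(gate_m, 9.0757, tolerance = 1e-4)
  closed_form <- 45 / (gate_m / 1000)   # birds per km front per hour
  expect_equal(est$birds_per_km_front_per_hour, closed_form,
               tolerance = 5e-5)
  # per-mile value in fixed statute ratio
  expect_equal(est$birds_per_mile_front_per_hour /
                 est$birds_per_km_front_per_hour, 1.609344)
})

test_that("zero tracks give a zero rate with the zero-count flag", {
  geom <- session_geometry(moon_altitude_deg = 60)
  est <- lowery_traffic_rate(numeric(0), geom, 500, 1)
  expect_equal(est$birds_per_km_front_per_hour, 0)
  expect_true(est$zero_count)
  expect_error(lowery_traffic_rate(10, session_geometry(moon_altitude_deg = 4),
                                   500, 1), "horizon")
})

test_that("the estimator recovers known fluxes across altitudes and direction fields", {
  F_true <- 3e5; H <- 700; dur_s <- 3600
  for (alt in c(20, 50, 70, 90)) {
    for (dist in list(direction_uniform(), direction_vonmises(290, 3))) {
      geom <- session_geometry(moon_azimuth_deg = 140,
                               moon_altitude_deg = alt)
      sc <- test_scene(geometry = geom)
      sch <- sample_transit_schedule(F_true, H, dist, dur_s, sc,
                                     seed = 100 + alt)
      expect_gt(length(sch), 200)
      # run each bird through the projection and back, as the analysis does
      bearings <- vapply(sch, function(sp) {
        ia <- bearing_to_image_angle(sp$ground_track_bearing_deg, geom)
        image_to_ground_track(ia, geom)$bearing_deg
      }, 0)
      est <- lowery_traffic_rate(bearings, geom, H, dur_s / 3600)
      expect_lt(abs(est$birds_per_km_front_per_hour - F_true) / F_true, 0.1)
    }
  }
})

test_that("session summary reports the rose and both direction conventions", {
  set.seed(33)
  n <- 60
  sol <- data.frame(
    track_id = 1:n, start_s = 1:n, end_s = 1:n + 0.5, duration_s = 0.5,
    n_frames = 5L, completeness = "full_crossing", flagged = FALSE,
    image_path_angle_deg = 0,
    ground_track_bearing_deg = rvonmises_deg(n, 340, 8),
    direction_north_of_east_deg = NA, body_orientation_bearing_deg = NA,
    drift_angle_deg = NA, mean_length_px = 5, angular_size_rad = 1e-4,
    distance_m = 1000, assumed_length_m = 0.15)
  geom <- session_geometry(moon_altitude_deg = 55)
  sm <- session_summary(sol, geom, duration_h = 1)
  expect_equal(sum(sm$rose$weight), 1)
  expect_lt(abs(wrap180(sm$circular_mean_bearing_deg - 340)), 6)
  expect_equal(wrap360(90 - sm$circular_mean_bearing_deg),
               sm$circular_mean_north_of_east_deg)
  expect_gt(sm$traffic_rate$birds_per_km_front_per_hour, 0)
})

test_that("the rose plot renders without error", {
  rose <- direction_rose(c(10, 20, 200, 300, 340, 350), 8)
  path <- withr::local_tempfile(fileext = ".png")
  grDevices::png(path, 300, 300)
  expect_no_error(plot_direction_rose(rose))
  grDevices::dev.off()
  expect_true(file.exists(path))
})
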