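# Scientific quantities from transit tracks: compass flight directions via
# the projection model, body orientation and wind-drift angles, distance from
# apparent size, the direction rose, and the Lowery-style traffic rate with
# an explicit elliptical viewing-gate correction.

#' Body orientation and drift angle for one track
#'
#' Averages per-frame silhouette major-axis angles (axial quantities, so the
#' angle is doubled before circular averaging), disambiguates the head end
#' with the direction of motion, maps the axis through the same projection as
#' the ground track, and reports the signed drift angle (ground-track bearing
#' minus body-orientation bearing, wrapped to (-180, 180]).  A perfectly
#' wind-compensating straight flyer has drift angle 0.
#'
#' @param axis_angles_deg per-frame blob major-axis angles (y-up image
#'   convention, defined mod 180)
#' @param elongations per-frame major/minor axis ratios; frames below
#'   `min_elongation` carry no usable axis
#' @param image_path_angle_deg the track's direction of motion (y-up)
#' @param track_bearing_deg the track's ground bearing from
#'   [image_to_ground_track()]
#' @param geometry a [session_geometry()]
#' @param min_elongation minimum usable elongation (default 1.5)
#' @param min_frames minimum number of usable frames (default 3)
#' @return list: `orientation_bearing_deg` (tail-to-beak compass) and
#'   `drift_angle_deg`, both `NA` when elongation or frame support is
#'   insufficient (orientation undefined, not zero)
#' @export
body_orientation <- function(axis_angles_deg, elongations,
                             image_path_angle_deg, track_bearing_deg,
                             geometry,
                             min_elongation = 1.5, min_frames = 3) {
  ok <- is.finite(axis_angles_deg) & elongations >= min_elongation
  if (sum(ok) < min_frames || !is.finite(image_path_angle_deg))
    return(list(orientation_bearing_deg = NA_real_,
                drift_angle_deg = NA_real_))
  # axial circular mean: double the angles, average, halve
  a2 <- deg2rad(2 * axis_angles_deg[ok])
  axis_img <- rad2deg(atan2(mean(sin(a2)), mean(cos(a2)))) / 2
  # head end: pick the axis direction within 90 deg of the motion
  if (abs(wrap180(axis_img - image_path_angle_deg)) > 90)
    axis_img <- axis_img + 180
  ob <- image_to_ground_track(wrap360(axis_img), geometry)$bearing_deg
  list(orientation_bearing_deg = ob,
       drift_angle_deg = wrap180(track_bearing_deg - ob))
}

#' Angular size and distance from apparent silhouette size
#'
#' The plate scale is anchored by the moon: angular diameter over pixel
#' diameter.  With an assumed body length (passerines of 10-100 g span
#' roughly 0.08-0.25 m) the distance follows from the small-angle relation
#' `distance = assumed_length / angular_size`.
#'
#' @param length_px silhouette length(s) in pixels
#' @param disk_radius_px fitted moon disk radius in pixels
#' @param moon_angular_diameter_deg apparent lunar diameter
#' @param assumed_length_m assumed bird body length, metres (in [0.08, 0.25])
#' @return data frame: `angular_size_rad`, `distance_m`, `lower_bound_only`
#'   (TRUE for sub-resolution silhouettes under 2 px, whose distance is only
#'   a lower bound)
#' @export
angular_size_and_distance <- function(length_px, disk_radius_px,
                                      moon_angular_diameter_deg = 0.52,
                                      assumed_length_m = 0.15) {
  if (assumed_length_m < 0.08 || assumed_length_m > 0.25)
    stop("assumed_length_m outside the 10-100 g passerine span [0.08, 0.25] m",
         call. = FALSE)
  scale_rad_per_px <- deg2rad(moon_angular_diameter_deg) / (2 * disk_radius_px)
  ang <- length_px * scale_rad_per_px
  data.frame(angular_size_rad = ang,
             distance_m = assumed_length_m / ang,
             lower_bound_only = length_px < 2)
}

#' Flight solutions for a set of tracks
#'
#' Joins tracks with the session geometry: compass ground-track bearing (and
#' the classical "north of east" reporting convention), body orientation and
#' drift angle where silhouettes are elongated enough, and distance from
#' apparent size.
#'
#' @param tracks data frame from [link_tracks()]
#' @param detections the detections the tracks index (attribute `members`)
#' @param geometry a [session_geometry()]
#' @param disk_radius_px analysis disk radius for the plate scale
#' @param assumed_length_m assumed body length for distance estimates
#' @return data frame of per-track solutions
#' @export
flight_solutions <- function(tracks, detections, geometry, disk_radius_px,
                             assumed_length_m = 0.15) {
  members <- attr(tracks, "members")
  n <- nrow(tracks)
  if (n == 0) {
    out <- data.frame(
      track_id = integer(0), start_s = numeric(0), end_s = numeric(0),
      duration_s = numeric(0), n_frames = integer(0),
      completeness = character(0), flagged = logical(0),
      image_path_angle_deg = numeric(0),
      ground_track_bearing_deg = numeric(0),
      direction_north_of_east_deg = numeric(0),
      body_orientation_bearing_deg = numeric(0),
      drift_angle_deg = numeric(0), mean_length_px = numeric(0),
      angular_size_rad = numeric(0), distance_m = numeric(0),
      assumed_length_m = numeric(0))
    return(out)
  }
  out <- data.frame(
    track_id = tracks$track_id,
    start_s = tracks$start_s, end_s = tracks$end_s,
    duration_s = tracks$duration_s, n_frames = tracks$n_frames,
    completeness = tracks$completeness, flagged = tracks$flagged,
    image_path_angle_deg = tracks$image_path_angle_deg,
    ground_track_bearing_deg = NA_real_,
    direction_north_of_east_deg = NA_real_,
    body_orientation_bearing_deg = NA_real_,
    drift_angle_deg = NA_real_,
    mean_length_px = NA_real_,
    angular_size_rad = NA_real_, distance_m = NA_real_,
    assumed_length_m = assumed_length_m)
  for (k in seq_len(n)) {
    d <- detections[members[[k]], , drop = FALSE]
    out$mean_length_px[k] <- mean(d$length_px)
    sz <- angular_size_and_distance(out$mean_length_px[k], disk_radius_px,
                                    geometry$moon_angular_diameter_deg,
                                    assumed_length_m)
    out$angular_size_rad[k] <- sz$angular_size_rad
    out$distance_m[k] <- sz$distance_m
    if (is.finite(tracks$image_path_angle_deg[k])) {
      sol <- image_to_ground_track(tracks$image_path_angle_deg[k], geometry)
      out$ground_track_bearing_deg[k] <- sol$bearing_deg
      out$direction_north_of_east_deg[k] <-
        bearing_to_north_of_east(sol$bearing_deg)
      bo <- body_orientation(d$axis_angle_deg, d$elongation,
                             tracks$image_path_angle_deg[k],
                             sol$bearing_deg, geometry)
      out$body_orientation_bearing_deg[k] <- bo$orientation_bearing_deg
      out$drift_angle_deg[k] <- bo$drift_angle_deg
    }
  }
  out
}

#' Lowery-style migration traffic rate with elliptical gate correction
#'
#' The viewing cone through the lunar disk, cut at the assumed flight
#' altitude H, is an ellipse with horizontal semi-axis a = (delta/2) D and
#' along-azimuth semi-axis b = a / sin(theta), D = H / sin(theta).  Each
#' observed bird contributes the reciprocal of the gate width perpendicular
#' to its bearing; the sum over birds divided by the watch duration is the
#' number of birds crossing a unit line of front per hour.  Birds without a
#' usable bearing (single-frame tracks) are still counted, at the mean
#' reciprocal gate of the birds with bearings (or the circular-uniform mean
#' if none have bearings): the classical argument that edge and single-frame
#' birds are real data, not discards.
#'
#' @param bearings_deg compass bearings of the observed birds (`NA` for
#'   tracks without a solvable direction)
#' @param geometry a [session_geometry()]
#' @param flight_altitude_m assumed flight altitude (default 500 m)
#' @param duration_h watch duration in hours (> 0)
#' @return list of class `traffic_rate_estimate`: `birds_per_km_front_per_hour`,
#'   `birds_per_mile_front_per_hour` (statute miles), `n_tracks`, `n_with_bearing`,
#'   `gate_width_summary_m`, `flight_altitude_assumption_m`, `duration_h`,
#'   `zero_count` flag
#' @export
lowery_traffic_rate <- function(bearings_deg, geometry,
                                flight_altitude_m = 500, duration_h) {
  if (duration_h <= 0) stop("duration_h must be > 0", call. = FALSE)
  if (geometry$moon_altitude_deg <= 5)
    stop("traffic rate refused near the horizon: the viewing gate is unbounded",
         call. = FALSE)
  n <- length(bearings_deg)
  if (n == 0) {
    return(structure(list(
      birds_per_km_front_per_hour = 0,
      birds_per_mile_front_per_hour = 0,
      n_tracks = 0L, n_with_bearing = 0L,
      gate_width_summary_m = c(min = NA_real_, mean = NA_real_, max = NA_real_),
      flight_altitude_assumption_m = flight_altitude_m,
      duration_h = duration_h, zero_count = TRUE),
      class = "traffic_rate_estimate"))
  }
  known <- is.finite(bearings_deg)
  g_known <- gate_width_m(bearings_deg[known], geometry, flight_altitude_m)
  inv_known <- 1 / (g_known / 1000)   # per km
  inv_fallback <- if (any(known)) mean(inv_known) else {
    beta <- seq(0, 359.5, by = 0.5)
    mean(1 / (gate_width_m(beta, geometry, flight_altitude_m) / 1000))
  }
  total <- sum(inv_known) + sum(!known) * inv_fallback
  rate_km <- total / duration_h
  g_all <- if (any(known)) g_known else numeric(0)
  structure(list(
    birds_per_km_front_per_hour = rate_km,
    birds_per_mile_front_per_hour = rate_km * KM_PER_MILE,
    n_tracks = as.integer(n), n_with_bearing = as.integer(sum(known)),
    gate_width_summary_m = c(min = if (length(g_all)) min(g_all) else NA_real_,
                             mean = if (length(g_all)) mean(g_all) else NA_real_,
                             max = if (length(g_all)) max(g_all) else NA_real_),
    flight_altitude_assumption_m = flight_altitude_m,
    duration_h = duration_h, zero_count = FALSE),
    class = "traffic_rate_estimate")
}

#' @export
print.traffic_rate_estimate <- function(x, ...) {
  cat(sprintf("Traffic rate: %.1f birds/km front/h (%.1f birds/mile front/h)\n",
              x$birds_per_km_front_per_hour, x$birds_per_mile_front_per_hour))
  cat(sprintf("  from %d tracks (%d with bearings) over %.2f h, H = %.0f m\n",
              x$n_tracks, x$n_with_bearing, x$duration_h,
              x$flight_altitude_assumption_m))
  invisible(x)
}

#' Session summary from flight solutions
#'
#' @param solutions data frame from [flight_solutions()]
#' @param geometry a [session_geometry()]
#' @param duration_h watch duration in hours
#' @param flight_altitude_m assumed flight altitude
#' @param n_rose_bins direction-rose bin count
#' @return list: counts, duration range, the direction rose, circular mean in
#'   both conventions, and the traffic rate in both units
#' @export
session_summary <- function(solutions, geometry, duration_h,
                            flight_altitude_m = 500, n_rose_bins = 16) {
  rose <- direction_rose(solutions$ground_track_bearing_deg, n_rose_bins)
  rate <- lowery_traffic_rate(solutions$ground_track_bearing_deg, geometry,
                              flight_altitude_m, duration_h)
  list(
    n_tracks = nrow(solutions),
    n_flagged = sum(solutions$flagged),
    duration_range_s = if (nrow(solutions))
      range(solutions$duration_s) else c(NA_real_, NA_real_),
    completeness_counts = if (nrow(solutions))
      table(solutions$completeness) else table(character(0)),
    rose = rose,
    circular_mean_bearing_deg = attr(rose, "circular_mean_deg"),
    circular_mean_north_of_east_deg =
      attr(rose, "circular_mean_north_of_east_deg"),
    traffic_rate = rate,
    assumptions = list(flight_altitude_m = flight_altitude_m,
                       moon_altitude_deg = geometry$moon_altitude_deg,
                       moon_azimuth_deg = geometry$moon_azimuth_deg))
}

#' Plot a direction rose
#'
#' Base-graphics polar histogram of flight bearings (north up, clockwise).
#'
#' @param rose a [direction_rose()] result
#' @param main plot title
#' @return invisibly, the rose
#' @export
plot_direction_rose <- function(rose, main = "Flight directions") {
  n <- nrow(rose)
  if (n == 0) { graphics::plot.new(); return(invisible(rose)) }
  graphics::plot(NA, xlim = c(-1.1, 1.1), ylim = c(-1.1, 1.1), asp = 1,
                 axes = FALSE, xlab = "", ylab = "", main = main)
  width <- 2 * pi / n
  for (k in seq_len(n)) {
    # compass angle -> plot angle (north up, clockwise)
    a0 <- pi / 2 - deg2rad(rose$bin_center_deg[k]) - width / 2
    th <- seq(a0, a0 + width, length.out = 16)
    r <- rose$weight[k] / max(rose$weight)
    graphics::polygon(c(0, r * cos(th), 0), c(0, r * sin(th), 0),
                      col = "steelblue", border = "white")
  }
  graphics::text(c(0, 1.05, 0, -1.05), c(1.05, 0, -1.05, 0),
                 c("N", "E", "S", "W"))
  invisible(rose)
}
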