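# Scene configuration and transit specifications for the synthetic
# lunar-observation simulator.

#' Synthetic scene configuration
#'
#' Parameters of the simulated field of view: a bright near-circular moon disk
#' drifting across a dark sky, with small dark silhouettes crossing it.  The
#' moon's pixel diameter follows from the angular diameter and the field of
#' view: `moon_angular_diameter_deg / field_of_view_deg * frame_width_px`.
#'
#' @param frame_width_px,frame_height_px frame dimensions in pixels
#' @param field_of_view_deg degrees of sky spanned by the frame width
#' @param moon_angular_diameter_deg apparent lunar diameter (default 0.52)
#' @param moon_brightness,sky_brightness 8-bit levels; moon must be brighter
#' @param drift_rate_deg_per_min apparent image-plane lunar drift magnitude
#' @param drift_direction_deg image-plane drift heading, y-up math convention
#' @param fps_nominal nominal frames per second
#' @param fog_attenuation multiplicative disk-brightness factor in [0, 1]
#'   (1 = clear sky); may also be a function of time returning such a factor
#' @param timing_jitter fraction of the nominal frame period by which actual
#'   frame times jitter uniformly (0 = exact clock; 0.2 models an imprecise
#'   software-timed camera)
#' @param n_maria number of static dark blotches on the disk (crude stand-ins
#'   for lunar maria, used to exercise background suppression; 0 = featureless)
#' @param maria_darkness 8-bit drop of maria below the disk brightness
#' @param geometry a [session_geometry()] giving the moon's sky position used
#'   to map compass directions into the image plane
#' @param rng_seed integer seed controlling all scene randomness
#' @return an object of class `scene_config`
#' @export
scene_config <- function(frame_width_px = 256, frame_height_px = 192,
                         field_of_view_deg = 1.0,
                         moon_angular_diameter_deg = 0.52,
                         moon_brightness = 230, sky_brightness = 10,
                         drift_rate_deg_per_min = 0.25,
                         drift_direction_deg = 200,
                         fps_nominal = 15,
                         fog_attenuation = 1,
                         timing_jitter = 0,
                         n_maria = 0, maria_darkness = 40,
                         geometry = session_geometry(),
                         rng_seed = 1L) {
  if (frame_width_px <= 0 || frame_height_px <= 0)
    stop("frame dimensions must be positive", call. = FALSE)
  if (moon_brightness <= sky_brightness)
    stop("moon_brightness must exceed sky_brightness", call. = FALSE)
  if (is.numeric(fog_attenuation) &&
      (fog_attenuation < 0 || fog_attenuation > 1))
    stop("fog_attenuation must lie in [0, 1]", call. = FALSE)
  diam_px <- moon_angular_diameter_deg / field_of_view_deg * frame_width_px
  if (diam_px >= min(frame_width_px, frame_height_px))
    stop(sprintf(
      "moon pixel diameter %.1f px does not fit in a %d x %d frame; widen the field of view",
      diam_px, frame_width_px, frame_height_px), call. = FALSE)
  structure(list(
    frame_width_px = as.integer(frame_width_px),
    frame_height_px = as.integer(frame_height_px),
    field_of_view_deg = field_of_view_deg,
    moon_angular_diameter_deg = moon_angular_diameter_deg,
    moon_brightness = moon_brightness,
    sky_brightness = sky_brightness,
    drift_rate_deg_per_min = drift_rate_deg_per_min,
    drift_direction_deg = drift_direction_deg,
    fps_nominal = fps_nominal,
    fog_attenuation = fog_attenuation,
    timing_jitter = timing_jitter,
    n_maria = as.integer(n_maria),
    maria_darkness = maria_darkness,
    geometry = geometry,
    rng_seed = as.integer(rng_seed)
  ), class = "scene_config")
}

#' Pixels per degree of the scene's plate scale
#' @param scene a [scene_config()]
#' @return pixels per degree
#' @export
px_per_deg <- function(scene) scene$frame_width_px / scene$field_of_view_deg

#' Moon disk radius implied by a scene, in pixels
#' @param scene a [scene_config()]
#' @return radius in pixels
#' @export
moon_radius_px <- function(scene)
  scene$moon_angular_diameter_deg * px_per_deg(scene) / 2

#' One planned silhouette transit
#'
#' Describes a single bird (or distractor) crossing the disk.  The flight is
#' specified in compass terms — ground-track bearing and tail-to-beak body
#' orientation — and mapped into the image plane through the scene geometry,
#' so detection and analytics can be validated against known truth.
#'
#' @param start_time_s session time at which the silhouette enters the disk
#' @param ground_track_bearing_deg compass bearing of flight
#' @param body_orientation_deg compass bearing of the tail-to-beak axis
#' @param angular_speed_deg_per_s image-plane angular speed (> 0)
#' @param silhouette_length_px major-axis length in pixels (>= 1)
#' @param silhouette_darkness 8-bit level of the silhouette interior
#' @param entry_chord_offset signed perpendicular offset of the crossing chord
#'   from the disk centre, as a fraction of disk radius in [-1, 1]
#' @param erratic logical; if `TRUE` the blob wanders (a slow non-bird
#'   distractor such as an insect) instead of flying straight
#' @return an object of class `transit_spec`
#' @export
transit_spec <- function(start_time_s,
                         ground_track_bearing_deg,
                         body_orientation_deg = ground_track_bearing_deg,
                         angular_speed_deg_per_s = 0.5,
                         silhouette_length_px = 6,
                         silhouette_darkness = 30,
                         entry_chord_offset = 0,
                         erratic = FALSE) {
  if (silhouette_length_px < 1) stop("silhouette_length_px must be >= 1", call. = FALSE)
  if (angular_speed_deg_per_s <= 0) stop("angular speed must be > 0", call. = FALSE)
  if (abs(entry_chord_offset) > 1) stop("|entry_chord_offset| must be <= 1", call. = FALSE)
  structure(list(
    start_time_s = start_time_s,
    ground_track_bearing_deg = wrap360(ground_track_bearing_deg),
    body_orientation_deg = wrap360(body_orientation_deg),
    angular_speed_deg_per_s = angular_speed_deg_per_s,
    silhouette_length_px = silhouette_length_px,
    silhouette_darkness = silhouette_darkness,
    entry_chord_offset = entry_chord_offset,
    erratic = isTRUE(erratic)
  ), class = "transit_spec")
}

# Per-transit image-plane kinematics relative to the moon centre.
# The chord is laid out in moon-fixed coordinates: unit direction d from the
# image path angle, perpendicular n, entry point at offset*R along n minus the
# half-chord along d.  Positions are (x right, y down) offsets from the disk
# centre.  Bird angular speeds dwarf lunar drift over a transit, so the path
# is frozen relative to the disk; this keeps entry/exit truth exact.
.transit_kinematics <- function(spec, scene) {
  R <- moon_radius_px(scene)
  alpha <- deg2rad(bearing_to_image_angle(spec$ground_track_bearing_deg,
                                          scene$geometry))
  d <- c(cos(alpha), -sin(alpha))          # y-down pixel frame
  n <- c(-sin(alpha), -cos(alpha))         # 90 deg CCW (y-up) from d
  speed_px <- spec$angular_speed_deg_per_s * px_per_deg(scene)
  off <- spec$entry_chord_offset * R
  half_chord <- sqrt(max(R^2 - off^2, 0))
  # entry margin: start half a body length before the rim so entry frame truth
  # is the first frame with the centroid on the disk
  entry <- off * n - (half_chord + 1e-9) * d
  list(entry_xy = entry, dir = d, speed_px_s = speed_px,
       chord_px = 2 * half_chord,
       axis_angle_deg = bearing_to_image_angle(spec$body_orientation_deg,
                                               scene$geometry))
}

# position of the silhouette centre (y-down offsets from moon centre) at
# session time t; erratic blobs superpose a slow quasi-periodic wander so
# their paths fail the straight-line flag downstream
.transit_position <- function(spec, kin, t) {
  dt <- t - spec$start_time_s
  pos <- kin$entry_xy + dt * kin$speed_px_s * kin$dir
  if (spec$erratic) {
    ph <- (spec$start_time_s * 7.31) %% (2 * pi)
    amp <- 2 + spec$silhouette_length_px
    pos <- pos + amp * c(sin(2 * pi * 0.9 * dt + ph),
                         cos(2 * pi * 1.4 * dt + 2 * ph))
  }
  pos
}

# duration the centre spends inside the disk
.transit_duration_s <- function(kin) kin$chord_px / kin$speed_px_s
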