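# Projection geometry between ground-track compass bearings and image-plane
# path angles, viewing-gate widths, and circular statistics.
#
# Conventions
# -----------
# * Compass bearings are degrees clockwise from north (N = 0, E = 90).
# * Image path angles are degrees counterclockwise from image +x (rightward)
#   with image "up" positive, i.e. mathematical convention in a y-up frame.
#   Pixel row indices increase downward; conversion happens at the pixel
#   boundary, not here.
# * The historical moon-watching literature reports directions
#   "north of east" (counterclockwise from east): bearing = 90 - value (mod 360).

#' Session viewing geometry
#'
#' Bundles the topocentric moon position and camera orientation needed to
#' convert image-plane motion to compass directions.  For field data these
#' come from [moon_topocentric()]; for simulated scenes they are set directly.
#'
#' @param moon_azimuth_deg topocentric moon azimuth, degrees clockwise from north
#' @param moon_altitude_deg topocentric moon altitude above horizon, degrees
#' @param moon_angular_diameter_deg apparent lunar diameter, degrees
#' @param camera_roll_deg rotation of image +x from the local horizontal at the
#'   moon, degrees counterclockwise as seen on screen
#' @param flip_x,flip_y logical; mirror flags for optical inversions
#' @param latitude_deg,longitude_deg optional site coordinates (metadata)
#' @return an object of class `session_geometry`
#' @export
session_geometry <- function(moon_azimuth_deg = 180,
                             moon_altitude_deg = 45,
                             moon_angular_diameter_deg = 0.52,
                             camera_roll_deg = 0,
                             flip_x = FALSE, flip_y = FALSE,
                             latitude_deg = NA_real_,
                             longitude_deg = NA_real_) {
  stopifnot_scalar(moon_azimuth_deg)
  stopifnot_scalar(moon_altitude_deg)
  if (moon_angular_diameter_deg <= 0)
    stop("moon angular diameter must be positive", call. = FALSE)
  structure(list(
    moon_azimuth_deg = wrap360(moon_azimuth_deg),
    moon_altitude_deg = moon_altitude_deg,
    moon_angular_diameter_deg = moon_angular_diameter_deg,
    camera_roll_deg = camera_roll_deg,
    flip_x = isTRUE(flip_x), flip_y = isTRUE(flip_y),
    latitude_deg = latitude_deg, longitude_deg = longitude_deg
  ), class = "session_geometry")
}

# apply/remove camera roll and mirror flags between the "horizon-aligned"
# image frame used by the projection model and the raw camera frame
.raw_to_aligned <- function(angle_deg, geometry) {
  a <- angle_deg
  if (geometry$flip_x) a <- 180 - a
  if (geometry$flip_y) a <- -a
  wrap360(a + geometry$camera_roll_deg)
}
.aligned_to_raw <- function(angle_deg, geometry) {
  a <- angle_deg - geometry$camera_roll_deg
  if (geometry$flip_y) a <- -a
  if (geometry$flip_x) a <- 180 - a
  wrap360(a)
}

#' Project a horizontal compass bearing to an image path angle
#'
#' For a bird in level flight with ground-track bearing `bearing_deg`, seen
#' against the moon at azimuth A and altitude theta, the image-plane velocity
#' components are u = sin(beta - A) horizontally and w = -cos(beta - A) *
#' sin(theta) vertically (y-up).  The image path angle is atan2(w, u).
#'
#' @param bearing_deg compass bearing(s) of the ground track
#' @param geometry a [session_geometry()]
#' @return image path angle(s) in degrees, y-up math convention, in [0, 360)
#' @export
bearing_to_image_angle <- function(bearing_deg, geometry) {
  A <- deg2rad(geometry$moon_azimuth_deg)
  th <- deg2rad(geometry$moon_altitude_deg)
  b <- deg2rad(bearing_deg)
  u <- sin(b - A)
  w <- -cos(b - A) * sin(th)
  .aligned_to_raw(rad2deg(atan2(w, u)), geometry)
}

#' Invert an image path angle to a ground-track compass bearing
#'
#' Inverts the level-flight projection model of [bearing_to_image_angle()].
#' The two-fold line ambiguity is resolved because the path angle carries the
#' direction of motion, not just the line.  Near-horizon moons foreshorten all
#' bearings onto nearly horizontal image motion and the inversion becomes
#' ill-conditioned; near-zenith moons make the azimuth reference itself weak.
#'
#' @param image_angle_deg image path angle(s), y-up math convention, degrees
#' @param geometry a [session_geometry()]
#' @param min_altitude_deg refuse inversion below this moon altitude (degeneracy
#'   guard; default 5)
#' @return a list with `bearing_deg` (compass, [0,360)) and `flag`
#'   (`"ok"` or `"wide_uncertainty"` for moon altitude above 85 degrees)
#' @export
image_to_ground_track <- function(image_angle_deg, geometry,
                                  min_altitude_deg = 5) {
  th_deg <- geometry$moon_altitude_deg
  if (th_deg <= min_altitude_deg)
    stop(sprintf(
      "moon altitude %.2f deg is at or below the %.1f deg degeneracy guard: %s",
      th_deg, min_altitude_deg,
      "image motion is foreshortened onto the horizontal and bearings are unrecoverable"
    ), call. = FALSE)
  a <- deg2rad(.raw_to_aligned(image_angle_deg, geometry))
  th <- deg2rad(th_deg)
  u <- cos(a)
  w <- sin(a)
  beta <- geometry$moon_azimuth_deg + rad2deg(atan2(u, -w / sin(th)))
  list(bearing_deg = wrap360(beta),
       flag = if (th_deg > 85) "wide_uncertainty" else "ok")
}

#' Convert between compass bearings and the "north of east" convention
#'
#' The classical moon-watching reports use degrees counterclockwise from east.
#' @param x angle(s) in degrees
#' @return converted angle(s) in [0, 360)
#' @export
bearing_to_north_of_east <- function(x) wrap360(90 - x)

#' @rdname bearing_to_north_of_east
#' @export
north_of_east_to_bearing <- function(x) wrap360(90 - x)

#' Width of the viewing gate at flight altitude, perpendicular to a bearing
#'
#' The cone of observation through the lunar disk, cut horizontally at flight
#' altitude H, is an ellipse: its horizontal semi-axis (perpendicular to the
#' moon azimuth) is a = (delta/2) * D and its along-azimuth semi-axis is
#' b = a / sin(theta), where D = H / sin(theta) is the slant range to the cut,
#' delta the moon's angular diameter (radians) and theta its altitude.  A bird
#' with ground-track bearing beta crosses a gate of width
#' 2 * sqrt(a^2 sin^2 psi + b^2 cos^2 psi) with psi = beta - moon azimuth.
#'
#' @param bearing_deg bird ground-track compass bearing(s)
#' @param geometry a [session_geometry()]
#' @param flight_altitude_m assumed flight altitude above the observer, metres
#' @return gate width(s) in metres
#' @export
gate_width_m <- function(bearing_deg, geometry, flight_altitude_m) {
  th <- deg2rad(geometry$moon_altitude_deg)
  if (geometry$moon_altitude_deg <= 5)
    stop("gate width is unbounded near the horizon (moon altitude <= 5 deg)",
         call. = FALSE)
  delta <- deg2rad(geometry$moon_angular_diameter_deg)
  D <- flight_altitude_m / sin(th)
  a <- (delta / 2) * D
  b <- a / sin(th)
  psi <- deg2rad(bearing_deg - geometry$moon_azimuth_deg)
  2 * sqrt(a^2 * sin(psi)^2 + b^2 * cos(psi)^2)
}

# ---- circular statistics ----------------------------------------------------

#' Circular mean of compass bearings
#' @param bearing_deg bearings in degrees
#' @param na.rm drop missing values
#' @return list with `mean_deg` (compass), `resultant_length` in [0,1];
#'   both `NA` for empty input
#' @export
circular_mean <- function(bearing_deg, na.rm = TRUE) {
  if (na.rm) bearing_deg <- bearing_deg[!is.na(bearing_deg)]
  n <- length(bearing_deg)
  if (n == 0L) return(list(mean_deg = NA_real_, resultant_length = NA_real_))
  b <- deg2rad(bearing_deg)
  s <- mean(sin(b)); c <- mean(cos(b))
  list(mean_deg = wrap360(rad2deg(atan2(s, c))),
       resultant_length = sqrt(s^2 + c^2))
}

#' Direction rose: normalised histogram of bearings with circular mean
#'
#' @param bearing_deg compass bearings in degrees
#' @param n_bins number of equal angular bins (>= 4); the first bin is
#'   centred on north
#' @return a data frame with `bin_center_deg` and `weight` (summing to 1),
#'   plus attributes `circular_mean_deg` (compass) and
#'   `circular_mean_north_of_east_deg`; zero rows for empty input
#' @export
direction_rose <- function(bearing_deg, n_bins = 16) {
  if (n_bins < 4) stop("n_bins must be >= 4", call. = FALSE)
  bearing_deg <- bearing_deg[!is.na(bearing_deg)]
  centers <- (seq_len(n_bins) - 1) * 360 / n_bins
  if (length(bearing_deg) == 0L) {
    out <- data.frame(bin_center_deg = numeric(0), weight = numeric(0))
    attr(out, "circular_mean_deg") <- NA_real_
    attr(out, "circular_mean_north_of_east_deg") <- NA_real_
    return(out)
  }
  half <- 180 / n_bins
  idx <- floor(wrap360(bearing_deg + half) / (360 / n_bins)) + 1
  counts <- tabulate(idx, nbins = n_bins)
  cm <- circular_mean(bearing_deg)
  out <- data.frame(bin_center_deg = centers, weight = counts / sum(counts))
  attr(out, "circular_mean_deg") <- cm$mean_deg
  attr(out, "circular_mean_north_of_east_deg") <-
    bearing_to_north_of_east(cm$mean_deg)
  out
}

#' Draw from a von Mises direction distribution
#'
#' Best-Fisher rejection sampler; used by the scene simulator to emulate a
#' directed migration night.
#'
#' @param n number of draws
#' @param mu_deg mean direction, compass degrees
#' @param kappa concentration (0 = uniform on the circle)
#' @return compass bearings in [0, 360)
#' @export
rvonmises_deg <- function(n, mu_deg, kappa) {
  if (kappa < 0) stop("kappa must be >= 0", call. = FALSE)
  if (kappa == 0) return(stats::runif(n, 0, 360))
  mu <- deg2rad(mu_deg)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u[2] > 0 || log(c_ / u[2]) + 1 - c_ >= 0) {
      theta <- mu + sign(u[3] - 0.5) * acos(f)
      out[i] <- wrap360(rad2deg(theta))
      i <- i + 1L
    }
  }
  out
}
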