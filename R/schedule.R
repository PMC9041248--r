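# Sampling transit schedules from a known migration flux.
#
# Birds are modelled as a uniform horizontal flux at an assumed flight
# altitude: F birds crossing each km of front per hour, with bearings drawn
# from a direction distribution.  The viewing cone through the lunar disk
# cuts that layer in an ellipse, so a bird of bearing beta is intercepted
# when it crosses a gate of width `gate_width_m(beta)`; the scheduler samples
# by Poisson thinning against the widest gate, which makes the realized
# transit count carry the true flux — the oracle for traffic-rate recovery.

#' Direction distribution specifications
#'
#' @param mu_deg mean compass direction
#' @param kappa von Mises concentration
#' @return a list understood by [sample_transit_schedule()]
#' @export
direction_uniform <- function() list(type = "uniform")

#' @rdname direction_uniform
#' @export
direction_vonmises <- function(mu_deg, kappa)
  list(type = "vonmises", mu_deg = mu_deg, kappa = kappa)

.sample_bearings <- function(n, dist) {
  switch(dist$type,
         uniform = stats::runif(n, 0, 360),
         vonmises = rvonmises_deg(n, dist$mu_deg, dist$kappa),
         stop("unknown direction distribution type: ", dist$type,
              call. = FALSE))
}

.direction_density <- function(beta_deg, dist) {
  switch(dist$type,
         uniform = rep(1 / 360, length(beta_deg)),
         vonmises = {
           k <- dist$kappa
           exp(k * cos(deg2rad(beta_deg - dist$mu_deg))) /
             (360 / (2 * pi) * 2 * pi * besselI(k, 0))
         })
}

#' Expected transit count for a flux and direction field
#'
#' Numerical integral of `flux * gate(beta) * p(beta)` over bearings times the
#' session duration; the analytic expectation the sampler is calibrated to.
#'
#' @param density_per_km_h flux, birds per km of front per hour
#' @param geometry a [session_geometry()]
#' @param flight_altitude_m assumed flight altitude
#' @param direction_distribution see [direction_uniform()]
#' @param duration_s session length
#' @return expected number of disk transits
#' @export
expected_transit_count <- function(density_per_km_h, geometry,
                                   flight_altitude_m,
                                   direction_distribution, duration_s) {
  beta <- seq(0, 360, length.out = 721)[-721]
  g_km <- gate_width_m(beta, geometry, flight_altitude_m) / 1000
  p <- .direction_density(beta, direction_distribution)
  density_per_km_h * sum(g_km * p) * (360 / length(beta)) * duration_s / 3600
}

#' Sample a transit schedule from a known flux
#'
#' Places birds by simulating a uniform horizontal flux at
#' `flight_altitude_m` intersecting the viewing cone, so the true flux is
#' known exactly and traffic-rate recovery can be validated.  Impact
#' parameters are uniform across the gate, which maps to entry-chord offsets
#' uniform across the disk diameter in the image plane.
#'
#' @param density_per_km_h true flux, birds per km of front per hour (>= 0)
#' @param flight_altitude_m assumed flight altitude above the observer (> 0)
#' @param direction_distribution a [direction_uniform()] or
#'   [direction_vonmises()]
#' @param duration_s session length in seconds (> 0)
#' @param scene a [scene_config()]; supplies the viewing geometry and plate
#'   scale
#' @param seed integer seed; identical arguments and seed reproduce the
#'   schedule exactly
#' @param airspeed_m_s range (length-2) or scalar bird airspeed, m/s
#' @param silhouette_length_px range or scalar silhouette lengths, px
#' @param silhouette_darkness range or scalar 8-bit silhouette levels
#' @param orientation_sd_deg circular s.d. of body orientation about the
#'   ground track (0 = fully wind-compensating flyers)
#' @return list of [transit_spec()] sorted by start time, with attribute
#'   `expected_count`
#' @export
sample_transit_schedule <- function(density_per_km_h, flight_altitude_m,
                                    direction_distribution = direction_uniform(),
                                    duration_s, scene, seed = 1L,
                                    airspeed_m_s = c(8, 18),
                                    silhouette_length_px = c(3, 15),
                                    silhouette_darkness = c(10, 60),
                                    orientation_sd_deg = 0) {
  if (density_per_km_h < 0) stop("density_per_km_h must be >= 0", call. = FALSE)
  if (duration_s <= 0) stop("duration_s must be > 0", call. = FALSE)
  if (flight_altitude_m <= 0) stop("flight_altitude_m must be > 0", call. = FALSE)
  geometry <- scene$geometry
  if (geometry$moon_altitude_deg <= 5)
    stop(sprintf(
      "degenerate session geometry: moon altitude %.1f deg is at or below the horizon guard (5 deg)",
      geometry$moon_altitude_deg), call. = FALSE)
  if (density_per_km_h == 0) {
    out <- list(); attr(out, "expected_count") <- 0
    return(out)
  }
  rng <- function(x, n) if (length(x) == 2) stats::runif(n, x[1], x[2])
                        else rep(x[1], n)
  th <- deg2rad(geometry$moon_altitude_deg)
  D <- flight_altitude_m / sin(th)
  # widest gate: along the moon azimuth, width 2b
  gmax_m <- gate_width_m(geometry$moon_azimuth_deg, geometry, flight_altitude_m)
  lambda <- density_per_km_h * (gmax_m / 1000) * duration_s / 3600
  .with_seed(as.integer(seed), {
    n_cand <- stats::rpois(1, lambda)
    if (n_cand == 0) {
      out <- list()
    } else {
      beta <- .sample_bearings(n_cand, direction_distribution)
      keep <- stats::runif(n_cand) <
        gate_width_m(beta, geometry, flight_altitude_m) / gmax_m
      beta <- beta[keep]
      n <- length(beta)
      if (n == 0) {
        out <- list()
      } else {
        speed <- rng(airspeed_m_s, n)
        ang_speed <- rad2deg(speed / D)
        starts <- stats::runif(n, 0, duration_s)
        offs <- stats::runif(n, -1, 1)
        lens <- rng(silhouette_length_px, n)
        dark <- rng(silhouette_darkness, n)
        orient <- if (orientation_sd_deg > 0)
          beta + stats::rnorm(n, 0, orientation_sd_deg) else beta
        ord <- order(starts)
        out <- lapply(ord, function(k) transit_spec(
          start_time_s = starts[k],
          ground_track_bearing_deg = beta[k],
          body_orientation_deg = orient[k],
          angular_speed_deg_per_s = ang_speed[k],
          silhouette_length_px = lens[k],
          silhouette_darkness = dark[k],
          entry_chord_offset = offs[k]))
      }
    }
    attr(out, "expected_count") <- expected_transit_count(
      density_per_km_h, geometry, flight_altitude_m, direction_distribution,
      duration_s)
    out
  })
}
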