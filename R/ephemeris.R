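# Topocentric lunar position from a truncated analytic lunar theory.
#
# The main-problem series below (the dominant periodic terms of the lunar
# longitude, latitude and distance, with the eccentricity damping factor E on
# terms involving the solar anomaly) delivers geocentric positions good to a
# few arcminutes, far inside the ~0.2 degree budget needed to rotate
# direction references for flight-path analysis.  Nutation and atmospheric
# refraction are neglected (both < 0.01 deg above 10 deg altitude at this
# accuracy level); the parallax correction to altitude uses the standard
# small-angle form.

# fundamental arguments, degrees, T in Julian centuries from J2000.0 (TT)
.moon_fundamental <- function(T) {
  list(
    Lp = 218.3164477 + 481267.88123421 * T - 0.0015786 * T^2 +
      T^3 / 538841 - T^4 / 65194000,
    D = 297.8501921 + 445267.1114034 * T - 0.0018819 * T^2 +
      T^3 / 545868 - T^4 / 113065000,
    M = 357.5291092 + 35999.0502909 * T - 0.0001536 * T^2 + T^3 / 24490000,
    Mp = 134.9633964 + 477198.8675055 * T + 0.0087414 * T^2 +
      T^3 / 69699 - T^4 / 14712000,
    F = 93.2720950 + 483202.0175233 * T - 0.0036539 * T^2 -
      T^3 / 3526000 + T^4 / 863310000,
    A1 = 119.75 + 131.849 * T,
    A2 = 53.09 + 479264.290 * T,
    A3 = 313.45 + 481266.484 * T,
    E = 1 - 0.002516 * T - 0.0000074 * T^2
  )
}

# periodic terms: columns D, M, Mp, F, longitude coeff (deg), distance coeff (km)
.moon_lr_terms <- matrix(c(
  0, 0, 1, 0, 6.288774, -20905.355,
  2, 0, -1, 0, 1.274027, -3699.111,
  2, 0, 0, 0, 0.658314, -2955.968,
  0, 0, 2, 0, 0.213618, -569.925,
  0, 1, 0, 0, -0.185116, 48.888,
  0, 0, 0, 2, -0.114332, -3.149,
  2, 0, -2, 0, 0.058793, 246.158,
  2, -1, -1, 0, 0.057066, -152.138,
  2, 0, 1, 0, 0.053322, -170.733,
  2, -1, 0, 0, 0.045758, -204.586,
  0, 1, -1, 0, -0.040923, -129.620,
  1, 0, 0, 0, -0.034720, 108.743,
  0, 1, 1, 0, -0.030383, 104.755,
  2, 0, 0, -2, 0.015327, 10.321,
  0, 0, 1, 2, -0.012528, 0,
  0, 0, 1, -2, -0.010980, 79.661,
  4, 0, -1, 0, 0.010675, -34.782,
  0, 0, 3, 0, 0.010034, -23.210,
  4, 0, -2, 0, 0.008548, -21.636,
  2, 1, -1, 0, -0.007888, 24.208,
  2, 1, 0, 0, -0.006766, 30.824,
  1, 0, -1, 0, -0.005163, -8.379,
  1, 1, 0, 0, 0.004987, -16.675,
  2, -1, 1, 0, 0.004036, -12.831,
  2, 0, 2, 0, 0.003994, -10.445,
  4, 0, 0, 0, 0.003861, -11.650,
  2, 0, -3, 0, 0.003665, 14.403,
  0, 1, -2, 0, -0.002689, -7.003,
  2, 0, -1, 2, -0.002602, 0,
  2, -1, -2, 0, 0.002390, 10.056,
  1, 0, 1, 0, -0.002348, 6.322,
  2, -2, 0, 0, 0.002236, -9.884,
  0, 1, 2, 0, -0.002120, 5.751,
  0, 2, 0, 0, -0.002069, 0,
  2, -2, -1, 0, 0.002048, -4.950,
  2, 0, 1, -2, -0.001773, 4.130,
  2, 0, 0, 2, -0.001595, 0,
  4, -1, -1, 0, 0.001215, -3.958,
  0, 0, 2, 2, -0.001110, 0,
  3, 0, -1, 0, -0.000892, 3.258,
  2, 1, 1, 0, -0.000810, 2.616,
  4, -1, -2, 0, 0.000759, -1.897,
  0, 2, -1, 0, -0.000713, -2.117,
  2, 2, -1, 0, -0.000700, 2.354
), ncol = 6, byrow = TRUE)

# periodic terms for latitude: D, M, Mp, F, coeff (deg)
.moon_b_terms <- matrix(c(
  0, 0, 0, 1, 5.128122,
  0, 0, 1, 1, 0.280602,
  0, 0, 1, -1, 0.277693,
  2, 0, 0, -1, 0.173237,
  2, 0, -1, 1, 0.055413,
  2, 0, -1, -1, 0.046271,
  2, 0, 0, 1, 0.032573,
  0, 0, 2, 1, 0.017198,
  2, 0, 1, -1, 0.009266,
  0, 0, 2, -1, 0.008822,
  2, -1, 0, -1, 0.008216,
  2, 0, -2, -1, 0.004324,
  2, 0, 1, 1, 0.004200,
  2, 1, 0, -1, -0.003359,
  2, -1, -1, 1, 0.002463,
  2, -1, 0, 1, 0.002211,
  2, -1, -1, -1, 0.002065,
  0, 1, -1, -1, -0.001870,
  4, 0, -1, -1, 0.001828,
  0, 1, 0, 1, -0.001794,
  0, 0, 0, 3, -0.001749,
  0, 1, -1, 1, -0.001565,
  1, 0, 0, 1, -0.001491,
  0, 1, 1, 1, -0.001475,
  0, 1, 1, -1, -0.001410,
  0, 1, 0, -1, -0.001344,
  1, 0, 0, -1, -0.001335,
  0, 0, 3, 1, 0.001107,
  4, 0, 0, -1, 0.001021,
  4, 0, -1, 1, 0.000833
), ncol = 5, byrow = TRUE)

# geocentric ecliptic position; jd_tt a Julian day (terrestrial time)
.moon_geocentric <- function(jd_tt) {
  T <- (jd_tt - 2451545.0) / 36525
  f <- .moon_fundamental(T)
  args <- deg2rad(
    .moon_lr_terms[, 1] * f$D + .moon_lr_terms[, 2] * f$M +
      .moon_lr_terms[, 3] * f$Mp + .moon_lr_terms[, 4] * f$F)
  efac <- f$E^abs(.moon_lr_terms[, 2])
  sum_l <- sum(.moon_lr_terms[, 5] * efac * sin(args))
  sum_r <- sum(.moon_lr_terms[, 6] * efac * cos(args))
  argsb <- deg2rad(
    .moon_b_terms[, 1] * f$D + .moon_b_terms[, 2] * f$M +
      .moon_b_terms[, 3] * f$Mp + .moon_b_terms[, 4] * f$F)
  efacb <- f$E^abs(.moon_b_terms[, 2])
  sum_b <- sum(.moon_b_terms[, 5] * efacb * sin(argsb))
  # planetary perturbation and flattening additives
  sum_l <- sum_l + 0.003958 * sin(deg2rad(f$A1)) +
    0.001962 * sin(deg2rad(f$Lp - f$F)) + 0.000318 * sin(deg2rad(f$A2))
  sum_b <- sum_b - 0.002235 * sin(deg2rad(f$Lp)) +
    0.000382 * sin(deg2rad(f$A3)) +
    0.000175 * sin(deg2rad(f$A1 - f$F)) +
    0.000175 * sin(deg2rad(f$A1 + f$F)) +
    0.000127 * sin(deg2rad(f$Lp - f$Mp)) -
    0.000115 * sin(deg2rad(f$Lp + f$Mp))
  list(lambda_deg = wrap360(f$Lp + sum_l),
       beta_deg = sum_b,
       distance_km = 385000.56 + sum_r)
}

# independent low-precision series (Astronomical Almanac style), used as an
# in-package cross-check route in the test suite; ~0.3 deg accuracy
.moon_geocentric_lowprecision <- function(jd_tt) {
  T <- (jd_tt - 2451545.0) / 36525
  s <- function(a, b) sin(deg2rad(a + b * T))
  c_ <- function(a, b) cos(deg2rad(a + b * T))
  lambda <- 218.32 + 481267.881 * T +
    6.29 * s(135.0, 477198.87) - 1.27 * s(259.3, -413335.36) +
    0.66 * s(235.7, 890534.22) + 0.21 * s(269.9, 954397.74) -
    0.19 * s(357.5, 35999.05) - 0.11 * s(186.5, 966404.03)
  beta <- 5.13 * s(93.3, 483202.02) + 0.28 * s(228.2, 960400.89) -
    0.28 * s(318.3, 6003.15) - 0.17 * s(217.6, -407332.21)
  par <- 0.9508 + 0.0518 * c_(135.0, 477198.87) +
    0.0095 * c_(259.3, -413335.36) + 0.0078 * c_(235.7, 890534.22) +
    0.0028 * c_(269.9, 954397.74)
  list(lambda_deg = wrap360(lambda), beta_deg = beta,
       distance_km = 6378.14 / sin(deg2rad(par)))
}

#' Julian day from a POSIXct instant
#' @param t POSIXct (interpreted on the UTC scale)
#' @return Julian day number (numeric)
#' @export
julian_day <- function(t) {
  as.numeric(t) / 86400 + 2440587.5
}

# Greenwich mean sidereal time, degrees
.gmst_deg <- function(jd) {
  T <- (jd - 2451545.0) / 36525
  wrap360(280.46061837 + 360.98564736629 * (jd - 2451545.0) +
            0.000387933 * T^2 - T^3 / 38710000)
}

#' Topocentric moon position
#'
#' Azimuth, altitude and apparent angular diameter of the moon for an observer
#' at the given site and instant.  Accuracy is a few arcminutes, sufficient for
#' rotating image-plane directions into compass bearings.  The 69 s offset
#' between terrestrial and universal time is applied as a fixed constant;
#' refraction is not applied.
#'
#' @param t POSIXct instant (UTC) or numeric Julian day (UT)
#' @param latitude_deg site latitude, degrees north
#' @param longitude_deg site longitude, degrees east
#' @return list with `azimuth_deg` (compass, clockwise from north),
#'   `altitude_deg`, `angular_diameter_deg` (topocentric),
#'   `distance_km` (geocentric) and `above_horizon` (logical)
#' @export
moon_topocentric <- function(t, latitude_deg, longitude_deg) {
  jd_ut <- if (inherits(t, "POSIXt")) julian_day(t) else as.numeric(t)
  jd_tt <- jd_ut + 69 / 86400
  geo <- .moon_geocentric(jd_tt)
  T <- (jd_tt - 2451545.0) / 36525
  eps <- deg2rad(23.4392911 - 0.0130042 * T)
  lam <- deg2rad(geo$lambda_deg); bet <- deg2rad(geo$beta_deg)
  ra <- atan2(sin(lam) * cos(eps) - tan(bet) * sin(eps), cos(lam))
  dec <- asin(sin(bet) * cos(eps) + cos(bet) * sin(eps) * sin(lam))
  lst <- deg2rad(.gmst_deg(jd_ut) + longitude_deg)
  H <- lst - ra
  phi <- deg2rad(latitude_deg)
  alt <- asin(sin(phi) * sin(dec) + cos(phi) * cos(dec) * cos(H))
  az_south <- atan2(sin(H), cos(H) * sin(phi) - tan(dec) * cos(phi))
  az <- wrap360(rad2deg(az_south) + 180)
  # parallax: depress altitude by the horizontal parallax times cos(alt)
  hp <- asin(6378.14 / geo$distance_km)
  alt_topo <- alt - hp * cos(alt)
  # topocentric enlargement of the apparent diameter
  diam <- 2 * asin(1737.4 / geo$distance_km) *
    (1 + sin(pmax(alt_topo, 0)) * 6378.14 / geo$distance_km)
  list(azimuth_deg = az,
       altitude_deg = rad2deg(alt_topo),
       angular_diameter_deg = rad2deg(diam),
       distance_km = geo$distance_km,
       above_horizon = rad2deg(alt_topo) > 0)
}

#' Session geometry from site and time
#'
#' Convenience wrapper building a [session_geometry()] from the lunar ephemeris.
#' Refuses a below-horizon moon, which cannot be observed.
#'
#' @inheritParams moon_topocentric
#' @param camera_roll_deg,flip_x,flip_y camera orientation, see
#'   [session_geometry()]
#' @return a [session_geometry()]
#' @export
session_geometry_at <- function(t, latitude_deg, longitude_deg,
                                camera_roll_deg = 0,
                                flip_x = FALSE, flip_y = FALSE) {
  m <- moon_topocentric(t, latitude_deg, longitude_deg)
  if (!m$above_horizon)
    stop(sprintf("moon is below the horizon (altitude %.2f deg) at this site and time",
                 m$altitude_deg), call. = FALSE)
  session_geometry(moon_azimuth_deg = m$azimuth_deg,
                   moon_altitude_deg = m$altitude_deg,
                   moon_angular_diameter_deg = m$angular_diameter_deg,
                   camera_roll_deg = camera_roll_deg,
                   flip_x = flip_x, flip_y = flip_y,
                   latitude_deg = latitude_deg, longitude_deg = longitude_deg)
}
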