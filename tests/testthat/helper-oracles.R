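# Shared fixtures and independent oracles used across the suite.

# compact analysis scene used by most simulator tests
test_scene <- function(seed = 1L, fps_nominal = 15, ...) {
  scene_config(frame_width_px = 256, frame_height_px = 192,
               field_of_view_deg = 1.0, fps_nominal = fps_nominal,
               rng_seed = seed, ...)
}

# tracker matched to the test scene's native resolution
test_tracker <- function(scene, sample_interval_s = 5, ...) {
  tracker_config(work_width_px = scene$frame_width_px,
                 work_height_px = scene$frame_height_px,
                 min_moon_area_px = 0.25 * pi * moon_radius_px(scene)^2,
                 sample_interval_s = sample_interval_s, ...)
}

# deterministic hand-built schedule of n transits spread over [t0, t1]
make_schedule <- function(n, t0, t1, seed, speed = c(0.3, 1.0),
                          len = c(3, 15), dark = c(10, 80),
                          off = 0.95, orient_offset = 0) {
  set.seed(seed)
  starts <- sort(runif(n, t0, t1))
  lapply(seq_len(n), function(k) {
    b <- runif(1, 0, 360)
    transit_spec(starts[k], b,
                 body_orientation_deg = b + orient_offset,
                 angular_speed_deg_per_s = runif(1, speed[1], speed[2]),
                 silhouette_length_px = runif(1, len[1], len[2]),
                 silhouette_darkness = runif(1, dark[1], dark[2]),
                 entry_chord_offset = runif(1, -off, off))
  })
}

# ---- independent 3-D ray-projection oracle ---------------------------------
# Image path angle of a level flyer, computed by placing the bird at a finite
# point on the line of sight, stepping it along its ground velocity, and
# perspective-projecting both positions through a pinhole camera aimed at the
# moon.  Shares only the compass/axis conventions with the package.
oracle_image_angle <- function(bearing_deg, az_deg, alt_deg, roll_deg = 0,
                               dist_m = 1000, step_m = 0.05) {
  d2r <- pi / 180
  A <- az_deg * d2r; th <- alt_deg * d2r; b <- bearing_deg * d2r
  m <- c(sin(A) * cos(th), cos(A) * cos(th), sin(th))   # ENU boresight
  hraw <- c(m[2], -m[1], 0)                             # m x z_hat
  h <- hraw / sqrt(sum(hraw^2))
  v <- c(h[2] * m[3] - h[3] * m[2],
         h[3] * m[1] - h[1] * m[3],
         h[1] * m[2] - h[2] * m[1])                     # h x m (image up)
  P1 <- dist_m * m
  P2 <- P1 + step_m * c(sin(b), cos(b), 0)
  proj <- function(P) {
    q <- P / sqrt(sum(P^2))
    c(sum(q * h), sum(q * v)) / sum(q * m)
  }
  dp <- proj(P2) - proj(P1)
  ang <- atan2(dp[2], dp[1]) / d2r
  (ang - roll_deg) %% 360   # camera roll rotates the image axes
}

# ---- independent cone-intersection flux oracle -----------------------------
# Monte-Carlo rain of straight horizontal tracks at altitude H: each bird gets
# a bearing from the direction sampler and an impact parameter uniform across
# a wide corridor centred on the viewing cone; it is counted when some point
# of its path lies within delta/2 of the moon direction as seen from the
# observer (numerical scan along the path).  Returns the expected transits
# per simulated bird-corridor, from which an expected count per flux follows.
oracle_cone_crossings <- function(n_rain, bearing_sampler, az_deg, alt_deg,
                                  delta_deg, H_m, corridor_m) {
  d2r <- pi / 180
  m <- c(sin(az_deg * d2r) * cos(alt_deg * d2r),
         cos(az_deg * d2r) * cos(alt_deg * d2r), sin(alt_deg * d2r))
  half_ang <- delta_deg / 2 * d2r
  center <- H_m / m[3] * m        # cone centre at altitude H
  bearings <- bearing_sampler(n_rain)
  hit <- logical(n_rain)
  svals <- seq(-3000, 3000, by = 4)  # path scan, metres
  for (k in seq_len(n_rain)) {
    b <- bearings[k] * d2r
    u <- c(sin(b), cos(b), 0)
    nperp <- c(-u[2], u[1], 0)
    d0 <- runif(1, -corridor_m / 2, corridor_m / 2)
    p0 <- center + d0 * nperp
    px <- p0[1] + svals * u[1]; py <- p0[2] + svals * u[2]; pz <- p0[3]
    nrm <- sqrt(px^2 + py^2 + pz^2)
    cosang <- (px * m[1] + py * m[2] + pz * m[3]) / nrm
    hit[k] <- any(cosang >= cos(half_ang))
  }
  mean(hit)
}

# brute-force per-frame capture clock with jittered periods (timing oracle)
oracle_jittered_clock <- function(n_frames, fps, jitter, seed) {
  set.seed(seed)
  period <- 1 / fps
  dt <- period * (1 + runif(n_frames - 1, -jitter, jitter))
  cumsum(c(0, dt))
}

# independent rasteriser: pixel centres inside a 3:1 ellipse drawn at
# (cx, cy) with the major axis at angle_deg (y-up), on the same half-integer
# pixel-centre lattice the renderer uses (render-mask oracle)
oracle_ellipse_pixels <- function(cx, cy, length_px, angle_deg = 0,
                                  aspect = 3) {
  a <- max(length_px / 2, 0.5); b <- max(a / aspect, 0.35)
  ext <- ceiling(a) + 2
  xs <- seq(floor(cx - ext) + 0.5, ceiling(cx + ext) - 0.5, by = 1)
  ys <- seq(floor(cy - ext) + 0.5, ceiling(cy + ext) - 0.5, by = 1)
  al <- angle_deg * pi / 180
  grid <- expand.grid(x = xs, y = ys)
  dx <- grid$x - cx; dy <- grid$y - cy
  u <- (dx * cos(al) + dy * -sin(al)) / a     # y-down pixel frame
  v <- (dx * sin(al) + dy * cos(al)) / b
  sum(u^2 + v^2 < 1)
}
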