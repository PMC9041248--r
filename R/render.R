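# Rasterisation of synthetic frames: an anti-aliased bright lunar disk on a
# dark sky, optional static maria blotches, and dark elliptical silhouettes
# drawn only where they overlap the disk.
#
# Frames are numeric matrices with `frame_height_px` rows and `frame_width_px`
# columns, values on the 8-bit scale [0, 255]; row index increases downward.
# Continuous image coordinates put pixel (col, row)'s centre at
# (col - 0.5, row - 0.5), x rightward, y downward.

# run expr with a private RNG stream, restoring the caller's stream
.with_seed <- function(seed, expr) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
    get(".Random.seed", envir = genv) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = genv)
    else assign(".Random.seed", old, envir = genv)
  })
  expr
}

# static maria layout (moon-fixed offsets), deterministic in the scene seed
.scene_maria <- function(scene) {
  if (scene$n_maria == 0L)
    return(data.frame(dx = numeric(0), dy = numeric(0), r = numeric(0)))
  R <- moon_radius_px(scene)
  .with_seed(scene$rng_seed + 77L, {
    rho <- sqrt(stats::runif(scene$n_maria)) * 0.7 * R
    ang <- stats::runif(scene$n_maria, 0, 2 * pi)
    data.frame(dx = rho * cos(ang), dy = rho * sin(ang),
               r = stats::runif(scene$n_maria, 0.05, 0.15) * R)
  })
}

# anti-aliased disk coverage on a pixel patch; returns list(rows, cols, cov)
# or NULL when the disk misses the frame entirely
.disk_patch <- function(cx, cy, R, width, height, pad = 1.5) {
  c0 <- max(1L, floor(cx - R - pad)); c1 <- min(width, ceiling(cx + R + pad))
  r0 <- max(1L, floor(cy - R - pad)); r1 <- min(height, ceiling(cy + R + pad))
  if (c0 > c1 || r0 > r1) return(NULL)
  cols <- c0:c1; rows <- r0:r1
  dx <- (cols - 0.5) - cx; dy <- (rows - 0.5) - cy
  dist <- sqrt(outer(dy^2, dx^2, `+`))
  cov <- clamp(R + 0.5 - dist, 0, 1)
  if (!any(cov > 0)) return(NULL)
  list(rows = rows, cols = cols, cov = cov)
}

# anti-aliased coverage of a filled 3:1 ellipse; axis_angle_deg in the y-up
# math convention
.ellipse_patch <- function(cx, cy, length_px, axis_angle_deg,
                           width, height, aspect = 3) {
  a <- max(length_px / 2, 0.5)
  b <- max(a / aspect, 0.35)
  ext <- a + 1.5
  c0 <- max(1L, floor(cx - ext)); c1 <- min(width, ceiling(cx + ext))
  r0 <- max(1L, floor(cy - ext)); r1 <- min(height, ceiling(cy + ext))
  if (c0 > c1 || r0 > r1) return(NULL)
  cols <- c0:c1; rows <- r0:r1
  al <- deg2rad(axis_angle_deg)
  e1 <- c(cos(al), -sin(al))   # major axis in y-down pixel coords
  e2 <- c(sin(al), cos(al))
  dx <- (cols - 0.5) - cx; dy <- (rows - 0.5) - cy
  U <- (outer(rep(1, length(rows)), dx) * e1[1] + outer(dy, rep(1, length(cols))) * e1[2]) / a
  V <- (outer(rep(1, length(rows)), dx) * e2[1] + outer(dy, rep(1, length(cols))) * e2[2]) / b
  rho <- sqrt(U^2 + V^2)
  cov <- clamp(0.5 + (1 - rho) * b, 0, 1)
  if (!any(cov > 0)) return(NULL)
  list(rows = rows, cols = cols, cov = cov)
}

#' Render one synthetic frame
#'
#' Draws the sky, the anti-aliased moon disk (attenuated by fog), any static
#' maria blotches, and each active silhouette as a dark 3:1 ellipse clipped to
#' the disk.  A moon centre off the frame yields an all-sky frame, which is
#' valid input for loss-of-moon tests.
#'
#' @param scene a [scene_config()]
#' @param moon_center_px numeric `c(x, y)` continuous image coordinates of the
#'   disk centre (y downward)
#' @param active_transits list of [transit_spec()] currently in flight
#' @param t session time in seconds (>= 0)
#' @return numeric matrix (height x width) on the 8-bit scale, with
#'   attributes `time_s` and `moon_center_px`
#' @export
render_frame <- function(scene, moon_center_px, active_transits = list(), t = 0) {
  if (t < 0) stop("t must be >= 0", call. = FALSE)
  W <- scene$frame_width_px; H <- scene$frame_height_px
  R <- moon_radius_px(scene)
  fog <- if (is.function(scene$fog_attenuation)) scene$fog_attenuation(t)
         else scene$fog_attenuation
  fog <- clamp(fog, 0, 1)
  frame <- matrix(scene$sky_brightness, nrow = H, ncol = W)
  cx <- moon_center_px[1]; cy <- moon_center_px[2]
  disk <- .disk_patch(cx, cy, R, W, H)
  if (!is.null(disk)) {
    bright <- scene$sky_brightness +
      fog * (scene$moon_brightness - scene$sky_brightness)
    sub <- frame[disk$rows, disk$cols, drop = FALSE]
    sub <- sub * (1 - disk$cov) + bright * disk$cov
    maria <- .scene_maria(scene)
    if (nrow(maria) > 0) {
      for (k in seq_len(nrow(maria))) {
        mp <- .disk_patch(cx + maria$dx[k], cy + maria$dy[k], maria$r[k], W, H)
        if (is.null(mp)) next
        ri <- match(mp$rows, disk$rows); ci <- match(mp$cols, disk$cols)
        keep_r <- !is.na(ri); keep_c <- !is.na(ci)
        if (!any(keep_r) || !any(keep_c)) next
        drop_cov <- mp$cov[keep_r, keep_c, drop = FALSE] *
          disk$cov[ri[keep_r], ci[keep_c], drop = FALSE]
        sub[ri[keep_r], ci[keep_c]] <- sub[ri[keep_r], ci[keep_c]] -
          fog * scene$maria_darkness * drop_cov
      }
    }
    for (spec in active_transits) {
      kin <- .transit_kinematics(spec, scene)
      pos <- .transit_position(spec, kin, t)
      ep <- .ellipse_patch(cx + pos[1], cy + pos[2],
                           spec$silhouette_length_px, kin$axis_angle_deg, W, H)
      if (is.null(ep)) next
      ri <- match(ep$rows, disk$rows); ci <- match(ep$cols, disk$cols)
      keep_r <- !is.na(ri); keep_c <- !is.na(ci)
      if (!any(keep_r) || !any(keep_c)) next
      ce <- ep$cov[keep_r, keep_c, drop = FALSE] *
        disk$cov[ri[keep_r], ci[keep_c], drop = FALSE]
      sub[ri[keep_r], ci[keep_c]] <- sub[ri[keep_r], ci[keep_c]] * (1 - ce) +
        spec$silhouette_darkness * ce
    }
    frame[disk$rows, disk$cols] <- sub
  }
  frame <- clamp(frame, 0, 255)
  attr(frame, "time_s") <- t
  attr(frame, "moon_center_px") <- c(cx, cy)
  frame
}
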