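#' @keywords internal
"_PACKAGE"

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Wrap an angle to [0, 360)
#' @param x angle in degrees (vectorised)
#' @return angle in [0, 360)
#' @export
wrap360 <- function(x) x %% 360

#' Wrap a signed angular difference to (-180, 180]
#' @param x angle in degrees (vectorised)
#' @return wrapped angle
#' @export
wrap180 <- function(x) {
  y <- (x + 180) %% 360 - 180
  ifelse(y == -180, 180, y)
}

# statute mile, km per mile
KM_PER_MILE <- 1.609344

stopifnot_scalar <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  invisible(x)
}
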