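#' Fold angles into the axial range [0, 180)
#'
#' Orientation (line) data are defined modulo 180 degrees: a cell whose major
#' axis points at 10 degrees is indistinguishable from one pointing at 190.
#'
#' @param deg numeric vector of angles in degrees (any sign).
#' @return angles in `[0, 180)`.
#' @export
fold_axial <- function(deg) {
  deg %% 180
}

#' Axial distance between two orientations
#'
#' Smallest angle between two undirected lines, in `[0, 90]` degrees.
#'
#' @param a,b numeric vectors of angles in degrees.
#' @return element-wise axial distances.
#' @export
axial_distance <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

deg2rad <- function(deg) deg * pi / 180
rad2deg <- function(rad) rad * 180 / pi

## Direction of vector (dx, dy_screen) in math convention: screen y grows
## downward, so the row component is sign-flipped before atan2.
vector_angle_deg <- function(dx, dy_screen) {
  rad2deg(atan2(-dy_screen, dx)) %% 360
}
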