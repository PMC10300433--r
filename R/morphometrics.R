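#' Tip width on a maximum projection
#'
#' Maximal chord of the projected foreground measured perpendicular to the
#' branch axis, emulating the line-tool measurement on a maximum-intensity
#' projection of the masked epithelium.
#'
#' @param mask an [epithelial_mask()] or a 2D logical matrix (already
#'   projected).
#' @param axis in-plane unit vector of the branch axis (2 components).
#' @param pixel_size pixel edge length of a plain-matrix input, µm (taken from
#'   the mask when an `epithelial_mask` is given).
#' @param region optional restriction: numeric length-2 range along the axis
#'   (µm, measured like the pixel coordinates) defining the tip region.
#' @param projection_axis axis collapsed by the maximum projection for 3D
#'   input (default `"z"`).
#' @return width, µm.
#' @export
measure_tip_width <- function(mask, axis = c(1, 0), pixel_size = 1,
                              region = NULL, projection_axis = "z") {
  if (inherits(mask, "epithelial_mask")) {
    pixel_size <- mask$voxel_size
    proj <- max_projection(mask, projection_axis)
  } else proj <- mask
  if (!any(proj)) stop("empty projection")
  a <- axis / sqrt(sum(axis^2))
  idx <- which(proj, arr.ind = TRUE)
  px <- (idx[, 1] - 0.5) * pixel_size
  py <- (idx[, 2] - 0.5) * pixel_size
  s <- px * a[1] + py * a[2]        # along-axis coordinate
  t <- -px * a[2] + py * a[1]       # perpendicular coordinate
  if (!is.null(region)) {
    keep <- s >= region[1] & s <= region[2]
    if (!any(keep)) stop("tip region is empty")
    s <- s[keep]; t <- t[keep]
  }
  bins <- floor(s / pixel_size)
  widths <- tapply(t, bins, function(v) max(v) - min(v) + pixel_size)
  max(widths)
}

#' Maximum projection of a binary mask
#'
#' @param mask an [epithelial_mask()].
#' @param axis `"x"`, `"y"` or `"z"` (collapsed axis).
#' @return 2D logical matrix.
#' @export
max_projection <- function(mask, axis = "z") {
  m <- mask$mask
  switch(axis,
         z = apply(m, c(1, 2), any),
         y = apply(m, c(1, 3), any),
         x = apply(m, c(2, 3), any),
         stop("axis must be x, y or z"))
}

#' Cleft angle and depth from landmark triples
#'
#' Angle at the cleft between the vectors toward the two daughter tips, and
#' the perpendicular distance from the cleft point to the straight line
#' through the tips (the cleft depth). A cleft lying on the tip-to-tip chord
#' gives depth 0 and angle 180 degrees (boundary case, not an error).
#'
#' @param tip_a,tip_b,cleft 3D points, µm.
#' @return list: angle (degrees), depth (µm), plus the input points.
#' @export
cleft_metrics <- function(tip_a, tip_b, cleft) {
  tip_a <- as.numeric(tip_a); tip_b <- as.numeric(tip_b)
  cleft <- as.numeric(cleft)
  if (all(tip_a == tip_b) || all(tip_a == cleft) || all(tip_b == cleft))
    stop("the three landmarks must be distinct")
  u <- tip_a - cleft
  v <- tip_b - cleft
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  angle <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  ab <- tip_b - tip_a
  t <- sum((cleft - tip_a) * ab) / sum(ab^2)
  foot <- tip_a + t * ab
  depth <- sqrt(sum((cleft - foot)^2))
  list(angle = angle, depth = depth,
       daughter_tip_positions = rbind(tip_a, tip_b), cleft_position = cleft)
}

#' Elongation rate series
#'
#' Finite-difference elongation rate (delta length / delta time) between
#' adjacent frames.
#'
#' @param lengths branch length per frame, µm.
#' @param frame_interval minutes between frames; or supply `times_h` directly.
#' @param times_h optional explicit time axis, h (strictly increasing).
#' @return list: `lengths` (per frame), `rate` (per interval, µm/h),
#'   `mean_rate`.
#' @export
elongation_series <- function(lengths, frame_interval = 20, times_h = NULL) {
  n <- length(lengths)
  if (n < 2) stop("need at least 2 frames")
  if (is.null(times_h)) times_h <- (seq_len(n) - 1) * frame_interval / 60
  if (any(diff(times_h) <= 0)) stop("time axis must be strictly increasing")
  rate <- diff(lengths) / diff(times_h)
  list(lengths = lengths, times_h = times_h, rate = rate,
       mean_rate = mean(rate))
}

#' Geodesic branch length between two landmarks
#'
#' Within-mask geodesic distance from the tip landmark to the origin landmark
#' (e.g., the latest branch point), the standard branch-length measurement.
#'
#' @param mask an [epithelial_mask()].
#' @param tip_landmark,origin_landmark 3D points inside the mask, µm.
#' @param connectivity passed to [geodesic_distance_field()].
#' @return length, µm.
#' @export
branch_length <- function(mask, tip_landmark, origin_landmark,
                          connectivity = 26) {
  if (all(as.numeric(tip_landmark) == as.numeric(origin_landmark)))
    return(0)
  fld <- geodesic_distance_field(mask, tip_landmark,
                                 connectivity = connectivity)
  val <- sample_field(fld, matrix(as.numeric(origin_landmark), 1))
  if (!is.finite(val))
    stop("landmarks are not connected within the mask")
  as.numeric(val)
}

#' Sphericity from volume and surface area
#'
#' The isoperimetric ratio `pi^(1/3) * (6V)^(2/3) / A`: exactly 1 for a ball
#' and < 1 for any other shape.
#'
#' @param volume µm³ (> 0).
#' @param surface_area µm² (> 0).
#' @return dimensionless sphericity.
#' @export
sphericity <- function(volume, surface_area) {
  if (any(volume <= 0) || any(surface_area <= 0))
    stop("volume and surface_area must be > 0")
  pi^(1 / 3) * (6 * volume)^(2 / 3) / surface_area
}
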