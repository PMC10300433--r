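#' Multi-channel 3D voxel stack with physical metadata
#'
#' The basic image container: a named list of congruent 3D numeric arrays (one
#' per channel), stored in `(x, y, z)` index order, plus voxel sizes in
#' micrometers. Voxel `(i, j, k)` has its center at
#' `origin + (c(i, j, k) - 0.5) * voxel_size`; all positions handled by the
#' package are physical (µm).
#'
#' @param channels named list of 3D numeric arrays with identical dimensions.
#'   Conventional channel names are `"green"` (S/G2/M reporter) and `"red"`
#'   (G1/G0 reporter).
#' @param voxel_size numeric length-3, µm per voxel along (x, y, z).
#' @param origin physical coordinate (µm) of the grid corner, default c(0,0,0).
#' @param frame frame index for time-lapse data (NA for single stacks).
#' @param frame_interval minutes between frames (NA for single stacks).
#' @return an object of class `voxel_stack`.
#' @export
voxel_stack <- function(channels, voxel_size, origin = c(0, 0, 0),
                        frame = NA_integer_, frame_interval = NA_real_) {
  if (!is.list(channels) || length(channels) == 0L || is.null(names(channels)))
    stop("`channels` must be a non-empty named list of 3D arrays")
  dims <- dim(channels[[1]])
  if (length(dims) != 3L)
    stop("channel arrays must be 3D (x, y, z)")
  for (ch in channels)
    if (!identical(dim(ch), dims)) stop("all channels must share dimensions")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("`voxel_size` must be 3 positive values (x, y, z) in um")
  structure(list(channels = channels, voxel_size = voxel_size,
                 origin = as.numeric(origin), frame = frame,
                 frame_interval = frame_interval),
            class = "voxel_stack")
}

#' @export
print.voxel_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("voxel_stack: %d x %d x %d voxels, %d channel(s) [%s]\n",
              d[1], d[2], d[3], length(x$channels),
              paste(names(x$channels), collapse = ", ")))
  cat(sprintf("  voxel size (x,y,z): %s um; origin: %s um\n",
              paste(signif(x$voxel_size, 3), collapse = " x "),
              paste(signif(x$origin, 3), collapse = ", ")))
  invisible(x)
}

#' Binary epithelial mask on an isotropic grid
#'
#' @param mask 3D logical (or 0/1) array in (x, y, z) order.
#' @param voxel_size isotropic voxel edge length, µm.
#' @param origin physical coordinate (µm) of the grid corner.
#' @param frame frame index (NA for static data).
#' @return an object of class `epithelial_mask`; `n_components` is filled in
#'   lazily by [connected_components()] callers that need it.
#' @export
epithelial_mask <- function(mask, voxel_size, origin = c(0, 0, 0),
                            frame = NA_integer_) {
  if (length(dim(mask)) != 3L) stop("`mask` must be a 3D array")
  storage.mode(mask) <- "logical"
  if (!any(mask)) stop("mask has no foreground voxel")
  if (length(voxel_size) != 1L || voxel_size <= 0)
    stop("`voxel_size` must be a single positive value (isotropic, um)")
  structure(list(mask = mask, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin), frame = frame),
            class = "epithelial_mask")
}

#' @export
print.epithelial_mask <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("epithelial_mask: %d x %d x %d @ %.3g um, %d fg voxels\n",
              d[1], d[2], d[3], x$voxel_size, sum(x$mask)))
  invisible(x)
}

#' Per-voxel scalar field (distance map) over an isotropic grid
#'
#' @param values 3D numeric array (µm); `NA` marks voxels outside the mask the
#'   field was computed on, `Inf` marks unreachable foreground (geodesics).
#' @param voxel_size isotropic voxel size, µm.
#' @param origin grid corner, µm.
#' @param kind `"surface_distance"` or `"geodesic_distance"`.
#' @param source free-text provenance (landmark name, method).
#' @param frame frame index.
#' @return an object of class `scalar_field`.
#' @export
scalar_field <- function(values, voxel_size, origin = c(0, 0, 0),
                         kind = c("surface_distance", "geodesic_distance"),
                         source = "", frame = NA_integer_) {
  kind <- match.arg(kind)
  if (length(dim(values)) != 3L) stop("`values` must be a 3D array")
  if (any(values < 0, na.rm = TRUE)) stop("distance values must be >= 0")
  structure(list(values = values, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin), kind = kind, source = source,
                 frame = frame),
            class = "scalar_field")
}

#' @export
print.scalar_field <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("scalar_field (%s): %d x %d x %d @ %.3g um [%s]\n",
              x$kind, d[1], d[2], d[3], x$voxel_size, x$source))
  invisible(x)
}

#' Construct a tidy cell table
#'
#' One row per detected or ground-truth nucleus. Positions are physical µm.
#'
#' @param frame,id,x,y,z,class vectors of equal length; `class` is
#'   `"green"` (S/G2/M), `"red"` (G1/G0) or `"generic"`.
#' @param ... further per-cell columns (intensities, distances, labels).
#' @return a `data.frame` with at least columns frame, id, x, y, z, class.
#' @export
cell_table <- function(frame, id, x, y, z, class = "generic", ...) {
  df <- data.frame(frame = as.integer(frame), id = as.integer(id),
                   x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                   class = as.character(class), ...,
                   stringsAsFactors = FALSE)
  df
}

#' Landmark annotation table
#'
#' Named reference points per frame (leading edge, cleft, daughter tips, neck,
#' duct/branch-point centers, gland origin).
#'
#' @param frame,name,x,y,z equal-length vectors; positions in µm.
#' @return a `data.frame` with columns frame, name, x, y, z.
#' @export
landmark_set <- function(frame, name, x, y, z) {
  data.frame(frame = as.integer(frame), name = as.character(name),
             x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
             stringsAsFactors = FALSE)
}

# physical coordinates of all voxel centers along one axis
.axis_centers <- function(n, voxel, origin) origin + (seq_len(n) - 0.5) * voxel

# physical point -> 1-based voxel index triple (may fall outside the grid)
.point_to_voxel <- function(pts, voxel_size, origin) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  idx <- sweep(pts, 2, origin, "-")
  idx <- sweep(idx, 2, rep_len(voxel_size, 3), "/")
  floor(idx) + 1L
}

.voxel_center <- function(ijk, voxel_size, origin) {
  ijk <- matrix(as.numeric(ijk), ncol = 3)
  sweep(sweep(ijk - 0.5, 2, rep_len(voxel_size, 3), "*"), 2, origin, "+")
}

#' Label connected components of a binary mask
#'
#' Flood fill over 26-connected foreground voxels; used to report component
#' counts for masks and to validate constructed geometries.
#'
#' @param mask `epithelial_mask` or 3D logical array.
#' @return integer array of component labels (0 = background).
#' @export
connected_components <- function(mask) {
  m <- if (inherits(mask, "epithelial_mask")) mask$mask else mask
  d <- dim(m)
  lab <- array(0L, d)
  nxt <- 0L
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  fg <- which(m)
  for (start in fg) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      k <- (v - 1L) %/% (d[1] * d[2])
      rem <- (v - 1L) - k * d[1] * d[2]
      j <- rem %/% d[1]
      i <- rem - j * d[1]
      nb <- cbind(i + 1L + offs[, 1], j + 1L + offs[, 2], k + 1L + offs[, 3])
      ok <- nb[, 1] >= 1 & nb[, 2] >= 1 & nb[, 3] >= 1 &
        nb[, 1] <= d[1] & nb[, 2] <= d[2] & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + d[1] * (nb[, 2] - 1L) + d[1] * d[2] * (nb[, 3] - 1L)
      lin <- lin[m[lin] & lab[lin] == 0L]
      if (length(lin)) {
        lab[lin] <- nxt
        queue <- c(queue, lin)
      }
    }
  }
  lab
}
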