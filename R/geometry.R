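#' Resample a stack, mask or field to isotropic voxels
#'
#' Masks resample by nearest neighbour, intensity channels and fields by
#' trilinear interpolation; physical extents are preserved to within one voxel
#' per axis.
#'
#' @param x a [voxel_stack()], [epithelial_mask()] or [scalar_field()].
#' @param target_voxel isotropic target voxel size, µm.
#' @return object of the same class on the isotropic grid.
#' @export
resample_isotropic <- function(x, target_voxel) {
  UseMethod("resample_isotropic")
}

.new_grid <- function(dims, vs, target) {
  extent <- dims * vs
  nd <- pmax(1L, round(extent / target))
  list(dims = as.integer(nd), extent = extent)
}

#' @export
resample_isotropic.epithelial_mask <- function(x, target_voxel) {
  vs <- rep(x$voxel_size, 3)
  dims <- dim(x$mask)
  if (all(abs(vs - target_voxel) < 1e-12)) return(x)
  g <- .new_grid(dims, vs, target_voxel)
  src <- .nn_index(g$dims, target_voxel, dims, vs)
  m <- array(x$mask[src], g$dims)
  epithelial_mask(m, target_voxel, origin = x$origin, frame = x$frame)
}

#' @export
resample_isotropic.voxel_stack <- function(x, target_voxel) {
  dims <- dim(x$channels[[1]])
  vs <- x$voxel_size
  if (all(abs(vs - target_voxel) < 1e-12)) return(x)
  g <- .new_grid(dims, vs, target_voxel)
  ctr <- .grid_centers(g$dims, rep(target_voxel, 3), x$origin)
  chans <- lapply(x$channels, function(ch) {
    v <- cpp_trilinear(as.numeric(ch), as.integer(dims), vs, x$origin, ctr)
    array(v, g$dims)
  })
  voxel_stack(chans, rep(target_voxel, 3), origin = x$origin,
              frame = x$frame, frame_interval = x$frame_interval)
}

#' @export
resample_isotropic.scalar_field <- function(x, target_voxel) {
  dims <- dim(x$values)
  vs <- rep(x$voxel_size, 3)
  if (all(abs(vs - target_voxel) < 1e-12)) return(x)
  g <- .new_grid(dims, vs, target_voxel)
  ctr <- .grid_centers(g$dims, rep(target_voxel, 3), x$origin)
  v <- cpp_trilinear(as.numeric(x$values), as.integer(dims), vs, x$origin, ctr)
  scalar_field(array(v, g$dims), target_voxel, origin = x$origin,
               kind = x$kind, source = x$source, frame = x$frame)
}

# all voxel centers of a grid as an (n x 3) matrix
.grid_centers <- function(dims, vs, origin) {
  gx <- .axis_centers(dims[1], vs[1], origin[1])
  gy <- .axis_centers(dims[2], vs[2], origin[2])
  gz <- .axis_centers(dims[3], vs[3], origin[3])
  cbind(rep(gx, times = dims[2] * dims[3]),
        rep(rep(gy, each = dims[1]), times = dims[3]),
        rep(gz, each = dims[1] * dims[2]))
}

# nearest-neighbour source indices for resampling (shared origin)
.nn_index <- function(new_dims, new_vs, old_dims, old_vs) {
  ctr <- .grid_centers(new_dims, rep(new_vs, 3), c(0, 0, 0))
  idx <- .point_to_voxel(ctr, old_vs, c(0, 0, 0))
  for (a in 1:3) idx[, a] <- pmin(pmax(idx[, a], 1L), old_dims[a])
  idx[, 1] + old_dims[1] * (idx[, 2] - 1L) +
    old_dims[1] * old_dims[2] * (idx[, 3] - 1L)
}

#' Build an epithelial mask from nuclear positions
#'
#' Union of balls of `radius` around the points, followed by morphological
#' closing with a ball of `closing_radius` (default 7 µm, about one nuclear
#' diameter, so the mask has no spurious holes between neighbouring nuclei).
#' Every input point is guaranteed foreground.
#'
#' @param points (n x 3) matrix or data.frame of positions, µm.
#' @param radius ball radius around each point, µm.
#' @param voxel_size isotropic voxel size of the mask grid, µm.
#' @param closing_radius structuring-ball radius for closing, µm (0 = none).
#' @param frame frame index carried on the mask.
#' @return an [epithelial_mask()].
#' @export
mask_from_points <- function(points, radius, voxel_size, closing_radius = 7,
                             frame = NA_integer_) {
  if (is.data.frame(points)) points <- as.matrix(points[, c("x", "y", "z")])
  points <- matrix(as.numeric(points), ncol = 3)
  if (nrow(points) == 0L) stop("need at least one point")
  if (radius <= 0 || voxel_size <= 0) stop("radius and voxel_size must be > 0")
  pad <- radius + closing_radius + 2 * voxel_size
  lo <- apply(points, 2, min) - pad
  hi <- apply(points, 2, max) + pad
  dims <- pmax(1L, ceiling((hi - lo) / voxel_size))
  origin <- lo
  m <- array(FALSE, dims)
  vs3 <- rep(voxel_size, 3)
  for (q in seq_len(nrow(points))) {
    sel <- .ball_voxels(dims, vs3, origin, points[q, ], radius)
    m[sel] <- TRUE
  }
  # make sure point voxels themselves are foreground even at tiny radius
  pv <- .point_to_voxel(points, voxel_size, origin)
  m[pv[, 1] + dims[1] * (pv[, 2] - 1L) + dims[1] * dims[2] * (pv[, 3] - 1L)] <- TRUE
  if (closing_radius > 0) {
    dil <- cpp_edt(as.logical(m), as.integer(dims), vs3) <= closing_radius
    dim(dil) <- dims
    ero <- cpp_edt(as.logical(!dil), as.integer(dims), vs3) > closing_radius
    dim(ero) <- dims
    m <- ero | m  # closing is extensive; keep original foreground explicitly
  }
  epithelial_mask(m, voxel_size, origin = origin, frame = frame)
}

#' Surface (depth) distance field of a mask
#'
#' For each foreground voxel, the distance to the nearest background voxel
#' center: the exact Euclidean transform by default, or the <3,4,5> chamfer
#' approximation (maximum relative error about 8%) to match classical
#' morphology toolboxes. Background voxels carry 0.
#'
#' @param mask an [epithelial_mask()].
#' @param method `"exact"` or `"chamfer"`.
#' @return a [scalar_field()] of kind `surface_distance`.
#' @export
surface_distance_field <- function(mask, method = c("exact", "chamfer")) {
  method <- match.arg(method)
  stopifnot(inherits(mask, "epithelial_mask"))
  m <- mask$mask
  if (all(m)) stop("mask has no background: no surface exists")
  dims <- dim(m)
  vs3 <- rep(mask$voxel_size, 3)
  vals <- if (method == "exact") {
    d <- cpp_edt(as.logical(!m), as.integer(dims), vs3)
    d[!m] <- 0
    d
  } else {
    cpp_chamfer(as.logical(m), as.integer(dims), mask$voxel_size)
  }
  dim(vals) <- dims
  scalar_field(vals, mask$voxel_size, origin = mask$origin,
               kind = "surface_distance",
               source = paste0("surface/", method), frame = mask$frame)
}

#' Geodesic distance field inside a mask
#'
#' Shortest within-mask path length from a seed point to every foreground
#' voxel (Dijkstra on the 26- or 6-connected voxel graph; edge weights are
#' Euclidean center-to-center distances). A seed falling in background is
#' snapped to the nearest foreground voxel within `snap_radius`.
#'
#' @param mask an [epithelial_mask()].
#' @param seed physical seed point (µm).
#' @param connectivity 26 (default) or 6.
#' @param snap_radius maximum snapping distance for background seeds, µm.
#' @return a [scalar_field()] of kind `geodesic_distance`; background is `NA`,
#'   unreachable foreground is `Inf`.
#' @export
geodesic_distance_field <- function(mask, seed, connectivity = 26,
                                    snap_radius = 5) {
  stopifnot(inherits(mask, "epithelial_mask"),
            connectivity %in% c(6, 26))
  dims <- dim(mask$mask)
  vs3 <- rep(mask$voxel_size, 3)
  sv <- .point_to_voxel(seed, mask$voxel_size, mask$origin)
  sv <- pmin(pmax(sv, 1L), matrix(dims, 1))
  lin <- sv[1] + dims[1] * (sv[2] - 1L) + dims[1] * dims[2] * (sv[3] - 1L)
  if (!mask$mask[lin]) {
    # snap to the nearest foreground voxel
    fg <- which(mask$mask)
    ctr <- .voxel_center(arrayInd(fg, dims), mask$voxel_size, mask$origin)
    d <- sqrt(colSums((t(ctr) - as.numeric(seed))^2))
    if (min(d) > snap_radius)
      stop("seed lies in background farther than snap_radius from the mask")
    lin <- fg[which.min(d)]
  }
  vals <- cpp_geodesic(as.logical(mask$mask), as.integer(dims), vs3,
                       as.integer(lin - 1L), as.integer(connectivity))
  dim(vals) <- dims
  scalar_field(vals, mask$voxel_size, origin = mask$origin,
               kind = "geodesic_distance",
               source = sprintf("seed(%.1f,%.1f,%.1f)", seed[1], seed[2],
                                seed[3]),
               frame = mask$frame)
}

#' Sample a scalar field at physical positions
#'
#' Trilinear interpolation at the cell positions; corners that are `NA`
#' (background) or infinite are dropped with weight renormalization, so cells
#' just inside the mask border still receive a value. Positions outside the
#' grid or fully in background return `NA`.
#'
#' @param field a [scalar_field()].
#' @param points (n x 3) matrix/data.frame of positions, µm.
#' @return numeric vector of sampled values (µm).
#' @export
sample_field <- function(field, points) {
  stopifnot(inherits(field, "scalar_field"))
  if (is.data.frame(points)) points <- as.matrix(points[, c("x", "y", "z")])
  points <- matrix(as.numeric(points), ncol = 3)
  v <- field$values
  v[!is.finite(v)] <- NA_real_
  cpp_trilinear(as.numeric(v), as.integer(dim(field$values)),
                rep(field$voxel_size, 3), field$origin, points)
}

#' Classify cells into basal vs inner compartments
#'
#' Basal if the interpolated surface distance at the cell position is at most
#' `threshold` (default 6 µm, the conventional outermost-layer depth); inner
#' otherwise; `unassigned` (with a warning) where the field has no value.
#'
#' @param cells cell table with x, y, z columns.
#' @param field surface-distance [scalar_field()].
#' @param threshold basal depth cutoff, µm.
#' @return `cells` with added `compartment` and `surface_distance` columns;
#'   attribute `threshold_used`.
#' @export
classify_compartment <- function(cells, field, threshold = 6) {
  stopifnot(field$kind == "surface_distance")
  d <- sample_field(field, cells)
  comp <- ifelse(is.na(d), "unassigned", ifelse(d <= threshold, "basal", "inner"))
  if (any(is.na(d)))
    warning(sum(is.na(d)), " cell(s) outside the mask: labeled unassigned")
  cells$surface_distance <- d
  cells$compartment <- comp
  attr(cells, "threshold_used") <- threshold
  cells
}

#' Assign tip / duct / branch-point domains (single frame)
#'
#' Pools cells by landmark-anchored distances: `tip` within `tip_extent`
#' (default 100 µm) of the leading-edge/tip landmark, `duct` and
#' `branch_point` within `center_radius` (50–100 µm by branch thickness) of
#' their centers. Precedence when regions overlap: tip > branch_point > duct.
#' In bifurcating tips (cleft and daughter-tip landmarks present), tip cells
#' are split into `daughter_tip` vs `cleft_region` by whichever landmark is
#' nearer (ties go to `daughter_tip`).
#'
#' @param cells single-frame cell table (x, y, z).
#' @param landmarks single-frame [landmark_set()]; recognized names:
#'   `leading_edge` (or `tip`), `duct_center`, `branch_point_center`,
#'   `daughter_tip_1`, `daughter_tip_2`, `cleft`.
#' @param fields optional named list of geodesic [scalar_field()]s keyed by
#'   landmark name; when absent, Euclidean distances to the landmarks are used.
#' @param tip_extent tip pooling distance, µm.
#' @param center_radius duct/branch-point pooling radius, µm (50–100).
#' @return `cells` with added `domain` column and the per-landmark distance
#'   columns `dist_<name>`.
#' @export
assign_domains <- function(cells, landmarks, fields = NULL,
                           tip_extent = 100, center_radius = 50) {
  if (center_radius < 50 || center_radius > 100)
    warning("center_radius outside the conventional 50-100 um range")
  lmn <- landmarks$name
  dist_to <- function(nm) {
    if (!nm %in% lmn) return(NULL)
    if (!is.null(fields) && nm %in% names(fields))
      return(sample_field(fields[[nm]], cells))
    p <- unlist(landmarks[match(nm, lmn), c("x", "y", "z")])
    sqrt((cells$x - p[1])^2 + (cells$y - p[2])^2 + (cells$z - p[3])^2)
  }
  tip_name <- if ("leading_edge" %in% lmn) "leading_edge"
    else if ("tip" %in% lmn) "tip" else NA
  d_tip <- if (!is.na(tip_name)) dist_to(tip_name) else NULL
  d_bp <- dist_to("branch_point_center")
  d_duct <- dist_to("duct_center")
  if (is.null(d_tip)) warning("no tip landmark: tip domain skipped")
  if (is.null(d_duct)) warning("no duct_center landmark: duct domain skipped")

  n <- nrow(cells)
  domain <- rep("unassigned", n)
  if (!is.null(d_duct)) {
    cells$dist_duct_center <- d_duct
    domain[!is.na(d_duct) & d_duct <= center_radius] <- "duct"
  }
  if (!is.null(d_bp)) {
    cells$dist_branch_point <- d_bp
    domain[!is.na(d_bp) & d_bp <= center_radius] <- "branch_point"
  }
  if (!is.null(d_tip)) {
    cells$dist_tip <- d_tip
    in_tip <- !is.na(d_tip) & d_tip <= tip_extent
    domain[in_tip] <- "tip"
    if (all(c("daughter_tip_1", "daughter_tip_2", "cleft") %in% lmn)) {
      d1 <- dist_to("daughter_tip_1")
      d2 <- dist_to("daughter_tip_2")
      dc <- dist_to("cleft")
      dd <- pmin(d1, d2)
      split <- ifelse(dc < dd, "cleft_region", "daughter_tip")  # tie -> daughter
      domain[in_tip] <- split[in_tip]
      cells$dist_cleft <- dc
      cells$dist_daughter <- dd
    }
  }
  cells$domain <- domain
  cells
}

#' Estimate the tip/duct boundary from the cycle-state profile
#'
#' In elongating branches there is no discernible neck; the tip is separated
#' from the trailing duct where the S/G2/M ("green") enrichment falls off.
#' Computes the green fraction in sliding windows of the distance to the
#' leading edge; the boundary is the largest distance at which the smoothed
#' fraction still reaches the midpoint between the front-window maximum and
#' the distal baseline (mean of the last quartile of windows). Flat profiles
#' fall back to `fallback` (100 µm, the conventional tip extent).
#'
#' @param cells cell table with a `class` column (green/red).
#' @param distances distance to the leading edge per cell, µm (e.g., sampled
#'   from a geodesic field); defaults to `cells$dist_to_edge`.
#' @param window,step sliding-window width and step, µm.
#' @param flat_epsilon minimal front-to-baseline drop for a detectable
#'   boundary.
#' @param min_cells minimal number of usable cells.
#' @param fallback boundary returned for flat profiles, µm.
#' @return boundary distance, µm; attributes carry the window profile.
#' @export
estimate_tip_boundary <- function(cells, distances = cells$dist_to_edge,
                                  window = 30, step = 10,
                                  flat_epsilon = 0.1, min_cells = 50,
                                  fallback = 100) {
  ok <- !is.na(distances) & cells$class %in% c("green", "red")
  d <- distances[ok]
  g <- cells$class[ok] == "green"
  if (length(d) < min_cells) stop("too few cells to estimate a boundary")
  centers <- seq(window / 2, max(d), by = step)
  if (length(centers) < 2) stop("cells span fewer than 2 windows")
  frac <- vapply(centers, function(cc) {
    inw <- abs(d - cc) <= window / 2
    if (sum(inw) == 0) NA_real_ else mean(g[inw])
  }, numeric(1))
  ok_w <- !is.na(frac)
  centers <- centers[ok_w]; frac <- frac[ok_w]
  nw <- length(frac)
  baseline <- mean(frac[seq.int(max(1, nw - floor(nw / 4) + 1), nw)])
  front_max <- max(frac)
  if (front_max - baseline < flat_epsilon) {
    out <- fallback
    attr(out, "flat") <- TRUE
  } else {
    midpoint <- (front_max + baseline) / 2
    out <- max(centers[frac >= midpoint])
    attr(out, "flat") <- FALSE
  }
  attr(out, "profile") <- data.frame(center = centers, green_fraction = frac)
  out
}
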