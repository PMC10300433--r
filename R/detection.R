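#' Otsu threshold of a numeric sample
#'
#' Histogram-based Otsu threshold (maximal between-class variance), used as the
#' automatic cutoff on the blob-response distribution in [detect_nuclei()].
#'
#' @param x numeric vector.
#' @param n_bins histogram resolution.
#' @return threshold value on the scale of `x`.
#' @export
otsu_threshold <- function(x, n_bins = 256) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) stop("no finite values")
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- as.numeric(tabulate(findInterval(x, br, rightmost.closed = TRUE),
                           n_bins))
  mids <- (br[-1] + br[-length(br)]) / 2
  w <- cumsum(h)
  m <- cumsum(h * mids)
  tot <- w[n_bins]
  mtot <- m[n_bins]
  w0 <- w[-n_bins]; w1 <- tot - w0
  ok <- w0 > 0 & w1 > 0
  between <- rep(-Inf, n_bins - 1)
  between[ok] <- (mtot * w0[ok] - tot * m[-n_bins][ok])^2 / (w0[ok] * w1[ok])
  mids[which.max(between)]
}

#' Detect nuclei as scale-matched blobs
#'
#' Laplacian-of-Gaussian blob detection at the scale of the expected nuclear
#' diameter, with anisotropy handled by per-axis sigmas in voxel units, local
#' 26-neighbourhood maxima, and greedy suppression at a minimum physical
#' separation of `diameter * separation_factor`. The conventional diameters
#' for Fucci-type nuclei are 6 µm for the red (G1/G0) and 7 µm for the green
#' (S/G2/M) channel ([detect_fucci()]).
#'
#' @param stack a [voxel_stack()].
#' @param channel channel name present in `stack`.
#' @param diameter expected nuclear diameter, µm; must be at least twice the
#'   smallest voxel dimension.
#' @param intensity_threshold `"auto"` (Otsu on the positive blob responses) or
#'   a numeric cutoff on the scale-normalized LoG response.
#' @param separation_factor minimum separation between accepted spots as a
#'   fraction of `diameter` (default 0.75: spots slightly smaller than nuclei
#'   so touching neighbours stay resolved).
#' @return a `data.frame` of spots: frame, id, channel, x, y, z (µm),
#'   diameter_used, response, peak_intensity, and `mean_<channel>` columns
#'   (mean raw intensity within `diameter / 2` per channel).
#' @export
detect_nuclei <- function(stack, channel, diameter,
                          intensity_threshold = "auto",
                          separation_factor = 0.75) {
  stopifnot(inherits(stack, "voxel_stack"))
  if (!channel %in% names(stack$channels))
    stop("channel '", channel, "' not present in stack")
  if (diameter < 2 * min(stack$voxel_size))
    stop("diameter must be at least twice the smallest voxel dimension")
  img <- stack$channels[[channel]]
  dims <- dim(img)
  vs <- stack$voxel_size
  sigma_um <- diameter / (2 * sqrt(3))  # LoG blob radius sqrt(3)*sigma
  sigma_vox <- sigma_um / vs
  sm <- cpp_gaussian_blur(as.numeric(img), as.integer(dims), sigma_vox)
  resp <- -sigma_um^2 * cpp_laplacian(sm, as.integer(dims), vs)

  if (all(resp <= 0)) return(.empty_spots(names(stack$channels)))
  cand <- cpp_local_maxima(resp, as.integer(dims), min_value = 0)
  if (length(cand) == 0L) return(.empty_spots(names(stack$channels)))

  thr <- if (identical(intensity_threshold, "auto"))
    otsu_threshold(resp[resp > 0]) else as.numeric(intensity_threshold)
  cand <- cand[resp[cand] > thr]
  if (length(cand) == 0L) return(.empty_spots(names(stack$channels)))

  ord <- cand[order(resp[cand], decreasing = TRUE)]
  ijk <- arrayInd(ord, dims)
  pos <- .voxel_center(ijk, vs, stack$origin)
  minsep <- diameter * separation_factor
  keep <- logical(length(ord))
  kept <- matrix(numeric(0), 0, 3)
  for (q in seq_along(ord)) {
    p <- pos[q, ]
    if (nrow(kept) == 0L ||
        min(sqrt(colSums((t(kept) - p)^2))) >= minsep) {
      keep[q] <- TRUE
      kept <- rbind(kept, p)
    }
  }
  ord <- ord[keep]
  pos <- pos[keep, , drop = FALSE]

  spots <- data.frame(frame = if (is.na(stack$frame)) 1L else stack$frame,
                      id = seq_along(ord), channel = channel,
                      x = pos[, 1], y = pos[, 2], z = pos[, 3],
                      diameter_used = diameter,
                      response = resp[ord],
                      peak_intensity = as.numeric(img[ord]),
                      stringsAsFactors = FALSE)
  for (ch in names(stack$channels)) {
    spots[[paste0("mean_", ch)]] <-
      .ball_means(stack$channels[[ch]], vs, stack$origin, pos, diameter / 2)
  }
  spots
}

.empty_spots <- function(chan_names) {
  df <- data.frame(frame = integer(), id = integer(), channel = character(),
                   x = numeric(), y = numeric(), z = numeric(),
                   diameter_used = numeric(), response = numeric(),
                   peak_intensity = numeric(), stringsAsFactors = FALSE)
  for (ch in chan_names) df[[paste0("mean_", ch)]] <- numeric()
  df
}

# mean intensity inside a physical ball around each position
.ball_means <- function(img, vs, origin, pos, radius) {
  dims <- dim(img)
  vapply(seq_len(nrow(pos)), function(q) {
    sel <- .ball_voxels(dims, vs, origin, pos[q, ], radius)
    if (length(sel) == 0L) NA_real_ else mean(img[sel])
  }, numeric(1))
}

# linear indices of voxels whose centers lie inside the ball
.ball_voxels <- function(dims, vs, origin, center, radius) {
  lo <- pmax(1L, floor((center - radius - origin) / vs - 0.5) + 1L)
  hi <- pmin(dims, ceiling((center + radius - origin) / vs - 0.5) + 1L)
  if (any(lo > hi)) return(integer(0))
  ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
  dx2 <- (origin[1] + (ii - 0.5) * vs[1] - center[1])^2
  dy2 <- (origin[2] + (jj - 0.5) * vs[2] - center[2])^2
  dz2 <- (origin[3] + (kk - 0.5) * vs[3] - center[3])^2
  d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
  inside <- d2 <= radius^2
  if (!any(inside)) return(integer(0))
  idx <- which(inside, arr.ind = TRUE)
  (ii[idx[, 1]]) + dims[1] * (jj[idx[, 2]] - 1L) +
    dims[1] * dims[2] * (kk[idx[, 3]] - 1L)
}

#' Detect both Fucci channels with their conventional spot sizes
#'
#' Runs [detect_nuclei()] on the red (G1/G0) channel at 6 µm and the green
#' (S/G2/M) channel at 7 µm and resolves double detections: when a green and a
#' red spot fall within half the smaller diameter of each other, the spot with
#' the higher scale-normalized response is kept (ties go to green, the rarer
#' class in ducts).
#'
#' @param stack a [voxel_stack()] with channels `"green"` and `"red"`.
#' @param diameters named numeric, spot diameters per channel (µm).
#' @param ... passed to [detect_nuclei()].
#' @return combined spot table with unique cell ids; `class` column equals the
#'   retained channel.
#' @export
detect_fucci <- function(stack, diameters = c(red = 6, green = 7), ...) {
  spots <- do.call(rbind, lapply(names(diameters), function(ch)
    detect_nuclei(stack, ch, diameters[[ch]], ...)))
  if (nrow(spots) == 0L) {
    spots$class <- character(0)
    return(spots)
  }
  spots$class <- spots$channel
  # resolve co-positive loci: keep the stronger response, ties -> green
  gr <- spots[spots$channel == "green", , drop = FALSE]
  rd <- spots[spots$channel == "red", , drop = FALSE]
  if (nrow(gr) > 0 && nrow(rd) > 0) {
    lim <- min(diameters) / 2
    drop_rd <- rep(FALSE, nrow(rd))
    drop_gr <- rep(FALSE, nrow(gr))
    for (q in seq_len(nrow(rd))) {
      d <- sqrt((gr$x - rd$x[q])^2 + (gr$y - rd$y[q])^2 + (gr$z - rd$z[q])^2)
      hit <- which(d < lim & !drop_gr)
      if (length(hit)) {
        best <- hit[which.max(gr$response[hit])]
        if (gr$response[best] >= rd$response[q]) drop_rd[q] <- TRUE
        else drop_gr[best] <- TRUE
      }
    }
    spots <- rbind(gr[!drop_gr, , drop = FALSE], rd[!drop_rd, , drop = FALSE])
  }
  spots$id <- seq_len(nrow(spots))
  rownames(spots) <- NULL
  spots
}

#' Contrast normalization with controlled saturation
#'
#' Linear rescale that saturates `saturated_fraction / 2` of the pixels at each
#' tail to the dtype range (default 0.02% total, 16-bit). Constant images are
#' returned unchanged.
#'
#' @param image numeric array or matrix.
#' @param saturated_fraction total fraction of pixels saturated (both tails).
#' @param max_value upper end of the output range (dtype max).
#' @return rescaled array of the same shape.
#' @export
normalize_contrast <- function(image, saturated_fraction = 0.0002,
                               max_value = 65535) {
  if (length(image) == 0L) stop("image is empty")
  if (saturated_fraction < 0 || saturated_fraction >= 1)
    stop("saturated_fraction must be in [0, 1)")
  v <- as.numeric(image)
  lo <- quantile(v, saturated_fraction / 2, names = FALSE, type = 7)
  hi <- quantile(v, 1 - saturated_fraction / 2, names = FALSE, type = 7)
  if (hi <= lo) return(image)  # constant (or degenerate) image
  out <- (v - lo) / (hi - lo) * max_value
  out <- pmin(pmax(out, 0), max_value)
  dim(out) <- dim(image)
  out
}

#' Regional intensities inside a spherical volume
#'
#' Sums and means of voxel intensities inside a ball, optionally partitioned by
#' an epithelial mask into "epithelium" (inside) and "mesenchyme" (outside);
#' the two partition sums add up exactly to the unpartitioned sum.
#'
#' @param stack a [voxel_stack()].
#' @param center ball center, µm.
#' @param radius ball radius, µm.
#' @param channel channel name (default first).
#' @param partition_mask optional [epithelial_mask()].
#' @return named list of regions (`total`, and `epithelium`/`mesenchyme` when a
#'   mask is given), each with `sum`, `mean`, `voxel_count`.
#' @export
regional_mean_intensity <- function(stack, center, radius, channel = NULL,
                                    partition_mask = NULL) {
  stopifnot(inherits(stack, "voxel_stack"), radius > 0)
  if (is.null(channel)) channel <- names(stack$channels)[1]
  img <- stack$channels[[channel]]
  sel <- .ball_voxels(dim(img), stack$voxel_size, stack$origin, center, radius)
  if (length(sel) == 0L)
    stop("spherical volume lies entirely outside the stack")
  vals <- img[sel]
  out <- list(total = list(sum = sum(vals), mean = mean(vals),
                           voxel_count = length(vals)))
  if (!is.null(partition_mask)) {
    ijk <- arrayInd(sel, dim(img))
    ctr <- .voxel_center(ijk, stack$voxel_size, stack$origin)
    mv <- .point_to_voxel(ctr, partition_mask$voxel_size,
                          partition_mask$origin)
    md <- dim(partition_mask$mask)
    inb <- mv[, 1] >= 1 & mv[, 2] >= 1 & mv[, 3] >= 1 &
      mv[, 1] <= md[1] & mv[, 2] <= md[2] & mv[, 3] <= md[3]
    inside <- rep(FALSE, length(sel))
    lin <- mv[inb, 1] + md[1] * (mv[inb, 2] - 1L) +
      md[1] * md[2] * (mv[inb, 3] - 1L)
    inside[inb] <- partition_mask$mask[lin]
    for (reg in c("epithelium", "mesenchyme")) {
      pick <- if (reg == "epithelium") inside else !inside
      out[[reg]] <- list(sum = sum(vals[pick]),
                         mean = if (any(pick)) mean(vals[pick]) else NA_real_,
                         voxel_count = sum(pick))
    }
  }
  out
}

#' Per-nucleus intensities with a region-size filter
#'
#' Mean intensity of each labeled 2D region, keeping only regions whose size
#' lies within `\[min_size, max_size\]` — the single-nucleus window that removes
#' debris and merged nuclei before distance-binned intensity profiles.
#'
#' @param labels integer matrix of region labels (0 = background).
#' @param intensity numeric matrix congruent with `labels`.
#' @param min_size,max_size inclusive size window (default 20–120).
#' @param pixel_size pixel edge length, µm.
#' @param size_metric `"area_um2"` (region area, µm²; default) or
#'   `"equivalent_diameter_um"` (diameter of the equal-area disk, µm).
#' @return `data.frame` with label, mean_intensity, size (in the chosen
#'   metric); empty with a warning when nothing survives.
#' @export
nuclear_intensity_by_size_filter <- function(labels, intensity,
                                             min_size = 20, max_size = 120,
                                             pixel_size = 1,
                                             size_metric = c("area_um2",
                                                             "equivalent_diameter_um")) {
  size_metric <- match.arg(size_metric)
  if (!identical(dim(labels), dim(intensity)))
    stop("labels and intensity must be congruent")
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0L) {
    warning("no labeled regions")
    return(data.frame(label = integer(), mean_intensity = numeric(),
                      size = numeric()))
  }
  counts <- tabulate(labels[labels > 0])
  counts <- counts[ids]
  area <- counts * pixel_size^2
  size <- if (size_metric == "area_um2") area else 2 * sqrt(area / pi)
  keep <- size >= min_size & size <= max_size
  if (!any(keep)) {
    warning("no regions survive the size filter")
    return(data.frame(label = integer(), mean_intensity = numeric(),
                      size = numeric()))
  }
  ids <- ids[keep]
  mi <- vapply(ids, function(l) mean(intensity[labels == l]), numeric(1))
  data.frame(label = ids, mean_intensity = mi, size = size[keep])
}
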