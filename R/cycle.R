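#' Cell-cycle fraction per group
#'
#' Exact counts of green (S/G2/M) and red (G1/G0) cells and the green fraction
#' per grouping key. Empty groups are kept and flagged (`fraction = NA`), never
#' silently dropped.
#'
#' @param cells cell table with a `class` column of `"green"`/`"red"`.
#' @param group_by character vector of grouping columns present in `cells`.
#' @return `data.frame` with the group keys, n_green, n_red, n, fraction.
#' @export
cycle_fraction <- function(cells, group_by = "domain") {
  if (!all(cells$class %in% c("green", "red")))
    stop("unknown class value(s): ",
         paste(setdiff(unique(cells$class), c("green", "red")), collapse = ", "))
  missing_keys <- setdiff(group_by, names(cells))
  if (length(missing_keys))
    stop("grouping column(s) not found: ", paste(missing_keys, collapse = ", "))
  keys <- lapply(group_by, function(k) {
    v <- cells[[k]]
    if (is.factor(v)) v else factor(v)  # preserve declared (empty) levels
  })
  names(keys) <- group_by
  tab_g <- tapply(cells$class == "green", keys, sum)
  tab_n <- tapply(rep(1L, nrow(cells)), keys, sum)
  grid <- expand.grid(lapply(keys, levels), stringsAsFactors = FALSE)
  names(grid) <- group_by
  n <- as.vector(tab_n); n[is.na(n)] <- 0L
  g <- as.vector(tab_g); g[is.na(g)] <- 0L
  out <- cbind(grid,
               data.frame(n_green = g, n_red = n - g, n = n,
                          fraction = ifelse(n > 0, g / n, NA_real_)))
  rownames(out) <- NULL
  out
}

#' Distance-binned cell-cycle profile
#'
#' Bins cells into right-open distance bins `[k*w, (k+1)*w)` and reports
#' per-bin counts and green fraction; typical widths are 1 µm for
#' distance-to-surface profiles and 10 µm along-branch.
#'
#' @param cells cell table with `class`.
#' @param distances per-cell distance, µm (e.g., from [sample_field()]);
#'   defaults to `cells$surface_distance`.
#' @param bin_width bin width, µm.
#' @return `data.frame` with bin_lo, bin_hi, n, n_green, fraction. Bin counts
#'   sum to the number of cells with a finite distance.
#' @export
distance_profile <- function(cells, distances = cells$surface_distance,
                             bin_width = 1) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  ok <- is.finite(distances)
  d <- distances[ok]
  g <- cells$class[ok] == "green"
  if (length(d) == 0L)
    return(data.frame(bin_lo = numeric(), bin_hi = numeric(), n = integer(),
                      n_green = integer(), fraction = numeric()))
  k <- floor(d / bin_width)
  ks <- seq(min(k), max(k))
  n <- vapply(ks, function(q) sum(k == q), integer(1))
  ng <- vapply(ks, function(q) sum(g[k == q]), integer(1))
  data.frame(bin_lo = ks * bin_width, bin_hi = (ks + 1) * bin_width,
             n = n, n_green = ng,
             fraction = ifelse(n > 0, ng / n, NA_real_))
}

#' Branch-point-to-tip cycle-status ratio over time
#'
#' Per-frame green fraction in the branch-point region (`branch_point` or
#' `cleft_region` domains) and in the daughter tips (`daughter_tip` or `tip`),
#' and their ratio, on a time axis in hours normalized so the cleft-appearance
#' frame (T0) maps to 0. Frames where either region holds fewer than
#' `min_cells` cells are flagged (`reliable = FALSE`); ratios of tiny counts
#' are unstable.
#'
#' @param cells multi-frame cell table with `domain` and `class` columns.
#' @param t0 T0 frame index.
#' @param frame_interval minutes per frame.
#' @param min_cells per-region minimal count for a reliable ratio.
#' @return `data.frame`: frame, time_h, branch_fraction, tip_fraction, ratio,
#'   n_branch, n_tip, reliable.
#' @export
branchpoint_tip_ratio <- function(cells, t0, frame_interval, min_cells = 10) {
  if (is.null(t0) || is.na(t0)) stop("t0 frame is required")
  frames <- sort(unique(cells$frame))
  if (!t0 %in% frames && (t0 < min(frames) || t0 > max(frames)))
    stop("t0 outside the frame range")
  branch_dom <- c("branch_point", "cleft_region")
  tip_dom <- c("daughter_tip", "tip")
  rows <- lapply(frames, function(fr) {
    cf <- cells[cells$frame == fr, ]
    b <- cf[cf$domain %in% branch_dom, ]
    t <- cf[cf$domain %in% tip_dom, ]
    fb <- if (nrow(b)) mean(b$class == "green") else NA_real_
    ft <- if (nrow(t)) mean(t$class == "green") else NA_real_
    data.frame(frame = fr, time_h = (fr - t0) * frame_interval / 60,
               branch_fraction = fb, tip_fraction = ft,
               ratio = ifelse(!is.na(fb) && !is.na(ft) && ft > 0,
                              fb / ft, NA_real_),
               n_branch = nrow(b), n_tip = nrow(t),
               reliable = nrow(b) >= min_cells && nrow(t) >= min_cells)
  })
  out <- do.call(rbind, rows)
  if (!any(out$n_branch > 0 & out$n_tip > 0))
    stop("no frame has both regions populated")
  out
}

#' Classify per-cell keratin dominance
#'
#' Cells negative for both keratins (both gray values below `floor`, default
#' 25) are excluded; otherwise the cell is K14-dominant if K14 > K8 and
#' K8-dominant if K8 > K14, exact ties going to K8 (documented convention).
#' The K14/K8 ratio is returned for distance-trend analyses.
#'
#' @param cells table with numeric `k14` and `k8` gray-value columns.
#' @param floor gray-value floor below which a channel counts as negative.
#' @return `cells` with added `dominance` (`"K14"`, `"K8"`, `"excluded"`) and
#'   `ratio` (K14/K8) columns.
#' @export
classify_marker_dominance <- function(cells, floor = 25) {
  if (any(cells$k14 < 0 | cells$k8 < 0, na.rm = TRUE))
    stop("negative keratin intensities")
  excluded <- cells$k14 < floor & cells$k8 < floor
  dom <- ifelse(excluded, "excluded",
                ifelse(cells$k14 > cells$k8, "K14", "K8"))
  cells$dominance <- dom
  cells$ratio <- ifelse(cells$k8 > 0, cells$k14 / cells$k8, NA_real_)
  attr(cells, "floor_used") <- floor
  cells
}
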