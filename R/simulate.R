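#' Parameters for a synthetic branching scene
#'
#' Describes an elongating (optionally bifurcating) epithelial branch populated
#' by motile nuclei carrying a two-colour cell-cycle label. Defaults encode the
#' qualitative regime the package is designed to quantify: a tipward motility
#' gradient, S/G2/M enrichment in the tip (~50%) over the trailing duct
#' (~15%), and, after cleft appearance (T0), slowed and cell-cycle-repressed
#' branch-point cells. Speeds are not reported quantitatively by typical
#' embryonic explant imaging at this scale; 20 µm/h at the leading edge with a
#' 50 µm decay length gives leading-front advance of a few tens of µm over a
#' 10 h movie, which is the regime the tool targets. All of these are exposed,
#' never hard-coded downstream.
#'
#' @param branch_axis_length initial cylindrical branch length, µm.
#' @param tube_radius branch radius, µm.
#' @param tip_radius spherical tip cap radius, µm.
#' @param n_cells number of nuclei (agents).
#' @param basal_shell_depth nominal depth of the outer cell layer, µm (used by
#'   [place_surface_shell()] helpers and reported in ground truth).
#' @param tip_cycle_fraction probability that a tip cell (within `tip_extent`
#'   of the leading edge) is in S/G2/M ("green").
#' @param duct_cycle_fraction same for duct cells.
#' @param tip_extent tip pooling distance from the leading edge, µm (default
#'   100, the conventional tip definition).
#' @param speed_at_edge mean agent speed at the leading edge, µm/h; also the
#'   hard per-step speed ceiling.
#' @param speed_decay_length exponential decay length of speed with distance
#'   to the leading edge, µm.
#' @param speed_noise per-step lognormal speed dispersion (sdlog;
#'   mean-preserving, clamped at `speed_at_edge`). Real track speeds are
#'   widely dispersed; 0.25 gives a realistic ~25% coefficient of variation.
#' @param directional_kappa von Mises concentration of headings about the
#'   branch axis (0 = isotropic).
#' @param frame_interval minutes between frames.
#' @param n_frames number of frames (>= 2).
#' @param bifurcation `NULL` for pure elongation, else a list from
#'   [bifurcation_params()].
#' @param seed integer RNG seed; identical parameters + seed reproduce the
#'   scene bit-for-bit.
#' @return a validated list of class `scenario_params`.
#' @export
scenario_params <- function(branch_axis_length = 150, tube_radius = 25,
                            tip_radius = 25, n_cells = 300,
                            basal_shell_depth = 6,
                            tip_cycle_fraction = 0.5,
                            duct_cycle_fraction = 0.15,
                            tip_extent = 100,
                            speed_at_edge = 20, speed_decay_length = 50,
                            speed_noise = 0.25,
                            directional_kappa = 2,
                            frame_interval = 20, n_frames = 30,
                            bifurcation = NULL, seed = 1L) {
  p <- list(branch_axis_length = branch_axis_length, tube_radius = tube_radius,
            tip_radius = tip_radius, n_cells = as.integer(n_cells),
            basal_shell_depth = basal_shell_depth,
            tip_cycle_fraction = tip_cycle_fraction,
            duct_cycle_fraction = duct_cycle_fraction,
            tip_extent = tip_extent,
            speed_at_edge = speed_at_edge,
            speed_decay_length = speed_decay_length,
            speed_noise = speed_noise,
            directional_kappa = directional_kappa,
            frame_interval = frame_interval, n_frames = as.integer(n_frames),
            bifurcation = bifurcation, seed = as.integer(seed))
  lens <- c(p$branch_axis_length, p$tube_radius, p$tip_radius,
            p$basal_shell_depth, p$tip_extent, p$speed_decay_length,
            p$frame_interval)
  if (any(lens <= 0)) stop("all lengths/intervals must be > 0")
  if (p$speed_at_edge < 0 || p$directional_kappa < 0 || p$speed_noise < 0)
    stop("speed_at_edge, directional_kappa and speed_noise must be >= 0")
  fr <- c(p$tip_cycle_fraction, p$duct_cycle_fraction)
  if (any(fr < 0 | fr > 1)) stop("cycle fractions must lie in [0, 1]")
  if (p$n_cells < 1) stop("n_cells must be >= 1")
  if (p$n_frames < 2) stop("n_frames must be >= 2 for a time-lapse")
  if (!is.null(bifurcation)) {
    if (is.null(bifurcation$t0_frame)) stop("bifurcation needs t0_frame")
    if (bifurcation$t0_frame >= p$n_frames)
      stop("t0_frame must be < n_frames")
  }
  structure(p, class = "scenario_params")
}

#' Bifurcation sub-parameters
#'
#' @param t0_frame frame index (1-based) at which the cleft first appears (T0).
#' @param widening_frames number of frames of tip widening before T0.
#' @param cleft_speed ingression speed of the cleft landmark, µm/h.
#' @param branchpoint_speed_factor multiplier on the speed of cleft-proximal
#'   agents after T0 (1 = no slowdown).
#' @param branchpoint_cycle_factor multiplier on the green-class probability
#'   applied to cleft-proximal agents at T0 (1 = no repression).
#' @param daughter_angle full angle between daughter branch axes, degrees.
#' @param widen_factor ratio of tip cap radius at T0 to the initial cap radius.
#' @return list usable as `bifurcation` in [scenario_params()].
#' @export
bifurcation_params <- function(t0_frame, widening_frames = 6,
                               cleft_speed = 10,
                               branchpoint_speed_factor = 0.3,
                               branchpoint_cycle_factor = 0.3,
                               daughter_angle = 70, widen_factor = 1.5) {
  stopifnot(t0_frame >= 1, widening_frames >= 0, cleft_speed >= 0,
            branchpoint_speed_factor >= 0, branchpoint_cycle_factor >= 0,
            daughter_angle > 0, daughter_angle < 180, widen_factor >= 1)
  list(t0_frame = as.integer(t0_frame),
       widening_frames = as.integer(widening_frames),
       cleft_speed = cleft_speed,
       branchpoint_speed_factor = branchpoint_speed_factor,
       branchpoint_cycle_factor = branchpoint_cycle_factor,
       daughter_angle = daughter_angle, widen_factor = widen_factor)
}

# von Mises sampler (Best & Fisher 1979); mu, output in radians
.rvonmises <- function(n, mu, kappa) {
  if (kappa <= 0) return(runif(n, -pi, pi) + mu)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- runif(1); u2 <- runif(1); u3 <- runif(1)
    zz <- cos(pi * u1)
    f <- (1 + r * zz) / (r + zz)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      out[i] <- sign(u3 - 0.5) * acos(f) + mu
      i <- i + 1L
    }
  }
  out
}

# --- scene geometry -----------------------------------------------------------
# A frame's geometry: parent cylinder [0, L] x disc(tube_radius) plus a
# spherical cap of radius cap_r centered at (L, 0, 0); after T0 also two
# daughter capsules of radius tube_radius and axial length dlen from the branch
# point B = (L, 0, 0) along directions at +/- daughter_angle/2 in the xy plane.
.geom_frame <- function(L, cap_r, phase, dlen = 0, half_angle = 0,
                        cleft_x = NA_real_) {
  list(L = L, cap_r = cap_r, phase = phase, dlen = dlen,
       half_angle = half_angle, cleft_x = cleft_x)
}

.daughter_dirs <- function(geom) {
  a <- geom$half_angle
  rbind(c(cos(a), sin(a), 0), c(cos(a), -sin(a), 0))
}

# squared distance from points (n x 3) to the segment B + t*u, t in [0, len]
.dist2_segment <- function(pts, B, u, len) {
  rel <- sweep(pts, 2, B, "-")
  t <- pmin(pmax(rel[, 1] * u[1] + rel[, 2] * u[2] + rel[, 3] * u[3], 0), len)
  dx <- rel[, 1] - t * u[1]
  dy <- rel[, 2] - t * u[2]
  dz <- rel[, 3] - t * u[3]
  dx^2 + dy^2 + dz^2
}

# containment test with an inward safety margin (um)
.inside_scene <- function(pts, geom, params, margin = 0) {
  pts <- matrix(pts, ncol = 3)
  R <- params$tube_radius - margin
  inside <- (pts[, 1] >= margin & pts[, 1] <= geom$L &
               pts[, 2]^2 + pts[, 3]^2 <= R^2)
  capR <- geom$cap_r - margin
  relc <- sweep(pts, 2, c(geom$L, 0, 0), "-")
  inside <- inside | (rowSums(relc^2) <= capR^2)
  if (geom$dlen > 0) {
    dirs <- .daughter_dirs(geom)
    B <- c(geom$L, 0, 0)
    for (q in 1:2) {
      d2 <- .dist2_segment(pts, B, dirs[q, ], geom$dlen)
      inside <- inside | (d2 <= R^2)
    }
  }
  inside
}

# settle a proposed step against the (already advanced) frame geometry:
# agents whose step would leave the epithelium re-draw their heading (same
# speed) up to `max_tries` times; stubborn cases are reflected/projected.
# Realized step speeds therefore equal the nominal speed law except for a
# negligible fallback fraction.
.settle_step <- function(from, to, step, mu, geom, params, margin,
                         max_tries = 10) {
  out <- !.inside_scene(to, geom, params, margin)
  tries <- 0L
  while (any(out) && tries < max_tries) {
    idx <- which(out)
    psi <- .rvonmises(length(idx), 0, params$directional_kappa) + mu[idx]
    phi <- rnorm(length(idx), 0, 0.15)
    to[idx, ] <- from[idx, , drop = FALSE] +
      cbind(step[idx] * cos(psi) * cos(phi),
            step[idx] * sin(psi) * cos(phi),
            step[idx] * sin(phi))
    out[idx] <- !.inside_scene(to[idx, , drop = FALSE], geom, params, margin)
    tries <- tries + 1L
  }
  if (any(out)) to <- .reflect_inside(to, geom, params, margin)
  to
}

# reflect stray agents at the boundary (preserves step magnitude); any point
# still outside after reflection is projected onto the nearest interior point,
# which guarantees the containment invariant
.reflect_inside <- function(pts, geom, params, margin) {
  out <- !.inside_scene(pts, geom, params, margin)
  if (!any(out)) return(pts)
  p <- matrix(pts[out, ], ncol = 3)
  R <- params$tube_radius - margin
  cand <- list()
  # cylinder: mirror the radial and axial overshoot
  c1 <- p
  c1[, 1] <- ifelse(c1[, 1] < margin, 2 * margin - c1[, 1], c1[, 1])
  r <- sqrt(c1[, 2]^2 + c1[, 3]^2)
  f <- ifelse(r > R & r > 0, pmax(2 * R - r, 0.1 * R) / r, 1)
  c1[, 2] <- c1[, 2] * f; c1[, 3] <- c1[, 3] * f
  cand[[1]] <- c1
  # tip cap: mirror the radial overshoot about the cap sphere
  capR <- geom$cap_r - margin
  relc <- sweep(p, 2, c(geom$L, 0, 0), "-")
  nr <- sqrt(rowSums(relc^2))
  f <- ifelse(nr > capR & nr > 0, pmax(2 * capR - nr, 0.1 * capR) / nr, 1)
  cand[[2]] <- sweep(relc * f, 2, c(geom$L, 0, 0), "+")
  if (geom$dlen > 0) {
    dirs <- .daughter_dirs(geom)
    B <- c(geom$L, 0, 0)
    for (q in 1:2) {
      u <- dirs[q, ]
      rel <- sweep(p, 2, B, "-")
      t <- pmin(pmax(rel %*% u, 0), geom$dlen)
      ax <- cbind(B[1] + t * u[1], B[2] + t * u[2], B[3] + t * u[3])
      rad <- p - ax
      nr <- sqrt(rowSums(rad^2))
      f <- ifelse(nr > R & nr > 0, pmax(2 * R - nr, 0.1 * R) / nr, 1)
      cand[[2 + q]] <- ax + rad * f
    }
  }
  # keep the nearest *valid* reflected candidate per point
  best <- matrix(NA_real_, nrow(p), 3)
  bestd <- rep(Inf, nrow(p))
  for (q in seq_along(cand)) {
    ok <- .inside_scene(cand[[q]], geom, params, margin)
    d <- rowSums((p - cand[[q]])^2)
    better <- ok & d < bestd
    best[better, ] <- cand[[q]][better, , drop = FALSE]
    bestd[better] <- d[better]
  }
  got <- is.finite(bestd)
  fixed <- pts
  idx_out <- which(out)
  fixed[idx_out[got], ] <- best[got, , drop = FALSE]
  # stubborn stragglers (corners): nearest-point projection
  if (any(!got)) {
    sub <- matrix(p[!got, ], ncol = 3)
    fixed[idx_out[!got], ] <- .project_inside(sub, geom, params, margin)
  }
  fixed
}

# project points onto the nearest interior point of the scene
.project_inside <- function(pts, geom, params, margin) {
  out <- !.inside_scene(pts, geom, params, margin)
  if (!any(out)) return(pts)
  p <- matrix(pts[out, ], ncol = 3)
  R <- params$tube_radius - margin
  cand <- list()
  # candidate 1: clamp into the parent cylinder
  c1 <- p
  c1[, 1] <- pmin(pmax(c1[, 1], margin), geom$L)
  r <- sqrt(c1[, 2]^2 + c1[, 3]^2)
  f <- ifelse(r > R & r > 0, R / r, 1)
  c1[, 2] <- c1[, 2] * f; c1[, 3] <- c1[, 3] * f
  cand[[1]] <- c1
  # candidate 2: clamp into the tip cap sphere
  capR <- geom$cap_r - margin
  relc <- sweep(p, 2, c(geom$L, 0, 0), "-")
  nr <- sqrt(rowSums(relc^2))
  f <- ifelse(nr > capR & nr > 0, capR / nr, 1)
  cand[[2]] <- sweep(relc * f, 2, c(geom$L, 0, 0), "+")
  # candidates 3,4: clamp into daughter capsules
  if (geom$dlen > 0) {
    dirs <- .daughter_dirs(geom)
    B <- c(geom$L, 0, 0)
    for (q in 1:2) {
      u <- dirs[q, ]
      rel <- sweep(p, 2, B, "-")
      t <- pmin(pmax(rel %*% u, 0), geom$dlen)
      ax <- cbind(B[1] + t * u[1], B[2] + t * u[2], B[3] + t * u[3])
      rad <- p - ax
      nr <- sqrt(rowSums(rad^2))
      f <- ifelse(nr > R & nr > 0, R / nr, 1)
      cand[[2 + q]] <- ax + rad * f
    }
  }
  best <- cand[[1]]
  bestd <- rowSums((p - best)^2)
  for (q in seq_along(cand)[-1]) {
    d <- rowSums((p - cand[[q]])^2)
    better <- d < bestd
    best[better, ] <- cand[[q]][better, ]
    bestd <- pmin(bestd, d)
  }
  pts[out, ] <- best
  pts
}

# true distance to the advancing front (um): axial distance to the leading
# edge pre-T0; after T0 the minimum over the two daughter fronts and the
# ingressing cleft (the cleft is part of the advancing tissue surface, so a
# null-factor scenario shows no geometric speed difference at the branch point)
.dist_to_edge <- function(pts, geom, params, include_cleft = TRUE) {
  pts <- matrix(pts, ncol = 3)
  if (geom$dlen <= 0) {
    front <- geom$L + geom$cap_r
    return(front - pts[, 1])
  }
  dirs <- .daughter_dirs(geom)
  B <- c(geom$L, 0, 0)
  front_len <- geom$dlen + params$tip_radius
  if (include_cleft) {
    # distance to the leading-edge landmark (midpoint of the daughter
    # fronts): the same reference the analysis pipeline uses for the tip, so
    # null branch-point factors introduce no geometric speed asymmetry
    mid <- B + c(front_len * cos(geom$half_angle), 0, 0)
    return(sqrt((pts[, 1] - mid[1])^2 + pts[, 2]^2 + pts[, 3]^2))
  }
  rel <- sweep(pts, 2, B, "-")
  d1 <- front_len - (rel %*% dirs[1, ])[, 1]
  d2 <- front_len - (rel %*% dirs[2, ])[, 1]
  pmin(d1, d2)
}

.scene_landmarks <- function(fr, geom, params) {
  lm <- list(origin = c(5, 0, 0),
             duct_center = c(max(params$tube_radius,
                                 geom$L + geom$cap_r - params$tip_extent - 50),
                             0, 0))
  if (geom$dlen <= 0 && is.na(geom$cleft_x) && geom$half_angle == 0) {
    lm$leading_edge <- c(geom$L + geom$cap_r, 0, 0)
  } else {
    dirs <- .daughter_dirs(geom)
    B <- c(geom$L, 0, 0)
    ext <- geom$dlen + params$tip_radius
    d1 <- B + dirs[1, ] * ext
    d2 <- B + dirs[2, ] * ext
    lm$daughter_tip_1 <- d1
    lm$daughter_tip_2 <- d2
    lm$leading_edge <- (d1 + d2) / 2
    lm$neck <- c(geom$L - geom$cap_r, 0, 0)
    if (!is.na(geom$cleft_x)) {
      lm$cleft <- c(geom$cleft_x, 0, 0)
      lm$branch_point_center <- B
    }
  }
  do.call(rbind, lapply(names(lm), function(nm)
    landmark_set(fr, nm, lm[[nm]][1], lm[[nm]][2], lm[[nm]][3])))
}

# rasterize one frame's geometry on a fixed isotropic grid
.rasterize_scene <- function(geom, params, grid) {
  ins <- .inside_scene(grid$pts, geom, params, margin = 0)
  m <- array(ins, grid$dims)
  epithelial_mask(m, grid$voxel, grid$origin, frame = geom$frame_index)
}

.make_grid <- function(xmax, rmax, voxel, pad) {
  x0 <- -pad; y0 <- -rmax - pad; z0 <- -rmax - pad
  nx <- ceiling((xmax + 2 * pad) / voxel)
  ny <- ceiling((2 * rmax + 2 * pad) / voxel)
  nz <- ny
  gx <- x0 + (seq_len(nx) - 0.5) * voxel
  gy <- y0 + (seq_len(ny) - 0.5) * voxel
  gz <- z0 + (seq_len(nz) - 0.5) * voxel
  pts <- cbind(rep(gx, times = ny * nz),
               rep(rep(gy, each = nx), times = nz),
               rep(gz, each = nx * ny))
  list(pts = pts, dims = c(nx, ny, nz), voxel = voxel,
       origin = c(x0, y0, z0))
}

# uniform rejection sampling of agent positions inside the frame-1 geometry
.sample_positions <- function(n, geom, params, margin) {
  xmax <- geom$L + geom$cap_r
  R <- max(params$tube_radius, geom$cap_r)
  out <- matrix(NA_real_, 0, 3)
  while (nrow(out) < n) {
    m <- 2L * (n - nrow(out)) + 16L
    cand <- cbind(runif(m, margin, xmax), runif(m, -R, R), runif(m, -R, R))
    keep <- .inside_scene(cand, geom, params, margin)
    out <- rbind(out, cand[keep, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

.simulate_scene <- function(params, mask_frames, mask_voxel) {
  if (!inherits(params, "scenario_params"))
    params <- do.call(scenario_params, params)
  bif <- params$bifurcation
  # isolate RNG
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(params$seed)

  nF <- params$n_frames
  dt_h <- params$frame_interval / 60
  margin <- sqrt(3) / 2 * mask_voxel + 0.1  # keeps every agent's voxel center inside
  half_angle <- if (!is.null(bif)) bif$daughter_angle / 2 * pi / 180 else 0
  widen_start <- if (!is.null(bif)) bif$t0_frame - bif$widening_frames else Inf
  t0 <- if (!is.null(bif)) bif$t0_frame else NA_integer_

  # frame-1 geometry
  L <- params$branch_axis_length
  cap_r <- params$tip_radius
  geom <- .geom_frame(L, cap_r, "elongation")

  pos <- .sample_positions(params$n_cells, geom, params, margin)
  d0 <- .dist_to_edge(pos, geom, params)
  pgreen <- ifelse(d0 <= params$tip_extent,
                   params$tip_cycle_fraction, params$duct_cycle_fraction)
  cls <- ifelse(runif(params$n_cells) < pgreen, "green", "red")
  repressed_drawn <- rep(FALSE, params$n_cells)

  cells <- vector("list", nF)
  geoms <- vector("list", nF)
  lms <- vector("list", nF)
  front_width <- 10  # um; cohort defining the mask's advance speed

  dlen <- 0
  cleft_x <- NA_real_
  pos_pending <- NULL
  for (fr in seq_len(nF)) {
    phase <- if (is.null(bif)) "elongation"
      else if (fr >= t0) "cleft"
      else if (fr >= widen_start) "widening"
      else "elongation"
    ha <- if (phase %in% c("widening", "cleft")) half_angle else 0
    # the cleft appears on the front surface between the daughter fronts
    if (phase == "cleft" && is.na(cleft_x))
      cleft_x <- L + (dlen + params$tip_radius) * cos(half_angle)
    geom <- .geom_frame(L, cap_r, phase, dlen = dlen, half_angle = ha,
                        cleft_x = cleft_x)
    geom$frame_index <- fr
    # agents and front move simultaneously: the step taken between the
    # previous frame and this one is settled against THIS frame's (already
    # advanced) boundary, so cells at the advancing front keep their speed
    if (!is.null(pos_pending))
      pos <- .settle_step(pos_pending$from, pos_pending$to, pos_pending$step,
                          pos_pending$mu, geom, params, margin)
    d <- .dist_to_edge(pos, geom, params)
    spd <- params$speed_at_edge * exp(-d / params$speed_decay_length)

    cleft_prox <- rep(FALSE, params$n_cells)
    if (phase == "cleft") {
      # within the bifurcating tip the base motility is uniform: the only
      # post-T0 speed contrast between branch point and daughter tips is the
      # configured branchpoint_speed_factor (null factors leave the groups
      # exchangeable); the trailing duct keeps the distance gradient
      spd[d <= params$tip_extent] <- params$speed_at_edge *
        exp(-params$tip_radius / params$speed_decay_length)
      C <- c(geom$cleft_x, 0, 0)
      dirs <- .daughter_dirs(geom)
      B <- c(geom$L, 0, 0)
      ext <- geom$dlen + params$tip_radius
      D1 <- B + dirs[1, ] * ext
      D2 <- B + dirs[2, ] * ext
      dC <- sqrt(rowSums(sweep(pos, 2, C, "-")^2))
      dD <- pmin(sqrt(rowSums(sweep(pos, 2, D1, "-")^2)),
                 sqrt(rowSums(sweep(pos, 2, D2, "-")^2)))
      # branch-point cells: nearer the cleft than either daughter tip, and
      # within the tip neighbourhood (trailing-duct cells are unaffected)
      cleft_prox <- dC < dD & dC <= params$tip_extent
      spd[cleft_prox] <- spd[cleft_prox] * bif$branchpoint_speed_factor
      if (bif$branchpoint_cycle_factor != 1) {
        # the class label tracks branch-point membership: re-drawn with the
        # repressed probability when an agent enters the region and with the
        # base probability when it leaves, so labels are piecewise constant
        # per agent and region-level fractions realize the configured factor
        entered <- which(cleft_prox & !repressed_drawn)
        if (length(entered)) {
          p0 <- ifelse(d[entered] <= params$tip_extent,
                       params$tip_cycle_fraction, params$duct_cycle_fraction)
          cls[entered] <- ifelse(runif(length(entered)) <
                                   p0 * bif$branchpoint_cycle_factor,
                                 "green", "red")
          repressed_drawn[entered] <- TRUE
        }
        left <- which(!cleft_prox & repressed_drawn)
        if (length(left)) {
          p0 <- ifelse(d[left] <= params$tip_extent,
                       params$tip_cycle_fraction, params$duct_cycle_fraction)
          cls[left] <- ifelse(runif(length(left)) < p0, "green", "red")
          repressed_drawn[left] <- FALSE
        }
      }
    }

    cells[[fr]] <- data.frame(frame = fr, id = seq_len(params$n_cells),
                              x = pos[, 1], y = pos[, 2], z = pos[, 3],
                              class = cls, dist_to_edge = d,
                              cleft_proximal = cleft_prox,
                              stringsAsFactors = FALSE)
    geoms[[fr]] <- geom
    lms[[fr]] <- .scene_landmarks(fr, geom, params)
    if (fr == nF) break

    # --- advance agents ------------------------------------------------------
    if (phase == "cleft") {
      # head toward the nearest daughter front
      dirs <- .daughter_dirs(geom)
      rel <- sweep(pos, 2, c(geom$L, 0, 0), "-")
      nearer1 <- (rel %*% dirs[1, ]) >= (rel %*% dirs[2, ])
      mu <- ifelse(nearer1, ha, -ha)
    } else {
      mu <- rep(0, params$n_cells)
    }
    psi <- .rvonmises(params$n_cells, 0, params$directional_kappa) + mu
    phi <- rnorm(params$n_cells, 0, 0.15)  # small out-of-plane jitter
    # mean-preserving lognormal per-step speed dispersion, capped at the
    # stated maximum (the edge speed)
    sn <- params$speed_noise
    noisy <- if (sn > 0)
      pmin(spd * exp(rnorm(params$n_cells, -sn^2 / 2, sn)),
           params$speed_at_edge) else spd
    step <- noisy * dt_h
    pos_old <- pos
    pos2 <- pos_old + cbind(step * cos(psi) * cos(phi),
                            step * sin(psi) * cos(phi),
                            step * sin(phi))

    # --- advance geometry ----------------------------------------------------
    # the front advances with its cells: mean intended axial displacement of
    # the cohort near the daughter fronts / leading edge (the mask is made of
    # nuclei, it cannot outrun them; the cleft does not pull the front)
    d_front <- .dist_to_edge(pos_old, geom, params, include_cleft = FALSE)
    front <- d_front <= front_width
    if (phase == "cleft") {
      dirs <- .daughter_dirs(geom)
      rel <- sweep(pos_old, 2, c(geom$L, 0, 0), "-")
      use1 <- (rel %*% dirs[1, ])[, 1] >= (rel %*% dirs[2, ])[, 1]
      u <- ifelse(use1, 1L, 2L)
      dispm <- pos2 - pos_old
      axial <- dispm[, 1] * dirs[u, 1] + dispm[, 2] * dirs[u, 2]
    } else {
      axial <- pos2[, 1] - pos_old[, 1]
    }
    if (!any(front)) front <- d_front <= 3 * front_width
    adv <- if (any(front)) max(0, mean(axial[front])) else 0
    pos_pending <- list(from = pos_old, to = pos2, step = step,
                        mu = as.numeric(mu))
    nxt <- fr + 1
    if (is.null(bif) || nxt < widen_start) {
      L <- L + adv
    } else if (nxt < t0) {
      # widening: the cap inflates linearly up to widen_factor x tip_radius
      w <- (nxt - widen_start + 1) / max(1, bif$widening_frames)
      cap_r <- params$tip_radius * (1 + (bif$widen_factor - 1) * min(1, w))
      L <- L + adv
    } else {
      # post-T0: parent frozen, daughters elongate, cleft ingresses
      cleft_x <- cleft_x - bif$cleft_speed * dt_h
      dlen <- dlen + adv
    }
  }

  cells <- do.call(rbind, cells)
  landmarks <- do.call(rbind, lms)

  masks <- vector("list", nF)
  if (!identical(mask_frames, FALSE)) {
    want <- if (isTRUE(mask_frames)) seq_len(nF) else as.integer(mask_frames)
    glast <- geoms[[nF]]
    xmax <- glast$L + glast$cap_r +
      (if (glast$dlen > 0) glast$dlen + params$tip_radius else 0)
    rmax <- max(params$tube_radius, params$tip_radius *
                  (if (!is.null(bif)) bif$widen_factor else 1),
                if (glast$dlen > 0)
                  (glast$dlen + params$tip_radius) * sin(half_angle) +
                  params$tube_radius else 0)
    grid <- .make_grid(xmax, rmax, mask_voxel, pad = 3 * mask_voxel)
    for (fr in want) masks[[fr]] <- .rasterize_scene(geoms[[fr]], params, grid)
  }

  structure(list(cells = cells, masks = masks, landmarks = landmarks,
                 params = params, t0_frame = t0,
                 geometry = geoms, frame_interval = params$frame_interval),
            class = "ground_truth")
}

#' Generate a ground-truthed elongating-branch scenario
#'
#' Agents move with mean speed `speed_at_edge * exp(-d / speed_decay_length)`
#' where `d` is the distance to the advancing leading edge, with headings von
#' Mises-distributed about the branch axis; the tip advances at the mean speed
#' of the front cohort (agents within 10 µm of the edge). Cycle class is drawn
#' once per agent: green with probability `tip_cycle_fraction` within
#' `tip_extent` of the edge, else `duct_cycle_fraction`.
#'
#' @param params a [scenario_params()] without a `bifurcation` field.
#' @param mask_frames `TRUE` (rasterize every frame), `FALSE` (no masks), or an
#'   integer vector of frames to rasterize.
#' @param mask_voxel isotropic voxel size of rasterized masks, µm.
#' @return a `ground_truth` object: `$cells` (tidy per-frame table with true
#'   positions, classes and distance-to-edge; agent `id` links frames into true
#'   tracks), `$masks`, `$landmarks`, `$params`, `$geometry`.
#' @export
generate_elongation_scenario <- function(params, mask_frames = TRUE,
                                         mask_voxel = 2) {
  if (!is.null(params$bifurcation))
    stop("elongation scenario must not carry a bifurcation field; ",
         "use generate_bifurcation_scenario()")
  .simulate_scene(params, mask_frames, mask_voxel)
}

#' Generate a ground-truthed bifurcating-tip scenario
#'
#' Identical to the elongation scenario until tip widening begins; during
#' widening the tip cap inflates and daughter-tip landmarks separate by
#' `daughter_angle`; from `t0_frame` (T0) a cleft landmark ingresses at
#' `cleft_speed` and agents nearer the cleft than either daughter tip have
#' their speed multiplied by `branchpoint_speed_factor`, with a one-time
#' class re-draw at T0 scaling the green probability by
#' `branchpoint_cycle_factor`.
#'
#' @inheritParams generate_elongation_scenario
#' @return a `ground_truth` object (see [generate_elongation_scenario()]),
#'   with `$t0_frame` set and per-frame daughter-tip/cleft/neck landmarks.
#' @export
generate_bifurcation_scenario <- function(params, mask_frames = TRUE,
                                          mask_voxel = 2) {
  if (is.null(params$bifurcation))
    stop("bifurcation scenario requires a bifurcation field; ",
         "see bifurcation_params()")
  .simulate_scene(params, mask_frames, mask_voxel)
}

#' Imaging parameters for rendering synthetic stacks
#'
#' Defaults emulate two-channel nuclear reporter confocal stacks: 0.7 µm/px in
#' xy, 2 µm z step, nuclei of ~6 µm diameter (Gaussian sigma 2.5 µm), Poisson
#' photon noise plus Gaussian read noise.
#'
#' @param voxel_size µm per voxel, named or ordered (x, y, z).
#' @param nucleus_sigma Gaussian blob sigma, µm.
#' @param photon_scale expected peak photon count of a nucleus.
#' @param gaussian_noise_sd read-noise standard deviation (counts).
#' @param bit_depth 8 or 16.
#' @param background constant background photon level (counts).
#' @return list of class `imaging_params`.
#' @export
imaging_params <- function(voxel_size = c(x = 0.7, y = 0.7, z = 2),
                           nucleus_sigma = 2.5, photon_scale = 200,
                           gaussian_noise_sd = 3, bit_depth = 16,
                           background = 2) {
  voxel_size <- as.numeric(voxel_size)
  if (any(voxel_size <= 0) || nucleus_sigma <= 0)
    stop("voxel sizes and nucleus_sigma must be > 0")
  if (!bit_depth %in% c(8, 16)) stop("bit_depth must be 8 or 16")
  structure(list(voxel_size = voxel_size, nucleus_sigma = nucleus_sigma,
                 photon_scale = photon_scale,
                 gaussian_noise_sd = gaussian_noise_sd,
                 bit_depth = bit_depth, background = background),
            class = "imaging_params")
}

#' Render a ground-truth scene into noisy voxel stacks
#'
#' Each nucleus becomes a Gaussian blob in the channel of its cycle class
#' (one-hot: an agent is never rendered into both channels), sampled on the
#' anisotropic grid, with Poisson photon noise and additive Gaussian read
#' noise, quantized to the requested bit depth.
#'
#' @param gt a `ground_truth` object.
#' @param imaging an [imaging_params()] object.
#' @param frames frames to render (default all).
#' @param noise set `FALSE` for a noise-free render (useful for localization
#'   oracles).
#' @return a list of [voxel_stack()] objects (one per rendered frame); a single
#'   `voxel_stack` if exactly one frame was requested.
#' @export
render_stack <- function(gt, imaging = imaging_params(), frames = NULL,
                         noise = TRUE) {
  stopifnot(inherits(gt, "ground_truth"))
  if (is.null(frames)) frames <- sort(unique(gt$cells$frame))
  if (any(imaging$voxel_size > 4 * imaging$nucleus_sigma))
    warning("voxel size exceeds 4 x nucleus sigma; nuclei may be undetectable")
  params <- gt$params
  glast <- gt$geometry[[max(frames)]]
  xmax <- glast$L + glast$cap_r +
    (if (glast$dlen > 0) glast$dlen + params$tip_radius else 0) + 10
  rmax <- max(params$tube_radius, glast$cap_r,
              if (glast$dlen > 0)
                (glast$dlen + params$tip_radius) * sin(glast$half_angle) +
                params$tube_radius else 0) + 10
  vs <- imaging$voxel_size
  origin <- c(-5, -rmax, -rmax)
  dims <- c(ceiling((xmax + 5) / vs[1]),
            ceiling(2 * rmax / vs[2]), ceiling(2 * rmax / vs[3]))
  out <- vector("list", length(frames))
  maxv <- 2^imaging$bit_depth - 1
  for (q in seq_along(frames)) {
    fr <- frames[q]
    cells <- gt$cells[gt$cells$frame == fr, , drop = FALSE]
    chans <- list()
    for (ch in c("green", "red")) {
      sub <- cells[cells$class == ch, , drop = FALSE]
      img <- if (nrow(sub) == 0) array(0, dims) else
        cpp_render_gaussians(as.integer(dims), vs, origin,
                             as.matrix(sub[, c("x", "y", "z")]),
                             rep(imaging$photon_scale, nrow(sub)),
                             imaging$nucleus_sigma)
      img <- img + imaging$background
      if (noise) {
        img <- array(rpois(length(img), lambda = img), dims) +
          array(rnorm(length(img), 0, imaging$gaussian_noise_sd), dims)
      }
      img <- round(pmin(pmax(img, 0), maxv))
      dim(img) <- dims
      chans[[ch]] <- img
    }
    out[[q]] <- voxel_stack(chans, voxel_size = vs, origin = origin,
                            frame = fr,
                            frame_interval = gt$frame_interval)
  }
  if (length(out) == 1L) out[[1]] else out
}

#' Write ground truth to plain-text files
#'
#' Emits `cells.csv`, `landmarks.csv` and `params.json` into `dir`.
#'
#' @param gt a `ground_truth` object.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_ground_truth <- function(gt, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(gt$cells, file.path(dir, "cells.csv"), row.names = FALSE)
  write.csv(gt$landmarks, file.path(dir, "landmarks.csv"), row.names = FALSE)
  p <- gt$params
  class(p) <- NULL
  jsonlite::write_json(p, file.path(dir, "params.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}

#' Place a synthetic shell of nuclei at fixed depth inside a mask geometry
#'
#' Utility for validating surface-distance profiles: positions `n` points on
#' the cylinder wall of an elongation scene at a given depth below the surface.
#'
#' @param params a [scenario_params()].
#' @param depth depth below the tube surface, µm.
#' @param n number of points.
#' @return matrix (n x 3) of positions, µm.
#' @export
place_surface_shell <- function(params, depth, n = 200) {
  r <- params$tube_radius - depth
  stopifnot(r > 0)
  theta <- runif(n, 0, 2 * pi)
  x <- runif(n, 2 * params$tube_radius,
             params$branch_axis_length - params$tube_radius)
  cbind(x, r * cos(theta), r * sin(theta))
}
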