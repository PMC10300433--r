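# Independent oracles and small fixture builders. Everything here is written
# against the definitions, not against the package's computational paths.

# brute-force distance of every foreground voxel to the nearest background
# voxel center (physical spacing), O(n_fg * n_bg) -- tiny grids only
bf_surface_distance <- function(mask, spacing = c(1, 1, 1)) {
  d <- dim(mask)
  fg <- which(mask, arr.ind = TRUE)
  bg <- which(!mask, arr.ind = TRUE)
  out <- array(0, d)
  bgp <- sweep(bg, 2, spacing, "*")
  for (q in seq_len(nrow(fg))) {
    p <- fg[q, ] * spacing
    out[fg[q, 1], fg[q, 2], fg[q, 3]] <-
      sqrt(min(colSums((t(bgp) - p)^2)))
  }
  out
}

# plain O(V^2) Dijkstra on the 26-connected voxel graph; returns array of
# within-mask path lengths from the seed voxel (index triple), Inf when
# unreachable, NA in background
bf_geodesic <- function(mask, seed_ijk, spacing = c(1, 1, 1)) {
  d <- dim(mask)
  fg <- which(mask)
  idx <- arrayInd(fg, d)
  n <- length(fg)
  key <- setNames(seq_len(n), fg)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  w <- sqrt((offs[, 1] * spacing[1])^2 + (offs[, 2] * spacing[2])^2 +
              (offs[, 3] * spacing[3])^2)
  dist <- rep(Inf, n)
  s_lin <- seed_ijk[1] + d[1] * (seed_ijk[2] - 1) + d[1] * d[2] * (seed_ijk[3] - 1)
  dist[key[as.character(s_lin)]] <- 0
  done <- rep(FALSE, n)
  for (it in seq_len(n)) {
    u <- which.min(ifelse(done, Inf, dist))
    if (!is.finite(dist[u])) break
    done[u] <- TRUE
    here <- idx[u, ]
    for (o in seq_len(nrow(offs))) {
      nb <- here + offs[o, ]
      if (any(nb < 1) || any(nb > d)) next
      lin <- nb[1] + d[1] * (nb[2] - 1) + d[1] * d[2] * (nb[3] - 1)
      v <- key[as.character(lin)]
      if (is.na(v)) next
      if (dist[u] + w[o] < dist[v]) dist[v] <- dist[u] + w[o]
    }
  }
  out <- array(NA_real_, d)
  out[fg] <- dist
  out
}

# von Mises sample in degrees (wraps the package's internal sampler; used
# only to construct inputs, never as the oracle under test)
rvm_deg <- function(n, mu_deg, kappa) {
  (branchmorph:::.rvonmises(n, mu_deg * pi / 180, kappa) * 180 / pi) %% 360
}

# exhaustive minimal-cost bipartite matching oracle for the linker objective:
# sum of linked distances + cap * (number of unlinked spots on either side)
bf_best_matching <- function(A, B, cap) {
  nA <- nrow(A); nB <- nrow(B)
  D <- matrix(Inf, nA, nB)
  for (q in seq_len(nA))
    D[q, ] <- sqrt(rowSums(sweep(B, 2, A[q, ])^2))
  best <- list(cost = Inf, assign = rep(NA_integer_, nA))
  rec <- function(i, usedB, assign, cost) {
    if (i > nA) {
      total <- cost + cap * (sum(is.na(assign)) + sum(!usedB))
      if (total < best$cost) best <<- list(cost = total, assign = assign)
      return()
    }
    for (j in seq_len(nB)) {
      if (!usedB[j] && D[i, j] <= cap) {
        usedB[j] <- TRUE
        assign[i] <- j
        rec(i + 1L, usedB, assign, cost + D[i, j])
        usedB[j] <- FALSE
        assign[i] <- NA_integer_
      }
    }
    rec(i + 1L, usedB, assign, cost)
  }
  rec(1L, rep(FALSE, nB), rep(NA_integer_, nA), 0)
  best
}

# capsule-shaped test mask: tube of length L and radius R along x plus a
# spherical cap, voxelized at `voxel` um
capsule_mask <- function(L = 60, R = 10, voxel = 2, cap = R) {
  pad <- 2 * voxel
  nx <- ceiling((L + cap + 2 * pad) / voxel)
  ny <- nz <- ceiling((2 * R + 2 * pad) / voxel)
  origin <- c(-pad, -R - pad, -R - pad)
  gx <- origin[1] + (seq_len(nx) - 0.5) * voxel
  gy <- origin[2] + (seq_len(ny) - 0.5) * voxel
  gz <- origin[3] + (seq_len(nz) - 0.5) * voxel
  m <- array(FALSE, c(nx, ny, nz))
  for (k in seq_len(nz)) for (j in seq_len(ny)) {
    r2 <- gy[j]^2 + gz[k]^2
    m[, j, k] <- (gx >= 0 & gx <= L & r2 <= R^2) |
      ((gx - L)^2 + r2 <= cap^2)
  }
  epithelial_mask(m, voxel, origin = origin)
}

# small deterministic elongation/bifurcation parameter sets used across files
small_elong_params <- function(seed = 1, ...) {
  scenario_params(branch_axis_length = 150, tube_radius = 25, tip_radius = 25,
                  n_cells = 300, n_frames = 12, seed = seed, ...)
}

small_bifurc_params <- function(seed = 1, ...) {
  scenario_params(branch_axis_length = 150, tube_radius = 25, tip_radius = 25,
                  n_cells = 400, n_frames = 20,
                  bifurcation = bifurcation_params(t0_frame = 8),
                  seed = seed, ...)
}

# pixel centers inside a w x h rectangle rotated by angle about its center
rasterize_rect <- function(w, h, angle_deg = 0, pixel = 1, pad = 10) {
  th <- angle_deg * pi / 180
  n <- ceiling((max(w, h) + 2 * pad) / pixel)
  m <- matrix(FALSE, n, n)
  cx <- n / 2 * pixel
  for (j in seq_len(n)) {
    px <- (seq_len(n) - 0.5) * pixel - cx
    py <- (j - 0.5) * pixel - cx
    u <- px * cos(th) + py * sin(th)
    v <- -px * sin(th) + py * cos(th)
    m[, j] <- abs(u) <= h / 2 & abs(v) <= w / 2
  }
  m
}

# lookup of mask membership at physical positions (containment oracle)
mask_contains <- function(mask, pts) {
  d <- dim(mask$mask)
  iv <- branchmorph:::.point_to_voxel(as.matrix(pts), mask$voxel_size,
                                      mask$origin)
  ok <- iv[, 1] >= 1 & iv[, 2] >= 1 & iv[, 3] >= 1 &
    iv[, 1] <= d[1] & iv[, 2] <= d[2] & iv[, 3] <= d[3]
  out <- rep(FALSE, nrow(iv))
  lin <- iv[ok, 1] + d[1] * (iv[ok, 2] - 1L) + d[1] * d[2] * (iv[ok, 3] - 1L)
  out[ok] <- mask$mask[lin]
  out
}
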