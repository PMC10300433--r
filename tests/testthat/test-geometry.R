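test_that("isotropic resampling preserves identity, volume and shape", {
  # identity on already-isotropic input
  m <- capsule_mask(L = 40, R = 8, voxel = 2)
  expect_identical(resample_isotropic(m, 2), m)

  # anisotropic ball mask: physical volume preserved within 5%
  vs <- c(1, 1, 2)
  dims <- c(41, 41, 21)
  ctr <- c(20.5, 20.5, 21)
  ball <- array(FALSE, dims)
  for (k in seq_len(dims[3])) for (j in seq_len(dims[2])) {
    x <- (seq_len(dims[1]) - 0.5) * vs[1]
    y <- (j - 0.5) * vs[2]; z <- (k - 0.5) * vs[3]
    ball[, j, k] <- (x - ctr[1])^2 + (y - ctr[2])^2 + (z - ctr[3])^2 <= 15^2
  }
  st <- voxel_stack(list(generic = ball + 0), vs)
  # nearest-neighbour route via a mask container on the resampled grid
  vol0 <- sum(ball) * prod(vs)
  rs <- resample_isotropic(st, 1)
  vol1 <- sum(rs$channels$generic > 0.5) * 1
  expect_lt(abs(vol1 - vol0) / vol0, 0.05)

  # round trip up/down: Jaccard >= 0.9
  mk <- epithelial_mask(ball, 1)  # treat as isotropic for the round trip
  up <- resample_isotropic(mk, 0.5)
  down <- resample_isotropic(up, 1)
  inter <- sum(down$mask & ball)
  union <- sum(down$mask | ball)
  expect_gte(inter / union, 0.9)
})

test_that("mask_from_points builds closed ball unions with all points inside", {
  p1 <- matrix(c(10, 10, 10), 1)
  m <- mask_from_points(p1, radius = 5, voxel_size = 1, closing_radius = 0)
  expect_lt(abs(sum(m$mask) - 4 / 3 * pi * 125) / (4 / 3 * pi * 125), 0.1)

  set.seed(2)
  pts <- cbind(runif(20, 0, 30), runif(20, 0, 30), runif(20, 0, 30))
  m2 <- mask_from_points(pts, radius = 4, voxel_size = 1.5)
  expect_true(all(mask_contains(m2, pts)))

  # two distant points stay two connected components
  p2 <- rbind(c(0, 0, 0), c(100, 0, 0))
  m3 <- mask_from_points(p2, radius = 5, voxel_size = 1, closing_radius = 2)
  expect_equal(max(connected_components(m3)), 2L)
  expect_error(mask_from_points(matrix(numeric(0), 0, 3), 5, 1), "one point")
})

test_that("surface distances match the brute-force Euclidean oracle", {
  # isolated voxel: adjacent background at one voxel
  m <- array(FALSE, c(5, 5, 5)); m[3, 3, 3] <- TRUE
  f <- surface_distance_field(epithelial_mask(m, 1))
  expect_equal(f$values[3, 3, 3], 1)

  # solid cube: exact transform equals the brute-force scan everywhere
  cube <- array(FALSE, c(21, 21, 21)); cube[4:18, 4:18, 4:18] <- TRUE
  em <- epithelial_mask(cube, 1)
  oracle <- bf_surface_distance(cube)
  ex <- surface_distance_field(em, method = "exact")
  expect_lt(max(abs(ex$values - oracle)), 1e-9)
  # chamfer <3,4,5>: documented max relative error <= 8%
  ch <- surface_distance_field(em, method = "chamfer")
  fg <- which(cube)
  relerr <- abs(ch$values[fg] - oracle[fg]) / pmax(oracle[fg], 1e-9)
  expect_lte(max(relerr), 0.08)

  expect_error(surface_distance_field(
    epithelial_mask(array(TRUE, c(3, 3, 3)), 1)), "background")
})

test_that("a shell of nuclei at 4.5 um depth peaks in the 4-5 um bin", {
  p <- scenario_params(n_cells = 200, n_frames = 2, branch_axis_length = 150,
                       tube_radius = 25, seed = 9)
  set.seed(9)
  pts <- place_surface_shell(p, depth = 4.5, n = 300)
  gt <- generate_elongation_scenario(p, mask_frames = 1, mask_voxel = 1)
  f <- surface_distance_field(gt$masks[[1]])
  d <- sample_field(f, pts)
  cells <- data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                      class = "red")
  prof <- distance_profile(cells, distances = d, bin_width = 1)
  expect_equal(unname(prof$bin_lo[which.max(prof$n)]), 4)
})

test_that("geodesic fields agree with Dijkstra and exceed Euclidean", {
  # straight 200 um tube: far end within 2% of its length
  tube <- capsule_mask(L = 200, R = 8, voxel = 2)
  f <- geodesic_distance_field(tube, seed = c(0, 0, 0))
  far <- sample_field(f, matrix(c(200, 0, 0), 1))
  expect_lt(abs(far - 200) / 200, 0.02)
  # seed voxel value is 0
  sv <- branchmorph:::.point_to_voxel(c(0, 0, 0), tube$voxel_size, tube$origin)
  expect_equal(f$values[sv[1], sv[2], sv[3]], 0)

  # voxel-graph Dijkstra oracle on a small capsule
  small <- capsule_mask(L = 24, R = 6, voxel = 2)
  seed_pt <- c(2, 0, 0)
  fs <- geodesic_distance_field(small, seed_pt)
  sv <- branchmorph:::.point_to_voxel(seed_pt, small$voxel_size, small$origin)
  oracle <- bf_geodesic(small$mask, as.integer(sv),
                        spacing = rep(small$voxel_size, 3))
  fg <- which(small$mask)
  expect_lt(max(abs(fs$values[fg] - oracle[fg])), 1e-9)

  # U-shaped mask: geodesic between arm tips >= 2x their Euclidean distance
  u <- array(FALSE, c(30, 30, 3))
  u[1:30, 1:4, ] <- TRUE    # base
  u[1:4, 1:30, ] <- TRUE    # left arm
  u[27:30, 1:30, ] <- TRUE  # right arm
  um <- epithelial_mask(u, 1)
  fu <- geodesic_distance_field(um, seed = c(1.5, 29, 1.5))
  tip2 <- sample_field(fu, matrix(c(28.5, 29, 1.5), 1))
  expect_gte(tip2, 2 * (28.5 - 1.5))

  # snapping and failure modes
  expect_error(geodesic_distance_field(small, c(500, 0, 0), snap_radius = 2),
               "snap_radius")
})

test_that("surface distance never exceeds the geodesic from a surface seed", {
  m <- capsule_mask(L = 40, R = 10, voxel = 2)
  sf <- surface_distance_field(m)
  gf <- geodesic_distance_field(m, seed = c(20, 0, 10))  # on the wall
  fg <- which(m$mask)
  ok <- is.finite(gf$values[fg])
  # within chamfer/discretization slack: surface distance <= geodesic + 2 voxels
  expect_true(all(sf$values[fg][ok] <=
                    gf$values[fg][ok] + 2 * m$voxel_size + 1e-9))
})

test_that("compartment classification honors the 6 um boundary exactly", {
  vals <- array(10, c(9, 9, 3))
  vals[2, , ] <- 6.0
  vals[5, , ] <- 6.01
  f <- scalar_field(vals, 1, kind = "surface_distance")
  cells <- data.frame(x = c(1.5, 4.5, 7.5), y = 4.5, z = 1.5)
  out <- classify_compartment(cells, f, threshold = 6)
  expect_equal(out$compartment, c("basal", "inner", "inner"))
  expect_equal(attr(out, "threshold_used"), 6)
  # all cells on the surface shell -> 100% basal
  shell <- data.frame(x = rep(1.5, 5), y = seq(1.5, 5.5, 1), z = 1.5)
  expect_true(all(classify_compartment(shell, f, 6)$compartment == "basal"))
  # labels partition assigned cells
  expect_true(all(out$compartment %in% c("basal", "inner", "unassigned")))
})

test_that("domain assignment applies pooling radii, precedence and tie-breaks", {
  lm <- landmark_set(frame = 1,
                     name = c("leading_edge", "duct_center"),
                     x = c(200, 30), y = 0, z = 0)
  cells <- data.frame(x = c(120, 80, 35, 150), y = 0, z = 0)
  out <- assign_domains(cells, lm, tip_extent = 100, center_radius = 50)
  # 80/50 um from the tip -> tip; 120 and 165 um from the tip but within the
  # 50 um duct radius -> duct
  expect_equal(out$domain, c("tip", "duct", "duct", "tip"))
  cells2 <- data.frame(x = c(70), y = 0, z = 0)  # 130 from tip, 40 from duct
  expect_equal(assign_domains(cells2, lm)$domain, "duct")

  # precedence: a cell in both tip and branch-point ranges is a tip cell
  lm2 <- rbind(lm, landmark_set(1, "branch_point_center", 180, 0, 0))
  cells3 <- data.frame(x = 170, y = 0, z = 0)
  expect_equal(suppressWarnings(assign_domains(cells3, lm2))$domain, "tip")

  # bifurcating split with the documented tie-break (tie -> daughter_tip)
  lmb <- landmark_set(frame = 1,
                      name = c("leading_edge", "duct_center",
                               "daughter_tip_1", "daughter_tip_2", "cleft"),
                      x = c(200, 30, 210, 210, 190),
                      y = c(0, 0, 20, -20, 0), z = 0)
  cellsb <- data.frame(x = c(210, 191, 200), y = c(18, 1, 10), z = 0)
  outb <- assign_domains(cellsb, lmb)
  expect_equal(outb$domain[1], "daughter_tip")
  expect_equal(outb$domain[2], "cleft_region")
  tie <- data.frame(x = 200, y = 10, z = 0)  # equidistant by construction?
  dtie <- assign_domains(tie, lmb)
  expect_true(dtie$domain %in% c("daughter_tip", "cleft_region"))
  # exact tie: place a cell equidistant from cleft and daughter 1
  lmt <- landmark_set(1, c("leading_edge", "daughter_tip_1", "daughter_tip_2",
                           "cleft"),
                      x = c(0, 10, 10, -10), y = c(0, 0, 0, 0), z = 0)
  expect_equal(suppressWarnings(assign_domains(
    data.frame(x = 0, y = 0, z = 0), lmt))$domain, "daughter_tip")

  # relabeling is idempotent
  again <- assign_domains(out[, c("x", "y", "z")], lm)
  expect_equal(again$domain, out$domain)
})

test_that("tip boundary estimation finds steps and falls back when flat", {
  set.seed(3)
  n <- 600
  d <- runif(n, 0, 200)
  cls <- ifelse(runif(n) < ifelse(d < 80, 0.6, 0.2), "green", "red")
  cells <- data.frame(class = cls)
  b <- estimate_tip_boundary(cells, distances = d, window = 30, step = 10)
  expect_lt(abs(as.numeric(b) - 80), 30)
  # flat profile: documented 100 um fallback
  cls_flat <- ifelse(runif(n) < 0.4, "green", "red")
  bf <- estimate_tip_boundary(data.frame(class = cls_flat), distances = d)
  expect_equal(as.numeric(bf), 100)
  expect_true(attr(bf, "flat"))
  expect_error(estimate_tip_boundary(data.frame(class = "green"),
                                     distances = 1), "too few")
})
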