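test_that("tip width is the maximal perpendicular chord of the projection", {
  # axis-aligned 30 x 80 rectangle, axis along the long side -> width 30
  r <- rasterize_rect(30, 80, 0)
  expect_lt(abs(measure_tip_width(r, axis = c(1, 0)) - 30), 1.5)
  # same rectangle rotated 37 degrees, with the rotated axis
  th <- 37 * pi / 180
  r2 <- rasterize_rect(30, 80, 37)
  w2 <- measure_tip_width(r2, axis = c(cos(th), sin(th)))
  expect_lt(abs(w2 - 30), 2)
  # disk of radius 20: any axis gives ~2r
  n <- 60
  disk <- outer(seq_len(n) - 0.5 - n / 2, seq_len(n) - 0.5 - n / 2,
                function(a, b) a^2 + b^2 <= 20^2)
  expect_lt(abs(measure_tip_width(disk, axis = c(1, 0)) - 40), 1.5)
  expect_lt(abs(measure_tip_width(disk, axis = c(0.6, 0.8)) - 40), 1.5)
  expect_error(measure_tip_width(matrix(FALSE, 5, 5)), "empty")
})

test_that("cleft metrics reproduce closed-form constructions", {
  cm <- cleft_metrics(c(-1, 1, 0), c(1, 1, 0), c(0, 0, 0))
  expect_equal(cm$angle, 90)
  expect_equal(cm$depth, 1)
  # cleft on the chord: depth 0, angle 180 (boundary case, not an error)
  cm2 <- cleft_metrics(c(-2, 0, 0), c(3, 0, 0), c(1, 0, 0))
  expect_equal(cm2$angle, 180)
  expect_equal(cm2$depth, 0)
  expect_error(cleft_metrics(c(0, 0, 0), c(0, 0, 0), c(1, 1, 1)), "distinct")

  # independent vector-algebra recomputation on random triples
  set.seed(6)
  for (q in 1:25) {
    a <- rnorm(3); b <- rnorm(3); cc <- rnorm(3)
    cm3 <- cleft_metrics(a, b, cc)
    u <- a - cc; v <- b - cc
    ang <- acos(max(-1, min(1, sum(u * v) /
                              sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
    # depth via the cross-product area formula: 2*area / base
    ab <- b - a
    cr <- c(ab[2] * u[3] - ab[3] * u[2], ab[3] * u[1] - ab[1] * u[3],
            ab[1] * u[2] - ab[2] * u[1])
    depth <- sqrt(sum(cr^2)) / sqrt(sum(ab^2))
    expect_lt(abs(cm3$angle - ang), 1e-9)
    expect_lt(abs(cm3$depth - depth), 1e-9)
  }
})

test_that("cleft metrics are invariant under rigid motion", {
  set.seed(7)
  a <- c(1, 2, 3); b <- c(4, 0, 1); cc <- c(2, -1, 0)
  base <- cleft_metrics(a, b, cc)
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3,
              byrow = TRUE)
  t3 <- c(5, -2, 8)
  rot <- function(p) as.numeric(R %*% p + t3)
  moved <- cleft_metrics(rot(a), rot(b), rot(cc))
  expect_lt(abs(moved$angle - base$angle), 1e-6)
  expect_lt(abs(moved$depth - base$depth), 1e-6)
})

test_that("elongation series computes finite-difference rates", {
  es <- elongation_series(c(100, 110, 120), times_h = c(0, 3, 6))
  expect_equal(es$rate, c(10 / 3, 10 / 3))
  expect_equal(elongation_series(c(50, 50, 50), frame_interval = 60)$rate,
               c(0, 0))
  expect_error(elongation_series(c(1, 2), times_h = c(2, 1)), "increasing")
  expect_error(elongation_series(100), "2 frames")
})

test_that("measured elongation matches the generator's true front advance", {
  p <- scenario_params(n_cells = 400, n_frames = 15, branch_axis_length = 200,
                       tube_radius = 30, seed = 3)
  gt <- generate_elongation_scenario(p, mask_frames = FALSE)
  lm <- gt$landmarks[gt$landmarks$name == "leading_edge", ]
  lm <- lm[order(lm$frame), ]
  es <- elongation_series(lm$x, frame_interval = p$frame_interval)
  true_adv <- vapply(gt$geometry, function(g) g$L + g$cap_r, numeric(1))
  true_rate <- mean(diff(true_adv)) / (p$frame_interval / 60)
  expect_lt(abs(es$mean_rate - true_rate) / true_rate, 0.15)
  expect_gt(es$mean_rate, 0)
})

test_that("branch length follows within-mask geodesics", {
  tube <- capsule_mask(L = 150, R = 8, voxel = 2)
  bl <- branch_length(tube, tip_landmark = c(150, 0, 0),
                      origin_landmark = c(0, 0, 0))
  expect_lt(abs(bl - 150) / 150, 0.02)
  expect_equal(branch_length(tube, c(10, 0, 0), c(10, 0, 0)), 0)

  # L-shaped tube, arms 100 + 100: geodesic ~200, >= 1.3x Euclidean
  Lm <- array(FALSE, c(60, 60, 5))
  Lm[1:55, 1:5, ] <- TRUE
  Lm[51:55, 1:55, ] <- TRUE
  em <- epithelial_mask(Lm, 2)
  g <- branch_length(em, tip_landmark = c(5, 5, 5),
                     origin_landmark = c(105, 105, 5))
  eucl <- sqrt(sum((c(5, 5, 5) - c(105, 105, 5))^2))
  expect_gt(g, 1.3 * eucl)
  expect_lt(abs(g - 200) / 200, 0.10)
})

test_that("sphericity evaluates the isoperimetric closed form", {
  r <- 3.2
  expect_equal(sphericity(4 / 3 * pi * r^3, 4 * pi * r^2), 1, tolerance = 1e-12)
  expect_equal(sphericity(1, 6), pi^(1 / 3) * 6^(2 / 3) / 6, tolerance = 1e-12)
  expect_lt(abs(sphericity(1, 6) - 0.8060), 5e-4)
  # prolate spheroid (spindle) of equal volume scores below the ball
  a <- 1; c3 <- 4  # semi-axes: a = b = 1, c = 4
  V <- 4 / 3 * pi * a^2 * c3
  e <- sqrt(1 - a^2 / c3^2)
  A <- 2 * pi * a^2 * (1 + c3 / (a * e) * asin(e))
  expect_lt(sphericity(V, A), 1)
  expect_error(sphericity(0, 1), "> 0")
})

test_that("bifurcation cleft narrows and deepens after T0", {
  gt <- generate_bifurcation_scenario(small_bifurc_params(seed = 6),
                                      mask_frames = FALSE)
  lm <- gt$landmarks
  frames <- sort(unique(lm$frame[lm$name == "cleft"]))
  geoms <- lapply(frames, function(fr) {
    lf <- lm[lm$frame == fr, ]
    g <- function(nm) unlist(lf[match(nm, lf$name), c("x", "y", "z")])
    cleft_metrics(g("daughter_tip_1"), g("daughter_tip_2"), g("cleft"))
  })
  ang <- vapply(geoms, `[[`, numeric(1), "angle")
  dep <- vapply(geoms, `[[`, numeric(1), "depth")
  expect_true(all(diff(ang) <= 1e-9))
  expect_true(all(diff(dep) >= -1e-9))
})
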