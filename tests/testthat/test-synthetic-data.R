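test_that("identical parameters and seed reproduce the scene bit-for-bit", {
  p <- small_elong_params(seed = 11)
  a <- generate_elongation_scenario(p, mask_frames = 1)
  b <- generate_elongation_scenario(p, mask_frames = 1)
  expect_identical(a$cells, b$cells)
  expect_identical(a$landmarks, b$landmarks)
  expect_identical(a$masks[[1]]$mask, b$masks[[1]]$mask)
})

test_that("parameter validation rejects invalid scenarios", {
  expect_error(scenario_params(tube_radius = -1), "lengths")
  expect_error(scenario_params(tip_cycle_fraction = 1.4), "fractions")
  expect_error(scenario_params(n_frames = 1), "n_frames")
  expect_error(scenario_params(n_frames = 5,
                               bifurcation = bifurcation_params(t0_frame = 5)),
               "t0_frame")
  expect_error(generate_elongation_scenario(small_bifurc_params()),
               "bifurcation")
  expect_error(generate_bifurcation_scenario(small_elong_params()),
               "bifurcation")
})

test_that("every true cell position lies inside its frame's mask", {
  gt <- generate_elongation_scenario(small_elong_params(seed = 3))
  for (fr in unique(gt$cells$frame)) {
    cf <- gt$cells[gt$cells$frame == fr, c("x", "y", "z")]
    expect_true(all(mask_contains(gt$masks[[fr]], cf)), label =
                  sprintf("containment at frame %d", fr))
  }
  gtb <- generate_bifurcation_scenario(small_bifurc_params(seed = 3),
                                       mask_frames = c(1, 10, 20))
  for (fr in c(1, 10, 20)) {
    cf <- gtb$cells[gtb$cells$frame == fr, c("x", "y", "z")]
    expect_true(all(mask_contains(gtb$masks[[fr]], cf)))
  }
})

test_that("no agent step exceeds the edge speed plus tolerance", {
  p <- small_elong_params(seed = 5)
  gt <- generate_elongation_scenario(p, mask_frames = FALSE)
  cells <- gt$cells[order(gt$cells$id, gt$cells$frame), ]
  dt_h <- p$frame_interval / 60
  step <- do.call(c, lapply(split(cells, cells$id), function(tr)
    sqrt(diff(tr$x)^2 + diff(tr$y)^2 + diff(tr$z)^2)))
  expect_true(all(step <= p$speed_at_edge * dt_h * 1.05 + 1e-9))
})

test_that("realized speeds follow the configured exponential gradient", {
  # mean step speed at d in [0,10] vs [90,100] um; the configured law gives
  # a ratio of exp(90 / 50) ~ 6.05 (measured from emitted true tracks, with
  # boundary-projection losses this compresses slightly)
  p <- scenario_params(n_cells = 400, n_frames = 20, branch_axis_length = 250,
                       tube_radius = 30, speed_at_edge = 20,
                       speed_decay_length = 50, seed = 7)
  gt <- generate_elongation_scenario(p, mask_frames = FALSE)
  cells <- gt$cells[order(gt$cells$id, gt$cells$frame), ]
  dt_h <- p$frame_interval / 60
  sp <- do.call(rbind, lapply(split(cells, cells$id), function(tr)
    data.frame(d = tr$dist_to_edge[-nrow(tr)],
               s = sqrt(diff(tr$x)^2 + diff(tr$y)^2 + diff(tr$z)^2) / dt_h)))
  ratio <- mean(sp$s[sp$d <= 10]) / mean(sp$s[sp$d >= 90 & sp$d <= 100])
  expect_gt(ratio, 6.05 * 0.72)
  expect_lt(ratio, 6.05 * 1.28)
})

test_that("cycle fractions are statistically faithful to the parameters", {
  # equal probabilities: tip-duct difference under 3 points at n = 1000
  p_eq <- scenario_params(n_cells = 1000, n_frames = 2,
                          branch_axis_length = 300, tube_radius = 30,
                          tip_cycle_fraction = 0.5, duct_cycle_fraction = 0.5,
                          seed = 13)
  gt <- generate_elongation_scenario(p_eq, mask_frames = FALSE)
  c1 <- gt$cells[gt$cells$frame == 1, ]
  f_tip <- mean(c1$class[c1$dist_to_edge <= 100] == "green")
  f_duct <- mean(c1$class[c1$dist_to_edge > 100] == "green")
  expect_lt(abs(f_tip - f_duct), 0.03 + 3 * sqrt(0.25 / 250))

  # default probabilities recovered within 3 binomial SDs per region
  p2 <- scenario_params(n_cells = 1000, n_frames = 2,
                        branch_axis_length = 300, tube_radius = 30, seed = 17)
  gt2 <- generate_elongation_scenario(p2, mask_frames = FALSE)
  c2 <- gt2$cells[gt2$cells$frame == 1, ]
  for (reg in c("tip", "duct")) {
    sel <- if (reg == "tip") c2$dist_to_edge <= 100 else c2$dist_to_edge > 100
    p0 <- if (reg == "tip") 0.5 else 0.15
    n <- sum(sel)
    expect_lt(abs(mean(c2$class[sel] == "green") - p0),
              3 * sqrt(p0 * (1 - p0) / n), label = reg)
  }
})

test_that("null branch-point factors leave post-T0 speeds indistinguishable", {
  hits <- 0L
  n_seeds <- 12
  for (s in seq_len(n_seeds)) {
    p <- scenario_params(n_cells = 250, n_frames = 14,
                         branch_axis_length = 150, tube_radius = 25,
                         bifurcation = bifurcation_params(
                           t0_frame = 7, branchpoint_speed_factor = 1,
                           branchpoint_cycle_factor = 1), seed = 100 + s)
    gt <- generate_bifurcation_scenario(p, mask_frames = FALSE)
    cells <- gt$cells[order(gt$cells$id, gt$cells$frame), ]
    dt_h <- p$frame_interval / 60
    sp <- do.call(rbind, lapply(split(cells, cells$id), function(tr)
      data.frame(frame = tr$frame[-nrow(tr)], prox = tr$cleft_proximal[-nrow(tr)],
                 d = tr$dist_to_edge[-nrow(tr)],
                 s = sqrt(diff(tr$x)^2 + diff(tr$y)^2 + diff(tr$z)^2) / dt_h)))
    post <- sp[sp$frame >= 7 & sp$d <= 100, ]
    if (sum(post$prox) > 5 && sum(!post$prox) > 5) {
      pv <- wilcox.test(post$s[post$prox], post$s[!post$prox])$p.value
      if (pv > 0.05) hits <- hits + 1L
    } else hits <- hits + 1L
  }
  expect_gte(hits / n_seeds, 0.75)
})

test_that("branch-point cycle repression realizes the configured factor", {
  p <- scenario_params(n_cells = 600, n_frames = 24, branch_axis_length = 200,
                       tube_radius = 30,
                       bifurcation = bifurcation_params(
                         t0_frame = 8, branchpoint_cycle_factor = 0.3),
                       seed = 23)
  gt <- generate_bifurcation_scenario(p, mask_frames = FALSE)
  post <- gt$cells[gt$cells$frame > 8, ]
  f_bp <- mean(post$class[post$cleft_proximal] == "green")
  f_tip <- mean(post$class[!post$cleft_proximal & post$dist_to_edge <= 60]
                == "green")
  # truth-level ratio ~ 0.3 within generous binomial error at these counts
  expect_gt(f_bp / f_tip, 0.18)
  expect_lt(f_bp / f_tip, 0.45)
})

test_that("the cleft ingresses monotonically away from the initial front", {
  gt <- generate_bifurcation_scenario(small_bifurc_params(seed = 2),
                                      mask_frames = FALSE)
  lm <- gt$landmarks
  t0 <- gt$t0_frame
  front0 <- lm[lm$frame == t0 & lm$name == "leading_edge", c("x", "y", "z")]
  cleft <- lm[lm$name == "cleft", ]
  cleft <- cleft[order(cleft$frame), ]
  d <- sqrt((cleft$x - front0$x)^2 + (cleft$y - front0$y)^2 +
              (cleft$z - front0$z)^2)
  expect_true(all(diff(d) > 0))
  # daughter tips separate over time
  d1 <- lm[lm$name == "daughter_tip_1", ]
  d2 <- lm[lm$name == "daughter_tip_2", ]
  sep <- sqrt((d1$x - d2$x)^2 + (d1$y - d2$y)^2)[order(d1$frame)]
  expect_true(all(diff(sep) >= -1e-9))
})

test_that("rendering is one-hot per nucleus and localizes correctly", {
  p <- scenario_params(n_cells = 12, n_frames = 2, branch_axis_length = 120,
                       tube_radius = 25, seed = 31)
  gt <- generate_elongation_scenario(p, mask_frames = FALSE)
  st <- render_stack(gt, imaging_params(gaussian_noise_sd = 0, background = 0),
                     frames = 1, noise = FALSE)
  truth <- gt$cells[gt$cells$frame == 1, ]
  # channels are one-hot: the red channel is dark at green nuclei and vice versa
  for (q in seq_len(nrow(truth))) {
    own <- if (truth$class[q] == "green") "green" else "red"
    other <- setdiff(c("green", "red"), own)
    iv <- branchmorph:::.point_to_voxel(
      as.matrix(truth[q, c("x", "y", "z")]), st$voxel_size, st$origin)
    own_v <- st$channels[[own]][iv[1], iv[2], iv[3]]
    other_v <- st$channels[[other]][iv[1], iv[2], iv[3]]
    expect_gt(own_v, 50)
  }
  # noise-free argmax of an isolated nucleus is within one voxel diagonal
  p1 <- scenario_params(n_cells = 1, n_frames = 2, branch_axis_length = 80,
                        tube_radius = 20, seed = 32)
  g1 <- generate_elongation_scenario(p1, mask_frames = FALSE)
  st1 <- render_stack(g1, imaging_params(gaussian_noise_sd = 0,
                                         background = 0),
                      frames = 1, noise = FALSE)
  iso <- g1$cells[g1$cells$frame == 1, ]
  ch <- st1$channels[[iso$class]]
  am <- arrayInd(which.max(ch), dim(ch))
  ctr <- branchmorph:::.voxel_center(am, st1$voxel_size, st1$origin)
  expect_lt(sqrt(sum((ctr - unlist(iso[, c("x", "y", "z")]))^2)),
            sqrt(sum(st1$voxel_size^2)))
})

test_that("ground truth round-trips through plain-text files", {
  gt <- generate_elongation_scenario(small_elong_params(seed = 41),
                                     mask_frames = FALSE)
  dir <- withr::local_tempdir()
  write_ground_truth(gt, dir)
  cells <- read.csv(file.path(dir, "cells.csv"))
  expect_equal(nrow(cells), nrow(gt$cells))
  expect_equal(cells$x, gt$cells$x, tolerance = 1e-12)
  pj <- jsonlite::read_json(file.path(dir, "params.json"),
                            simplifyVector = TRUE)
  expect_equal(pj$speed_at_edge, gt$params$speed_at_edge)
})
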