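test_that("drift correction cancels known drift exactly", {
  set.seed(4)
  base <- data.frame(frame = rep(1:10, each = 5), id = rep(1:5, 10),
                     x = runif(50, 0, 100), y = runif(50, 0, 100),
                     z = runif(50, 0, 20))
  ref0 <- data.frame(frame = 1:10, x = 10, y = 10, z = 5)
  # stationary reference: identity
  out0 <- drift_correct(base, ref0)
  expect_equal(out0$x, base$x)

  # constant drift added to points and reference cancels exactly
  drift <- data.frame(frame = 1:10, dx = (0:9) * 2, dy = 0, dz = 0)
  shifted <- base
  m <- match(shifted$frame, drift$frame)
  shifted$x <- shifted$x + drift$dx[m]
  refd <- ref0
  refd$x <- refd$x + drift$dx
  out <- drift_correct(shifted, refd)
  expect_equal(out$x, base$x, tolerance = 1e-12)

  # sinusoidal drift: corrected positions equal the originals up to the
  # frame-1 anchor offset (correction pins the reference at its frame-1
  # location), i.e. the residual reference motion is < 1e-6
  refs <- ref0
  refs$y <- refs$y + 5 * sin(1:10)
  shifted2 <- base
  shifted2$y <- shifted2$y + 5 * sin(shifted2$frame)
  out2 <- drift_correct(shifted2, refs)
  expect_lt(max(abs((out2$y - base$y) - 5 * sin(1))), 1e-6)
  drift2 <- attr(out2, "drift")
  ref_residual <- (refs$y - drift2$dy) - refs$y[1]
  expect_lt(max(abs(ref_residual)), 1e-6)

  expect_error(drift_correct(base, ref0[1:4, ]), "50%")
})

test_that("linking respects caps, durations and the no-gap rule", {
  # 5 um/frame over 8 frames at 20 min: one track, 2.33 h, retained
  sp <- data.frame(frame = 1:8, id = 1L, class = "green",
                   x = (0:7) * 5, y = 0, z = 0)
  tr <- link_tracks(sp, frame_interval = 20)
  expect_equal(length(unique(tr$track_id)), 1L)
  mt <- track_metrics(tr, 20)
  expect_equal(mt$duration_h, 7 * 20 / 60)
  expect_equal(mt$velocity, 15)

  # 10 um steps exceed the green 9.3 um cap: fragments all below 2 h, excluded
  sp2 <- data.frame(frame = 1:8, id = 1L, class = "green",
                    x = (0:7) * 10, y = 0, z = 0)
  tr2 <- link_tracks(sp2, frame_interval = 20)
  expect_equal(nrow(tr2), 0L)
  expect_equal(attr(tr2, "n_excluded_short"), 8L)

  # the same geometry under the red 8 um cap also refuses links
  sp3 <- transform(sp2, class = "red", x = (0:7) * 8.5)
  expect_equal(nrow(link_tracks(sp3, frame_interval = 20)), 0L)
  # but 8.0 um steps are allowed for red (cap inclusive)
  sp4 <- transform(sp2, class = "red", x = (0:7) * 8)
  expect_equal(length(unique(link_tracks(sp4, frame_interval = 20)$track_id)),
               1L)
  expect_error(link_tracks(rbind(sp, sp), frame_interval = 20), "duplicate")
})

test_that("no linked step exceeds its class cap and tracks have no gaps", {
  set.seed(12)
  frames <- 1:10
  sp <- do.call(rbind, lapply(frames, function(fr)
    data.frame(frame = fr, id = 1:40,
               class = rep(c("red", "green"), 20),
               x = runif(40, 0, 150), y = runif(40, 0, 60),
               z = runif(40, 0, 20))))
  tr <- link_tracks(sp, frame_interval = 20, min_duration_h = 0)
  caps <- c(red = 8, green = 9.3)
  for (tid in unique(tr$track_id)) {
    t1 <- tr[tr$track_id == tid, ]
    t1 <- t1[order(t1$frame), ]
    expect_true(all(diff(t1$frame) == 1L))
    if (nrow(t1) > 1) {
      steps <- sqrt(diff(t1$x)^2 + diff(t1$y)^2 + diff(t1$z)^2)
      expect_true(all(steps <= caps[[t1$class[1]]] + 1e-9))
    }
  }
})

test_that("the linker equals the exhaustive minimal-cost matching oracle", {
  set.seed(21)
  cap <- 9.3
  for (rep_i in 1:20) {
    nA <- sample(2:5, 1); nB <- sample(2:5, 1)
    A <- cbind(runif(nA, 0, 15), runif(nA, 0, 15), 0)
    B <- cbind(runif(nB, 0, 15), runif(nB, 0, 15), 0)
    got <- branchmorph:::.match_pair(A, B, cap, method = "optimal")
    oracle <- bf_best_matching(A, B, cap)
    # equal objective value (multiple optima may differ in assignment)
    cost <- function(asg) {
      linked <- which(!is.na(asg))
      sum(sqrt(rowSums((A[linked, , drop = FALSE] -
                          B[asg[linked], , drop = FALSE])^2))) +
        cap * (sum(is.na(asg)) + (nB - length(linked)))
    }
    expect_equal(cost(got), oracle$cost, tolerance = 1e-9)
  }
  # a crossing configuration where greedy is suboptimal
  A <- rbind(c(0, 0, 0), c(4, 0, 0))
  B <- rbind(c(3, 0, 0), c(7, 0, 0))
  got <- branchmorph:::.match_pair(A, B, cap = 9)
  expect_equal(got, c(1L, 2L))
})

test_that("track identity is near-perfect when spacing exceeds twice the cap", {
  set.seed(33)
  n <- 30
  # nuclei on a 25 um grid (spacing >> 2 x 9.3), jittered small random walks
  base <- expand.grid(x = seq(0, 125, 25), y = seq(0, 100, 25))[1:n, ]
  frames <- 1:10
  truth <- do.call(rbind, lapply(frames, function(fr)
    data.frame(frame = fr, id = 1:n, class = "green",
               x = base$x + cumsum(rnorm(n, 0, 1))[n] * 0 +
                 rnorm(n, 0, 2),
               y = base$y + rnorm(n, 0, 2), z = 0)))
  tr <- link_tracks(truth, frame_interval = 20, min_duration_h = 0)
  # every reconstructed track must follow a single true id
  purity <- vapply(split(tr, tr$track_id), function(t1) {
    ids <- truth$id[match(paste(t1$frame, round(t1$x, 6)),
                          paste(truth$frame, round(truth$x, 6)))]
    max(table(ids)) / length(ids)
  }, numeric(1))
  expect_gte(mean(purity == 1), 0.99)
})

test_that("track metrics follow their defining formulas", {
  tr <- data.frame(track_id = 1L, class = "green", frame = 1:3,
                   x = c(0, 3, 6), y = c(0, 4, 8), z = 0)
  mt <- track_metrics(tr, frame_interval = 20)
  expect_equal(mt$velocity, 15)
  expect_equal(mt$net_velocity, 15)
  expect_equal(mt$straightness, 1)

  # closed loop: straightness 0, net velocity 0, velocity > 0
  loop <- data.frame(track_id = 1L, class = "red", frame = 1:5,
                     x = c(0, 5, 5, 0, 0), y = c(0, 0, 5, 5, 0), z = 0)
  ml <- track_metrics(loop, 20)
  expect_equal(ml$straightness, 0)
  expect_equal(ml$net_velocity, 0)
  expect_gt(ml$velocity, 0)
  expect_error(track_metrics(data.frame(track_id = 1, class = "red",
                                        frame = 1, x = 0, y = 0, z = 0), 20),
               "single point")

  # net velocity <= velocity for random tracks (triangle inequality)
  set.seed(2)
  rnd <- do.call(rbind, lapply(1:50, function(tid)
    data.frame(track_id = tid, class = "red", frame = 1:8,
               x = cumsum(rnorm(8, 0, 2)), y = cumsum(rnorm(8, 0, 2)),
               z = cumsum(rnorm(8, 0, 1)))))
  mr <- track_metrics(rnd, 20)
  expect_true(all(mr$net_velocity <= mr$velocity + 1e-12))
})

test_that("mean straightness of unbiased random walks decreases with length", {
  set.seed(44)
  mk <- function(len, n = 300) {
    m <- vapply(seq_len(n), function(i) {
      P <- cbind(cumsum(rnorm(len)), cumsum(rnorm(len)), cumsum(rnorm(len)))
      sqrt(sum((P[len, ] - P[1, ])^2)) / sum(sqrt(rowSums(diff(P)^2)))
    }, numeric(1))
    mean(m)
  }
  s10 <- mk(10); s40 <- mk(40)
  expect_gt(s10, s40)
})

test_that("displacement vectors and flow summaries follow the sign conventions", {
  tr <- data.frame(track_id = c(1, 1, 2, 2), class = "green",
                   frame = c(1, 2, 1, 2),
                   x = c(0, 10, 5, 5), y = c(0, 0, 5, 5), z = 0)
  dv <- displacement_vector(tr)
  expect_equal(unname(unlist(dv[1, c("dx", "dy", "dz")])), c(10, 0, 0))
  expect_true(dv$zero[2])

  tt <- data.frame(track_id = 1:4, class = c("green", "red", "green", "red"),
                   start_domain = c("tip", "duct", "tip", "tip"),
                   end_domain = c("duct", "tip", "tip", "branch_point"),
                   start_compartment = c("basal", "inner", "basal", "basal"),
                   end_compartment = c("inner", "inner", "basal", "basal"),
                   start_edge_dist = c(50, 150, 30, 40),
                   end_edge_dist = c(120, 60, 30, 45))
  fl <- flow_analysis(tt)
  expect_equal(fl$transitions$tip_to_duct, 0.25)
  expect_equal(fl$transitions$duct_to_tip, 0.25)
  expect_equal(fl$transitions$basal_to_inner, 0.25)
  # start - end: positive = moved closer to the edge
  expect_equal(fl$delta_edge$delta_edge, c(-70, 90, 0, -5))
  expect_equal(fl$branch_flux$red[["into_branch_point"]], 0.5)
})
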