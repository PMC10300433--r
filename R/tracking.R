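#' Rigid drift correction against a reference point
#'
#' Translates all positions so the reference (e.g., the gland origin, marked
#' by a stationary bright cell cluster) stays at its first-frame location.
#' Sparsely annotated references are linearly interpolated across frames; an
#' error is raised when the reference is annotated in fewer than half of the
#' frames.
#'
#' @param cells cell/spot table with frame, x, y, z.
#' @param reference data.frame with frame, x, y, z of the reference per
#'   (some) frames.
#' @return `cells` with corrected coordinates; attribute `drift` holds the
#'   per-frame translation applied.
#' @export
drift_correct <- function(cells, reference) {
  frames <- sort(unique(cells$frame))
  have <- frames %in% reference$frame
  if (mean(have) < 0.5)
    stop("reference missing in more than 50% of frames")
  ref <- reference[order(reference$frame), ]
  interp <- function(col) approx(ref$frame, ref[[col]], xout = frames,
                                 rule = 2)$y
  rx <- interp("x"); ry <- interp("y"); rz <- interp("z")
  drift <- data.frame(frame = frames,
                      dx = rx - rx[1], dy = ry - ry[1], dz = rz - rz[1])
  m <- match(cells$frame, frames)
  cells$x <- cells$x - drift$dx[m]
  cells$y <- cells$y - drift$dy[m]
  cells$z <- cells$z - drift$dz[m]
  attr(cells, "drift") <- drift
  cells
}

# ---------------------------------------------------------------------------
# frame-pair assignment: minimize sum(linked distances) + cap * (#unlinked),
# links only allowed at distance <= cap. Exact by branch and bound within
# connected components of the candidate graph; large components fall back to
# greedy nearest-pair linking.
.match_pair <- function(A, B, cap, method = "optimal", exact_limit = 12L) {
  nA <- nrow(A); nB <- nrow(B)
  if (nA == 0L || nB == 0L) return(integer(0))
  D <- matrix(Inf, nA, nB)
  for (q in seq_len(nA))
    D[q, ] <- sqrt((B[, 1] - A[q, 1])^2 + (B[, 2] - A[q, 2])^2 +
                     (B[, 3] - A[q, 3])^2)
  D[D > cap] <- Inf
  assign_out <- rep(NA_integer_, nA)

  if (method == "greedy") {
    ord <- order(D)
    usedA <- logical(nA); usedB <- logical(nB)
    for (t in ord) {
      if (!is.finite(D[t])) break
      i <- (t - 1L) %% nA + 1L
      j <- (t - 1L) %/% nA + 1L
      if (!usedA[i] && !usedB[j]) {
        assign_out[i] <- j
        usedA[i] <- TRUE; usedB[j] <- TRUE
      }
    }
    return(assign_out)
  }

  # connected components over the bipartite candidate graph
  compA <- rep(0L, nA); compB <- rep(0L, nB)
  ncomp <- 0L
  for (s in seq_len(nA)) {
    if (compA[s] != 0L) next
    ncomp <- ncomp + 1L
    qa <- s
    compA[s] <- ncomp
    qb <- integer(0)
    while (length(qa) || length(qb)) {
      if (length(qa)) {
        i <- qa[1]; qa <- qa[-1]
        js <- which(is.finite(D[i, ]) & compB == 0L)
        compB[js] <- ncomp
        qb <- c(qb, js)
      } else {
        j <- qb[1]; qb <- qb[-1]
        is <- which(is.finite(D[, j]) & compA == 0L)
        compA[is] <- ncomp
        qa <- c(qa, is)
      }
    }
  }

  for (cc in seq_len(ncomp)) {
    ia <- which(compA == cc)
    jb <- which(compB == cc)
    if (length(jb) == 0L) next
    if (length(ia) + length(jb) > exact_limit) {
      # large tangle: greedy within the component
      sub <- D[ia, jb, drop = FALSE]
      ord <- order(sub)
      usedA <- logical(length(ia)); usedB <- logical(length(jb))
      for (t in ord) {
        if (!is.finite(sub[t])) break
        i <- (t - 1L) %% length(ia) + 1L
        j <- (t - 1L) %/% length(ia) + 1L
        if (!usedA[i] && !usedB[j]) {
          assign_out[ia[i]] <- jb[j]
          usedA[i] <- TRUE; usedB[j] <- TRUE
        }
      }
    } else {
      sub <- D[ia, jb, drop = FALSE]
      best <- .bb_assign(sub, cap)
      assign_out[ia] <- ifelse(is.na(best), NA_integer_, jb[best])
    }
  }
  assign_out
}

# branch-and-bound exact assignment on a small cost matrix; unmatched rows and
# columns each cost `cap`
.bb_assign <- function(D, cap) {
  n <- nrow(D); m <- ncol(D)
  best_cost <- Inf
  best <- rep(NA_integer_, n)
  cur <- rep(NA_integer_, n)
  usedB <- logical(m)
  rec <- function(i, cost) {
    if (cost >= best_cost) return()
    if (i > n) {
      total <- cost + cap * sum(!usedB)
      if (total < best_cost) {
        best_cost <<- total
        best <<- cur
      }
      return()
    }
    opts <- which(is.finite(D[i, ]) & !usedB)
    opts <- opts[order(D[i, opts])]
    for (j in opts) {
      cur[i] <<- j
      usedB[j] <<- TRUE
      rec(i + 1L, cost + D[i, j])
      usedB[j] <<- FALSE
      cur[i] <<- NA_integer_
    }
    rec(i + 1L, cost + cap)  # leave row i unmatched
  }
  rec(1L, 0)
  best
}

#' Link per-frame spots into gap-free tracks
#'
#' Frame-to-frame assignment minimizing total linked distance per frame pair,
#' subject to a per-class maximum step (8 µm for red/G1G0, 9.3 µm for
#' green/S-G2-M nuclei by convention); no gaps are tolerated, and tracks
#' shorter than `min_duration_h` (default 2 h) are discarded and counted.
#' Spots are only linked within their class.
#'
#' @param spots spot table with frame, id, class (or channel), x, y, z.
#' @param max_step named numeric of per-class step caps, µm; unnamed single
#'   value applies to all classes.
#' @param frame_interval minutes between frames.
#' @param min_duration_h minimal track duration, h.
#' @param method `"optimal"` (component-wise exact matching) or `"greedy"`.
#' @return `data.frame` of track points (track_id, class, frame, x, y, z,
#'   spot_id); attributes `n_excluded_short` and `min_duration_h`.
#' @export
link_tracks <- function(spots, max_step = c(red = 8, green = 9.3),
                        frame_interval = 20, min_duration_h = 2,
                        method = c("optimal", "greedy")) {
  method <- match.arg(method)
  if (!"class" %in% names(spots)) spots$class <- spots$channel
  if (anyDuplicated(spots[, c("frame", "class", "id")]))
    stop("duplicate spot ids within a frame/class")
  classes <- unique(spots$class)
  caps <- if (is.null(names(max_step)))
    setNames(rep(max_step[1], length(classes)), classes) else max_step
  if (!all(classes %in% names(caps)))
    stop("no step cap for class(es): ",
         paste(setdiff(classes, names(caps)), collapse = ", "))

  all_pts <- list()
  next_tid <- 1L
  for (cl in classes) {
    sc <- spots[spots$class == cl, ]
    frames <- sort(unique(sc$frame))
    open <- list()   # each: list(tid, pts = list of rows)
    done <- list()
    prev <- NULL
    for (fr in frames) {
      cur <- sc[sc$frame == fr, ]
      if (!is.null(prev) && prev$frame[1] == fr - 1L) {
        A <- as.matrix(prev[, c("x", "y", "z")])
        B <- as.matrix(cur[, c("x", "y", "z")])
        asg <- .match_pair(A, B, caps[[cl]], method)
      } else {
        asg <- rep(NA_integer_, if (is.null(prev)) 0L else nrow(prev))
        done <- c(done, open)
        open <- list()
      }
      new_open <- vector("list", nrow(cur))
      taken <- rep(FALSE, nrow(cur))
      for (q in seq_along(asg)) {
        j <- asg[q]
        if (!is.na(j)) {
          tr <- open[[q]]
          tr$pts[[length(tr$pts) + 1L]] <- cur[j, ]
          new_open[[j]] <- tr
          taken[j] <- TRUE
        } else {
          done <- c(done, open[q])
        }
      }
      for (j in which(!taken)) {
        new_open[[j]] <- list(tid = next_tid, pts = list(cur[j, ]))
        next_tid <- next_tid + 1L
      }
      open <- new_open
      prev <- cur
    }
    done <- c(done, open)
    all_pts <- c(all_pts, done)
  }

  dur_h <- vapply(all_pts, function(tr) (length(tr$pts) - 1L), numeric(1)) *
    frame_interval / 60
  keep <- dur_h >= min_duration_h
  n_excl <- sum(!keep)
  rows <- lapply(all_pts[keep], function(tr) {
    df <- do.call(rbind, tr$pts)
    data.frame(track_id = tr$tid, class = df$class, frame = df$frame,
               x = df$x, y = df$y, z = df$z, spot_id = df$id,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(track_id = integer(), class = character(), frame = integer(),
               x = numeric(), y = numeric(), z = numeric(),
               spot_id = integer())
  rownames(out) <- NULL
  attr(out, "n_excluded_short") <- n_excl
  attr(out, "min_duration_h") <- min_duration_h
  out
}

#' Per-track kinematic metrics
#'
#' Velocity = path length / duration; net velocity = displacement / duration;
#' straightness = displacement / path length (1 for straight motion, 0 for a
#' closed loop).
#'
#' @param tracks track-point table from [link_tracks()] (track_id, frame,
#'   x, y, z, class).
#' @param frame_interval minutes between frames.
#' @return one row per track: track_id, class, n_points, duration_h,
#'   path_length, displacement, velocity, net_velocity, straightness.
#' @export
track_metrics <- function(tracks, frame_interval = 20) {
  ids <- unique(tracks$track_id)
  rows <- lapply(ids, function(tid) {
    tr <- tracks[tracks$track_id == tid, ]
    tr <- tr[order(tr$frame), ]
    if (nrow(tr) < 2) stop("track ", tid, " has a single point")
    if (any(diff(tr$frame) != 1L)) stop("track ", tid, " contains frame gaps")
    P <- as.matrix(tr[, c("x", "y", "z")])
    steps <- sqrt(rowSums(diff(P)^2))
    path <- sum(steps)
    disp <- sqrt(sum((P[nrow(P), ] - P[1, ])^2))
    dur <- (nrow(P) - 1) * frame_interval / 60
    data.frame(track_id = tid, class = tr$class[1], n_points = nrow(P),
               duration_h = dur, path_length = path, displacement = disp,
               velocity = path / dur, net_velocity = disp / dur,
               straightness = if (path > 0) disp / path else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Displacement vectors of tracks
#'
#' End-minus-start position per track in (drift-corrected) coordinates; zero
#' displacements are flagged and should be excluded from angle statistics.
#'
#' @param tracks track-point table.
#' @return one row per track: track_id, class, dx, dy, dz, zero (logical).
#' @export
displacement_vector <- function(tracks) {
  ids <- unique(tracks$track_id)
  rows <- lapply(ids, function(tid) {
    tr <- tracks[tracks$track_id == tid, ]
    tr <- tr[order(tr$frame), ]
    v <- unlist(tr[nrow(tr), c("x", "y", "z")]) - unlist(tr[1, c("x", "y", "z")])
    data.frame(track_id = tid, class = tr$class[1],
               dx = v[1], dy = v[2], dz = v[3],
               zero = all(v == 0), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Annotate tracks with start/end region labels and edge distances
#'
#' Helper joining per-track start and end positions with domain and
#' compartment labels and leading-edge distances evaluated at the start and
#' end frames.
#'
#' @param tracks track-point table.
#' @param label_fun function(frame, positions_matrix) returning a data.frame
#'   with columns `domain`, `compartment` (optional) and `edge_dist` for the
#'   given positions at that frame.
#' @return one row per track with start_/end_ label columns.
#' @export
annotate_tracks <- function(tracks, label_fun) {
  ids <- unique(tracks$track_id)
  rows <- lapply(ids, function(tid) {
    tr <- tracks[tracks$track_id == tid, ]
    tr <- tr[order(tr$frame), ]
    s <- label_fun(tr$frame[1], as.matrix(tr[1, c("x", "y", "z")]))
    e <- label_fun(tr$frame[nrow(tr)],
                   as.matrix(tr[nrow(tr), c("x", "y", "z")]))
    data.frame(track_id = tid, class = tr$class[1],
               start_frame = tr$frame[1], end_frame = tr$frame[nrow(tr)],
               start_domain = s$domain %||% NA_character_,
               end_domain = e$domain %||% NA_character_,
               start_compartment = s$compartment %||% NA_character_,
               end_compartment = e$compartment %||% NA_character_,
               start_edge_dist = s$edge_dist %||% NA_real_,
               end_edge_dist = e$edge_dist %||% NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Flow analysis of labeled tracks
#'
#' Transition fractions between regions and compartments from (start, end)
#' label pairs, branch-point in/out fractions per cycle class, and the
#' per-track change in distance to the leading edge (start minus end, so
#' positive = the cell ended closer to the edge).
#'
#' @param track_table annotated per-track table (see [annotate_tracks()]).
#' @return list with `transitions` (named fractions and counts),
#'   `delta_edge` (per-track data.frame), `branch_flux` (in/out by class),
#'   and `n_dropped` (tracks lacking labels, excluded and counted).
#' @export
flow_analysis <- function(track_table) {
  tt <- track_table
  has_dom <- !is.na(tt$start_domain) & !is.na(tt$end_domain)
  n_dropped <- sum(!has_dom)
  td <- tt[has_dom, ]
  tip_like <- c("tip", "daughter_tip", "cleft_region")
  s_tip <- td$start_domain %in% tip_like
  e_tip <- td$end_domain %in% tip_like
  s_duct <- td$start_domain == "duct"
  e_duct <- td$end_domain == "duct"
  n <- nrow(td)
  frac <- function(x) if (n > 0) sum(x) / n else NA_real_
  transitions <- list(
    n_tracks = n,
    tip_to_duct = frac(s_tip & e_duct),
    duct_to_tip = frac(s_duct & e_tip),
    basal_to_inner = NA_real_, inner_to_basal = NA_real_,
    no_transition = frac(td$start_domain == td$end_domain))
  has_comp <- !is.na(td$start_compartment) & !is.na(td$end_compartment)
  if (any(has_comp)) {
    tc <- td[has_comp, ]
    transitions$basal_to_inner <-
      sum(tc$start_compartment == "basal" & tc$end_compartment == "inner") /
      nrow(tc)
    transitions$inner_to_basal <-
      sum(tc$start_compartment == "inner" & tc$end_compartment == "basal") /
      nrow(tc)
  }
  delta <- data.frame(track_id = tt$track_id, class = tt$class,
                      start_edge_dist = tt$start_edge_dist,
                      delta_edge = tt$start_edge_dist - tt$end_edge_dist)
  bp_like <- c("branch_point", "cleft_region")
  flux <- lapply(split(td, td$class), function(dd) {
    s_bp <- dd$start_domain %in% bp_like
    e_bp <- dd$end_domain %in% bp_like
    c(into_branch_point = sum(!s_bp & e_bp) / max(1, nrow(dd)),
      out_of_branch_point = sum(s_bp & !e_bp) / max(1, nrow(dd)))
  })
  list(transitions = transitions, delta_edge = delta, branch_flux = flux,
       n_dropped = n_dropped)
}
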