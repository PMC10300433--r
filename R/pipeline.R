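#' Analysis run configuration
#'
#' Central defaults for both end-to-end analyses; every value is echoed into
#' the output bundle for provenance.
#'
#' @param compartment_threshold basal depth cutoff, µm.
#' @param tip_extent tip pooling distance, µm.
#' @param center_radius duct/branch-point pooling radius, µm.
#' @param keratin_floor gray-value floor for keratin dominance.
#' @param max_step per-class tracking step caps, µm.
#' @param min_duration_h minimal track duration, h.
#' @param detect_diameters per-class spot diameters, µm.
#' @param mask_voxel isotropic mask voxel, µm.
#' @param mask_point_radius ball radius when building masks from nuclei, µm.
#' @param distance_method `"exact"` or `"chamfer"` surface distances.
#' @param use_geodesic use geodesic (vs Euclidean) landmark distances where
#'   masks are available.
#' @param min_cells_ratio per-region floor for ratio time series.
#' @param alpha significance level used in reports.
#' @param seed RNG seed echoed into outputs.
#' @return list of class `run_config`.
#' @export
run_config <- function(compartment_threshold = 6, tip_extent = 100,
                       center_radius = 50, keratin_floor = 25,
                       max_step = c(red = 8, green = 9.3),
                       min_duration_h = 2,
                       detect_diameters = c(red = 6, green = 7),
                       mask_voxel = 2, mask_point_radius = 6,
                       distance_method = "exact", use_geodesic = TRUE,
                       min_cells_ratio = 10, alpha = 0.05, seed = 1L) {
  cfg <- list(compartment_threshold = compartment_threshold,
              tip_extent = tip_extent, center_radius = center_radius,
              keratin_floor = keratin_floor, max_step = max_step,
              min_duration_h = min_duration_h,
              detect_diameters = detect_diameters,
              mask_voxel = mask_voxel,
              mask_point_radius = mask_point_radius,
              distance_method = distance_method,
              use_geodesic = use_geodesic,
              min_cells_ratio = min_cells_ratio, alpha = alpha,
              seed = as.integer(seed))
  if (any(unlist(cfg[c("compartment_threshold", "tip_extent",
                       "center_radius", "keratin_floor", "max_step",
                       "min_duration_h", "mask_voxel")]) <= 0))
    stop("all thresholds must be positive")
  structure(cfg, class = "run_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage: %s] %s", name, conditionMessage(e)), call. = FALSE))
}

.log_line <- function(lines, msg)
  c(lines, paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " ", msg))

#' Fixed-gland spatial cell-cycle analysis
#'
#' End-to-end single-time-point pipeline: nuclei (detected from a rendered
#' stack, or taken from a provided cell table) -> isotropic epithelial mask ->
#' surface and landmark geodesic distance fields -> basal/inner and
#' tip/duct/branch-point labels -> cycle fractions, distance profile, and a
#' tip-vs-duct proportion test.
#'
#' @param input a `ground_truth` object (one frame is analyzed, default the
#'   last), or a list with elements `cells` (tidy table) or `stack`
#'   (a [voxel_stack()]), plus `landmarks` and optionally `mask`.
#' @param config a [run_config()].
#' @param frame frame to analyze when `input` is a time-lapse ground truth.
#' @param outdir optional output directory for CSV/JSON artifacts.
#' @return list: cells (annotated), fractions, profile, tip_vs_duct test,
#'   mask, config echo, log.
#' @export
run_fixed_analysis <- function(input, config = run_config(), frame = NULL,
                               outdir = NULL) {
  log <- character(0)
  log <- .log_line(log, sprintf("branchmorph %s fixed analysis",
                                as.character(packageVersion("branchmorph"))))
  if (inherits(input, "ground_truth")) {
    # default to the first frame: classes are drawn from the positional
    # probabilities there, so it is the faithful static scene
    fr <- if (is.null(frame)) min(input$cells$frame) else frame
    cells <- input$cells[input$cells$frame == fr, ]
    landmarks <- input$landmarks[input$landmarks$frame == fr, ]
    mask <- input$masks[[fr]]
  } else {
    fr <- if (is.null(frame)) 1L else frame
    landmarks <- .stage("landmarks", {
      if (is.null(input$landmarks)) stop("landmark table is required")
      lm <- input$landmarks
      if ("frame" %in% names(lm)) lm[lm$frame == fr | is.na(lm$frame), ] else lm
    })
    cells <- if (!is.null(input$cells)) input$cells else
      .stage("detect", detect_fucci(input$stack,
                                    diameters = config$detect_diameters))
    if ("frame" %in% names(cells)) cells <- cells[cells$frame %in% fr, ]
    mask <- input$mask
  }
  log <- .log_line(log, sprintf("frame %d: %d cells", fr, nrow(cells)))

  if (is.null(mask))
    mask <- .stage("mask", mask_from_points(cells, config$mask_point_radius,
                                            config$mask_voxel, frame = fr))
  sfield <- .stage("surface_distance",
                   surface_distance_field(mask, method = config$distance_method))
  cells <- .stage("compartments",
                  suppressWarnings(classify_compartment(
                    cells, sfield, config$compartment_threshold)))

  fields <- NULL
  if (config$use_geodesic) {
    fields <- .stage("geodesic_fields", {
      fl <- list()
      for (nm in intersect(c("leading_edge", "tip", "duct_center",
                             "branch_point_center"), landmarks$name)) {
        p <- unlist(landmarks[match(nm, landmarks$name), c("x", "y", "z")])
        fl[[nm]] <- geodesic_distance_field(mask, p,
                                            snap_radius = 4 * mask$voxel_size)
      }
      fl
    })
  }
  cells <- .stage("domains",
                  suppressWarnings(assign_domains(
                    cells, landmarks, fields = fields,
                    tip_extent = config$tip_extent,
                    center_radius = config$center_radius)))

  fractions <- .stage("cycle_fractions",
                      cycle_fraction(cells, c("domain", "compartment")))
  profile <- .stage("distance_profile", distance_profile(cells, bin_width = 1))

  tip <- cells[cells$domain %in% c("tip", "daughter_tip", "cleft_region"), ]
  duct <- cells[cells$domain == "duct", ]
  tip_vs_duct <- NULL
  if (nrow(tip) >= 5 && nrow(duct) >= 5) {
    pt <- suppressWarnings(prop.test(c(sum(tip$class == "green"),
                                       sum(duct$class == "green")),
                                     c(nrow(tip), nrow(duct))))
    tip_vs_duct <- list(tip_fraction = mean(tip$class == "green"),
                        duct_fraction = mean(duct$class == "green"),
                        difference = mean(tip$class == "green") -
                          mean(duct$class == "green"),
                        p_value = pt$p.value,
                        n_tip = nrow(tip), n_duct = nrow(duct))
    log <- .log_line(log, sprintf(
      "tip %.3f vs duct %.3f green fraction (p = %.3g)",
      tip_vs_duct$tip_fraction, tip_vs_duct$duct_fraction, tip_vs_duct$p_value))
  }

  out <- list(frame = fr, cells = cells, fractions = fractions,
              profile = profile, tip_vs_duct = tip_vs_duct, mask = mask,
              config = unclass(config), log = log)
  if (!is.null(outdir)) .write_bundle(out, outdir, "fixed")
  out
}

#' Time-lapse behaviour analysis
#'
#' End-to-end 4D pipeline: per-frame nuclei -> drift correction -> gap-free
#' linking with per-class step caps -> track metrics -> start/end region
#' labels and flow -> velocity-distance correlation -> displacement-vector
#' angles with Rayleigh/Watson tests -> morphometrics (elongation rate; for
#' bifurcations the branch-point-to-tip ratio series and per-frame cleft
#' geometry).
#'
#' @param input a `ground_truth` object, or a list with `cells` (multi-frame
#'   tidy table), `landmarks` (per frame), optional `masks` (per-frame list),
#'   optional `t0_frame`, and `frame_interval` (min).
#' @param config a [run_config()].
#' @param outdir optional output directory.
#' @return list with tracks, metrics, flow, velocity_vs_distance, angles,
#'   circular tests, morpho series, config echo, log.
#' @export
run_timelapse_analysis <- function(input, config = run_config(),
                                   outdir = NULL) {
  log <- character(0)
  log <- .log_line(log, sprintf("branchmorph %s timelapse analysis",
                                as.character(packageVersion("branchmorph"))))
  if (inherits(input, "ground_truth")) {
    cells <- input$cells
    landmarks <- input$landmarks
    masks <- input$masks
    t0 <- input$t0_frame
    dt_min <- input$frame_interval
  } else {
    cells <- .stage("cells", {
      if (is.null(input$cells)) stop("per-frame cell table is required")
      input$cells
    })
    landmarks <- input$landmarks
    masks <- input$masks
    t0 <- input$t0_frame
    dt_min <- if (!is.null(input$frame_interval)) input$frame_interval else 20
  }
  if (is.null(landmarks)) stop("[stage: landmarks] landmark table is required")
  frames <- sort(unique(cells$frame))

  if ("origin" %in% landmarks$name) {
    ref <- landmarks[landmarks$name == "origin", c("frame", "x", "y", "z")]
    cells <- .stage("drift_correct", drift_correct(cells, ref))
  }

  tracks <- .stage("link", link_tracks(cells, max_step = config$max_step,
                                       frame_interval = dt_min,
                                       min_duration_h = config$min_duration_h))
  log <- .log_line(log, sprintf(
    "%d tracks retained, %d excluded (< %g h)",
    length(unique(tracks$track_id)), attr(tracks, "n_excluded_short"),
    config$min_duration_h))
  metrics <- .stage("metrics", track_metrics(tracks, frame_interval = dt_min))

  # for bifurcations, also metrics restricted to the post-T0 segment of each
  # track (velocity comparisons between branch point and daughter tips are
  # made within the cleft stage, as track stratification by morphogenesis
  # stage requires)
  metrics_post_t0 <- NULL
  if (!is.null(t0) && !is.na(t0)) {
    sub <- tracks[tracks$frame >= t0, ]
    npts <- table(sub$track_id)
    sub <- sub[sub$track_id %in% names(npts)[npts >= 2], ]
    if (nrow(sub) > 0)
      metrics_post_t0 <- .stage("metrics_post_t0",
                                track_metrics(sub, frame_interval = dt_min))
  }

  lm_frame <- function(fr) landmarks[landmarks$frame == fr, ]
  edge_name <- function(lf)
    if ("leading_edge" %in% lf$name) "leading_edge" else "tip"
  field_cache <- new.env(parent = emptyenv())
  frame_fields <- function(fr) {
    key <- as.character(fr)
    if (!is.null(field_cache[[key]])) return(field_cache[[key]])
    lf <- lm_frame(fr)
    fields <- NULL
    if (config$use_geodesic && !is.null(masks) && length(masks) >= fr &&
        !is.null(masks[[fr]])) {
      nm <- edge_name(lf)
      p <- unlist(lf[match(nm, lf$name), c("x", "y", "z")])
      fields <- list()
      fields[[nm]] <- geodesic_distance_field(
        masks[[fr]], p, snap_radius = 4 * masks[[fr]]$voxel_size)
    }
    field_cache[[key]] <- if (is.null(fields)) list() else fields
    field_cache[[key]]
  }
  label_fun <- function(fr, pos) {
    lf <- lm_frame(fr)
    df <- data.frame(x = pos[, 1], y = pos[, 2], z = pos[, 3])
    fields <- frame_fields(fr)
    if (length(fields) == 0L) fields <- NULL
    lab <- suppressWarnings(assign_domains(df, lf, fields = fields,
                                           tip_extent = config$tip_extent,
                                           center_radius = config$center_radius))
    data.frame(domain = lab$domain,
               edge_dist = if ("dist_tip" %in% names(lab)) lab$dist_tip
               else NA_real_)
  }
  annotated <- .stage("annotate", annotate_tracks(tracks, label_fun))
  flow <- .stage("flow", flow_analysis(annotated))

  vv <- merge(metrics, annotated[, c("track_id", "start_edge_dist",
                                     "start_domain", "end_domain")],
              by = "track_id")
  vel_dist <- NULL
  okv <- is.finite(vv$start_edge_dist)
  if (sum(okv) >= 3 && sd(vv$start_edge_dist[okv]) > 0)
    vel_dist <- .stage("velocity_vs_distance",
                       pearson_fit(vv$start_edge_dist[okv], vv$velocity[okv]))

  # reference vector: leading-edge displacement (elongation) or neck -> cleft
  lf_first <- lm_frame(min(frames)); lf_last <- lm_frame(max(frames))
  ref_vec <- .stage("reference_vector", {
    if (!is.null(t0) && !is.na(t0) && all(c("neck", "cleft") %in% lf_last$name)) {
      unlist(lf_last[match("cleft", lf_last$name), c("x", "y", "z")]) -
        unlist(lf_last[match("neck", lf_last$name), c("x", "y", "z")])
    } else {
      nm <- edge_name(lf_first)
      unlist(lf_last[match(nm, lf_last$name), c("x", "y", "z")]) -
        unlist(lf_first[match(nm, lf_first$name), c("x", "y", "z")])
    }
  })
  disp <- displacement_vector(tracks)
  disp <- merge(disp, annotated[, c("track_id", "start_domain")],
                by = "track_id")
  usable <- !disp$zero
  angles <- data.frame(track_id = disp$track_id[usable],
                       domain = disp$start_domain[usable])
  circ <- NULL
  if (sum(usable) >= 4 && any(ref_vec != 0)) {
    angles$signed <- suppressWarnings(angle_to_reference(
      as.matrix(disp[usable, c("dx", "dy", "dz")]), ref_vec))
    angles$folded <- pmin(angles$signed, 360 - angles$signed)
    tip_like <- c("tip", "daughter_tip", "cleft_region")
    a_tip <- angles$folded[angles$domain %in% tip_like & !is.na(angles$folded)]
    a_duct <- angles$folded[angles$domain == "duct" & !is.na(angles$folded)]
    circ <- list()
    if (length(a_tip) >= 10)
      circ$rayleigh_tip <- suppressWarnings(rayleigh_test(a_tip, folded = TRUE))
    if (length(a_duct) >= 10)
      circ$rayleigh_duct <- suppressWarnings(rayleigh_test(a_duct, folded = TRUE))
    if (length(a_tip) >= 8 && length(a_duct) >= 8)
      circ$watson_tip_vs_duct <- watson_u2_test(a_tip, a_duct,
                                                seed = config$seed)
  }

  # morphometrics on the landmark series
  nm_edge <- edge_name(lf_first)
  edge_x <- vapply(frames, function(fr) {
    lf <- lm_frame(fr)
    if (nm_edge %in% lf$name)
      unlist(lf[match(nm_edge, lf$name), c("x", "y", "z")])[1] else NA_real_
  }, numeric(1))
  elong <- NULL
  if (sum(is.finite(edge_x)) >= 2)
    elong <- elongation_series(edge_x[is.finite(edge_x)],
                               frame_interval = dt_min)

  ratio_series <- NULL
  cleft_series <- NULL
  if (!is.null(t0) && !is.na(t0)) {
    labeled <- .stage("domain_series", {
      do.call(rbind, lapply(frames, function(fr) {
        cf <- cells[cells$frame == fr, ]
        lab <- suppressWarnings(assign_domains(cf, lm_frame(fr),
                                               tip_extent = config$tip_extent,
                                               center_radius = config$center_radius))
        lab[, c(names(cf), "domain")]  # landmark sets differ across frames
      }))
    })
    ratio_series <- .stage("ratio_series",
                           branchpoint_tip_ratio(labeled, t0, dt_min,
                                                 min_cells = config$min_cells_ratio))
    cleft_series <- do.call(rbind, lapply(frames, function(fr) {
      lf <- lm_frame(fr)
      if (!all(c("daughter_tip_1", "daughter_tip_2", "cleft") %in% lf$name))
        return(NULL)
      g <- function(nm) unlist(lf[match(nm, lf$name), c("x", "y", "z")])
      cm <- cleft_metrics(g("daughter_tip_1"), g("daughter_tip_2"), g("cleft"))
      data.frame(frame = fr, time_h = (fr - t0) * dt_min / 60,
                 angle = cm$angle, depth = cm$depth)
    }))
  }

  vel_test <- NULL
  tip_like <- c("tip", "daughter_tip", "cleft_region")
  v_tip <- vv$velocity[vv$start_domain %in% tip_like]
  v_duct <- vv$velocity[vv$start_domain == "duct"]
  if (length(v_tip) >= 3 && length(v_duct) >= 3)
    vel_test <- .stage("velocity_test", compare_groups(v_tip, v_duct))

  out <- list(cells = cells, tracks = tracks, metrics = metrics,
              metrics_post_t0 = metrics_post_t0,
              annotated = annotated, flow = flow,
              velocity_vs_distance = vel_dist,
              angles = angles, circular = circ,
              elongation = elong, ratio_series = ratio_series,
              cleft_series = cleft_series,
              velocity_tip_vs_duct = vel_test,
              t0_frame = t0, frame_interval = dt_min,
              config = unclass(config), log = log)
  if (!is.null(outdir)) .write_bundle(out, outdir, "timelapse")
  out
}

.write_bundle <- function(out, outdir, kind) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, nm) if (!is.null(df) && is.data.frame(df))
    write.csv(df, file.path(outdir, nm), row.names = FALSE)
  if (kind == "fixed") {
    wr(out$cells, "cells.csv")
    wr(out$fractions, "fractions.csv")
    wr(out$profile, "distance_profile.csv")
    summ <- list(kind = kind, frame = out$frame,
                 tip_vs_duct = out$tip_vs_duct, config = out$config)
  } else {
    wr(out$tracks, "tracks.csv")
    wr(out$metrics, "track_metrics.csv")
    wr(out$annotated, "track_labels.csv")
    wr(out$angles, "angles.csv")
    wr(out$ratio_series, "ratio_series.csv")
    wr(out$cleft_series, "cleft_series.csv")
    summ <- list(kind = kind,
                 flow = out$flow$transitions,
                 velocity_vs_distance = out$velocity_vs_distance,
                 t0_frame = out$t0_frame, config = out$config)
  }
  jsonlite::write_json(summ, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  writeLines(out$log, file.path(outdir, "log.txt"))
  invisible(outdir)
}

#' Command-line entry point
#'
#' `Rscript -e 'branchmorph::branchmorph_main()' simulate --config cfg.json
#' --seed 1 --outdir out/` (an installed copy lives in
#' `inst/cli/branchmorph.R`). Subcommands: `simulate`, `analyze-fixed`,
#' `analyze-timelapse`. The JSON config may carry `scenario` (scenario
#' parameters, with optional `bifurcation`) and `config` (run_config
#' overrides).
#'
#' @param args character vector (default `commandArgs(trailingOnly = TRUE)`).
#' @return invisibly, the result object of the subcommand.
#' @export
branchmorph_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste("usage: branchmorph <simulate|analyze-fixed|analyze-timelapse>",
                 "[--config cfg.json] [--seed N] [--outdir PATH]")
  if (length(args) < 1) stop(usage, call. = FALSE)
  cmd <- args[1]
  opt <- list(config = NULL, seed = 1L, outdir = "branchmorph_out")
  q <- 2L
  while (q <= length(args)) {
    key <- sub("^--", "", args[q])
    if (!key %in% names(opt)) stop("unknown option: ", args[q], call. = FALSE)
    opt[[key]] <- args[q + 1L]
    q <- q + 2L
  }
  opt$seed <- as.integer(opt$seed)
  cfg_json <- if (!is.null(opt$config))
    jsonlite::read_json(opt$config, simplifyVector = TRUE) else list()
  sp_args <- cfg_json$scenario %||% list()
  if (!is.null(sp_args$bifurcation))
    sp_args$bifurcation <- do.call(bifurcation_params, sp_args$bifurcation)
  sp_args$seed <- opt$seed
  rc <- do.call(run_config, c(cfg_json$config %||% list(),
                              list(seed = opt$seed)))
  sp <- do.call(scenario_params, sp_args)
  gt <- if (is.null(sp$bifurcation)) generate_elongation_scenario(sp)
        else generate_bifurcation_scenario(sp)
  res <- switch(cmd,
    "simulate" = { write_ground_truth(gt, opt$outdir); gt },
    "analyze-fixed" = run_fixed_analysis(gt, rc, outdir = opt$outdir),
    "analyze-timelapse" = run_timelapse_analysis(gt, rc, outdir = opt$outdir),
    stop(usage, call. = FALSE))
  message("branchmorph: wrote ", normalizePath(opt$outdir, mustWork = FALSE))
  invisible(res)
}
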