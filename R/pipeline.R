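#' Pipeline configuration
#'
#' Collects every stage parameter of the end-to-end pipeline with
#' documented defaults. The segmentation defaults are sized for the
#' default synthetic regime (0.8 um/px, cells at 4000/cm^2); the
#' brightness-window multipliers and the clustering sensitivity are the
#' per-dataset tunables (see the methods vignette).
#'
#' @param ... named overrides of the default fields; nested lists
#'   (`nuclei_adjust`, `golgi_adjust`, `golgi_seg`, `link`, `pair`) may be
#'   given partially.
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  def <- list(
    nuclei_path = NULL,
    golgi_path = NULL,
    out_dir = "ngv_out",
    pixel_size = 0.8,
    frame_interval = 5,
    wrinkle_angle = 0,
    seed = 1L,
    nuclei_adjust = list(n_low = 1, n_high = 30),
    golgi_adjust = list(n_low = 1, n_high = 60),
    nucleus_min_area = 50,
    nucleus_max_area = 400,
    nucleus_threshold = "otsu",
    nucleus_min_threshold = 21845,   # a third of the 16-bit range
    min_track_length = NULL,
    golgi_seg = list(hard_cutoff = 30000, sensitivity = 0.006,
                     min_cluster_px = 3, merge_distance = 25),
    link = list(max_displacement = 15, memory = 10),
    pair = list(max_pair_distance = 40),
    windows = NULL)
  over <- list(...)
  if (length(over) == 1 && is.null(names(over)) && is.list(over[[1]]))
    over <- over[[1]]
  bad <- setdiff(names(over), names(def))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  for (nm in names(over)) {
    if (is.list(def[[nm]]) && is.list(over[[nm]]) && !is.null(names(over[[nm]]))) {
      sub <- setdiff(names(over[[nm]]), names(def[[nm]]))
      if (length(sub)) stop("unknown ", nm, " field(s): ", paste(sub, collapse = ", "))
      def[[nm]][names(over[[nm]])] <- over[[nm]]
    } else {
      def[nm] <- list(over[[nm]])   # preserves NULL-valued fields
    }
  }
  structure(def, class = "pipeline_config")
}

#' Read or write a pipeline configuration
#'
#' Configurations are stored as flat YAML mirroring the
#' [pipeline_config()] field names; a written file read back yields an
#' identical configuration.
#'
#' @param path file path.
#' @return for `read_config`, a `pipeline_config`.
#' @export
read_config <- function(path) {
  pipeline_config(yaml::read_yaml(path))
}

#' @param config a `pipeline_config`.
#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full tracking pipeline
#'
#' Streams both channels frame by frame through preprocessing and
#' segmentation (so long movies never sit in memory), links detections
#' into trajectories with gap memory, fills positional gaps, pairs Golgi
#' with nuclei by time-averaged proximity, and computes the polarity and
#' motility statistics. All tables are written as CSV under
#' `config$out_dir` together with a run log of every parameter; the same
#' configuration and seed always reproduce byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param nuclei_stack,golgi_stack optional `ngv_stack` objects overriding
#'   the configured file paths (e.g. lazy synthetic stacks).
#' @return invisibly, a list with detections, trajectories, pairs and all
#'   computed metrics.
#' @export
run_pipeline <- function(config, nuclei_stack = NULL, golgi_stack = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(nuclei_stack)) {
    if (is.null(config$nuclei_path)) stop("no nuclei stack given")
    nuclei_stack <- read_stack(config$nuclei_path, lazy = TRUE)
  }
  if (is.null(golgi_stack)) {
    if (is.null(config$golgi_path)) stop("no golgi stack given")
    golgi_stack <- read_stack(config$golgi_path, lazy = TRUE)
  }
  if (n_frames(nuclei_stack) != n_frames(golgi_stack))
    stop("channel stacks differ in frame count")
  tt <- n_frames(nuclei_stack)
  nadj <- do.call(adjust_params, config$nuclei_adjust)
  gadj <- do.call(adjust_params, config$golgi_adjust)
  gseg <- do.call(golgi_seg_params, config$golgi_seg)
  lpar <- do.call(link_params, config$link)
  ppar <- do.call(pair_params, config$pair)

  nuc_det <- vector("list", tt)
  gol_det <- vector("list", tt)
  for (f in seq_len(tt)) {
    nf <- get_frame(nuclei_stack, f)
    nf <- rescale_frame(nf, compute_bounds(fit_intensity_distribution(nf), nadj))
    nuc_det[[f]] <- tryCatch(
      segment_nuclei(nf, min_area = config$nucleus_min_area,
                     threshold = config$nucleus_threshold,
                     max_area = config$nucleus_max_area,
                     min_threshold = config$nucleus_min_threshold),
      error = function(e) stop("nuclei segmentation failed at frame ",
                               f - 1, ": ", conditionMessage(e)))
    gf <- get_frame(golgi_stack, f)
    gf <- rescale_frame(gf, compute_bounds(fit_intensity_distribution(gf), gadj))
    gol_det[[f]] <- tryCatch(
      segment_golgi(gf, gseg),
      error = function(e) stop("golgi segmentation failed at frame ",
                               f - 1, ": ", conditionMessage(e)))
  }
  nuc_tracks <- link(nuc_det, lpar)
  gol_tracks <- link(gol_det, lpar)
  nuc_filled <- structure(lapply(nuc_tracks, fill_gaps), class = "ngv_tracks")
  gol_filled <- structure(lapply(gol_tracks, fill_gaps), class = "ngv_tracks")
  ## stub filtering before pairing: ephemeral trajectory segments carry
  ## too little evidence for a stable identity; pair ids stay track ids.
  ## Default: a track must be observed for a quarter of the movie.
  mtl <- if (is.null(config$min_track_length)) tt %/% 4 else
    config$min_track_length
  n_obs <- function(tr) sum(!tr$interpolated)
  keep_n <- which(vapply(nuc_filled, n_obs, integer(1)) >= mtl)
  keep_g <- which(vapply(gol_filled, n_obs, integer(1)) >= mtl)
  pairs <- pair_trajectories(nuc_filled[keep_n], gol_filled[keep_g], ppar)
  pairs$nucleus_id <- keep_n[pairs$nucleus_id]
  pairs$golgi_id <- keep_g[pairs$golgi_id]

  metrics <- compute_pipeline_metrics(config, tt, nuc_det, nuc_filled,
                                      gol_filled, pairs)
  out <- list(config = config,
              nuclei_detections = nuc_det, golgi_detections = gol_det,
              nuclei_tracks = nuc_filled, golgi_tracks = gol_filled,
              pairs = pairs, metrics = metrics)
  if (!is.null(config$out_dir)) write_pipeline_outputs(out)
  invisible(out)
}

## windows come as a list of c(first, last) 0-based inclusive frame ranges;
## NULL means one window covering the whole movie.
resolve_windows <- function(windows, tt) {
  if (is.null(windows)) windows <- list(c(0, tt - 1))
  lapply(windows, function(w) {
    w <- as.integer(unlist(w))
    if (length(w) != 2 || w[1] > w[2] || w[1] < 0 || w[2] > tt - 1)
      stop("invalid analysis window: ", paste(w, collapse = "-"))
    w
  })
}

compute_pipeline_metrics <- function(config, tt, nuc_det, nuc_filled,
                                     gol_filled, pairs) {
  px <- config$pixel_size
  wa <- config$wrinkle_angle
  windows <- resolve_windows(config$windows, tt)
  win_name <- vapply(windows, function(w) paste0(w[1], "-", w[2]), character(1))

  ## nucleus orientations per frame from the detections
  nuc_angles <- lapply(seq_len(tt) - 1L, function(f) {
    det <- nuc_det[[f + 1]]
    if (!NROW(det)) numeric(0) else wrap_apolar(det$orientation - wa)
  })
  ## NGV angles per frame over resolved pairs
  ngv_by_frame <- rep(list(numeric(0)), tt)
  if (nrow(pairs)) {
    for (i in seq_len(nrow(pairs))) {
      ang <- ngv_angle(nuc_filled[[pairs$nucleus_id[i]]],
                       gol_filled[[pairs$golgi_id[i]]])
      for (j in seq_len(nrow(ang))) {
        f <- ang$frame[j] + 1L
        ngv_by_frame[[f]] <- c(ngv_by_frame[[f]],
                               wrap_apolar(ang$angle[j] - wa))
      }
    }
  }
  collect <- function(per_frame, w) unlist(per_frame[(w[1]:w[2]) + 1L])
  orientation_stats <- do.call(rbind, lapply(seq_along(windows), function(k) {
    rows <- lapply(list(nuclei = nuc_angles, ngv = ngv_by_frame), function(pf) {
      a <- collect(pf, windows[[k]])
      if (length(a) >= 2) {
        st <- truncated_sd(a)
        c(mean = st$mean_orientation, sigma_t = st$sigma_t, n = length(a))
      } else c(mean = NA_real_, sigma_t = NA_real_, n = length(a))
    })
    data.frame(group = names(rows), window = win_name[k],
               mean_deg = vapply(rows, `[[`, numeric(1), "mean"),
               sigma_t_deg = vapply(rows, `[[`, numeric(1), "sigma_t"),
               n = vapply(rows, `[[`, numeric(1), "n"))
  }))
  rownames(orientation_stats) <- NULL

  ## trajectory statistics in the wrinkle frame, um
  to_um <- function(tr) {
    r <- rotate_to_wrinkle_frame(cbind(tr$x, tr$y) * px, wa)
    data.frame(frame = tr$frame, x = r[, 1], y = r[, 2],
               interpolated = tr$interpolated)
  }
  nt_um <- lapply(nuc_filled, to_um)
  long <- nt_um[vapply(nt_um, nrow, integer(1)) >= 2]
  speeds <- do.call(rbind, lapply(seq_along(long), function(i) {
    s <- compute_speed(long[[i]], pixel_size = 1,
                       frame_interval = config$frame_interval)
    if (!nrow(s)) return(NULL)
    data.frame(track_id = i, s, vx_vy_ratio = attr(s, "vx_vy_ratio"))
  }))
  if (is.null(speeds))
    speeds <- data.frame(track_id = integer(0), frame = integer(0),
                         speed = numeric(0), abs_vx = numeric(0),
                         abs_vy = numeric(0), vx_vy_ratio = numeric(0))
  metrics <- list(orientation_stats = orientation_stats, speeds = speeds)
  metrics$msd <- if (length(long)) msd(long, config$frame_interval) else
    data.frame(lag = numeric(0), msd = numeric(0))
  metrics$gyration <- if (length(long))
    tryCatch(gyration_ratio(long), error = function(e) NULL) else NULL
  metrics$vacf <- if (length(long)) vacf(long, config$frame_interval) else
    data.frame(lag = numeric(0), vacf = numeric(0))
  metrics$persistence <- tryCatch(fit_persistence(metrics$vacf),
                                  error = function(e) NULL)
  metrics$polar_histogram <- do.call(rbind, lapply(seq_along(windows),
    function(k) {
      h <- angle_histogram(collect(nuc_angles, windows[[k]]))
      data.frame(group = "nuclei", window = win_name[k], h)
    }))
  ## across-window comparison of orientation samples (needs >= 2 windows)
  gt <- NULL
  if (length(windows) >= 2) {
    samples <- lapply(windows, function(w) collect(nuc_angles, w))
    names(samples) <- win_name
    ok <- vapply(samples, length, integer(1)) >= 2
    if (sum(ok) >= 2) {
      cg <- compare_groups(samples[ok])
      gt <- data.frame(metric = "nucleus_orientation", cg$pairwise,
                       kruskal_p = cg$kruskal$p.value)
    }
  }
  metrics$group_tests <- if (is.null(gt))
    data.frame(metric = character(0), group1 = character(0),
               group2 = character(0), p_adjusted = numeric(0),
               significance = character(0), kruskal_p = numeric(0)) else gt
  metrics
}

detections_table <- function(nuc_det, gol_det) {
  tt <- length(nuc_det)
  rows <- list()
  for (f in seq_len(tt)) {
    nd <- nuc_det[[f]]
    if (NROW(nd))
      rows[[length(rows) + 1]] <- data.frame(
        frame = f - 1L, channel = "nuclei",
        id_within_frame = seq_len(nrow(nd)),
        x_px = nd$x, y_px = nd$y, orientation_deg = nd$orientation,
        major_px = nd$major, minor_px = nd$minor, size_px = nd$area)
    gd <- gol_det[[f]]
    if (NROW(gd))
      rows[[length(rows) + 1]] <- data.frame(
        frame = f - 1L, channel = "golgi",
        id_within_frame = seq_len(nrow(gd)),
        x_px = gd$x, y_px = gd$y, orientation_deg = NA_real_,
        major_px = NA_real_, minor_px = NA_real_, size_px = gd$size)
  }
  if (!length(rows))
    return(data.frame(frame = integer(0), channel = character(0),
                      id_within_frame = integer(0), x_px = numeric(0),
                      y_px = numeric(0), orientation_deg = numeric(0),
                      major_px = numeric(0), minor_px = numeric(0),
                      size_px = integer(0)))
  do.call(rbind, rows)
}

trajectories_table <- function(tracks, channel) {
  rows <- lapply(seq_along(tracks), function(id) {
    tr <- tracks[[id]]
    data.frame(channel = channel, track_id = id, frame = tr$frame,
               x_px = tr$x, y_px = tr$y, interpolated = tr$interpolated)
  })
  if (!length(rows))
    return(data.frame(channel = character(0), track_id = integer(0),
                      frame = integer(0), x_px = numeric(0),
                      y_px = numeric(0), interpolated = logical(0)))
  do.call(rbind, rows)
}

write_pipeline_outputs <- function(res) {
  dir.create(res$config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(res$config$out_dir, name)
  wcsv <- function(df, name) utils::write.csv(df, out(name), row.names = FALSE)
  wcsv(detections_table(res$nuclei_detections, res$golgi_detections),
       "detections.csv")
  wcsv(rbind(trajectories_table(res$nuclei_tracks, "nuclei"),
             trajectories_table(res$golgi_tracks, "golgi")),
       "trajectories.csv")
  pr <- as.data.frame(res$pairs)
  names(pr) <- c("nucleus_id", "golgi_id", "mean_distance_px",
                 "co_visible_frames")
  wcsv(pr, "pairs.csv")
  m <- res$metrics
  wcsv(m$orientation_stats, "orientation_stats.csv")
  wcsv(m$speeds, "speeds.csv")
  wcsv(m$msd, "msd.csv")
  wcsv(as.data.frame(m$vacf), "vacf.csv")
  gy <- if (is.null(m$gyration))
    data.frame(r_xx = numeric(0), r_yy = numeric(0), ratio = numeric(0)) else
      data.frame(r_xx = m$gyration$r_xx, r_yy = m$gyration$r_yy,
                 ratio = m$gyration$ratio)
  wcsv(gy, "gyration.csv")
  wcsv(m$polar_histogram, "polar_histogram.csv")
  wcsv(m$group_tests, "group_tests.csv")
  cfg <- res$config
  log_lines <- c("ngvtrack pipeline run",
                 paste0("seed: ", cfg$seed),
                 paste0("frames: ", length(res$nuclei_detections)),
                 paste0("pixel_size: ", cfg$pixel_size),
                 paste0("frame_interval: ", cfg$frame_interval),
                 paste0("wrinkle_angle: ", cfg$wrinkle_angle),
                 paste0("config: ", paste(utils::capture.output(
                   utils::str(unclass(cfg), give.attr = FALSE)), collapse = " ")))
  writeLines(log_lines, out("run_log.txt"))
  invisible(res$config$out_dir)
}
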