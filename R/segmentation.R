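#' Segment nuclei in one frame
#'
#' Nuclei are bright ellipsoidal objects: a global threshold (Otsu by
#' default) is followed by connected-component labelling, a minimum-area
#' filter, and a per-component ellipse fit from second central moments of
#' the component's pixel positions. The orientation is the major-axis
#' angle, apolar in [0, 180), measured from +x (columns) toward +y (rows);
#' full axis lengths are 4*sqrt(eigenvalue), the moment-matched values for
#' a filled ellipse.
#'
#' @param frame numeric matrix (preprocessed).
#' @param min_area px^2; smaller components are dropped.
#' @param threshold "otsu" or a numeric intensity threshold.
#' @param max_area px^2; larger components are dropped. Touching nuclei
#'   merge into one oversized component whose centroid belongs to neither
#'   cell; gating on size (the usual particle-identification practice)
#'   discards the ambiguous blob and lets the tracker's gap memory carry
#'   both identities through the contact.
#' @param min_threshold floor applied to the automatic threshold. Otsu's
#'   method always splits a histogram, even of an empty noise-only frame;
#'   on frames normalised so that nuclei saturate, a threshold below a
#'   fraction of the intensity range indicates there is nothing to
#'   segment.
#' @return data.frame with `x`, `y` (0-based centroid px), `major`,
#'   `minor` (px), `orientation` (deg), `area` (px), `degenerate`
#'   (TRUE when major ~ minor and the orientation is arbitrary).
#' @export
segment_nuclei <- function(frame, min_area = 50, threshold = "otsu",
                           max_area = Inf, min_threshold = 0) {
  empty <- data.frame(x = numeric(0), y = numeric(0), major = numeric(0),
                      minor = numeric(0), orientation = numeric(0),
                      area = integer(0), degenerate = logical(0))
  if (identical(threshold, "otsu")) {
    rng <- range(frame)
    if (rng[1] == rng[2]) return(empty)
    ## Otsu level from a strided pixel sample: deterministic and
    ## statistically equivalent for a global threshold on large frames
    v <- as.numeric(frame)
    if (length(v) > 500000)
      v <- v[seq(1, length(v), by = ceiling(length(v) / 500000))]
    threshold <- EBImage::otsu(matrix(v, ncol = 1), range = rng)
    if (threshold < min_threshold) return(empty)
  }
  mask <- frame > threshold
  if (!any(mask)) return(empty)
  lab <- EBImage::bwlabel(mask)
  idx <- which(lab > 0)
  comp <- as.integer(lab[idx])
  rows <- ((idx - 1) %% nrow(frame))          # 0-based y
  cols <- ((idx - 1) %/% nrow(frame))         # 0-based x
  n <- tabulate(comp)
  keep <- which(n >= min_area & n <= max_area)
  if (!length(keep)) return(empty)
  sx <- rowsum(cols, comp); sy <- rowsum(rows, comp)
  sxx <- rowsum(cols^2, comp); syy <- rowsum(rows^2, comp)
  sxy <- rowsum(cols * rows, comp)
  out <- lapply(keep, function(k) {
    nk <- n[k]
    mx <- sx[k] / nk; my <- sy[k] / nk
    ## second central moments, with the 1/12 variance of a unit pixel so
    ## single-pixel rows/columns keep a finite axis
    mxx <- sxx[k] / nk - mx^2 + 1 / 12
    myy <- syy[k] / nk - my^2 + 1 / 12
    mxy <- sxy[k] / nk - mx * my
    tr <- mxx + myy
    disc <- sqrt(max(0, (mxx - myy)^2 + 4 * mxy^2))
    l1 <- (tr + disc) / 2
    l2 <- max((tr - disc) / 2, 1e-9)
    ang <- wrap_apolar(0.5 * atan2(2 * mxy, mxx - myy) * 180 / pi)
    data.frame(x = mx, y = my, major = 4 * sqrt(l1), minor = 4 * sqrt(l2),
               orientation = ang, area = nk,
               degenerate = disc < 1e-3 * tr)
  })
  do.call(rbind, out)
}

#' Foreground pixel coordinates above a hard cutoff
#'
#' The Golgi channel is background-suppressed with a plain hard threshold:
#' every pixel strictly brighter than the cutoff is foreground.
#'
#' @param frame numeric matrix (preprocessed).
#' @param hard_cutoff intensity threshold.
#' @return integer matrix with columns `x`, `y` (0-based px), one row per
#'   foreground pixel, in column-major frame order.
#' @export
threshold_golgi <- function(frame, hard_cutoff) {
  idx <- which(frame > hard_cutoff)
  cbind(x = (idx - 1L) %/% nrow(frame),
        y = (idx - 1L) %% nrow(frame))
}

#' Group foreground pixels by single-linkage distance clustering
#'
#' Two pixels share a cluster iff they are connected by a chain of
#' pairwise distances no larger than `sensitivity` times the frame
#' diagonal. The published sensitivity (0.1) is deliberately permissive so
#' that fragmented Golgi split rather than fuse; [merge_fragments()]
#' reassembles them.
#'
#' @param coords two-column matrix of (x, y) pixel coordinates.
#' @param sensitivity dimensionless in (0, 1).
#' @param frame_shape integer c(height, width) of the source frame.
#' @return list of coordinate matrices, one per cluster; empty input gives
#'   an empty list.
#' @export
cluster_golgi_pixels <- function(coords, sensitivity, frame_shape) {
  if (is.null(coords) || nrow(coords) == 0) return(list())
  if (sensitivity <= 0 || sensitivity >= 1)
    stop("sensitivity must be in (0, 1)")
  cutoff <- sensitivity * sqrt(sum(as.numeric(frame_shape)^2))
  if (nrow(coords) == 1) return(list(coords))
  labs <- stats::cutree(stats::hclust(stats::dist(coords), method = "single"),
                        h = cutoff)
  lapply(split(seq_len(nrow(coords)), labs),
         function(i) coords[i, , drop = FALSE])
}

#' Merge cluster fragments into Golgi detections, largest first
#'
#' Clusters below `min_cluster_px` pixels are discarded as noise. Then,
#' repeatedly: the largest remaining cluster (ties broken by the first
#' pixel in row-major order) computes its convex hull and absorbs every
#' cluster whose nearest hull-vertex-to-hull-vertex distance is within
#' `merge_distance`, recomputing the hull after each absorption round until
#' nothing more is absorbed; the assembled cluster becomes one detection
#' and leaves the pool. Degenerate hulls (fewer than 3 distinct points, or
#' collinear) fall back to the raw point set.
#'
#' @param clusters list of coordinate matrices from
#'   [cluster_golgi_pixels()].
#' @param merge_distance px.
#' @param min_cluster_px minimum cluster size kept.
#' @return data.frame with `x`, `y` (0-based centroid of the merged pixel
#'   set), `size` (px count), plus a list-column `pixels` of coordinate
#'   matrices.
#' @export
merge_fragments <- function(clusters, merge_distance, min_cluster_px = 3) {
  clusters <- Filter(function(cl) nrow(cl) >= min_cluster_px, clusters)
  out_x <- out_y <- numeric(0); out_size <- integer(0); out_px <- list()
  ## key: row-major order of each cluster's first pixel (deterministic ties)
  pool <- lapply(clusters, function(cl) {
    list(px = cl, hull = hull_points(cl), size = nrow(cl),
         key = min(cl[, "y"] * 2^26 + cl[, "x"]))
  })
  while (length(pool)) {
    sizes <- vapply(pool, `[[`, numeric(1), "size")
    keys <- vapply(pool, `[[`, numeric(1), "key")
    i <- order(-sizes, keys)[1]
    cur <- pool[[i]]
    pool[[i]] <- NULL
    repeat {
      if (!length(pool)) break
      d <- vapply(pool, function(cl) min_vertex_distance(cur$hull, cl$hull),
                  numeric(1))
      near <- which(d <= merge_distance)
      if (!length(near)) break
      for (j in near) cur$px <- rbind(cur$px, pool[[j]]$px)
      pool <- pool[-near]
      cur$hull <- hull_points(cur$px)
    }
    out_x <- c(out_x, mean(cur$px[, "x"]))
    out_y <- c(out_y, mean(cur$px[, "y"]))
    out_size <- c(out_size, nrow(cur$px))
    out_px <- c(out_px, list(cur$px))
  }
  out <- data.frame(x = out_x, y = out_y, size = out_size)
  out$pixels <- out_px
  out
}

## Convex hull vertices of a pixel set; degenerate sets (< 3 points or
## collinear) fall back to the raw points.
hull_points <- function(px) {
  if (nrow(px) < 3) return(px)
  h <- tryCatch(grDevices::chull(px[, "x"], px[, "y"]), error = function(e) NULL)
  if (is.null(h) || length(h) < 3) return(px)
  px[h, , drop = FALSE]
}

min_vertex_distance <- function(a, b) {
  dx <- outer(a[, "x"], b[, "x"], "-")
  dy <- outer(a[, "y"], b[, "y"], "-")
  sqrt(min(dx^2 + dy^2))
}

#' Detect Golgi bodies in one frame
#'
#' Convenience wrapper chaining [threshold_golgi()],
#' [cluster_golgi_pixels()] and [merge_fragments()].
#'
#' @param frame numeric matrix (preprocessed).
#' @param params a [golgi_seg_params()] object.
#' @return data.frame of Golgi detections (see [merge_fragments()]).
#' @export
segment_golgi <- function(frame, params = golgi_seg_params()) {
  coords <- threshold_golgi(frame, params$hard_cutoff)
  clusters <- cluster_golgi_pixels(coords, params$sensitivity, dim(frame))
  merge_fragments(clusters, params$merge_distance, params$min_cluster_px)
}
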