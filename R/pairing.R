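#' Time-averaged nucleus-to-Golgi distance table
#'
#' For every nucleus trajectory and every Golgi trajectory, the mean over
#' their co-visible frames of the centroid-to-centroid distance. The mean
#' is normalised by the number of co-visible frames (a Golgi seen in only
#' a few frames at distance d still averages d, not d divided by the movie
#' length); pairs that are never co-visible are absent from the table.
#'
#' @param nucleus_trajs,golgi_trajs lists of trajectory data.frames
#'   (`frame`, `x`, `y`), typically gap-filled.
#' @return data.frame with `nucleus_id`, `golgi_id`, `mean_distance` (px),
#'   `co_visible_frames`.
#' @export
candidate_distances <- function(nucleus_trajs, golgi_trajs) {
  rows <- list()
  for (ni in seq_along(nucleus_trajs)) {
    nt <- nucleus_trajs[[ni]]
    for (gi in seq_along(golgi_trajs)) {
      gt <- golgi_trajs[[gi]]
      common <- intersect(nt$frame, gt$frame)
      if (!length(common)) next
      a <- match(common, nt$frame); b <- match(common, gt$frame)
      d <- sqrt((nt$x[a] - gt$x[b])^2 + (nt$y[a] - gt$y[b])^2)
      rows[[length(rows) + 1]] <-
        data.frame(nucleus_id = ni, golgi_id = gi,
                   mean_distance = mean(d),
                   co_visible_frames = length(common))
    }
  }
  if (!length(rows))
    return(data.frame(nucleus_id = integer(0), golgi_id = integer(0),
                      mean_distance = numeric(0),
                      co_visible_frames = integer(0)))
  do.call(rbind, rows)
}

#' Resolve nucleus-Golgi pairings by global best-first assignment
#'
#' Commits the globally smallest remaining mean distance within the
#' cutoff, removes both members from contention, and repeats: when a Golgi
#' is the closest candidate of two nuclei the nearer nucleus wins and the
#' other defers to its next-best choice. The result is one-to-one; nuclei
#' and Golgi with no admissible partner stay unpaired.
#'
#' @param distance_table from [candidate_distances()].
#' @param params a [pair_params()] object.
#' @return data.frame of class `cell_pairs` with `nucleus_id`, `golgi_id`,
#'   `mean_distance`, `co_visible_frames`.
#' @export
resolve_pairs <- function(distance_table, params = pair_params()) {
  tab <- distance_table[distance_table$mean_distance <= params$max_pair_distance, ,
                        drop = FALSE]
  out <- tab[0, , drop = FALSE]
  ## deterministic order: distance, then ids
  tab <- tab[order(tab$mean_distance, tab$nucleus_id, tab$golgi_id), ,
             drop = FALSE]
  while (nrow(tab)) {
    pick <- tab[1, , drop = FALSE]
    out <- rbind(out, pick)
    tab <- tab[tab$nucleus_id != pick$nucleus_id &
                 tab$golgi_id != pick$golgi_id, , drop = FALSE]
  }
  rownames(out) <- NULL
  stopifnot(!anyDuplicated(out$nucleus_id), !anyDuplicated(out$golgi_id))
  class(out) <- c("cell_pairs", "data.frame")
  out
}

#' Pair nucleus and Golgi trajectories
#'
#' Convenience wrapper chaining [candidate_distances()] and
#' [resolve_pairs()].
#'
#' @param nucleus_trajs,golgi_trajs lists of trajectory data.frames.
#' @param params a [pair_params()] object.
#' @return a `cell_pairs` data.frame.
#' @export
pair_trajectories <- function(nucleus_trajs, golgi_trajs,
                              params = pair_params()) {
  resolve_pairs(candidate_distances(nucleus_trajs, golgi_trajs), params)
}
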