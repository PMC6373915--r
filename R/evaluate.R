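#' Map tracked trajectories to ground-truth cell identities
#'
#' Each observed (non-interpolated) trajectory point is matched to the
#' nearest visible ground-truth object of the same channel in that frame,
#' within `tol` px; a trajectory's identity is the majority vote over its
#' points.
#'
#' @param tracks an `ngv_tracks` list (positions in px, frames 0-based).
#' @param truth an `ngv_truth` object.
#' @param channel "nuclei" or "golgi".
#' @param tol px; match radius.
#' @return integer vector: ground-truth cell id per trajectory (NA when no
#'   point matched).
#' @export
match_tracks_to_truth <- function(tracks, truth, channel = c("nuclei", "golgi"),
                                  tol = 10) {
  channel <- match.arg(channel)
  p <- truth$params
  tx <- (if (channel == "nuclei") truth$x else truth$golgi_x) / p$pixel_size
  ty <- (if (channel == "nuclei") truth$y else truth$golgi_y) / p$pixel_size
  vis <- if (channel == "nuclei") truth$nuc_visible else truth$golgi_visible
  vapply(tracks, function(tr) {
    obs <- tr[!tr$interpolated, , drop = FALSE]
    ids <- vapply(seq_len(nrow(obs)), function(i) {
      f <- obs$frame[i] + 1L
      cand <- which(vis[f, ])
      if (!length(cand)) return(NA_integer_)
      d2 <- (tx[f, cand] - obs$x[i])^2 + (ty[f, cand] - obs$y[i])^2
      j <- which.min(d2)
      if (d2[j] <= tol^2) cand[j] else NA_integer_
    }, integer(1))
    ids <- ids[!is.na(ids)]
    if (!length(ids)) return(NA_integer_)
    as.integer(names(which.max(table(ids))))
  }, integer(1))
}

#' Fraction of frame-to-frame links that connect the same true cell
#'
#' A link is a pair of consecutive observed points within one trajectory;
#' it is correct when both endpoints map to the same ground-truth cell.
#'
#' @inheritParams match_tracks_to_truth
#' @return list with `correct_link_fraction`, `n_links`, and
#'   `n_trajectories`.
#' @export
track_link_accuracy <- function(tracks, truth, channel = c("nuclei", "golgi"),
                                tol = 10) {
  channel <- match.arg(channel)
  p <- truth$params
  tx <- (if (channel == "nuclei") truth$x else truth$golgi_x) / p$pixel_size
  ty <- (if (channel == "nuclei") truth$y else truth$golgi_y) / p$pixel_size
  vis <- if (channel == "nuclei") truth$nuc_visible else truth$golgi_visible
  good <- 0L; total <- 0L
  for (tr in tracks) {
    obs <- tr[!tr$interpolated, , drop = FALSE]
    if (nrow(obs) < 2) next
    ids <- vapply(seq_len(nrow(obs)), function(i) {
      f <- obs$frame[i] + 1L
      cand <- which(vis[f, ])
      if (!length(cand)) return(NA_integer_)
      d2 <- (tx[f, cand] - obs$x[i])^2 + (ty[f, cand] - obs$y[i])^2
      j <- which.min(d2)
      if (d2[j] <= tol^2) cand[j] else NA_integer_
    }, integer(1))
    ok <- !is.na(ids[-1]) & !is.na(ids[-length(ids)])
    good <- good + sum(ids[-1][ok] == ids[-length(ids)][ok])
    total <- total + sum(ok)
  }
  list(correct_link_fraction = if (total) good / total else NA_real_,
       n_links = total, n_trajectories = length(tracks))
}

#' Agreement between reported and ground-truth nucleus-Golgi pairs
#'
#' A reported pairing is correct when its nucleus trajectory and Golgi
#' trajectory both map to the same labeled ground-truth cell. `precision`
#' is the fraction of reported pairs that are correct (the fraction of
#' pairs matching the ground-truth pairing table); `recall` is the
#' fraction of labeled cells recovered by at least one correct pair.
#'
#' @param pairs a `cell_pairs` data.frame from [resolve_pairs()].
#' @param nucleus_tracks,golgi_tracks the `ngv_tracks` the pairing was run
#'   on.
#' @param truth an `ngv_truth` object.
#' @param tol px; identity match radius.
#' @return list with `precision`, `recall`, `n_truth_pairs`, `n_reported`,
#'   `n_correct_pairs`, `n_cells_recovered`.
#' @export
pairing_accuracy <- function(pairs, nucleus_tracks, golgi_tracks, truth,
                             tol = 10) {
  nid <- match_tracks_to_truth(nucleus_tracks, truth, "nuclei", tol)
  gid <- match_tracks_to_truth(golgi_tracks, truth, "golgi", tol)
  truth_pairs <- truth$pairs$nucleus_id
  pn <- nid[pairs$nucleus_id]
  pg <- gid[pairs$golgi_id]
  good <- !is.na(pn) & !is.na(pg) & pn == pg & pn %in% truth_pairs
  cells <- unique(pn[good])
  list(precision = if (nrow(pairs)) sum(good) / nrow(pairs) else NA_real_,
       recall = if (length(truth_pairs))
         length(cells) / length(truth_pairs) else NA_real_,
       n_truth_pairs = length(truth_pairs),
       n_reported = nrow(pairs),
       n_correct_pairs = sum(good),
       n_cells_recovered = length(cells))
}
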