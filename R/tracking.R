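#' Link per-frame detections into trajectories with gap memory
#'
#' Frame-to-frame linking in the cost-minimising tradition of standard
#' particle tracking: for each new frame, candidate links run from every
#' active track endpoint to every detection within `max_displacement`, and
#' the assignment minimising the total squared displacement (with a
#' non-match option costing `max_displacement^2`) is chosen. The candidate
#' graph is split into connected components, each solved exactly by
#' branch-and-bound, so the optimum does not depend on detection order.
#' An unmatched track stays eligible for re-linking for up to `memory`
#' frames of absence before its identity is retired; detections that match
#' nothing start fresh trajectories.
#'
#' @param detections_by_frame list over frames (1-based position = frame
#'   index - `frame0`); each element a data.frame or matrix with `x`, `y`
#'   columns (0-based px), possibly empty or NULL.
#' @param params a [link_params()] object.
#' @param frame0 frame index of the first list element (default 0).
#' @return list of class `ngv_tracks`: trajectories as data.frames with
#'   `frame` (0-based), `x`, `y`, `detection` (row index within the frame's
#'   detection table), `interpolated` (FALSE; see [fill_gaps()]).
#' @export
link <- function(detections_by_frame, params = link_params(), frame0 = 0) {
  b <- params$max_displacement^2
  active <- list()    # each: id, x, y, last_frame
  done <- list()
  tracks <- list()    # id -> data.frame rows accumulated as lists
  next_id <- 1L
  for (fi in seq_along(detections_by_frame)) {
    frame <- frame0 + fi - 1L
    det <- detections_by_frame[[fi]]
    if (is.null(det) || NROW(det) == 0) det <- NULL
    ## retire tracks dark for more than `memory` frames
    if (length(active)) {
      last <- vapply(active, `[[`, numeric(1), "last_frame")
      expired <- frame - last > params$memory + 1
      done <- c(done, active[expired])
      active <- active[!expired]
    }
    if (is.null(det)) next
    dx <- if (is.data.frame(det)) det$x else det[, "x"]
    dy <- if (is.data.frame(det)) det$y else det[, "y"]
    nd <- length(dx)
    assigned <- rep(NA_integer_, nd)
    if (length(active)) {
      ax <- vapply(active, `[[`, numeric(1), "x")
      ay <- vapply(active, `[[`, numeric(1), "y")
      cost <- outer(ax, dx, "-")^2 + outer(ay, dy, "-")^2
      cost[cost > b] <- Inf
      assigned <- solve_links(cost, b)     # per detection: active index or NA
    }
    for (j in seq_len(nd)) {
      if (is.na(assigned[j])) {
        active[[length(active) + 1]] <-
          list(id = next_id, x = dx[j], y = dy[j], last_frame = frame)
        tracks[[next_id]] <- list(frame = frame, x = dx[j], y = dy[j],
                                  detection = j)
        next_id <- next_id + 1L
      } else {
        a <- assigned[j]
        id <- active[[a]]$id
        tracks[[id]]$frame <- c(tracks[[id]]$frame, frame)
        tracks[[id]]$x <- c(tracks[[id]]$x, dx[j])
        tracks[[id]]$y <- c(tracks[[id]]$y, dy[j])
        tracks[[id]]$detection <- c(tracks[[id]]$detection, j)
        active[[a]]$x <- dx[j]; active[[a]]$y <- dy[j]
        active[[a]]$last_frame <- frame
      }
    }
  }
  out <- lapply(seq_along(tracks), function(id) {
    tr <- tracks[[id]]
    data.frame(frame = tr$frame, x = tr$x, y = tr$y,
               detection = tr$detection, interpolated = FALSE)
  })
  structure(out, class = "ngv_tracks")
}

#' @export
print.ngv_tracks <- function(x, ...) {
  len <- vapply(x, nrow, integer(1))
  cat(sprintf("%d trajectories (length %d-%d frames)\n",
              length(x), if (length(len)) min(len) else 0,
              if (length(len)) max(len) else 0))
  invisible(x)
}

## Optimal one-to-one assignment of tracks (rows) to detections (cols)
## minimising sum of finite link costs plus `b` per unmatched row/col,
## solved exactly per connected component of the candidate graph.
## Returns, per detection, the matched row index or NA.
solve_links <- function(cost, b) {
  nr <- nrow(cost); nc <- ncol(cost)
  det_match <- rep(NA_integer_, nc)
  if (nr == 0 || nc == 0) return(det_match)
  finite <- is.finite(cost)
  ## connected components over the bipartite candidate graph
  row_comp <- rep(0L, nr); col_comp <- rep(0L, nc); comp <- 0L
  for (r in seq_len(nr)) {
    if (row_comp[r] > 0 || !any(finite[r, ])) next
    comp <- comp + 1L
    rq <- r
    while (length(rq)) {
      rr <- rq[1]; rq <- rq[-1]
      if (row_comp[rr] > 0) next
      row_comp[rr] <- comp
      for (cc in which(finite[rr, ] & col_comp == 0)) {
        col_comp[cc] <- comp
        more <- which(finite[, cc] & row_comp == 0)
        rq <- c(rq, more)
      }
    }
  }
  for (k in seq_len(comp)) {
    rows <- which(row_comp == k); cols <- which(col_comp == k)
    sub <- cost[rows, cols, drop = FALSE]
    sol <- assign_component(sub, b)
    for (j in seq_along(cols))
      if (!is.na(sol[j])) det_match[cols[j]] <- rows[sol[j]]
  }
  det_match
}

## Exact branch-and-bound over one component: returns per column the row
## index (within the component) or NA. Cost of leaving a row or column
## unmatched is b; every candidate link costs less than 2b, so optimal
## solutions have maximum cardinality with minimum summed displacement.
assign_component <- function(cost, b) {
  nr <- nrow(cost); nc <- ncol(cost)
  if (nr == 1 && nc == 1) {
    return(if (is.finite(cost[1, 1])) 1L else NA_integer_)
  }
  best <- list(cost = Inf, match = rep(NA_integer_, nc))
  ## order rows by number of options (fewest first) for early pruning
  ord <- order(rowSums(is.finite(cost)))
  col_used <- rep(FALSE, nc)
  match_row <- rep(NA_integer_, nc)
  recurse <- function(i, acc) {
    if (acc >= best$cost) return()
    if (i > nr) {
      total <- acc + b * sum(!col_used) # unmatched detections
      if (total < best$cost) best <<- list(cost = total, match = match_row)
      return()
    }
    r <- ord[i]
    opts <- which(is.finite(cost[r, ]) & !col_used)
    if (length(opts)) opts <- opts[order(cost[r, opts])]
    for (cc in opts) {
      col_used[cc] <<- TRUE; match_row[cc] <<- r
      recurse(i + 1, acc + cost[r, cc])
      col_used[cc] <<- FALSE; match_row[cc] <<- NA_integer_
    }
    recurse(i + 1, acc + b)             # leave this track unmatched
  }
  recurse(1L, 0)
  best$match
}

#' Fill interior gaps of a trajectory by linear interpolation
#'
#' While an object is undetected it is assumed to travel in a straight
#' line between its last known position and the first position after
#' reappearing; every missing interior frame receives the interpolated
#' position and is flagged. Endpoints are never extrapolated.
#'
#' @param traj a trajectory data.frame (`frame`, `x`, `y`, ...).
#' @return the trajectory with every interior frame present and an
#'   `interpolated` flag.
#' @export
fill_gaps <- function(traj) {
  if (nrow(traj) < 2) {
    traj$interpolated <- rep(FALSE, nrow(traj))
    return(traj)
  }
  traj <- traj[order(traj$frame), ]
  full <- seq(min(traj$frame), max(traj$frame))
  if (length(full) == nrow(traj)) {
    traj$interpolated <- FALSE
    return(traj)
  }
  x <- stats::approx(traj$frame, traj$x, xout = full)$y
  y <- stats::approx(traj$frame, traj$y, xout = full)$y
  out <- data.frame(frame = full, x = x, y = y,
                    detection = NA_integer_,
                    interpolated = !(full %in% traj$frame))
  if ("detection" %in% names(traj))
    out$detection[!out$interpolated] <- traj$detection
  else
    out$detection <- NULL
  out
}
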