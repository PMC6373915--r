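## Independent brute-force oracles: deliberately plain, loop-based
## re-implementations used only to cross-check the package's algorithms on
## small instances. They share no code with the implementation.

## Transitive closure over the pairwise distance matrix: two points share a
## group iff connected by a chain of steps <= cutoff.
bf_cluster <- function(coords, cutoff) {
  n <- nrow(coords)
  adj <- as.matrix(stats::dist(coords)) <= cutoff
  group <- rep(0L, n)
  g <- 0L
  for (i in seq_len(n)) {
    if (group[i] > 0) next
    g <- g + 1L
    frontier <- i
    while (length(frontier)) {
      group[frontier] <- g
      nxt <- integer(0)
      for (f in frontier) nxt <- c(nxt, which(adj[f, ] & group == 0L))
      frontier <- unique(nxt)
    }
  }
  group
}

## Canonical form of a pixel partition: sorted list of sorted "x,y" keys.
partition_key <- function(groups_of_coords) {
  keys <- vapply(groups_of_coords, function(m) {
    paste(sort(paste(m[, 1], m[, 2], sep = ",")), collapse = ";")
  }, character(1))
  sort(keys)
}

## Straight-line re-implementation of largest-first hull merging.
bf_merge <- function(clusters, merge_distance, min_px) {
  clusters <- clusters[vapply(clusters, nrow, integer(1)) >= min_px]
  hull_of <- function(m) {
    if (nrow(m) < 3) return(m)
    h <- grDevices::chull(m[, 1], m[, 2])
    if (length(h) < 3) m else m[h, , drop = FALSE]
  }
  setdist <- function(a, b) {
    best <- Inf
    for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
      d <- sqrt((a[i, 1] - b[j, 1])^2 + (a[i, 2] - b[j, 2])^2)
      if (d < best) best <- d
    }
    best
  }
  first_key <- function(m) min(m[, 2] * 2^26 + m[, 1])
  out <- list()
  while (length(clusters)) {
    sizes <- vapply(clusters, nrow, integer(1))
    keys <- vapply(clusters, first_key, numeric(1))
    pick <- order(-sizes, keys)[1]
    cur <- clusters[[pick]]
    clusters <- clusters[-pick]
    repeat {
      absorbed <- FALSE
      h <- hull_of(cur)
      i <- 1
      drop <- integer(0)
      for (i in seq_along(clusters)) {
        if (setdist(h, hull_of(clusters[[i]])) <= merge_distance) {
          cur <- rbind(cur, clusters[[i]])
          drop <- c(drop, i)
          absorbed <- TRUE
        }
      }
      if (length(drop)) clusters <- clusters[-drop]
      if (!absorbed) break
    }
    out[[length(out) + 1]] <- cur
  }
  out
}

## Exhaustive frame-by-frame linker with the same semantics as link():
## per frame, enumerate every injective partial matching of active tracks
## to detections (links only within max_displacement) and take the one
## minimising sum of squared displacements + b per unmatched track and
## detection.
bf_link <- function(detections_by_frame, max_displacement, memory,
                    frame0 = 0) {
  b <- max_displacement^2
  active <- list(); tracks <- list(); next_id <- 1L
  enumerate <- function(cost) {
    nr <- nrow(cost); nc <- ncol(cost)
    best <- list(cost = Inf, match = rep(NA_integer_, nc))
    rec <- function(r, match, acc) {
      if (r > nr) {
        tot <- acc + b * sum(is.na(match)) + b * (nr - sum(!is.na(match)))
        if (tot < best$cost) best <<- list(cost = tot, match = match)
        return()
      }
      rec(r + 1, match, acc)                     # row unmatched
      for (cc in seq_len(nc)) {
        if (is.finite(cost[r, cc]) && !(r %in% match)) {
          m2 <- match; m2[cc] <- r
          rec(r + 1, m2, acc + cost[r, cc])
        }
      }
    }
    if (nc == 0 || nr == 0) return(best$match)
    rec(1L, rep(NA_integer_, nc), 0)
    best$match
  }
  for (fi in seq_along(detections_by_frame)) {
    frame <- frame0 + fi - 1L
    if (length(active)) {
      keep <- vapply(active, function(a) frame - a$last <= memory + 1,
                     logical(1))
      active <- active[keep]
    }
    det <- detections_by_frame[[fi]]
    if (is.null(det) || NROW(det) == 0) next
    dx <- det$x; dy <- det$y
    nd <- length(dx)
    match <- rep(NA_integer_, nd)
    if (length(active)) {
      cost <- matrix(Inf, length(active), nd)
      for (i in seq_along(active)) for (j in seq_len(nd)) {
        d2 <- (active[[i]]$x - dx[j])^2 + (active[[i]]$y - dy[j])^2
        if (d2 <= b) cost[i, j] <- d2
      }
      match <- enumerate(cost)
    }
    for (j in seq_len(nd)) {
      if (is.na(match[j])) {
        active[[length(active) + 1]] <- list(id = next_id, x = dx[j],
                                             y = dy[j], last = frame)
        tracks[[next_id]] <- data.frame(frame = frame, x = dx[j], y = dy[j])
        next_id <- next_id + 1L
      } else {
        a <- match[j]
        id <- active[[a]]$id
        tracks[[id]] <- rbind(tracks[[id]],
                              data.frame(frame = frame, x = dx[j], y = dy[j]))
        active[[a]]$x <- dx[j]; active[[a]]$y <- dy[j]
        active[[a]]$last <- frame
      }
    }
  }
  tracks
}

## Exhaustive best-first pairing: scan the whole table for the global
## minimum each round.
bf_pair <- function(tab, cutoff) {
  tab <- tab[tab$mean_distance <= cutoff, , drop = FALSE]
  out <- NULL
  while (nrow(tab)) {
    best <- 1
    for (i in seq_len(nrow(tab))) {
      if (tab$mean_distance[i] < tab$mean_distance[best] ||
          (tab$mean_distance[i] == tab$mean_distance[best] &&
           (tab$nucleus_id[i] < tab$nucleus_id[best] ||
            (tab$nucleus_id[i] == tab$nucleus_id[best] &&
             tab$golgi_id[i] < tab$golgi_id[best]))))
        best <- i
    }
    out <- rbind(out, tab[best, ])
    tab <- tab[tab$nucleus_id != tab$nucleus_id[best] &
                 tab$golgi_id != tab$golgi_id[best], , drop = FALSE]
  }
  out
}
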