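# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# All frame-(f, f+1) links satisfying: distance <= max_step, and the
# partner is the unique point strictly within the exclusion radius on both
# sides. Returns a data.frame of (row_a, row_b) indices into the
# frame-sorted table.
oracle_link_pairs <- function(locs, max_step = 600, excl = 900) {
  locs <- locs[order(locs$frame), , drop = FALSE]
  n <- nrow(locs)
  out <- list()
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (locs$frame[b] != locs$frame[a] + 1) next
      d <- sqrt((locs$x_nm[a] - locs$x_nm[b])^2 +
                  (locs$y_nm[a] - locs$y_nm[b])^2)
      if (d > max_step) next
      ok <- TRUE
      for (b2 in seq_len(n)) {         # competitors in frame f+1
        if (b2 == b || locs$frame[b2] != locs$frame[a] + 1) next
        if (sqrt((locs$x_nm[a] - locs$x_nm[b2])^2 +
                   (locs$y_nm[a] - locs$y_nm[b2])^2) < excl) ok <- FALSE
      }
      for (a2 in seq_len(n)) {         # competitors in frame f
        if (a2 == a || locs$frame[a2] != locs$frame[a]) next
        if (sqrt((locs$x_nm[a2] - locs$x_nm[b])^2 +
                   (locs$y_nm[a2] - locs$y_nm[b])^2) < excl) ok <- FALSE
      }
      if (ok) out[[length(out) + 1L]] <- c(a, b)
    }
  }
  if (!length(out)) return(data.frame(row_a = integer(), row_b = integer()))
  m <- do.call(rbind, out)
  data.frame(row_a = m[, 1], row_b = m[, 2])
}

# Links actually present in a link_localizations() result, as (row_a,
# row_b) pairs of frame-sorted input rows.
linked_pairs <- function(trajs) {
  if (nrow(trajs) == 0) {
    return(data.frame(row_a = integer(), row_b = integer()))
  }
  out <- lapply(split(trajs, trajs$trajectory_id), function(tr) {
    tr <- tr[order(tr$frame), ]
    data.frame(row_a = tr$loc_row[-nrow(tr)], row_b = tr$loc_row[-1])
  })
  d <- do.call(rbind, out)
  d <- d[order(d$row_a), , drop = FALSE]
  rownames(d) <- NULL
  d
}

# O(n^2) DBSCAN* oracle: full distance matrix, core points, BFS over the
# core-core adjacency graph.
oracle_dbscan_star <- function(x, y, eps, min_pts) {
  n <- length(x)
  if (n == 0) return(integer(0))
  d2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2
  adj <- d2 <= eps^2
  core <- rowSums(adj) >= min_pts     # self counted on the diagonal
  labels <- integer(n)
  lab <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    lab <- lab + 1L
    queue <- i
    labels[i] <- lab
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      nb <- which(adj[j, ] & core & labels == 0L)
      labels[nb] <- lab
      queue <- c(queue, nb)
    }
  }
  labels
}

# canonical form of a labelling: relabel clusters by order of first
# appearance so two labellings can be compared directly
canon_labels <- function(l) {
  pos <- l > 0
  l[pos] <- match(l[pos], unique(l[pos]))
  l
}

# polygon area by triangle-fan decomposition (independent of shoelace)
oracle_fan_area <- function(poly) {
  n <- nrow(poly)
  a <- 0
  for (i in 2:(n - 1)) {
    v1 <- poly[i, ] - poly[1, ]
    v2 <- poly[i + 1, ] - poly[1, ]
    a <- a + (v1[1] * v2[2] - v1[2] * v2[1]) / 2
  }
  abs(a)
}

# direct re-summation of the lag-1 MSD in um^2
oracle_msd <- function(traj) {
  tr <- traj[order(traj$frame), ]
  s <- 0
  for (i in 2:nrow(tr)) {
    s <- s + (tr$x_nm[i] - tr$x_nm[i - 1])^2 +
      (tr$y_nm[i] - tr$y_nm[i - 1])^2
  }
  s / (nrow(tr) - 1) / 1e6
}

# small helper: build a localization table quickly
loc_table <- function(frame, x, y) data.frame(frame = frame, x_nm = x, y_nm = y)
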