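# Frame-to-frame trajectory linking with a maximum step distance and a
# nearest-neighbour exclusion radius.

#' Tracking parameters
#'
#' Defaults are the linking rules used for bacterial single-molecule
#' tracking here: a maximum step distance of 0.6 um between consecutive
#' frames and a nearest-neighbour exclusion radius of 0.9 um.
#'
#' @param max_step maximum frame-to-frame step in nm (default 600).
#' @param exclusion_radius nearest-neighbour exclusion radius in nm
#'   (default 900); must be >= `max_step`.
#' @param exclusion_mode `"veto"` (default): any competing localization
#'   strictly within the exclusion radius of either end point cancels the
#'   link. `"nearest"`: competitors only disqualify a link if they are at
#'   least as close as the candidate (mutual-nearest-neighbour linking
#'   within `max_step`).
#' @return a `tracking_params` list.
#' @export
tracking_params <- function(max_step = 600, exclusion_radius = 900,
                            exclusion_mode = c("veto", "nearest")) {
  check_number(max_step, "max_step", lower = .Machine$double.xmin)
  check_number(exclusion_radius, "exclusion_radius", lower = max_step)
  exclusion_mode <- match.arg(exclusion_mode)
  structure(list(max_step = max_step, exclusion_radius = exclusion_radius,
                 exclusion_mode = exclusion_mode),
            class = "tracking_params")
}

#' Link localizations into single-molecule trajectories
#'
#' Greedy frame-to-frame linking: a localization L in frame f links to M in
#' frame f+1 iff (i) dist(L, M) <= `max_step`, (ii) M is the only frame-f+1
#' localization strictly within `exclusion_radius` of L, and (iii) L is the
#' only frame-f localization strictly within `exclusion_radius` of M. Any
#' ambiguity (a second localization within the radius on either side)
#' vetoes the link. Chains of links over strictly consecutive frames form
#' trajectories; localizations that link to nothing are discarded. There is
#' no gap closing: a dark frame terminates a trajectory.
#'
#' @param locs data.frame with columns `frame` (0-based integer), `x_nm`,
#'   `y_nm`; sorted or sortable by frame.
#' @param params a [tracking_params()].
#' @return data.frame with columns `trajectory_id`, `frame`, `x_nm`,
#'   `y_nm`, plus `loc_row` (the row index of each localization in the
#'   sorted input, for provenance). Empty input gives an empty result.
#' @export
link_localizations <- function(locs, params = tracking_params()) {
  stopifnot(inherits(params, "tracking_params"))
  empty <- data.frame(trajectory_id = integer(), frame = integer(),
                      x_nm = numeric(), y_nm = numeric(),
                      loc_row = integer())
  if (nrow(locs) == 0) return(empty)
  stop_if(!all(c("frame", "x_nm", "y_nm") %in% names(locs)),
          "localization table must have columns frame, x_nm, y_nm")
  stop_if(any(!is.finite(locs$x_nm)) || any(!is.finite(locs$y_nm)),
          "localization coordinates must be finite")
  stop_if(any(locs$frame < 0) || any(locs$frame != round(locs$frame)),
          "frames must be non-negative integers")
  ord <- order(locs$frame)
  locs <- locs[ord, , drop = FALSE]
  n <- nrow(locs)
  frames <- locs$frame
  by_frame <- split(seq_len(n), frames)
  frame_keys <- as.numeric(names(by_frame))

  succ <- rep(NA_integer_, n)  # successor row for each localization
  for (fi in seq_along(frame_keys)) {
    nj <- match(frame_keys[fi] + 1, frame_keys)
    if (is.na(nj)) next
    a <- by_frame[[fi]]; b <- by_frame[[nj]]
    dx <- outer(locs$x_nm[a], locs$x_nm[b], "-")
    dy <- outer(locs$y_nm[a], locs$y_nm[b], "-")
    d <- sqrt(dx^2 + dy^2)
    if (params$exclusion_mode == "veto") {
      in_excl <- d < params$exclusion_radius
      ok <- d <= params$max_step &
        rowSums(in_excl) == 1L &
        matrix(colSums(in_excl), nrow = length(a), ncol = length(b),
               byrow = TRUE) == 1L
    } else {
      # mutual nearest neighbour within max_step; exact ties veto
      ok <- d <= params$max_step
      if (any(ok)) {
        row_min <- apply(d, 1, min)
        col_min <- apply(d, 2, min)
        is_row_min <- sweep(d, 1, row_min, "<=") &
          rowSums(sweep(d, 1, row_min, "==")) == 1L
        is_col_min <- sweep(d, 2, col_min, "<=") &
          matrix(colSums(sweep(d, 2, col_min, "==")), nrow = length(a),
                 ncol = length(b), byrow = TRUE) == 1L
        ok <- ok & is_row_min & is_col_min
      }
    }
    w <- which(ok, arr.ind = TRUE)
    if (nrow(w)) succ[a[w[, 1]]] <- b[w[, 2]]
  }

  has_pred <- logical(n)
  has_pred[succ[!is.na(succ)]] <- TRUE
  starts <- which(!is.na(succ) & !has_pred)
  if (!length(starts)) return(empty)
  pieces <- vector("list", length(starts))
  for (t in seq_along(starts)) {
    rows <- starts[t]
    while (!is.na(succ[rows[length(rows)]])) {
      rows <- c(rows, succ[rows[length(rows)]])
    }
    pieces[[t]] <- data.frame(trajectory_id = t, frame = frames[rows],
                              x_nm = locs$x_nm[rows], y_nm = locs$y_nm[rows],
                              loc_row = rows)
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Keep trajectories with at least a minimum number of steps
#'
#' @param trajs trajectory data.frame from [link_localizations()].
#' @param min_steps minimum number of displacement steps (a trajectory of k
#'   localizations has k - 1 steps); default 4.
#' @return filtered trajectory data.frame.
#' @export
filter_trajectories <- function(trajs, min_steps = 4) {
  check_count(min_steps, "min_steps", lower = 1)
  if (nrow(trajs) == 0) return(trajs)
  len <- table(trajs$trajectory_id)
  keep <- names(len)[len >= min_steps + 1]
  out <- trajs[as.character(trajs$trajectory_id) %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read / write trajectory tables
#' @param trajs trajectory data.frame.
#' @param path file path.
#' @return `read_trajectories` returns the trajectory data.frame.
#' @export
write_trajectories <- function(trajs, path) {
  utils::write.csv(trajs[, c("trajectory_id", "frame", "x_nm", "y_nm")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  d <- utils::read.csv(path)
  stop_if(!all(c("trajectory_id", "frame", "x_nm", "y_nm") %in% names(d)),
          "trajectory CSV must have columns trajectory_id,frame,x_nm,y_nm")
  d
}
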