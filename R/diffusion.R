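# Apparent diffusion coefficients from mean squared displacement, and the
# immobile-fraction (%H_IM) condensation proxy.

#' Lag-1 mean squared displacement of a trajectory
#'
#' Mean over all consecutive-frame pairs of the squared 2D displacement,
#' in um^2 (input coordinates are nm).
#'
#' @param traj data.frame with `frame`, `x_nm`, `y_nm` for one trajectory
#'   (strictly consecutive frames).
#' @return MSD at lag 1 in um^2.
#' @export
msd_lag1 <- function(traj) {
  n <- nrow(traj)
  stop_if(n < 2, "MSD undefined for a single-localization trajectory")
  ord <- order(traj$frame)
  x <- traj$x_nm[ord]; y <- traj$y_nm[ord]
  stop_if(any(diff(traj$frame[ord]) != 1),
          "trajectory frames must be strictly consecutive")
  mean(diff(x)^2 + diff(y)^2) / 1e6
}

# MSD at lags 1..max_lag (um^2), for the multi-lag estimator
msd_multilag <- function(x, y, max_lag) {
  vapply(seq_len(max_lag), function(k) {
    n <- length(x)
    mean((x[(k + 1):n] - x[1:(n - k)])^2 +
           (y[(k + 1):n] - y[1:(n - k)])^2) / 1e6
  }, numeric(1))
}

#' Apparent diffusion coefficient of one trajectory
#'
#' Default estimator: D* = MSD(lag 1) / (4 * frame_interval), the standard
#' apparent-diffusion convention for short 2D single-molecule tracks.
#' `estimator = "fit"` instead fits MSD(k) ~ slope * (k * frame_interval)
#' through the origin over lags 1..4 and returns slope / 4.
#'
#' No localization-noise correction is applied; with per-axis noise sd
#' sigma the lag-1 estimator has expectation D + sigma^2 / frame_interval.
#'
#' @param traj one trajectory (data.frame `frame`, `x_nm`, `y_nm`).
#' @param frame_interval frame interval in seconds.
#' @param estimator `"lag1"` (default) or `"fit"`.
#' @return one-row data.frame: `D_star` (um^2/s), `n_steps`.
#' @export
apparent_diffusion <- function(traj, frame_interval = 1 / 66,
                               estimator = c("lag1", "fit")) {
  check_number(frame_interval, "frame_interval",
               lower = .Machine$double.xmin)
  estimator <- match.arg(estimator)
  n_steps <- nrow(traj) - 1L
  if (estimator == "lag1") {
    d_star <- msd_lag1(traj) / (4 * frame_interval)
  } else {
    ord <- order(traj$frame)
    max_lag <- min(4L, n_steps)
    m <- msd_multilag(traj$x_nm[ord], traj$y_nm[ord], max_lag)
    tau <- seq_len(max_lag) * frame_interval
    d_star <- sum(m * tau) / sum(tau^2) / 4
  }
  data.frame(D_star = d_star, n_steps = n_steps)
}

#' Per-trajectory apparent diffusion for a trajectory table
#'
#' Applies the minimum-step filter (at least `min_steps` displacement
#' steps, default 4) and computes D* for each retained trajectory.
#'
#' @param trajs trajectory data.frame from [link_localizations()].
#' @param frame_interval frame interval in seconds (default 1/66).
#' @param min_steps minimum steps per trajectory (default 4).
#' @param estimator passed to [apparent_diffusion()].
#' @return data.frame `trajectory_id`, `D_star`, `n_steps`.
#' @export
compute_diffusion <- function(trajs, frame_interval = 1 / 66, min_steps = 4,
                              estimator = c("lag1", "fit")) {
  estimator <- match.arg(estimator)
  trajs <- filter_trajectories(trajs, min_steps)
  if (nrow(trajs) == 0) {
    return(data.frame(trajectory_id = integer(), D_star = numeric(),
                      n_steps = integer()))
  }
  recs <- lapply(split(trajs, trajs$trajectory_id), function(tr) {
    cbind(trajectory_id = tr$trajectory_id[1],
          apparent_diffusion(tr, frame_interval, estimator))
  })
  out <- do.call(rbind, recs)
  out <- out[order(out$trajectory_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Immobile fraction (%H_IM)
#'
#' Percentage of trajectories whose apparent diffusion coefficient falls at
#' or below the immobile threshold (0.08 um^2/s by default, the study's
#' condensation proxy). `inclusive = FALSE` uses a strict < comparison.
#'
#' @param d_star numeric vector of per-trajectory D* values (um^2/s), or a
#'   data.frame with a `D_star` column.
#' @param threshold immobile threshold in um^2/s (default 0.08).
#' @param inclusive count values equal to the threshold as immobile
#'   (default TRUE).
#' @return percentage in [0, 100].
#' @export
immobile_fraction <- function(d_star, threshold = 0.08, inclusive = TRUE) {
  if (is.data.frame(d_star)) d_star <- d_star$D_star
  check_number(threshold, "threshold", lower = .Machine$double.xmin)
  stop_if(length(d_star) == 0,
          "immobile fraction undefined for an empty record set")
  imm <- if (inclusive) d_star <= threshold else d_star < threshold
  100 * mean(imm)
}

#' Pool immobile fractions over fields of view
#'
#' The pooled %H_IM is computed over the concatenation of all trajectories
#' (trajectory-weighted), not as a mean of per-FOV percentages.
#'
#' @param fov_records named list of per-FOV D* vectors or diffusion
#'   data.frames.
#' @param threshold,inclusive passed to [immobile_fraction()].
#' @return list with `per_fov` (data.frame `fov_id`, `n_trajectories`,
#'   `H_IM`) and `pooled` (scalar percent).
#' @export
pool_fovs <- function(fov_records, threshold = 0.08, inclusive = TRUE) {
  stop_if(length(fov_records) == 0, "need at least one field of view")
  vals <- lapply(fov_records, function(r) {
    if (is.data.frame(r)) r$D_star else r
  })
  ids <- names(vals)
  if (is.null(ids)) ids <- as.character(seq_along(vals))
  per_fov <- data.frame(
    fov_id = ids,
    n_trajectories = vapply(vals, length, integer(1)),
    H_IM = vapply(vals, immobile_fraction, numeric(1),
                  threshold = threshold, inclusive = inclusive))
  rownames(per_fov) <- NULL
  list(per_fov = per_fov,
       pooled = immobile_fraction(unlist(vals), threshold, inclusive))
}
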