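# Synthetic PALM acquisitions: rod-shaped cells, two-population Brownian
# motion (freely diffusing vs condensate-confined), stochastic
# photoactivation, Gaussian localization noise.

#' Acquisition settings for a synthetic PALM movie
#'
#' Defaults mirror a typical PALM single-molecule-tracking acquisition on a
#' bacterial field of view: 66 frames per second over 10 000 frames, with
#' isotropic Gaussian localization error.
#'
#' @param frame_interval frame interval in seconds (default 1/66).
#' @param n_frames number of frames in the acquisition.
#' @param localization_sigma per-axis localization error sd in nm.
#' @param activation_rate per-molecule per-frame photoactivation probability.
#' @param mean_on_frames expected number of emitting frames before bleaching
#'   (geometric on-time, minimum 1 frame).
#' @param field_width,field_height field of view extent in nm.
#' @return an `acquisition_config` list.
#' @export
acquisition_config <- function(frame_interval = 1 / 66,
                               n_frames = 10000,
                               localization_sigma = 20,
                               activation_rate = 5e-4,
                               mean_on_frames = 15,
                               field_width = 40000,
                               field_height = 20000) {
  check_number(frame_interval, "frame_interval", lower = .Machine$double.xmin)
  check_count(n_frames, "n_frames", lower = 1)
  check_number(localization_sigma, "localization_sigma", lower = 0)
  check_number(activation_rate, "activation_rate", lower = 0, upper = 1)
  check_number(mean_on_frames, "mean_on_frames", lower = 1)
  check_number(field_width, "field_width", lower = 1)
  check_number(field_height, "field_height", lower = 1)
  structure(list(frame_interval = frame_interval,
                 n_frames = as.integer(n_frames),
                 localization_sigma = localization_sigma,
                 activation_rate = activation_rate,
                 mean_on_frames = mean_on_frames,
                 field_width = field_width,
                 field_height = field_height),
            class = "acquisition_config")
}

#' Cell-population settings for a synthetic PALM field
#'
#' Encodes the two-population structure behind the immobile-fraction
#' statistic: each molecule is either freely diffusing (`D_mobile`) or
#' confined to a polar condensate disc (`D_immobile`), and a configurable
#' fraction of cells carries a condensate.
#'
#' @param n_cells number of rod-shaped cells placed in the field.
#' @param cell_length,cell_width overall rod dimensions in nm (length
#'   includes the two semicircular caps of radius `cell_width / 2`).
#' @param molecules_per_cell photoactivatable molecules per cell.
#' @param D_mobile,D_immobile diffusion coefficients in um^2/s for the two
#'   populations; `D_mobile > D_immobile >= 0` required.
#' @param immobile_fraction probability a molecule is condensate-confined
#'   (realized only in cells flagged as carrying a condensate).
#' @param condensate_radius condensate disc radius in nm.
#' @param condensate_offset distance of the condensate centre from the cell
#'   pole tip along the long axis, in nm.
#' @param cells_with_condensate_fraction fraction of cells flagged as
#'   carrying a condensate (exactly `round(n_cells * fraction)` are flagged).
#' @param seed integer seed; all simulator randomness flows from it.
#' @return a `population_config` list.
#' @export
population_config <- function(n_cells = 100,
                              cell_length = 3000,
                              cell_width = 1000,
                              molecules_per_cell = 60,
                              D_mobile = 0.5,
                              D_immobile = 0.01,
                              immobile_fraction = 0.5,
                              condensate_radius = 100,
                              condensate_offset = 400,
                              cells_with_condensate_fraction = 0.85,
                              seed = 1L) {
  check_count(n_cells, "n_cells", lower = 1)
  check_number(cell_length, "cell_length", lower = 1)
  check_number(cell_width, "cell_width", lower = 1)
  stop_if(cell_width > cell_length,
          "'cell_width' must not exceed 'cell_length'")
  check_count(molecules_per_cell, "molecules_per_cell", lower = 1)
  check_number(D_mobile, "D_mobile", lower = 0)
  check_number(D_immobile, "D_immobile", lower = 0)
  stop_if(D_mobile < D_immobile, "'D_mobile' must be >= 'D_immobile'")
  check_number(immobile_fraction, "immobile_fraction", lower = 0, upper = 1)
  check_number(condensate_radius, "condensate_radius", lower = 0)
  check_number(condensate_offset, "condensate_offset", lower = 0)
  check_number(cells_with_condensate_fraction,
               "cells_with_condensate_fraction", lower = 0, upper = 1)
  stop_if(condensate_radius + condensate_offset > cell_length / 2,
          "condensate does not fit: condensate_radius + condensate_offset must be <= cell_length/2")
  stop_if(condensate_radius > 0 &&
            condensate_radius > min(cell_width / 2, condensate_offset),
          "condensate disc pokes outside the rod: need condensate_radius <= min(cell_width/2, condensate_offset)")
  check_count(seed, "seed")
  structure(list(n_cells = as.integer(n_cells),
                 cell_length = cell_length,
                 cell_width = cell_width,
                 molecules_per_cell = as.integer(molecules_per_cell),
                 D_mobile = D_mobile,
                 D_immobile = D_immobile,
                 immobile_fraction = immobile_fraction,
                 condensate_radius = condensate_radius,
                 condensate_offset = condensate_offset,
                 cells_with_condensate_fraction = cells_with_condensate_fraction,
                 seed = as.integer(seed)),
            class = "population_config")
}

# Rod geometry: the rod is the set of points within cell_width/2 of the
# central axis segment; total length = segment length + cell_width.

rod_axis_half <- function(cell) (cell$length - cell$width) / 2

#' Area of a rod-shaped cell (rectangle plus two semicircular caps)
#' @param cell_length,cell_width rod dimensions in nm.
#' @return area in nm^2.
#' @export
rod_area <- function(cell_length, cell_width) {
  (cell_length - cell_width) * cell_width + pi * (cell_width / 2)^2
}

#' Polygon outline of a rod cell
#' @param cx,cy centre; `length`,`width` in nm; `n_cap` vertices per cap.
#' @return two-column matrix of vertices (counter-clockwise).
#' @export
rod_polygon <- function(cx, cy, length, width, n_cap = 24) {
  h <- (length - width) / 2
  r <- width / 2
  th_r <- seq(-pi / 2, pi / 2, length.out = n_cap)   # right cap
  th_l <- seq(pi / 2, 3 * pi / 2, length.out = n_cap) # left cap
  x <- c(cx + h + r * cos(th_r), cx - h + r * cos(th_l))
  y <- c(cy + r * sin(th_r), cy + r * sin(th_l))
  cbind(x = x, y = y)
}

# signed clearance: distance from the rod boundary, positive inside
rod_clearance <- function(x, y, cx, cy, half, r) {
  dx <- pmin(pmax(x - cx, -half), half)
  r - sqrt((x - cx - dx)^2 + (y - cy)^2)
}

#' Place rod-shaped cells in a field of view
#'
#' Cells are laid on a jittered grid (axis-aligned rods) so they never
#' overlap; exactly `round(n_cells * cells_with_condensate_fraction)` cells
#' are flagged as carrying a condensate, whose centre sits
#' `condensate_offset` nm from one pole on the long axis.
#'
#' @param pop a [population_config()].
#' @param acq an [acquisition_config()] supplying the field extent.
#' @return data.frame with one row per cell: `cell_id`, centre (`cx`, `cy`),
#'   `length`, `width`, `has_condensate`, condensate centre (`cond_x`,
#'   `cond_y`) and radius `cond_r` (NA when absent), `area_nm2`.
#' @export
simulate_cells <- function(pop, acq = acquisition_config()) {
  stopifnot(inherits(pop, "population_config"),
            inherits(acq, "acquisition_config"))
  margin <- 400
  sx <- pop$cell_length + margin
  sy <- pop$cell_width + margin
  n_col <- floor(acq$field_width / sx)
  n_row <- floor(acq$field_height / sy)
  if (n_col * n_row < pop$n_cells) {
    need_cols <- ceiling(sqrt(pop$n_cells * sx / sy))
    stop(sprintf(paste0("field %g x %g nm holds at most %d non-overlapping ",
                        "cells; need >= %g x %g nm for %d cells"),
                 acq$field_width, acq$field_height, n_col * n_row,
                 need_cols * sx, ceiling(pop$n_cells / need_cols) * sy,
                 pop$n_cells), call. = FALSE)
  }
  withr::with_seed(pop$seed, {
    slots <- seq_len(n_col * n_row)[seq_len(pop$n_cells)]
    col <- (slots - 1L) %% n_col
    row <- (slots - 1L) %/% n_col
    jit <- margin / 2 - 10
    cx <- col * sx + sx / 2 + stats::runif(pop$n_cells, -jit / 2, jit / 2)
    cy <- row * sy + sy / 2 + stats::runif(pop$n_cells, -jit / 2, jit / 2)
    n_flag <- round(pop$n_cells * pop$cells_with_condensate_fraction)
    has_cond <- logical(pop$n_cells)
    if (n_flag > 0) has_cond[sample.int(pop$n_cells, n_flag)] <- TRUE
    pole <- sample(c(-1, 1), pop$n_cells, replace = TRUE)
    cond_x <- ifelse(has_cond,
                     cx + pole * (pop$cell_length / 2 - pop$condensate_offset),
                     NA_real_)
    cond_y <- ifelse(has_cond, cy, NA_real_)
    data.frame(cell_id = seq_len(pop$n_cells),
               cx = cx, cy = cy,
               length = pop$cell_length, width = pop$cell_width,
               has_condensate = has_cond,
               cond_x = cond_x, cond_y = cond_y,
               cond_r = ifelse(has_cond, pop$condensate_radius, NA_real_),
               area_nm2 = rod_area(pop$cell_length, pop$cell_width))
  })
}

# Reflect a proposed position back inside a rod (fold across the boundary).
reflect_rod <- function(x, y, cx, cy, half, r) {
  for (k in 1:25) {
    dx <- min(max(x - cx, -half), half)
    nx <- cx + dx; ny <- cy
    d <- sqrt((x - nx)^2 + (y - ny)^2)
    if (d <= r) return(c(x, y))
    if (d == 0) return(c(nx + r, ny))
    ux <- (x - nx) / d; uy <- (y - ny) / d
    exc <- d - r
    x <- x - 2 * exc * ux
    y <- y - 2 * exc * uy
  }
  # pathological step length: clamp just inside
  dx <- min(max(x - cx, -half), half)
  d <- sqrt((x - cx - dx)^2 + (y - cy)^2)
  c(cx + dx + (x - cx - dx) / d * r * 0.99, cy + (y - cy) / d * r * 0.99)
}

reflect_disc <- function(x, y, ox, oy, r) {
  for (k in 1:25) {
    d <- sqrt((x - ox)^2 + (y - oy)^2)
    if (d <= r) return(c(x, y))
    exc <- d - r
    x <- x - 2 * exc * (x - ox) / d
    y <- y - 2 * exc * (y - oy) / d
  }
  d <- sqrt((x - ox)^2 + (y - oy)^2)
  c(ox + (x - ox) / d * r * 0.99, oy + (y - oy) / d * r * 0.99)
}

# uniform point inside a rod, by rejection in the bounding box
runif_rod <- function(cx, cy, half, r) {
  repeat {
    x <- stats::runif(1, cx - half - r, cx + half + r)
    y <- stats::runif(1, cy - r, cy + r)
    dx <- min(max(x - cx, -half), half)
    if ((x - cx - dx)^2 + (y - cy)^2 <= r^2) return(c(x, y))
  }
}

runif_disc <- function(ox, oy, r) {
  th <- stats::runif(1, 0, 2 * pi)
  rr <- r * sqrt(stats::runif(1))
  c(ox + rr * cos(th), oy + rr * sin(th))
}

#' Simulate a PALM movie over a cell field
#'
#' Each molecule photoactivates stochastically (per-frame probability
#' `activation_rate`), emits for a geometric number of frames with mean
#' `mean_on_frames`, and performs 2D Brownian motion with the diffusion
#' coefficient of its state (mobile or condensate-confined), reflected at
#' the cell boundary (and at the condensate disc for confined molecules).
#' Every emitted position is reported with isotropic Gaussian localization
#' noise of sd `localization_sigma`.
#'
#' Molecules draw the condensed state i.i.d. with probability
#' `immobile_fraction`; in cells without a condensate, condensed draws are
#' re-assigned mobile and the realized fraction is recorded in the ground
#' truth.
#'
#' @param cells output of [simulate_cells()].
#' @param pop a [population_config()].
#' @param acq an [acquisition_config()].
#' @return list with `localizations` (data.frame `frame` 0-based, `x_nm`,
#'   `y_nm`, sorted by frame) and `ground_truth` (list: `molecules`
#'   data.frame row-aligned with `localizations` carrying `molecule_id`,
#'   `cell_id`, `state`, `frame`, true coordinates; `cells`; and
#'   `realized_immobile_fraction`).
#' @export
simulate_movie <- function(cells, pop, acq = acquisition_config()) {
  stopifnot(is.data.frame(cells), inherits(pop, "population_config"),
            inherits(acq, "acquisition_config"))
  dt <- acq$frame_interval
  sd_mob <- sqrt(2 * pop$D_mobile * dt) * 1000  # um -> nm
  sd_imm <- sqrt(2 * pop$D_immobile * dt) * 1000
  half <- (pop$cell_length - pop$cell_width) / 2
  r_cell <- pop$cell_width / 2

  withr::with_seed(pop$seed + 1L, {
    n_mol <- nrow(cells) * pop$molecules_per_cell
    mol_cell <- rep(cells$cell_id, each = pop$molecules_per_cell)
    want_cond <- stats::runif(n_mol) < pop$immobile_fraction
    cell_has <- cells$has_condensate[mol_cell]
    state <- ifelse(want_cond & cell_has, "condensed", "mobile")

    # activation frame: first success of a Bernoulli(activation_rate) chain
    act <- if (acq$activation_rate > 0) {
      stats::rgeom(n_mol, acq$activation_rate)
    } else rep(Inf, n_mol)
    n_on <- 1L + stats::rgeom(n_mol, 1 / acq$mean_on_frames)

    out <- vector("list", n_mol)
    for (m in seq_len(n_mol)) {
      if (act[m] >= acq$n_frames) next
      ci <- mol_cell[m]
      cl <- cells[ci, ]
      frames <- act[m]:min(act[m] + n_on[m] - 1L, acq$n_frames - 1L)
      k <- length(frames)
      condensed <- state[m] == "condensed"
      if (condensed) {
        p <- runif_disc(cl$cond_x, cl$cond_y, cl$cond_r)
        sdstep <- sd_imm
      } else {
        p <- runif_rod(cl$cx, cl$cy, half, r_cell)
        sdstep <- sd_mob
      }
      xs <- numeric(k); ys <- numeric(k)
      xs[1] <- p[1]; ys[1] <- p[2]
      if (k > 1 && sdstep > 0) {
        stepx <- stats::rnorm(k - 1, 0, sdstep)
        stepy <- stats::rnorm(k - 1, 0, sdstep)
        for (j in 2:k) {
          px <- xs[j - 1] + stepx[j - 1]
          py <- ys[j - 1] + stepy[j - 1]
          p <- if (condensed) {
            reflect_disc(px, py, cl$cond_x, cl$cond_y, cl$cond_r)
          } else {
            reflect_rod(px, py, cl$cx, cl$cy, half, r_cell)
          }
          xs[j] <- p[1]; ys[j] <- p[2]
        }
      } else if (k > 1) {
        xs[2:k] <- xs[1]; ys[2:k] <- ys[1]
      }
      out[[m]] <- data.frame(molecule_id = m, cell_id = ci,
                             state = state[m], frame = frames,
                             x_true_nm = xs, y_true_nm = ys)
    }
    mol <- do.call(rbind, out)
    if (is.null(mol)) {
      mol <- data.frame(molecule_id = integer(), cell_id = integer(),
                        state = character(), frame = integer(),
                        x_true_nm = numeric(), y_true_nm = numeric())
    }
    nr <- nrow(mol)
    mol$x_obs_nm <- mol$x_true_nm +
      stats::rnorm(nr, 0, acq$localization_sigma)
    mol$y_obs_nm <- mol$y_true_nm +
      stats::rnorm(nr, 0, acq$localization_sigma)
    ord <- order(mol$frame, mol$molecule_id)
    mol <- mol[ord, , drop = FALSE]
    rownames(mol) <- NULL
    locs <- data.frame(frame = mol$frame, x_nm = mol$x_obs_nm,
                       y_nm = mol$y_obs_nm)
    list(localizations = locs,
         ground_truth = list(
           molecules = mol,
           cells = cells,
           realized_immobile_fraction = mean(state == "condensed")))
  })
}

# I/O --------------------------------------------------------------------

#' Read / write localization tables
#'
#' CSV with header `frame,x_nm,y_nm`; extra columns (e.g. intensity,
#' precision_nm) are ignored on read.
#' @param locs data.frame with `frame`, `x_nm`, `y_nm`.
#' @param path file path.
#' @return `read_localizations` returns the localization data.frame.
#' @export
write_localizations <- function(locs, path) {
  utils::write.csv(locs[, c("frame", "x_nm", "y_nm")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_localizations
#' @export
read_localizations <- function(path) {
  d <- utils::read.csv(path)
  stop_if(!all(c("frame", "x_nm", "y_nm") %in% names(d)),
          "localization CSV must have columns frame,x_nm,y_nm")
  d[, c("frame", "x_nm", "y_nm")]
}

#' Rasterize a cell field to a labelled mask
#'
#' @param cells output of [simulate_cells()].
#' @param px_size_nm pixel size (default 65 nm/px).
#' @param width_nm,height_nm field extent; defaults tightly bound the cells.
#' @return integer matrix (rows = y, cols = x); 0 = background, otherwise
#'   the `cell_id` occupying the pixel.
#' @export
rasterize_cells <- function(cells, px_size_nm = 65,
                            width_nm = max(cells$cx + cells$length / 2) + px_size_nm,
                            height_nm = max(cells$cy + cells$width / 2) + px_size_nm) {
  nx <- ceiling(width_nm / px_size_nm)
  ny <- ceiling(height_nm / px_size_nm)
  mask <- matrix(0L, nrow = ny, ncol = nx)
  pxx <- (seq_len(nx) - 0.5) * px_size_nm
  pxy <- (seq_len(ny) - 0.5) * px_size_nm
  for (i in seq_len(nrow(cells))) {
    cl <- cells[i, ]
    half <- (cl$length - cl$width) / 2
    r <- cl$width / 2
    ix <- which(pxx >= cl$cx - cl$length / 2 & pxx <= cl$cx + cl$length / 2)
    iy <- which(pxy >= cl$cy - r & pxy <= cl$cy + r)
    if (!length(ix) || !length(iy)) next
    g <- expand.grid(ix = ix, iy = iy)
    keep <- rod_clearance(pxx[g$ix], pxy[g$iy], cl$cx, cl$cy, half, r) >= 0
    mask[cbind(g$iy[keep], g$ix[keep])] <- cl$cell_id
  }
  mask
}

#' Read / write labelled cell masks as 16-bit TIFF
#' @param mask integer label matrix.
#' @param path file path.
#' @return `read_mask_tiff` returns the integer label matrix.
#' @export
write_mask_tiff <- function(mask, path) {
  stop_if(max(mask) > 65535, "mask labels exceed 16-bit range")
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_mask_tiff
#' @export
read_mask_tiff <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  storage.mode(m) <- "integer"
  m
}

#' Write ground truth (molecules + cells CSV, labelled-mask TIFF)
#' @param gt `ground_truth` element of [simulate_movie()] output.
#' @param dir output directory (created if needed).
#' @param px_size_nm mask pixel size in nm.
#' @return invisibly, the output directory.
#' @export
write_ground_truth <- function(gt, dir, px_size_nm = 65) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(gt$molecules, file.path(dir, "molecules.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(gt$cells, file.path(dir, "cells.csv"),
                   row.names = FALSE, quote = FALSE)
  write_mask_tiff(rasterize_cells(gt$cells, px_size_nm),
                  file.path(dir, "cell_mask.tiff"))
  invisible(dir)
}
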