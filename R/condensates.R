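# Condensate detection on pooled localizations: DBSCAN* clustering,
# convex-hull size/density measurement, count/density filters, and per-cell
# summaries.

#' Condensate clustering and filter parameters
#'
#' Presets encode the two condensate definitions used here:
#' `"hfq"` — eps 75 nm, clusters kept with > 50 localizations and density
#' > 0.0015 localizations/nm^2; `"tmar"` — eps 100 nm, > 100 localizations,
#' no density filter. Both filters use strict inequalities. `min_pts` (the
#' DBSCAN core-point neighbour minimum, self included) is not part of
#' either condensate definition and defaults to 5.
#'
#' @param preset `"hfq"`, `"tmar"`, or NULL for fully manual parameters.
#' @param eps DBSCAN neighbourhood radius in nm.
#' @param min_pts core-point minimum neighbour count (self included).
#' @param min_locs_per_cluster keep clusters with strictly more
#'   localizations than this.
#' @param min_density keep clusters with density strictly above this, in
#'   localizations/nm^2; NULL disables the density filter.
#' @return a `cluster_params` list.
#' @export
cluster_params <- function(preset = NULL, eps = NULL, min_pts = 5,
                           min_locs_per_cluster = NULL, min_density = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("hfq", "tmar"))
    def <- switch(preset,
                  hfq = list(eps = 75, min_locs_per_cluster = 50,
                             min_density = 0.0015),
                  tmar = list(eps = 100, min_locs_per_cluster = 100,
                              min_density = NULL))
    if (is.null(eps)) eps <- def$eps
    if (is.null(min_locs_per_cluster))
      min_locs_per_cluster <- def$min_locs_per_cluster
    if (missing(min_density)) min_density <- def$min_density
  }
  check_number(eps, "eps", lower = .Machine$double.xmin)
  check_count(min_pts, "min_pts", lower = 2)
  check_count(min_locs_per_cluster, "min_locs_per_cluster", lower = 1)
  if (!is.null(min_density))
    check_number(min_density, "min_density", lower = 0)
  structure(list(preset = preset, eps = eps, min_pts = as.integer(min_pts),
                 min_locs_per_cluster = as.integer(min_locs_per_cluster),
                 min_density = min_density),
            class = "cluster_params")
}

#' Choose a core-point threshold from the background localization density
#'
#' For pooled single-molecule-tracking localizations, freely diffusing
#' molecules form a diffuse background of density rho (localizations/nm^2).
#' A background point then has Poisson(rho * pi * eps^2) neighbours in its
#' eps-disc, and if `min_pts` is below that count's upper tail, background
#' points become core points and chain condensate clusters into the
#' diffuse cloud (percolation), diluting their hull density. This returns
#' the smallest `min_pts` for which a background point is a core point
#' with probability at most `alpha`.
#'
#' @param bg_density background localization density in localizations/nm^2.
#' @param eps DBSCAN neighbourhood radius in nm.
#' @param alpha acceptable probability that a background point qualifies as
#'   core (default 0.01).
#' @return integer `min_pts` (self included), at least 2.
#' @export
core_min_pts <- function(bg_density, eps, alpha = 0.01) {
  check_number(bg_density, "bg_density", lower = 0)
  check_number(eps, "eps", lower = .Machine$double.xmin)
  check_number(alpha, "alpha", lower = 1e-12, upper = 1)
  lambda <- bg_density * pi * eps^2
  max(2L, as.integer(stats::qpois(1 - alpha, lambda)) + 2L)
}

#' DBSCAN* clustering of 2D localizations
#'
#' DBSCAN* semantics: core points are points with at least `min_pts`
#' neighbours within `eps` (counting themselves); clusters are the
#' connected components of core points under eps-adjacency; all non-core
#' (border) points are noise. Neighbour search uses an eps-sized grid hash,
#' so runtime is near-linear for bounded local densities.
#'
#' @param x,y localization coordinates in nm.
#' @param eps neighbourhood radius in nm.
#' @param min_pts core-point minimum neighbour count, self included.
#' @return integer vector of cluster labels (0 = noise; clusters numbered
#'   1, 2, ... in order of first member appearance).
#' @export
dbscan_star <- function(x, y, eps, min_pts = 5) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n == 0) return(integer(0))
  check_number(eps, "eps", lower = .Machine$double.xmin)
  min_pts <- check_count(min_pts, "min_pts", lower = 2)
  eps2 <- eps^2

  # integer-encoded eps-grid; the +2 stride guard keeps +1 offsets unique
  ix <- as.integer(floor(x / eps)); iy <- as.integer(floor(y / eps))
  ix <- ix - min(ix); iy <- iy - min(iy)
  stride <- max(ix) + 2L
  code <- ix + iy * stride
  cell_of <- split(seq_len(n), code)
  cell_code <- as.integer(names(cell_of))
  n_cells <- length(cell_of)
  # half the 3x3 stencil, so each cell pair is visited exactly once
  offsets <- c(1L, stride - 1L, stride, stride + 1L)
  nb_cell <- lapply(offsets, function(o) match(cell_code + o, cell_code))

  n_nb <- integer(n)
  edge_a <- vector("list", 5L * n_cells)
  edge_b <- vector("list", 5L * n_cells)
  ne <- 0L
  for (ci in seq_len(n_cells)) {
    a_idx <- cell_of[[ci]]
    na <- length(a_idx)
    if (na > 1) {
      d2 <- outer(x[a_idx], x[a_idx], "-")^2 +
        outer(y[a_idx], y[a_idx], "-")^2
      hits <- which(d2 <= eps2, arr.ind = TRUE)
      hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
      if (nrow(hits)) {
        n_nb[a_idx] <- n_nb[a_idx] +
          tabulate(c(hits[, 1], hits[, 2]), nbins = na)
        ne <- ne + 1L
        edge_a[[ne]] <- a_idx[hits[, 1]]
        edge_b[[ne]] <- a_idx[hits[, 2]]
      }
    }
    for (oi in 1:4) {
      cj <- nb_cell[[oi]][ci]
      if (is.na(cj)) next
      b_idx <- cell_of[[cj]]
      d2 <- outer(x[a_idx], x[b_idx], "-")^2 +
        outer(y[a_idx], y[b_idx], "-")^2
      hits <- which(d2 <= eps2, arr.ind = TRUE)
      if (nrow(hits)) {
        n_nb[a_idx] <- n_nb[a_idx] +
          tabulate(hits[, 1], nbins = na)
        n_nb[b_idx] <- n_nb[b_idx] +
          tabulate(hits[, 2], nbins = length(b_idx))
        ne <- ne + 1L
        edge_a[[ne]] <- a_idx[hits[, 1]]
        edge_b[[ne]] <- b_idx[hits[, 2]]
      }
    }
  }
  core <- n_nb + 1L >= min_pts  # self included in the neighbour count

  # clusters = connected components of core points over eps-edges
  labels <- integer(n)
  if (!any(core)) return(labels)
  ea <- unlist(edge_a[seq_len(ne)], use.names = FALSE)
  eb <- unlist(edge_b[seq_len(ne)], use.names = FALSE)
  keep <- core[ea] & core[eb]
  g <- igraph::make_graph(rbind(ea[keep], eb[keep]), n = n,
                          directed = FALSE)
  membership <- igraph::components(g)$membership
  labels[core] <- match(membership[core], unique(membership[core]))
  labels
}

#' Measure one localization cluster
#'
#' @param x,y coordinates (nm) of the cluster's member localizations.
#' @return one-row data.frame: `n_locs`, `hull_area_nm2` (convex hull; NA
#'   when fewer than 3 distinct non-collinear points), `density`
#'   (localizations/nm^2; NA for degenerate hulls), centroid coordinates.
#' @export
measure_cluster <- function(x, y) {
  n <- length(x)
  hull_area <- NA_real_
  if (n >= 3) {
    h <- grDevices::chull(x, y)
    if (length(h) >= 3) {
      a <- polygon_area(cbind(x[h], y[h]))
      if (a > 0) hull_area <- a
    }
  }
  data.frame(n_locs = n, hull_area_nm2 = hull_area,
             density = if (is.na(hull_area)) NA_real_ else n / hull_area,
             centroid_x_nm = mean(x), centroid_y_nm = mean(y))
}

#' Detect and measure condensate candidates in a localization table
#'
#' Runs [dbscan_star()] on the pooled localizations, measures every
#' cluster, and applies the count/density filters.
#'
#' @param locs data.frame with `x_nm`, `y_nm` (frames pooled).
#' @param params a [cluster_params()].
#' @return data.frame, one row per cluster: `cluster_id`, measurements from
#'   [measure_cluster()], and `passes_filter`. The attribute `"labels"`
#'   carries the per-localization cluster label vector (0 = noise).
#' @export
detect_condensates <- function(locs, params) {
  stopifnot(inherits(params, "cluster_params"))
  labels <- dbscan_star(locs$x_nm, locs$y_nm, params$eps, params$min_pts)
  ids <- sort(unique(labels[labels > 0]))
  rows <- lapply(ids, function(k) {
    sel <- labels == k
    cbind(cluster_id = k, measure_cluster(locs$x_nm[sel], locs$y_nm[sel]))
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster_id = integer(), n_locs = integer(),
               hull_area_nm2 = numeric(), density = numeric(),
               centroid_x_nm = numeric(), centroid_y_nm = numeric())
  out$passes_filter <- filter_clusters(out, params)
  attr(out, "labels") <- labels
  out
}

#' Apply condensate count/density filters
#'
#' A cluster passes iff `n_locs > min_locs_per_cluster` and, when a density
#' filter is set, `density > min_density` (strict inequalities; degenerate
#' hulls with undefined density fail any density filter).
#'
#' @param clusters measured cluster data.frame (needs `n_locs`, `density`).
#' @param params a [cluster_params()].
#' @return logical vector, one element per cluster.
#' @export
filter_clusters <- function(clusters, params) {
  ok <- clusters$n_locs > params$min_locs_per_cluster
  if (!is.null(params$min_density)) {
    ok <- ok & !is.na(clusters$density) & clusters$density > params$min_density
  }
  ok
}

#' Assign condensates to cells by centroid containment
#'
#' @param condensates measured cluster data.frame (centroid columns).
#' @param cells either a cell table from [simulate_cells()] (rod geometry)
#'   or a list of polygons (two-column matrices) named by cell id.
#' @return the condensate data.frame with a `cell_id` column (NA, with a
#'   warning, for centroids outside all cells).
#' @export
assign_to_cells <- function(condensates, cells) {
  n <- nrow(condensates)
  cell_id <- rep(NA_integer_, n)
  if (n > 0) {
    px <- condensates$centroid_x_nm; py <- condensates$centroid_y_nm
    if (is.data.frame(cells)) {
      for (i in seq_len(nrow(cells))) {
        cl <- cells[i, ]
        inside <- rod_clearance(px, py, cl$cx, cl$cy,
                                (cl$length - cl$width) / 2,
                                cl$width / 2) >= 0
        cell_id[is.na(cell_id) & inside] <- cl$cell_id
      }
    } else {
      ids <- names(cells)
      if (is.null(ids)) ids <- as.character(seq_along(cells))
      for (i in seq_along(cells)) {
        inside <- point_in_polygon(px, py, cells[[i]])
        cell_id[is.na(cell_id) & inside] <- as.integer(ids[i])
      }
    }
    if (anyNA(cell_id)) {
      warning(sprintf("%d condensate centroid(s) outside all cells",
                      sum(is.na(cell_id))), call. = FALSE)
    }
  }
  condensates$cell_id <- cell_id
  condensates
}

#' Fraction of cells containing condensates
#'
#' Default `"per_cell"` mode: number of cells containing at least one
#' passing condensate, over the number of cells. `"per_fov"` mode divides
#' the total condensate count by the cell count (capped at 1), the
#' field-of-view-level bookkeeping sometimes used for this statistic.
#'
#' @param condensates condensate data.frame with `passes_filter` and (for
#'   per_cell mode) `cell_id` from [assign_to_cells()].
#' @param cells cell table (its row count defines the denominator).
#' @param mode `"per_cell"` (default) or `"per_fov"`.
#' @return proportion in [0, 1].
#' @export
fraction_cells_with_condensates <- function(condensates, cells,
                                            mode = c("per_cell", "per_fov")) {
  mode <- match.arg(mode)
  n_cells <- if (is.data.frame(cells)) nrow(cells) else length(cells)
  stop_if(n_cells == 0, "no cells: fraction undefined")
  passing <- condensates[condensates$passes_filter, , drop = FALSE]
  if (mode == "per_fov") return(min(1, nrow(passing) / n_cells))
  stop_if(nrow(passing) > 0 && !"cell_id" %in% names(passing),
          "per_cell mode needs cell assignments; run assign_to_cells() first")
  length(unique(stats::na.omit(passing$cell_id))) / n_cells
}

#' Fraction of localizations inside passing condensates
#'
#' @param condensates output of [detect_condensates()] (must carry its
#'   `"labels"` attribute, i.e. be computed on the same localization set).
#' @param n_locs total number of localizations; defaults to the length of
#'   the label vector.
#' @return proportion in [0, 1].
#' @export
localization_condensate_occupancy <- function(condensates,
                                              n_locs = length(attr(condensates, "labels"))) {
  labels <- attr(condensates, "labels")
  stop_if(is.null(labels), "condensates must carry the 'labels' attribute")
  stop_if(n_locs == 0, "occupancy undefined for an empty localization set")
  pass_ids <- condensates$cluster_id[condensates$passes_filter]
  sum(labels %in% pass_ids) / n_locs
}

#' Per-cell cytoplasmic area from a labelled mask
#'
#' @param mask integer label matrix (0 = background) as from
#'   [rasterize_cells()] or [read_mask_tiff()].
#' @param px_size_nm pixel size in nm (default 65).
#' @return data.frame `cell_id`, `area_px2` (arbitrary units), `area_nm2`.
#' @export
cytoplasmic_area <- function(mask, px_size_nm = 65) {
  stop_if(length(mask) == 0 || all(mask == 0), "empty mask")
  tab <- table(mask[mask > 0])
  data.frame(cell_id = as.integer(names(tab)),
             area_px2 = as.numeric(tab),
             area_nm2 = as.numeric(tab) * px_size_nm^2)
}

#' Rank-based comparison of per-cell areas between groups
#'
#' Kruskal-Wallis test across groups followed by Dunn's pairwise z tests
#' (tie-corrected, Benjamini-Hochberg adjusted).
#'
#' @param values numeric vector (e.g. per-cell areas).
#' @param groups factor of group labels, same length.
#' @return list: `medians` (named), `kruskal` (htest), `dunn` (data.frame
#'   `group1`, `group2`, `z`, `p_value`, `p_adj`).
#' @export
compare_cell_areas <- function(values, groups) {
  groups <- factor(groups)
  stop_if(nlevels(groups) < 2, "need at least two groups")
  kw <- stats::kruskal.test(values, groups)
  r <- rank(values)
  n <- length(values)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  lev <- levels(groups)
  combs <- utils::combn(lev, 2)
  dunn <- do.call(rbind, lapply(seq_len(ncol(combs)), function(i) {
    g1 <- combs[1, i]; g2 <- combs[2, i]
    n1 <- sum(groups == g1); n2 <- sum(groups == g2)
    mdiff <- mean(r[groups == g1]) - mean(r[groups == g2])
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / n1 + 1 / n2))
    z <- mdiff / se
    data.frame(group1 = g1, group2 = g2, z = z,
               p_value = 2 * stats::pnorm(-abs(z)))
  }))
  dunn$p_adj <- stats::p.adjust(dunn$p_value, method = "BH")
  list(medians = tapply(values, groups, stats::median),
       kruskal = kw, dunn = dunn)
}
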