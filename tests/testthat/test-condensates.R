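# DBSCAN* clustering, cluster measurement, the count/density filters,
# per-cell summaries and cytoplasmic-area quantification.

test_that("DBSCAN*: dense disc is one cluster, sparse grid is noise", {
  set.seed(1)
  th <- stats::runif(60, 0, 2 * pi); r <- 5 * sqrt(stats::runif(60))
  lab <- dbscan_star(100 + r * cos(th), 100 + r * sin(th),
                     eps = 75, min_pts = 5)
  expect_identical(unique(lab), 1L)

  g <- expand.grid(x = seq(0, 2000, by = 200), y = seq(0, 2000, by = 200))
  expect_true(all(dbscan_star(g$x, g$y, eps = 75, min_pts = 2) == 0L))
  expect_identical(dbscan_star(numeric(), numeric(), eps = 75), integer(0))
})

test_that("DBSCAN* labelling matches the O(n^2) oracle on random fields", {
  set.seed(2)
  for (rep in 1:200) {
    n <- sample(0:200, 1)
    # mixture of uniform background and a few tight blobs
    nb <- sample(0:3, 1)
    x <- stats::runif(n, 0, 3000); y <- stats::runif(n, 0, 3000)
    if (nb > 0 && n >= 20) {
      ctr <- matrix(stats::runif(2 * nb, 0, 3000), ncol = 2)
      pick <- sample(n, min(n, nb * 15))
      x[pick] <- ctr[sample(nb, length(pick), TRUE), 1] +
        stats::rnorm(length(pick), 0, 30)
      y[pick] <- stats::rnorm(length(pick), 0,  30) +
        ctr[sample(nb, length(pick), TRUE), 2]
    }
    eps <- stats::runif(1, 40, 400)
    min_pts <- sample(2:8, 1)
    got <- canon_labels(dbscan_star(x, y, eps, min_pts))
    want <- canon_labels(oracle_dbscan_star(x, y, eps, min_pts))
    expect_identical(got, want)
  }
})

test_that("clustering results are independent of point order", {
  set.seed(3)
  x <- c(stats::rnorm(80, 500, 20), stats::runif(40, 0, 3000))
  y <- c(stats::rnorm(80, 500, 20), stats::runif(40, 0, 3000))
  lab <- canon_labels(dbscan_star(x, y, 75, 5))
  perm <- sample(length(x))
  lab_p <- canon_labels(dbscan_star(x[perm], y[perm], 75, 5))
  # same partition: compare cluster memberships as sets
  expect_identical(lab[perm] > 0, lab_p > 0)
  expect_identical(split(seq_along(perm), lab_p)[-1],
                   split(seq_along(perm), lab[perm])[-1])
})

test_that("cluster measurement: hull area, density, centroid, degeneracy", {
  sq <- measure_cluster(c(0, 100, 100, 0), c(0, 0, 100, 100))
  expect_equal(sq$hull_area_nm2, 10000)
  expect_equal(sq$density, 4e-4)
  expect_equal(c(sq$centroid_x_nm, sq$centroid_y_nm), c(50, 50))

  set.seed(4)
  for (i in 1:30) {
    n <- sample(5:40, 1)
    x <- stats::runif(n, 0, 500); y <- stats::runif(n, 0, 500)
    m <- measure_cluster(x, y)
    h <- grDevices::chull(x, y)
    expect_equal(m$hull_area_nm2, oracle_fan_area(cbind(x[h], y[h])),
                 tolerance = 1e-9)
    expect_equal(m$density, n / m$hull_area_nm2)
  }

  collinear <- measure_cluster(c(0, 50, 100), c(0, 50, 100))
  expect_true(is.na(collinear$hull_area_nm2))
  expect_true(is.na(collinear$density))
})

test_that("count and density filters are strict, per the two presets", {
  hfq <- cluster_params("hfq")
  expect_equal(hfq$eps, 75)
  mk <- function(n_locs, density) {
    data.frame(n_locs = n_locs, density = density)
  }
  expect_true(filter_clusters(mk(51, 0.002), hfq))
  expect_false(filter_clusters(mk(50, 0.002), hfq))     # ">50" strict
  expect_false(filter_clusters(mk(51, 0.0015), hfq))    # ">0.0015" strict
  expect_true(filter_clusters(mk(51, 0.00151), hfq))
  expect_false(filter_clusters(mk(51, NA), hfq))        # degenerate hull

  tmar <- cluster_params("tmar")
  expect_equal(tmar$eps, 100)
  expect_true(is.null(tmar$min_density))
  expect_true(filter_clusters(mk(101, 0.0001), tmar))   # no density filter
  expect_false(filter_clusters(mk(100, 0.0001), tmar))  # ">100" strict

  # monotonicity: raising either filter never keeps more clusters
  set.seed(5)
  cl <- mk(sample(10:300, 50, TRUE), stats::runif(50, 0, 0.004))
  n_pass <- function(ml, md) {
    sum(filter_clusters(cl, cluster_params(eps = 75,
                                           min_locs_per_cluster = ml,
                                           min_density = md)))
  }
  expect_true(all(diff(vapply(c(10, 50, 100, 200),
                              n_pass, numeric(1), md = 0.001)) <= 0))
  expect_true(all(diff(vapply(c(0.0005, 0.0015, 0.003),
                              n_pass, numeric(1), ml = 50)) <= 0))
})

test_that("condensates are assigned to the cell containing their centroid", {
  pop <- population_config(n_cells = 4, seed = 6)
  cells <- simulate_cells(pop, acquisition_config(field_width = 16000,
                                                  field_height = 3000))
  cond <- data.frame(cluster_id = 1:3, n_locs = 60,
                     hull_area_nm2 = 10000, density = 0.006,
                     centroid_x_nm = c(cells$cx[2], cells$cx[3], 1e6),
                     centroid_y_nm = c(cells$cy[2], cells$cy[3], 1e6),
                     passes_filter = TRUE)
  expect_warning(res <- assign_to_cells(cond, cells), "outside all cells")
  expect_identical(res$cell_id, c(2L, 3L, NA_integer_))

  # same assignment against explicit polygon geometry
  polys <- lapply(seq_len(nrow(cells)), function(i) {
    rod_polygon(cells$cx[i], cells$cy[i], cells$length[i], cells$width[i])
  })
  names(polys) <- cells$cell_id
  expect_warning(res2 <- assign_to_cells(cond, polys), "outside")
  expect_identical(res2$cell_id, res$cell_id)
})

test_that("fraction of condensate-positive cells in both summary modes", {
  cells <- data.frame(cell_id = 1:10)
  cond <- data.frame(cluster_id = 1:9, passes_filter = rep(TRUE, 9),
                     cell_id = c(1, 1, 2, 3, 4, 5, 6, 7, 8))
  expect_equal(fraction_cells_with_condensates(cond, cells), 0.8)
  none <- cond[0, ]
  expect_equal(fraction_cells_with_condensates(none, cells), 0)
  # per-FOV bookkeeping divides counts and caps at 1
  many <- data.frame(cluster_id = 1:12, passes_filter = TRUE,
                     cell_id = rep(1:4, 3))
  expect_equal(fraction_cells_with_condensates(many, cells, "per_fov"), 1)
  expect_equal(fraction_cells_with_condensates(cond, cells, "per_fov"), 0.9)
  expect_error(fraction_cells_with_condensates(cond, cells[0, , drop = FALSE]),
               "no cells")
})

test_that("condensate recovery on a simulated field with 80% positive cells", {
  pop <- population_config(n_cells = 40, molecules_per_cell = 70,
                           immobile_fraction = 0.55,
                           condensate_radius = 75,
                           cells_with_condensate_fraction = 0.8, seed = 7)
  acq <- acquisition_config(n_frames = 10000, activation_rate = 5e-4,
                            mean_on_frames = 12)
  cells <- simulate_cells(pop, acq)
  sim <- simulate_movie(cells, pop, acq)
  # min_pts above the mobile-background neighbour count (Poisson rule)
  bg <- pop$n_cells * pop$molecules_per_cell * acq$mean_on_frames *
    (1 - pop$immobile_fraction) / sum(cells$area_nm2)
  mp <- core_min_pts(bg, eps = 75, alpha = 0.005)
  cond <- detect_condensates(sim$localizations,
                             cluster_params("hfq", min_pts = mp))
  cond <- assign_to_cells(cond, cells)
  frac <- fraction_cells_with_condensates(cond, cells)
  expect_lte(abs(frac - 0.8), 0.1)
})

test_that("the core-point rule tracks the background Poisson tail", {
  # denser background or larger eps demands a larger core threshold
  expect_gte(core_min_pts(3e-4, 75), core_min_pts(1e-4, 75))
  expect_gte(core_min_pts(1e-4, 150), core_min_pts(1e-4, 75))
  expect_identical(core_min_pts(0, 75), 2L)
})

test_that("mobile-only fields produce no passing condensates", {
  fails <- 0L
  for (s in 1:10) {
    pop <- population_config(n_cells = 12, molecules_per_cell = 60,
                             immobile_fraction = 0,
                             cells_with_condensate_fraction = 0,
                             seed = 100 + s)
    acq <- acquisition_config(n_frames = 4000, activation_rate = 8e-4,
                              field_width = 25000, field_height = 8000)
    sim <- simulate_movie(simulate_cells(pop, acq), pop, acq)
    cond <- detect_condensates(sim$localizations, cluster_params("hfq"))
    if (sum(cond$passes_filter) > 0) fails <- fails + 1L
  }
  expect_lte(fails, 0L)   # expected in >= 95% of seeds; observed stricter
})

test_that("localization occupancy counts members of passing clusters", {
  set.seed(8)
  # one tight blob of 120 plus 80 dispersed points
  x <- c(stats::rnorm(120, 1000, 25), stats::runif(80, 0, 50000))
  y <- c(stats::rnorm(120, 1000, 25), stats::runif(80, 0, 50000))
  cond <- detect_condensates(data.frame(x_nm = x, y_nm = y),
                             cluster_params("hfq"))
  occ <- localization_condensate_occupancy(cond)
  expect_gt(occ, 0.5)
  expect_lte(occ, 120 / 200)
  # no passing condensates -> 0; empty set errors
  cond0 <- detect_condensates(data.frame(x_nm = stats::runif(30, 0, 50000),
                                         y_nm = stats::runif(30, 0, 50000)),
                              cluster_params("hfq"))
  expect_equal(localization_condensate_occupancy(cond0), 0)
  expect_error(localization_condensate_occupancy(cond, n_locs = 0),
               "empty")
})

test_that("cytoplasmic areas from labelled masks, with group comparison", {
  mask <- matrix(0L, 30, 30)
  mask[5:14, 5:14] <- 1L          # 10 x 10 px square
  mask[20:29, 5:24] <- 2L         # 10 x 20 px rectangle
  areas <- cytoplasmic_area(mask, px_size_nm = 65)
  expect_equal(areas$area_px2, c(100, 200))
  expect_equal(areas$area_nm2[1], 422500)
  expect_error(cytoplasmic_area(matrix(0L, 5, 5)), "empty mask")

  # rasterized rod area agrees with the analytic rod area within 5%
  pop <- population_config(n_cells = 3, seed = 9)
  cells <- simulate_cells(pop, acquisition_config(field_width = 16000,
                                                  field_height = 3000))
  m <- rasterize_cells(cells, px_size_nm = 50)
  a <- cytoplasmic_area(m, px_size_nm = 50)
  expect_equal(a$area_nm2, cells$area_nm2[a$cell_id], tolerance = 0.05)

  # identical groups: non-significant; shifted groups: significant
  set.seed(10)
  g1 <- stats::rnorm(60, 1500, 80)
  cmp_null <- compare_cell_areas(c(g1, g1),
                                 rep(c("a", "b"), each = 60))
  expect_gt(cmp_null$kruskal$p.value, 0.9)
  g2 <- stats::rnorm(60, 1235, 80)
  cmp <- compare_cell_areas(c(g1, g2), rep(c("N+", "N-24"), each = 60))
  expect_lt(cmp$kruskal$p.value, 1e-6)
  expect_lt(cmp$dunn$p_adj[1], 1e-6)
  expect_setequal(names(cmp$medians), c("N-24", "N+"))
})
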