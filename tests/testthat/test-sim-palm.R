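# Synthetic PALM generator: geometry, motion law, noise law, bookkeeping.

test_that("cell placement: rod area, condensate flags, placement errors", {
  pop1 <- population_config(n_cells = 1, cell_length = 3000,
                            cell_width = 1000, seed = 1)
  cells <- simulate_cells(pop1, acquisition_config())
  expect_equal(cells$area_nm2, 2000 * 1000 + pi * 500^2)
  # polygon outline area converges on the analytic rod area
  poly <- rod_polygon(cells$cx, cells$cy, 3000, 1000, n_cap = 200)
  expect_equal(polygon_area(poly), cells$area_nm2, tolerance = 1e-3)

  none <- simulate_cells(population_config(
    n_cells = 10, cells_with_condensate_fraction = 0, seed = 2))
  expect_false(any(none$has_condensate))
  expect_true(all(is.na(none$cond_x)))

  some <- simulate_cells(population_config(
    n_cells = 10, cells_with_condensate_fraction = 0.8, seed = 3))
  expect_identical(sum(some$has_condensate), 8L)
  # condensate centre sits condensate_offset from a pole tip, on-axis
  flagged <- some[some$has_condensate, ]
  offs <- abs(abs(flagged$cond_x - flagged$cx) - (3000 / 2 - 400))
  expect_true(all(offs < 1e-9))
  expect_equal(flagged$cond_y, flagged$cy)

  expect_error(
    simulate_cells(population_config(n_cells = 500),
                   acquisition_config(field_width = 10000,
                                      field_height = 5000)),
    "holds at most")
})

test_that("cells never overlap and stay inside the field", {
  pop <- population_config(n_cells = 60, seed = 11)
  acq <- acquisition_config()
  cells <- simulate_cells(pop, acq)
  expect_true(all(cells$cx + cells$length / 2 <= acq$field_width))
  expect_true(all(cells$cy + cells$width / 2 <= acq$field_height))
  # pairwise: either x-spans or y-spans disjoint
  dx <- abs(outer(cells$cx, cells$cx, "-"))
  dy <- abs(outer(cells$cy, cells$cy, "-"))
  sep <- dx >= cells$length[1] | dy >= cells$width[1]
  diag(sep) <- TRUE
  expect_true(all(sep))
})

test_that("no motion and no noise gives identical positions per molecule", {
  pop <- population_config(n_cells = 3, molecules_per_cell = 5,
                           D_mobile = 0, D_immobile = 0,
                           immobile_fraction = 0, seed = 4)
  acq <- acquisition_config(n_frames = 500, localization_sigma = 0,
                            activation_rate = 0.01,
                            field_width = 12000, field_height = 3000)
  sim <- simulate_movie(simulate_cells(pop, acq), pop, acq)
  mol <- sim$ground_truth$molecules
  spread <- tapply(mol$x_obs_nm, mol$molecule_id, function(v) diff(range(v)))
  expect_true(all(spread == 0))
})

test_that("localization rows equal emitted molecule-frames (conservation)", {
  pop <- population_config(n_cells = 5, molecules_per_cell = 20, seed = 5)
  acq <- acquisition_config(n_frames = 2000, field_width = 20000,
                            field_height = 4000)
  sim <- simulate_movie(simulate_cells(pop, acq), pop, acq)
  expect_identical(nrow(sim$localizations),
                   nrow(sim$ground_truth$molecules))
  # trajectories are capped at the acquisition end
  expect_true(all(sim$localizations$frame < acq$n_frames))
  expect_true(all(sim$localizations$frame >= 0))
})

test_that("squared single-frame displacements follow the 4*D*dt law", {
  # unconfined regime: huge cell so the boundary is never touched
  pop <- population_config(n_cells = 1, cell_length = 2e5, cell_width = 4e4,
                           molecules_per_cell = 1500, D_mobile = 0.5,
                           immobile_fraction = 0,
                           cells_with_condensate_fraction = 0, seed = 6)
  acq <- acquisition_config(n_frames = 40, localization_sigma = 0,
                            activation_rate = 0.5, mean_on_frames = 12,
                            field_width = 2.2e5, field_height = 5e4)
  sim <- simulate_movie(simulate_cells(pop, acq), pop, acq)
  mol <- sim$ground_truth$molecules
  mol <- mol[order(mol$molecule_id, mol$frame), ]
  same <- diff(mol$molecule_id) == 0
  sq <- (diff(mol$x_true_nm)^2 + diff(mol$y_true_nm)^2)[same] / 1e6  # um^2
  # interior steps only: cell is so large reflections are impossible
  expect_gt(length(sq), 1e4)
  expected_mean <- 4 * 0.5 * (1 / 66)
  expect_lt(abs(mean(sq) - expected_mean),
            3 * stats::sd(sq) / sqrt(length(sq)))
  # full distributional check: squared displacement ~ Exp(mean 4 D dt)
  ks <- stats::ks.test(sq, "pexp", rate = 1 / expected_mean)
  expect_gt(ks$p.value, 0.01)
})

test_that("localization noise is Gaussian with the configured sd", {
  pop <- population_config(n_cells = 4, molecules_per_cell = 300,
                           D_mobile = 0, D_immobile = 0,
                           immobile_fraction = 0, seed = 7)
  acq <- acquisition_config(n_frames = 300, localization_sigma = 20,
                            activation_rate = 0.05, mean_on_frames = 20,
                            field_width = 16000, field_height = 3000)
  sim <- simulate_movie(simulate_cells(pop, acq), pop, acq)
  mol <- sim$ground_truth$molecules
  errs <- c(mol$x_obs_nm - mol$x_true_nm, mol$y_obs_nm - mol$y_true_nm)
  expect_gt(length(errs), 2e4)
  expect_lt(abs(stats::sd(errs) - 20) / 20, 0.05)
  expect_lt(abs(mean(errs)), 1)
})

test_that("condensate-confined molecules stay inside their disc", {
  pop <- population_config(n_cells = 5, molecules_per_cell = 40,
                           immobile_fraction = 1,
                           condensate_radius = 75, condensate_offset = 400,
                           cells_with_condensate_fraction = 1, seed = 8)
  acq <- acquisition_config(n_frames = 1000, field_width = 20000,
                            field_height = 4000)
  cells <- simulate_cells(pop, acq)
  sim <- simulate_movie(cells, pop, acq)
  mol <- sim$ground_truth$molecules
  expect_true(all(mol$state == "condensed"))
  cc <- cells[mol$cell_id, ]
  d <- sqrt((mol$x_true_nm - cc$cond_x)^2 + (mol$y_true_nm - cc$cond_y)^2)
  expect_true(all(d <= 75 + 1e-9))
})

test_that("every true position lies inside its cell", {
  pop <- population_config(n_cells = 6, molecules_per_cell = 30, seed = 9)
  acq <- acquisition_config(n_frames = 1500, field_width = 24000,
                            field_height = 4000)
  cells <- simulate_cells(pop, acq)
  sim <- simulate_movie(cells, pop, acq)
  mol <- sim$ground_truth$molecules
  cc <- cells[mol$cell_id, ]
  clear <- rep(NA_real_, nrow(mol))
  for (i in seq_len(nrow(mol))) {
    poly <- rod_polygon(cc$cx[i], cc$cy[i], cc$length[i], cc$width[i],
                        n_cap = 90)
    clear[i] <- point_in_polygon(mol$x_true_nm[i], mol$y_true_nm[i], poly)
  }
  expect_gt(mean(clear), 0.999)  # polygon is a discretized rod outline
})

test_that("identical seed and config reproduce byte-identical output", {
  pop <- population_config(n_cells = 4, molecules_per_cell = 15, seed = 10)
  acq <- acquisition_config(n_frames = 800, field_width = 16000,
                            field_height = 3000)
  s1 <- simulate_movie(simulate_cells(pop, acq), pop, acq)
  s2 <- simulate_movie(simulate_cells(pop, acq), pop, acq)
  expect_identical(s1, s2)
  pop2 <- population_config(n_cells = 4, molecules_per_cell = 15, seed = 99)
  s3 <- simulate_movie(simulate_cells(pop2, acq), pop2, acq)
  expect_false(identical(s1$localizations, s3$localizations))
})

test_that("config validation rejects impossible settings", {
  expect_error(acquisition_config(frame_interval = 0), "frame_interval")
  expect_error(acquisition_config(activation_rate = 1.5), "activation_rate")
  expect_error(population_config(immobile_fraction = 2), "immobile_fraction")
  expect_error(population_config(D_mobile = 0.1, D_immobile = 0.5),
               "D_mobile")
  expect_error(population_config(condensate_radius = 1200,
                                 condensate_offset = 600,
                                 cell_length = 3000), "condensate")
})

test_that("localization and mask round-trips preserve the data", {
  pop <- population_config(n_cells = 3, molecules_per_cell = 10, seed = 12)
  acq <- acquisition_config(n_frames = 500, field_width = 12000,
                            field_height = 3000)
  cells <- simulate_cells(pop, acq)
  sim <- simulate_movie(cells, pop, acq)
  f <- withr::local_tempfile(fileext = ".csv")
  write_localizations(sim$localizations, f)
  back <- read_localizations(f)
  expect_equal(back$frame, sim$localizations$frame)
  expect_equal(back$x_nm, sim$localizations$x_nm, tolerance = 1e-9)

  mask <- rasterize_cells(cells, px_size_nm = 65)
  tf <- withr::local_tempfile(fileext = ".tiff")
  write_mask_tiff(mask, tf)
  expect_identical(read_mask_tiff(tf), mask)
  expect_setequal(setdiff(unique(as.vector(mask)), 0L), cells$cell_id)
})
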