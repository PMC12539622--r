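#!/usr/bin/env Rscript
# Detect condensates on the pooled localizations with DBSCAN* and the
# Hfq filter set (eps 75 nm, > 50 localizations, density > 0.0015 nm^-2),
# assign them to cells, and summarize per-cell prevalence, localization
# occupancy and cytoplasmic areas.

library(palmpipe)

locs <- read_localizations("results/palm/localizations.csv")
cells <- utils::read.csv("results/palm/ground_truth/cells.csv")
gt_mol <- utils::read.csv("results/palm/ground_truth/molecules.csv")

# core-point threshold from the mobile-background density (Poisson rule)
bg <- sum(gt_mol$state == "mobile") / sum(cells$area_nm2)
params <- cluster_params("hfq", min_pts = core_min_pts(bg, 75, 0.005))
cat(sprintf("background density %.2e locs/nm^2 -> min_pts = %d\n",
            bg, params$min_pts))

cond <- assign_to_cells(detect_condensates(locs, params), cells)
utils::write.csv(cond, "results/palm/condensates.csv", row.names = FALSE)

frac <- fraction_cells_with_condensates(cond, cells)
occ <- localization_condensate_occupancy(cond, nrow(locs))
cat(sprintf("%d passing condensates; %.0f%% of cells condensate-positive (designed 85%%)\n",
            sum(cond$passes_filter), 100 * frac))
cat(sprintf("%.0f%% of localizations inside condensates (designed ~50%%)\n",
            100 * occ))

# cytoplasmic area from the labelled mask, in 65 nm/px arbitrary units
mask <- read_mask_tiff("results/palm/ground_truth/cell_mask.tiff")
areas <- cytoplasmic_area(mask, px_size_nm = 65)
utils::write.csv(areas, "results/palm/cell_areas.csv", row.names = FALSE)
cat(sprintf("median cytoplasmic area: %.0f px^2 (%.2f um^2)\n",
            stats::median(areas$area_px2),
            stats::median(areas$area_nm2) / 1e6))

summary <- data.frame(n_cells = nrow(cells),
                      n_condensates = sum(cond$passes_filter),
                      fraction_cells_with_condensates = frac,
                      occupancy = occ)
utils::write.table(summary, "results/palm/condensate_summary.tsv",
                   sep = "\t", row.names = FALSE, quote = FALSE)
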