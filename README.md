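# palmpipe

Analysis pipeline for single-molecule localization microscopy of bacterial
protein condensates, with a companion transcription-shutoff RNA-decay
module. It targets the quantitative workflow used to study stress-induced
ribonucleoprotein condensates (such as polar Hfq and TmaR condensates in
nitrogen-starved *E. coli*): photoactivated localization microscopy (PALM)
movies are reduced to per-frame localization tables, linked into
single-molecule trajectories, classified by apparent diffusion, and mined
for condensates as dense localization clusters; rifampicin-chase RNA-seq
count matrices are reduced to per-gene stability estimates.

## What it computes

**Trajectory linking.** Localizations in consecutive frames are linked
when they are within a maximum step distance (default 0.6 µm) and neither
end has a competing localization within the nearest-neighbour exclusion
radius (default 0.9 µm); any ambiguity vetoes the link. Trajectories are
chains of such links; a dark frame terminates a trajectory.

**Apparent diffusion and the immobile fraction.** For each trajectory with
at least four steps, the apparent diffusion coefficient is the lag-1 mean
squared displacement estimator

    D* = MSD(Δt) / (4 Δt),   MSD(Δt) = ⟨(x_{i+1} − x_i)² + (y_{i+1} − y_i)²⟩

with Δt the frame interval (default 1/66 s). The condensation proxy
statistic %H_IM is the percentage of trajectories with D* ≤ 0.08 µm²/s,
pooled trajectory-weighted over fields of view. No localization-noise
correction is applied; with per-axis noise σ the estimator's expectation
is D + σ²/Δt, and this noise floor is documented rather than subtracted.

**Condensate detection.** DBSCAN* (border points are noise; clusters are
connected components of core points) on the pooled localizations, then
strict count/density filters: the Hfq preset keeps clusters with eps =
75 nm, > 50 localizations and convex-hull density > 0.0015
localizations/nm²; the TmaR preset uses eps = 100 nm and > 100
localizations with no density filter. Per-cell summaries report the
fraction of cells containing a condensate and the fraction of
localizations inside condensates. `core_min_pts()` gives the Poisson-tail
rule for choosing the core-point threshold above the diffuse background
density.

**Cytoplasmic area.** Per-cell areas from labelled masks (px² "arbitrary
units" and nm²), with Kruskal–Wallis + Dunn's rank tests across
conditions.

**Transcription-shutoff decay.** Counts are normalized per sample to a
stable reference gene (6S RNA / *ssrS*), and per-gene destabilization at
time *t* after rifampicin is log2 of the normalized abundance relative to
*t* = 0. Differential-abundance statistics are classified with the
padj < 0.05, |log2FC| ≥ 1 gates into down / partial_down / up /
partial_up / ns.

**Synthetic generators.** Both data types are generated with known ground
truth: PALM movies from rod-shaped cells with a two-population Brownian
model (freely diffusing vs condensate-confined molecules, stochastic
photoactivation, geometric bleaching, Gaussian localization noise), and
count matrices with per-gene exponential decay, Poisson sampling and
sample-specific library sizes. Every analysis stage is tested against
this ground truth or an independent brute-force oracle.

## Worked example

The numbered scripts under `analysis/` run the full workflow on the
package's reference simulation (100 cells, 85% carrying a condensate,
50% of molecules drawn condensate-confined, 10 000 frames at 66 fps):

```sh
Rscript analysis/01_simulate_palm.R
Rscript analysis/02_track_diffusion.R
Rscript analysis/03_condensates.R
Rscript analysis/04_decay.R
```

which prints (tables written under `results/`):

```
simulated 100 cells (85 with condensates), 6000 molecules
emitted localizations: 91969 over 10000 frames
realized condensed-molecule fraction: 0.437 (designed 0.50)

linked 80183 localizations into 5830 trajectories
4509 trajectories with >= 4 steps analysed
%H_IM = 42.3% (designed condensed fraction 42.5%)

background density 1.82e-04 locs/nm^2 -> min_pts = 11
85 passing condensates; 85% of cells condensate-positive (designed 85%)
47% of localizations inside condensates (designed ~50%)
median cytoplasmic area: 648 px^2 (2.74 um^2)
```

Condensed draws realize only in the 85% of cells that carry a
condensate, so the designed condensed-molecule fraction is 0.5 × 0.85 =
42.5%; the recovered %H_IM (42.3%) and the per-cell condensate fraction
(85/100) match their designed values. The decay script prints per-gene
log2 destabilization at 60 min against the analytic −t/t½ (e.g. −1.98
measured vs −2.00 for a 30-min half-life).

In R, the same pipeline is one call:

```r
library(palmpipe)
cfg <- run_config(seed = 1, condensates = list(preset = "hfq"))
manifest <- run_palm_pipeline(cfg, "results/run1")
manifest$summary$H_IM_percent
```

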