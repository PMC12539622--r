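---
title: "Methods: single-molecule condensate analysis and shutoff decay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-molecule condensate analysis and shutoff decay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palmpipe)
```

This vignette is the package's account of its models, parameter choices
and numerical decisions. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The measurement problem

PALM imaging of a photoactivatable fusion protein in bacteria yields a
table of per-frame point localizations. Two quantitative questions drive
the pipeline:

1. *How mobile are the molecules?* Condensate formation sequesters
   molecules into slowly diffusing assemblies, so the fraction of
   trajectories with low apparent diffusion (%H_IM) acts as a
   condensation proxy that can be followed over time and conditions.
2. *Where are the condensates and how prevalent are they?* Pooled over
   all frames, condensates appear as dense localization clusters; after
   cluster detection and filtering, the fraction of cells containing one
   summarizes the population state.

A companion module asks a third question from rifampicin-chase RNA-seq:
*how fast does each transcript decay once transcription stops?*

## Trajectory linking

Localizations in frame *f* + 1 are linked to localizations in frame *f*
under three conditions: the step is at most `max_step` (600 nm default),
and on each side the partner is the *only* localization strictly within
`exclusion_radius` (900 nm default). The second and third conditions
implement nearest-neighbour exclusion as a mutual-ambiguity veto: when
two candidates compete on either side of a putative link, the link is
dropped rather than guessed. This is the conservative reading of
"nearest-neighbour exclusion" — in dense fields it sacrifices links to
avoid cross-molecule joins, which matters because a single wrong join
contaminates a trajectory's MSD. The alternative semantics (keep the
nearest candidate, discard only the farther) is available as
`exclusion_mode = "nearest"` without changing defaults. Exact distance
ties veto in both modes. Comparisons use ≤ for the step bound and < for
competitor interiority.

There is no gap closing: a molecule dark for one frame starts a new
trajectory. Blinking-induced fragmentation shortens trajectories but
does not bias D* (each fragment still samples the same motion), whereas
gap closing risks joining different molecules; with the simulator's
single-on-interval photophysics the issue does not arise at all.

## Apparent diffusion and %H_IM

For a trajectory of *n* ≥ 5 localizations (≥ 4 steps), the default
estimator is the lag-1 MSD divided by 4Δt, the standard apparent
diffusion convention for short 2D tracks: it uses every step, has the
smallest variance among unbiased lag choices for free diffusion, and
requires no fit. A multi-lag alternative (ordinary least squares of
MSD(k) through the origin over lags 1–4, `estimator = "fit"`) is
provided for sensitivity analysis; both agree on free diffusion (tested)
and differ for confined motion, where neither is "correct" — hence
*apparent* diffusion.

No localization-noise correction is applied, matching how the statistic
is used in the field: with a per-axis noise sd σ the lag-1 estimator has
expectation D + σ²/Δt. At σ = 20 nm and Δt = 1/66 s the floor is
0.0264 µm²/s — a third of the immobile threshold — so genuinely immobile
molecules remain comfortably below 0.08 µm²/s, and the threshold
implicitly absorbs the floor. The test suite verifies the floor
analytically rather than subtracting it.

The immobile threshold is 0.08 µm²/s, *inclusive* (D* = 0.08 counts as
immobile), with a flag to switch to strict comparison; the choice is
measure-zero for continuous data but pinned down by a boundary test.
%H_IM pools trajectories over fields of view trajectory-weighted (the
concatenation of all records), not as a mean of per-FOV percentages:
FOVs with more trajectories carry proportionally more information.
Whether one molecule contributing several trajectories should be
down-weighted is unknowable post-tracking; %H_IM is per-trajectory.

## Condensate detection

Clustering is DBSCAN* — core points are points with at least `min_pts`
neighbours (self included) within `eps`; clusters are connected
components of core points; border points are noise — run on
localizations pooled over all frames, standard SMLM practice. Two filter
presets follow the condensate definitions used for Hfq and TmaR:

| preset | eps | count filter | density filter |
|--------|-----|--------------|----------------|
| `hfq`  | 75 nm | > 50 localizations | > 0.0015 locs/nm² |
| `tmar` | 100 nm | > 100 localizations | none |

Both filters are strict inequalities. Cluster "density" needs an area
the filter definition leaves open; the package uses the convex hull
(deterministic, parameter-free) and flags this in the output schema. A
degenerate (collinear) hull has undefined density and fails any density
filter. Hull areas are computed by the shoelace formula and tested
against an independent triangle-fan oracle.

`min_pts` is not part of either preset and defaults to 5. For pooled SMT
data this default deserves care: freely diffusing molecules deposit a
diffuse background of density ρ, and a background point has
Poisson(ρ·π·eps²) neighbours in its eps-disc. If `min_pts` sits inside
that distribution's bulk, background points become core and chain
condensate clusters into the diffuse cloud; the merged hull dilutes the
cluster density below the 0.0015 nm⁻² filter and true condensates are
*lost*, not gained. `core_min_pts(rho, eps, alpha)` returns the smallest
threshold for which a background point is core with probability ≤ α
(default 0.01); the analysis scripts apply it with ρ estimated from the
mobile localization count over the cell area. At the reference
simulation's ρ ≈ 1.8 × 10⁻⁴ nm⁻² this gives `min_pts` = 11 versus a
background neighbour mean of ≈ 3.2.

Two summary modes exist because "number of condensates over number of
cells" can exceed 1 when cells hold several condensates: the default
`per_cell` mode counts cells containing ≥ 1 assigned condensate (by
centroid containment); `per_fov` divides counts and caps at 1. Both are
reported by the pipeline manifest.

## Cytoplasmic area

Per-cell areas come from labelled masks (pixel counts × px², default
65 nm/px, reported both in px² "arbitrary units" and nm²). Group
comparisons use Kruskal–Wallis plus Dunn's pairwise z tests with tie
correction and Benjamini–Hochberg adjustment; Dunn's statistic is
implemented in-package because no installed package provides it, and is
exercised against null (identical groups) and shifted alternatives.

## Shutoff decay

Counts are normalized per sample by the count of a stable, abundant
reference (6S RNA / *ssrS*), which removes library-size effects exactly
(tested as invariance under per-sample rescaling). Destabilization of
gene *g* at time *t* is log2 of its replicate-mean normalized abundance
relative to *t* = 0; under exponential decay the expectation is −*t*/t½.
Replicates are averaged before the log ratio (arithmetic mean default;
geometric mean and per-replicate log-then-average orders behind flags —
the orders agree to < 0.1 log2 units on clean simulated data and differ
materially only near zero counts). Zero late abundances propagate as
flagged −Inf sentinels, never silently dropped or imputed; no pseudocount
is added by default. Classification of differential-abundance statistics
applies padj < 0.05 with |log2FC| ≥ 1 separating full from partial
changes; the negative-binomial DE model that produces those statistics
is out of scope — they are accepted as input.

## The synthetic generators

The PALM generator emulates: rod-shaped cells (rectangle plus
semicircular caps, axis-aligned, non-overlapping grid placement with
jitter); per-molecule stochastic activation (geometric waiting time,
default rate 5 × 10⁻⁴/frame over 10 000 frames at 1/66 s); a single
geometric on-interval (mean 15 frames); two-population Brownian motion
(D_mobile = 0.5, D_immobile = 0.01 µm²/s) with reflecting boundaries at
the cell wall and, for condensed molecules, at a polar condensate disc
(radius 100 nm, centre 400 nm from a pole); and isotropic Gaussian
localization noise (σ = 20 nm, a typical photoactivatable-fluorophore
precision — the instrument value is not published, so it is
configurable). Reflection preserves the uniform stationary density;
displacement and noise laws are verified distributionally
(Kolmogorov–Smirnov / moment tests at n ≥ 10⁴).

Defaults encode the study conditions the analyses presume: 100 cells per
field (fields of 50–200 cells are the statistic's pooling unit), 85% of
cells carrying a condensate, and a 50% condensate-confined molecule
fraction, which in combination yields a designed condensed fraction of
42.5% of molecules.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: no camera/PSF rendering or localization
artifacts (merging, multi-emitter fits), no re-activation/blinking of a
molecule into several trajectories, no drift, no 3D, no cell growth or
movement, no heterogeneous per-cell expression, and condensates are
static discs rather than exchanging, irregular assemblies. Tracking and
clustering performance on real dense movies will be worse than on these
fields; the generator's role is to verify the estimators and rules, not
to certify instrument-level performance.

The decay generator produces Poisson counts around
size_factor × baseline × 2^(−t/t½) with a stable reference gene; it
deliberately omits overdispersion, so recovery tolerances (±0.15 log2
units at baseline 5000, 3 replicates) reflect Poisson noise only.

## Numerical and size choices

Neighbour search uses an eps-sized grid hash with a half 3×3 stencil
(each cell pair visited once); connected components of the core-point
graph are delegated to igraph. Labels are deterministic (numbered by
first member appearance) and order-invariant (tested under
permutation). Union of reflecting steps is folded iteratively with a
25-iteration guard and an interior clamp for pathological step lengths.
Seeds: every simulator takes one integer seed; `simulate_movie` derives
its stream from `seed + 1` so cell placement and motion are independent
but jointly reproducible; identical config + seed reproduces
byte-identical output (tested).

Test problem sizes were chosen to keep the default suite around a
minute while leaving clear statistical margins: 200-instance oracle
sweeps for linking and clustering; 600 trajectories for estimator
calibration (SE of the mean ≈ 1.7% at D = 0.5); ~1 800 analysed
trajectories for %H_IM recovery (±5 pp band vs ±2.3 pp binomial SE);
40-cell fields for condensate recovery; 10 seeds for the false-positive
control.

## Known limitations

- The exclusion-radius semantics of the original vendor tracker are
  undocumented; the veto interpretation is an explicit assumption with a
  switchable alternative.
- Convex-hull density under-reports for crescent or hollow clusters; an
  alpha-shape area would be tighter but needs a scale parameter.
- %H_IM conflates confinement and slow diffusion; it is a proxy, not a
  state segmentation.
- Reference-gene normalization propagates the reference's own sampling
  noise into every gene; with a high-baseline reference (50 000 counts
  default) this contributes < 0.01 log2 units.
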