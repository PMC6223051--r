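---
title: "Quantifying membrane localization, adhesion and interaction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying membrane localization, adhesion and interaction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(junctionr)
```

# The scientific problem

Junctional proteins such as p120-catenin and E-cadherin change their
subcellular localization when cadherin signaling is perturbed: stable
epithelial junctions show the protein concentrated at the cell membrane,
whereas invasive phenotypes delocalize it to the cytoplasm. junctionr
quantifies that localization from fluorescence images, and connects it to
two orthogonal readouts — cell-cell adhesion strength measured by
single-cell force spectroscopy, and protein-protein interaction frequency
measured by proximity ligation — plus the cohort-level IHC statistics that
tie cell-line observations to tumor series.

This vignette is the package's own account of the models, the tunable
parameters, the numerical choices, and the limits of what the synthetic
data can establish.

# Internuclear profile analysis

## The profile map

For each selected pair of contiguous cells, the marker intensity is
sampled along the straight segment joining the two nucleus centroids (an
*IN profile*; *RD profiles* run from one nucleus toward the periphery).
Every sample is the mean of bilinear interpolations at
`2 * band_halfwidth + 1` points spaced one pixel apart perpendicular to the
path, which suppresses single-pixel noise without committing to a
segmentation of the junction.

Because the path was never published as a protocol, two conventions are
package decisions, stated here and used consistently:

* coordinates are 1-based `(row, col)` with pixel centers at integer
  positions (matching R matrix indexing);
* the IN path is the straight centroid-to-centroid segment, and
  `band_halfwidth` (default 2 px) and `sampling_step` (default 1 px) are
  exposed parameters rather than fixed constants.

Profiles from cells of different sizes are made comparable by linear
resampling onto a common axis of `L = 100` arbitrary units
(`normalize_profile_length()`), endpoints preserved exactly. The
normalized profiles are stacked as columns of the `L x n` *profile map*,
the object every downstream step operates on.

## Poisson denoising

Photon counting makes fluorescence noise Poisson, so the denoiser is the
maximum a posteriori estimate under a Poisson likelihood with a quadratic
smoothness prior on first differences along the position axis:

$$\hat u = \arg\min_{u > 0} \sum_p \left(u_p - y_p \log u_p\right)
  + \lambda \sum_p (u_{p+1} - u_p)^2 .$$

Each column is solved independently by damped Newton iterations with
backtracking line search (the Hessian `diag(y/u^2) + 2 lambda D'D` is
solved directly at `L = 100`), so the objective decreases monotonically;
convergence is declared at a relative objective change below `1e-10` or
100 iterations. Exact zeros are lifted to a floor of `1e-8` because the
Poisson mean must be positive; `lambda = 0` therefore returns the input up
to that floor.

`lambda` trades smoothing against peak preservation. The default
`lambda = 10` is tuned for count levels around 50 photons/pixel on
near-constant maps, where it removes roughly 88% of the absolute error
against the true rate; on maps carrying a narrow junction peak it smooths
aggressively, and smaller values (`lambda ~ 1`) are more appropriate. The
choice is deliberately exposed and echoed in results rather than hidden.

## Geometric compensation

Cell-size and cell-shape variability misaligns profiles even after length
normalization. Compensation re-parameterizes each column with a warp of
the position axis and minimizes across-profile variability along the rows:

$$\min_{w_1..w_n} \sum_p \sum_j \left(Y_j(w_j(p)) - \bar r(p)\right)^2
  + \gamma \sum_j \lVert w_j - \mathrm{id} \rVert^2,$$

where `r` is the row-wise mean of the current compensated map. This is a
Bayesian registration in the MAP sense: a Gaussian likelihood on the
row-wise residuals and a Gaussian prior (weight `gamma`, default 1) on
warp deviations from identity, which anchors columns in flat,
uninformative profile regions.

Design choices, made where the method family is genuinely open:

* **Warp family** — endpoint-fixed, strictly monotone, piecewise-linear
  with `n_knots = 3` interior knots at equally spaced positions. This is
  the cheapest family expressive enough for the shift-plus-stretch
  distortions that cell-size variability produces; endpoint fixing makes
  every warp a bijection of `[1, L]`.
* **Optimization** — block-coordinate descent: the reference is the
  current row mean; each column's knots are refined one at a time by a
  25-point grid search bracketing a golden-section refinement, with a
  minimum knot spacing of 0.5 positions enforcing monotonicity. Column
  updates are accepted only when they lower the penalized objective;
  because the row mean minimizes the row-wise sum of squares for fixed
  columns, the global objective trace is non-increasing by construction
  (asserted in tests).
* **Degenerate columns** — zero-variance columns receive identity warps
  without entering the optimizer; a single-column map is returned
  unchanged.
* **Order of operations** — denoising precedes compensation in
  `analyze_profile_group()`, matching the pipeline's step order;
  `denoise_first = FALSE` swaps them for sensitivity analysis.
* **Convergence** — relative objective change below `1e-6` or 50
  iterations, both defaults reported by `glance()`.

On ensembles of integer-shifted unimodal templates (`L = 100`, `n = 30`,
shifts up to 5 positions, noise-free) the compensation reduces the mean
row-wise SD by two orders of magnitude and the warp displacement evaluated
at the template peak recovers the true shift within one position for every
column — this is the package's registration acceptance bar (SD at most
half of pre-compensation; at least 90% of shifts within one position).

## Localization statistics

The *maximum mean ratio* `MMR = max(profile) / mean(profile)` is
scale-invariant, equals 1 for uniform signal, and `L` for a single spike
among zeros. By default it is computed on the mean profile of a compensated
map; per-profile computation is available since the original choice is not
documented. The *membrane mean intensity* averages the summary profile over
a junction window; the default `[46, 55]` covers the central tenth of the
normalized axis, where the junction lies for an IN profile between two
similarly sized cells. The window was never published; it is configurable
and always reported.

A practical note from the synthetic experiments: the absolute
membrane-window mean compares conditions of the *same* marker, but across
localization patterns the within-profile enrichment (window mean relative
to the profile mean, or the MMR) is the more faithful contrast — a
cytoplasmic marker can carry a higher absolute plateau than a membrane
marker's window average while showing no enrichment at all.

# AFM detachment work

Retract curves are baseline-corrected by subtracting the median force of
the last 10% of the retract segment (the fully detached region). Adhesion
is negative force (a stated sign convention; the instrument convention was
never published), and the detachment work is

$$W = \int_{\mathrm{contact}}^{\mathrm{detach}} \max(0, -F)\, dz$$

by the trapezoidal rule, in joules (`pN x um = 1e-18 J`). The detachment
point is the first position after the force minimum where the force stays
within a noise band of baseline for 10 consecutive samples; the band is 3
times the SD of the detached tail, with a small positive floor so that
noise-free curves terminate at the first return to baseline. This
integration contract is the standard force-spectroscopy concretization
and is documented as such: bounds and baseline handling were not published
with the original measurements.

Work distributions are summarized exactly as instrument practice does it:
a frequency histogram (Freedman-Diaconis binning by default, or an exact
bin count) with a least-squares Gaussian `A exp(-(x-mu)^2 / 2 sigma^2)`
fitted to bin centers and counts, initialized at the sample mean and SD.
Fitting counts rather than maximizing a likelihood on raw values
reproduces the histogram-fit workflow; for perfectly symmetric histograms
the location gradient vanishes at the initialization, in which case `mu`
is held at the sample mean and only amplitude and width are fitted.
Conditions are compared with two-sided pooled-variance t-tests.

# PLA quantification

Dot counting is a self-contained reimplementation of standard
scale-normalized Laplacian-of-Gaussian blob detection (the original
counts came from an external tool whose parameters are unpublished, so
equivalence is functional, not bit-exact): Gaussian smoothing at a
geometric sigma ladder over `sigma_range` (default 1-4 px, 5 scales), a
`sigma^2`-normalized negated Laplacian, 3x3xscale local maxima above a
*relative* threshold (default 0.1 of the maximum response, making
detection invariant to global intensity scaling), and overlap suppression
keeping the stronger detection. Counts divided by the DAPI nucleus count
give blobs/cell, and condition means are normalized to a control
condition's mean. Z-stacks are reduced to maximum-intensity projections
before detection, consistent with the profile module.

# Cohort statistics

* IHC extension bands map percentages to scores 0-3 with edges at
  10/25/50%; the published band notation overlaps at the edges, so edges
  are assigned to the lower score (a flagged choice). Positivity is
  marker-specific: score >= 2 for E-cadherin and total SRC, >= 1 for
  P-cadherin and pSRC(Tyr416).
* Cohort percentages are rounded half-up (`percent_of_total()`), which is
  what reproduces printed figures such as 44% from 18/41 = 43.90%.
  Denominators include cases with missing marker data: 140/416 = 33.7%
  reproduces the published estrogen-receptor row only under that
  convention, which is therefore used for all series percentages.
* Chi-square is Pearson's without continuity correction, two-sided; zero
  marginals are an error rather than a silent `NaN`.
* Mann-Whitney uses the exact null distribution when `n*m <= 400` and no
  ties are present, otherwise a tie-corrected normal approximation
  without continuity correction; the exact branch is verified against a
  full enumeration oracle for all group sizes up to 6. Bonferroni
  adjustment is `min(1, p*m)`.
* Tumor volume is `V = 0.5 a b^2` (caliper major/minor axes in mm).

# What the synthetic data emulates — and what it does not

The generators are pure functions of their parameters and a required seed,
and ground truth is always recorded from the construction, never measured
back from the rendered data.

* **Two-cell scenes** (`sim_cell_pair_scene()`): elliptical cells whose
  membrane shell straddles the boundary (thickness 3 px), so the apposed
  shells of touching cells overlap at the junction and their expected
  intensities add — the doubled junction staining of a real cadherin
  junction. `membrane_fraction` splits a fixed per-cell signal budget
  between shell and uniform cytoplasm; Poisson noise is applied to the
  expected photon counts. Defaults (128x128 px at 0.2 um/px, cell radii
  ~27-30 px, 50 photons/px base, background 5) are chosen as plausible
  conditions for cultured epithelial pairs at moderate magnification;
  the original imaging parameters were never published, so these are free
  choices, not calibrations.
* **Profile ensembles**: the template shifted by uniform integer offsets
  (replicate-padded so ends stay boundary-like), amplitude-jittered,
  resampled to random raw lengths, optionally Poisson-corrupted.
* **Force curves**: piecewise-linear rupture events (triangle, plateau
  with short release ramps, three-step staircase) whose breakpoints are
  inserted into the sampling grid so the recorded truth work is the exact
  area of the constructed waveform.
* **PLA fields**: Gaussian spots placed by rejection sampling with
  separation at least 4 sigma, over a grid of nuclear disks.

What passing tests on this data do **not** show: robustness to optics
(PSF, chromatic shift, uneven illumination), 3D structure beyond max
projection, irregular cell shapes, touching or overlapping PLA dots,
multi-rupture AFM tethers, or segmentation errors in crowded fields. The
generators are statistical emulations of the analyses' assumptions, not a
microscope simulator; conclusions about real images need the usual
controls.

# Problem sizes and runtime choices

The test suite and the acceptance script run the registration benchmark at
`L = 100, n = 30`, denoising at 100x20 over 20 seeds, the end-to-end
localization comparison at 30 scenes per group for 20 replicates, the
Mann-Whitney property sweep at 100 random small-sample cases, and the
Gaussian-fit recovery at 10^4 draws. These sizes were picked to estimate
each rate or ratio stably while keeping a full run in the order of a
minute; all of them scale up by changing one argument.

# Known limitations

* The original profile software's exact Bayesian formulation is
  unpublished; the Poisson-MAP denoiser and the Gaussian-prior warp model
  here are a documented concretization of the stated noise assumption and
  variability objective, not a reimplementation of unpublished code.
* Compensation optimizes a non-convex objective by coordinate descent; it
  is guaranteed monotone, not globally optimal. Large shifts (beyond
  `max_knot_shift`, default 15 positions) are outside the warp search
  range.
* Blob detection reports integer-pixel centers (sub-pixel refinement is
  unnecessary at the 1 px acceptance tolerance) and assigns no blob to a
  specific cell.
* Automatic cell-boundary segmentation is out of scope: RD profile
  endpoints and, optionally, manual pair lists are user inputs, matching
  the semi-automated selection the workflow assumes.
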