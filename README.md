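# junctionr

Quantitative tools for cell-cell junction biology in breast cancer cell
models. The package answers a recurring question in cadherin/catenin
research: **is a junctional protein (p120-catenin, E-cadherin, ...) sitting
at the cell membrane or delocalized to the cytoplasm**, and how does that
localization relate to cell-cell adhesion strength, protein-protein
interaction frequency, and marker expression across tumor cohorts? It is
written for cell biologists and image analysts working with
immunofluorescence, single-cell force spectroscopy (AFM), proximity
ligation assays (PLA), and immunohistochemistry (IHC) series.

## What it implements

**Internuclear profile analysis.** For a pair of contiguous cells, the 1D
fluorescence profile is sampled along the segment joining the two nuclei
(IN profile), or from a nucleus toward the periphery within one cell (RD
profile). Profiles are length-normalized to 100 arbitrary units and
stacked as the columns of an *L x n* profile map **Y**. The map is then

1. **denoised** under a Poisson photon-noise model — each column is the MAP
   estimate minimizing `sum(u - y log u) + lambda * sum((du)^2)` over
   `u > 0`;
2. **geometrically compensated** — each column is re-parameterized by a
   monotone, endpoint-fixed, piecewise-linear warp `w_j` minimizing the
   row-wise variability `sum_j sum_p (Y_j(w_j(p)) - r(p))^2` plus a
   Gaussian prior `gamma * ||w_j - id||^2` that anchors warps to the
   identity (this absorbs cell-size and cell-shape variability);
3. **summarized** into average and SD profiles, from which two statistics
   are computed:
   - **MMR (maximum mean ratio)** = max(profile) / mean(profile), which is
     scale-invariant, equals 1 for uniform (cytoplasmic) signal and grows
     with junction-peaked (membrane) signal;
   - **membrane mean intensity**, the mean over a junction-centered window
     (default positions 46-55 of 100).

**AFM cell-cell adhesion.** Force-distance curves (Hooke conversion
`F = k * deflection`, nominal `k = 0.03 N/m`) are baseline-corrected on the
detached tail, and the **detachment work** — the area between baseline and
the adhesive (negative) part of the retract curve, in joules — is
integrated up to the detachment point. Work distributions are modeled with
frequency histograms plus least-squares Gaussian fits, and conditions are
compared with two-sided pooled-variance t-tests.

**PLA quantification.** Interaction dots are detected with scale-normalized
Laplacian-of-Gaussian blob detection, divided by the DAPI nucleus count,
and expressed as fold change over a control condition.

**Cohort statistics.** IHC extension scoring (0-3 bands at 10/25/50%),
marker-specific positivity cut-offs, rounded cohort percentages,
chi-square association on contingency tables, exact/approximate
Mann-Whitney tests with Bonferroni correction, and the caliper tumor-volume
formula `V = 0.5 a b^2`.

**Synthetic data.** Seeded generators emulate every input with recorded
ground truth: two-cell scenes with a tunable membrane/cytoplasm split and
Poisson noise, jittered profile ensembles with known shifts, sawtooth-like
retract curves with analytically known work, and separated Gaussian spot
fields. They make the whole pipeline testable end to end.

## Worked example

```r
library(junctionr)

# ten membrane-localized two-cell scenes -> normalized IN profiles
scenes   <- lapply(1:10, function(s) sim_cell_pair_scene(membrane_fraction = 0.8, seed = s))
profiles <- lapply(scenes, function(sc) scene_internuclear_profile(sc$marker, sc$nuclei))

res <- analyze_profile_group(profiles, lambda = 1)
res$stats
#> # A tibble: 1 × 3
#>     mmr membrane_mean n_profiles
#>   <dbl>         <dbl>      <int>
#> 1  1.88          31.1         10
```

The MMR of 1.88 (well above the uniform-signal value of 1) and the
junction-window mean of 31.1 a.u. (versus a cytoplasmic plateau of ~15
a.u. in these scenes) report membrane localization of the simulated
marker. A cytoplasm-localized group (`membrane_fraction = 0.2`) gives MMR
close to 1, and group membrane means are compared with
`mann_whitney_test()` + `bonferroni_adjust()`.

```r
# AFM: detachment work of a 200 pN x 2 um triangular rupture, 5 pN noise
fc <- sim_force_curve(f_max_pN = 200, shape = "triangular", event_um = 2,
                      noise_sd_pN = 5, seed = 3)
compute_detachment_work(baseline_correct(fc$curve))
#> # A tibble: 1 × 4
#>     work_J f_max_pN baseline_pN detach_index
#>      <dbl>    <dbl>       <dbl>        <int>
#> 1 2.00e-16     203.      -0.218          197
```

The recovered work, 2.00e-16 J, matches the constructed triangle area
(0.5 * 200 pN * 2 um). For cohort arithmetic:
`percent_of_total(18, 41)` prints `44` — of 41 pSRC(Tyr416)-positive
tumors, 18 (44%) are also P-cadherin positive.

Each result type has `autoplot()` (profile maps, summaries, force curves,
histogram fits) and broom-style `tidy()`/`glance()` methods.

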