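---
title: "Surface-based morphometry of the cervical spinal cord: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface-based morphometry of the cervical spinal cord}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cordmorph)
```

## The analysis in one paragraph

Lower-motor-neuron diseases such as SMN1-linked spinal muscular atrophy thin
the cervical spinal cord where anterior-horn motor neurons are lost. Given a
T2-weighted-like volume per subject, the pipeline crops the cervical region
between two operator-placed landmarks (top of the C2 odontoid process, middle
of the C7/T1 vertebral body), resamples it to an isotropic 0.3 mm working
grid, segments the cord, straightens the mask slice by slice, rescales every
subject to a common slice count so that slices correspond across subjects,
and then measures two quantities per slice: the cross-sectional area (CSA,
mm^2) and 72 radial distances (RD, mm) from the slice's center of mass to
the cord border, one every 5 degrees with 0 degrees pointing anterior.
Patients and controls are compared site-by-site with a one-sided permutation
test (values lower in patients), and atrophy is summarized as
`100 * (mean_ctrl - mean_pat) / mean_ctrl` per slice. Clinical scores enter
only through rank statistics: site-wise Spearman correlation maps, a
Spearman correlation between per-subject CSA and strength gradients, and a
Wilcoxon signed-rank test of proximal (C5) versus distal (C8) strength.

## Statistical model and assumptions

* **Permutation maps.** At each site the statistic is the difference of
  group means, `T = mean(controls) - mean(patients)`. Group labels are
  permuted with fixed group sizes; one shuffle is shared by all sites, which
  preserves the spatial coherence of the null field and makes a 72 x 413
  map affordable. The add-one estimator `p = (1 + #{T* >= T}) / (B + 1)`
  is used, so `p` is never zero and the smallest attainable value with
  `B = 100,000` permutations is `1e-5`. With equal group sizes, shuffles are
  drawn in antithetic pairs (each relabeling plus its group swap): the
  sampled null is then exactly symmetric, which in particular guarantees
  `p >= 0.5` at every site when the groups are identical. A Welch-t site
  statistic is available via `statistic = "t"`.
* **Supra-significance.** No formal multiple-testing correction is applied
  across the 413 (CSA) or 72 x 413 (RD) sites; instead a deliberately
  stringent threshold `alpha = 1e-3` is used, and the binomial standard
  error of each permutation p-value is reported alongside it.
* **Direction of the test.** One-sided, atrophy-oriented (patients below
  controls). Configurable (`side`).
* **Rank statistics for clinical data.** Ordinal, non-normal scores are
  handled with average-rank Spearman correlation (exact permutation null for
  n <= 8, t approximation above) and an exact tie-aware signed-rank test
  (dynamic-programming distribution for up to 25 non-zero pairs, normal
  approximation with tie correction beyond). Manual-muscle-testing scores
  enter as percent of maximum because the per-level maxima differ
  (C5, C6: /10; C7: /30; C8: /20).

## Geometry processing choices

* **Straightening is translation-only.** Each axial slice is shifted by an
  integer number of 0.3 mm voxels so its center of mass lands on the grid
  center. This preserves per-slice area *exactly* and radial distances up to
  the border-search resolution, at the cost of ignoring through-plane
  obliquity - acceptable because the acquisition protocol already minimizes
  cervical lordosis, and bowing in the phantom cohort is a few millimetres
  over ~12 cm.
* **Length standardization is nearest-neighbor.** Output slice `k` (0-based,
  inferior first) maps to input slice `round(k * (N-1) / (L-1))` with
  half-integer ties rounded toward inferior; masks stay binary and runs are
  bit-reproducible. The cohort target length is the *lower* median of
  subject lengths, so the target is an actually observed length. A full
  cervical cord at 0.3 mm is 413 slices.
* **Radial distances.** Rays are cast from the per-slice center of mass,
  sampled every 0.1 voxel with nearest-voxel membership; the
  inside-to-outside crossing is then refined by bisection to ~1e-5 voxel.
  The worst-case error against the underlying continuous boundary is half a
  voxel (0.15 mm); the test suite verifies circle/ellipse recovery at this
  tolerance and agreement with an independent boundary-pixel oracle (the
  per-5-degree maximum distance over boundary pixels) within one voxel
  diagonal. Sub-voxel ray casting is the primary method; the boundary-pixel
  method is deliberately kept as the test oracle only.
* **Vertebral levels.** The C2..C7 levels are fractional intervals of the
  standardized axis (equal sixths by default, configurable) because level
  boundaries were localized visually in the source protocol. The
  vertebral-to-spinal-segment lookup follows clinical usage: a span
  `Ck`-`Cm` of vertebrae overlies segments `C(k+1)`-`C(m+1)`, and a single
  vertebra `Ck` overlies `C(k+1)`-`C(k+2)` (so C3-C6 vertebrae correspond
  to C4-C7 segments).

## Segmentation: a declared reconstruction

The published analysis used a double-threshold segmentation whose exact
equations live in an earlier methods paper that this package does not
reproduce. `segment_dtbm()` is therefore a *declared reconstruction* with a
fixed contract, and any external segmentation can be swapped in through
`load_external_mask()` (which validates the single-component/no-hole
invariants and logs repairs). The reconstruction: per axial slice, two
thresholds are taken as intensity quantiles (defaults 0.5 and 0.8) of a
15 x 15 mm window centered on the propagated centerline estimate; on
T2-like contrast these bracket the cord band (background below, CSF above).
The band's connected component containing the propagated seed is kept,
interior holes are filled, and the window center propagates from the slice
center of mass. One caveat found during development: because the window
position depends on the previous slice's mask, mask monotonicity in
`t_low_q` is guaranteed per slice (fixed window) but can be perturbed by a
boundary voxel across a whole volume. Quantile thresholds make the method
exactly invariant to intensity shift and positive rescaling. Slice-level
smoothing is available but off by default: on sharp-edged phantoms it blends
boundary voxels into the cord band and dilates the mask by up to half a
voxel along the CSF interface, while the quantile band plus hole-filling is
already robust to 10% noise without it.

Bias-field correction is likewise a stand-in for the external N3 tool used
in the original preprocessing: a total-degree polynomial (default 2) is fit
to the log intensity of the brightest tissue class (voxels above 70% of the
99.5th intensity percentile - within one class the log-intensity variation
*is* the bias), the volume is divided by the exponentiated fit, and the
global mean is restored. `poly_order = 0` is a mean-preserving no-op.
Cubic (Catmull-Rom) resampling reproduces constants exactly; overshoot at
hard edges is clamped to the input intensity range.

## The synthetic cohort: what it emulates and what it does not

`phantom_spec()` renders a curved elliptical tube (the cord) inside a
brighter CSF sheath on a dark background: T2-like contrast with defaults
cord 100, CSF 200, background 20, additive Gaussian noise, an optional
multiplicative linear bias field, a half-sine anterior-posterior bow
(default 4 mm) emulating residual lordosis, and 0.9 mm acquisition or
0.3 mm working voxels. A voxel belongs to the mask iff its center lies
inside the ellipse - unambiguous and convergent under grid refinement
(the suite checks that voxel-count CSA error strictly decreases from 0.9 to
0.3 to 0.1 mm).

No absolute control CSA values are printed in the source material, so the
default semi-axis control points are the implementer's assumption, chosen to
match published normative shapes: CSA ~69 mm^2 at C2, peaking ~83 mm^2 near
C4-C5 (cervical enlargement), ~60 mm^2 at C7/T1, via anterior-posterior
semi-axes 3.8-4.2 mm and right-left semi-axes 5.0-6.3 mm. They are
configuration, not constants.

`atrophy_field()` imposes a fractional reduction profile (smoothstep ramps
over 10% of the extent, plateau between) on a chosen direction:
anterior-posterior or right-left semi-axis, isotropic area, or - beyond the
three symmetric options - `"anterior"`, which shrinks only the anterior
half-ellipse. The anterior option exists because symmetric scaling cannot
displace the center of mass: with anterior-only atrophy of fraction `p` the
center of mass moves posteriorly by `(4 / 3 pi) * a * p`, so measured radii
fall at *both* anterior (`-0.576 a p`) and posterior (`-0.424 a p`) angles -
the mechanism by which ventral-horn atrophy produces apparent dorsal RD
loss, which the acceptance suite reproduces.

Cohorts (`cohort_spec()`, default 18 patients + 18 controls) draw
per-subject semi-axis factors and patient atrophy peaks from mean-one
lognormals with a configurable coefficient of variation (default 5%).
Clinical records follow the study's descriptive statistics (MMT percent
means 73.3/84.4/86.9/72.2 with SDs 19.4/18.9/15.2/13.5 for C5..C8, MFM,
ALSFRS-R, disease duration 26 +- 15 years); controls are healthy
(full-strength, functional scales not administered). A latent-Gaussian
construction couples MMT percents to each patient's realized peak atrophy
with correlation `clinical_coupling` (default 0, matching the null clinical
findings the analysis is calibrated against); a strictly monotone soft
clamp keeps percents inside (0, 100) without creating rank ties, so
`clinical_coupling = 1` yields exactly rank-correlation 1. Raw subscores are
the rounded percent-of-maximum values.

The generator does not emulate MR physics (no k-space, no Rician noise -
additive Gaussian is justified because segmentation operates far above the
noise floor and all group statistics are rank- or permutation-based), no
vertebrae, no gray/white contrast, and no partial-volume intensity mixing.
A green test therefore establishes correctness of the measurement and
inference chain on known geometry, not robustness to scanner artifacts.

## Numerical details worth knowing

* Half-integer rounding: slice standardization rounds half toward inferior;
  straightening shifts use R's default round-half-even. Both are stated so
  outputs are bit-reproducible.
* Permutation p-values are compared with a relative tolerance of 1e-12 when
  counting `T* >= T` so that exact ties (identical groups) are counted as
  ties rather than resolved by floating-point noise.
* The Spearman exact path enumerates all `n!` score-rank permutations and is
  limited to `n <= 8` (40,320 permutations, shared across sites); beyond
  that the t approximation is used. The signed-rank exact path works on
  doubled ranks (average ranks are half-integers) and a subset-sum
  generating function, so ties are exact too.
* Every output CSV/JSON embeds an MD5 hash of the analysis configuration
  (excluding the output directory), and reruns with the same configuration
  are byte-identical.

## Known limitations

* The segmentation is a reconstruction, not the published implementation;
  accuracy claims transfer only through the phantom calibration (Dice >=
  0.95 noise-free, median CSA error < 5% at 10% contrast noise).
* Straightening by translation cannot correct severe curvature; volumes
  should be acquired (or simulated) with limited lordosis.
* Level boundaries are fractional conventions, not anatomical detections;
  per-level statements inherit that convention.
* The deposited cohort MAT-file loader reads the uncompressed MAT v5 subset
  (numeric/char/struct/cell) and discovers its schema by field-name
  matching; compressed or HDF5-based files must be re-saved as `-v6`.
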