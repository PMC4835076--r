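# cordmorph

Surface-based morphometry of the cervical spinal cord in R.

## What problem this solves

In lower-motor-neuron diseases (the motivating case is adult SMN1-linked
spinal muscular atrophy), loss of anterior-horn motor neurons thins the
cervical cord. `cordmorph` turns per-subject T2-weighted-like volumes (or
ready-made binary cord masks) into slice-wise atrophy statistics that can be
compared across a cohort:

* **preprocess** — crop the cervical region between the C2 odontoid tip and
  the C7/T1 vertebral body, cubic-resample to an isotropic 0.3 mm grid,
  optional polynomial bias-field correction;
* **segment** — double-threshold cord segmentation (quantile band between
  dark background and bright CSF, seeded connected component, hole filling,
  slice-to-slice centerline propagation), or ingestion of externally edited
  masks with invariant checking;
* **standardize** — straighten each mask by per-slice integer translation
  (area-preserving) and rescale every subject to a common slice count
  (nearest neighbor; 413 slices for a full cervical cord at 0.3 mm) so that
  slice *k* means the same anatomy in every subject;
* **morphometry** — per slice, the cross-sectional area
  `CSA(z) = voxel count x 0.09 mm^2` and 72 radial distances `RD(z, theta)`
  from the slice center of mass to the cord border, one every 5 deg
  (0 deg = anterior);
* **stats** — one-sided site-wise permutation maps
  (`T = mean_ctrl - mean_pat`, add-one estimator
  `p = (1 + #{T* >= T})/(B + 1)`, supra-significance threshold
  `alpha = 1e-3`, default `B = 100,000` so `min p = 1e-5`), the atrophy-rate
  profile `100 (mean_ctrl - mean_pat)/mean_ctrl`, Spearman correlation maps
  against clinical scores, CSA-gradient vs MMT-gradient correlation, and an
  exact Wilcoxon signed-rank test of proximal (C5) vs distal (C8) strength;
* **phantom** — a synthetic cord generator (elliptical tube + CSF sheath +
  noise/bias, cervical-enlargement CSA profile, parametric atrophy fields,
  clinical scores with configurable coupling to atrophy) with analytic
  ground truth, used for validation and calibration throughout the tests.

## Worked example

Simulate an 18 + 18 cohort with a 20% anterior-posterior atrophy plateau
over the C3–C6 vertebral levels (5% between-subject variability), measure
everyone on the standardized grid, and map the group difference:

```r
library(cordmorph)

atr    <- atrophy_field(direction = "anterior-posterior", peak = 0.20,
                        extent = c("C3", "C6"))
cohort <- cohort_spec(n_patients = 18, n_controls = 18, atrophy = atr,
                      between_subject_cv = 0.05, seed = 42)
phant  <- phantom_spec(cord_length_mm = 124, voxel_mm = 0.3)

prof <- cohort_profiles(cohort, phant)     # generate -> straighten ->
cat("L =", prof$L, "\n")                   # standardize -> measure
#> L = 413

pat <- prof$csa[prof$records$group == "patient", ]
ctl <- prof$csa[prof$records$group == "control", ]
map <- permutation_map(pat, ctl, n_perm = 10000, alpha = 1e-3, seed = 42)
map
#> <comparison_map> 413 sites, 10000 permutations (decrease, mean_diff)
#>   min p = 0.0001 (SEp = 0.0001), 249 sites < alpha = 0.001

rate <- atrophy_rate(pat, ctl, map)
sig  <- attr(rate, "significant")
cat(sprintf("atrophy rate over significant sites: %.1f%% to %.1f%%\n",
            min(rate[sig]), max(rate[sig])))
#> atrophy rate over significant sites: 9.0% to 19.9%

wt <- proximal_distal_test(prof$records$mmt_pct_c5[1:18],
                           prof$records$mmt_pct_c8[1:18])
cat(sprintf("proximal vs distal strength: V = %.1f, p = %.3f\n",
            wt$statistic, wt$p))
#> proximal vs distal strength: V = 104.0, p = 0.442
```

Reading the numbers: the standardized cord is 413 slices; 249 of them fall
below the supra-significance threshold, and the measured atrophy rate over
those slices spans ~9–20%, i.e. the injected 20% plateau plus its ramps.
The permutation floor at 10,000 shuffles is 1/10001 ~ 1e-4. The clinical
generator was left at `clinical_coupling = 0`, so strength scores carry no
signal (p = 0.44 for the proximal-distal contrast, and correlation maps
stay empty at `alpha = 1e-3`).

`run_pipeline(run_config(...))` drives the same chain from NIfTI volumes on
disk (landmark JSON sidecars, optional external masks) and writes profiles,
maps, the atrophy-rate curve, clinical correlations, a summary table and a
provenance log, every file stamped with the configuration hash. A CLI with
verbs `simulate / preprocess / segment / standardize / measure / compare /
correlate / report / run-all` is installed under `inst/cli/cordmorph`.

## Documentation

See the methods vignette
(`vignettes/cord-atrophy-morphometry.Rmd`) for the statistical model, the
geometry-processing choices, what the phantom cohort does and does not
emulate, and known limitations.
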