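# wmhresample

How many manually delineated training cases does a trainable white matter
hyperintensity (WMH) segmenter need before its volume estimates become
accurate *and robust* in a population where most people have almost no
lesions? `wmhresample` implements that question as a fully reproducible
resampling experiment for R: a synthetic 3D phantom cohort with known
ground truth, a leakage-aware draw/validate design, a voxel-wise k-nearest
neighbour lesion classifier, and an evaluation harness for volume error,
Dice overlap, threshold selection and training-set composition. It is aimed
at neuroimaging methodologists planning manual-segmentation budgets for
population studies, and at anyone who wants a tested sandbox for
sample-size behaviour of trainable voxel classifiers.

## The model in brief

* **Cohort.** `n` participants with paired baseline/follow-up scans plus a
  fixed external validation partition. Lesion loads follow a zero-inflated
  log-normal: `P(V = 0) = p0`, `V | V > 0 ~ LogNormal(mu, sigma)`, with
  `(mu, sigma)` calibrated by quantile matching to a median of 0.34 ml and
  an IQR of 1.6 ml at `p0 = 0.13` — the signature of a low-load, normally
  aging cohort. Follow-up volumes grow multiplicatively (mean factor 1.6)
  with Poisson de-novo lesions.
* **Design.** At each training size `n ∈ {10, ..., 40}`, 100 draws without
  replacement, at most one scan per participant; validation on internal BL,
  internal FU (participants wholly excluded once trained on — no
  participant-level leakage) and the external set.
* **Classifier.** Per brain voxel, features are standardized FLAIR and T1
  intensities plus spatially weighted grid coordinates; the lesion
  probability is `#lesion neighbours among k nearest / k` (default
  `k = 40`, reference caps 2000 lesion / 10000 non-lesion points).
* **Evaluation.** Volumes in ml; signed error `predicted − manual`
  (positive = overestimation); per-model mean/SD/median/IQR; global
  threshold `t* = argmin_t |mean error|` over an 11-point grid; Dice
  `2|A∩B| / (|A|+|B|)`; composition (share of low-volume training members)
  and volume-stratified error analyses.

## Worked example

The design bookkeeping at study scale (80 paired participants, 41 external
observations, 7 sizes × 100 draws) is exact arithmetic:

```r
library(wmhresample)
d <- enumerate_design(design_params())
d
#> # A tibble: 7 × 6
#>   sample_size internal_bl internal_fu external per_model overall
#>         <int>       <int>       <int>    <int>     <int>   <int>
#> 1          10          70          70       41       181   18100
#> 2          15          65          65       41       171   17100
#> 3          20          60          60       41       161   16100
#> 4          25          55          55       41       151   15100
#> 5          30          50          50       41       141   14100
#> 6          35          45          45       41       131   13100
#> 7          40          40          40       41       121   12100
attr(d, "total_models")        # 700
attr(d, "total_predictions")   # 105700
```

The calibrated lesion-volume simulator reproduces the cohort statistics it
targets:

```r
m <- lesion_volume_model()
v <- sample_lesion_volume(m, 1e5, seed = 1)
c(median = median(v), iqr = IQR(v), zero = mean(v == 0))
#>   median      iqr     zero
#> 0.340000 1.588000 0.132000   (targets: 0.34 ml, 1.6 ml, 0.13)
```

A desk-scale version of the full experiment (40 paired + 20 external
phantoms on 32³ grids, training sizes {5, 10, 20}, 20 draws each; about ten
minutes on one core):

```r
cfg <- experiment_profile("scaled", seed = 1)
res <- run_experiment(cfg, "scaled_run", quiet = FALSE)

res$selected_threshold
#> [1] 0.6

res$error_by_size   # mean (SD) across models of per-model mean error, at t*
#>   sample_size validation_set n_models mean_of_means sd_of_means
#> 1           5 external             20      -0.298         0.293
#> 2           5 internal_bl          20       0.0508        0.259
#> 3           5 internal_fu          20      -0.201         0.308
#> ...
#> 7          20 external             20      -0.323         0.106
#> 8          20 internal_bl          20       0.00640       0.181
#> 9          20 internal_fu          20      -0.245         0.220
```

Reading this: at every validation set the *SD across models* shrinks as the
training sample grows (external: 0.293 → 0.203 → 0.106 ml) — drawing a
"bad" training set becomes less likely, the robustness effect that
motivates larger training samples. The stratified table shows the error
direction flipping with lesion size (zero-volume subjects can only be
overestimated; large lesions lose ambiguous boundary voxels and are
underestimated):

```r
res$stratified
#>   bin           n mean_error mean_dice
#> 1 0           200     0.702      0
#> 2 (0,0.1]     685     0.638      0.120
#> 3 (0.1,0.5]  1370     0.451      0.435
#> 4 (0.5,2]    1058    -0.0993     0.789
#> 5 >2         1287    -1.43       0.670
```

`run_experiment()` writes everything to the output directory: `design.csv`,
`raw_records.csv` (one row per draw × observation × threshold), `draws.csv`,
`summaries.csv`, `threshold_selection.csv`, `error_by_size.csv`,
`composition*.csv`, `stratified.csv` and a `manifest.json` with seeds and
checksums. Runs are resumable per (size, replicate) unit and byte-identical
under the same seed. A thin command-line wrapper with `generate`, `design`,
`run-all` and `report` subcommands is in `inst/cli/wmh-experiment.R`.

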