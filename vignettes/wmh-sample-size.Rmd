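---
title: "How training sample size shapes trainable WMH volumetry: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How training sample size shapes trainable WMH volumetry: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

White matter hyperintensities (WMH) are bright FLAIR lesions used as an
imaging marker of cerebral small-vessel disease. In healthy, normally aging
cohorts most participants carry little or no lesion load (medians well below
1 ml, with a substantial lesion-free fraction), which makes trainable
segmentation tools hard to calibrate: they are usually developed on
high-load clinical populations. A central practical question for population
studies is therefore how many manually delineated training cases a
voxel-wise lesion classifier needs before its *volume* estimates become both
accurate (small mean signed error against the manual standard) and robust
(small spread of that error across the luck of the training draw).

`wmhresample` implements that question end to end as a resampling
experiment: generate a cohort with known ground truth, repeatedly draw
training sets of increasing size under strict leakage rules, train a
voxel-wise k-NN classifier per draw, predict lesion-probability maps on the
held-out observations, and analyse volume errors, Dice overlap, threshold
choice, and training-set composition.

## The synthetic cohort

Real MRI with manual lesion masks cannot be redistributed, so the package
ships a phantom generator whose *population statistics* are the quantity of
interest, not anatomical realism.

**Geometry.** Each subject is a nested-ellipsoid head on a configurable
grid: a brain ellipsoid, a thin cortical (GM-like) shell, a central
CSF-like core, and white matter in between. All subjects on a grid share
this geometry (they are "co-registered" by construction, standing in for
the registration steps of a real pipeline); spatial position is expressed
in grid-normalized coordinates rather than template (MNI) coordinates.

**Lesion-volume law.** Lesion loads are drawn from a zero-inflated
log-normal mixture: a subject is lesion-free with probability `p_zero`
(default 0.13) and otherwise receives a log-normal volume. The defaults are
*calibrated by quantile matching*: the constructor solves for
`(log_mu, log_sigma)` so that the mixture attains a median of 0.34 ml and
an IQR of 1.6 ml — the pooled summary statistics of the low-load cohort the
experiment emulates. Only empirical summaries of such cohorts are ever
published, not a distributional law; the zero-inflated log-normal is our
modelling choice for the right-skewed, zero-inflated shape, and the
calibration makes it reproduce the published quartiles exactly in
expectation. A consequence worth knowing: a log-normal matched to these
quartiles has `sigma ~ 2.1` and hence a heavy upper tail, so its *mean*
(~4 ml) is far above its median — heavier than the cohorts it mimics, which
top out at moderate volumes. Target volumes are therefore clamped at 85% of
the phantom's WM-eligible capacity during cohort generation; on the 64^3
default grid the clamp almost never binds, on small test grids it truncates
the top few percent. The calibration checks in the test suite run on
`sample_lesion_volume()` itself, before clamping.

**Lesion placement.** A target volume is realized as randomly seeded
quasi-spherical blobs grown voxel-by-voxel inside the WM-eligible region
(an ellipsoidal annulus that keeps lesions off the CSF core and the
cortical shell), so the realized mask volume equals the target up to voxel
rounding. Blob sizes are Poisson with mean `blob_mean_voxels` (default 30),
which is the granularity of the realization.

**Longitudinal progression.** A follow-up (FU) scan reuses the baseline
(BL) head: existing lesions are dilated outward to a target of
`BL volume x growth factor` (growth factors are normal with mean 1.6,
SD 0.3, floored at 1), and de-novo lesions arrive with a Poisson count
(rate 0.2). Growth is monotone by construction — FU masks always contain BL
masks — which encodes the observed intra-individual volume increase over
time. The pooled calibration (median 0.34 ml) is applied to BL draws and FU
volumes then grow from there, so the simulated pooled median sits slightly
above the pooled target while reproducing the BL < FU ordering and the
slightly lower FU zero-fraction; we prefer this one-knob construction over
separately calibrated BL and FU laws.

**Intensities.** Tissue classes get constant means per channel (FLAIR:
lesion 170 vs WM 100, so lesions are hyperintense; T1: lesion mildly
hypointense), followed by an optional one-pass 6-neighbour box smoothing
that emulates partial-volume averaging at boundaries, additive Gaussian
noise (SD 10 by default against a 70-unit FLAIR contrast), and zeroing
outside the brain (brain-extracted images). The smoothing matters: it makes
boundary voxels genuinely ambiguous, which is what produces the
characteristic behaviour of threshold-based segmentation on low-load data
(false positives on lesion-free subjects, trimmed boundaries on large
lesions).

**What the phantom does not emulate** — and what passing tests therefore do
not show about real data: cortical anatomy and lesion taxonomy
(periventricular vs deep), bias fields, registration error, scanner
artifacts, and manual-rater noise. The phantom isolates the *sampling*
question (how training-set size and composition propagate into volume
error) from the *image-quality* question, and only the former is claimed.

## The resampling design

From a cohort of `n_paired` participants with BL and FU scans (the
resampling partition, 2 x 80 observations at study scale) plus a fixed
external partition (41 observations), training sets of sizes 10-40 (step 5)
are drawn 100 times each, uniformly without replacement, with at most one
observation per participant. Validation uses three sets per draw: internal
BL and internal FU (all scans of participants *not* in the draw — if either
scan of a participant was trained on, both are excluded, eliminating
participant-level leakage) and the external set. The bookkeeping identity
`|internal BL| + |internal FU| = 2 (n_paired - n)` and the grand totals
(700 models, 105,700 predicted maps at study defaults) are enumerated by
`enumerate_design()` and verified in the tests. Within a draw, sampling is
without replacement; across replicates draws are independent, so duplicate
training sets are possible in principle — `report_duplicate_draws()`
reports rather than forbids them. The timepoint of a drawn participant is
chosen uniformly (BL or FU with probability 1/2 each), the natural reading
of drawing from the pooled 160-image set under the one-per-participant
constraint.

## The classifier

The per-draw model is a voxel-wise k-nearest-neighbour classifier, a
re-implementation of the class of trainable intensity classifiers used for
WMH segmentation (k-NN over intensity plus spatial features). Features per
brain-mask voxel: each modality's intensity standardized within the
subject's own brain mask (zero-variance guard: constant images standardize
to zero), then the three grid coordinates normalized to [0, 1] and scaled
by a spatial weight (default 1; 0 gives a pure intensity classifier).
Reference points are pooled across the training subjects' masks and
subsampled per class to caps (defaults 2000 lesion / 10000 non-lesion,
k = 40 — the recommended operating point in the literature this design
follows; all config-exposed). Non-lesion points come from the whole brain
mask: no white-matter exclusion masks and no minimum-cluster thresholds are
applied. The probability at a voxel is the fraction of lesion-labelled
points among its k nearest references (Euclidean distance in feature
space).

Numerical contracts, all tested against a brute-force distance-sort oracle:
probabilities are exact multiples of 1/k; neighbour selection follows the
total order (distance, reference row index), so ties at the k-th distance
resolve to the earlier reference row and results are independent of query
order; a training set with zero lesion voxels yields a degenerate model
that predicts 0 everywhere (with a warning). Thresholding uses `>= t` for
`t > 0` and `> 0` at `t = 0` (so the zero threshold returns "any lesion
evidence" rather than the whole brain); comparisons carry a 1e-9 guard so
the decimal threshold grid meets the rational probabilities exactly.

## Evaluation

Volumes are voxel counts times voxel volume (ml). The primary error is the
*signed* volume error, predicted minus manual (positive = overestimation).
We deliberately avoid the ambiguous phrase "mean absolute error" — the
study tradition uses it for the mean of signed deviations — and name the
statistics `mean_error` and `abs_mean_error` explicitly. Per model,
validation set and threshold we report mean, sample SD (n-1), median and
IQR (linear-interpolation quartiles, `quantile` type 7; stated because
median/IQR values depend on the convention). The global threshold t* is the
argmin over the 11-point grid of |across-model mean signed error| in the
two internal sets (configurable; magnitude is the default objective, the
signed value is available by flag), ties broken toward the larger — more
conservative — threshold. Dice similarity is `2|A n B| / (|A| + |B|)`; an
empty manual mask with a non-empty prediction scores 0, and the both-empty
case is undefined and excluded from averages (an option maps it to 1
instead). Composition analysis relates each draw's proportion of low-volume
training members (< 0.1 ml, < 0.5 ml) to its model-level mean error;
stratified analysis bins observations by ground-truth volume (0, (0, 0.1],
(0.1, 0.5], (0.5, 2], > 2 ml by default).

## Orchestration and reproducibility

`run_experiment()` executes generate → draw → fit → predict → evaluate.
Work units are (sample size, replicate) pairs; each unit's raw records are
written as they complete, `resume = TRUE` skips finished units, and a
populated output directory is refused without it. All randomness descends
from one master seed through named substreams (FNV-1a hashes of
"stage/size/replicate" labels), so cohorts are stable under extension and
identical configurations give byte-identical raw-record CSVs. Summary
tables are always recomputed from the raw-records CSV (never from in-memory
state), so deleting them and re-running `report_experiment()` reproduces
them exactly. A manifest (config echo, seeds, file checksums) accompanies
every run.

Three profiles fix the problem sizes: `"toy"` (8 paired + 4 external, 24^3,
sizes {2, 4}, 5 draws — seconds; used by the test suite), `"scaled"`
(40 paired + 20 external, 32^3, sizes {5, 10, 20}, 20 draws, reference caps
200/1000 — about ten minutes; used for the convergence and direction
analyses), and `"full"` (80 + 41, 64^3, 7 sizes x 100 draws, caps
2000/10000 — the full design, an overnight run). The scaled profile's caps
are smaller than the defaults in proportion to its grid; they keep the
classifier's behaviour (noisy at small n, stable at large n) while making
repeated desk-scale runs practical.

```{r example}
library(wmhresample)
cfg <- experiment_profile("scaled", seed = 1)
res <- run_experiment(cfg, "scaled_run", quiet = FALSE)
res$selected_threshold
res$error_by_size
```

## What the experiment shows, and its limits

On the synthetic cohort the harness reproduces the qualitative findings
that motivate it: the across-draw SD of the per-model mean signed error
shrinks as the training sample grows (robustness increases with n); models
trained with few low-volume subjects overestimate while those trained with
many underestimate (negative rank correlation between the < 0.5 ml training
proportion and the model's mean error); and the mean signed error falls
from positive in the zero-volume stratum (a zero volume cannot be
underestimated) to negative in the largest stratum (thresholding trims
ambiguous boundary voxels, and boundary volume grows with lesion size).
These are direction checks, not magnitude claims: absolute error levels on
phantoms depend on the phantom's contrast and noise and do not transfer to
any particular scanner or cohort. The quantitative anchors that *are*
checked exactly are the design bookkeeping and the simulator calibration;
everything downstream is validated against independent oracles
(enumeration, brute-force k-NN, naive statistics) rather than against
numbers from any real dataset.
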