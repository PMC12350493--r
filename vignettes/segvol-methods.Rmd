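---
title: "Segmentation and volumetry of small brain structures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmentation and volumetry of small brain structures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(segvol)
```

`segvol` quantifies the volume of a small bilateral brain structure (the
hypothalamus) and the intracranial volume (ICV) from stacks of preprocessed
2D grayscale PNG slices. This vignette documents the models, the defaults
and the reasoning behind every genuinely open design choice. It states no
empirical result beyond what the package's test suite and acceptance script
themselves compute.

## Input contract

The unit of work is a *slice stack*: an ordered set of single-channel PNG
slices named `<subjectID>_<NNN>.png` with zero-padded, 0-based slice
indices, plus a voxel geometry. Two clinical presets are built in:
50 slices of 512×512 at 0.125 × 0.125 × 0.5 mm (hypothalamus) and
512 slices of 512×512 at 0.5 × 0.5 × 0.5 mm (ICV). Upstream steps —
DICOM conversion, rigid reorientation, upsampling, and the selection of the
50 hypothalamus slices — are treated as an input contract, not reproduced
here. Stacks violating the geometry (wrong slice count or matrix) are
reported, never silently dropped; gaps or duplicates in a slice sequence
are hard errors, because a silently missing slice corrupts a volume
estimate. Slice indices are assumed to restart per subject.

Masks are stored as 8-bit grayscale PNGs, foreground 255. Decoding maps
values above 127 to foreground so that anti-aliased manual edits survive a
round trip; with the package's own writer the round trip is bit-exact.

## Cohort z-score normalization

Scanner and session differences shift the global intensity scale per
subject. The normalization used here is deliberately cohort-level and
global: with per-subject mean intensities $m_1, \dots, m_n$ (over **all**
voxels of a stack, background included), every voxel of every stack maps to

$$ v \mapsto \frac{v - \mu}{\sigma}, \qquad
   \mu = \overline{m}, \quad \sigma = \mathrm{sd}(m_1,\dots,m_n) $$

with the sample (n−1) standard deviation. Two readings of "the SD of the
means" are possible — the SD of per-subject means, or a pooled voxel SD; the
former is implemented because it is what the phrase literally describes, and
a foreground-only variant of the per-subject mean is available but off by
default. Note this is *not* per-image standardization: a single affine map
is applied to the whole cohort, so between-subject contrast relationships
are preserved while between-subject offset/gain variation is compressed.

The parameters are estimated on the training cohort only and frozen
(`cohort_stats.json` next to the models) so validation, test and inference
subjects cannot leak into them. At least two subjects are required; a
zero-variance cohort is an error rather than a silent division by zero.

## The segmentation network

The backbone is a plain U-Net-style encoder–decoder: per stage two 3×3
convolutions + ReLU, 2×2 max-pooling on the way down, nearest-neighbour 2×
upsampling and skip concatenation on the way up, and a 1×1 convolution to a
2-class softmax. Depth (down-sampling stages) and width (channels of the
first stage) are configurable (`net_config()`); the defaults used by the
tests are depth 2, 8 base channels — a deliberately small network, because
the package must train on one CPU and the pretrained large-backbone variant
of this architecture is a configuration point rather than something the
package can ship. Convolutions (forward and backward) are implemented in
compiled code (RcppArmadillo, im2col + GEMM); the backward pass is verified
against finite differences in the test suite.

**Loss.** The training loss is the sum of the mean per-pixel categorical
cross-entropy and a soft-Jaccard term:

$$ L = \mathrm{CE}(p, t) + \Bigl(1 - \tfrac1C \sum_c
   \frac{\sum p_c t_c}{\sum p_c + \sum t_c - \sum p_c t_c + \varepsilon}\Bigr) $$

with $\varepsilon = 10^{-6}$. The Jaccard sums run over the whole batch
tensor. The loss is zero (up to $\varepsilon$) iff the prediction equals
the target exactly.

**Optimization.** Adam at learning rate $10^{-4}$ with the conventional
remaining defaults ($\beta_1 = 0.9$, $\beta_2 = 0.999$), batches of 4
slices, at most 25 epochs. Early stopping monitors the validation loss:
"improvement" means strictly better than the best value so far by at least
$10^{-6}$, and training stops after 10 consecutive non-improving epochs,
returning the best-epoch parameters. The epoch cap is treated as a hard
cap, configurable. Per-epoch slice shuffling is seeded from the
configuration seed, so training is bit-reproducible in a single-threaded
run.

**Splits.** Cross-validation folds are assigned *by subject* — all slices
of a subject share a fold — because neighbouring slices of one subject are
strongly correlated and slice-level splitting would leak. A fixed test set
is removed first and never enters any fold; fold sizes differ by at most
one (k = 5 gives the 20% held-out validation share).

**Validation metric.** Mean IoU over the two classes of the
argmax-binarized prediction (equivalent to a 0.5 threshold on the
foreground probability), averaged over validation subjects. A class empty
in both masks contributes IoU 1.

## Ensembling

Inference uses the weighted ensemble of the K fold models with fixed
weights proportional to each fold's validation IoU,
$w_i = \mathrm{IoU}_i / \sum_j \mathrm{IoU}_j$. Averaging happens in
probability space *before* thresholding: that is the standard reading of an
"averaged ensemble", it keeps probabilities convex, and it makes the
single-model case an exact special case (weights = [1]). Binarization is
at 0.5 with ties to foreground; degenerate folds (validation IoU ≤ 0) are
an error rather than a zero weight. The ICV task uses a single model
(single-validation training) — the task has much stronger contrast and a
simple convex target, so the ensemble machinery is reserved for the
hypothalamus.

## Evaluation metrics

* **Dice** $= 2TP/(2TP+FP+FN)$.
* **HD95**: the maximum of the two directed 95th percentiles of
  minimum Euclidean distances between mask point sets. Point sets are
  *boundary* voxels (mask voxels with at least one 6-neighbour outside the
  mask, the stack treated as a 3D grid); voxel centers are scaled by
  (dy, dx, dz) before distances, so the result is in millimetres and
  respects anisotropic slices. Whether to use boundary or all mask voxels
  is not universally standardized; boundary extraction is the common
  convention and the brute-force oracle in the tests uses the same
  convention, while `points = "all"` is available. The percentile is the
  linear-interpolation (type-7) estimator.
* **Volume similarity** $= 1 - ||A|-|B||/(|A|+|B|)$, identically equal to
  $1 - |FN-FP|/(2TP+FP+FN)$; the test suite asserts the two forms agree
  exactly.

Edge conventions are fixed and documented: two empty masks give Dice 1,
VS 1, HD95 0; one empty mask gives Dice 0, VS by formula, and an
*undefined* HD95 reported as `NA` with a warning — never silently zero.
`evaluate_models()` assembles the per-fold + ensemble, group-stratified
mean ± SD table with a paired two-sided t-test of predicted vs ground-truth
volumes per row.

## Volumetry and ICV normalization

Volume is positive-voxel counting times the voxel volume — exact by
construction, additive over slices, with the two presets giving
0.0078125 mm³ and 0.125 mm³ per voxel. The ICV normalization is a ratio
scaled by a reference ICV:

$$ V_{\mathrm{norm}} = V_{\mathrm{hyp}} \cdot
   \frac{\mathrm{ICV}_{\mathrm{ref}}}{\mathrm{ICV}_{\mathrm{subject}}} $$

The scaling by a reference (default: the analyzed cohort's mean ICV after
QC) keeps results in mm³, which is how normalized hypothalamic volumes are
conventionally reported; a bare ratio would be dimensionless. The exact
form is isolated in one function (`normalize_hypothalamic_volume()`) so an
alternative convention is a one-line replacement.

## Quality control and statistics

ICV outliers are flagged within sex strata (clinical groups pooled — the
stratification is by sex, not by diagnosis) when a value deviates from the
stratum mean by strictly more than 2 sample SDs; the boundary case is *not*
flagged. Mean and SD include the candidates themselves; strata under 3
records are skipped with a warning. Flagging is scale-invariant. Flagged
subjects can be manually re-segmented; `apply_manual_correction()`
recomputes the volumes from the corrected mask, marks the record, and keeps
the superseded record in an audit log.

Descriptive summaries use linear-interpolation (type-7) quartiles for
median and IQR plus mean and sample SD. The group comparison is the
equal-variance (pooled) unpaired Student's t-test with
$df = n_a + n_b - 2$ — Student's, not Welch's, because that is the named
test of the workflow this package operationalizes; Welch is available via
an option. Degenerate inputs are resolved explicitly: identical constant
groups give t = 0, p = 1; zero pooled variance with unequal means is
reported as p = 0 with a warning.

## The head phantom

The generator (`phantom_spec()`) builds, per subject: an ellipsoidal head
with a bright rim ("skull"), the rim interior as the ICV, and two small
ellipsoids inside it as the bilateral target. Intensities are
`structure × gain + offset + N(0, noise_sd)` with per-subject gain and
offset; a group effect shrinks the target semi-axes isotropically by
$(1-e)^{1/3}$ in patients (volume reduction $e$), leaving the ICV
untouched — an atrophy model matched to the normalization logic. Ellipsoids
rather than anatomy, because every downstream stage only needs compact
structures with contrast, and ellipsoids have closed-form volumes to test
against.

Defaults (chosen once as the package's study conditions): 16 slices of
64×64 at 2.5 × 2.5 × 6 mm; head semi-axes (65, 75, 42) mm; rim 5 mm;
target semi-axes (8, 10, 12) mm at ±12 mm lateral offset; intensities
10/90/190/230 (background/ICV/target/rim) in 8-bit-compatible units; noise
SD 5; subject gain SD 0.05 and offset SD 5. These give an ICV of ~0.65 l
and a target of ~210 voxels — large enough that discretization error stays
within a few percent, small enough that a full train-and-evaluate cycle
runs in minutes on one CPU. Masks are voxel-center-in-ellipsoid tests; the
discrete ICV volume is within 5% of the analytic value at the default grid
and converges as the grid is refined (both asserted in the tests). Two
options exist purely to exercise downstream stages: a sex-linked ICV
enlargement (+10% male head volume) for the sex-stratified QC rule, and an
allometric-target mode (target volume proportional to ICV) for the
normalization property. Sex is otherwise independent of all volumes.

What the phantom does *not* emulate: MRI physics (bias fields, partial
volume, k-space artifacts), anatomical shape variability, or
between-subject size variation beyond the optional sex effect. Passing
tests therefore demonstrate that the pipeline's machinery is correct and
that its statistics recover a known injected effect under controlled
conditions — they do not certify segmentation accuracy on clinical data.

## Problem sizes used by the tests and the acceptance script

Chosen to exercise every stage meaningfully while keeping a full run in the
minutes range on a single CPU:

* Unit tests of the training machinery run on a coarse 16×16×8 phantom.
* The end-to-end smoke training uses 12 subjects at 64×64×16 (8
  cross-validation subjects in 2 folds + 4 test subjects), learning rate
  $10^{-3}$, at most 12 epochs, patience 6, 8 base channels. The higher
  learning rate and smaller epoch cap relative to the clinical defaults
  match the much smaller problem; the clinical-scale defaults remain
  $10^{-4}$/25/10.
* Parameter recovery runs the full pipeline (normalize → ensemble predict →
  quantify → ICV-normalize → t-test) on ten 20/20-subject cohorts with a
  10% injected atrophy and ten null cohorts, reusing the cached fold
  models.

## Known limitations

* The encoder–decoder is intentionally small; clinical-scale 512×512
  training is supported by the code path but not by the desk-scale testing
  budget, and no pretrained weights ship with the package.
* HD95 on very large dense masks computes a chunked distance matrix between
  boundary sets; for full-resolution ICV masks this is memory-bounded but
  slower than a distance-transform approach.
* The cohort normalization assumes the inference cohort's intensity regime
  matches the training cohort's; a scanner change invalidates the frozen
  statistics.
* `group_compare()` performs a single comparison; no multiple-testing
  correction is applied or needed in this workflow.
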