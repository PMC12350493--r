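# segvol

Automated segmentation and volumetry of small brain structures from MRI
slice stacks, with the hypothalamus and the intracranial volume (ICV) as the
two built-in tasks.

The hypothalamus is a small diencephalic structure (roughly 0.7–0.9 cm³)
whose volume is of interest in neurodegenerative disease, but it is tedious
to delineate by hand and small enough that raw volumes are dominated by head
size. `segvol` implements the full quantification workflow around an
encoder–decoder segmentation network:

1. **Cohort z-score intensity normalization.** Every voxel `v` is mapped to
   `(v − μ) / σ`, where `μ` and `σ` are the mean and sample standard
   deviation of the *per-subject mean* intensities across the training
   cohort. The parameters are frozen after training and reused at inference.
2. **Subject-level K-fold training** of a configurable U-Net-style
   encoder–decoder (2 classes, softmax output) with the combined loss
   `L = CE + (1 − J)`, where CE is the mean per-pixel categorical
   cross-entropy and `J` the class-averaged soft Jaccard index
   `Σ(p·t) / (Σp + Σt − Σ(p·t) + ε)`. Optimization is Adam
   (default learning rate 10⁻⁴, batch size 4, at most 25 epochs, early
   stopping after 10 stale epochs on the validation loss).
3. **Validation-IoU-weighted ensembling.** Fold `i` gets the fixed convex
   weight `wᵢ = IoUᵢ / Σⱼ IoUⱼ`; ensemble probability maps are the weighted
   average of the per-fold maps, binarized at 0.5 (ties to foreground).
4. **Evaluation metrics**: Dice `2TP/(2TP+FP+FN)`, the 95th-percentile
   Hausdorff distance in millimetres (boundary voxels, anisotropic voxel
   spacing, `HD95 = max{h95(A,B), h95(B,A)}`), and volume similarity
   `VS = 1 − ||A|−|B|| / (|A|+|B|)`.
5. **Volumetry**: positive-voxel counting, `volume = count · dx·dy·dz`
   (hypothalamus preset 0.125 × 0.125 × 0.5 mm → 0.0078125 mm³/voxel; ICV
   preset 0.5³ mm → 0.125 mm³/voxel), and ICV normalization
   `V_norm = V_hyp · ICV_ref / ICV_subject` with the post-QC cohort mean ICV
   as the default reference.
6. **Quality control and statistics**: sex-stratified flagging of records
   deviating by more than 2 SD from their stratum mean, ingestion of
   manually corrected masks with an audit log, median/IQR/mean/SD summaries,
   and an unpaired pooled-variance Student's t-test for group comparison.

Because no patient data ship with the package, a synthetic head-phantom
generator (`phantom_spec()`, `generate_cohort()`) produces slice stacks with
analytically known ground truth — an ellipsoidal head with a bright rim, an
interior ICV region and a small bilateral target — so the entire pipeline is
testable end to end.

## Worked example

```r
library(segvol)

# a 24-subject phantom cohort: 10% hypothalamic atrophy in the patients,
# plus a +10% male ICV shift (so head size varies across subjects)
spec <- phantom_spec(group_effect = 0.10, sex_icv_shift = 0.10, seed = 42)
cohort <- generate_cohort(spec, n_control = 12, n_patient = 12)

# volumetry on the ground-truth masks (predicted masks work the same way)
hyp <- vapply(cohort$target_masks, function(m) mask_volume(m)$volume_mm3, numeric(1))
icv <- vapply(cohort$icv_masks, function(m) mask_volume(m, "icv")$volume_ml, numeric(1))

# sex-stratified 2-SD quality control on the ICV
qc <- flag_outliers(cbind(cohort$metadata, icv_ml = icv), "icv_ml")
cat(sprintf("QC: %d of %d subjects flagged\n", sum(qc$flagged), nrow(qc)))

# ICV normalization, descriptive summaries, group comparison
norm <- normalize_hypothalamic_volume(hyp, icv, reference_icv_ml = mean(icv))
grp <- cohort$metadata$group
print(cohort_summary(norm[grp == "control"]))
print(cohort_summary(norm[grp == "patient"]))
res <- group_compare(norm[grp == "control"], norm[grp == "patient"])
cat(sprintf("unpaired t: t = %.2f, df = %d, p = %.2g\n", res$t, res$df, res$p))
```

prints

```
QC: 0 of 24 subjects flagged
n = 12, median 7992 (IQR 859.8), mean 8279 +/- 423.4
n = 12, median 7903 (IQR 767.7), mean 7648 +/- 378
unpaired t: t = 3.85, df = 22, p = 0.00086
```

The normalized volumes of the two groups differ by about 8% (the injected
10% atrophy, attenuated by voxel discretization), the within-group spread
comes from the sex-linked head-size variation that ICV normalization cannot
remove perfectly at this grid resolution, and the t-test recovers the group
difference. Training and prediction follow the same pattern
(`make_folds()`, `train_fold()`, `compute_weights()`, `ensemble_predict()`);
see the methods vignette (`vignettes/segvol-methods.Rmd`) for the model
details and the choice of every default.

## Command line

A thin CLI over the same functions lives at `inst/cli/segvol.R`:

```sh
Rscript inst/cli/segvol.R simulate --out data/ --n-control 6 --n-patient 6
Rscript inst/cli/segvol.R train --in data/ --out models/hyp --task hypothalamus --folds 2
Rscript inst/cli/segvol.R train --in data/ --out models/icv --task icv --folds 2
Rscript inst/cli/segvol.R run --in data/images --out results/ \
    --models-hyp models/hyp --models-icv models/icv --meta data/metadata.csv
Rscript inst/cli/segvol.R qc --volumes results/volumes.csv --meta data/metadata.csv --out qc.csv
```

Exit codes: 0 ok, 2 configuration error, 3 data-contract error, 4 runtime
failure.

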