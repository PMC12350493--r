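# Shared phantom configurations and a one-time training cache so that the
# end-to-end blocks (smoke training, parameter recovery) train the fold
# models once per test run.

# Coarse 16 x 16 x 8 phantom for fast unit tests of the training machinery.
tiny_spec <- function(...) {
  phantom_spec(geometry = voxel_geometry(10, 10, 12, n_slices = 8L,
                                         matrix = c(16L, 16L)),
               head_semi_axes = c(65, 70, 40), rim_mm = 10,
               target_semi_axes = c(12, 14, 16), target_offset_mm = 16,
               ...)
}

tiny_config <- function(max_epochs = 3L, patience = min(2L, max_epochs),
                        seed = 2L, learning_rate = 1e-3, ...) {
  net_config(input_size = c(16L, 16L), base_channels = 4L,
             encoder_depth = 2L, learning_rate = learning_rate,
             max_epochs = max_epochs, patience = patience, seed = seed, ...)
}

# A trained_fold whose parameters are all zero: every logit is 0, so the
# softmax foreground probability is exactly 0.5 at every pixel (useful to
# test the tie-to-foreground binarization rule).
zero_fold <- function(geometry, base_channels = 4L) {
  cfg <- net_config(input_size = geometry$matrix,
                    base_channels = base_channels, encoder_depth = 2L,
                    learning_rate = 1e-3, seed = 1L)
  params <- segvol:::unet_init(cfg)
  params <- rapply(params, function(x) x * 0, classes = c("numeric", "matrix", "array"),
                   how = "replace")
  structure(list(fold_index = 1L, params = params, config = cfg,
                 val_iou = 0.5, history = NULL),
            class = "trained_fold")
}

# --- one-time training cache for the acceptance-style end-to-end checks ---

.acceptance_cache <- new.env(parent = emptyenv())

# Trains, once per test run: two hypothalamus folds and one ICV model on a
# 12-subject phantom cohort (8 cross-validation + 4 held-out test subjects)
# at 64 x 64 x 16, and evaluates per-fold and ensemble Dice on the test set.
acceptance_models <- function() {
  if (!is.null(.acceptance_cache$models)) return(.acceptance_cache$models)
  spec <- phantom_spec(seed = 101L)
  cohort <- generate_cohort(spec, 6, 6)
  ids <- cohort$metadata$subject_id
  test_ids <- ids[c(3L, 6L, 9L, 12L)]
  split <- make_folds(ids, k = 2, seed = 11L, test_ids = test_ids)
  cstats <- compute_cohort_stats(cohort$stacks[!(ids %in% test_ids)])
  norm <- lapply(cohort$stacks, zscore_normalize, stats = cstats)
  cfg <- net_config(input_size = c(64L, 64L), learning_rate = 1e-3,
                    max_epochs = 12L, patience = 6L, seed = 7L)

  hyp_folds <- lapply(1:2, function(f) {
    val_ids <- names(split$assignments)[split$assignments == f]
    tr <- which(!(ids %in% c(val_ids, test_ids)))
    va <- which(ids %in% val_ids)
    train_fold(norm[tr], cohort$target_masks[tr], norm[va],
               cohort$target_masks[va], config = cfg, fold_index = f)
  })
  # single-validation ICV model: 7 train / 1 validation subject
  cv_idx <- which(!(ids %in% test_ids))
  icv_fold <- train_fold(norm[cv_idx[-1]], cohort$icv_masks[cv_idx[-1]],
                         norm[cv_idx[1]], cohort$icv_masks[cv_idx[1]],
                         config = cfg, fold_index = 1L)

  weights <- compute_weights(vapply(hyp_folds, `[[`, numeric(1), "val_iou"))
  te <- which(ids %in% test_ids)
  fold_dice <- vapply(hyp_folds, function(fold) {
    mean(vapply(te, function(i) {
      pr <- predict_stack(fold, norm[[i]])
      m <- mask_stack(ids[i], lapply(pr, function(p) (p >= 0.5) + 0),
                      spec$geometry, "predicted")
      dice(m, cohort$target_masks[[i]])
    }, numeric(1)))
  }, numeric(1))
  ens_dice <- mean(vapply(te, function(i) {
    pr <- ensemble_predict(hyp_folds, weights, norm[[i]])
    dice(pr$mask, cohort$target_masks[[i]])
  }, numeric(1)))

  .acceptance_cache$models <- list(
    spec = spec, cstats = cstats, cfg = cfg,
    hyp_folds = hyp_folds, icv_fold = icv_fold, weights = weights,
    fold_dice = fold_dice, ensemble_dice = ens_dice)
  .acceptance_cache$models
}

# Full pipeline on a fresh 20/20 cohort with the cached models: returns the
# two-sided p-value of the normalized-volume group comparison.
recovery_pvalue <- function(models, group_effect, seed) {
  spec <- phantom_spec(group_effect = group_effect, seed = seed)
  cohort <- generate_cohort(spec, 20, 20)
  norm <- lapply(cohort$stacks, zscore_normalize, stats = models$cstats)
  g <- spec$geometry
  hyp_mm3 <- icv_ml <- numeric(length(norm))
  for (i in seq_along(norm)) {
    pr <- ensemble_predict(models$hyp_folds, models$weights, norm[[i]])
    hyp_mm3[i] <- mask_volume(pr$mask)$volume_mm3
    pi_ <- predict_stack(models$icv_fold, norm[[i]])
    icv_mask <- mask_stack(norm[[i]]$subject_id,
                           lapply(pi_, function(p) (p >= 0.5) + 0),
                           g, "predicted")
    icv_ml[i] <- mask_volume(icv_mask, "icv")$volume_ml
  }
  normalized <- normalize_hypothalamic_volume(hyp_mm3, icv_ml,
                                              mean(icv_ml))
  grp <- cohort$metadata$group
  group_compare(normalized[grp == "control"],
                normalized[grp == "patient"])$p
}

# Strata with exact floating-point mean/SD arithmetic, built around 0 so
# that the extreme member sits at a chosen exact z-score:
#  - stratum_at_2sd(): {+6, -6, 0 x 7}: mean 0, sample SD exactly 3, so the
#    value 6 lies at exactly +2 SD.
#  - stratum_at_3sd(): {+9, -9, 0 x 17}: mean 0, sample SD exactly 3, so the
#    value 9 lies at exactly +3 SD.
# An additive offset shifts them to a realistic scale without breaking
# exactness concerns for the deviation test (deviations are offset-free).
stratum_at_2sd <- function() c(6, -6, rep(0, 7))
stratum_at_3sd <- function() c(9, -9, rep(0, 17))
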