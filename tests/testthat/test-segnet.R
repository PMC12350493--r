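one_hot <- function(fg) {
  d <- dim(fg)
  y <- array(0, c(d[1], d[2], 2, if (length(d) > 2) d[3] else 1))
  y[, , 1, ] <- 1 - fg
  y[, , 2, ] <- fg
  y
}

test_that("combined loss matches closed forms", {
  fg <- matrix(c(1, 1, 0, 0), 2, 2)
  target <- one_hot(array(fg, c(2, 2, 1)))

  # perfect hard prediction: loss ~ 0
  expect_lt(combined_loss(target, target), 1e-5)

  # uniform prediction: CE term is exactly ln 2
  unif <- array(0.5, dim(target))
  l <- combined_loss(unif, target)
  expect_equal(attr(l, "ce"), log(2), tolerance = 1e-12)
  # 4-pixel image, 2 fg / 2 bg: soft Jaccard per class 2*0.5/(2+2-1) = 1/3
  expect_equal(attr(l, "jaccard"), 2 / 3, tolerance = 1e-5)
  expect_equal(as.numeric(l), log(2) + 2 / 3, tolerance = 1e-5)
})

test_that("combined loss is nonnegative and zero only at the target", {
  set.seed(4)
  for (i in 1:20) {
    fg <- array(rbinom(32, 1, 0.4), c(4, 8, 1))
    target <- one_hot(fg)
    p_fg <- array(runif(32), c(4, 8, 1))
    pred <- array(0, dim(target))
    pred[, , 1, ] <- 1 - p_fg
    pred[, , 2, ] <- p_fg
    l <- as.numeric(combined_loss(pred, target))
    expect_gte(l, 0)
    if (any(abs(pred - target) > 0.05)) expect_gt(l, 1e-4)
  }
})

test_that("the loss gradient matches finite differences through the network", {
  sv <- asNamespace("segvol")
  cfg <- net_config(input_size = c(8L, 8L), base_channels = 2L, seed = 3L)
  params <- sv$unet_init(cfg)
  set.seed(42)
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 1, 2))
  target <- one_hot(array(rbinom(128, 1, 0.5), c(8, 8, 2)))
  fw <- sv$unet_fwd(params, x)
  lg <- sv$loss_and_grad(fw$logits, target)
  grads <- sv$unet_bwd(params, fw$cache, lg$dlogits)
  loss_of <- function(p)
    sv$loss_and_grad(sv$unet_fwd(p, x, keep_cache = FALSE)$logits, target)$loss
  leaves <- list(
    list(get = function(p) p$enc[[1]]$w1,
         set = function(p, v) { p$enc[[1]]$w1[] <- v; p },
         g = grads$enc[[1]]$w1),
    list(get = function(p) p$bott$w2,
         set = function(p, v) { p$bott$w2[] <- v; p },
         g = grads$bott$w2),
    list(get = function(p) p$dec[[2]]$w1,
         set = function(p, v) { p$dec[[2]]$w1[] <- v; p },
         g = grads$dec[[2]]$w1),
    list(get = function(p) p$head_w,
         set = function(p, v) { p$head_w[] <- v; p },
         g = grads$head_w))
  eps <- 1e-5
  for (leaf in leaves) {
    v0 <- leaf$get(params)
    for (i in sample(length(v0), 3)) {
      v <- v0; v[i] <- v[i] + eps
      f1 <- loss_of(leaf$set(params, v))
      v <- v0; v[i] <- v[i] - eps
      f0 <- loss_of(leaf$set(params, v))
      num <- (f1 - f0) / (2 * eps)
      expect_equal(num, leaf$g[i], tolerance = 1e-4)
    }
  }
})

test_that("mean IoU averages the two class IoUs with the both-empty rule", {
  g <- voxel_geometry(1, 1, 1, 1L, c(10L, 10L))
  a <- array(0, c(10, 10, 1))
  expect_equal(mean_iou(a, a), 1)          # both empty: fg class scores 1

  # TP=2 FP=1 FN=1 on 100 pixels: fg 2/4, bg 96/98
  pred <- a; tgt <- a
  pred[1, 1:3, 1] <- 1
  tgt[1, c(1, 2, 4), 1] <- 1
  expect_equal(mean_iou(pred, tgt), (2 / 4 + 96 / 98) / 2, tolerance = 1e-12)

  # complement masks: both class IoUs are 0
  expect_equal(mean_iou(a + 1, a), 0)

  # symmetry and slice-permutation invariance
  set.seed(5)
  p3 <- array(rbinom(300, 1, 0.3), c(10, 10, 3))
  t3 <- array(rbinom(300, 1, 0.3), c(10, 10, 3))
  expect_equal(mean_iou(p3, t3), mean_iou(t3, p3))
  perm <- c(3, 1, 2)
  expect_equal(mean_iou(p3[, , perm], t3[, , perm]), mean_iou(p3, t3))
})

test_that("fold splitting is by subject, balanced, deterministic and test-excluding", {
  ids <- sprintf("s%03d", 1:105)
  test_ids <- ids[1:30]
  sp <- make_folds(ids, k = 5, seed = 9, test_ids = test_ids)
  expect_equal(as.integer(table(sp$assignments)), rep(15L, 5))   # 75 / 5
  expect_false(any(test_ids %in% names(sp$assignments)))
  sp2 <- make_folds(ids, k = 5, seed = 9, test_ids = test_ids)
  expect_identical(sp$assignments, sp2$assignments)
  sp3 <- make_folds(ids, k = 5, seed = 10, test_ids = test_ids)
  expect_false(identical(sp$assignments, sp3$assignments))

  expect_error(make_folds(ids, k = 5, test_ids = c("nope")), "subset")
  expect_error(make_folds(ids[1:4], k = 5), ">= 2|at least")
})

test_that("training improves on the phantom and is reproducible", {
  spec <- tiny_spec()
  cohort <- generate_cohort(spec, 4, 0)
  cstats <- compute_cohort_stats(cohort$stacks)
  norm <- lapply(cohort$stacks, zscore_normalize, stats = cstats)
  cfg <- tiny_config()
  fold <- train_fold(norm[1:3], cohort$target_masks[1:3], norm[4],
                     cohort$target_masks[4], cfg)
  expect_s3_class(fold, "trained_fold")
  expect_lte(nrow(fold$history), cfg$max_epochs)
  expect_true(fold$val_iou >= 0 && fold$val_iou <= 1)

  # same config: identical history; the frozen-optimizer run is a baseline
  fold2 <- train_fold(norm[1:3], cohort$target_masks[1:3], norm[4],
                      cohort$target_masks[4], cfg)
  expect_identical(fold$history, fold2$history)
  frozen <- train_fold(norm[1:3], cohort$target_masks[1:3], norm[4],
                       cohort$target_masks[4],
                       tiny_config(learning_rate = 1e-12))
  expect_lt(min(fold$history$val_loss), min(frozen$history$val_loss))

  expect_error(train_fold(list(), list(), norm[4],
                          cohort$target_masks[4], cfg), "empty")
})

test_that("early stopping halts after `patience` stale epochs", {
  spec <- tiny_spec()
  cohort <- generate_cohort(spec, 3, 0)
  cstats <- compute_cohort_stats(cohort$stacks)
  norm <- lapply(cohort$stacks, zscore_normalize, stats = cstats)
  # a vanishing learning rate never improves the validation loss, so
  # training stops right after the first stale epoch
  cfg <- tiny_config(learning_rate = 1e-13, max_epochs = 10L, patience = 1L)
  fold <- train_fold(norm[1:2], cohort$target_masks[1:2], norm[3],
                     cohort$target_masks[3], cfg)
  expect_lte(nrow(fold$history), 2L)
})

test_that("prediction yields one bounded, deterministic map per slice", {
  spec <- tiny_spec()
  s <- generate_subject(spec, "A", "control", seed = 2)
  cstats <- structure(list(mu_of_means = 40, sd_of_means = 5,
                           n_subjects = 2L), class = "cohort_stats")
  norm <- zscore_normalize(s$stack, cstats)
  cohort <- generate_cohort(spec, 3, 0)
  nrm <- lapply(cohort$stacks, zscore_normalize, stats = cstats)
  fold <- train_fold(nrm[1:2], cohort$target_masks[1:2], nrm[3],
                     cohort$target_masks[3], tiny_config(max_epochs = 1L))
  p1 <- predict_stack(fold, norm)
  expect_length(p1, spec$geometry$n_slices)
  expect_true(all(vapply(p1, function(m) all(m >= 0 & m <= 1), logical(1))))
  p2 <- predict_stack(fold, norm)
  expect_identical(p1, p2)
})
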