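#' Network / training configuration
#'
#' Defaults follow the training recipe used throughout the package: Adam at
#' learning rate 1e-4, batches of 4 slices, at most 25 epochs with early
#' stopping once the validation loss has not improved for 10 consecutive
#' epochs. The backbone is a plain U-Net-style encoder-decoder whose depth
#' (number of 2x down-sampling stages) and width (channels of the first
#' stage) are configurable.
#'
#' @param input_size `c(rows, cols)` of the slices; both must be divisible by
#'   `2^encoder_depth`.
#' @param n_classes Number of classes (2: background/foreground).
#' @param encoder_depth Number of down-sampling stages.
#' @param base_channels Channels in the first encoder stage.
#' @param batch_size Slices per optimizer step.
#' @param max_epochs Hard cap on training epochs.
#' @param patience Early-stopping patience in epochs (<= `max_epochs`).
#' @param learning_rate Adam learning rate (> 0).
#' @param seed Integer seed controlling weight initialization and per-epoch
#'   slice shuffling.
#' @return A `net_config` object (named list).
#' @export
net_config <- function(input_size = c(64L, 64L), n_classes = 2L,
                       encoder_depth = 2L, base_channels = 8L,
                       batch_size = 4L, max_epochs = 25L, patience = 10L,
                       learning_rate = 1e-4, seed = 1L) {
  if (n_classes < 2L) stop("n_classes must be >= 2", call. = FALSE)
  if (patience > max_epochs)
    stop("patience must not exceed max_epochs", call. = FALSE)
  if (learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  if (any(input_size %% 2^encoder_depth != 0))
    stop("input_size must be divisible by 2^encoder_depth", call. = FALSE)
  structure(list(input_size = as.integer(input_size),
                 n_classes = as.integer(n_classes),
                 encoder_depth = as.integer(encoder_depth),
                 base_channels = as.integer(base_channels),
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 learning_rate = learning_rate,
                 seed = as.integer(seed)),
            class = "net_config")
}

#' Subject-level K-fold split with a fixed held-out test set
#'
#' Splits subjects (not slices) into `k` cross-validation folds so that all
#' slices of a subject share one fold, after removing a fixed test set that
#' never enters any fold. Fold sizes differ by at most one.
#'
#' @param subject_ids Character vector of all subject ids.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed; the split is deterministic given the seed.
#' @param test_ids Subjects held out from all folds (may be empty).
#' @return A `fold_split`: list with `k`, `assignments` (named integer vector
#'   mapping non-test subject to fold 1..k), and `test_ids`.
#' @export
make_folds <- function(subject_ids, k, seed = 1L, test_ids = character(0)) {
  if (!all(test_ids %in% subject_ids))
    stop("test_ids must be a subset of subject_ids", call. = FALSE)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  pool <- setdiff(subject_ids, test_ids)
  if (length(pool) < k)
    stop("need at least k non-test subjects", call. = FALSE)
  shuffled <- with_seed(seed, sample(sort(pool)))
  assignments <- stats::setNames(rep_len(seq_len(k), length(shuffled)),
                                 shuffled)
  structure(list(k = as.integer(k), assignments = assignments,
                 test_ids = test_ids),
            class = "fold_split")
}

#' Combined categorical cross-entropy + soft-Jaccard loss
#'
#' The training loss: mean per-pixel categorical cross-entropy plus
#' `1 - soft-Jaccard`, where the soft Jaccard index for class c is
#' `sum(p*t) / (sum(p) + sum(t) - sum(p*t) + eps)` over all pixels of the
#' tensor, averaged over classes. Zero (up to `eps`) iff the prediction
#' equals the target exactly.
#'
#' @param pred_probs Array of class probabilities, dim `(H, W, C)` or
#'   `(H, W, C, B)`, class on the third dimension, summing to 1 per pixel.
#' @param target One-hot target of the same shape.
#' @param eps Soft-Jaccard smoothing constant.
#' @return Scalar loss (>= 0), with attributes `ce` and `jaccard` holding the
#'   two terms.
#' @export
combined_loss <- function(pred_probs, target, eps = 1e-6) {
  if (!identical(dim(pred_probs), dim(target)))
    stop("pred_probs and target shapes differ", call. = FALSE)
  d <- dim(pred_probs)
  if (length(d) == 3L) {
    dim(pred_probs) <- c(d, 1L)
    dim(target) <- c(d, 1L)
    d <- dim(pred_probs)
  }
  n_classes <- d[3]
  n_pix <- d[1] * d[2] * d[4]
  ce <- -sum(target * log(pmax(pred_probs, 1e-12))) / n_pix
  jacc <- 0
  for (c in seq_len(n_classes)) {
    p <- pred_probs[, , c, , drop = FALSE]
    t <- target[, , c, , drop = FALSE]
    inter <- sum(p * t)
    jacc <- jacc + inter / (sum(p) + sum(t) - inter + eps)
  }
  loss <- ce + (1 - jacc / n_classes)
  attr(loss, "ce") <- ce
  attr(loss, "jaccard") <- 1 - jacc / n_classes
  loss
}

# Softmax over the class dimension of a logits array (H, W, C, B),
# vectorized over pixels (no apply: the class count is small).
softmax4 <- function(z) {
  d <- dim(z)
  zmax <- z[, , 1L, , drop = FALSE]
  for (c in seq_len(d[3])[-1])
    zmax <- pmax(zmax, z[, , c, , drop = FALSE])
  e <- array(0, d)
  s <- array(0, dim(zmax))
  for (c in seq_len(d[3])) {
    e[, , c, ] <- exp(z[, , c, , drop = FALSE] - zmax)
    s <- s + e[, , c, , drop = FALSE]
  }
  for (c in seq_len(d[3])) e[, , c, ] <- e[, , c, , drop = FALSE] / s
  e
}

# Loss + gradient w.r.t. logits for training. target is one-hot (H, W, C, B).
loss_and_grad <- function(logits, target, eps = 1e-6) {
  p <- softmax4(logits)
  d <- dim(p)
  n_classes <- d[3]
  n_pix <- d[1] * d[2] * d[4]
  ce <- -sum(target * log(pmax(p, 1e-12))) / n_pix
  # d(CE)/d(logits) via softmax identity
  dlogits <- (p - target) / n_pix
  jacc <- 0
  dLdp <- array(0, d)
  for (c in seq_len(n_classes)) {
    pc <- p[, , c, , drop = FALSE]
    tc <- target[, , c, , drop = FALSE]
    inter <- sum(pc * tc)
    union <- sum(pc) + sum(tc) - inter + eps
    jacc <- jacc + inter / union
    # dJ/dp = (t*U - I*(1-t)) / U^2 ; loss term is -J/n_classes
    dLdp[, , c, ] <- -(tc * union - inter * (1 - tc)) / union^2 / n_classes
  }
  # chain rule through softmax for the Jaccard part
  inner <- array(0, c(d[1], d[2], 1L, d[4]))
  for (c in seq_len(n_classes))
    inner <- inner + dLdp[, , c, , drop = FALSE] * p[, , c, , drop = FALSE]
  dj <- array(0, d)
  for (c in seq_len(n_classes))
    dj[, , c, ] <- p[, , c, , drop = FALSE] *
      (dLdp[, , c, , drop = FALSE] - inner)
  dlogits <- dlogits + dj
  loss <- ce + (1 - jacc / n_classes)
  list(loss = as.numeric(loss), ce = ce,
       jaccard = 1 - jacc / n_classes, dlogits = dlogits, probs = p)
}

#' Mean intersection-over-union of two binary masks
#'
#' Per-class IoU `TP / (TP + FP + FN)` for foreground and background,
#' averaged over the two classes. A class that is empty in both masks
#' contributes IoU 1.
#'
#' @param pred,target [mask_stack()]s (or 3D binary arrays) with matching
#'   shapes.
#' @return Mean IoU in `[0, 1]`.
#' @export
mean_iou <- function(pred, target) {
  a <- if (inherits(pred, "mask_stack")) stack_array(pred) else pred
  b <- if (inherits(target, "mask_stack")) stack_array(target) else target
  if (!identical(dim(a), dim(b)))
    stop("mask shapes differ", call. = FALSE)
  ious <- vapply(c(1, 0), function(cls) {
    pa <- a == cls
    pb <- b == cls
    tp <- sum(pa & pb)
    denom <- sum(pa | pb)
    if (denom == 0) 1 else tp / denom
  }, numeric(1))
  mean(ious)
}

# Assemble all slices of a list of stacks into (H, W, 1, N) plus one-hot
# labels (H, W, 2, N) and a subject index per slice.
assemble_slices <- function(stacks, masks) {
  g <- stacks[[1]]$geometry
  n <- sum(vapply(stacks, function(s) length(s$slices), integer(1)))
  x <- array(0, c(g$matrix[1], g$matrix[2], 1L, n))
  y <- array(0, c(g$matrix[1], g$matrix[2], 2L, n))
  subj <- integer(n)
  i <- 0L
  for (s in seq_along(stacks)) {
    for (k in seq_along(stacks[[s]]$slices)) {
      i <- i + 1L
      x[, , 1L, i] <- stacks[[s]]$slices[[k]]
      fg <- masks[[s]]$slices[[k]]
      y[, , 1L, i] <- 1 - fg   # class 1 = background
      y[, , 2L, i] <- fg       # class 2 = foreground
      subj[i] <- s
    }
  }
  list(x = x, y = y, subject = subj, geometry = g)
}

#' Train one cross-validation fold
#'
#' Trains the encoder-decoder with Adam on the combined cross-entropy +
#' soft-Jaccard loss. After each epoch the validation loss and validation
#' mean IoU (on argmax-binarized predictions, averaged over validation
#' subjects) are recorded. Training stops at `max_epochs` or once the
#' validation loss has not improved (by at least 1e-6 below the best value so
#' far) for `patience` consecutive epochs; the parameters returned are those
#' of the best-validation-loss epoch.
#'
#' @param train_stacks,train_masks Normalized training [slice_stack()]s and
#'   aligned ground-truth [mask_stack()]s.
#' @param val_stacks,val_masks Validation subjects.
#' @param config A [net_config()].
#' @param fold_index Integer label stored on the result.
#' @param verbose Print one line per epoch.
#' @return A `trained_fold`: list with `fold_index`, `params`, `config`,
#'   `val_iou`, `history` (data frame epoch/train_loss/val_loss/val_iou).
#' @export
train_fold <- function(train_stacks, train_masks, val_stacks, val_masks,
                       config = net_config(), fold_index = 1L,
                       verbose = FALSE) {
  if (length(train_stacks) == 0L)
    stop("empty training set", call. = FALSE)
  stopifnot(length(train_stacks) == length(train_masks),
            length(val_stacks) == length(val_masks))
  tr <- assemble_slices(train_stacks, train_masks)
  va <- assemble_slices(val_stacks, val_masks)
  params <- unet_init(config)
  opt <- NULL
  n <- dim(tr$x)[4]
  bs <- config$batch_size
  best <- list(loss = Inf, params = params, iou = NA_real_)
  stale <- 0L
  hist <- list()
  for (epoch in seq_len(config$max_epochs)) {
    ord <- with_seed(config$seed + 1000L * epoch, sample.int(n))
    ep_loss <- 0
    nb <- 0L
    for (start in seq.int(1L, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1L, n)]
      xb <- tr$x[, , , idx, drop = FALSE]
      yb <- tr$y[, , , idx, drop = FALSE]
      fw <- unet_fwd(params, xb)
      lg <- loss_and_grad(fw$logits, yb)
      grads <- unet_bwd(params, fw$cache, lg$dlogits)
      if (is.null(opt)) opt <- adam_init(grads)
      st <- adam_step(params, grads, opt, config$learning_rate)
      params <- st$params
      opt <- st$state
      ep_loss <- ep_loss + lg$loss
      nb <- nb + 1L
    }
    val <- evaluate_on(params, va)
    hist[[epoch]] <- data.frame(epoch = epoch, train_loss = ep_loss / nb,
                                val_loss = val$loss, val_iou = val$iou)
    if (verbose)
      message(sprintf("fold %d epoch %2d: train %.4f val %.4f iou %.4f",
                      fold_index, epoch, ep_loss / nb, val$loss, val$iou))
    if (val$loss < best$loss - 1e-6) {
      best <- list(loss = val$loss, params = params, iou = val$iou)
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= config$patience) break
    }
  }
  structure(list(fold_index = as.integer(fold_index), params = best$params,
                 config = config, val_iou = best$iou,
                 history = do.call(rbind, hist)),
            class = "trained_fold")
}

# Validation loss + subject-mean IoU for the current parameters.
evaluate_on <- function(params, data, chunk = 16L) {
  n <- dim(data$x)[4]
  loss_sum <- 0
  probs <- array(0, c(dim(data$x)[1], dim(data$x)[2], n))
  for (start in seq.int(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    fw <- unet_fwd(params, data$x[, , , idx, drop = FALSE],
                   keep_cache = FALSE)
    lg <- loss_and_grad(fw$logits, data$y[, , , idx, drop = FALSE])
    loss_sum <- loss_sum + lg$loss * length(idx)
    probs[, , idx] <- lg$probs[, , 2L, ]
  }
  ious <- vapply(unique(data$subject), function(s) {
    sel <- data$subject == s
    tgt <- data$y[, , 2L, sel, drop = FALSE]
    dim(tgt) <- c(dim(data$x)[1], dim(data$x)[2], sum(sel))
    mean_iou((probs[, , sel, drop = FALSE] >= 0.5) + 0, tgt)
  }, numeric(1))
  list(loss = loss_sum / n, iou = mean(ious))
}

#' Per-slice foreground probability maps for a stack
#'
#' Deterministic forward pass of a trained fold over every slice of a stack.
#'
#' @param fold A `trained_fold` from [train_fold()].
#' @param stack A (normalized) [slice_stack()].
#' @param chunk Slices per forward pass.
#' @return List of `rows x cols` matrices of foreground probabilities in
#'   `[0, 1]`, one per slice, in slice order.
#' @export
predict_stack <- function(fold, stack, chunk = 16L) {
  stopifnot(inherits(fold, "trained_fold"), inherits(stack, "slice_stack"))
  g <- stack$geometry
  n <- g$n_slices
  x <- array(unlist(stack$slices, use.names = FALSE),
             dim = c(g$matrix[1], g$matrix[2], 1L, n))
  out <- vector("list", n)
  for (start in seq.int(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    fw <- unet_fwd(fold$params, x[, , , idx, drop = FALSE],
                   keep_cache = FALSE)
    p <- softmax4(fw$logits)
    for (j in seq_along(idx)) out[[idx[j]]] <- p[, , 2L, j]
  }
  out
}

#' @export
print.trained_fold <- function(x, ...) {
  cat(sprintf("trained_fold %d: %d epochs, val IoU %.4f\n", x$fold_index,
              nrow(x$history), x$val_iou))
  invisible(x)
}
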