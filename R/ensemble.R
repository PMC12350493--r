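#' Ensemble weights from validation IoU scores
#'
#' Fixed convex weights proportional to each fold's validation mean IoU:
#' `w_i = IoU_i / sum(IoU)`. Weights sum to 1.
#'
#' @param val_ious Numeric vector of per-fold validation IoUs, all > 0.
#' @return An `ensemble_weights` numeric vector.
#' @export
compute_weights <- function(val_ious) {
  if (length(val_ious) == 0L) stop("no validation IoUs given", call. = FALSE)
  if (any(!is.finite(val_ious)) || any(val_ious <= 0))
    stop("degenerate fold: validation IoU must be > 0", call. = FALSE)
  structure(val_ious / sum(val_ious), class = "ensemble_weights")
}

#' Weighted-ensemble prediction for a stack
#'
#' Averages the per-fold foreground probability maps with the given convex
#' weights (probability-space averaging), then binarizes at 0.5 with ties to
#' foreground. With a single fold and weight 1 this reduces exactly to
#' [predict_stack()].
#'
#' @param folds List of `trained_fold` objects.
#' @param weights An [compute_weights()] result (or numeric vector summing
#'   to 1) of the same length.
#' @param stack A (normalized) [slice_stack()].
#' @param threshold Binarization threshold on the ensemble foreground
#'   probability (mask = 1 where probability >= threshold).
#' @return List with `probs` (list of per-slice ensemble probability
#'   matrices) and `mask` (a [mask_stack()] with provenance `"predicted"`).
#' @export
ensemble_predict <- function(folds, weights, stack, threshold = 0.5) {
  if (length(folds) != length(weights))
    stop("number of folds and weights differ", call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-12)
    stop("weights must sum to 1", call. = FALSE)
  g <- stack$geometry
  acc <- NULL
  for (i in seq_along(folds)) {
    p <- predict_stack(folds[[i]], stack)
    if (is.null(acc)) {
      acc <- lapply(p, function(m) weights[i] * m)
    } else {
      for (k in seq_along(acc)) {
        if (!identical(dim(acc[[k]]), dim(p[[k]])))
          stop("geometry mismatch across folds", call. = FALSE)
        acc[[k]] <- acc[[k]] + weights[i] * p[[k]]
      }
    }
  }
  mask <- mask_stack(stack$subject_id,
                     lapply(acc, function(m) (m >= threshold) + 0),
                     g, provenance = "predicted")
  list(probs = acc, mask = mask)
}
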