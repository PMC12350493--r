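#' Confusion counts between two binary masks
#' @param pred,target [mask_stack()]s or 3D binary arrays of matching shape.
#' @return List with `TP`, `FP`, `FN`, `TN` voxel counts.
#' @export
confusion_counts <- function(pred, target) {
  a <- as_mask_array(pred)
  b <- as_mask_array(target)
  if (!identical(dim(a), dim(b)))
    stop("mask geometries differ", call. = FALSE)
  tp <- sum(a == 1 & b == 1)
  fp <- sum(a == 1 & b == 0)
  fn <- sum(a == 0 & b == 1)
  list(TP = tp, FP = fp, FN = fn, TN = length(a) - tp - fp - fn)
}

as_mask_array <- function(x) {
  if (inherits(x, "mask_stack")) stack_array(x) else x
}

#' Dice similarity coefficient
#'
#' `2 TP / (2 TP + FP + FN)`, the overlap between predicted and ground-truth
#' segmentation. Two empty masks score 1; one empty mask scores 0.
#'
#' @inheritParams confusion_counts
#' @return Dice in `[0, 1]`.
#' @export
dice <- function(pred, target) {
  cc <- confusion_counts(pred, target)
  denom <- 2 * cc$TP + cc$FP + cc$FN
  if (denom == 0) 1 else 2 * cc$TP / denom
}

#' Volume similarity
#'
#' `VS = 1 - ||A| - |B|| / (|A| + |B|)`, equivalently
#' `1 - |FN - FP| / (2 TP + FP + FN)`: agreement of the two total volumes
#' irrespective of overlap. Two empty masks score 1.
#'
#' @inheritParams confusion_counts
#' @return VS in `[0, 1]`.
#' @export
volume_similarity <- function(pred, target) {
  cc <- confusion_counts(pred, target)
  denom <- 2 * cc$TP + cc$FP + cc$FN
  if (denom == 0) 1 else 1 - abs(cc$FN - cc$FP) / denom
}

#' 95th-percentile Hausdorff distance in millimetres
#'
#' `HD95(A, B) = max(h95(A, B), h95(B, A))` where `h95(A, B)` is the 95th
#' percentile (linear interpolation between order statistics) of the minimum
#' Euclidean distances from points of A to points of B. Point sets are the
#' boundary voxels of each mask (mask voxels with at least one
#' face-neighbour outside the mask, the stack treated as a 3D grid), with
#' voxel centers scaled by the anisotropic spacings `(dy, dx, dz)` along
#' (rows, cols, slices) before measuring distances. Set `points = "all"` to
#' use every mask voxel instead of the boundary.
#'
#' @inheritParams confusion_counts
#' @param geometry A [voxel_geometry()]; defaults to the geometry carried by
#'   `pred` when it is a [mask_stack()].
#' @param percentile Percentile of the directed distance distribution
#'   (default 95).
#' @param points `"boundary"` (default) or `"all"`.
#' @return Distance in mm, or `NA` with a warning when either mask is empty
#'   (undefined metric). Identical masks give 0.
#' @export
hd95 <- function(pred, target, geometry = NULL, percentile = 95,
                 points = c("boundary", "all")) {
  points <- match.arg(points)
  if (is.null(geometry) && inherits(pred, "mask_stack"))
    geometry <- pred$geometry
  if (is.null(geometry))
    stop("geometry required when masks are plain arrays", call. = FALSE)
  a <- as_mask_array(pred)
  b <- as_mask_array(target)
  if (!identical(dim(a), dim(b)))
    stop("mask geometries differ", call. = FALSE)
  if (sum(a) == 0 || sum(b) == 0) {
    warning("hd95 undefined: at least one mask is empty", call. = FALSE)
    return(NA_real_)
  }
  pa <- mask_points_mm(a, geometry, points)
  pb <- mask_points_mm(b, geometry, points)
  max(directed_percentile_dist(pa, pb, percentile / 100),
      directed_percentile_dist(pb, pa, percentile / 100))
}

# Coordinates (mm) of the mask's point set; rows scaled by dy, cols by dx,
# slices by dz.
mask_points_mm <- function(arr, geometry, points = "boundary") {
  sel <- if (points == "boundary") boundary_voxels(arr) else arr == 1
  idx <- which(sel, arr.ind = TRUE)
  cbind(idx[, 1] * geometry$dy, idx[, 2] * geometry$dx,
        idx[, 3] * geometry$dz)
}

# Mask voxels with >= 1 face neighbour (6-connectivity) outside the mask;
# the grid border counts as outside.
boundary_voxels <- function(arr) {
  d <- dim(arr)
  m <- arr == 1
  interior <- array(TRUE, d)
  shift_ok <- function(axis, by) {
    out <- array(FALSE, d)
    if (axis == 1L) {
      if (by == 1L) out[seq_len(d[1] - 1L), , ] <- m[2:d[1], , ]
      else out[2:d[1], , ] <- m[seq_len(d[1] - 1L), , ]
    } else if (axis == 2L) {
      if (by == 1L) out[, seq_len(d[2] - 1L), ] <- m[, 2:d[2], ]
      else out[, 2:d[2], ] <- m[, seq_len(d[2] - 1L), ]
    } else {
      if (by == 1L) out[, , seq_len(d[3] - 1L)] <- m[, , 2:d[3]]
      else out[, , 2:d[3]] <- m[, , seq_len(d[3] - 1L)]
    }
    out
  }
  for (axis in 1:3) for (by in c(1L, -1L))
    interior <- interior & shift_ok(axis, by)
  m & !interior
}

# 95th-percentile (type-7 linear interpolation) of minimum distances from
# each row of `from` to the point set `to`. Chunked so the distance matrix
# never exceeds ~chunk x nrow(to).
directed_percentile_dist <- function(from, to, prob, chunk = 512L) {
  nf <- nrow(from)
  to_sq <- rowSums(to^2)
  mins <- numeric(nf)
  for (start in seq.int(1L, nf, by = chunk)) {
    idx <- start:min(start + chunk - 1L, nf)
    fr <- from[idx, , drop = FALSE]
    d2 <- outer(rowSums(fr^2), to_sq, "+") - 2 * tcrossprod(fr, to)
    mins[idx] <- sqrt(pmax(apply(d2, 1L, min), 0))
  }
  as.numeric(stats::quantile(mins, prob, type = 7, names = FALSE))
}

#' Full metrics report for one prediction
#'
#' @inheritParams hd95
#' @return List with `dice`, `hd95` (mm, `NA` when undefined), `vs`,
#'   `pred_volume` and `gt_volume` (mm^3).
#' @export
metrics_report <- function(pred, target, geometry = NULL) {
  if (is.null(geometry) && inherits(pred, "mask_stack"))
    geometry <- pred$geometry
  vv <- voxel_volume(geometry)
  a <- as_mask_array(pred)
  b <- as_mask_array(target)
  h <- if (sum(a) == 0 || sum(b) == 0) NA_real_ else
    hd95(a, b, geometry = geometry)
  list(dice = dice(a, b), hd95 = h, vs = volume_similarity(a, b),
       pred_volume = sum(a) * vv, gt_volume = sum(b) * vv)
}

#' Per-model / ensemble evaluation table
#'
#' Evaluates each fold's predictions and the ensemble's against ground truth,
#' stratified by clinical group: mean and SD of predicted volume (mm^3),
#' Dice, HD95 (mm) and volume similarity, plus a paired two-sided t-test
#' p-value of predicted vs ground-truth volumes per row. Row order is fold
#' 1..k followed by `"ensemble"`.
#'
#' @param predictions Named list: one entry per model (e.g. `fold1` ..
#'   `foldk`, `ensemble`), each a list of predicted [mask_stack()]s indexed
#'   like `gt_masks`.
#' @param gt_masks List of ground-truth [mask_stack()]s.
#' @param groups Character vector of group labels, one per subject (a single
#'   common label gives an unstratified table).
#' @return Data frame with columns `model`, `group`, `n`, `volume_mean`,
#'   `volume_sd`, `gt_volume_mean`, `gt_volume_sd`, `p_vs_gt`, `dice_mean`,
#'   `dice_sd`, `hd95_mean`, `hd95_sd`, `vs_mean`, `vs_sd`.
#' @export
evaluate_models <- function(predictions, gt_masks,
                            groups = rep("all", length(gt_masks))) {
  stopifnot(length(groups) == length(gt_masks))
  sd0 <- function(x) if (length(x) < 2L) 0 else stats::sd(x)
  rows <- list()
  for (model in names(predictions)) {
    preds <- predictions[[model]]
    reports <- lapply(seq_along(gt_masks), function(i)
      metrics_report(preds[[i]], gt_masks[[i]]))
    for (grp in unique(groups)) {
      sel <- which(groups == grp)
      pv <- vapply(reports[sel], `[[`, numeric(1), "pred_volume")
      gv <- vapply(reports[sel], `[[`, numeric(1), "gt_volume")
      dif <- pv - gv
      p_vs_gt <- if (length(sel) >= 2L && stats::sd(dif) > 0)
        stats::t.test(pv, gv, paired = TRUE)$p.value
      else if (all(dif == 0)) 1 else NA_real_
      dc <- vapply(reports[sel], `[[`, numeric(1), "dice")
      hd <- vapply(reports[sel], `[[`, numeric(1), "hd95")
      vs <- vapply(reports[sel], `[[`, numeric(1), "vs")
      rows[[length(rows) + 1L]] <- data.frame(
        model = model, group = grp, n = length(sel),
        volume_mean = mean(pv), volume_sd = sd0(pv),
        gt_volume_mean = mean(gv), gt_volume_sd = sd0(gv),
        p_vs_gt = p_vs_gt,
        dice_mean = mean(dc), dice_sd = sd0(dc),
        hd95_mean = mean(hd, na.rm = TRUE),
        hd95_sd = sd0(hd[!is.na(hd)]),
        vs_mean = mean(vs), vs_sd = sd0(vs))
    }
  }
  do.call(rbind, rows)
}
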