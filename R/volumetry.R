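#' Positive-voxel volumetry of a mask stack
#'
#' Counts foreground voxels across all slices and converts to physical
#' volume: `volume_mm3 = n_positive * dx * dy * dz` (exact), and
#' `volume_ml = volume_mm3 / 1000`.
#'
#' @param mask A [mask_stack()].
#' @param structure Label for the quantified structure,
#'   `"hypothalamus"` or `"icv"`.
#' @return A `volume_result`: list with `subject_id`, `structure`,
#'   `n_positive`, `volume_mm3`, `volume_ml`, `provenance`.
#' @examples
#' g <- voxel_geometry(0.5, 0.5, 0.5, n_slices = 2, matrix = c(8, 8))
#' m <- array_mask("s1", array(c(rep(1, 10), rep(0, 118)), c(8, 8, 2)), g)
#' mask_volume(m)$volume_mm3  # 10 * 0.125 = 1.25
#' @export
mask_volume <- function(mask, structure = c("hypothalamus", "icv")) {
  stopifnot(inherits(mask, "mask_stack"))
  structure_label <- match.arg(structure)
  n_pos <- sum(vapply(mask$slices, sum, numeric(1)))
  v <- n_pos * voxel_volume(mask$geometry)
  res <- list(subject_id = mask$subject_id, structure = structure_label,
              n_positive = n_pos, volume_mm3 = v, volume_ml = v / 1000,
              provenance = if (mask$provenance == "manual") "manual"
                           else "predicted")
  class(res) <- "volume_result"
  res
}

#' @export
print.volume_result <- function(x, ...) {
  cat(sprintf("%s %s: %d voxels, %.3f mm^3 (%.4f ml) [%s]\n", x$subject_id,
              x$structure, x$n_positive, x$volume_mm3, x$volume_ml,
              x$provenance))
  invisible(x)
}

#' ICV-normalized hypothalamic volume
#'
#' Rescales the hypothalamic volume by the ratio of a reference intracranial
#' volume to the subject's ICV, removing head-size (allometric) effects while
#' keeping the result in mm^3:
#' `normalized = hyp_volume_mm3 * reference_icv_ml / subject_icv_ml`.
#' The reference defaults to the analyzed cohort's mean ICV after quality
#' control.
#'
#' @param hyp A `volume_result` for the hypothalamus (or its `volume_mm3`).
#' @param icv A `volume_result` for the ICV (or its `volume_ml`), > 0.
#' @param reference_icv_ml Reference ICV in ml, > 0.
#' @return Normalized hypothalamic volume in mm^3.
#' @export
normalize_hypothalamic_volume <- function(hyp, icv, reference_icv_ml) {
  hyp_mm3 <- if (inherits(hyp, "volume_result")) hyp$volume_mm3 else hyp
  icv_ml <- if (inherits(icv, "volume_result")) icv$volume_ml else icv
  if (any(!is.finite(icv_ml)) || any(icv_ml <= 0))
    stop("subject ICV must be positive", call. = FALSE)
  if (any(!is.finite(reference_icv_ml)) || any(reference_icv_ml <= 0))
    stop("reference ICV must be positive", call. = FALSE)
  hyp_mm3 * reference_icv_ml / icv_ml
}
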