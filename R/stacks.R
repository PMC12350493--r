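#' Slice stack: ordered 2D grayscale slices for one subject
#'
#' The unit of segmentation: an ordered list of 2D intensity matrices
#' (nonnegative reals, or 8/16-bit integer values decoded from PNG) together
#' with the subject id and the voxel geometry. All slices must share the
#' geometry's matrix size and the list length must equal `geometry$n_slices`.
#'
#' @param subject_id Character scalar.
#' @param slices List of numeric matrices, ordered by increasing slice index.
#' @param geometry A [voxel_geometry()].
#' @return An object of class `slice_stack`.
#' @export
slice_stack <- function(subject_id, slices, geometry) {
  stopifnot(is.character(subject_id), length(subject_id) == 1L,
            is.list(slices), inherits(geometry, "voxel_geometry"))
  if (length(slices) != geometry$n_slices)
    stop(sprintf("subject %s: %d slices but geometry expects %d",
                 subject_id, length(slices), geometry$n_slices), call. = FALSE)
  for (i in seq_along(slices)) {
    d <- dim(slices[[i]])
    if (is.null(d) || length(d) != 2L || any(d != geometry$matrix))
      stop(sprintf("subject %s slice %d: shape does not match geometry matrix %d x %d",
                   subject_id, i - 1L, geometry$matrix[1], geometry$matrix[2]),
           call. = FALSE)
  }
  structure(list(subject_id = subject_id, slices = slices, geometry = geometry),
            class = "slice_stack")
}

#' Mask stack: binary labels aligned to a slice stack
#'
#' @param subject_id Character scalar.
#' @param slices List of binary (0/1) matrices.
#' @param geometry A [voxel_geometry()].
#' @param provenance One of `"ground_truth"`, `"predicted"`, `"manual"`.
#' @return An object of class `mask_stack`.
#' @export
mask_stack <- function(subject_id, slices, geometry,
                       provenance = c("ground_truth", "predicted", "manual")) {
  provenance <- match.arg(provenance)
  stopifnot(is.character(subject_id), length(subject_id) == 1L,
            is.list(slices), inherits(geometry, "voxel_geometry"))
  if (length(slices) != geometry$n_slices)
    stop(sprintf("mask for %s: %d slices but geometry expects %d",
                 subject_id, length(slices), geometry$n_slices), call. = FALSE)
  for (i in seq_along(slices)) {
    s <- slices[[i]]
    d <- dim(s)
    if (is.null(d) || length(d) != 2L || any(d != geometry$matrix))
      stop(sprintf("mask for %s slice %d: shape mismatch", subject_id, i - 1L),
           call. = FALSE)
    if (!all(s %in% c(0, 1)))
      stop(sprintf("mask for %s slice %d: values must be 0/1", subject_id, i - 1L),
           call. = FALSE)
    storage.mode(slices[[i]]) <- "double"
  }
  structure(list(subject_id = subject_id, slices = slices, geometry = geometry,
                 provenance = provenance),
            class = "mask_stack")
}

#' @export
print.slice_stack <- function(x, ...) {
  cat(sprintf("slice_stack '%s': %d slices of %d x %d\n", x$subject_id,
              length(x$slices), x$geometry$matrix[1], x$geometry$matrix[2]))
  invisible(x)
}

#' @export
print.mask_stack <- function(x, ...) {
  cat(sprintf("mask_stack '%s' (%s): %d slices, %d positive voxels\n",
              x$subject_id, x$provenance, length(x$slices),
              sum(vapply(x$slices, sum, numeric(1)))))
  invisible(x)
}

#' Collapse a stack's slices into a 3D array (rows, cols, slices)
#' @param x A `slice_stack` or `mask_stack`.
#' @return A 3D numeric array.
#' @export
stack_array <- function(x) {
  stopifnot(inherits(x, "slice_stack") || inherits(x, "mask_stack"))
  g <- x$geometry
  array(unlist(x$slices, use.names = FALSE),
        dim = c(g$matrix[1], g$matrix[2], g$n_slices))
}

#' Build a mask stack from a 3D binary array
#' @param subject_id Character scalar.
#' @param arr 3D array of 0/1 values, dim (rows, cols, slices).
#' @param geometry A [voxel_geometry()] matching `dim(arr)`.
#' @param provenance Mask provenance.
#' @return A [mask_stack()].
#' @export
array_mask <- function(subject_id, arr, geometry, provenance = "ground_truth") {
  stopifnot(length(dim(arr)) == 3L)
  mask_stack(subject_id,
             lapply(seq_len(dim(arr)[3]), function(k) arr[, , k]),
             geometry, provenance)
}

#' Build a slice stack from a 3D array
#' @inheritParams array_mask
#' @return A [slice_stack()].
#' @export
array_stack <- function(subject_id, arr, geometry) {
  stopifnot(length(dim(arr)) == 3L)
  slice_stack(subject_id,
              lapply(seq_len(dim(arr)[3]), function(k) arr[, , k]),
              geometry)
}
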