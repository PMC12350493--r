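#' Cohort-level intensity statistics for z-score normalization
#'
#' Computes, over the given (training) cohort, the mean and sample standard
#' deviation (n - 1 denominator) of the per-subject mean intensities; the
#' per-subject mean is taken over all voxels of the stack. These two numbers
#' drive the cohort-level z-score normalization and are estimated on the
#' training cohort only, then frozen for validation/test/inference subjects.
#'
#' @param stacks List of at least two [slice_stack()]s.
#' @param foreground_threshold Optional: when non-`NULL`, per-subject means
#'   are computed over voxels strictly above this intensity only
#'   (off by default; the default uses all voxels including background).
#' @return A `cohort_stats`: list with `mu_of_means`, `sd_of_means`,
#'   `n_subjects`.
#' @export
compute_cohort_stats <- function(stacks, foreground_threshold = NULL) {
  if (length(stacks) < 2L)
    stop("insufficient cohort: need >= 2 stacks for a finite z-score",
         call. = FALSE)
  means <- vapply(stacks, function(s) {
    v <- unlist(s$slices, use.names = FALSE)
    if (!is.null(foreground_threshold)) v <- v[v > foreground_threshold]
    mean(v)
  }, numeric(1))
  sd_m <- stats::sd(means)
  if (sd_m == 0)
    stop("degenerate cohort: per-subject means have zero variance",
         call. = FALSE)
  res <- list(mu_of_means = mean(means), sd_of_means = sd_m,
              n_subjects = length(stacks))
  class(res) <- "cohort_stats"
  res
}

#' Apply cohort z-score normalization to a stack
#'
#' Every voxel `v` maps to `(v - mu_of_means) / sd_of_means`; geometry and
#' slice order are unchanged. The transform is affine, so intensity ordering
#' is preserved within every slice.
#'
#' @param stack A [slice_stack()].
#' @param stats A `cohort_stats` from [compute_cohort_stats()].
#' @return The normalized [slice_stack()].
#' @export
zscore_normalize <- function(stack, stats) {
  stopifnot(inherits(stack, "slice_stack"), inherits(stats, "cohort_stats"))
  if (!is.finite(stats$sd_of_means) || stats$sd_of_means <= 0)
    stop("degenerate cohort stats", call. = FALSE)
  stack$slices <- lapply(stack$slices, function(s)
    (s - stats$mu_of_means) / stats$sd_of_means)
  stack
}

#' Save / load cohort statistics as JSON
#'
#' A small sidecar (`cohort_stats.json`) so that inference reuses the exact
#' training-time normalization parameters.
#'
#' @param stats A `cohort_stats`.
#' @param path JSON file path.
#' @return `path` (save) or a `cohort_stats` (load).
#' @export
save_cohort_stats <- function(stats, path) {
  stopifnot(inherits(stats, "cohort_stats"))
  jsonlite::write_json(unclass(stats), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export a normalized stack as PNG slices with a scale sidecar
#'
#' Normalized intensities are floating-point; to store them as grayscale
#' PNGs they are linearly rescaled to the full 8-bit range, and the affine
#' map is recorded in a JSON sidecar (`<subject>_scale.json`) so that
#' [read_normalized_stack()] recovers the values (to quantization
#' precision). The in-memory pipeline never quantizes.
#'
#' @param stack A (normalized) [slice_stack()].
#' @param out_dir Output directory.
#' @return Paths written, invisibly.
#' @export
write_normalized_stack <- function(stack, out_dir) {
  stopifnot(inherits(stack, "slice_stack"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  v <- unlist(stack$slices, use.names = FALSE)
  lo <- min(v); hi <- max(v)
  span <- if (hi > lo) hi - lo else 1
  width <- max(3L, nchar(as.character(stack$geometry$n_slices - 1L)))
  paths <- character(length(stack$slices))
  for (i in seq_along(stack$slices)) {
    fn <- file.path(out_dir, sprintf("%s_%0*d.png", stack$subject_id,
                                     width, i - 1L))
    png::writePNG((stack$slices[[i]] - lo) / span, fn)
    paths[i] <- fn
  }
  sidecar <- file.path(out_dir, paste0(stack$subject_id, "_scale.json"))
  jsonlite::write_json(list(offset = lo, scale = span, bit_depth = 8L),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, sidecar))
}

#' @rdname write_normalized_stack
#' @param dir Directory holding the exported slices and sidecar.
#' @param subject_id Subject to read.
#' @param geometry Expected [voxel_geometry()].
#' @export
read_normalized_stack <- function(dir, subject_id, geometry) {
  sc <- jsonlite::read_json(file.path(dir,
                                      paste0(subject_id, "_scale.json")),
                            simplifyVector = TRUE)
  raw <- ingest_bulk(dir, geometry)
  ids <- vapply(raw, `[[`, character(1), "subject_id")
  stack <- raw[[match(subject_id, ids)]]
  stack$slices <- lapply(stack$slices, function(s)
    s / 255 * sc$scale + sc$offset)
  stack
}

#' @rdname save_cohort_stats
#' @export
load_cohort_stats <- function(path) {
  res <- jsonlite::read_json(path, simplifyVector = TRUE)
  res <- list(mu_of_means = as.numeric(res$mu_of_means),
              sd_of_means = as.numeric(res$sd_of_means),
              n_subjects = as.integer(res$n_subjects))
  class(res) <- "cohort_stats"
  res
}
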