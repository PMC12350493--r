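#' Synthetic head-phantom specification
#'
#' Defines the study conditions for the built-in phantom cohort: an
#' ellipsoidal head with a bright 1-2 voxel rim ("skull"), an interior ICV
#' region, and a small bilateral target structure (two ellipsoids, the
#' hypothalamus stand-in) strictly inside the ICV. Per-subject variation is
#' an intensity gain and offset plus additive Gaussian noise; an optional
#' group-level effect shrinks the target volume in the patient group
#' (atrophy model) while leaving the ICV untouched.
#'
#' Defaults describe a desk-scale stack (16 slices of 64 x 64 at
#' 2.5 x 2.5 x 6 mm) whose structures mirror the relative proportions of
#' the clinical task: an ICV of roughly 0.65 l and a bilateral target of a
#' few hundred voxels.
#'
#' @param geometry [voxel_geometry()] of the generated stacks.
#' @param head_semi_axes Head (outer skull) ellipsoid semi-axes in mm along
#'   (rows, cols, slices).
#' @param rim_mm Skull rim thickness in mm (the ICV ellipsoid is the head
#'   ellipsoid shrunk by this amount on every semi-axis).
#' @param target_semi_axes Semi-axes (mm) of each of the two target
#'   ellipsoids.
#' @param target_offset_mm Lateral offset (mm, along columns) of the two
#'   target centers from the midline.
#' @param background_intensity,icv_intensity,target_intensity,rim_intensity
#'   Structure intensities in arbitrary units (>= 0).
#' @param noise_sd SD of additive voxelwise Gaussian noise.
#' @param subject_gain_sd SD of the per-subject multiplicative gain
#'   (gain = 1 + N(0, subject_gain_sd)).
#' @param subject_offset_sd SD of the per-subject additive intensity offset.
#' @param group_effect Fractional target-volume reduction in the patient
#'   group, in `[0, 1)`; applied isotropically as `(1 - group_effect)^(1/3)`
#'   on the target semi-axes.
#' @param sex_ratio Fraction of male subjects.
#' @param sex_icv_shift Optional fractional ICV enlargement for males (e.g.
#'   0.10 for +10%), applied as an isotropic head scaling; 0 disables it.
#' @param allometric_target When `TRUE`, the target scales with the
#'   subject's head scaling factor, making target volume proportional to ICV
#'   (used to exercise ICV normalization).
#' @param seed Integer master seed for cohort generation.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(geometry = voxel_geometry(2.5, 2.5, 6,
                                                   n_slices = 16L,
                                                   matrix = c(64L, 64L)),
                         head_semi_axes = c(65, 75, 42),
                         rim_mm = 5,
                         target_semi_axes = c(8, 10, 12),
                         target_offset_mm = 12,
                         background_intensity = 10,
                         icv_intensity = 90,
                         target_intensity = 190,
                         rim_intensity = 230,
                         noise_sd = 5,
                         subject_gain_sd = 0.05,
                         subject_offset_sd = 5,
                         group_effect = 0,
                         sex_ratio = 0.5,
                         sex_icv_shift = 0,
                         allometric_target = FALSE,
                         seed = 1L) {
  stopifnot(inherits(geometry, "voxel_geometry"))
  ints <- c(background_intensity, icv_intensity, target_intensity,
            rim_intensity)
  if (any(ints < 0)) stop("intensities must be >= 0", call. = FALSE)
  if (group_effect < 0 || group_effect >= 1)
    stop("group_effect must be in [0, 1)", call. = FALSE)
  fov <- c(geometry$matrix[1] * geometry$dy, geometry$matrix[2] * geometry$dx,
           geometry$n_slices * geometry$dz)
  if (any(head_semi_axes >= fov / 2))
    stop("head semi-axes must fit inside the field of view", call. = FALSE)
  if (any(head_semi_axes - rim_mm <= 0))
    stop("rim thicker than the head", call. = FALSE)
  res <- list(geometry = geometry, head_semi_axes = head_semi_axes,
              rim_mm = rim_mm, target_semi_axes = target_semi_axes,
              target_offset_mm = target_offset_mm,
              background_intensity = background_intensity,
              icv_intensity = icv_intensity,
              target_intensity = target_intensity,
              rim_intensity = rim_intensity, noise_sd = noise_sd,
              subject_gain_sd = subject_gain_sd,
              subject_offset_sd = subject_offset_sd,
              group_effect = group_effect, sex_ratio = sex_ratio,
              sex_icv_shift = sex_icv_shift,
              allometric_target = allometric_target, seed = as.integer(seed))
  class(res) <- "phantom_spec"
  res
}

# Voxel-center coordinates (mm) along each axis, centered on the FOV.
axis_coords <- function(n, h) (seq_len(n) - (n + 1) / 2) * h

# Logical array: voxel centers inside an ellipsoid at `center` (mm) with
# the given semi-axes (mm).
ellipsoid_mask <- function(geometry, semi, center = c(0, 0, 0)) {
  r <- axis_coords(geometry$matrix[1], geometry$dy) - center[1]
  c_ <- axis_coords(geometry$matrix[2], geometry$dx) - center[2]
  z <- axis_coords(geometry$n_slices, geometry$dz) - center[3]
  q <- outer(outer((r / semi[1])^2, (c_ / semi[2])^2, "+"),
             (z / semi[3])^2, "+")
  q < 1
}

#' Generate one synthetic subject
#'
#' Deterministic given `(spec, subject_id, group, seed)`. The target mask is
#' the union of the two target ellipsoids, scaled isotropically by
#' `(1 - group_effect)^(1/3)` for patients; the ICV mask is the rim
#' interior. Voxel intensities are
#' `structure_value * gain + offset + N(0, noise_sd)`.
#'
#' @param spec A [phantom_spec()].
#' @param subject_id Character id.
#' @param group `"control"` or `"patient"`.
#' @param seed Integer seed for this subject's random draws.
#' @return List with `stack` ([slice_stack()]), `target_mask` and `icv_mask`
#'   (ground-truth [mask_stack()]s) and `sex` (`"male"`/`"female"`).
#' @export
generate_subject <- function(spec, subject_id, group = c("control", "patient"),
                             seed = spec$seed) {
  group <- match.arg(group)
  stopifnot(inherits(spec, "phantom_spec"))
  g <- spec$geometry
  with_seed(seed, {
    sex <- if (stats::runif(1) < spec$sex_ratio) "male" else "female"
    head_scale <- if (sex == "male" && spec$sex_icv_shift > 0)
      (1 + spec$sex_icv_shift)^(1 / 3) else 1
    head_ax <- spec$head_semi_axes * head_scale
    icv_ax <- head_ax - spec$rim_mm
    t_scale <- if (group == "patient") (1 - spec$group_effect)^(1 / 3) else 1
    if (spec$allometric_target) t_scale <- t_scale * head_scale
    t_ax <- spec$target_semi_axes * t_scale

    head <- ellipsoid_mask(g, head_ax)
    icv <- ellipsoid_mask(g, icv_ax)
    rim <- head & !icv
    off <- spec$target_offset_mm
    target <- ellipsoid_mask(g, t_ax, c(0, -off, 0)) |
      ellipsoid_mask(g, t_ax, c(0, off, 0))
    if (any(target & !icv))
      stop("phantom spec error: target not strictly inside the ICV",
           call. = FALSE)

    base <- array(spec$background_intensity, dim(head))
    base[icv] <- spec$icv_intensity
    base[target] <- spec$target_intensity
    base[rim] <- spec$rim_intensity
    gain <- 1 + stats::rnorm(1, sd = spec$subject_gain_sd)
    offset <- stats::rnorm(1, sd = spec$subject_offset_sd)
    img <- base * gain + offset +
      array(stats::rnorm(length(base), sd = spec$noise_sd), dim(base))

    list(stack = array_stack(subject_id, img, g),
         target_mask = array_mask(subject_id, target + 0, g, "ground_truth"),
         icv_mask = array_mask(subject_id, icv + 0, g, "ground_truth"),
         sex = sex)
  })
}

#' Generate a phantom cohort
#'
#' Subject seeds are derived deterministically from `spec$seed`, so two
#' cohorts generated from the same spec are identical.
#'
#' @param spec A [phantom_spec()].
#' @param n_control,n_patient Group sizes (>= 0).
#' @return List with `stacks`, `target_masks`, `icv_masks` (parallel lists)
#'   and `metadata` (data frame: subject_id, sex, group, seed).
#' @export
generate_cohort <- function(spec, n_control, n_patient) {
  stopifnot(n_control >= 0, n_patient >= 0)
  n <- n_control + n_patient
  ids <- c(sprintf("C%03d", seq_len(n_control)),
           sprintf("P%03d", seq_len(n_patient)))
  groups <- rep(c("control", "patient"), c(n_control, n_patient))
  if (n == 0L)
    return(list(stacks = list(), target_masks = list(), icv_masks = list(),
                metadata = data.frame(subject_id = character(0),
                                      sex = character(0),
                                      group = character(0),
                                      seed = integer(0))))
  seeds <- with_seed(spec$seed, sample.int(.Machine$integer.max - 1L, n))
  subjects <- lapply(seq_len(n), function(i)
    generate_subject(spec, ids[i], groups[i], seeds[i]))
  list(stacks = lapply(subjects, `[[`, "stack"),
       target_masks = lapply(subjects, `[[`, "target_mask"),
       icv_masks = lapply(subjects, `[[`, "icv_mask"),
       metadata = data.frame(subject_id = ids,
                             sex = vapply(subjects, `[[`, character(1), "sex"),
                             group = groups, seed = seeds,
                             stringsAsFactors = FALSE))
}

#' Analytic phantom volumes
#'
#' Closed-form volumes of the generated structures (before discretization):
#' target = two ellipsoids `2 * (4/3) pi a b c`, ICV = one ellipsoid with the
#' rim-shrunk semi-axes. Useful as ground truth for volumetry checks.
#'
#' @param spec A [phantom_spec()].
#' @param group `"control"` or `"patient"` (the patient target is shrunk by
#'   `group_effect`).
#' @return List with `target_mm3` and `icv_mm3`.
#' @export
phantom_analytic_volumes <- function(spec, group = c("control", "patient")) {
  group <- match.arg(group)
  t_ax <- spec$target_semi_axes
  if (group == "patient") t_ax <- t_ax * (1 - spec$group_effect)^(1 / 3)
  icv_ax <- spec$head_semi_axes - spec$rim_mm
  list(target_mm3 = 2 * 4 / 3 * pi * prod(t_ax),
       icv_mm3 = 4 / 3 * pi * prod(icv_ax))
}

#' Write a phantom cohort to disk in the bulk-upload layout
#'
#' Writes 8-bit grayscale PNG slice stacks (intensities clipped to 0..255)
#' under `images/`, ground-truth masks under `masks_hypothalamus/` and
#' `masks_icv/`, and a `metadata.csv` — the exact layout [ingest_bulk()]
#' consumes.
#'
#' @param cohort Result of [generate_cohort()].
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  img_dir <- file.path(out_dir, "images")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$stacks) {
    width <- max(3L, nchar(as.character(s$geometry$n_slices - 1L)))
    for (i in seq_along(s$slices)) {
      v <- pmin(pmax(round(s$slices[[i]]), 0), 255) / 255
      png::writePNG(v, file.path(img_dir, sprintf("%s_%0*d.png",
                                                  s$subject_id, width,
                                                  i - 1L)))
    }
  }
  for (m in cohort$target_masks)
    write_mask_stack(m, file.path(out_dir, "masks_hypothalamus"))
  for (m in cohort$icv_masks)
    write_mask_stack(m, file.path(out_dir, "masks_icv"))
  utils::write.csv(cohort$metadata, file.path(out_dir, "metadata.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(out_dir)
}
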