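#' Voxel geometry of a slice stack
#'
#' Describes the physical sampling grid of a stack of 2D slices: in-plane
#' voxel spacing, slice thickness, slice count and matrix size. All distances
#' are in millimetres. The first matrix dimension (rows) is spaced by `dy`,
#' the second (columns) by `dx`, and consecutive slices by `dz`.
#'
#' @param dx In-plane voxel spacing along columns (mm), > 0.
#' @param dy In-plane voxel spacing along rows (mm), > 0.
#' @param dz Slice thickness / spacing (mm), > 0.
#' @param n_slices Number of slices in a stack (>= 1).
#' @param matrix Integer vector `c(rows, cols)`, each >= 8.
#' @return An object of class `voxel_geometry`.
#' @examples
#' g <- voxel_geometry(0.5, 0.5, 0.5, n_slices = 512, matrix = c(512, 512))
#' voxel_volume(g)  # 0.125 mm^3
#' @export
voxel_geometry <- function(dx, dy, dz, n_slices, matrix = c(512L, 512L)) {
  stopifnot(is.numeric(dx), is.numeric(dy), is.numeric(dz))
  if (dx <= 0 || dy <= 0 || dz <= 0)
    stop("voxel spacings dx, dy, dz must be positive", call. = FALSE)
  n_slices <- as.integer(n_slices)
  matrix <- as.integer(matrix)
  if (n_slices < 1L) stop("n_slices must be >= 1", call. = FALSE)
  if (length(matrix) != 2L || any(matrix < 8L))
    stop("matrix must be c(rows, cols) with both >= 8", call. = FALSE)
  structure(
    list(dx = as.numeric(dx), dy = as.numeric(dy), dz = as.numeric(dz),
         n_slices = n_slices, matrix = matrix),
    class = "voxel_geometry"
  )
}

#' Named geometry presets
#'
#' `"hypothalamus"`: 50 slices of 512 x 512 at 0.125 x 0.125 x 0.5 mm.
#' `"icv"`: 512 slices of 512 x 512 at 0.5 x 0.5 x 0.5 mm.
#'
#' @param name Preset name, `"hypothalamus"` or `"icv"`.
#' @return A [voxel_geometry()].
#' @export
geometry_preset <- function(name = c("hypothalamus", "icv")) {
  name <- match.arg(name)
  switch(name,
    hypothalamus = voxel_geometry(0.125, 0.125, 0.5, n_slices = 50L,
                                  matrix = c(512L, 512L)),
    icv = voxel_geometry(0.5, 0.5, 0.5, n_slices = 512L,
                         matrix = c(512L, 512L))
  )
}

#' Physical volume of a single voxel in mm^3
#' @param geometry A [voxel_geometry()].
#' @return `dx * dy * dz` in mm^3.
#' @export
voxel_volume <- function(geometry) {
  stopifnot(inherits(geometry, "voxel_geometry"))
  geometry$dx * geometry$dy * geometry$dz
}

#' @export
print.voxel_geometry <- function(x, ...) {
  cat(sprintf("voxel_geometry: %d slices of %d x %d, spacing %.4g x %.4g x %.4g mm\n",
              x$n_slices, x$matrix[1], x$matrix[2], x$dx, x$dy, x$dz))
  invisible(x)
}

geometry_equal <- function(a, b) {
  isTRUE(all.equal(a$dx, b$dx)) && isTRUE(all.equal(a$dy, b$dy)) &&
    isTRUE(all.equal(a$dz, b$dz)) && a$n_slices == b$n_slices &&
    all(a$matrix == b$matrix)
}
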