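#' Ingest a bulk upload of PNG slices
#'
#' Unpacks a ZIP archive (or reads a directory) of PNG files named
#' `<subjectID>_<NNN>.png` (zero-padded, 0-based slice index), groups files by
#' subject, sorts slices numerically by index and subjects lexicographically,
#' and decodes each file to a grayscale intensity matrix (8-bit PNGs decode to
#' 0..255, 16-bit to 0..65535). Stacks whose slice count or matrix size does
#' not match `geometry` are reported in the `problems` attribute (and via a
#' warning), never silently dropped.
#'
#' @param path Path to a ZIP archive of PNGs, or to a directory containing them.
#' @param geometry Expected [voxel_geometry()].
#' @return A list of [slice_stack()]s (subjects in lexicographic order), with
#'   attribute `problems`: a data frame of stacks that failed the geometry
#'   contract (`subject_id`, `reason`).
#' @details A missing slice index within a subject's sequence raises a gap
#'   error; a duplicate (subject, index) pair raises a collision error; an
#'   undecodable or multi-channel PNG raises a format error.
#' @export
ingest_bulk <- function(path, geometry) {
  stopifnot(inherits(geometry, "voxel_geometry"))
  if (dir.exists(path)) {
    dir <- path
  } else {
    if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
    dir <- tempfile("ingest_")
    dir.create(dir)
    on.exit(unlink(dir, recursive = TRUE), add = TRUE)
    utils::unzip(path, exdir = dir)
  }
  files <- list.files(dir, pattern = "\\.png$", recursive = TRUE,
                      full.names = TRUE)
  if (length(files) == 0L) stop("no PNG files found in ", path, call. = FALSE)
  parsed <- parse_slice_names(basename(files))
  parsed$path <- files

  key <- paste(parsed$subject_id, parsed$index, sep = "\r")
  if (anyDuplicated(key)) {
    d <- parsed[duplicated(key), , drop = FALSE]
    stop(sprintf("duplicate slice file for subject %s index %d",
                 d$subject_id[1], d$index[1]), call. = FALSE)
  }

  stacks <- list()
  problems <- list()
  for (sid in sort(unique(parsed$subject_id))) {
    sub <- parsed[parsed$subject_id == sid, , drop = FALSE]
    sub <- sub[order(sub$index), , drop = FALSE]
    expect <- seq_len(nrow(sub)) - 1L
    if (!all(sub$index == expect)) {
      miss <- setdiff(seq.int(0L, max(sub$index)), sub$index)
      stop(sprintf("subject %s: missing slice index %d", sid, miss[1]),
           call. = FALSE)
    }
    if (nrow(sub) != geometry$n_slices) {
      problems[[length(problems) + 1L]] <- data.frame(
        subject_id = sid,
        reason = sprintf("%d slices, geometry expects %d",
                         nrow(sub), geometry$n_slices))
      next
    }
    slices <- lapply(sub$path, read_png_gray)
    bad <- which(vapply(slices, function(s) any(dim(s) != geometry$matrix),
                        logical(1)))
    if (length(bad)) {
      problems[[length(problems) + 1L]] <- data.frame(
        subject_id = sid,
        reason = sprintf("slice %d matrix size mismatch", sub$index[bad[1]]))
      next
    }
    stacks[[sid]] <- slice_stack(sid, slices, geometry)
  }
  problems <- if (length(problems)) do.call(rbind, problems) else
    data.frame(subject_id = character(0), reason = character(0))
  if (nrow(problems))
    warning(sprintf("%d stack(s) failed the geometry contract; see attr(,'problems')",
                    nrow(problems)), call. = FALSE)
  structure(unname(stacks[sort(names(stacks))]), problems = problems)
}

parse_slice_names <- function(names) {
  m <- regmatches(names, regexec("^(.*)_([0-9]+)\\.png$", names))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad))
    stop("file name does not follow <subjectID>_<NNN>.png: ", names[bad][1],
         call. = FALSE)
  data.frame(
    subject_id = vapply(m, `[`, character(1), 2L),
    index = as.integer(vapply(m, `[`, character(1), 3L)),
    stringsAsFactors = FALSE
  )
}

# Decode a single-channel PNG to an integer-valued intensity matrix
# (0..255 for 8-bit, 0..65535 for 16-bit). Multi-channel input is rejected.
read_png_gray <- function(path) {
  img <- tryCatch(png::readPNG(path, info = TRUE),
                  error = function(e) stop("undecodable PNG: ", path,
                                           call. = FALSE))
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] == 1L) img <- img[, , 1L]
    else stop("multi-channel PNG rejected (single-channel grayscale expected): ",
              path, call. = FALSE)
  }
  depth <- attr(img, "info")$bit.depth
  if (is.null(depth)) depth <- 8L
  out <- round(img * (2^depth - 1))
  attributes(out) <- list(dim = dim(out))
  out
}

#' Write a mask stack as grayscale PNG files
#'
#' One 8-bit grayscale PNG per slice, foreground 255 and background 0, named
#' `<subjectID>_<NNN>.png` so that [read_mask_stack()] (and [ingest_bulk()])
#' recover them. Writing then reading yields a bit-identical mask.
#'
#' @param mask A [mask_stack()].
#' @param out_dir Output directory (created if needed).
#' @return Character vector of file paths written, in slice order.
#' @export
write_mask_stack <- function(mask, out_dir) {
  stopifnot(inherits(mask, "mask_stack"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  width <- max(3L, nchar(as.character(mask$geometry$n_slices - 1L)))
  paths <- character(mask$geometry$n_slices)
  for (i in seq_along(mask$slices)) {
    fn <- file.path(out_dir, sprintf("%s_%0*d.png", mask$subject_id, width, i - 1L))
    png::writePNG(mask$slices[[i]], target = fn)  # 0/1 -> 0/255 at 8 bit
    paths[i] <- fn
  }
  paths
}

#' Read a mask stack written as grayscale PNG files
#'
#' Decodes `<subject_id>_<NNN>.png` files from `dir`; pixels with decoded
#' value > 127 map to 1, the rest to 0 (tolerating anti-aliased manual edits).
#'
#' @param dir Directory holding the PNG files.
#' @param subject_id Subject whose mask to read.
#' @param geometry Expected [voxel_geometry()].
#' @param provenance Provenance to record, default `"predicted"`.
#' @return A [mask_stack()].
#' @export
read_mask_stack <- function(dir, subject_id, geometry,
                            provenance = "predicted") {
  files <- list.files(dir, pattern = paste0("^", escape_regex(subject_id),
                                            "_[0-9]+\\.png$"),
                      full.names = TRUE)
  if (length(files) == 0L)
    stop("no mask PNGs for subject ", subject_id, " in ", dir, call. = FALSE)
  parsed <- parse_slice_names(basename(files))
  files <- files[order(parsed$index)]
  if (length(files) != geometry$n_slices)
    stop(sprintf("subject %s: %d mask slices, geometry expects %d",
                 subject_id, length(files), geometry$n_slices), call. = FALSE)
  slices <- lapply(files, function(f) {
    s <- read_png_gray(f)
    if (any(dim(s) != geometry$matrix))
      stop("mask slice shape mismatch vs geometry: ", f, call. = FALSE)
    (s > 127) + 0
  })
  mask_stack(subject_id, slices, geometry, provenance)
}

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

#' Write subject volumetry records to the results CSV
#'
#' Deterministic output: one row per record, sorted by `subject_id`
#' (ties broken by `structure`), with the fixed header
#' `subject_id, group, sex, structure, n_positive_voxels, volume_mm3,
#' volume_ml, normalized_volume_mm3, qc_flag, provenance`.
#'
#' @param records Data frame of subject records (missing columns are filled
#'   with NA).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(records, path) {
  cols <- c("subject_id", "group", "sex", "structure", "n_positive_voxels",
            "volume_mm3", "volume_ml", "normalized_volume_mm3", "qc_flag",
            "provenance")
  if (is.null(records) || nrow(as.data.frame(records)) == 0L) {
    out <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)),
                                         cols))
  } else {
    records <- as.data.frame(records)
    for (cn in setdiff(cols, names(records))) records[[cn]] <- NA
    out <- records[order(records$subject_id,
                         if ("structure" %in% names(records))
                           records$structure else records$subject_id),
                   cols, drop = FALSE]
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
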