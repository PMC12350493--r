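#' Save / load trained cross-validation folds
#'
#' Writes one model file per fold (`fold_<i>.rds`), a per-fold training
#' history CSV, and a `folds.json` manifest recording fold indices,
#' validation IoUs and file names. `load_trained_folds()` reads the manifest
#' back into a list of `trained_fold` objects.
#'
#' @param folds List of `trained_fold` objects.
#' @param dir Model directory (created if needed).
#' @return `dir` (save) or a list of `trained_fold`s (load), with the
#'   manifest attached as attribute `manifest`.
#' @export
save_trained_folds <- function(folds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("fold_%d.rds", vapply(folds, `[[`, integer(1),
                                         "fold_index"))
  for (i in seq_along(folds)) {
    saveRDS(folds[[i]], file.path(dir, files[i]))
    utils::write.csv(folds[[i]]$history,
                     file.path(dir, sprintf("history_fold_%d.csv",
                                            folds[[i]]$fold_index)),
                     row.names = FALSE)
  }
  manifest <- list(k = length(folds),
                   fold_index = vapply(folds, `[[`, integer(1), "fold_index"),
                   val_iou = vapply(folds, `[[`, numeric(1), "val_iou"),
                   files = files)
  jsonlite::write_json(manifest, file.path(dir, "folds.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_trained_folds
#' @export
load_trained_folds <- function(dir) {
  mf <- file.path(dir, "folds.json")
  if (!file.exists(mf))
    stop("no folds.json manifest in ", dir, call. = FALSE)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  folds <- lapply(manifest$files, function(f) readRDS(file.path(dir, f)))
  attr(folds, "manifest") <- manifest
  folds
}

#' Pipeline run configuration
#'
#' @param input Directory (or ZIP) of PNG slice stacks to segment.
#' @param out_dir Output directory for masks and the results CSV.
#' @param models Named list of model directories by task, e.g.
#'   `list(hypothalamus = "models/hyp", icv = "models/icv")`.
#' @param tasks Tasks to run; both tasks enable ICV normalization of the
#'   hypothalamic volumes.
#' @param geometry A [voxel_geometry()] describing the input stacks (one
#'   geometry; use separate runs for inputs of different geometry), or a
#'   named list per task.
#' @param ensemble Use the validation-IoU-weighted ensemble of all folds
#'   (`TRUE`, default) or a single fold selected by `model`.
#' @param model Fold index used when `ensemble = FALSE`.
#' @param metadata Optional path to a metadata CSV with columns
#'   `subject_id`, `sex`, `group` merged into the results.
#' @return A `run_config` list.
#' @export
run_config <- function(input, out_dir, models,
                       tasks = c("hypothalamus", "icv"),
                       geometry = geometry_preset("hypothalamus"),
                       ensemble = TRUE, model = NULL, metadata = NULL) {
  tasks <- match.arg(tasks, several.ok = TRUE)
  if (identical(normalizePath(input, mustWork = FALSE),
                normalizePath(out_dir, mustWork = FALSE)))
    stop("input and output paths must be distinct", call. = FALSE)
  if (!all(tasks %in% names(models)))
    stop("a model directory is required for every task", call. = FALSE)
  res <- list(input = input, out_dir = out_dir, models = models,
              tasks = tasks, geometry = geometry, ensemble = ensemble,
              model = model, metadata = metadata)
  class(res) <- "run_config"
  res
}

#' Run the upload-to-CSV segmentation workflow
#'
#' Executes, per task: ingest -> z-score normalize (with the training-time
#' cohort statistics stored next to the models, when present) -> predict
#' (weighted ensemble or a single fold) -> write predicted masks -> quantify
#' volumes; then assembles all records, computes ICV-normalized hypothalamic
#' volumes when both tasks ran, and writes `volumes.csv`. Per-stage counts
#' are logged via [message()].
#'
#' @param config A [run_config()].
#' @return Data frame of subject records (also written to
#'   `<out_dir>/volumes.csv`), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  records <- list()
  for (task in config$tasks) {
    geom <- if (inherits(config$geometry, "voxel_geometry")) config$geometry
            else config$geometry[[task]]
    message(sprintf("[%s] ingest: %s", task, config$input))
    stacks <- ingest_bulk(config$input, geom)
    probs <- attr(stacks, "problems")
    if (nrow(probs))
      message(sprintf("[%s] %d stack(s) failed the geometry contract",
                      task, nrow(probs)))
    message(sprintf("[%s] ingested %d subject(s)", task, length(stacks)))
    if (length(stacks) == 0L) stop("no ingestible stacks", call. = FALSE)

    stats_path <- file.path(config$models[[task]], "cohort_stats.json")
    if (file.exists(stats_path)) {
      cstats <- load_cohort_stats(stats_path)
      message(sprintf("[%s] using stored cohort stats (mu=%.3f, sd=%.3f)",
                      task, cstats$mu_of_means, cstats$sd_of_means))
    } else {
      cstats <- compute_cohort_stats(stacks)
      message(sprintf("[%s] no stored cohort stats; estimated from input",
                      task))
    }
    normalized <- lapply(stacks, zscore_normalize, stats = cstats)

    folds <- load_trained_folds(config$models[[task]])
    if (config$ensemble && length(folds) > 1L) {
      weights <- compute_weights(attr(folds, "manifest")$val_iou)
    } else {
      sel <- if (!is.null(config$model)) {
        which(vapply(folds, `[[`, integer(1), "fold_index") ==
                config$model)
      } else 1L
      if (length(sel) != 1L)
        stop("no such fold: ", config$model, call. = FALSE)
      folds <- folds[sel]
      weights <- compute_weights(1)
    }
    mask_dir <- file.path(config$out_dir, paste0("masks_", task))
    for (st in normalized) {
      pr <- ensemble_predict(folds, weights, st)
      write_mask_stack(pr$mask, mask_dir)
      vol <- mask_volume(pr$mask, structure = task)
      records[[length(records) + 1L]] <- data.frame(
        subject_id = vol$subject_id, structure = vol$structure,
        n_positive_voxels = vol$n_positive, volume_mm3 = vol$volume_mm3,
        volume_ml = vol$volume_ml, qc_flag = "ok",
        provenance = vol$provenance, stringsAsFactors = FALSE)
    }
    message(sprintf("[%s] segmented and quantified %d subject(s)",
                    task, length(normalized)))
  }
  records <- do.call(rbind, records)
  records$normalized_volume_mm3 <- NA_real_
  if (all(c("hypothalamus", "icv") %in% config$tasks)) {
    hyp <- records[records$structure == "hypothalamus", ]
    icv <- records[records$structure == "icv", ]
    ref <- mean(icv$volume_ml)
    idx <- match(hyp$subject_id, icv$subject_id)
    norm <- normalize_hypothalamic_volume(hyp$volume_mm3,
                                          icv$volume_ml[idx], ref)
    records$normalized_volume_mm3[records$structure == "hypothalamus"] <-
      norm
    message(sprintf("normalized hypothalamic volumes to reference ICV %.1f ml",
                    ref))
  }
  if (!is.null(config$metadata) && file.exists(config$metadata)) {
    meta <- utils::read.csv(config$metadata, stringsAsFactors = FALSE)
    keep <- intersect(c("subject_id", "sex", "group"), names(meta))
    records <- merge(records, meta[keep], by = "subject_id",
                     all.x = TRUE, sort = FALSE)
  }
  write_results_csv(records, file.path(config$out_dir, "volumes.csv"))
  message(sprintf("wrote %d record(s) to %s", nrow(records),
                  file.path(config$out_dir, "volumes.csv")))
  invisible(records)
}
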