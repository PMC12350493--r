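#' Sex-stratified 2-SD outlier flagging
#'
#' Within each sex stratum (clinical groups pooled), flags records whose
#' value deviates from the stratum mean by strictly more than
#' `k_sd` sample standard deviations; mean and SD are computed over the full
#' stratum, candidates included. A value at exactly `mean + k_sd * SD` is
#' not flagged. Strata with fewer than 3 records are skipped with a warning
#' (`flagged = NA`). Flagging is scale-invariant within a stratum.
#'
#' @param records Data frame with a `sex` column and the column named in
#'   `field`.
#' @param field Column to screen, e.g. `"icv_ml"` or `"hyp_volume_mm3"`.
#' @param k_sd Flagging threshold in SD units (default 2).
#' @param stratify_by Stratification column (default `"sex"`); set to
#'   `c("sex", "group")` for per-group strata.
#' @return Data frame: `subject_id`, stratum columns, `value`,
#'   `stratum_mean`, `stratum_sd`, `deviation_sd` (|x - mean| / SD) and
#'   logical `flagged`.
#' @export
flag_outliers <- function(records, field, k_sd = 2, stratify_by = "sex") {
  records <- as.data.frame(records)
  stopifnot(field %in% names(records), all(stratify_by %in% names(records)))
  strata <- interaction(records[stratify_by], drop = TRUE)
  out <- records[c("subject_id", stratify_by)]
  out$value <- records[[field]]
  out$stratum_mean <- NA_real_
  out$stratum_sd <- NA_real_
  out$deviation_sd <- NA_real_
  out$flagged <- NA
  for (s in levels(strata)) {
    sel <- strata == s
    x <- out$value[sel]
    if (sum(sel) < 3L) {
      warning(sprintf("stratum '%s' has %d record(s) (< 3); skipped",
                      s, sum(sel)), call. = FALSE)
      next
    }
    m <- mean(x)
    sdev <- stats::sd(x)
    out$stratum_mean[sel] <- m
    out$stratum_sd[sel] <- sdev
    if (sdev == 0) {
      out$deviation_sd[sel] <- 0
      out$flagged[sel] <- FALSE
    } else {
      out$deviation_sd[sel] <- abs(x - m) / sdev
      out$flagged[sel] <- abs(x - m) > k_sd * sdev
    }
  }
  out
}

#' Ingest a manual mask correction for one subject record
#'
#' Recomputes the record's volumes from the manually corrected mask, marks
#' the record `manually_corrected`, and appends the original record to an
#' audit log.
#'
#' @param record One-row data frame (a results-CSV row) with at least
#'   `subject_id`, `structure`, `n_positive_voxels`, `volume_mm3`,
#'   `volume_ml`, `qc_flag`, `provenance`.
#' @param corrected A [mask_stack()] with provenance `"manual"` and the same
#'   geometry the record was quantified under.
#' @param audit_log Data frame of previously superseded records (or `NULL`).
#' @return List with `record` (updated) and `audit_log` (one row longer).
#' @export
apply_manual_correction <- function(record, corrected, audit_log = NULL) {
  stopifnot(inherits(corrected, "mask_stack"))
  if (corrected$provenance != "manual")
    stop("corrected mask must have provenance 'manual'", call. = FALSE)
  record <- as.data.frame(record)
  stopifnot(nrow(record) == 1L)
  if (!identical(record$subject_id, corrected$subject_id))
    stop("subject id mismatch between record and corrected mask",
         call. = FALSE)
  vol <- mask_volume(corrected, structure = record$structure)
  old <- record
  old$superseded_at <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  audit_log <- if (is.null(audit_log)) old else rbind(audit_log, old)
  record$n_positive_voxels <- vol$n_positive
  record$volume_mm3 <- vol$volume_mm3
  record$volume_ml <- vol$volume_ml
  record$qc_flag <- "manually_corrected"
  record$provenance <- "manual"
  list(record = record, audit_log = audit_log)
}

#' Descriptive summary of a cohort field
#'
#' Median and IQR via linear-interpolation quartiles (type-7 rule), plus
#' mean and sample SD. A single value yields IQR 0 and SD 0.
#'
#' @param x Numeric vector, or a data frame together with `field`.
#' @param field Column name when `x` is a data frame.
#' @return A `group_summary`: list with `n`, `median`, `iqr`, `mean`, `sd`.
#' @export
cohort_summary <- function(x, field = NULL) {
  if (is.data.frame(x)) {
    stopifnot(!is.null(field), field %in% names(x))
    x <- x[[field]]
  }
  x <- x[!is.na(x)]
  if (length(x) == 0L) stop("no values to summarize", call. = FALSE)
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  res <- list(n = length(x), median = q[2], iqr = q[3] - q[1],
              mean = mean(x), sd = if (length(x) < 2L) 0 else stats::sd(x))
  class(res) <- "group_summary"
  res
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("n = %d, median %.4g (IQR %.4g), mean %.4g +/- %.4g\n",
              x$n, x$median, x$iqr, x$mean, x$sd))
  invisible(x)
}

#' Unpaired Student's t-test group comparison
#'
#' Pooled-variance (equal-variance) two-sided t-test with
#' `df = n_a + n_b - 2`. Degenerate inputs are resolved explicitly: two
#' identical constant groups give `t = 0, p = 1`; zero pooled variance with
#' unequal means gives `p = 0` with a warning. Set `welch = TRUE` for the
#' unequal-variance variant.
#'
#' @param values_a,values_b Numeric vectors, each of length >= 2.
#' @param welch Use Welch's correction instead of the pooled test.
#' @return List with `t`, `p`, `df`, `mean_a`, `mean_b`.
#' @export
group_compare <- function(values_a, values_b, welch = FALSE) {
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("each group needs >= 2 values", call. = FALSE)
  na <- length(values_a); nb <- length(values_b)
  pooled_var <- ((na - 1) * stats::var(values_a) +
                   (nb - 1) * stats::var(values_b)) / (na + nb - 2)
  if (pooled_var == 0) {
    if (mean(values_a) == mean(values_b))
      return(list(t = 0, p = 1, df = na + nb - 2,
                  mean_a = mean(values_a), mean_b = mean(values_b)))
    warning("zero pooled variance with unequal means; p reported as 0",
            call. = FALSE)
    return(list(t = sign(mean(values_a) - mean(values_b)) * Inf, p = 0,
                df = na + nb - 2,
                mean_a = mean(values_a), mean_b = mean(values_b)))
  }
  ht <- stats::t.test(values_a, values_b, var.equal = !welch)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter),
       mean_a = mean(values_a), mean_b = mean(values_b))
}
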