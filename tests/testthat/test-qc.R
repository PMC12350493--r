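qc_records <- function(values, sex = rep("male", length(values)),
                       ids = sprintf("s%02d", seq_along(values))) {
  data.frame(subject_id = ids, sex = sex, icv_ml = values,
             stringsAsFactors = FALSE)
}

test_that("2-SD flagging uses the full-stratum mean and SD with a strict boundary", {
  # nine values of 1500 and one 1800: sample SD 94.87, deviation 270 -> flag
  rec <- qc_records(c(rep(1500, 9), 1800))
  rep_ <- flag_outliers(rec, "icv_ml")
  expect_equal(rep_$stratum_sd[1], 94.8683, tolerance = 1e-4)
  expect_identical(which(rep_$flagged), 10L)

  # all equal: nothing flagged
  expect_false(any(flag_outliers(qc_records(rep(1500, 8)), "icv_ml")$flagged))

  # a value at exactly mean + 2 SD is NOT flagged (strict inequality);
  # {+6, -6, 0 x 7} has mean 0 and sample SD exactly 3
  rep2 <- flag_outliers(qc_records(stratum_at_2sd()), "icv_ml")
  expect_identical(rep2$stratum_sd[1], 3)
  expect_false(any(rep2$flagged))

  # one at exactly mean + 3 SD is flagged
  rep3 <- flag_outliers(qc_records(stratum_at_3sd()), "icv_ml")
  expect_identical(which(rep3$flagged), c(1L, 2L))  # both +3 and -3 SD

  # the boundary rule holds for other k as well: in {0, 1, 2} the value 2
  # sits at exactly +1 SD
  rep1 <- flag_outliers(qc_records(c(0, 1, 2)), "icv_ml", k_sd = 1)
  expect_false(any(rep1$flagged))
  rep1b <- flag_outliers(qc_records(c(0, 1, 2)), "icv_ml", k_sd = 0.999)
  expect_true(rep1b$flagged[3])
})

test_that("flagging is sex-stratified and scale-invariant", {
  sex <- rep(c("male", "female"), each = 10)
  vals <- c(rep(1500, 9), 1800, rep(1300, 9), 1560)
  rec <- qc_records(vals, sex)
  rep_ <- flag_outliers(rec, "icv_ml")
  expect_identical(which(rep_$flagged), c(10L, 20L))
  # male outlier value 1800 is unremarkable in the female stratum scale-wise
  rep_scaled <- flag_outliers(qc_records(vals * 3.7, sex), "icv_ml")
  expect_identical(rep_scaled$flagged, rep_$flagged)
})

test_that("strata below three records are skipped with a warning", {
  rec <- qc_records(c(1500, 1600, 1400, 1450, 1700),
                    sex = c("male", "male", "male", "male", "female"))
  expect_warning(rep_ <- flag_outliers(rec, "icv_ml"), "female.*skipped")
  expect_true(is.na(rep_$flagged[5]))
  expect_false(any(rep_$flagged[1:4]))
})

test_that("manual corrections recompute volumes and append to the audit log", {
  g <- voxel_geometry(0.5, 0.5, 0.5, n_slices = 2L, matrix = c(10L, 10L))
  arr <- array(0, c(10, 10, 2)); arr[1:50] <- 1        # 50 voxels
  auto <- mask_volume(array_mask("s1", arr, g), "icv")
  record <- data.frame(subject_id = "s1", structure = "icv",
                       n_positive_voxels = auto$n_positive,
                       volume_mm3 = auto$volume_mm3,
                       volume_ml = auto$volume_ml,
                       qc_flag = "outlier_flagged", provenance = "predicted")

  # identical mask: volumes unchanged, flag and provenance updated
  same <- array_mask("s1", arr, g, "manual")
  r1 <- apply_manual_correction(record, same)
  expect_equal(r1$record$volume_mm3, record$volume_mm3)
  expect_equal(r1$record$qc_flag, "manually_corrected")
  expect_equal(r1$record$provenance, "manual")
  expect_equal(nrow(r1$audit_log), 1L)

  # 10% more voxels: volume up by exactly 10%
  arr2 <- arr; arr2[51:55] <- 1
  bigger <- array_mask("s1", arr2, g, "manual")
  r2 <- apply_manual_correction(r1$record, bigger, r1$audit_log)
  expect_equal(r2$record$volume_mm3, record$volume_mm3 * 1.10)
  expect_equal(nrow(r2$audit_log), 2L)

  # non-manual provenance is rejected
  expect_error(apply_manual_correction(record,
                                       array_mask("s1", arr, g, "predicted")),
               "manual")
})

test_that("cohort summaries use interpolated quartiles and sample SD", {
  s <- cohort_summary(c(1, 2, 3, 4, 5))
  expect_equal(s$median, 3)
  expect_equal(s$mean, 3)
  s2 <- cohort_summary(c(1, 2, 3, 4))
  expect_equal(s2$iqr, 1.5)       # Q3 - Q1 = 3.25 - 1.75
  s3 <- cohort_summary(42)
  expect_equal(s3$iqr, 0)
  expect_equal(s3$sd, 0)
  # mean equals the arithmetic mean to machine precision
  set.seed(2)
  x <- rnorm(101)
  expect_equal(cohort_summary(x)$mean, mean(x), tolerance = 1e-12)
  # data-frame interface
  df <- data.frame(v = c(1, 2, 3))
  expect_equal(cohort_summary(df, "v")$median, 2)
})

test_that("group comparison is a pooled-variance unpaired t-test", {
  r <- group_compare(c(1, 2, 3, 4), c(3, 4, 5, 6))
  expect_equal(r$t, -2.1909, tolerance = 1e-4)
  expect_equal(r$df, 6)
  expect_equal(r$p, 2 * pt(-abs(r$t), 6), tolerance = 1e-12)
  expect_equal(r$p, 0.070988, tolerance = 1e-4)
  # cross-check against the standard implementation
  ht <- t.test(c(1, 2, 3, 4), c(3, 4, 5, 6), var.equal = TRUE)
  expect_equal(r$t, unname(ht$statistic), tolerance = 1e-12)
  expect_equal(r$p, ht$p.value, tolerance = 1e-12)

  # antisymmetry
  r2 <- group_compare(c(3, 4, 5, 6), c(1, 2, 3, 4))
  expect_equal(r2$t, -r$t)
  expect_equal(r2$p, r$p)

  # identical constant groups; zero variance with unequal means
  expect_equal(group_compare(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_equal(group_compare(c(5, 5), c(5, 5))$p, 1)
  expect_warning(rz <- group_compare(c(5, 5), c(6, 6)), "zero pooled")
  expect_equal(rz$p, 0)

  expect_error(group_compare(1, c(1, 2)), ">= 2")
})
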