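small_geom <- function(n_slices = 4L, m = c(16L, 16L))
  voxel_geometry(0.5, 0.5, 0.5, n_slices = n_slices, matrix = m)

write_pngs <- function(dir, subject, slices, width = 3L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(slices))
    png::writePNG(slices[[i]] / 255,
                  file.path(dir, sprintf("%s_%0*d.png", subject, width,
                                         i - 1L)))
}

random_slices <- function(n, m = c(16L, 16L))
  lapply(seq_len(n), function(i)
    matrix(sample(0:255, prod(m), replace = TRUE), m[1], m[2]))

test_that("bulk ingest groups, sorts and counts subjects and slices", {
  g <- small_geom()
  d <- withr::local_tempdir()
  set.seed(1)
  sl_a <- random_slices(4)
  sl_b <- random_slices(4)
  write_pngs(d, "B", sl_b)   # written out of subject order on purpose
  write_pngs(d, "A", sl_a)
  stacks <- ingest_bulk(d, g)
  expect_length(stacks, 2L)
  expect_equal(vapply(stacks, `[[`, character(1), "subject_id"),
               c("A", "B"))
  expect_true(all(vapply(stacks, function(s) length(s$slices), integer(1)) ==
                    4L))
  # every ingested pixel preserved (lossless 8-bit round trip)
  expect_equal(sum(unlist(stacks[[1]]$slices)), sum(unlist(sl_a)))
  expect_identical(stacks[[1]]$slices[[3]], sl_a[[3]] * 1.0)
})

test_that("ingest accepts a long stack and a zip archive, invariant to file order", {
  g <- small_geom(n_slices = 50L)
  d <- withr::local_tempdir()
  write_pngs(d, "S1", random_slices(50))
  stacks <- ingest_bulk(d, g)
  expect_length(stacks, 1L)
  expect_equal(stacks[[1]]$geometry$n_slices, 50L)

  # zip with files added in shuffled order ingests identically
  z1 <- file.path(withr::local_tempdir(), "a.zip")
  z2 <- file.path(withr::local_tempdir(), "b.zip")
  files <- list.files(d, full.names = TRUE)
  make_zip(z1, files)
  make_zip(z2, sample(files))
  s1 <- ingest_bulk(z1, g)
  s2 <- ingest_bulk(z2, g)
  attr(s1, "problems") <- attr(s2, "problems") <- NULL
  expect_identical(s1, s2)
})

test_that("ingest reports contract violations instead of dropping silently", {
  g <- small_geom()
  d <- withr::local_tempdir()
  write_pngs(d, "A", random_slices(4))
  write_pngs(d, "Bad", random_slices(3))  # wrong slice count
  expect_warning(stacks <- ingest_bulk(d, g), "geometry contract")
  expect_length(stacks, 1L)
  probs <- attr(stacks, "problems")
  expect_equal(probs$subject_id, "Bad")

  # gap in the slice sequence is an error naming subject and index
  d2 <- withr::local_tempdir()
  sl <- random_slices(3)
  png::writePNG(sl[[1]] / 255, file.path(d2, "A_000.png"))
  png::writePNG(sl[[2]] / 255, file.path(d2, "A_002.png"))
  expect_error(ingest_bulk(d2, g), "A.*missing slice index 1")

  # multi-channel PNG rejected
  g1 <- small_geom(n_slices = 1L)
  d3 <- withr::local_tempdir()
  rgb <- array(runif(16 * 16 * 3), c(16, 16, 3))
  png::writePNG(rgb, file.path(d3, "A_000.png"))
  expect_error(ingest_bulk(d3, g1), "multi-channel")
})

test_that("mask write/read round trip is bit-exact on random stacks", {
  g <- small_geom(n_slices = 2L, m = c(8L, 8L))
  set.seed(42)
  for (rep in 1:100) {
    m <- array_mask(sprintf("s%03d", rep),
                    array(rbinom(8 * 8 * 2, 1, runif(1)), c(8, 8, 2)), g)
    d <- tempfile("mask_")
    paths <- write_mask_stack(m, d)
    expect_length(paths, 2L)
    back <- read_mask_stack(d, m$subject_id, g)
    expect_identical(back$slices, m$slices)
    unlink(d, recursive = TRUE)
  }
})

test_that("mask decoding thresholds anti-aliased gray at 127", {
  g <- small_geom(n_slices = 1L, m = c(8L, 8L))
  d <- withr::local_tempdir()
  px <- matrix(0, 8, 8)
  px[3, 3] <- 200 / 255   # anti-aliased edit, decodes to foreground
  px[4, 4] <- 100 / 255   # below threshold, background
  png::writePNG(px, file.path(d, "A_000.png"))
  m <- read_mask_stack(d, "A", g)
  expect_equal(m$slices[[1]][3, 3], 1)
  expect_equal(m$slices[[1]][4, 4], 0)
})

test_that("empty mask writes all-black PNGs and zero volume downstream", {
  g <- small_geom(n_slices = 2L, m = c(8L, 8L))
  m <- array_mask("z", array(0, c(8, 8, 2)), g)
  d <- withr::local_tempdir()
  write_mask_stack(m, d)
  back <- read_mask_stack(d, "z", g)
  expect_equal(sum(unlist(back$slices)), 0)
  expect_equal(mask_volume(back)$volume_mm3, 0)
})

test_that("results CSV has the fixed header, deterministic order and exact volumes", {
  d <- withr::local_tempdir()
  path <- file.path(d, "volumes.csv")
  recs <- data.frame(
    subject_id = c("B", "A"), group = c("patient", "control"),
    sex = c("male", "female"), structure = "icv",
    n_positive_voxels = c(1000, 10), volume_mm3 = c(125, 1.25),
    volume_ml = c(0.125, 0.00125), normalized_volume_mm3 = NA,
    qc_flag = "ok", provenance = "predicted")
  write_results_csv(recs, path)
  lines <- readLines(path)
  expect_length(lines, 3L)
  expect_match(lines[1], "^subject_id,group,sex,structure,n_positive_voxels")
  back <- read.csv(path)
  expect_equal(back$subject_id, c("A", "B"))      # sorted
  expect_equal(back$volume_mm3[back$subject_id == "B"], 125)

  write_results_csv(NULL, path)
  expect_length(readLines(path), 1L)              # header only
})
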