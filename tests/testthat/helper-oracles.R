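# Independent brute-force oracles for the evaluation metrics. These are
# deliberately naive (explicit loops, hand-coded percentile interpolation)
# and share no code with the package implementation.

oracle_dice <- function(a, b) {
  inter <- sum(a == 1 & b == 1)
  na <- sum(a == 1); nb <- sum(b == 1)
  if (na + nb == 0) 1 else 2 * inter / (na + nb)
}

oracle_vs <- function(a, b) {
  na <- sum(a == 1); nb <- sum(b == 1)
  if (na + nb == 0) 1 else 1 - abs(na - nb) / (na + nb)
}

# Boundary voxels by explicit neighbour checks (6-connectivity).
oracle_boundary <- function(m) {
  d <- dim(m)
  rows <- vector("list", sum(m == 1))
  n <- 0L
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (m[i, j, k] != 1) next
    nb <- c(
      if (i > 1) m[i - 1, j, k] else 0, if (i < d[1]) m[i + 1, j, k] else 0,
      if (j > 1) m[i, j - 1, k] else 0, if (j < d[2]) m[i, j + 1, k] else 0,
      if (k > 1) m[i, j, k - 1] else 0, if (k < d[3]) m[i, j, k + 1] else 0)
    if (any(nb == 0)) {
      n <- n + 1L
      rows[[n]] <- c(i, j, k)
    }
  }
  do.call(rbind, rows[seq_len(n)])
}

# Linear-interpolation percentile between order statistics, hand-coded.
oracle_percentile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  if (n == 1L) return(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (lo >= n) return(x[n])
  x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}

oracle_hd95 <- function(a, b, geom, p = 0.95) {
  pa <- oracle_boundary(a)
  pb <- oracle_boundary(b)
  sc <- c(geom$dy, geom$dx, geom$dz)
  directed <- function(from, to) {
    to_sc <- t(to * rep(sc, each = nrow(to)))   # 3 x n, scaled to mm
    mins <- numeric(nrow(from))
    for (i in seq_len(nrow(from))) {
      diffs <- to_sc - from[i, ] * sc
      mins[i] <- sqrt(min(colSums(diffs * diffs)))
    }
    oracle_percentile(mins, p)
  }
  max(directed(pa, pb), directed(pb, pa))
}

# Build a ZIP archive with entries in the given order (no zip binary in the
# toolchain; python's zipfile module stands in).
make_zip <- function(zipfile, files) {
  script <- paste0(
    "import zipfile, sys, os\n",
    "z = zipfile.ZipFile(sys.argv[1], 'w')\n",
    "for f in sys.argv[2:]:\n",
    "    z.write(f, arcname=os.path.basename(f))\n",
    "z.close()\n")
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  status <- system2("python", c(sf, zipfile, files), stdout = FALSE)
  stopifnot(status == 0L)
  zipfile
}

# Random non-empty binary mask on a small grid.
random_mask_array <- function(d, p = NULL) {
  if (is.null(p)) p <- stats::runif(1, 0.05, 0.5)
  m <- array(stats::rbinom(prod(d), 1, p), d)
  if (sum(m) == 0) m[sample(length(m), 1)] <- 1
  m
}
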