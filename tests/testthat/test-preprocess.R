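coded_volume <- function() {
  # value encodes its own (x, y, z) so sub-volume corners are checkable
  a <- array(0, c(4, 4, 4))
  for (z in 0:3) for (y in 0:3) for (x in 0:3)
    a[y + 1, x + 1, z + 1] <- x + 10 * y + 100 * z
  image_volume(a, 26, "raw-float")
}

test_that("ROI extraction selects the half-open block in (x, y, z)", {
  v <- coded_volume()
  full <- extract_roi(v, roi_spec(c(0, 0, 0), c(4, 4, 4)))
  expect_identical(full$values, v$values)
  sub <- extract_roi(v, roi_spec(c(1, 1, 1), c(2, 2, 2)))
  expect_equal(dim(sub$values), c(2, 2, 2))
  expect_equal(sub$values[1, 1, 1], 1 + 10 + 100)  # parent (x,y,z) = (1,1,1)
  expect_equal(sub$voxel_size, v$voxel_size)
  expect_error(extract_roi(v, roi_spec(c(3, 0, 0), c(2, 4, 4))),
               "nearest in-bounds origin")
})

test_that("an (nx, ny, nz) ROI shape is stored as a (ny, nx, nz) array", {
  v <- image_volume(array(0, c(64, 64, 64)), 26, "raw-float")
  roi <- roi_spec(c(2, 2, 2), c(50, 40, 30))
  sub <- extract_roi(v, roi)
  # stored [y, x, z]: shape (ny, nx, nz) = (40, 50, 30)
  expect_equal(dim(sub$values), c(40, 50, 30))
})

test_that("auto ROI centres on the mask centroid and clamps at boundaries", {
  v <- image_volume(array(0, c(32, 32, 32)), 26, "raw-float")
  # centred spherical mask -> centred ROI
  ctr_mask <- array(FALSE, c(32, 32, 32))
  for (z in 1:32) for (x in 1:32) for (y in 1:32)
    ctr_mask[y, x, z] <- (x - 16.5)^2 + (y - 16.5)^2 + (z - 16.5)^2 <= 64
  roi <- auto_roi(v, ctr_mask, c(10, 10, 10))
  expect_equal(roi$origin, c(11L, 11L, 11L))  # (31 - 9) / 2 = 11
  # off-centre point mass: ROI centred at the centroid
  pt_mask <- array(FALSE, c(32, 32, 32)); pt_mask[5, 21, 9] <- TRUE
  roi <- auto_roi(v, pt_mask, c(4, 4, 4))
  expect_equal(roi$origin, c(19L, 3L, 7L))  # centroid (20,4,8) - 1.5, rounded
  # mask hugging a corner: clamped inside with a warning
  corner <- array(FALSE, c(32, 32, 32)); corner[1, 1, 1] <- TRUE
  expect_warning(roi <- auto_roi(v, corner, c(8, 8, 8)), "shifted")
  expect_equal(roi$origin, c(0L, 0L, 0L))
  expect_error(auto_roi(v, ctr_mask, c(40, 8, 8)), "exceeds volume")
})

test_that("8-bit scaling maps the range onto 0..255 with round-half-up", {
  v <- image_volume(array(c(0, 1, 2, 2, 1, 0, 0, 2), c(2, 2, 2)), 26,
                    "raw-float")
  q <- scale_to_8bit(v)
  expect_equal(sort(unique(as.vector(q$values))), c(0L, 128L, 255L))
  expect_equal(q$dtype_role, "quantised-8bit")
  # constant input: zero-range convention maps to all zeros
  qc <- scale_to_8bit(image_volume(array(5, c(2, 2, 2)), 26, "raw-float"))
  expect_true(all(qc$values == 0L))
  # extremes map exactly
  set.seed(4)
  r <- image_volume(array(rnorm(64), c(4, 4, 4)), 26, "raw-float")
  qr <- scale_to_8bit(r)
  expect_equal(qr$values[which.min(r$values)], 0L)
  expect_equal(qr$values[which.max(r$values)], 255L)
})

test_that("histogram equalisation follows the cdf mapping", {
  # 50/50 two-level volume maps to the full range {0, 255}
  v <- image_volume(array(c(10L, 200L), c(4, 4, 4)), 26, "quantised-8bit")
  e <- equalize_histogram(v)
  expect_setequal(unique(as.vector(e$values)), c(0L, 255L))
  # constant volume unchanged
  vc <- image_volume(array(7L, c(3, 3, 3)), 26, "quantised-8bit")
  expect_identical(equalize_histogram(vc)$values, vc$values)
  # equalised output's cumulative histogram deviates from uniform by at
  # most the mass of one input level, and the mapping is monotone
  set.seed(5)
  for (rep in 1:4) {
    raw <- array(sample(0:255, 1000, TRUE, prob = runif(256)^2), c(10, 10, 10))
    v <- image_volume(raw, 26, "quantised-8bit")
    e <- equalize_histogram(v)
    n <- length(raw)
    max_level_mass <- max(tabulate(raw + 1, 256)) / n
    cdf_out <- cumsum(tabulate(as.vector(e$values) + 1, 256)) / n
    uniform <- (1:256) / 256
    expect_lt(max(abs(cdf_out - uniform)), max_level_mass + 1 / 256)
    # monotone: sort order of levels preserved
    lut <- vapply(sort(unique(as.vector(raw))), function(l)
      e$values[which(raw == l)[1]], 0L)
    expect_true(all(diff(lut) >= 0))
  }
})

test_that("equalisation is idempotent up to one grey level", {
  set.seed(6)
  raw <- array(sample(0:255, 4096, TRUE, prob = runif(256)), c(16, 16, 16))
  e1 <- equalize_histogram(image_volume(raw, 26, "quantised-8bit"))
  e2 <- equalize_histogram(e1)
  expect_lte(max(abs(e2$values - e1$values)), 1)
})

test_that("median filter removes impulses and matches the gather-and-sort oracle", {
  a <- array(1, c(5, 5, 5)); a[3, 3, 3] <- 100
  v <- image_volume(a, 26, "raw-float")
  f <- median_filter(v, 3)
  expect_equal(f$values[3, 3, 3], 1)
  # constant volume unchanged
  vc <- image_volume(array(4, c(4, 4, 4)), 26, "raw-float")
  expect_equal(median_filter(vc)$values, vc$values)
  # random volume equals the naive per-voxel oracle everywhere
  set.seed(7)
  r <- array(rnorm(216), c(6, 6, 6))
  f <- median_filter(image_volume(r, 26, "raw-float"), 3)
  expect_equal(f$values, oracle_median_filter(r, 3))
  # 2-D input filters with a 2-D window
  m <- matrix(rnorm(49), 7, 7)
  f2 <- median_filter(image_volume(m, 26, "raw-float"), 3)
  expect_equal(f2$values, oracle_median_filter(array(m, c(7, 7, 1)), 3))
  expect_error(median_filter(vc, 4), "odd")
})

test_that("median filtering is value-preserving (never invents intensities)", {
  set.seed(8)
  r <- array(sample(c(0.5, 1.25, 7), 125, TRUE), c(5, 5, 5))
  f <- median_filter(image_volume(r, 26, "raw-float"), 3)
  expect_true(all(f$values %in% r))
})

test_that("the preprocessing chain records its order and yields 8-bit output", {
  set.seed(9)
  v <- image_volume(array(rnorm(1000), c(10, 10, 10)), 26, "raw-float")
  p1 <- preprocess_roi(v, order = "equalize-then-median")
  expect_equal(p1$dtype_role, "quantised-8bit")
  expect_true(any(grepl("equalised", p1$provenance)))
  expect_true(any(grepl("median filter", p1$provenance)))
  p2 <- preprocess_roi(v, order = "median-then-equalize")
  # both orders valid; they genuinely differ on noisy input
  expect_false(identical(p1$values, p2$values))
})
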