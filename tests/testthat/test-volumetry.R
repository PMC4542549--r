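# circle polygon with vertices at pixel-centre coordinates
circle_poly <- function(cx, cy, r, n = 180) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(x = cx + r * cos(th), y = cy + r * sin(th))
}

test_that("volume measurement is voxel count times voxel volume in mm^3", {
  mask <- structure(list(mask = array(FALSE, c(4, 4, 4)),
                         voxel_volume = (26e-3)^3), class = "volume_mask")
  expect_equal(measure_volume(mask), 0)
  # a million (26 um)^3 voxels measure 17.576 mm^3
  expect_equal(measure_volume(array(TRUE, c(100, 100, 100)),
                              voxel_volume = (26e-3)^3), 17.576)
})

test_that("a rasterised digital sphere recovers the analytic volume within 2%", {
  r <- 30
  n <- 2 * r + 9
  kf <- list()
  for (z in seq(0, n - 1, by = 2)) {
    rz2 <- r^2 - (z - (n - 1) / 2)^2
    if (rz2 < 4) next
    kf[[as.character(z)]] <- circle_poly((n - 1) / 2, (n - 1) / 2, sqrt(rz2))
  }
  cs <- contour_stack(kf, 2, c(n, n, n), voxel_size = 26)
  mask <- interpolate_contours(cs)
  measured <- measure_volume(mask)
  analytic <- 4 / 3 * pi * r^3 * (26e-3)^3
  expect_lt(abs(measured - analytic) / analytic, 0.02)
})

test_that("identical keyframes interpolate to identical intermediate slices", {
  poly <- circle_poly(15, 15, 8)
  cs <- contour_stack(list(`0` = poly, `10` = poly), 10, c(31, 31, 12))
  mask <- interpolate_contours(cs)
  for (z in 1:9)
    expect_identical(mask$mask[, , z + 1], mask$mask[, , 1])
  # slices outside the keyframe range stay empty
  expect_false(any(mask$mask[, , 12]))
})

test_that("signed-distance interpolation of concentric circles gives mid radii", {
  cs <- contour_stack(list(`0` = circle_poly(25, 25, 10),
                           `20` = circle_poly(25, 25, 20)),
                      20, c(51, 51, 21))
  mask <- interpolate_contours(cs)
  area10 <- sum(mask$mask[, , 11])  # slice z = 10: radius ~ 15
  r_eff <- sqrt(area10 / pi)
  expect_lt(abs(r_eff - 15), 1)
  # monotone nesting: every intermediate slice contains the small disc
  inner <- rasterise_disc <- matrix(FALSE, 51, 51)
  for (x in 0:50) for (y in 0:50)
    inner[y + 1, x + 1] <- (x - 25)^2 + (y - 25)^2 <= 9^2
  for (z in 0:20)
    expect_true(all(mask$mask[, , z + 1][inner]))
})

test_that("keyframe slices reproduce their rasterised polygons exactly", {
  p1 <- circle_poly(12, 14, 7); p2 <- circle_poly(14, 12, 9)
  cs <- contour_stack(list(`2` = p1, `8` = p2), 6, c(27, 27, 11))
  mask <- interpolate_contours(cs)
  r1 <- splenotex:::rasterise_polygon(p1, 27, 27)
  r2 <- splenotex:::rasterise_polygon(p2, 27, 27)
  expect_identical(mask$mask[, , 3], r1)
  expect_identical(mask$mask[, , 9], r2)
  expect_error(interpolate_contours(
    contour_stack(list(`0` = p1), 20, c(27, 27, 5))), "slice_step")
})

test_that("automatic keyframe contours recover phantom cross-sections", {
  sp <- tiny_phantom_spec(seed = 31)
  sp$noise_sd <- 0; sp$artifact_count <- 0L
  ph <- generate_spleen_phantom(sp)
  cs <- auto_contour_keyframes(ph$volume, slice_step = 8)
  truth <- truth_mask(ph$truth)
  for (nm in names(cs$keyframes)) {
    z <- as.integer(nm) + 1
    poly_area <- sum(splenotex:::rasterise_polygon(cs$keyframes[[nm]], 48, 48))
    true_area <- sum(truth[, , z])
    expect_lt(abs(poly_area - true_area) / true_area, 0.03)
  }
})

test_that("bright streak artifacts are excluded from contours by the intensity cap", {
  sp <- tiny_phantom_spec(seed = 32)
  sp$noise_sd <- 0; sp$artifact_count <- 0L
  ph <- generate_spleen_phantom(sp)
  v <- ph$volume$values
  # inject a horizontal streak through the organ mid-slice, far brighter
  # than tissue
  zmid <- 24
  v[20, , zmid] <- 10
  vol <- image_volume(v, 26, "raw-float")
  cs <- suppressWarnings(  # terminal slices hold too few voxels to trace
    auto_contour_keyframes(vol, slice_step = 1, artifact_percentile = 97))
  kf <- cs$keyframes[[as.character(zmid - 1)]]
  expect_false(is.null(kf))
  m <- splenotex:::rasterise_polygon(kf, 48, 48)
  # streak voxels outside the organ must not be captured
  outside <- !truth_mask(ph$truth)[20, , zmid]
  expect_false(any(m[20, outside]))
})

test_that("end-to-end volumetry error shrinks as the keyframe step shrinks", {
  # what governs accuracy is the keyframe spacing relative to the organ
  # height; an elongated phantom (~130 occupied slices) probes spacings
  # of ~15%, 7.5% and 4% of the height
  sp <- tiny_phantom_spec(seed = 33, grid_shape = c(48, 48, 144),
                          spleen_semi_axes = c(19, 16, 66))
  ph <- generate_spleen_phantom(sp)
  truth_mm3 <- ph$truth$spleen_voxel_count * (26e-3)^3
  err <- vapply(c(20, 10, 5), function(step) {
    m <- suppressWarnings(measure_sample_volume(ph$volume, slice_step = step))
    abs(m$volume_mm3 - truth_mm3) / truth_mm3
  }, 0)
  expect_true(all(diff(err) < 0))
  expect_lt(err[2], 0.05)
  expect_lt(err[3], 0.02)
})

test_that("contour stacks round-trip through JSON", {
  p1 <- circle_poly(12, 14, 7); p2 <- circle_poly(14, 12, 9)
  cs <- contour_stack(list(`2` = p1, `8` = p2), 6, c(27, 27, 11),
                      voxel_size = 10.4)
  f <- withr::local_tempfile(fileext = ".json")
  write_contours(cs, f)
  back <- read_contours(f)
  expect_equal(back$volume_shape, cs$volume_shape)
  expect_equal(back$voxel_size, 10.4)
  expect_equal(back$keyframes[["2"]], p1, tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(interpolate_contours(back)$mask,
                   interpolate_contours(cs)$mask)
})
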