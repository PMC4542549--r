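test_that("displacement offsets follow d cos/sin with round-half-away", {
  o <- displacement_offsets(1, 0)
  expect_equal(c(o$dx, o$dy, o$dz), c(1, 0, 1))
  o <- displacement_offsets(1, 90)
  expect_equal(c(o$dx, o$dy, o$dz), c(0, 1, 0))
  o <- displacement_offsets(2, 45)  # round(1.414) = 1
  expect_equal(c(o$dx, o$dy, o$dz), c(1, 1, 1))
  o <- displacement_offsets(1, 45)  # 0.707 rounds half-away to 1
  expect_equal(c(o$dx, o$dy, o$dz), c(1, 1, 1))
  o <- displacement_offsets(2, 135)  # negative dx = dz
  expect_equal(c(o$dx, o$dy, o$dz), c(-1, 1, -1))
  expect_error(displacement_offsets(0, 0), "positive integer")
})

test_that("chessboard convention uses full +/- d on both axes at diagonals", {
  o <- displacement_offsets(3, 45, convention = "chessboard")
  expect_equal(c(o$dx, o$dy), c(3, 3))
  o <- displacement_offsets(3, 135, convention = "chessboard")
  expect_equal(c(o$dx, o$dy), c(-3, 3))
  # axis-aligned angles unaffected
  o <- displacement_offsets(3, 0, convention = "chessboard")
  expect_equal(c(o$dx, o$dy), c(3, 0))
})

test_that("2-D GLCM matches enumeration on small cases", {
  # constant image: all mass at (v, v)
  g <- compute_glcm2d(matrix(5L, 4, 4), 1, 0, Ng = 8)
  expect_equal(g$P[6, 6], 1)
  expect_equal(sum(g$P), 1)
  # 2x2 image [[0,1],[0,1]] at d=1, theta=0: both pairs are (0, 1)
  m <- cbind(c(0L, 0L), c(1L, 1L))
  g <- compute_glcm2d(m, 1, 0, Ng = 2)
  expect_equal(g$valid_pair_count, 2)
  expect_equal(g$P[1, 2], 1)
  expect_error(compute_glcm2d(m, 1, 0, Ng = 1), "Ng")
})

test_that("2-D GLCM equals the brute-force double-loop oracle", {
  set.seed(11)
  for (theta in c(0, 45, 90, 135)) for (d in c(1, 2, 3)) {
    m <- matrix(sample(0:7, 64, replace = TRUE), 8, 8)
    g <- compute_glcm2d(m, d, theta, Ng = 8)
    off <- displacement_offsets(d, theta)
    o <- oracle_glcm2(m, off$dx, off$dy, 8)
    expect_equal(g$P, o$P, info = sprintf("d=%d theta=%g", d, theta))
    expect_equal(g$valid_pair_count, o$n)
  }
})

test_that("3-D GLCM equals the brute-force triple-loop oracle exactly", {
  set.seed(12)
  dims_list <- list(c(4, 4, 3), c(6, 5, 4), c(10, 10, 6))
  for (dims in dims_list) for (theta in c(0, 45, 90, 135)) for (d in c(1, 2)) {
    a <- random_levels(dims, 8)
    g <- compute_glcm3d(a, d, theta, Ng = 8)
    off <- displacement_offsets(d, theta)
    o <- oracle_glcm3(a, off$dx, off$dy, off$dz, 8)
    expect_equal(dense_from_entries(g), o$P,
                 info = sprintf("dims=%s d=%d theta=%g",
                                paste(dims, collapse = "x"), d, theta))
    expect_equal(g$valid_triple_count, o$n)
  }
})

test_that("3-D GLCM on the coordinate-coded cube has the two expected triples", {
  g <- compute_glcm3d(coord_cube(), 1, 0, Ng = 8)
  expect_equal(g$valid_triple_count, 2)
  expect_equal(g$entries$p, c(0.5, 0.5))
  expect_equal(g$entries[, c("i", "j", "k")],
               data.frame(i = c(0, 2), j = c(1, 3), k = c(4, 6)),
               ignore_attr = TRUE)
})

test_that("at theta = 90 all 3-D mass lies on j = k", {
  set.seed(13)
  a <- random_levels(c(6, 6, 5), 8)
  for (d in 1:3) {
    g <- compute_glcm3d(a, d, 90, Ng = 8)
    expect_true(all(g$entries$j == g$entries$k))
  }
})

test_that("constant volume gives diagonal mass, zero contrast, unit homogeneity", {
  g <- compute_glcm3d(array(3L, c(4, 4, 4)), 1, 45, Ng = 8)
  expect_equal(g$entries, data.frame(i = 3, j = 3, k = 3, p = 1),
               ignore_attr = TRUE)
  expect_equal(contrast3d(g), 0)
  expect_equal(homogeneity3d(g), 1)
})

test_that("features match direct substitution and brute-force sums", {
  # single off-diagonal cell: contrast (0-1)^2+(0-2)^2+(1-2)^2 = 6
  g <- structure(list(entries = data.frame(i = 0, j = 1, k = 2, p = 1),
                      Ng = 8L, d = 1L, theta = 0,
                      valid_triple_count = 1L), class = "glcm3")
  expect_equal(contrast3d(g), 6)
  expect_equal(homogeneity3d(g), 1 / 7)
  # random sparse tensors against the dense triple-loop oracle
  set.seed(14)
  for (rep in 1:5) {
    a <- random_levels(c(7, 6, 4), 6)
    gg <- compute_glcm3d(a, 2, 45, Ng = 6)
    expected <- oracle_features3(dense_from_entries(gg))
    expect_equal(contrast3d(gg), expected[["contrast"]])
    expect_equal(homogeneity3d(gg), expected[["homogeneity"]])
  }
  # unnormalised input is rejected
  bad <- g; bad$entries$p <- 0.5
  expect_error(contrast3d(bad), "normalis")
})

test_that("2-D features: substitution values and cross-implementation check", {
  mk2 <- function(cells, Ng = 4) {
    P <- matrix(0, Ng, Ng)
    for (r in seq_len(nrow(cells))) P[cells[r, 1] + 1, cells[r, 2] + 1] <- cells[r, 3]
    structure(list(P = P, Ng = Ng, d = 1L, theta = 0, valid_pair_count = 1L),
              class = "glcm2")
  }
  g <- mk2(cbind(0, 2, 1))
  expect_equal(contrast2d(g), 4)
  expect_equal(homogeneity2d(g), 1 / 5)
  diag_g <- mk2(cbind(c(0, 3), c(0, 3), c(0.5, 0.5)))
  expect_equal(contrast2d(diag_g), 0)
  expect_equal(homogeneity2d(diag_g), 1)
  # independent elementwise-sum reference on a random normalised matrix
  set.seed(15)
  P <- matrix(runif(64), 8, 8); P <- P / sum(P)
  g <- structure(list(P = P, Ng = 8L, d = 1L, theta = 0,
                      valid_pair_count = 100L), class = "glcm2")
  con_ref <- 0; hom_ref <- 0
  for (i in 0:7) for (j in 0:7) {
    con_ref <- con_ref + P[i + 1, j + 1] * (i - j)^2
    hom_ref <- hom_ref + P[i + 1, j + 1] / (1 + (i - j)^2)
  }
  expect_equal(contrast2d(g), con_ref)
  expect_equal(homogeneity2d(g), hom_ref)
})

test_that("every GLCM is non-negative and sums to one", {
  set.seed(16)
  for (rep in 1:8) {
    a <- random_levels(c(9, 8, 5), 8)
    d <- sample(1:3, 1); th <- sample(c(0, 45, 90, 135), 1)
    g3 <- compute_glcm3d(a, d, th, Ng = 8)
    expect_true(all(g3$entries$p >= 0))
    expect_equal(sum(g3$entries$p), 1)
    g2 <- compute_glcm2d(a[, , 1], d, th, Ng = 8)
    expect_true(all(g2$P >= 0))
    expect_equal(sum(g2$P), 1)
    ga <- average_over_angles(a, d, Ng = 8)
    expect_equal(sum(ga$entries$p), 1)
  }
})

test_that("angle averaging equals the explicit mean of per-angle matrices", {
  set.seed(17)
  a <- random_levels(c(10, 10, 6), 8)
  ga <- average_over_angles(a, 2, c(0, 45, 90, 135), Ng = 8)
  dense <- Reduce(`+`, lapply(c(0, 45, 90, 135), function(th)
    dense_from_entries(compute_glcm3d(a, 2, th, Ng = 8)))) / 4
  expect_equal(dense_from_entries(ga), dense)
  # single angle: identical to the direct computation
  g1 <- average_over_angles(a, 2, 45, Ng = 8)
  expect_equal(dense_from_entries(g1),
               dense_from_entries(compute_glcm3d(a, 2, 45, Ng = 8)))
})

test_that("degenerate-angle law: 3-D contrast at 90 deg is twice the 2-D contrast", {
  # with dx = dz = 0 the second and third points coincide, so the triple
  # weight collapses to 2 (i - j)^2
  set.seed(18)
  a <- random_levels(c(8, 8, 4), 8)
  g3 <- compute_glcm3d(a, 2, 90, Ng = 8)
  # corresponding two-point distribution over the same positions
  off <- displacement_offsets(2, 90)
  o2 <- oracle_glcm3(a, off$dx, off$dy, off$dz, 8)
  two_point <- apply(o2$P, c(1, 2), sum)
  idx <- 0:7
  con2 <- sum(two_point * outer(idx, idx, function(i, j) (i - j)^2))
  expect_equal(contrast3d(g3), 2 * con2)
})

test_that("contrast and homogeneity move oppositely with index separation", {
  sep_glcm <- function(delta, Ng = 16) {
    structure(list(entries = data.frame(i = 0, j = delta, k = delta, p = 1),
                   Ng = Ng, d = 1L, theta = 0, valid_triple_count = 1L),
              class = "glcm3")
  }
  cons <- vapply(1:5, function(s) contrast3d(sep_glcm(s)), 0)
  homs <- vapply(1:5, function(s) homogeneity3d(sep_glcm(s)), 0)
  expect_true(all(diff(cons) > 0))
  expect_true(all(diff(homs) < 0))
})

test_that("grey-level reversal leaves contrast and homogeneity unchanged", {
  set.seed(19)
  a <- random_levels(c(8, 7, 5), 8)
  rev_a <- 7L - a
  for (th in c(0, 45)) {
    g <- compute_glcm3d(a, 2, th, Ng = 8)
    gr <- compute_glcm3d(rev_a, 2, th, Ng = 8)
    expect_equal(contrast3d(gr), contrast3d(g))
    expect_equal(homogeneity3d(gr), homogeneity3d(g))
  }
})

test_that("texture curves stream the same values as explicit matrix averaging", {
  set.seed(20)
  a <- random_levels(c(12, 12, 8), 16)
  cu <- texture_curve(a, "contrast", "3D", d_range = 1:4, Ng = 16)
  hu <- texture_curve(a, "homogeneity", "3D", d_range = 1:4, Ng = 16)
  for (q in 1:4) {
    g <- average_over_angles(a, q, Ng = 16)
    expect_equal(cu$values[q], contrast3d(g))
    expect_equal(hu$values[q], homogeneity3d(g))
  }
  both <- texture_curves(a, "3D", d_range = 1:4, Ng = 16)
  expect_equal(both$contrast$values, cu$values)
  expect_equal(both$homogeneity$values, hu$values)
})

test_that("curves on constant volumes are flat at the feature's degenerate value", {
  a <- array(7L, c(6, 6, 6))
  cu <- texture_curve(a, "contrast", "3D", d_range = 1:3, Ng = 8)
  expect_equal(cu$values, rep(0, 3))
  hu <- texture_curve(a, "homogeneity", "3D", d_range = 1:3, Ng = 8)
  expect_equal(hu$values, rep(1, 3))
})

test_that("smaller features move the 2-D contrast peak to smaller displacements", {
  small <- generate_feature_image(
    feature_image_spec(image_size = 120, ln_radius = 8, mz_thickness = 2))
  large <- generate_feature_image(
    feature_image_spec(image_size = 120, ln_radius = 18, mz_thickness = 2))
  pk <- function(img) find_peak(
    texture_curve(img, "contrast", "2D", 1:40, Ng = 256, slice_index = 1))
  expect_lt(pk(small)$displacement, pk(large)$displacement)
})

test_that("peak finding refines interior maxima quadratically", {
  # symmetric three-point peak
  p <- find_peak(make_curve(9:11, c(1, 3, 1)))
  expect_equal(p$displacement, 10)
  expect_false(p$at_boundary)
  # exact samples of a parabola with vertex at 18.2
  d <- 15:22
  p <- find_peak(make_curve(d, -(d - 18.2)^2))
  expect_equal(p$displacement, 18.2, tolerance = 1e-9)
  # strictly increasing curve peaks at the boundary, unrefined
  p <- find_peak(make_curve(1:5, 1:5))
  expect_true(p$at_boundary)
  expect_equal(p$displacement, 5)
  expect_error(find_peak(make_curve(1:5, rep(2, 5))), "no unique peak")
})
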