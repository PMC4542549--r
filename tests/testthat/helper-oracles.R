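# Independent brute-force oracles and small fixtures shared by the
# suite. The oracles enumerate positions one by one and never share code
# with the package's vectorised/streamed implementations.

# dense three-point co-occurrence tensor by explicit triple loop over
# 0-based reference positions; returns list(P = Ng^3 array, n = count)
oracle_glcm3 <- function(a, dx, dy, dz, Ng) {
  ny <- dim(a)[1]; nx <- dim(a)[2]; nz <- dim(a)[3]
  P <- array(0, rep(Ng, 3)); n <- 0L
  for (x in 0:(nx - 1)) for (y in 0:(ny - 1)) for (z in 0:(nz - 1)) {
    x2 <- x + dx; y2 <- y + dy; z3 <- z + dz
    if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z3 < 0 || z3 >= nz)
      next
    i <- a[y + 1, x + 1, z + 1]
    j <- a[y2 + 1, x2 + 1, z + 1]
    k <- a[y2 + 1, x + 1, z3 + 1]
    P[i + 1, j + 1, k + 1] <- P[i + 1, j + 1, k + 1] + 1
    n <- n + 1L
  }
  list(P = if (n > 0) P / n else P, n = n)
}

# dense pair co-occurrence matrix by explicit double loop
oracle_glcm2 <- function(m, dx, dy, Ng) {
  ny <- nrow(m); nx <- ncol(m)
  P <- matrix(0, Ng, Ng); n <- 0L
  for (x in 0:(nx - 1)) for (y in 0:(ny - 1)) {
    x2 <- x + dx; y2 <- y + dy
    if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny) next
    P[m[y + 1, x + 1] + 1, m[y2 + 1, x2 + 1] + 1] <-
      P[m[y + 1, x + 1] + 1, m[y2 + 1, x2 + 1] + 1] + 1
    n <- n + 1L
  }
  list(P = if (n > 0) P / n else P, n = n)
}

# contrast/homogeneity of a dense 3-way tensor by triple loop
oracle_features3 <- function(P) {
  Ng <- dim(P)[1]; con <- 0; hom <- 0
  for (i in 0:(Ng - 1)) for (j in 0:(Ng - 1)) for (k in 0:(Ng - 1)) {
    p <- P[i + 1, j + 1, k + 1]
    if (p == 0) next
    w <- (i - j)^2 + (i - k)^2 + (j - k)^2
    con <- con + p * w
    hom <- hom + p / (1 + w)
  }
  c(contrast = con, homogeneity = hom)
}

# per-voxel gather-and-sort median with truncated windows and the lower
# median for even window sizes
oracle_median_filter <- function(a, width) {
  h <- width %/% 2
  ny <- dim(a)[1]; nx <- dim(a)[2]; nz <- dim(a)[3]
  hz <- if (nz > 1) h else 0
  out <- array(0, dim(a))
  for (z in 1:nz) for (x in 1:nx) for (y in 1:ny) {
    w <- a[max(1, y - h):min(ny, y + h),
           max(1, x - h):min(nx, x + h),
           max(1, z - hz):min(nz, z + hz)]
    s <- sort(as.vector(w))
    out[y, x, z] <- s[(length(s) + 1) %/% 2]
  }
  out
}

# sparse glcm3 -> dense array (independent of as.array.glcm3)
dense_from_entries <- function(g) {
  P <- array(0, rep(g$Ng, 3))
  for (r in seq_len(nrow(g$entries)))
    P[g$entries$i[r] + 1, g$entries$j[r] + 1, g$entries$k[r] + 1] <-
      g$entries$p[r]
  P
}

# small, fast phantom used across volumetry/pipeline tests
tiny_phantom_spec <- function(seed = 42, ...) {
  args <- modifyList(
    list(grid_shape = c(48, 48, 48), spleen_semi_axes = c(19, 16, 21),
         nodule_count = 5, nodule_radius_mean = 3.5,
         nodule_radius_sd = 0.5, mz_thickness = 1.5,
         vessel_count = 2, vessel_radius = 1, noise_sd = 0.03,
         artifact_count = 1, seed = seed),
    list(...))
  do.call(phantom_spec, args)
}

# coordinate-coded 2x2x2 volume I = x + 2y + 4z
coord_cube <- function() {
  a <- array(0L, c(2, 2, 2))
  for (z in 0:1) for (y in 0:1) for (x in 0:1)
    a[y + 1, x + 1, z + 1] <- x + 2L * y + 4L * z
  a
}

random_levels <- function(dims, Ng) {
  array(sample(0:(Ng - 1), prod(dims), replace = TRUE), dims)
}

make_curve <- function(d, v, metric = "contrast") {
  structure(list(sample_id = "s", metric = metric, dimensionality = "3D",
                 displacements = as.integer(d), values = v,
                 slice_index = NA_integer_),
            class = "texture_curve")
}
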