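# Grey-level co-occurrence texture.
#
# The standard 2-D GLCM counts ordered grey-level pairs at a fixed pixel
# displacement. To capture 3-D structure, the co-occurrence is extended
# to a third reference point displaced in z: for a reference voxel at
# (x, y, z), the second point sits at (x + dx, y + dy, z) and the third
# at (x, y + dy, z + dz), with
#
#   dx = dz = round(d cos(theta)),  dy = round(d sin(theta)).
#
# The resulting three-way tensor P(i, j, k), normalised over the valid
# triples, yields the texture features
#
#   contrast    = sum P(i,j,k) [ (i-j)^2 + (i-k)^2 + (j-k)^2 ]
#   homogeneity = sum P(i,j,k) / [ 1 + (i-j)^2 + (i-k)^2 + (j-k)^2 ].
#
# Matrices are unsymmetrised; triples falling outside the volume are
# skipped, never padded. Both features are linear in P, so computing a
# feature of the angle-averaged matrix equals averaging per-angle
# feature values; the displacement-sweep code exploits this to stream
# over triples without materialising the Ng^3 tensor.

#' Displacement offsets for a pixel displacement and angle
#'
#' Converts a displacement `d` (pixels) and angle `theta` (degrees) into
#' integer voxel offsets with `dx = dz = round(d cos(theta))` and
#' `dy = round(d sin(theta))`, rounding half away from zero. The
#' `"chessboard"` convention instead uses the full `+/- d` on both axes
#' at the diagonal angles (45 and 135 degrees).
#'
#' @param d positive integer pixel displacement.
#' @param theta angle in degrees (0, 45, 90, 135 by default usage;
#'   arbitrary angles are allowed).
#' @param convention `"round"` (default) or `"chessboard"`.
#' @return An object of class `offset3` with fields `dx`, `dy`, `dz`,
#'   `d`, `theta`.
#' @export
displacement_offsets <- function(d, theta, convention = c("round", "chessboard")) {
  convention <- match.arg(convention)
  if (length(d) != 1L || d != floor(d) || d < 1)
    stop("'d' must be a positive integer (self-co-occurrence at d = 0 is meaningless)")
  ct <- cospi(theta / 180); st <- sinpi(theta / 180)
  if (convention == "chessboard" && theta %% 90 != 0) {
    dx <- d * sign(round(ct * 1e8)); dy <- d * sign(round(st * 1e8))
  } else {
    dx <- round_half_away(d * ct); dy <- round_half_away(d * st)
  }
  structure(list(dx = as.integer(dx), dy = as.integer(dy),
                 dz = as.integer(dx), d = as.integer(d), theta = theta),
            class = "offset3")
}

#' @export
print.offset3 <- function(x, ...) {
  cat(sprintf("<offset3> d=%d theta=%g deg -> (dx,dy,dz) = (%d,%d,%d)\n",
              x$d, x$theta, x$dx, x$dy, x$dz))
  invisible(x)
}

# requantise 8-bit levels 0..255 to 0..Ng-1
# Values already within 0..Ng-1 are used as levels directly; wider 8-bit
# ranges are rebinned linearly from 256 levels down to Ng.
quantise_levels <- function(v, Ng) {
  if (Ng == 256L || max(v) <= Ng - 1) return(v)
  out <- pmin(floor(v * (Ng / 256)), Ng - 1)
  dim(out) <- dim(v)
  out
}

# values of an image_volume (or plain array/matrix), checked quantised
quantised_values <- function(x, Ng) {
  v <- if (inherits(x, "image_volume")) {
    if (x$dtype_role != "quantised-8bit")
      stop("GLCM computation requires a quantised-8bit volume; ",
           "run scale_to_8bit() first")
    x$values
  } else x
  if (min(v) < 0 || max(v) > 255) stop("grey values must lie in [0, 255]")
  quantise_levels(v, Ng)
}

# ordered grey-level pairs of one slice at one offset; NULL if no pair fits
glcm2_pairs <- function(m, off) {
  ny <- nrow(m); nx <- ncol(m)
  xr <- max(1, 1 - off$dx):min(nx, nx - off$dx)
  yr <- max(1, 1 - off$dy):min(ny, ny - off$dy)
  if (xr[1] > xr[length(xr)] || yr[1] > yr[length(yr)]) return(NULL)
  if (length(xr) * length(yr) == 0) return(NULL)
  list(i = as.vector(m[yr, xr]),
       j = as.vector(m[yr + off$dy, xr + off$dx]))
}

# grey-level triples of a volume at one offset; NULL if no triple fits
glcm3_triples <- function(a, off) {
  ny <- dim(a)[1]; nx <- dim(a)[2]; nz <- dim(a)[3]
  xlo <- max(1, 1 - off$dx); xhi <- min(nx, nx - off$dx)
  ylo <- max(1, 1 - off$dy); yhi <- min(ny, ny - off$dy)
  zlo <- max(1, 1 - off$dz); zhi <- min(nz, nz - off$dz)
  if (xlo > xhi || ylo > yhi || zlo > zhi) return(NULL)
  xr <- xlo:xhi; yr <- ylo:yhi; zr <- zlo:zhi
  list(i = as.vector(a[yr, xr, zr, drop = FALSE]),
       j = as.vector(a[yr + off$dy, xr + off$dx, zr, drop = FALSE]),
       k = as.vector(a[yr + off$dy, xr, zr + off$dz, drop = FALSE]))
}

#' Compute a 2-D grey-level co-occurrence matrix
#'
#' Ordered (unsymmetrised) pair counts of `I(x, y)` against
#' `I(x + dx, y + dy)` over all in-bounds positions of one slice,
#' normalised by the number of valid pairs.
#'
#' @param slice 2-D [image_volume()], matrix of grey levels in 0..255,
#'   or a 3-D volume with a single slice.
#' @param d,theta displacement and angle (degrees).
#' @param Ng number of grey levels (levels 0..255 are requantised to
#'   `Ng` bins when `Ng < 256`).
#' @param convention offset convention, see [displacement_offsets()].
#' @return An object of class `glcm2`: normalised `Ng x Ng` matrix `P`
#'   (rows = reference level i, columns = level j), plus offset metadata
#'   and `valid_pair_count`.
#' @export
compute_glcm2d <- function(slice, d, theta, Ng = 256L,
                           convention = c("round", "chessboard")) {
  if (Ng < 2) stop("'Ng' must be >= 2")
  off <- displacement_offsets(d, theta, match.arg(convention))
  m <- quantised_values(slice, Ng)
  if (length(dim(m)) == 3L) {
    if (dim(m)[3] != 1L) stop("compute_glcm2d expects a single 2-D slice")
    m <- m[, , 1]
  }
  pr <- glcm2_pairs(m, off)
  if (is.null(pr)) stop("no valid pairs for d=", d, ", theta=", theta)
  counts <- tabulate(pr$i + Ng * pr$j + 1L, nbins = Ng * Ng)
  n <- length(pr$i)
  structure(list(P = matrix(counts / n, Ng, Ng), Ng = as.integer(Ng),
                 d = off$d, theta = off$theta, offset = off,
                 valid_pair_count = n),
            class = "glcm2")
}

#' Compute the three-reference-point 3-D GLCM
#'
#' For every in-bounds reference voxel `(x, y, z)` the grey levels
#' `i = I(x, y, z)`, `j = I(x + dx, y + dy, z)` and
#' `k = I(x, y + dy, z + dz)` are counted into a three-way tensor,
#' normalised by the number of valid triples. Triples with any point
#' outside the volume are skipped. The tensor is held sparsely as the
#' occupied cells `(i, j, k, p)`.
#'
#' Note that at `theta = 90` degrees `dx = dz = 0`, so the second and
#' third points coincide and all mass lies on `j = k`.
#'
#' @inheritParams compute_glcm2d
#' @param volume 3-D quantised [image_volume()] or array.
#' @return An object of class `glcm3`: data frame `entries` with columns
#'   `i`, `j`, `k`, `p` (levels 0-based, `sum(p) == 1`), plus `Ng`,
#'   offset metadata and `valid_triple_count`.
#' @export
compute_glcm3d <- function(volume, d, theta, Ng = 256L,
                           convention = c("round", "chessboard")) {
  if (Ng < 2) stop("'Ng' must be >= 2")
  off <- displacement_offsets(d, theta, match.arg(convention))
  a <- quantised_values(volume, Ng)
  if (length(dim(a)) != 3L) stop("compute_glcm3d expects a 3-D volume")
  if (abs(off$dz) > 0 && dim(a)[3] <= abs(off$dz))
    stop("no valid triples: volume thinner than |dz| = ", abs(off$dz))
  tr <- glcm3_triples(a, off)
  if (is.null(tr)) stop("no valid triples for d=", d, ", theta=", theta)
  glcm3_from_triples(tr, Ng, off)
}

glcm3_from_triples <- function(tr, Ng, off, angles = off$theta) {
  code <- tr$i + Ng * (tr$j + Ng * tr$k)
  r <- rle(sort(code))
  n <- length(tr$i)
  ent <- data.frame(i = r$values %% Ng,
                    j = (r$values %/% Ng) %% Ng,
                    k = r$values %/% (Ng * Ng),
                    p = r$lengths / n)
  structure(list(entries = ent, Ng = as.integer(Ng),
                 d = off$d, theta = angles, offset = off,
                 valid_triple_count = n),
            class = "glcm3")
}

#' @export
print.glcm3 <- function(x, ...) {
  cat(sprintf("<glcm3> Ng=%d, d=%d, theta={%s}, %d occupied cells, %d triples\n",
              x$Ng, x$d, paste(x$theta, collapse = ","),
              nrow(x$entries), x$valid_triple_count))
  invisible(x)
}

#' @export
print.glcm2 <- function(x, ...) {
  cat(sprintf("<glcm2> Ng=%d, d=%d, theta=%g, %d pairs\n",
              x$Ng, x$d, x$theta, x$valid_pair_count))
  invisible(x)
}

#' Dense array view of a sparse 3-D GLCM
#'
#' @param x a `glcm3`.
#' @param ... unused.
#' @return An `Ng x Ng x Ng` array with `P[i+1, j+1, k+1]`.
#' @export
as.array.glcm3 <- function(x, ...) {
  a <- array(0, rep(x$Ng, 3))
  a[cbind(x$entries$i, x$entries$j, x$entries$k) + 1L] <- x$entries$p
  a
}

#' Angle-averaged co-occurrence matrix
#'
#' Arithmetic mean of the per-angle normalised matrices at one
#' displacement. Angles with no valid triples (pairs) are excluded with
#' a warning; if all are excluded, an error is raised.
#'
#' @param volume quantised [image_volume()] or array; a single-slice
#'   input yields an angle-averaged 2-D GLCM.
#' @param d pixel displacement.
#' @param angles angles in degrees.
#' @param Ng number of grey levels.
#' @param convention offset convention.
#' @return A `glcm3` (or `glcm2` for a slice) whose `theta` records the
#'   averaged angles.
#' @export
average_over_angles <- function(volume, d, angles = c(0, 45, 90, 135),
                                Ng = 256L,
                                convention = c("round", "chessboard")) {
  convention <- match.arg(convention)
  if (!length(angles)) stop("at least one angle is required")
  v <- if (inherits(volume, "image_volume")) volume$values else volume
  two_d <- is.matrix(v) || dim(v)[3] == 1L
  gs <- list(); used <- numeric()
  for (th in angles) {
    g <- tryCatch(
      if (two_d) compute_glcm2d(volume, d, th, Ng, convention)
      else compute_glcm3d(volume, d, th, Ng, convention),
      error = function(e) e)
    if (inherits(g, "error")) {
      warning("angle ", th, " excluded: ", conditionMessage(g))
    } else {
      gs[[length(gs) + 1L]] <- g; used <- c(used, th)
    }
  }
  if (!length(gs)) stop("no valid triples at any angle for d = ", d)
  if (two_d) {
    P <- Reduce(`+`, lapply(gs, `[[`, "P")) / length(gs)
    out <- gs[[1]]
    out$P <- P
    out$theta <- used
    out$valid_pair_count <- sum(vapply(gs, `[[`, 0, "valid_pair_count"))
    out
  } else {
    ent <- do.call(rbind, lapply(gs, `[[`, "entries"))
    ent$p <- ent$p / length(gs)
    code <- ent$i + gs[[1]]$Ng * (ent$j + gs[[1]]$Ng * ent$k)
    agg <- rowsum(ent$p, code)
    codes <- as.numeric(rownames(agg))
    Ng <- gs[[1]]$Ng
    out <- gs[[1]]
    out$entries <- data.frame(i = codes %% Ng, j = (codes %/% Ng) %% Ng,
                              k = codes %/% (Ng * Ng), p = as.vector(agg))
    out$theta <- used
    out$valid_triple_count <- sum(vapply(gs, `[[`, 0, "valid_triple_count"))
    out
  }
}

check_normalised <- function(p, what) {
  if (abs(sum(p) - 1) > 1e-8)
    stop(what, " is not normalised (entries must sum to 1)")
}

glcm3_weights <- function(e) (e$i - e$j)^2 + (e$i - e$k)^2 + (e$j - e$k)^2

#' 3-D GLCM contrast
#'
#' `sum P(i,j,k) [(i-j)^2 + (i-k)^2 + (j-k)^2]`. Zero exactly when all
#' mass lies on the diagonal i = j = k.
#'
#' @param glcm a normalised `glcm3`.
#' @return Non-negative scalar.
#' @export
contrast3d <- function(glcm) {
  stopifnot(inherits(glcm, "glcm3"))
  check_normalised(glcm$entries$p, "GLCM3")
  sum(glcm$entries$p * glcm3_weights(glcm$entries))
}

#' 3-D GLCM homogeneity
#'
#' `sum P(i,j,k) / (1 + (i-j)^2 + (i-k)^2 + (j-k)^2)`, in (0, 1]; equals
#' 1 exactly when all mass lies on the diagonal.
#'
#' @param glcm a normalised `glcm3`.
#' @return Scalar in (0, 1].
#' @export
homogeneity3d <- function(glcm) {
  stopifnot(inherits(glcm, "glcm3"))
  check_normalised(glcm$entries$p, "GLCM3")
  sum(glcm$entries$p / (1 + glcm3_weights(glcm$entries)))
}

#' 2-D GLCM contrast and homogeneity
#'
#' The standard two-point specialisations `sum P(i,j) (i-j)^2` and
#' `sum P(i,j) / (1 + (i-j)^2)` on the unsymmetrised, normalised matrix.
#'
#' @param glcm a normalised `glcm2`.
#' @return Scalar feature value.
#' @export
contrast2d <- function(glcm) {
  stopifnot(inherits(glcm, "glcm2"))
  check_normalised(glcm$P, "GLCM2")
  idx <- 0:(glcm$Ng - 1)
  sum(glcm$P * outer(idx, idx, function(i, j) (i - j)^2))
}

#' @rdname contrast2d
#' @export
homogeneity2d <- function(glcm) {
  stopifnot(inherits(glcm, "glcm2"))
  check_normalised(glcm$P, "GLCM2")
  idx <- 0:(glcm$Ng - 1)
  sum(glcm$P / (1 + outer(idx, idx, function(i, j) (i - j)^2)))
}

# contrast and homogeneity at one displacement, streamed over triples
# (exactly the matrix-averaged feature, by linearity of both features);
# returns c(contrast, homogeneity, n_angles_used) or NULL
stream_features <- function(a, d, angles, Ng, convention, two_d) {
  con <- hom <- 0; used <- 0L
  for (th in angles) {
    off <- displacement_offsets(d, th, convention)
    if (two_d) {
      pr <- glcm2_pairs(a[, , 1], off)
      if (is.null(pr)) next
      w <- (pr$i - pr$j)^2
    } else {
      pr <- glcm3_triples(a, off)
      if (is.null(pr)) next
      w <- (pr$i - pr$j)^2 + (pr$i - pr$k)^2 + (pr$j - pr$k)^2
    }
    con <- con + mean(w)
    hom <- hom + mean(1 / (1 + w))
    used <- used + 1L
  }
  if (!used) return(NULL)
  c(contrast = con / used, homogeneity = hom / used, n_angles = used)
}

#' Texture metric as a function of pixel displacement
#'
#' Sweeps the displacement range, computing the metric on the
#' angle-averaged co-occurrence matrix at each `d`. In 2-D mode the curve
#' is computed on a single x-y slice (`slice_index`); in 3-D mode on the
#' whole volume with the three-reference-point GLCM. With
#' `average = "matrix"` (default) the feature is evaluated on the
#' angle-averaged matrix; `average = "feature"` averages per-angle
#' feature values — identical for contrast and homogeneity, which are
#' linear in P.
#'
#' @param volume quantised [image_volume()] (3-D, or 2-D for a single
#'   image).
#' @param metric `"contrast"` or `"homogeneity"`.
#' @param dimensionality `"3D"` or `"2D"`.
#' @param d_range increasing positive integers (default 1..40).
#' @param angles angles in degrees.
#' @param Ng number of grey levels.
#' @param slice_index 1-based slice for 2-D mode (default 1).
#' @param convention offset convention.
#' @param average `"matrix"` or `"feature"` (equal for these metrics).
#' @param sample_id identifier carried into results.
#' @return An object of class `texture_curve` with fields `sample_id`,
#'   `metric`, `dimensionality`, `displacements`, `values`,
#'   `slice_index`.
#' @export
texture_curve <- function(volume, metric = c("contrast", "homogeneity"),
                          dimensionality = c("3D", "2D"),
                          d_range = 1:40, angles = c(0, 45, 90, 135),
                          Ng = 256L, slice_index = NULL,
                          convention = c("round", "chessboard"),
                          average = c("matrix", "feature"),
                          sample_id = "sample") {
  metric <- match.arg(metric)
  dimensionality <- match.arg(dimensionality)
  convention <- match.arg(convention)
  average <- match.arg(average)
  if (!length(d_range) || any(diff(d_range) <= 0) || any(d_range < 1))
    stop("'d_range' must be non-empty increasing positive integers")
  a <- quantised_values(volume, 256L)  # requantised inside stream via Ng
  if (length(dim(a)) == 2L) dim(a) <- c(dim(a), 1L)
  a <- quantise_levels(a, Ng)
  two_d <- dimensionality == "2D"
  if (two_d) {
    z <- slice_index %||% 1L
    if (z < 1 || z > dim(a)[3]) stop("'slice_index' out of range")
    a <- a[, , z, drop = FALSE]
  } else if (dim(a)[3] == 1L)
    stop("3-D texture requires a volume with more than one slice")
  vals <- numeric(length(d_range))
  for (q in seq_along(d_range)) {
    f <- stream_features_ng(a, d_range[q], angles, Ng, convention, two_d)
    if (is.null(f)) stop("no valid triples at any angle for d = ", d_range[q])
    vals[q] <- f[[metric]]
  }
  structure(list(sample_id = sample_id, metric = metric,
                 dimensionality = dimensionality,
                 displacements = as.integer(d_range), values = vals,
                 slice_index = if (two_d) as.integer(slice_index %||% 1L) else NA_integer_),
            class = "texture_curve")
}

# stream_features on already-requantised levels (0..Ng-1)
stream_features_ng <- function(a, d, angles, Ng, convention, two_d)
  stream_features(a, d, angles, Ng, convention, two_d)

#' Contrast and homogeneity curves in one sweep
#'
#' Computes both metrics over the displacement range in a single pass
#' over the co-occurring triples (cheaper than two [texture_curve()]
#' calls; identical values).
#'
#' @inheritParams texture_curve
#' @return Named list of two `texture_curve`s: `contrast`, `homogeneity`.
#' @export
texture_curves <- function(volume, dimensionality = c("3D", "2D"),
                           d_range = 1:40, angles = c(0, 45, 90, 135),
                           Ng = 256L, slice_index = NULL,
                           convention = c("round", "chessboard"),
                           sample_id = "sample") {
  dimensionality <- match.arg(dimensionality)
  convention <- match.arg(convention)
  a <- quantised_values(volume, 256L)
  if (length(dim(a)) == 2L) dim(a) <- c(dim(a), 1L)
  a <- quantise_levels(a, Ng)
  two_d <- dimensionality == "2D"
  if (two_d) a <- a[, , slice_index %||% 1L, drop = FALSE]
  con <- hom <- numeric(length(d_range))
  for (q in seq_along(d_range)) {
    f <- stream_features(a, d_range[q], angles, Ng, convention, two_d)
    if (is.null(f)) stop("no valid triples at any angle for d = ", d_range[q])
    con[q] <- f[["contrast"]]; hom[q] <- f[["homogeneity"]]
  }
  mk <- function(metric, v) structure(
    list(sample_id = sample_id, metric = metric,
         dimensionality = dimensionality,
         displacements = as.integer(d_range), values = v,
         slice_index = if (two_d) as.integer(slice_index %||% 1L) else NA_integer_),
    class = "texture_curve")
  list(contrast = mk("contrast", con), homogeneity = mk("homogeneity", hom))
}

#' @export
print.texture_curve <- function(x, ...) {
  cat(sprintf("<texture_curve> %s, %s %s, d = %d..%d (%d points)\n",
              x$sample_id, x$dimensionality, x$metric,
              min(x$displacements), max(x$displacements),
              length(x$displacements)))
  invisible(x)
}

#' @export
as.data.frame.texture_curve <- function(x, ...) {
  data.frame(sample_id = x$sample_id, dims = x$dimensionality,
             metric = x$metric, d = x$displacements, value = x$values,
             slice_index = x$slice_index)
}

#' @export
plot.texture_curve <- function(x, ...) {
  graphics::plot(x$displacements, x$values, type = "b", pch = 16,
                 xlab = "pixel displacement d",
                 ylab = sprintf("%s %s", x$dimensionality, x$metric), ...)
  invisible(x)
}

#' Locate the peak of a texture curve
#'
#' Argmax over the sampled displacements; an interior peak is refined to
#' the vertex of the quadratic through the three points around the
#' argmax, yielding fractional displacements. A peak at the end of the
#' sweep is flagged `at_boundary` and not refined.
#'
#' @param curve a `texture_curve` (>= 3 points for interior refinement).
#' @return An object of class `peak_estimate`: `displacement`, `value`,
#'   `at_boundary`.
#' @export
find_peak <- function(curve) {
  stopifnot(inherits(curve, "texture_curve"))
  d <- curve$displacements; v <- curve$values
  if (length(unique(v)) == 1L) stop("no unique peak: curve is constant")
  idx <- which.max(v)
  if (idx == 1L || idx == length(v)) {
    return(structure(list(displacement = as.numeric(d[idx]), value = v[idx],
                          at_boundary = TRUE), class = "peak_estimate"))
  }
  x1 <- d[idx - 1]; x2 <- d[idx]; x3 <- d[idx + 1]
  y1 <- v[idx - 1]; y2 <- v[idx]; y3 <- v[idx + 1]
  den <- (x2 - x1) * (y2 - y3) - (x2 - x3) * (y2 - y1)
  if (abs(den) < .Machine$double.eps * max(abs(c(y1, y2, y3, 1)))) {
    xv <- x2; yv <- y2  # locally flat: keep the sampled argmax
  } else {
    xv <- x2 - 0.5 * ((x2 - x1)^2 * (y2 - y3) - (x2 - x3)^2 * (y2 - y1)) / den
    xv <- min(max(xv, x1), x3)
    # value at the vertex from the Lagrange form of the parabola
    yv <- y1 * (xv - x2) * (xv - x3) / ((x1 - x2) * (x1 - x3)) +
          y2 * (xv - x1) * (xv - x3) / ((x2 - x1) * (x2 - x3)) +
          y3 * (xv - x1) * (xv - x2) / ((x3 - x1) * (x3 - x2))
  }
  structure(list(displacement = xv, value = yv, at_boundary = FALSE),
            class = "peak_estimate")
}

#' @export
print.peak_estimate <- function(x, ...) {
  cat(sprintf("<peak_estimate> d = %.3f, value = %.6g%s\n", x$displacement,
              x$value, if (x$at_boundary) " (at sweep boundary)" else ""))
  invisible(x)
}
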