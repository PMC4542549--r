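# Volumetry by sparse keyframe contours.
#
# The organ is outlined on keyframe slices (every `slice_step` axial
# slices, anchored at the first and last slices containing the object),
# intermediate slices are interpolated by linearly blending the signed
# distance transforms of the bracketing keyframe regions, and the volume
# is the voxel count times the known voxel volume. Keyframe outlining is
# automatic here (Otsu threshold, artifact intensity cap, largest
# connected component, hole filling, boundary trace); externally drawn
# keyframe polygons can be supplied instead via contour_stack() /
# read_contours() to mirror a manual workflow.

#' Keyframe contour stack
#'
#' @param keyframes named list mapping slice index (0-based, as a name)
#'   to an n x 2 matrix of polygon vertices `(x, y)` in 0-based pixel
#'   coordinates (x = column, y = row); polygons are closed implicitly.
#' @param slice_step nominal keyframe spacing in slices.
#' @param volume_shape `(nx, ny, nz)` of the source volume.
#' @param voxel_size voxel edge length, micrometres.
#' @return An object of class `contour_stack`.
#' @export
contour_stack <- function(keyframes, slice_step, volume_shape,
                          voxel_size = 26) {
  stopifnot(length(keyframes) >= 1, slice_step >= 1,
            length(volume_shape) == 3L, voxel_size > 0)
  z <- as.integer(names(keyframes))
  if (anyNA(z) || any(z < 0) || any(z >= volume_shape[3]))
    stop("keyframe slice indices must be 0-based and within the volume")
  keyframes <- keyframes[order(z)]
  for (nm in names(keyframes)) {
    kf <- keyframes[[nm]]
    if (!is.matrix(kf) || ncol(kf) != 2 || nrow(kf) < 3)
      stop("keyframe ", nm, ": polygon needs an n x 2 vertex matrix, n >= 3")
  }
  structure(list(keyframes = keyframes, slice_step = as.integer(slice_step),
                 volume_shape = as.integer(volume_shape),
                 voxel_size = voxel_size),
            class = "contour_stack")
}

#' @export
print.contour_stack <- function(x, ...) {
  cat(sprintf("<contour_stack> %d keyframes (slices %s), step %d, volume %s\n",
              length(x$keyframes),
              paste(names(x$keyframes), collapse = ","), x$slice_step,
              paste(x$volume_shape, collapse = "x")))
  invisible(x)
}

#' Write/read keyframe contours as JSON
#'
#' @param contours a [contour_stack()].
#' @param path JSON file path.
#' @return `path` invisibly / a `contour_stack`.
#' @export
write_contours <- function(contours, path) {
  stopifnot(inherits(contours, "contour_stack"))
  obj <- list(slice_step = contours$slice_step,
              volume_shape = contours$volume_shape,
              voxel_size_um = contours$voxel_size,
              keyframes = lapply(contours$keyframes, function(m)
                unname(apply(m, 1, function(r) c(x = r[1], y = r[2]),
                             simplify = FALSE))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_contours
#' @export
read_contours <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  kf <- lapply(obj$keyframes, function(v) {
    m <- if (is.matrix(v)) v else do.call(rbind, lapply(v, unlist))
    m <- matrix(as.numeric(m), ncol = 2)
    colnames(m) <- c("x", "y"); m
  })
  contour_stack(kf, obj$slice_step, obj$volume_shape, obj$voxel_size_um)
}

# Otsu threshold of a slice or value set, computed on its own range
slice_otsu <- function(s) {
  s <- as.vector(s)
  rng <- range(s)
  if (rng[2] <= rng[1]) return(Inf)
  u <- (s - rng[1]) / (rng[2] - rng[1])
  t <- EBImage::otsu(EBImage::Image(matrix(u, nrow = 1)),
                     range = c(0, 1), levels = 256)
  t * (rng[2] - rng[1]) + rng[1]
}

# largest connected component of a logical matrix, holes filled
largest_component_filled <- function(seg) {
  lab <- EBImage::bwlabel(seg)
  if (max(lab) == 0) return(NULL)
  sizes <- tabulate(lab[lab > 0])
  comp <- lab == which.max(sizes)
  EBImage::fillHull(comp) > 0
}

# boundary polygon (0-based (x, y) vertices) of a logical matrix [y, x]
trace_boundary <- function(mask) {
  oc <- EBImage::ocontour(EBImage::Image(mask * 1))
  if (!length(oc)) return(NULL)
  oc <- oc[[which.max(vapply(oc, nrow, 0L))]]
  # ocontour indexes along the array's first dimension first; our first
  # dimension is y (row), so swap to (x, y)
  cbind(x = oc[, 2], y = oc[, 1])
}

#' Automatic keyframe contouring
#'
#' Selects keyframe slices (first and last slices intersecting the
#' object, then every `slice_step`), and on each: thresholds with Otsu,
#' removes voxels above the `artifact_percentile` within-slice intensity
#' cap (excluding highly attenuating streak artifacts), keeps the
#' largest connected component, fills holes, and traces the boundary to
#' a polygon. Keyframes without an object are skipped with a warning.
#'
#' @param volume an [image_volume()] with a bright object on a darker
#'   background.
#' @param slice_step keyframe spacing in slices (default 20).
#' @param artifact_percentile intensity cap percentile (default 99.9).
#' @param min_area smallest pixel area accepted as an object slice.
#' @return A [contour_stack()].
#' @export
auto_contour_keyframes <- function(volume, slice_step = 20,
                                   artifact_percentile = 99.9,
                                   min_area = 16) {
  stopifnot(inherits(volume, "image_volume"))
  v <- volume$values
  nz <- dim(v)[3]
  # object extent along z from a volume-wide Otsu threshold
  thr_global <- slice_otsu(v)
  areas <- vapply(seq_len(nz), function(z) sum(v[, , z] > thr_global), 0)
  occ <- which(areas >= min_area)
  if (!length(occ)) stop("no object found in any slice")
  zs <- unique(c(seq(occ[1], occ[length(occ)], by = slice_step),
                 occ[length(occ)]))
  keyframes <- list()
  for (z in zs) {
    s <- v[, , z]
    cap <- quantile(s, artifact_percentile / 100, names = FALSE)
    # threshold estimated on the capped values so bright artifacts cannot
    # drag it above the tissue intensities
    seg <- s > slice_otsu(s[s <= cap]) & s <= cap
    comp <- largest_component_filled(seg)
    if (is.null(comp) || sum(comp) < min_area) {
      warning("keyframe slice ", z - 1L, " contains no object; skipped")
      next
    }
    poly <- trace_boundary(comp)
    if (is.null(poly)) {
      warning("keyframe slice ", z - 1L, ": boundary trace failed; skipped")
      next
    }
    keyframes[[as.character(z - 1L)]] <- poly
  }
  if (!length(keyframes)) stop("all keyframes empty: no object contoured")
  contour_stack(keyframes, slice_step, vol_dim(volume), volume$voxel_size)
}

# rasterise a polygon ((x, y), 0-based pixel-centre coordinates) onto an
# ny x nx grid by the even-odd rule. Vertices lying exactly on pixel
# centres (the case for boundary chains traced from a binary component)
# are additionally included, so rasterising a traced contour recovers the
# component including its boundary pixels; analytic polygons are
# unaffected (their vertices almost never coincide with pixel centres).
rasterise_polygon <- function(poly, nx, ny) {
  crossings <- matrix(0L, ny, nx)
  n <- nrow(poly)
  px <- 0:(nx - 1)
  for (e in seq_len(n)) {
    a <- poly[e, ]; b <- poly[if (e == n) 1L else e + 1L, ]
    if (a[2] == b[2]) next  # horizontal edge: no crossing
    rows <- which((a[2] > (0:(ny - 1))) != (b[2] > (0:(ny - 1))))
    if (!length(rows)) next
    py <- rows - 1
    xint <- a[1] + (py - a[2]) * (b[1] - a[1]) / (b[2] - a[2])
    for (q in seq_along(rows))
      crossings[rows[q], px < xint[q]] <- crossings[rows[q], px < xint[q]] + 1L
  }
  m <- crossings %% 2L == 1L
  on_centre <- abs(poly[, 1] - round(poly[, 1])) < 1e-9 &
               abs(poly[, 2] - round(poly[, 2])) < 1e-9
  vx <- as.integer(round(poly[on_centre, 1])) + 1L
  vy <- as.integer(round(poly[on_centre, 2])) + 1L
  ok <- vx >= 1 & vx <= nx & vy >= 1 & vy <= ny
  m[cbind(vy[ok], vx[ok])] <- TRUE
  m
}

# signed Euclidean distance transform: negative inside, positive outside
signed_distance <- function(mask) {
  if (!any(mask)) return(matrix(Inf, nrow(mask), ncol(mask)))
  if (all(mask)) return(matrix(-Inf, nrow(mask), ncol(mask)))
  outside <- EBImage::distmap(EBImage::Image((!mask) * 1))
  inside <- EBImage::distmap(EBImage::Image(mask * 1))
  as.matrix(outside) - as.matrix(inside)
}

#' Interpolate keyframe contours to a full volume mask
#'
#' Rasterises every keyframe polygon and fills intermediate slices by
#' linear interpolation of the signed distance transforms of the two
#' bracketing keyframes, thresholded at zero. Keyframe slices reproduce
#' their rasterised polygons exactly; slices before the first or after
#' the last keyframe are empty.
#'
#' @param contours a [contour_stack()] with >= 2 keyframes.
#' @return An object of class `volume_mask`: logical `mask` array and
#'   `voxel_volume` (mm^3 per voxel).
#' @export
interpolate_contours <- function(contours) {
  stopifnot(inherits(contours, "contour_stack"))
  if (length(contours$keyframes) < 2)
    stop("need >= 2 keyframes to interpolate; reduce slice_step")
  shp <- contours$volume_shape  # (nx, ny, nz)
  nx <- shp[1]; ny <- shp[2]; nz <- shp[3]
  zk <- as.integer(names(contours$keyframes))
  rast <- lapply(contours$keyframes, rasterise_polygon, nx = nx, ny = ny)
  sdfs <- lapply(rast, signed_distance)
  mask <- array(FALSE, c(ny, nx, nz))
  for (q in seq_along(zk)) mask[, , zk[q] + 1L] <- rast[[q]]
  for (q in seq_len(length(zk) - 1L)) {
    z0 <- zk[q]; z1 <- zk[q + 1]
    if (z1 - z0 < 2) next
    for (z in (z0 + 1):(z1 - 1)) {
      w <- (z - z0) / (z1 - z0)
      mask[, , z + 1L] <- ((1 - w) * sdfs[[q]] + w * sdfs[[q + 1]]) <= 0
    }
  }
  voxel_volume <- (contours$voxel_size * 1e-3)^3  # um -> mm edge, cubed
  structure(list(mask = mask, voxel_volume = voxel_volume,
                 voxel_size = contours$voxel_size),
            class = "volume_mask")
}

#' @export
print.volume_mask <- function(x, ...) {
  cat(sprintf("<volume_mask> %s voxels, %d set, voxel volume %.4g mm^3\n",
              paste(dim(x$mask)[c(2, 1, 3)], collapse = "x"),
              sum(x$mask), x$voxel_volume))
  invisible(x)
}

#' Measure a mask's volume
#'
#' Voxel count times voxel volume, in mm^3 (e.g. a (26 um)^3 voxel is
#' 1.7576e-5 mm^3).
#'
#' @param mask a `volume_mask` (or logical array with `voxel_volume`
#'   passed explicitly).
#' @param voxel_volume mm^3 per voxel, for plain arrays.
#' @return Volume in mm^3.
#' @export
measure_volume <- function(mask, voxel_volume = NULL) {
  if (inherits(mask, "volume_mask")) {
    voxel_volume <- mask$voxel_volume
    mask <- mask$mask
  }
  stopifnot(!is.null(voxel_volume), voxel_volume > 0)
  sum(mask) * voxel_volume
}

#' Keyframe-contour volumetry of one sample
#'
#' Convenience wrapper: automatic keyframe contours, signed-distance
#' interpolation, volume measurement.
#'
#' @inheritParams auto_contour_keyframes
#' @return List: `volume_mm3`, `mask` (a `volume_mask`), `contours`.
#' @export
measure_sample_volume <- function(volume, slice_step = 20,
                                  artifact_percentile = 99.9) {
  contours <- auto_contour_keyframes(volume, slice_step, artifact_percentile)
  mask <- interpolate_contours(contours)
  list(volume_mm3 = measure_volume(mask), mask = mask, contours = contours)
}
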