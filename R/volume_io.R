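#' Construct an image volume
#'
#' The container carried through the whole pipeline: a 2-D image or 3-D
#' scalar grid plus its isotropic voxel size and a provenance trail.
#' Arrays are stored `[row, column, slice]` (`[y, x, z]`); user-facing
#' coordinates are 0-based `(x, y, z)`.
#'
#' @param values numeric matrix (2-D image) or 3-D array.
#' @param voxel_size isotropic voxel edge length in micrometres.
#' @param dtype_role `"raw-float"` for unconstrained scalars (e.g. raw
#'   attenuation) or `"quantised-8bit"` for integers in 0..255.
#' @param provenance character vector of free-text processing notes.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(values, voxel_size,
                         dtype_role = c("raw-float", "quantised-8bit"),
                         provenance = character()) {
  dtype_role <- match.arg(dtype_role)
  if (is.matrix(values)) dim(values) <- c(dim(values), 1L)
  if (length(dim(values)) != 3L)
    stop("'values' must be a 2-D matrix or 3-D array")
  if (any(dim(values) < 1L)) stop("all dimensions must be >= 1")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("'voxel_size' must be a single positive number (micrometres)")
  if (dtype_role == "quantised-8bit") {
    if (anyNA(values) || any(values != floor(values)) ||
        min(values) < 0 || max(values) > 255)
      stop("quantised-8bit values must be integers in [0, 255]")
    storage.mode(values) <- "integer"
  } else {
    if (any(!is.finite(values))) stop("raw-float values must be finite")
    storage.mode(values) <- "double"
  }
  structure(
    list(values = values, voxel_size = voxel_size,
         dtype_role = dtype_role, provenance = as.character(provenance)),
    class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<image_volume> %d x %d x %d (nx x ny x nz), %s, voxel %g um\n",
              d[2], d[1], d[3], x$dtype_role, x$voxel_size))
  cat(sprintf("  range [%g, %g]\n", min(x$values), max(x$values)))
  if (length(x$provenance))
    cat("  provenance:", paste(x$provenance, collapse = " | "), "\n")
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$values)

# named (nx, ny, nz) dimensions
vol_dim <- function(volume) {
  d <- dim(volume$values)
  c(nx = d[2], ny = d[1], nz = d[3])
}

is_2d <- function(volume) dim(volume$values)[3] == 1L

# drop a volume to a plain 2-D matrix (first slice)
vol_slice <- function(volume, z = 1L) volume$values[, , z, drop = TRUE]

#' Region-of-interest specification
#'
#' 0-based, half-open sub-volume selection: voxels with
#' `x0 <= x < x0 + nx` (and likewise y, z) are selected.
#'
#' @param origin integer vector `(x0, y0, z0)`, 0-based.
#' @param shape integer vector `(nx, ny, nz)`, all >= 1.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(origin, shape) {
  origin <- as.integer(origin); shape <- as.integer(shape)
  if (length(origin) != 3L || length(shape) != 3L)
    stop("'origin' and 'shape' must have length 3: (x, y, z)")
  if (any(origin < 0L)) stop("ROI origin must be >= 0")
  if (any(shape < 1L)) stop("ROI shape must be >= 1 in every dimension")
  structure(list(origin = origin, shape = shape), class = "roi_spec")
}

#' @export
print.roi_spec <- function(x, ...) {
  cat(sprintf("<roi_spec> origin (x,y,z) = (%s), shape (nx,ny,nz) = (%s)\n",
              paste(x$origin, collapse = ","), paste(x$shape, collapse = ",")))
  invisible(x)
}

sidecar_path <- function(path) paste0(path, ".json")

guess_format <- function(path) {
  if (dir.exists(path)) return("dir")
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  switch(ext,
         tif = , tiff = "tiff",
         nii = "nifti",
         stop("cannot infer volume format from path: ", path))
}

#' Read an image volume
#'
#' Supported formats: multi-page TIFF (primary; raw-float volumes are
#' stored rescaled to unit range with the affine transform recorded in a
#' JSON sidecar written by [write_volume()]), NIfTI-1, and a directory of
#' 2-D greyscale PNG/JPEG slices stacked in lexicographic filename order.
#' JPEG slices are accepted but flagged as lossy in the provenance.
#'
#' @param path file (TIFF/NIfTI) or directory of 2-D images.
#' @param format `"auto"` (default), `"tiff"`, `"nifti"` or `"dir"`.
#' @param voxel_size voxel edge length in micrometres; overrides (and is
#'   required in the absence of) stored metadata.
#' @return An [image_volume()].
#' @export
read_volume <- function(path, format = c("auto", "tiff", "nifti", "dir"),
                        voxel_size = NULL) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  switch(format,
         tiff = read_volume_tiff(path, voxel_size),
         nifti = read_volume_nifti(path, voxel_size),
         dir = read_volume_dir(path, voxel_size))
}

read_volume_tiff <- function(path, voxel_size) {
  if (!file.exists(path)) stop("no such file: ", path)
  meta <- if (file.exists(sidecar_path(path)))
    jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE) else NULL
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  bits <- attr(pages[[1]], "bits.per.sample")
  vals <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (z in seq_along(pages)) {
    s <- pages[[z]]
    if (length(dim(s)) == 3L) s <- s[, , 1]
    vals[, , z] <- as.numeric(s)
  }
  role <- if (!is.null(meta$dtype_role)) meta$dtype_role
          else if (identical(bits, 8L)) "quantised-8bit" else "raw-float"
  if (role == "raw-float") {
    slope <- if (is.null(meta$slope)) 1 else meta$slope
    intercept <- if (is.null(meta$intercept)) 0 else meta$intercept
    vals <- vals * slope + intercept
  } else {
    vals <- round_half_up(vals * 255)  # 8-bit samples arrive in [0, 1]
  }
  vs <- voxel_size %||% meta$voxel_size_um %||%
    stop("voxel size not stored with ", path, "; pass 'voxel_size'")
  image_volume(vals, vs, role,
               provenance = c(meta$provenance, sprintf("read TIFF %s", path)))
}

read_volume_nifti <- function(path, voxel_size) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  hdr <- RNifti::niftiHeader(img)
  pd <- RNifti::pixdim(img)[1:3]
  if (max(pd) - min(pd) > 1e-6 * max(pd))
    stop("anisotropic voxels in ", path, " are not supported")
  vs <- voxel_size %||% signif(pd[1] * 1000, 6)  # header stores mm as float32
  vals <- array(as.numeric(img), dim = dim(img))
  # integer on-disk datatypes (uint8/int16/int32/uint16) carry quantised
  # volumes; raw floats are written as float64
  role <- if (hdr$datatype %in% c(2L, 4L, 8L, 512L)) "quantised-8bit"
          else "raw-float"
  image_volume(vals, vs, role, provenance = sprintf("read NIfTI %s", path))
}

read_volume_dir <- function(path, voxel_size) {
  files <- sort(list.files(path, pattern = "\\.(png|jpe?g)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (!length(files)) stop("no PNG/JPEG slices found in ", path)
  lossy <- FALSE
  read_slice <- function(f) {
    if (grepl("\\.png$", f, ignore.case = TRUE)) {
      png::readPNG(f)
    } else {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stop("the 'jpeg' package is required to read JPEG slices")
      lossy <<- TRUE
      jpeg::readJPEG(f)
    }
  }
  slices <- lapply(files, function(f) {
    s <- read_slice(f)
    if (length(dim(s)) == 3L) s <- s[, , 1]  # greyscale stored as RGB
    s
  })
  shp <- dim(slices[[1]])
  for (i in seq_along(slices))
    if (!identical(dim(slices[[i]]), shp))
      stop("slice shape mismatch in ", files[i], ": expected ",
           paste(shp, collapse = "x"), ", got ",
           paste(dim(slices[[i]]), collapse = "x"))
  vals <- array(0L, c(shp, length(slices)))
  for (z in seq_along(slices))
    vals[, , z] <- as.integer(round_half_up(slices[[z]] * 255))
  if (is.null(voxel_size)) stop("'voxel_size' is required for image directories")
  prov <- sprintf("read %d slices from %s", length(files), path)
  if (lossy) prov <- c(prov, "contains lossy JPEG input")
  image_volume(vals, voxel_size, "quantised-8bit", provenance = prov)
}

#' Write an image volume
#'
#' Multi-page TIFF (one page per z slice) or NIfTI-1. Quantised volumes
#' are stored as 8-bit samples; raw-float volumes as 32-bit float TIFF
#' samples (affinely rescaled to unit range, transform in a `.json`
#' sidecar) or as 64-bit NIfTI (lossless).
#'
#' @param volume an [image_volume()].
#' @param path output file; extension `.tif`/`.tiff` or `.nii` decides
#'   the format when `format = "auto"`.
#' @param format `"auto"`, `"tiff"` or `"nifti"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, format = c("auto", "tiff", "nifti")) {
  stopifnot(inherits(volume, "image_volume"))
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (format == "tiff") write_volume_tiff(volume, path)
  else write_volume_nifti(volume, path)
  invisible(path)
}

write_volume_tiff <- function(volume, path) {
  v <- volume$values
  meta <- list(format_version = 1L, dtype_role = volume$dtype_role,
               voxel_size_um = volume$voxel_size,
               provenance = volume$provenance)
  if (volume$dtype_role == "quantised-8bit") {
    pages <- lapply(seq_len(dim(v)[3]), function(z) v[, , z] / 255)
    bits <- 8L
  } else {
    rng <- range(v)
    slope <- rng[2] - rng[1]
    intercept <- rng[1]
    scaled <- if (slope > 0) (v - intercept) / slope else array(0, dim(v))
    meta$slope <- slope; meta$intercept <- intercept
    pages <- lapply(seq_len(dim(v)[3]), function(z) scaled[, , z])
    bits <- 32L
  }
  ok <- tiff::writeTIFF(pages, path, bits.per.sample = bits,
                        compression = "none", reduce = FALSE)
  if (!isTRUE(ok == length(pages))) stop("failed to write TIFF ", path)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
}

write_volume_nifti <- function(volume, path) {
  v <- volume$values
  v <- array(as.numeric(v), dim = dim(v))
  if (volume$dtype_role == "quantised-8bit") storage.mode(v) <- "integer"
  img <- RNifti::asNifti(v, internal = FALSE)
  RNifti::pixdim(img) <- rep(volume$voxel_size / 1000, 3)  # header in mm
  RNifti::writeNifti(img, path,
                     datatype = if (is.integer(v)) "int" else "double")
}

#' Save tabular records as CSV
#'
#' @param records a data.frame (possibly 0-row; the header is still
#'   written).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
save_table <- function(records, path) {
  if (!is.data.frame(records)) records <- as.data.frame(records)
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Voxel edge length from field of view
#'
#' Isotropic voxel size in micrometres for a cubic field of view
#' reconstructed on an n-cube grid, e.g. a 13.3 mm field of view at
#' 512 voxels gives 26 um voxels.
#'
#' @param fov_mm field-of-view edge length in millimetres.
#' @param n_voxels grid size along one edge.
#' @return Voxel edge length in micrometres.
#' @export
voxel_size_um <- function(fov_mm, n_voxels) {
  stopifnot(fov_mm > 0, n_voxels >= 1)
  fov_mm * 1000 / n_voxels
}

`%||%` <- function(a, b) if (is.null(a)) b else a
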