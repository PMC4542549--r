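# Preprocessing chain applied to each sample region of interest before
# texture analysis: ROI extraction, linear 32-bit -> 8-bit scaling,
# per-ROI histogram equalisation, and a width-3 median filter. Per-ROI
# equalisation maintains intra-sample contrast in the presence of highly
# attenuating artifacts, at the cost of inter-sample comparability of
# absolute grey values; because it can amplify noise, the median filter
# is applied around it (after it by default, order configurable).

#' Extract a region of interest
#'
#' @param volume an [image_volume()].
#' @param roi an [roi_spec()] (0-based origin, half-open).
#' @return An [image_volume()] of exactly `roi$shape`.
#' @export
extract_roi <- function(volume, roi) {
  stopifnot(inherits(volume, "image_volume"), inherits(roi, "roi_spec"))
  d <- vol_dim(volume)
  hi <- roi$origin + roi$shape
  if (any(hi > d)) {
    clip <- pmin(roi$origin, pmax(0L, d - roi$shape))
    stop("ROI [origin (", paste(roi$origin, collapse = ","), "), shape (",
         paste(roi$shape, collapse = ","), ")] exceeds volume (",
         paste(d, collapse = ","), "); nearest in-bounds origin: (",
         paste(clip, collapse = ","), ")")
  }
  v <- volume$values[roi$origin[2] + seq_len(roi$shape[2]),
                     roi$origin[1] + seq_len(roi$shape[1]),
                     roi$origin[3] + seq_len(roi$shape[3]), drop = FALSE]
  image_volume(v, volume$voxel_size, volume$dtype_role,
               provenance = c(volume$provenance,
                              sprintf("ROI origin (%s) shape (%s)",
                                      paste(roi$origin, collapse = ","),
                                      paste(roi$shape, collapse = ","))))
}

#' Place an ROI automatically on a mask centroid
#'
#' Centres an ROI of the requested shape on the centroid of a boolean
#' mask (e.g. a phantom's ground-truth spleen mask), shifting it
#' minimally to fit inside the volume.
#'
#' @param volume an [image_volume()].
#' @param mask logical array of the volume's shape (or a `phantom_truth`,
#'   whose spleen mask is used).
#' @param shape ROI shape `(nx, ny, nz)`.
#' @return An [roi_spec()].
#' @export
auto_roi <- function(volume, mask, shape) {
  stopifnot(inherits(volume, "image_volume"))
  if (inherits(mask, "phantom_truth")) mask <- truth_mask(mask)
  d <- vol_dim(volume)
  shape <- as.integer(shape)
  if (any(shape > d))
    stop("ROI shape (", paste(shape, collapse = ","),
         ") exceeds volume (", paste(d, collapse = ","), ")")
  if (!any(mask)) stop("mask is empty")
  idx <- which(mask, arr.ind = TRUE)  # (y, x, z), 1-based
  centroid <- c(mean(idx[, 2]), mean(idx[, 1]), mean(idx[, 3])) - 1  # (x,y,z)
  origin <- as.integer(round_half_up(centroid - (shape - 1) / 2))
  clamped <- pmin(pmax(origin, 0L), d - shape)
  if (any(clamped != origin))
    warning("ROI shifted to fit inside the volume")
  roi_spec(clamped, shape)
}

#' Linear scaling to 8-bit grey levels
#'
#' Maps `v` to `round(255 * (v - min) / (max - min))` with round-half-up;
#' the input minimum maps to 0 and the maximum to 255. A constant volume
#' maps to all zeros.
#'
#' @param volume a raw-float [image_volume()].
#' @return A quantised-8bit [image_volume()].
#' @export
scale_to_8bit <- function(volume) {
  stopifnot(inherits(volume, "image_volume"))
  v <- volume$values
  rng <- range(v)
  out <- if (rng[2] > rng[1])
    round_half_up(255 * (v - rng[1]) / (rng[2] - rng[1]))
  else array(0, dim(v))
  image_volume(out, volume$voxel_size, "quantised-8bit",
               provenance = c(volume$provenance, "scaled to 8-bit"))
}

#' Histogram equalisation (per ROI)
#'
#' Classical cumulative-histogram equalisation of an 8-bit volume:
#' `v -> round(255 * (cdf(v) - cdf_min) / (N - cdf_min))`, where `cdf` is
#' the cumulative voxel count and `cdf_min` the count at the lowest
#' occupied grey level. The mapping is monotone non-decreasing; constant
#' input is returned unchanged. Applied per ROI, this preserves
#' intra-sample contrast but sacrifices inter-sample comparability of
#' absolute values (recorded in provenance).
#'
#' @param volume a quantised-8bit [image_volume()].
#' @return A quantised-8bit [image_volume()].
#' @export
equalize_histogram <- function(volume) {
  stopifnot(inherits(volume, "image_volume"))
  if (volume$dtype_role != "quantised-8bit")
    stop("histogram equalisation requires a quantised-8bit volume")
  v <- volume$values
  counts <- tabulate(as.vector(v) + 1L, nbins = 256L)
  cdf <- cumsum(counts)
  n <- length(v)
  cdf_min <- cdf[which(counts > 0)[1]]
  lut <- if (n > cdf_min)
    as.integer(round_half_up(255 * (cdf - cdf_min) / (n - cdf_min)))
  else 0:255  # constant volume: identity
  out <- array(lut[v + 1L], dim(v))
  image_volume(out, volume$voxel_size, "quantised-8bit",
               provenance = c(volume$provenance,
                 "histogram equalised per ROI (absolute values not comparable across samples)"))
}

#' Median filter
#'
#' Each voxel is replaced by the median of its `width`-cube (3-D input)
#' or `width`-square (single-slice input) neighbourhood. Windows are
#' truncated at the volume boundary rather than padded, and truncated
#' even-sized windows use the lower median, so the filter never
#' introduces a value absent from the window.
#'
#' @param volume an [image_volume()] (either dtype role).
#' @param width odd window edge length; the customary choice is 3.
#' @return An [image_volume()] of the same dtype role.
#' @export
median_filter <- function(volume, width = 3L) {
  stopifnot(inherits(volume, "image_volume"))
  width <- as.integer(width)
  if (width < 1L || width %% 2L == 0L) stop("'width' must be odd and >= 1")
  v <- volume$values
  storage.mode(v) <- "double"
  out <- .median_filter_cpp(v, width)
  image_volume(out, volume$voxel_size, volume$dtype_role,
               provenance = c(volume$provenance,
                              sprintf("median filter width %d (%s)", width,
                                      if (is_2d(volume)) "2-D" else "3-D")))
}

#' Full ROI preprocessing chain
#'
#' Runs extraction (optional), 8-bit scaling (skipped for already
#' quantised input), histogram equalisation and median filtering in a
#' configurable order. Every step is appended to the provenance.
#'
#' @param volume an [image_volume()].
#' @param roi optional [roi_spec()].
#' @param order `"equalize-then-median"` (default: the filter suppresses
#'   the noise that equalisation amplifies) or `"median-then-equalize"`.
#' @param median_width odd median window width.
#' @return A quantised-8bit [image_volume()].
#' @export
preprocess_roi <- function(volume, roi = NULL,
                           order = c("equalize-then-median",
                                     "median-then-equalize"),
                           median_width = 3L) {
  order <- match.arg(order)
  v <- if (is.null(roi)) volume else extract_roi(volume, roi)
  if (v$dtype_role == "raw-float") v <- scale_to_8bit(v)
  if (order == "equalize-then-median")
    median_filter(equalize_histogram(v), median_width)
  else
    equalize_histogram(median_filter(v, median_width))
}
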