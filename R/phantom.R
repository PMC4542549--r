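# Synthetic spleen phantoms.
#
# Optical-CT scans of cleared spleen at haemoglobin-absorbing wavelengths
# show bright (highly attenuating) red pulp, dark white-pulp nodules,
# intermediate marginal-zone shells around the nodules, bright blood
# vessels, and occasional very bright streak artifacts. The generators
# here emulate exactly that anatomy, in 2-D (single-slice feature images
# with three flat grey levels) and in 3-D (ellipsoidal organ with nodules,
# shells, vessel tubes, additive Gaussian noise and streaks), with full
# ground truth, so that texture and volumetry methods can be exercised
# against known geometry.

#' Specification of a 2-D spleen-feature image
#'
#' A flat red-pulp background containing circular white-pulp "lymph node"
#' discs, each wrapped in a marginal-zone annulus. Grey levels default to
#' the three-level scheme 0 (node), 128 (marginal zone) and 256 for the
#' red pulp; 256 exceeds the 8-bit maximum and is clamped to 255 (the
#' clamp is recorded in the image provenance).
#'
#' @param image_size square image edge length in pixels.
#' @param ln_radius lymph-node (white pulp) disc radius, pixels.
#' @param mz_thickness marginal-zone annulus thickness, pixels.
#' @param n_features number of features; used only when
#'   `feature_centres` is NULL, in which case the features are laid out
#'   on a centred grid.
#' @param ln_level,mz_level,rp_level grey levels for node, marginal zone
#'   and red pulp; values above 255 are clamped to 255.
#' @param feature_centres optional list/matrix of (x, y) pixel centres
#'   (0-based).
#' @return An object of class `feature_image_spec`.
#' @export
feature_image_spec <- function(image_size = 200, ln_radius = 10,
                               mz_thickness = 4, n_features = 4,
                               ln_level = 0, mz_level = 128, rp_level = 256,
                               feature_centres = NULL) {
  stopifnot(image_size >= 1, ln_radius >= 0, mz_thickness >= 0,
            n_features >= 1)
  clamped <- rp_level > 255 || mz_level > 255 || ln_level > 255
  levels <- pmin(c(ln = ln_level, mz = mz_level, rp = rp_level), 255)
  if (any(levels < 0)) stop("grey levels must be >= 0")
  if (is.null(feature_centres)) {
    k <- ceiling(sqrt(n_features))
    step <- image_size / k
    centres <- expand.grid(x = (seq_len(k) - 0.5) * step,
                           y = (seq_len(k) - 0.5) * step)
    feature_centres <- as.matrix(centres[seq_len(n_features), , drop = FALSE])
  } else {
    if (is.list(feature_centres))
      feature_centres <- do.call(rbind, feature_centres)
    feature_centres <- matrix(as.numeric(feature_centres), ncol = 2,
                              dimnames = list(NULL, c("x", "y")))
  }
  spec <- structure(
    list(image_size = as.integer(image_size),
         n_features = nrow(feature_centres),
         ln_radius = ln_radius, mz_thickness = mz_thickness,
         levels = levels, levels_clamped = clamped,
         feature_centres = feature_centres),
    class = "feature_image_spec")
  validate_feature_spec(spec)
  spec
}

validate_feature_spec <- function(spec) {
  r <- spec$ln_radius + spec$mz_thickness
  ctr <- spec$feature_centres
  out <- ctr[, 1] - r < 0 | ctr[, 1] + r > spec$image_size - 1 |
         ctr[, 2] - r < 0 | ctr[, 2] + r > spec$image_size - 1
  if (any(out))
    stop("feature at centre (", paste(round(ctr[which(out)[1], ], 2),
         collapse = ", "), ") exceeds image bounds")
  if (nrow(ctr) > 1) {
    dd <- as.matrix(dist(ctr))
    diag(dd) <- Inf
    bad <- which(dd < 2 * r, arr.ind = TRUE)
    if (nrow(bad))
      stop("features at centres (",
           paste(round(ctr[bad[1, 1], ], 2), collapse = ", "), ") and (",
           paste(round(ctr[bad[1, 2], ], 2), collapse = ", "), ") overlap")
  }
  invisible(spec)
}

#' Generate a 2-D spleen-feature image
#'
#' Pixels within `ln_radius` (boundary inclusive, centre-of-pixel
#' Euclidean distance) of a feature centre take the node level; the
#' annulus out to `ln_radius + mz_thickness` takes the marginal-zone
#' level; everything else is red pulp.
#'
#' @param spec a [feature_image_spec()].
#' @param voxel_size pixel edge length in micrometres (metadata only).
#' @return A 2-D quantised [image_volume()].
#' @export
generate_feature_image <- function(spec, voxel_size = 10.4) {
  stopifnot(inherits(spec, "feature_image_spec"))
  n <- spec$image_size
  xs <- matrix(0:(n - 1), n, n, byrow = TRUE)   # column index = x
  ys <- matrix(0:(n - 1), n, n)                 # row index = y
  img <- matrix(spec$levels[["rp"]], n, n)
  r_out <- spec$ln_radius + spec$mz_thickness
  for (f in seq_len(nrow(spec$feature_centres))) {
    d <- sqrt((xs - spec$feature_centres[f, 1])^2 +
              (ys - spec$feature_centres[f, 2])^2)
    if (spec$mz_thickness > 0)
      img[d <= r_out & d > spec$ln_radius] <- spec$levels[["mz"]]
    img[d <= spec$ln_radius] <- spec$levels[["ln"]]
  }
  prov <- sprintf("feature image: %d features, ln_radius=%g, mz_thickness=%g",
                  spec$n_features, spec$ln_radius, spec$mz_thickness)
  if (spec$levels_clamped) prov <- c(prov, "grey level > 255 clamped to 255")
  image_volume(img, voxel_size, "quantised-8bit", provenance = prov)
}

#' Specification of a 3-D spleen phantom
#'
#' Geometry is in voxels, intensities in arbitrary attenuation units with
#' the tissue ordering red pulp > marginal zone > white pulp (blood is
#' highly attenuating, so blood-rich tissue is bright). `cohort_scale`
#' shrinks the whole organ and its features linearly (a treated cohort
#' with 28% volume loss corresponds to `cohort_scale = 0.896`, since
#' 0.896^3 ~ 0.72); `feature_scale` additionally shrinks only the
#' internal features (nodule radius, shell thickness), emulating
#' marginal-zone contraction.
#'
#' @param grid_shape `(nx, ny, nz)` voxels.
#' @param voxel_size voxel edge length, micrometres.
#' @param spleen_semi_axes ellipsoid semi-axes `(a, b, c)` along
#'   `(x, y, z)`, voxels.
#' @param nodule_count number of white-pulp nodules.
#' @param nodule_radius_mean,nodule_radius_sd nodule radius distribution,
#'   voxels.
#' @param mz_thickness marginal-zone shell thickness, voxels.
#' @param rp_intensity,mz_intensity,wp_intensity,background_intensity,vessel_intensity
#'   attenuation levels; must satisfy rp > mz > wp.
#' @param vessel_count,vessel_radius bright vessel tubes through the organ.
#' @param noise_sd additive Gaussian noise, attenuation units.
#' @param artifact_count,artifact_intensity bright full-field streak lines.
#' @param cohort_scale linear organ+feature scale in (0, 1].
#' @param feature_scale extra linear scale on nodule radius and shell
#'   thickness only.
#' @param seed integer seed making generation deterministic.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(128, 128, 128), voxel_size = 26,
                         spleen_semi_axes = c(52, 44, 56),
                         nodule_count = 16,
                         nodule_radius_mean = 7, nodule_radius_sd = 1.2,
                         mz_thickness = 3,
                         rp_intensity = 1.0, mz_intensity = 0.55,
                         wp_intensity = 0.15, background_intensity = 0.02,
                         vessel_intensity = 1.35,
                         vessel_count = 5, vessel_radius = 2,
                         noise_sd = 0.04,
                         artifact_count = 2, artifact_intensity = 2.5,
                         cohort_scale = 1, feature_scale = 1,
                         seed = 1L) {
  spec <- structure(as.list(environment()), class = "phantom_spec")
  spec$grid_shape <- as.integer(grid_shape)
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    stopifnot(length(grid_shape) == 3L, all(grid_shape >= 8L),
              voxel_size > 0, length(spleen_semi_axes) == 3L,
              all(spleen_semi_axes > 0), nodule_count >= 0,
              nodule_radius_mean >= 0, nodule_radius_sd >= 0,
              mz_thickness >= 0, vessel_count >= 0, vessel_radius >= 0,
              noise_sd >= 0, artifact_count >= 0,
              cohort_scale > 0, cohort_scale <= 1, feature_scale > 0)
    if (!(rp_intensity > mz_intensity && mz_intensity > wp_intensity))
      stop("tissue intensities must satisfy rp > mz > wp ",
           "(blood-rich tissue is bright)")
  })
  invisible(spec)
}

#' Treated-cohort variant of a phantom specification
#'
#' Applies the treated-cohort defaults: linear organ scale 0.896 (i.e.
#' ~72% of the vehicle volume, a 28% loss) and an additional 0.9 linear
#' contraction of nodule radius and marginal-zone thickness.
#'
#' @param spec a vehicle [phantom_spec()].
#' @param cohort_scale,feature_scale treated-cohort scales.
#' @return A `phantom_spec`.
#' @export
treated_spec <- function(spec, cohort_scale = 0.896, feature_scale = 0.9) {
  stopifnot(inherits(spec, "phantom_spec"))
  spec$cohort_scale <- cohort_scale
  spec$feature_scale <- feature_scale
  validate_phantom_spec(spec)
  spec
}

# tissue label codes in ground-truth label volumes
PHANTOM_LABELS <- c(background = 0L, rp = 1L, mz = 2L, wp = 3L,
                    vessel = 4L, artifact = 5L)

#' Generate a 3-D spleen phantom
#'
#' Deterministic given `spec$seed`. Returns the noisy attenuation volume
#' and a ground truth holding the noiseless tissue-label volume, the
#' spleen voxel count (labels red pulp / marginal zone / white pulp /
#' vessel) and the nodule geometry.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `volume` ([image_volume()]) and `truth`
#'   (class `phantom_truth`).
#' @export
generate_spleen_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    nx <- spec$grid_shape[1]; ny <- spec$grid_shape[2]; nz <- spec$grid_shape[3]
    s <- spec$cohort_scale
    semi <- spec$spleen_semi_axes * s
    r_nod_mean <- spec$nodule_radius_mean * s * spec$feature_scale
    r_nod_sd <- spec$nodule_radius_sd * s * spec$feature_scale
    mz_t <- spec$mz_thickness * s * spec$feature_scale
    r_ves <- spec$vessel_radius * s

    ctr <- (c(nx, ny, nz) - 1) / 2
    xs <- array(rep(0:(nx - 1), each = ny), c(ny, nx, nz))
    ys <- array(0:(ny - 1), c(ny, nx, nz))
    zs <- array(rep(0:(nz - 1), each = nx * ny), c(ny, nx, nz))
    enorm <- sqrt(((xs - ctr[1]) / semi[1])^2 + ((ys - ctr[2]) / semi[2])^2 +
                  ((zs - ctr[3]) / semi[3])^2)
    label <- array(PHANTOM_LABELS[["background"]], c(ny, nx, nz))
    label[enorm <= 1] <- PHANTOM_LABELS[["rp"]]

    # nodule placement: rejection sampling with a minimum separation so
    # marginal-zone shells never merge
    nodules <- matrix(numeric(0), 0, 4,
                      dimnames = list(NULL, c("x", "y", "z", "radius")))
    tries <- 0L; max_tries <- 300L * max(1L, spec$nodule_count)
    while (nrow(nodules) < spec$nodule_count && tries < max_tries) {
      tries <- tries + 1L
      r <- max(1, rnorm(1, r_nod_mean, r_nod_sd))
      u <- runif(3, -1, 1)
      cand <- ctr + u * (semi - (r + mz_t + 1.5))
      if (any(semi - (r + mz_t + 1.5) <= 0)) break
      en <- sqrt(sum(((cand - ctr) / (semi - (r + mz_t + 1.5)))^2))
      if (en > 1) next
      if (nrow(nodules)) {
        dd <- sqrt(colSums((t(nodules[, 1:3, drop = FALSE]) - cand)^2))
        if (any(dd < nodules[, 4] + r + 2 * mz_t + 1)) next
      }
      nodules <- rbind(nodules, c(cand, r))
    }
    if (nrow(nodules) < spec$nodule_count)
      stop("could not place ", spec$nodule_count, " nodules; achieved ",
           nrow(nodules), " (reduce count/radius or enlarge the organ)")

    for (f in seq_len(nrow(nodules))) {
      d <- sqrt((xs - nodules[f, 1])^2 + (ys - nodules[f, 2])^2 +
                (zs - nodules[f, 3])^2)
      inside <- label != PHANTOM_LABELS[["background"]]
      if (mz_t > 0)
        label[inside & d <= nodules[f, 4] + mz_t & d > nodules[f, 4]] <-
          PHANTOM_LABELS[["mz"]]
      label[inside & d <= nodules[f, 4]] <- PHANTOM_LABELS[["wp"]]
    }

    # vessels: straight bright tubes through random chords of the organ
    for (v in seq_len(spec$vessel_count)) {
      p0 <- ctr + runif(3, -0.4, 0.4) * semi
      dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
      rel <- list(xs - p0[1], ys - p0[2], zs - p0[3])
      t_par <- rel[[1]] * dir[1] + rel[[2]] * dir[2] + rel[[3]] * dir[3]
      d_perp <- sqrt(pmax(0, rel[[1]]^2 + rel[[2]]^2 + rel[[3]]^2 - t_par^2))
      inside <- label != PHANTOM_LABELS[["background"]]
      label[inside & d_perp <= r_ves] <- PHANTOM_LABELS[["vessel"]]
    }

    intens <- c(spec$background_intensity, spec$rp_intensity,
                spec$mz_intensity, spec$wp_intensity, spec$vessel_intensity)
    values <- array(intens[label + 1L], dim(label))

    # streak artifacts: very bright straight lines across the whole field
    # (reconstruction streaks); labelled only where they lie outside the
    # organ so tissue ground truth stays intact
    for (a in seq_len(spec$artifact_count)) {
      z0 <- sample.int(nz, 1) - 1L
      y0 <- runif(1, 0, ny - 1)
      slope <- runif(1, -0.3, 0.3)
      line_y <- y0 + slope * (0:(nx - 1))
      sel_x <- which(line_y >= 0 & line_y <= ny - 1)
      iy <- as.integer(round(line_y[sel_x])) + 1L
      idx <- cbind(iy, sel_x, z0 + 1L)
      values[idx] <- values[idx] + spec$artifact_intensity
      bg <- label[idx] == PHANTOM_LABELS[["background"]]
      label[idx[bg, , drop = FALSE]] <- PHANTOM_LABELS[["artifact"]]
    }

    if (spec$noise_sd > 0)
      values <- values + rnorm(length(values), 0, spec$noise_sd)

    spleen_count <- sum(label >= PHANTOM_LABELS[["rp"]] &
                        label <= PHANTOM_LABELS[["vessel"]])
    truth <- structure(
      list(label_volume = label, spleen_voxel_count = spleen_count,
           nodule_centres_radii = as.data.frame(nodules),
           labels = PHANTOM_LABELS, spec = spec),
      class = "phantom_truth")
    list(volume = image_volume(values, spec$voxel_size, "raw-float",
                               provenance = sprintf(
                                 "spleen phantom seed=%s cohort_scale=%g feature_scale=%g",
                                 format(spec$seed), s, spec$feature_scale)),
         truth = truth)
  })
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> %s voxels, %d spleen voxels, %d nodules\n",
              paste(dim(x$label_volume)[c(2, 1, 3)], collapse = "x"),
              x$spleen_voxel_count, nrow(x$nodule_centres_radii)))
  invisible(x)
}

# spleen mask (tissue labels) from a ground truth
truth_mask <- function(truth) {
  truth$label_volume >= PHANTOM_LABELS[["rp"]] &
    truth$label_volume <= PHANTOM_LABELS[["vessel"]]
}

#' Generate a two-cohort phantom set
#'
#' `n_per_group` phantoms per label ("vehicle", "treated"), with
#' per-sample seeds derived reproducibly from `base_seed`.
#'
#' @param vehicle_spec,treated_spec [phantom_spec()]s for the two groups.
#' @param n_per_group samples per group (>= 1).
#' @param base_seed integer; per-sample seeds are derived from it.
#' @return A list of samples, each a list with `label`, `sample_id`,
#'   `seed`, `volume`, `truth`.
#' @export
generate_cohort <- function(vehicle_spec, treated_spec, n_per_group = 3,
                            base_seed = 1L) {
  stopifnot(inherits(vehicle_spec, "phantom_spec"),
            inherits(treated_spec, "phantom_spec"), n_per_group >= 1)
  specs <- c(rep(list(vehicle_spec), n_per_group),
             rep(list(treated_spec), n_per_group))
  labels <- rep(c("vehicle", "treated"), each = n_per_group)
  ids <- c(paste0("V", seq_len(n_per_group)), paste0("T", seq_len(n_per_group)))
  out <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    sp$seed <- derive_seed(base_seed, i)
    ph <- generate_spleen_phantom(sp)
    out[[i]] <- list(label = labels[i], sample_id = ids[i], seed = sp$seed,
                     volume = ph$volume, truth = ph$truth)
  }
  out
}

derive_seed <- function(base_seed, index) {
  as.integer((as.numeric(base_seed) * 1009 + 7919 * index) %% 2147483647)
}
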