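# Group-level statistics for small cohorts: the exact one-tailed
# Mann-Whitney U test by complete enumeration (with three animals per
# group the smallest attainable one-tailed p is exactly
# 1 / choose(6, 3) = 0.05, so asymptotic approximations are useless),
# group mean curves with separation ranges, peak-displacement summaries
# and percent change.

#' Exact one-tailed Mann-Whitney U test
#'
#' Enumerates all `choose(nA + nB, nA)` assignments of the pooled
#' observations to group A and computes the exact permutation
#' distribution of the U statistic (rank-sum form, midranks for ties).
#' The one-tailed p-value is the proportion of assignments with U at
#' least (`alternative = "greater"`) or at most (`"less"`) the observed
#' value. Restricted to `nA + nB <= 20` observations, where complete
#' enumeration is instant.
#'
#' @param group_a,group_b numeric measurement vectors.
#' @param alternative `"greater"` (A tends larger) or `"less"`.
#' @return An object of class `group_comparison` with `U` (for group A),
#'   `p_value`, `alternative`, the data and group sizes.
#' @export
mann_whitney_exact <- function(group_a, group_b,
                               alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  na <- length(group_a); nb <- length(group_b)
  if (na == 0 || nb == 0) stop("both groups must be non-empty")
  n <- na + nb
  if (n > 20)
    stop("exact enumeration is limited to 20 observations; ",
         "use a large-sample approximation instead (out of scope here)")
  r <- rank(c(group_a, group_b))  # midranks for ties
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  sets <- combn(n, na)
  u_perm <- colSums(matrix(r[sets], nrow = na)) - na * (na + 1) / 2
  eps <- 1e-9
  p <- if (alternative == "greater") mean(u_perm >= u_obs - eps)
       else mean(u_perm <= u_obs + eps)
  structure(list(U = u_obs, p_value = p, alternative = alternative,
                 n_a = na, n_b = nb, group_a = group_a, group_b = group_b,
                 n_assignments = ncol(sets)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "Exact Mann-Whitney U test (one-tailed, '%s')\n  n = %d vs %d, U = %g, p = %g (over %d assignments)\n",
    x$alternative, x$n_a, x$n_b, x$U, x$p_value, x$n_assignments))
  invisible(x)
}

#' Group mean curves and separation ranges
#'
#' Per-group mean of texture curves sharing one displacement grid, and
#' the displacements at which the groups separate completely (the
#' maximum of one group falls below the minimum of the other).
#'
#' @param curves list of `texture_curve`s.
#' @param labels group label per curve (two groups).
#' @return An object of class `separation_report`: `displacements`,
#'   `group_means` (matrix, one column per group), `separated` (logical
#'   per displacement), `separated_interval` (data frame of maximal
#'   runs).
#' @export
group_curves <- function(curves, labels) {
  stopifnot(length(curves) == length(labels), length(curves) >= 2)
  d <- curves[[1]]$displacements
  for (cu in curves)
    if (!identical(cu$displacements, d))
      stop("all curves must share the same displacement grid")
  labels <- as.character(labels)
  groups <- unique(labels)
  if (length(groups) != 2) stop("exactly two groups are required")
  vals <- vapply(curves, `[[`, numeric(length(d)), "values")
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = length(d))
  mean_by <- vapply(groups, function(g)
    rowMeans(vals[, labels == g, drop = FALSE]), numeric(length(d)))
  min_by <- vapply(groups, function(g)
    apply(vals[, labels == g, drop = FALSE], 1, min), numeric(length(d)))
  max_by <- vapply(groups, function(g)
    apply(vals[, labels == g, drop = FALSE], 1, max), numeric(length(d)))
  separated <- max_by[, 1] < min_by[, 2] | max_by[, 2] < min_by[, 1]
  runs <- rle(separated)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- runs$values
  separated_interval <- data.frame(d_start = d[starts[keep]],
                                   d_end = d[ends[keep]])
  structure(list(displacements = d, groups = groups, group_means = mean_by,
                 separated = separated,
                 separated_interval = separated_interval,
                 metric = curves[[1]]$metric),
            class = "separation_report")
}

#' @export
print.separation_report <- function(x, ...) {
  cat(sprintf("<separation_report> %s: groups %s vs %s, separated at %d/%d displacements\n",
              x$metric, x$groups[1], x$groups[2], sum(x$separated),
              length(x$displacements)))
  if (nrow(x$separated_interval))
    cat("  separated runs:",
        paste(sprintf("[%g, %g]", x$separated_interval$d_start,
                      x$separated_interval$d_end), collapse = " "), "\n")
  invisible(x)
}

#' Per-group peak-displacement summary
#'
#' Mean and spread of peak displacements per group; with two groups and
#' a voxel size, also the physical displacement difference
#' `(mean_1 - mean_2) * voxel_size` in micrometres.
#'
#' @param peaks list of `peak_estimate`s (or numeric displacements).
#' @param labels group label per peak.
#' @param spread `"sd"` (sample standard deviation, default) or `"sem"`.
#' @param voxel_size optional voxel edge length (micrometres).
#' @return An object of class `peak_stats`: per-group `mean`, `spread`,
#'   `n`, `n_at_boundary`, and `physical_difference_um` when applicable.
#' @export
peak_stats <- function(peaks, labels, spread = c("sd", "sem"),
                       voxel_size = NULL) {
  spread <- match.arg(spread)
  stopifnot(length(peaks) == length(labels), length(peaks) >= 1)
  disp <- vapply(peaks, function(p)
    if (inherits(p, "peak_estimate")) p$displacement else as.numeric(p), 0)
  bnd <- vapply(peaks, function(p)
    inherits(p, "peak_estimate") && isTRUE(p$at_boundary), FALSE)
  labels <- as.character(labels)
  groups <- unique(labels)
  per_group <- lapply(groups, function(g) {
    x <- disp[labels == g]
    s <- if (length(x) > 1) sd(x) else NA_real_
    if (spread == "sem" && !is.na(s)) s <- s / sqrt(length(x))
    list(mean = mean(x), spread = s, n = length(x),
         n_at_boundary = sum(bnd[labels == g]))
  })
  names(per_group) <- groups
  out <- list(groups = groups, per_group = per_group,
              spread_convention = spread)
  if (length(groups) == 2 && !is.null(voxel_size))
    out$physical_difference_um <-
      (per_group[[1]]$mean - per_group[[2]]$mean) * voxel_size
  structure(out, class = "peak_stats")
}

#' @export
print.peak_stats <- function(x, ...) {
  for (g in x$groups) {
    pg <- x$per_group[[g]]
    cat(sprintf("  %s: peak d = %.3f +/- %.3f px (%s, n = %d%s)\n", g,
                pg$mean, pg$spread, x$spread_convention, pg$n,
                if (pg$n_at_boundary)
                  sprintf(", %d at sweep boundary", pg$n_at_boundary) else ""))
  }
  if (!is.null(x$physical_difference_um))
    cat(sprintf("  physical difference: %.4g um\n", x$physical_difference_um))
  invisible(x)
}

#' Percent change relative to a reference
#'
#' `100 (reference - comparison) / reference`; e.g. mean volumes 61 and
#' 44 mm^3 give 27.9, a 28% shrinkage.
#'
#' @param reference_mean positive reference value.
#' @param comparison_mean comparison value.
#' @return Percent change (positive = decrease).
#' @export
percent_change <- function(reference_mean, comparison_mean) {
  if (!is.numeric(reference_mean) || reference_mean <= 0)
    stop("'reference_mean' must be positive")
  100 * (reference_mean - comparison_mean) / reference_mean
}
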