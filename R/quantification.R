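# Immunofluorescence and compression-assay quantification: nuclear and
# membrane protein expression, pooled-Otsu positivity calling,
# triangle-threshold viability, Hotelling's two-sample T-squared,
# Mann-Whitney wrapper, and per-patient bivariate summary statistics.

#' Nuclear protein expression of one nucleus
#'
#' Total in-mask stain intensity divided by the mask volume. The
#' denominator defaults to the voxel count (units: intensity per
#' voxel); set `per_um3 = TRUE` for physical um^-3 density.
#'
#' @param stack co-registered stain [image_stack].
#' @param mask logical 3D nuclear mask.
#' @param per_um3 use physical volume as denominator.
#' @return Numeric expression value.
#' @export
nuclear_expression <- function(stack, mask, per_um3 = FALSE) {
  stopifnot(inherits(stack, "image_stack"), all(dim(mask) == dim(stack$voxels)))
  nvox <- sum(mask != 0)
  if (nvox == 0) stop("empty nuclear mask")
  denom <- if (per_um3) nvox * voxel_volume(stack$spacing) else nvox
  sum(stack$voxels[mask != 0]) / denom
}

#' Membrane / cytoplasmic expression density of one cell
#'
#' Dilates the nuclear mask by `radius_um` (default 2 um, physical
#' units) and returns the total stain intensity inside the dilated mask
#' divided by its volume. Cohort-level min-max scaling to `[0, 1]` is a
#' separate step ([membrane_expression_norm()]) because the scale is
#' defined across all analyzed cells.
#'
#' @param stack stain [image_stack].
#' @param mask logical 3D nuclear mask.
#' @param radius_um dilation radius in um.
#' @param per_um3 use physical volume as denominator.
#' @return Numeric density.
#' @export
membrane_expression_density <- function(stack, mask, radius_um = 2,
                                        per_um3 = FALSE) {
  stopifnot(inherits(stack, "image_stack"))
  dmask <- dilate_mask(mask, radius_um = radius_um, spacing = stack$spacing)
  nuclear_expression(stack, dmask, per_um3 = per_um3)
}

#' Min-max normalized membrane expression across a cell cohort
#'
#' @param densities numeric vector of per-cell densities (one channel,
#'   all disease groups pooled).
#' @return Values scaled to `[0, 1]`; degenerate cohorts map to 0 with
#'   a warning.
#' @export
membrane_expression_norm <- function(densities) {
  minmax_scale(densities)
}

#' Positivity calling by pooled Otsu threshold
#'
#' A single Otsu threshold is computed on the pooled histogram of
#' normalized expression values from all cells (all disease stages
#' together); cells strictly above the threshold are positive.
#'
#' @param values normalized expression values.
#' @param groups optional grouping (e.g. disease stage) for per-group
#'   positive fractions.
#' @param nbins histogram bins for the threshold.
#' @return list with `threshold`, `positive` (logical), and
#'   `positive_fraction` (overall, or per group).
#' @export
positivity_by_otsu <- function(values, groups = NULL, nbins = 256) {
  thr <- otsu_threshold(values, nbins = nbins)
  pos <- values > thr
  frac <- if (is.null(groups)) mean(pos) else
    tapply(pos, groups, mean)
  list(threshold = thr, positive = pos, positive_fraction = frac)
}

#' Viability from DRAQ7 intensity by triangle thresholding
#'
#' DRAQ7 marks membrane-compromised (dead) cells, so cells *below* the
#' triangle threshold of the per-nucleus DRAQ7 intensity histogram are
#' live.
#'
#' @param intensities per-nucleus DRAQ7 intensities (>= 10 cells).
#' @param nbins histogram bins.
#' @return list with `threshold`, `live` (logical), `live_fraction`.
#' @export
viability_triangle <- function(intensities, nbins = 128) {
  if (length(intensities) < 10) stop("viability needs at least 10 cells")
  # the dead population is high-intensity, so threshold the upper tail
  thr <- triangle_threshold(intensities, nbins = nbins, tail = "upper")
  live <- intensities < thr
  list(threshold = thr, live = live, live_fraction = mean(live))
}

#' Two-sample Hotelling's T-squared test
#'
#' Compares bivariate (or p-variate) group means of per-patient
#' observations with the standard pooled-covariance T-squared statistic
#' and its exact F transformation.
#'
#' @param group_a,group_b numeric matrices (patients x variables).
#' @return list with `T2`, `F`, `df1`, `df2`, `p_value`.
#' @export
hotelling_two_sample <- function(group_a, group_b) {
  A <- as.matrix(group_a); B <- as.matrix(group_b)
  stopifnot(ncol(A) == ncol(B))
  p <- ncol(A)
  n1 <- nrow(A); n2 <- nrow(B)
  if (n1 < 3 || n2 < 3) stop("each group needs at least 3 patients")
  d <- colMeans(A) - colMeans(B)
  S <- ((n1 - 1) * cov(A) + (n2 - 1) * cov(B)) / (n1 + n2 - 2)
  Sinv <- tryCatch(solve(S), error = function(e)
    stop("singular pooled covariance"))
  T2 <- (n1 * n2) / (n1 + n2) * as.numeric(t(d) %*% Sinv %*% d)
  df2 <- n1 + n2 - p - 1
  Fstat <- T2 * df2 / ((n1 + n2 - 2) * p)
  list(T2 = T2, F = Fstat, df1 = p, df2 = df2,
       p_value = pf(Fstat, p, df2, lower.tail = FALSE))
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison: exact enumeration for small samples
#' without ties, tie-corrected normal approximation otherwise (the
#' behavior of [stats::wilcox.test()]).
#'
#' @param values_a,values_b numeric samples.
#' @return list with `U` and `p_value`.
#' @export
mann_whitney <- function(values_a, values_b) {
  stopifnot(length(values_a) > 0, length(values_b) > 0)
  wt <- suppressWarnings(wilcox.test(values_a, values_b, exact = NULL,
                                     correct = TRUE))
  list(U = unname(wt$statistic), p_value = wt$p.value)
}

#' Box-plot statistics under the reporting conventions
#'
#' Box limits at the 25th/75th percentiles (linear-interpolation
#' quantiles), whiskers at 1.5 x IQR fences, values beyond the fences
#' flagged as outliers.
#'
#' @param values numeric vector.
#' @return list with `q1`, `median`, `q3`, `lower_fence`,
#'   `upper_fence`, `outliers`.
#' @export
boxplot_stats <- function(values) {
  q <- quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lf <- q[1] - 1.5 * iqr
  uf <- q[3] + 1.5 * iqr
  list(q1 = q[1], median = q[2], q3 = q[3],
       lower_fence = lf, upper_fence = uf,
       outliers = values[values < lf | values > uf])
}

# 1-SD ellipse of a set of bivariate points: center, principal axis
# standard deviations, orientation (radians)
sd_ellipse <- function(xy) {
  xy <- as.matrix(xy)
  ctr <- colMeans(xy)
  if (nrow(xy) < 2) {
    return(list(center = ctr, radii = c(0, 0), angle = 0))
  }
  cv <- cov(xy)
  e <- eigen(cv, symmetric = TRUE)
  list(center = ctr, radii = sqrt(pmax(0, e$values)),
       angle = atan2(e$vectors[2, 1], e$vectors[1, 1]))
}

#' Compression-assay summary statistics
#'
#' Per patient and assay arm: mean and SEM of the projected area and of
#' the mean nuclear-dye intensity. Per condition and arm: the 1-SD
#' ellipse of the patient-level means and pairwise Hotelling T-squared
#' p-values between conditions on the (area, intensity) patient means.
#'
#' @param nuclei `data.frame` with `individual_id`, `condition`, `arm`
#'   (e.g. control / compressed), `projected_area_um2`,
#'   `mean_intensity`.
#' @return list of class `compression_summary` with `patient_stats`,
#'   `ellipses`, `hotelling`.
#' @export
compression_summary <- function(nuclei) {
  need <- c("individual_id", "condition", "arm",
            "projected_area_um2", "mean_intensity")
  stopifnot(all(need %in% names(nuclei)))
  sem <- function(x) if (length(x) < 2) NA_real_ else sd(x) / sqrt(length(x))
  ps <- aggregate(
    cbind(projected_area_um2, mean_intensity) ~ individual_id + condition + arm,
    data = nuclei, FUN = mean
  )
  names(ps)[4:5] <- c("area_mean", "intensity_mean")
  sems <- aggregate(
    cbind(projected_area_um2, mean_intensity) ~ individual_id + condition + arm,
    data = nuclei, FUN = sem
  )
  ps$area_sem <- sems$projected_area_um2
  ps$intensity_sem <- sems$mean_intensity
  ps$n_nuclei <- aggregate(mean_intensity ~ individual_id + condition + arm,
                           data = nuclei, FUN = length)$mean_intensity
  if (any(ps$n_nuclei < 2)) {
    warning("patient-arm group(s) with a single nucleus: SEM undefined")
  }
  ellipses <- list()
  hotelling <- list()
  for (arm in unique(ps$arm)) {
    sub <- ps[ps$arm == arm, ]
    conds <- unique(sub$condition)
    for (cond in conds) {
      xy <- sub[sub$condition == cond, c("area_mean", "intensity_mean")]
      ellipses[[paste(arm, cond, sep = ":")]] <- sd_ellipse(xy)
    }
    if (length(conds) >= 2) {
      pairs <- utils::combn(sort(conds), 2)
      for (j in seq_len(ncol(pairs))) {
        a <- pairs[1, j]; b <- pairs[2, j]
        ht <- tryCatch(
          hotelling_two_sample(
            sub[sub$condition == a, c("area_mean", "intensity_mean")],
            sub[sub$condition == b, c("area_mean", "intensity_mean")]
          ),
          error = function(e) list(p_value = NA_real_)
        )
        hotelling[[paste(arm, a, "vs", b)]] <- ht$p_value
      }
    }
  }
  structure(list(patient_stats = ps, ellipses = ellipses,
                 hotelling = unlist(hotelling)),
            class = "compression_summary")
}
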