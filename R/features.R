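# Handcrafted nuclear and dense-chromatin morphometrics. The feature
# list is a documented approximation of the published morphometric set:
# size, projection shape, intensity distribution, and the dense-domain
# geometry descriptors D3 (median radial domain placement, normalized by
# the equivalent radius) and D4 (median domain-to-boundary separation in
# um) that are the most disease-discriminative descriptors here.

#' Maximum-intensity z projection
#'
#' @param stack an [image_stack] (or a plain 3D array).
#' @param mask logical 3D array; voxels outside the mask are ignored
#'   (treated as 0).
#' @return list with `image` (2D numeric matrix of per-pixel maxima) and
#'   `mask` (2D logical z-union of the 3D mask).
#' @export
max_z_projection <- function(stack, mask = NULL) {
  vox <- if (inherits(stack, "image_stack")) stack$voxels else stack
  stopifnot(is.array(vox), length(dim(vox)) == 3)
  if (!is.null(mask)) {
    stopifnot(all(dim(mask) == dim(vox)))
    vox <- vox * (mask != 0)
  }
  img <- apply(vox, c(1, 2), max)
  m2 <- if (is.null(mask)) img > 0 else apply(mask != 0, c(1, 2), any)
  list(image = img, mask = m2)
}

#' Detect dense chromatin domains inside a nuclear mask
#'
#' Thresholds in-mask intensities at their `q`-quantile, labels the
#' 6-connected super-threshold components, and discards components
#' smaller than `min_voxels`. A constant-intensity nucleus yields an
#' empty domain set.
#'
#' @param stack an [image_stack].
#' @param mask logical 3D array (the nucleus).
#' @param q in-mask intensity quantile in (0, 1); default 0.85.
#' @param min_voxels minimum component size in voxels; default 8.
#' @return `data.frame` with one row per domain: physical centroid (um),
#'   `voxel_count`, `mean_intensity`.
#' @export
detect_dense_domains <- function(stack, mask, q = 0.85, min_voxels = 8) {
  stopifnot(inherits(stack, "image_stack"), q > 0, q < 1)
  vox <- stack$voxels
  stopifnot(all(dim(mask) == dim(vox)))
  inmask <- vox[mask != 0]
  if (length(inmask) == 0) stop("empty nuclear mask")
  empty <- data.frame(
    centroid_x = numeric(0), centroid_y = numeric(0), centroid_z = numeric(0),
    voxel_count = integer(0), mean_intensity = numeric(0)
  )
  if (diff(range(inmask)) == 0) return(empty)
  thr <- quantile(inmask, q, names = FALSE)
  dm <- (vox > thr) & (mask != 0)
  labels <- label_components(dm)
  k <- max(labels)
  if (k == 0) return(empty)
  counts <- tabulate(labels[labels > 0], nbins = k)
  keep <- which(counts >= min_voxels)
  if (length(keep) == 0) return(empty)
  sp <- stack$spacing
  rows <- lapply(keep, function(l) {
    idx <- which(labels == l)
    pos <- arrayInd(idx, dim(labels))
    ctr <- (colMeans(pos) - 0.5) * sp
    data.frame(
      centroid_x = ctr[1], centroid_y = ctr[2], centroid_z = ctr[3],
      voxel_count = counts[l], mean_intensity = mean(vox[idx])
    )
  })
  do.call(rbind, rows)
}

#' Domain geometry descriptors D3 and D4
#'
#' D3 is the median over domains of the distance from domain centroid to
#' the nuclear centroid, normalized by the nucleus' equivalent-sphere
#' radius (size-comparable across nuclei). D4 is the median physical
#' distance (um) from domain centroids to the nearest voxel outside the
#' nuclear mask. An empty domain set gives both as 0. The unnormalized
#' D3 (um) is returned as well.
#'
#' @param domains output of [detect_dense_domains()].
#' @param mask logical 3D nuclear mask.
#' @param spacing `(dx, dy, dz)` in um.
#' @return Named numeric vector `c(d3, d4_um, d3_um)`.
#' @export
domain_geometry <- function(domains, mask, spacing = c(0.25, 0.25, 1)) {
  if (nrow(domains) == 0) return(c(d3 = 0, d4_um = 0, d3_um = 0))
  idx <- which(mask != 0)
  pos <- arrayInd(idx, dim(mask))
  nuc_ctr <- (colMeans(pos) - 0.5) * spacing
  eq_r <- effective_diameter(length(idx), spacing) / 2
  cen <- as.matrix(domains[, c("centroid_x", "centroid_y", "centroid_z")])
  d_ctr <- sqrt(rowSums(sweep(cen, 2, nuc_ctr)^2))

  # distance from each domain centroid to the nearest outside-mask voxel,
  # searched in the mask bounding box expanded by one voxel
  d <- dim(mask)
  lo <- pmax(apply(pos, 2, min) - 1L, 1L)
  hi <- pmin(apply(pos, 2, max) + 1L, d)
  sub <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  out_idx <- which(sub == 0)
  d_bnd <- rep(Inf, nrow(cen))
  if (length(out_idx) > 0) {
    opos <- arrayInd(out_idx, dim(sub))
    opos <- sweep(opos, 2, lo - 1L, "+")
    ophys <- sweep(opos - 0.5, 2, spacing, "*")
    for (i in seq_len(nrow(cen))) {
      d_bnd[i] <- sqrt(min(rowSums(sweep(ophys, 2, cen[i, ])^2)))
    }
  }
  c(d3 = median(d_ctr) / eq_r, d4_um = median(d_bnd), d3_um = median(d_ctr))
}

# 2D shape descriptors of a projected mask: eccentricity from second
# central moments, solidity against the rasterized convex hull.
projection_shape <- function(mask2d, spacing_xy) {
  pix <- which(mask2d, arr.ind = TRUE)
  if (nrow(pix) < 3) return(c(eccentricity = 0, solidity = 1))
  xy <- sweep(pix - 0.5, 2, spacing_xy, "*")
  cv <- cov(xy) * (nrow(xy) - 1) / nrow(xy)
  ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ecc <- if (ev[1] <= 0) 0 else sqrt(max(0, 1 - ev[2] / ev[1]))
  hull <- chull(xy)
  hx <- xy[hull, 1]; hy <- xy[hull, 2]
  # count pixel centers inside (or on) the hull polygon: even-odd rule
  cand <- which(array(TRUE, dim(mask2d)), arr.ind = TRUE)
  cxy <- sweep(cand - 0.5, 2, spacing_xy, "*")
  nh <- length(hx)
  inside <- rep(FALSE, nrow(cxy))
  j <- nh
  for (i in seq_len(nh)) {
    xi <- hx[i]; yi <- hy[i]; xj <- hx[j]; yj <- hy[j]
    crosses <- ((yi > cxy[, 2]) != (yj > cxy[, 2])) &
      (cxy[, 1] < (xj - xi) * (cxy[, 2] - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside <- inside | mask2d[cand] # mask pixels always count as convex area
  convex_area <- sum(inside)
  c(eccentricity = ecc, solidity = min(1, nrow(pix) / max(1, convex_area)))
}

#' Handcrafted feature vector for one segmented nucleus
#'
#' @param stack an [image_stack].
#' @param mask logical 3D array selecting the nucleus' voxels.
#' @param q,min_voxels dense-domain detector parameters, see
#'   [detect_dense_domains()].
#' @return One-row `data.frame` of named features: `volume_um3`,
#'   `projected_area_um2`, `equivalent_diameter_um`, `mean_intensity`,
#'   `intensity_sd`, `intensity_skewness`, `eccentricity`, `solidity`,
#'   `n_dense_domains`, `d3_radial` (normalized), `d3_um`,
#'   `d4_boundary_um`, `dense_chromatin_fraction`.
#' @export
compute_features <- function(stack, mask, q = 0.85, min_voxels = 8) {
  stopifnot(inherits(stack, "image_stack"))
  sp <- stack$spacing
  nvox <- sum(mask != 0)
  if (nvox == 0) stop("empty nuclear mask")
  inten <- stack$voxels[mask != 0]
  proj <- max_z_projection(stack, mask)
  shape <- projection_shape(proj$mask, sp[1:2])
  domains <- detect_dense_domains(stack, mask, q = q, min_voxels = min_voxels)
  geom <- domain_geometry(domains, mask, sp)
  data.frame(
    volume_um3 = nvox * voxel_volume(sp),
    projected_area_um2 = sum(proj$mask) * sp[1] * sp[2],
    equivalent_diameter_um = effective_diameter(nvox, sp),
    mean_intensity = mean(inten),
    intensity_sd = sd(inten) * sqrt((length(inten) - 1) / length(inten)),
    intensity_skewness = skewness(inten),
    eccentricity = unname(shape["eccentricity"]),
    solidity = unname(shape["solidity"]),
    n_dense_domains = nrow(domains),
    d3_radial = unname(geom["d3"]),
    d3_um = unname(geom["d3_um"]),
    d4_boundary_um = unname(geom["d4_um"]),
    dense_chromatin_fraction = sum(domains$voxel_count) / nvox
  )
}

#' Feature matrix for all nuclei of a segmented stack
#'
#' Runs [compute_features()] on every labeled nucleus of a
#' [segment_stack()] result.
#'
#' @param stack the [image_stack] that was segmented.
#' @param segmentation result of [segment_stack()].
#' @param ... passed to [compute_features()].
#' @return `data.frame` with one row per nucleus, keyed by `label_id`.
#' @export
compute_feature_matrix <- function(stack, segmentation, ...) {
  recs <- segmentation$records
  if (nrow(recs) == 0) {
    return(cbind(recs[, c("label_id", "individual_id", "condition"), drop = FALSE]))
  }
  rows <- lapply(seq_len(nrow(recs)), function(i) {
    mask <- segmentation$labels == recs$label_id[i]
    cbind(
      recs[i, c("label_id", "individual_id", "condition"), drop = FALSE],
      compute_features(stack, mask, ...)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
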