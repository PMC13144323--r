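# Nuclear segmentation of 8-bit 3D stacks: conditional multi-Otsu
# threshold selection, 6-connectivity labeling, and physical-unit
# effective-diameter filtering.

#' Select the segmentation threshold for a stack
#'
#' Computes the two 3-class multi-Otsu thresholds `t1 <= t2` on the full
#' 3D intensity histogram and applies the conditional rule: use the
#' minimum if it exceeds 10 (strictly), otherwise the maximum. The low
#' guard protects against the first threshold collapsing into the dark
#' background band on low-contrast images.
#'
#' @param stack an [image_stack].
#' @return Integer threshold; voxels with intensity `>=` the threshold
#'   are foreground.
#' @export
select_threshold <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  th <- multiotsu_thresholds(stack$voxels)
  if (min(th) > 10) min(th) else max(th)
}

#' Equivalent-sphere diameter of a voxel region
#'
#' Diameter (um) of the sphere whose volume equals
#' `voxel_count * dx * dy * dz`.
#'
#' @param voxel_count positive integer voxel count.
#' @param spacing `(dx, dy, dz)` in um.
#' @return Numeric diameter in um.
#' @export
effective_diameter <- function(voxel_count, spacing) {
  stopifnot(all(voxel_count > 0))
  vol <- voxel_count * voxel_volume(spacing)
  (6 * vol / pi)^(1 / 3)
}

#' Segment all nuclei in a stack
#'
#' Thresholds the stack ([select_threshold()], inclusive comparison),
#' labels 6-connected components ([label_components()]), measures each
#' component's equivalent-sphere diameter, and keeps regions with
#' diameters in the closed interval `[min_diameter, max_diameter]` um.
#' Surviving labels are re-indexed densely from 1.
#'
#' @param stack an [image_stack].
#' @param min_diameter,max_diameter diameter filter bounds in um.
#' @param individual_id,condition optional provenance carried into the
#'   records.
#' @return A list with `records` (one row per kept nucleus: `label_id`,
#'   `voxel_count`, `effective_diameter`, centroid and bounding box in
#'   physical um) and `labels` (filtered, re-indexed label array).
#' @export
segment_stack <- function(stack, min_diameter = 4.5, max_diameter = 13.5,
                          individual_id = NA_character_,
                          condition = NA_character_) {
  stopifnot(inherits(stack, "image_stack"))
  thr <- select_threshold(stack)
  mask <- stack$voxels >= thr
  labels <- label_components(mask)
  sp <- stack$spacing
  empty <- list(
    records = data.frame(
      label_id = integer(0), voxel_count = integer(0),
      effective_diameter = numeric(0),
      centroid_x = numeric(0), centroid_y = numeric(0), centroid_z = numeric(0),
      bbox_x0 = integer(0), bbox_x1 = integer(0),
      bbox_y0 = integer(0), bbox_y1 = integer(0),
      bbox_z0 = integer(0), bbox_z1 = integer(0),
      individual_id = character(0), condition = character(0),
      stringsAsFactors = FALSE
    ),
    labels = labels, threshold = thr
  )
  k <- max(labels)
  if (k == 0) return(empty)
  idx <- which(labels > 0)
  lab <- labels[idx]
  pos <- arrayInd(idx, dim(labels))
  counts <- tabulate(lab, nbins = k)
  diam <- effective_diameter(counts, sp)
  keep <- which(diam >= min_diameter & diam <= max_diameter)
  if (length(keep) == 0) {
    empty$labels <- array(0L, dim(labels))
    return(empty)
  }
  relab <- integer(k)
  relab[keep] <- seq_along(keep)
  new_labels <- array(0L, dim(labels))
  sel <- lab %in% keep
  new_labels[idx[sel]] <- relab[lab[sel]]
  recs <- lapply(seq_along(keep), function(j) {
    old <- keep[j]
    rows <- pos[lab == old, , drop = FALSE]
    ctr <- (colMeans(rows) - 0.5) * sp
    data.frame(
      label_id = j,
      voxel_count = counts[old],
      effective_diameter = diam[old],
      centroid_x = ctr[1], centroid_y = ctr[2], centroid_z = ctr[3],
      bbox_x0 = min(rows[, 1]), bbox_x1 = max(rows[, 1]),
      bbox_y0 = min(rows[, 2]), bbox_y1 = max(rows[, 2]),
      bbox_z0 = min(rows[, 3]), bbox_z1 = max(rows[, 3]),
      individual_id = individual_id, condition = condition,
      stringsAsFactors = FALSE
    )
  })
  list(records = do.call(rbind, recs), labels = new_labels, threshold = thr)
}
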