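# FOV preparation for the latent representation: maximum-intensity
# projection of each segmented nucleus centered in a zero-padded
# 128x128 frame, and the train/validation/test split.

#' Split FOVs into train / validation / test sets
#'
#' Uses the assay's standard split proportions (85.5% / 4.55% / 10%).
#' Fractions are treated as weights and converted to integer set sizes
#' by the largest-remainder rule (any sub-unity remainder goes to the
#' training set); the assignment itself is a seeded uniform shuffle.
#'
#' @param n number of FOVs (or anything with a length to tag).
#' @param fractions train/val/test weights.
#' @param seed RNG seed.
#' @return Factor of length `n` with levels `train`, `val`, `test`.
#' @export
make_splits <- function(n, fractions = c(0.855, 0.0455, 0.10), seed = 1) {
  if (length(n) > 1) n <- length(n)
  n <- as.integer(n)
  if (n < 3) stop("need at least 3 FOVs to split")
  stopifnot(length(fractions) == 3, all(fractions >= 0), sum(fractions) > 0)
  w <- fractions / max(1, sum(fractions))
  quota <- n * w
  base <- floor(quota)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  # any rounding shortfall when fractions sum below 1 goes to train
  short <- n - sum(base)
  base[1] <- base[1] + short
  tags <- rep(c("train", "val", "test"), times = base)
  with_seed(seed, factor(sample(tags), levels = c("train", "val", "test")))
}

#' Preprocess one nucleus into a 128x128 FOV
#'
#' Maximum-intensity z projection of the masked nucleus, cropped to the
#' mask bounding box, centered in a zero-padded square frame, and
#' scaled to `[0, 1]` by the 8-bit maximum.
#'
#' @param stack an [image_stack].
#' @param mask logical 3D nucleus mask.
#' @param size frame side length in pixels (default 128).
#' @return `size x size` numeric matrix in `[0, 1]`.
#' @export
preprocess_fov <- function(stack, mask, size = 128) {
  proj <- max_z_projection(stack, mask)
  img <- proj$image
  m2 <- proj$mask
  if (!any(m2)) {
    return(matrix(0, size, size))
  }
  pix <- which(m2, arr.ind = TRUE)
  x0 <- min(pix[, 1]); x1 <- max(pix[, 1])
  y0 <- min(pix[, 2]); y1 <- max(pix[, 2])
  crop <- img[x0:x1, y0:y1, drop = FALSE] * m2[x0:x1, y0:y1, drop = FALSE]
  w <- nrow(crop); h <- ncol(crop)
  if (w > size || h > size)
    stop("projection (", w, "x", h, ") larger than the ", size, "x", size, " frame")
  out <- matrix(0, size, size)
  ox <- floor((size - w) / 2)
  oy <- floor((size - h) / 2)
  out[(ox + 1):(ox + w), (oy + 1):(oy + h)] <- crop / 255
  out
}

#' Build the FOV array for a set of segmented nuclei
#'
#' @param stacks list of [image_stack]s.
#' @param masks list of matching 3D masks.
#' @param size frame side length.
#' @return `(size, size, N)` numeric array.
#' @export
build_fov_array <- function(stacks, masks, size = 128) {
  stopifnot(length(stacks) == length(masks))
  n <- length(stacks)
  out <- array(0, c(size, size, n))
  for (i in seq_len(n)) {
    out[, , i] <- preprocess_fov(stacks[[i]], masks[[i]], size = size)
  }
  out
}
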