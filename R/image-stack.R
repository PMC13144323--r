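# The ImageStack container: an 8-bit 3D voxel grid with physical spacing
# and a channel tag, plus plain multi-page TIFF I/O.

#' Construct an 8-bit 3D image stack
#'
#' @param voxels 3D integer array with values in `[0, 255]`. Dimensions
#'   are `(x, y, z)`.
#' @param spacing numeric triple `(dx, dy, dz)` in micrometres; defaults
#'   to the assay's confocal geometry of 250 nm in-plane and 1 um axial.
#' @param channel stain name, e.g. `"nuclear_dye"`.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(voxels, spacing = c(0.25, 0.25, 1), channel = "nuclear_dye") {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3)
  if (any(voxels < 0) || any(voxels > 255))
    stop("image_stack requires 8-bit voxel values in [0, 255]")
  if (length(spacing) != 3 || any(spacing <= 0))
    stop("spacing must be three positive values (dx, dy, dz) in um")
  structure(
    list(
      voxels = array(as.integer(round(voxels)), dim(voxels)),
      spacing = as.numeric(spacing),
      channel = channel
    ),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<image_stack> %dx%dx%d voxels, spacing (%.3g, %.3g, %.3g) um, channel '%s'\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3], x$channel
  ))
  invisible(x)
}

#' Write an image stack as a multi-page 8-bit TIFF
#'
#' One page per z slice; values stored as gray levels 0..255.
#'
#' @param stack an [image_stack].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$voxels)
  pages <- lapply(seq_len(d[3]), function(z) {
    # TIFF pages are row-major 2D matrices (rows = y)
    t(stack$voxels[, , z]) / 255
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "none")
  invisible(path)
}

#' Read a multi-page 8-bit TIFF into an image stack
#'
#' @param path TIFF file path.
#' @param spacing voxel spacing `(dx, dy, dz)` in um.
#' @param channel stain name.
#' @return An [image_stack].
#' @export
read_stack <- function(path, spacing = c(0.25, 0.25, 1), channel = "nuclear_dye") {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nx <- ncol(pages[[1]])
  ny <- nrow(pages[[1]])
  vox <- array(0L, c(nx, ny, length(pages)))
  for (z in seq_along(pages)) {
    vox[, , z] <- as.integer(round(t(pages[[z]]) * 255))
  }
  image_stack(vox, spacing = spacing, channel = channel)
}
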