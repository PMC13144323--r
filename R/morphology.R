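# Binary 3D morphology: face-connected component labeling and the
# anisotropic Euclidean distance transform used for boundary distances
# and physical-unit mask dilation.

#' Label 6-connected components of a binary 3D mask
#'
#' Voxels are connected only through shared faces (the 6-neighborhood);
#' in-plane diagonal contact does not join components. Components are
#' labeled 1..K in order of their first voxel in array (column-major)
#' order, background is 0.
#'
#' @param mask logical or 0/1 3D array.
#' @return Integer array of the same dimension with component labels.
#' @export
label_components <- function(mask) {
  stopifnot(is.array(mask), length(dim(mask)) == 3)
  mask <- mask != 0
  d <- dim(mask)
  labels <- array(0L, d)
  idx <- which(mask)
  if (length(idx) == 0) return(labels)
  pos <- arrayInd(idx, d)
  # map voxel linear index -> vertex id
  vid <- array(0L, d)
  vid[idx] <- seq_along(idx)
  edges <- NULL
  for (axis in 1:3) {
    ok <- pos[, axis] < d[axis]
    if (!any(ok)) next
    step <- c(1L, d[1], d[1] * d[2])[axis]
    nb <- idx[ok] + step
    hit <- mask[nb]
    if (!any(hit)) next
    edges <- rbind(edges, cbind(vid[idx[ok][hit]], vid[nb[hit]]))
  }
  if (is.null(edges) || nrow(edges) == 0) {
    comp <- seq_along(idx) # all isolated voxels
    labels[idx] <- comp
    return(labels)
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(idx) - igraph::vcount(g)))
  memb <- igraph::components(g)$membership
  # relabel deterministically by first occurrence in array order
  first <- match(unique(memb), memb)
  relab <- integer(max(memb))
  relab[memb[sort(first)]] <- seq_along(first)
  labels[idx] <- relab[memb]
  labels
}

# Felzenszwalb & Huttenlocher 1D squared distance transform of a
# sampled function f with sample step `w` (physical units).
dt1d <- function(f, w) {
  n <- length(f)
  if (n == 1) return(f)
  d <- numeric(n)
  v <- integer(n)  # parabola sites
  z <- numeric(n + 1)
  k <- 1L
  v[1] <- 1L
  z[1] <- -Inf
  z[2] <- Inf
  w2 <- w * w
  for (q in 2:n) {
    if (!is.finite(f[q]) && !is.finite(f[v[k]])) {
      # both infinite: skip adding (site useless) unless current is finite
      next
    }
    repeat {
      s <- ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
        (2 * w2 * (q - v[k]))
      if (s <= z[k]) {
        k <- k - 1L
        if (k == 0L) { k <- 1L; v[1] <- q; z[1] <- -Inf; z[2] <- Inf; break }
      } else {
        k <- k + 1L
        v[k] <- q
        z[k] <- s
        z[k + 1] <- Inf
        break
      }
    }
  }
  k <- 1L
  for (q in 1:n) {
    while (z[k + 1] < q) k <- k + 1L
    d[q] <- w2 * (q - v[k])^2 + f[v[k]]
  }
  d
}

#' Anisotropic Euclidean distance transform of a 3D mask
#'
#' For every voxel, the physical (um) distance to the nearest voxel
#' where `mask` is `TRUE` (zero inside the mask itself). Spacing-aware
#' separable transform.
#'
#' @param mask logical 3D array of source voxels.
#' @param spacing `(dx, dy, dz)` in um.
#' @return Numeric 3D array of distances in um.
#' @export
distance_transform <- function(mask, spacing = c(0.25, 0.25, 1)) {
  stopifnot(is.array(mask), length(dim(mask)) == 3)
  d <- dim(mask)
  f <- array(ifelse(mask != 0, 0, Inf), d)
  # pass along x
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) {
    f[, y, z] <- dt1d(f[, y, z], spacing[1])
  }
  for (z in seq_len(d[3])) for (x in seq_len(d[1])) {
    f[x, , z] <- dt1d(f[x, , z], spacing[2])
  }
  for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    f[x, y, ] <- dt1d(f[x, y, ], spacing[3])
  }
  sqrt(f)
}

#' Dilate a binary mask by a physical radius
#'
#' Adds every voxel whose center lies within `radius_um` of the original
#' mask (Euclidean distance with anisotropic spacing). Used to capture
#' the membrane/cytoplasmic shell around a nuclear mask. Dilation is
#' clipped at the stack bounds with a warning when the mask comes close
#' enough to the border that clipping actually occurs.
#'
#' @param mask logical 3D array.
#' @param radius_um dilation radius in um (default 2).
#' @param spacing `(dx, dy, dz)` in um.
#' @return Logical 3D array containing the original mask.
#' @export
dilate_mask <- function(mask, radius_um = 2, spacing = c(0.25, 0.25, 1)) {
  stopifnot(is.array(mask), length(dim(mask)) == 3)
  mask <- mask != 0
  if (radius_um <= 0) return(mask)
  if (!any(mask)) return(mask)
  dt <- distance_transform(mask, spacing)
  out <- dt <= radius_um
  # clipping check: would the dilation extend past the array border?
  d <- dim(mask)
  border <- out
  border[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] <- FALSE
  if (any(border)) {
    warning("dilated mask touches the stack boundary; dilation clipped")
  }
  out
}
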