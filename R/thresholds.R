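# Histogram thresholding primitives used by segmentation and
# quantification: 3-class multi-Otsu, single Otsu, and the triangle
# method. All operate on integer gray levels (0..255) or on continuous
# values binned into a fixed number of histogram bins.

#' Two thresholds from 3-class multi-Otsu
#'
#' Exhaustively maximizes the between-class variance of a three-class
#' split of the 8-bit intensity histogram. Classes are
#' `v < t1`, `t1 <= v < t2`, `v >= t2` for thresholds `t1 < t2`.
#'
#' @param x integer vector or array of gray levels in `[0, 255]`.
#' @return Sorted integer vector `c(t1, t2)`.
#' @export
multiotsu_thresholds <- function(x) {
  v <- as.integer(x)
  if (length(v) == 0) stop("empty image")
  if (min(v) < 0 || max(v) > 255) stop("gray levels must lie in [0, 255]")
  if (min(v) == max(v)) stop("constant image: multi-Otsu thresholds are undefined")
  counts <- tabulate(v + 1L, nbins = 256L)
  p <- counts / sum(counts)
  lev <- 0:255
  cw <- cumsum(p)              # cumulative weight up to level g (inclusive)
  cm <- cumsum(p * lev)        # cumulative first moment
  total_mean <- cm[256]

  # Candidate thresholds t1 < t2 in 1..255; class boundaries at t-0.5.
  # Between-class variance = sum_k w_k * mu_k^2 - total_mean^2; maximize
  # sum_k w_k mu_k^2 over all (t1, t2) pairs using vectorized cumulatives.
  best <- -Inf
  best_pair <- c(1L, 2L)
  for (t1 in 1:254) {
    w1 <- cw[t1]
    m1 <- cm[t1]
    t2 <- (t1 + 1L):255L
    w2 <- cw[t2] - w1
    m2 <- cm[t2] - m1
    w3 <- 1 - cw[t2]
    m3 <- total_mean - cm[t2]
    s <- ifelse(w1 > 0, m1^2 / w1, 0) +
      ifelse(w2 > 0, m2^2 / w2, 0) +
      ifelse(w3 > 0, m3^2 / w3, 0)
    i <- which.max(s)
    if (s[i] > best) {
      best <- s[i]
      best_pair <- c(t1, t2[i])
    }
  }
  as.integer(best_pair)
}

#' Single Otsu threshold on continuous values
#'
#' Bins values into `nbins` equal-width bins and maximizes the
#' between-class variance of the two-class split. The returned threshold
#' is the upper edge of the optimal background bin, so "positive" means
#' strictly greater than the threshold.
#'
#' @param x numeric vector.
#' @param nbins number of histogram bins.
#' @return Numeric threshold on the scale of `x`.
#' @export
otsu_threshold <- function(x, nbins = 256) {
  if (length(x) < 2 || diff(range(x)) == 0)
    stop("Otsu threshold requires at least two distinct values")
  rng <- range(x)
  edges <- seq(rng[1], rng[2], length.out = nbins + 1)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  counts <- tabulate(
    pmin(pmax(findInterval(x, edges, all.inside = TRUE), 1L), nbins),
    nbins = nbins
  )
  p <- counts / sum(counts)
  cw <- cumsum(p)
  cm <- cumsum(p * mids)
  mt <- cm[nbins]
  t_idx <- 1:(nbins - 1)
  w0 <- cw[t_idx]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, nbins - 1)
  sigma_b[valid] <- (mt * w0[valid] - cm[t_idx][valid])^2 /
    (w0[valid] * w1[valid])
  k <- which.max(sigma_b)
  edges[k + 1]
}

#' Triangle-method threshold
#'
#' Standard image-cytometry triangle thresholding: a chord is drawn from
#' the histogram peak to the far end of the longer tail, and the
#' threshold is placed at the bin with maximum perpendicular distance
#' between histogram and chord.
#'
#' @param x numeric vector of intensities.
#' @param nbins number of histogram bins.
#' @param tail which side of the peak carries the population of
#'   interest: `"auto"` (the longer tail), `"upper"`, or `"lower"`.
#' @return Numeric threshold on the scale of `x`.
#' @export
triangle_threshold <- function(x, nbins = 128,
                               tail = c("auto", "upper", "lower")) {
  tail <- match.arg(tail)
  if (length(x) < 2 || diff(range(x)) == 0) {
    warning("degenerate histogram: triangle threshold placed at the maximum")
    return(max(x))
  }
  rng <- range(x)
  edges <- seq(rng[1], rng[2], length.out = nbins + 1)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  counts <- tabulate(
    pmin(pmax(findInterval(x, edges, all.inside = TRUE), 1L), nbins),
    nbins = nbins
  )
  # light running-mean smoothing stabilizes the peak and the chord
  # geometry on sparse histograms
  counts <- as.numeric(stats::filter(counts, rep(1 / 3, 3), sides = 2))
  counts[is.na(counts)] <- 0
  peak <- which.max(counts)
  nz <- which(counts > 0)
  lo <- nz[1]
  hi <- nz[length(nz)]
  span <- switch(
    tail,
    upper = peak:hi,
    lower = peak:lo,
    auto = if ((hi - peak) >= (peak - lo)) peak:hi else peak:lo
  )
  if (length(span) < 3) {
    warning("degenerate histogram: triangle threshold placed at the tail end")
    return(mids[span[length(span)]])
  }
  x0 <- span[1]; y0 <- counts[peak]
  x1 <- span[length(span)]; y1 <- counts[x1]
  dx <- x1 - x0; dy <- y1 - y0
  nrm <- sqrt(dx^2 + dy^2)
  d <- abs(dy * (span - x0) - dx * (counts[span] - y0)) / nrm
  k <- span[which.max(d)]
  mids[k]
}
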