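# Independent brute-force oracles. These deliberately share no code
# with the package implementations they check.

# flood-fill (BFS) 6-connectivity labeling
bfs_label <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nxt <- 0L
  nbr <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
               c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (start in which(mask != 0)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- list(arrayInd(start, d)[1, ])
    lab[start] <- nxt
    while (length(queue) > 0) {
      v <- queue[[1]]
      queue <- queue[-1]
      for (j in 1:6) {
        w <- v + nbr[j, ]
        if (any(w < 1) || any(w > d)) next
        if (mask[w[1], w[2], w[3]] != 0 && lab[w[1], w[2], w[3]] == 0L) {
          lab[w[1], w[2], w[3]] <- nxt
          queue[[length(queue) + 1]] <- w
        }
      }
    }
  }
  lab
}

# same-component relation comparison (labels may be permuted)
same_partition <- function(a, b) {
  fa <- as.integer(factor(as.vector(a)))
  fb <- as.integer(factor(as.vector(b)))
  all(outer(fa, fa, "==") == outer(fb, fb, "=="))
}

# naive between-class variance of a 3-class split of raw pixel values
naive_sigma3 <- function(v, t1, t2) {
  cls <- list(v[v < t1], v[v >= t1 & v < t2], v[v >= t2])
  mt <- mean(v)
  s <- 0
  for (cl in cls) {
    if (length(cl) > 0) s <- s + length(cl) / length(v) * (mean(cl) - mt)^2
  }
  s
}

# exhaustive 2-threshold search over candidate split points
naive_multiotsu_max <- function(v) {
  cand <- sort(unique(c(v, v + 1L)))
  cand <- cand[cand >= 1 & cand <= 255]
  best <- -Inf
  for (t1 in cand) for (t2 in cand) {
    if (t2 <= t1) next
    s <- naive_sigma3(v, t1, t2)
    if (s > best) best <- s
  }
  best
}

# naive single-Otsu objective on binned values (between-class variance
# at a given threshold, raw-value computation)
naive_sigma2 <- function(v, thr) {
  lo <- v[v <= thr]
  hi <- v[v > thr]
  if (length(lo) == 0 || length(hi) == 0) return(-Inf)
  w0 <- length(lo) / length(v)
  w0 * (1 - w0) * (mean(lo) - mean(hi))^2
}

# brute-force kNN neighbor lists from an all-pairs distance sort
naive_knn <- function(X, k) {
  n <- nrow(X)
  out <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    dd <- sqrt(colSums((t(X) - X[i, ])^2))
    dd[i] <- Inf
    out[i, ] <- order(dd)[seq_len(k)]
  }
  out
}

# double-loop co-association matrix
naive_coassoc <- function(partitions) {
  n <- length(partitions[[1]])
  P <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    P[i, j] <- mean(vapply(partitions, function(m) m[i] == m[j], logical(1)))
  }
  P
}

# literal step-by-step simulation of the iterative trim rule
naive_trim <- function(b, k_min) {
  B <- b
  while (sum(B) > k_min) {
    i <- which(B == max(B))[1]  # lowest index among maxima
    B[i] <- B[i] - 1L
  }
  B
}

# triple-loop expression sum
naive_expression <- function(vox, mask) {
  s <- 0; n <- 0
  d <- dim(vox)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    if (mask[x, y, z]) {
      s <- s + vox[x, y, z]
      n <- n + 1
    }
  }
  s / n
}

# Monte-Carlo KL divergence of N(mu, sigma^2) from N(0, 1)
mc_kl <- function(mu, logvar, n = 2e5, seed = 1) {
  set.seed(seed)
  sd_ <- exp(logvar / 2)
  x <- rnorm(n, mu, sd_)
  mean(dnorm(x, mu, sd_, log = TRUE) - dnorm(x, log = TRUE))
}
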