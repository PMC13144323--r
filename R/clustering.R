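# Consensus Leiden clustering: Euclidean kNN graph, an ensemble of
# seeded Leiden runs, the co-association matrix, an average-linkage
# consensus cut, iterative removal of sub-minimum clusters into the
# "UC" (unclustered) sentinel, and ARI stability scoring.

#' Consensus clustering configuration
#'
#' Defaults follow the procedure's standard operating point: kNN
#' neighborhood `k = 10`, `n_runs = 30` Leiden runs at resolution 1.0,
#' consensus cut at minimum co-association 0.8, minimum cluster size 30.
#'
#' @param k kNN neighborhood size.
#' @param n_runs number of Leiden runs in the ensemble.
#' @param resolution Leiden resolution parameter (modularity objective).
#' @param min_coassoc minimum co-association in (0, 1] for the consensus
#'   dendrogram cut.
#' @param min_cluster_size clusters smaller than this are relabeled UC.
#' @param max_iterations cap on consensus iterations.
#' @param seed master seed; per-run seeds are derived from it.
#' @return A `clustering_config` object.
#' @export
clustering_config <- function(k = 10, n_runs = 30, resolution = 1.0,
                              min_coassoc = 0.8, min_cluster_size = 30,
                              max_iterations = 10, seed = 1) {
  stopifnot(min_coassoc > 0, min_coassoc <= 1, k >= 1, n_runs >= 1)
  structure(
    list(k = as.integer(k), n_runs = as.integer(n_runs),
         resolution = resolution, min_coassoc = min_coassoc,
         min_cluster_size = as.integer(min_cluster_size),
         max_iterations = as.integer(max_iterations),
         seed = as.integer(seed)),
    class = "clustering_config"
  )
}

#' Build a symmetric Euclidean kNN graph
#'
#' An undirected edge joins `i` and `j` when either is among the other's
#' `k` nearest neighbors (ties broken by index).
#'
#' @param X numeric feature matrix (cells in rows).
#' @param k neighborhood size; must be `< nrow(X)`.
#' @return An undirected `igraph` graph with a `knn` attribute holding
#'   the `n x k` neighbor index matrix.
#' @export
build_knn_graph <- function(X, k = 10) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k >= n) stop("k must be smaller than the number of cells")
  D <- as.matrix(dist(X))
  diag(D) <- Inf
  nn <- t(apply(D, 1, function(row) order(row)[seq_len(k)]))
  dimnames(nn) <- NULL
  edges <- cbind(rep(seq_len(n), each = k), as.vector(t(nn)))
  edges <- t(apply(edges, 1, sort))
  edges <- unique(edges)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  g$knn <- nn
  g
}

#' Run an ensemble of seeded Leiden partitions
#'
#' @param graph igraph graph (from [build_knn_graph()]).
#' @param config a [clustering_config()]; per-run seeds are derived from
#'   `config$seed`.
#' @return list of integer membership vectors, one per run.
#' @export
run_leiden_ensemble <- function(graph, config) {
  lapply(seq_len(config$n_runs), function(r) {
    with_seed(derive_seed(config$seed, paste0("leiden_", r)), {
      cl <- igraph::cluster_leiden(
        graph,
        objective_function = "modularity",
        resolution = config$resolution,
        n_iterations = 3
      )
      as.integer(igraph::membership(cl))
    })
  })
}

#' Co-association matrix of a partition ensemble
#'
#' Entry `(i, j)` is the fraction of runs assigning cells `i` and `j`
#' to the same cluster: symmetric, unit diagonal, entries quantized to
#' multiples of `1 / n_runs`.
#'
#' @param partitions list of membership vectors over the same cells.
#' @return Numeric `n x n` matrix.
#' @export
coassociation <- function(partitions) {
  stopifnot(length(partitions) >= 1)
  n <- length(partitions[[1]])
  stopifnot(all(lengths(partitions) == n))
  P <- matrix(0, n, n)
  for (m in partitions) {
    P <- P + outer(m, m, "==")
  }
  P <- P / length(partitions)
  diag(P) <- 1
  P
}

#' Consensus cut of a co-association matrix
#'
#' Average-linkage hierarchical clustering of the dissimilarity
#' `D = 1 - P`, with flat clusters formed at cophenetic distance
#' `<= 1 - min_coassoc`.
#'
#' @param P co-association matrix.
#' @param min_coassoc minimum co-association threshold.
#' @return Integer label vector (labels ordered by first occurrence).
#' @export
consensus_cut <- function(P, min_coassoc = 0.8) {
  n <- nrow(P)
  if (n == 1) return(1L)
  hc <- hclust(as.dist(1 - P), method = "average")
  # cutree merges clusters joined at height <= h
  labs <- cutree(hc, h = 1 - min_coassoc + 1e-12)
  as.integer(labs)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement under the permutation model,
#' computed from the contingency table.
#'
#' @param labels_a,labels_b label vectors over the same cells (any
#'   atomic type).
#' @return Numeric ARI in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  stopifnot(length(labels_a) == length(labels_b))
  n <- length(labels_a)
  if (n < 2) stop("ARI needs at least two cells")
  tab <- table(labels_a, labels_b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  a <- sum(choose2(rowSums(tab)))
  b <- sum(choose2(colSums(tab)))
  total <- choose2(n)
  expected <- a * b / total
  max_index <- (a + b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Iterative consensus Leiden clustering
#'
#' Repeats kNN graph construction, the Leiden ensemble, co-association
#' and the consensus cut; clusters smaller than
#' `config$min_cluster_size` are relabeled "UC" and their cells removed
#' from subsequent iterations. The loop stops when the cluster count and
#' size multiset converge between iterations, when the mean ARI between
#' the consensus and the individual runs reaches 0.8, when nothing is
#' removable, or at `max_iterations`. Sub-minimum clusters are always
#' reported as UC in the final labeling, whichever rule stops the loop.
#'
#' @param X numeric feature matrix (cells in rows).
#' @param config a [clustering_config()].
#' @return list of class `consensus_partition`: `labels` (character,
#'   cluster ids "1".."K" by decreasing size plus "UC"), `mean_ari`,
#'   `sd_ari`, `n_iterations`, `cluster_sizes`, `uc_fraction`,
#'   `no_stable_clusters` flag.
#' @export
iterate_consensus <- function(X, config = clustering_config()) {
  X <- as.matrix(X)
  n <- nrow(X)
  active <- seq_len(n)
  final <- rep(NA_integer_, n)
  prev_sizes <- NULL
  iter <- 0L
  mean_ari <- NA_real_
  sd_ari <- NA_real_
  labs <- integer(0)
  repeat {
    iter <- iter + 1L
    if (length(active) <= config$k) break
    g <- build_knn_graph(X[active, , drop = FALSE], k = config$k)
    runs <- run_leiden_ensemble(g, config)
    P <- coassociation(runs)
    labs <- consensus_cut(P, config$min_coassoc)
    aris <- vapply(runs, function(m) adjusted_rand_index(labs, m), numeric(1))
    mean_ari <- mean(aris)
    sd_ari <- sd(aris)
    sizes <- table(labs)
    small <- as.integer(names(sizes)[sizes < config$min_cluster_size])
    is_small <- labs %in% small
    converged <- !is.null(prev_sizes) &&
      length(sizes) == length(prev_sizes) &&
      all(sort(as.integer(sizes)) == sort(as.integer(prev_sizes)))
    stop_now <- converged || mean_ari >= 0.8 || !any(is_small) ||
      iter >= config$max_iterations
    if (stop_now) {
      final[active[!is_small]] <- labs[!is_small]
      final[active[is_small]] <- 0L  # UC
      break
    }
    final[active[is_small]] <- 0L
    active <- active[!is_small]
    prev_sizes <- sizes[sizes >= config$min_cluster_size]
  }
  if (all(is.na(final)) || all(final == 0L, na.rm = TRUE)) {
    warning("no stable clusters: every cell ended unclustered")
    return(structure(
      list(labels = rep("UC", n), mean_ari = mean_ari, sd_ari = sd_ari,
           n_iterations = iter, cluster_sizes = integer(0),
           uc_fraction = 1, no_stable_clusters = TRUE),
      class = "consensus_partition"
    ))
  }
  final[is.na(final)] <- 0L
  # relabel clusters 1..K by decreasing size
  kept <- final[final > 0]
  size_tab <- sort(table(kept), decreasing = TRUE)
  remap <- setNames(seq_along(size_tab), names(size_tab))
  out <- ifelse(final == 0L, "UC", as.character(remap[as.character(final)]))
  sizes_out <- table(factor(out, levels = c(as.character(seq_along(size_tab)), "UC")))
  structure(
    list(labels = out, mean_ari = mean_ari, sd_ari = sd_ari,
         n_iterations = iter,
         cluster_sizes = as.integer(sizes_out[names(sizes_out) != "UC"]),
         uc_fraction = mean(out == "UC"),
         no_stable_clusters = FALSE),
    class = "consensus_partition"
  )
}

#' @export
print.consensus_partition <- function(x, ...) {
  cat(sprintf(
    "<consensus_partition> %d clusters (%s), UC %.2f%%, ARI %.3f +/- %.3f, %d iteration(s)\n",
    length(x$cluster_sizes), paste(x$cluster_sizes, collapse = ", "),
    100 * x$uc_fraction, x$mean_ari, x$sd_ari, x$n_iterations
  ))
  invisible(x)
}
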