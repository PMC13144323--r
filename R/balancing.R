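# Four-step per-condition subsampling / class balancing: cap
# per-individual counts at the condition mean, find the minimum capped
# condition total K_min, then iteratively remove nuclei from the largest
# contributors until every condition totals exactly K_min.

#' Cap per-individual counts at the condition mean
#'
#' Computes the (real-valued) mean count across the individuals of one
#' condition and caps every count exceeding it. Because counts must be
#' integers, a capped value is rounded down by default
#' (`round_mode = "floor"`); `"half_even"` banker's rounding is
#' available.
#'
#' @param p integer vector of per-individual nucleus counts for one
#'   condition.
#' @param round_mode `"floor"` or `"half_even"`.
#' @return Integer vector `b` of coarse-balanced counts.
#' @export
cap_to_mean <- function(p, round_mode = c("floor", "half_even")) {
  round_mode <- match.arg(round_mode)
  if (length(p) == 0) stop("empty condition: no individuals to balance")
  stopifnot(all(p >= 0))
  p_hat <- mean(p)
  cap <- if (round_mode == "floor") floor(p_hat) else round(p_hat)
  ifelse(p > p_hat, as.integer(cap), as.integer(p))
}

#' Minimum capped total across conditions
#'
#' @param b_list list of capped count vectors, one per condition.
#' @return Integer `K_min`, the smallest condition total.
#' @export
compute_kmin <- function(b_list) {
  stopifnot(length(b_list) >= 1, all(lengths(b_list) >= 1))
  min(vapply(b_list, sum, numeric(1)))
}

#' Trim a capped count vector down to K_min
#'
#' Reproduces the iterative rule "remove one nucleus from the current
#' maximum entry (ties broken by lowest individual index) until the
#' total equals K_min" via its closed-form water-filling equivalent:
#' all entries are capped at a level `L`, and the first `r` individuals
#' (by index) still at `L` lose one more nucleus.
#'
#' @param b integer vector of capped counts.
#' @param k_min target total; must not exceed `sum(b)`.
#' @return list with `B` (trimmed counts summing to `k_min`) and
#'   `t_removed` (total nuclei removed).
#' @export
trim_to_kmin <- function(b, k_min) {
  stopifnot(all(b >= 0), k_min >= 0)
  total <- sum(b)
  if (total < k_min)
    stop("cannot trim: capped total (", total, ") is below K_min (", k_min, ")")
  t_rm <- total - k_min
  if (t_rm == 0) return(list(B = as.integer(b), t_removed = 0L))
  # smallest integer level L with sum(pmax(b - L, 0)) <= t_removed,
  # found segment-wise on the sorted counts
  bs <- sort(b, decreasing = TRUE)
  S <- cumsum(bs)
  n <- length(bs)
  L <- 0L
  for (m in seq_len(n)) {
    lower <- if (m < n) bs[m + 1] else 0L
    cand <- max(0, ceiling((S[m] - t_rm) / m))
    if (cand >= lower) {
      L <- as.integer(cand)
      break
    }
  }
  B <- pmin(b, L)
  r <- t_rm - sum(pmax(b - L, 0))
  if (r > 0) {
    eligible <- which(b >= L)
    B[eligible[seq_len(r)]] <- L - 1L
  }
  list(B = as.integer(B), t_removed = as.integer(t_rm))
}

#' Balance a full cohort count table
#'
#' Applies [cap_to_mean()] per condition, [compute_kmin()] across
#' conditions, and [trim_to_kmin()] per condition, so that every
#' condition's balanced total equals `K_min` exactly.
#'
#' @param counts `data.frame` with `individual_id`, `condition`,
#'   `n_nuclei` (e.g. from [sample_cohort()]).
#' @param round_mode see [cap_to_mean()].
#' @return `counts` with added columns `b` (capped) and `B` (final);
#'   attributes `k_min` and `t_removed` (named per condition).
#' @export
balance_counts <- function(counts, round_mode = "floor") {
  stopifnot(all(c("individual_id", "condition", "n_nuclei") %in% names(counts)))
  conds <- unique(counts$condition)
  counts$b <- NA_integer_
  for (cond in conds) {
    i <- counts$condition == cond
    counts$b[i] <- cap_to_mean(counts$n_nuclei[i], round_mode = round_mode)
  }
  k_min <- compute_kmin(split(counts$b, counts$condition))
  counts$B <- NA_integer_
  t_removed <- setNames(integer(length(conds)), conds)
  for (cond in conds) {
    i <- counts$condition == cond
    tr <- trim_to_kmin(counts$b[i], k_min)
    counts$B[i] <- tr$B
    t_removed[cond] <- tr$t_removed
  }
  attr(counts, "k_min") <- as.integer(k_min)
  attr(counts, "t_removed") <- t_removed
  counts
}

#' Select the retained nuclei for a balanced cohort
#'
#' For every individual, draws its balanced number of nuclei uniformly
#' at random without replacement from the manifest.
#'
#' @param manifest `data.frame` with at least `nucleus_id` and
#'   `individual_id`.
#' @param balanced output of [balance_counts()].
#' @param seed RNG seed.
#' @return The subsampled manifest (row order follows the input).
#' @export
select_nuclei <- function(manifest, balanced, seed = 1) {
  stopifnot(all(c("nucleus_id", "individual_id") %in% names(manifest)))
  with_seed(seed, {
    keep <- logical(nrow(manifest))
    for (i in seq_len(nrow(balanced))) {
      id <- balanced$individual_id[i]
      rows <- which(manifest$individual_id == id)
      n_keep <- balanced$B[i]
      if (n_keep > length(rows))
        stop("balanced count exceeds available nuclei for ", id)
      keep[sample(rows, n_keep)] <- TRUE
    }
    manifest[keep, , drop = FALSE]
  })
}
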