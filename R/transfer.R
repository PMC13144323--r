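# kNN label transfer to independent cohorts with confidence scoring and
# rejection, plus operating-point evaluation with exact binomial CIs.

# cosine distance matrix between rows of A and rows of B
cosine_dist <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  na <- sqrt(rowSums(A^2)); nb <- sqrt(rowSums(B^2))
  na[na == 0] <- 1; nb[nb == 0] <- 1
  1 - (A %*% t(B)) / outer(na, nb)
}

#' Reference-set neighbor distance statistics
#'
#' For each reference point, the mean distance to its `k` nearest
#' non-self reference neighbors; `mu_ref` / `sigma_ref` are the mean
#' and standard deviation of those per-point means. They calibrate the
#' compactness term of the transfer confidence.
#'
#' @param X_ref reference feature matrix.
#' @param k neighborhood size (reference must have more than `k + 1`
#'   points).
#' @param metric `"cosine"` (default) or `"euclidean"`.
#' @return list with `mu_ref`, `sigma_ref`, `mean_distances`.
#' @export
reference_distance_stats <- function(X_ref, k = 10, metric = c("cosine", "euclidean")) {
  metric <- match.arg(metric)
  X_ref <- as.matrix(X_ref)
  n <- nrow(X_ref)
  if (n <= k + 1) stop("reference needs more than k + 1 points")
  D <- if (metric == "cosine") cosine_dist(X_ref, X_ref) else as.matrix(dist(X_ref))
  diag(D) <- Inf
  md <- unname(apply(D, 1, function(row) mean(sort(row)[seq_len(k)])))
  mu <- mean(md)
  sig <- sd(md)
  if (sig == 0) stop("sigma_ref is zero: reference neighbor distances are degenerate")
  list(mu_ref = mu, sigma_ref = sig, mean_distances = md)
}

#' Transfer cluster labels to an independent set by kNN voting
#'
#' Fits a kNN index (cosine distance by default) on the reference
#' features; each query's per-label probabilities are the normalized
#' neighbor vote counts and the prediction is their argmax. Confidence
#' combines the vote probability with a distance-compactness term,
#' `confidence = p/2 + sigmoid((mu_ref - d) / sigma_ref)/2`, where `d`
#' is the query's mean neighbor distance; predictions below the
#' threshold `t` are flagged rejected. Vote ties are broken by the
#' smaller mean distance to the tied label's neighbors, then by label
#' order.
#'
#' @param X_ref,labels_ref reference features and labels.
#' @param X_query query features.
#' @param k neighborhood size.
#' @param threshold rejection threshold `t` on the confidence.
#' @param metric distance metric.
#' @param ref_stats optional precomputed [reference_distance_stats()].
#' @return `data.frame` with `predicted`, `vote_probability`,
#'   `confidence`, `mean_distance`, `rejected`, and one `prob_<label>`
#'   column per reference label.
#' @export
transfer_labels <- function(X_ref, labels_ref, X_query, k = 10, threshold = 0.5,
                            metric = c("cosine", "euclidean"),
                            ref_stats = NULL) {
  metric <- match.arg(metric)
  X_ref <- as.matrix(X_ref); X_query <- as.matrix(X_query)
  if (nrow(X_query) == 0) stop("empty query set")
  labels_ref <- as.character(labels_ref)
  stopifnot(length(labels_ref) == nrow(X_ref))
  if (is.null(ref_stats)) ref_stats <- reference_distance_stats(X_ref, k, metric)
  lab_levels <- sort(unique(labels_ref))
  D <- if (metric == "cosine") cosine_dist(X_query, X_ref) else {
    t(apply(X_query, 1, function(q) sqrt(colSums((t(X_ref) - q)^2))))
  }
  nq <- nrow(X_query)
  probs <- matrix(0, nq, length(lab_levels), dimnames = list(NULL, lab_levels))
  pred <- character(nq)
  pvote <- numeric(nq)
  mdist <- numeric(nq)
  for (i in seq_len(nq)) {
    ord <- order(D[i, ])[seq_len(k)]
    dd <- D[i, ord]
    ll <- labels_ref[ord]
    votes <- table(factor(ll, levels = lab_levels))
    probs[i, ] <- as.numeric(votes) / k
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1) {
      mean_d <- vapply(top, function(l) mean(dd[ll == l]), numeric(1))
      top <- top[order(mean_d, top)][1]
    }
    pred[i] <- top
    pvote[i] <- max(votes) / k
    mdist[i] <- mean(dd)
  }
  conf <- 0.5 * pvote +
    0.5 * plogis((ref_stats$mu_ref - mdist) / ref_stats$sigma_ref)
  out <- data.frame(
    predicted = pred,
    vote_probability = pvote,
    confidence = conf,
    mean_distance = mdist,
    rejected = conf < threshold,
    stringsAsFactors = FALSE
  )
  colnames(probs) <- paste0("prob_", lab_levels)
  cbind(out, as.data.frame(probs))
}

#' Transfer confidence score
#'
#' The closed-form confidence used by [transfer_labels()], exposed for
#' direct evaluation: `p/2 + sigmoid((mu_ref - d)/sigma_ref)/2`.
#'
#' @param p vote probability of the predicted label.
#' @param d mean neighbor distance of the query.
#' @param mu_ref,sigma_ref reference distance statistics.
#' @return Numeric confidence in (0, 1).
#' @export
transfer_confidence <- function(p, d, mu_ref, sigma_ref) {
  0.5 * p + 0.5 * plogis((mu_ref - d) / sigma_ref)
}

#' Evaluate patient prediction on an independent cohort
#'
#' Fits a random forest on the training cohort's enrichment profiles,
#' picks the decision threshold on the *training* out-of-fold (LOPO)
#' probabilities so the target sensitivity for the positive (disease)
#' class is met, then applies that fixed threshold to the held-out
#' cohort. Sensitivity and specificity come with exact Clopper-Pearson
#' two-sided confidence intervals.
#'
#' @param train_profiles,train_labels training cohort (binary task).
#' @param test_profiles,test_labels independent cohort.
#' @param positive the positive (disease) class label.
#' @param target_sensitivity training-set sensitivity target (default
#'   0.8).
#' @param n_estimators,seed random-forest settings.
#' @param conf_level CI level.
#' @return list with `threshold`, `sensitivity`, `specificity`,
#'   `sensitivity_ci`, `specificity_ci`, `predicted`, `truth`.
#' @export
evaluate_independent <- function(train_profiles, train_labels,
                                 test_profiles, test_labels,
                                 positive, target_sensitivity = 0.8,
                                 n_estimators = 10, seed = 1,
                                 conf_level = 0.95) {
  train_profiles <- as.matrix(train_profiles)
  test_profiles <- as.matrix(test_profiles)
  if (is.null(names(train_labels))) names(train_labels) <- rownames(train_profiles)
  classes <- sort(unique(as.character(train_labels)))
  stopifnot(length(classes) == 2, positive %in% classes)
  if (all(apply(train_profiles, 2, function(col) var(col) == 0)))
    stop("training enrichment profiles are constant; no classifier can be fit")
  if (!any(test_labels == positive) || all(test_labels == positive))
    stop("independent set must contain both positive and negative patients")
  # training-set operating point from out-of-fold probabilities
  lopo <- lopo_predict(train_profiles, train_labels,
                       n_estimators = n_estimators, seed = seed,
                       keep_models = FALSE)
  pos_prob <- lopo$probabilities[, positive]
  pos_truth <- lopo$truth == positive
  cand <- sort(unique(c(0, pos_prob)), decreasing = TRUE)
  sens_at <- vapply(cand, function(th) mean(pos_prob[pos_truth] >= th), numeric(1))
  ok <- which(sens_at >= target_sensitivity)
  threshold <- if (length(ok) > 0) cand[ok[1]] else min(cand)
  # final model on all training patients, applied to the held-out cohort
  fit <- with_seed(derive_seed(seed, "final_rf"), {
    randomForest::randomForest(
      x = train_profiles, y = factor(train_labels[rownames(train_profiles)]),
      ntree = n_estimators
    )
  })
  prob_test <- predict(fit, test_profiles, type = "prob")[, positive]
  pred_pos <- prob_test >= threshold
  truth_pos <- test_labels == positive
  tp <- sum(pred_pos & truth_pos); fn <- sum(!pred_pos & truth_pos)
  tn <- sum(!pred_pos & !truth_pos); fp <- sum(pred_pos & !truth_pos)
  sens_ci <- binom.test(tp, tp + fn, conf.level = conf_level)$conf.int
  spec_ci <- binom.test(tn, tn + fp, conf.level = conf_level)$conf.int
  list(
    threshold = threshold,
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    sensitivity_ci = as.numeric(sens_ci),
    specificity_ci = as.numeric(spec_ci),
    predicted = ifelse(pred_pos, positive, setdiff(classes, positive)),
    truth = as.character(test_labels)
  )
}
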