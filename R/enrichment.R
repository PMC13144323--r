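# Cluster-enrichment profiles and patient-level prediction:
# disease- / cluster- / individual-normalized composition matrices,
# leave-one-patient-out random-forest classification with permutation
# nulls and Gini importances.

#' Cluster-by-group count cube
#'
#' Tabulates cells per (condition, cluster) and per (individual,
#' cluster), including the "UC" sentinel as a regular cluster column.
#'
#' @param cells `data.frame` with `individual_id`, `condition`,
#'   `cluster` (character labels incl. "UC").
#' @param k_min optional balanced per-condition total carried over from
#'   balancing.
#' @return list of class `count_cube`: `by_disease` (conditions x
#'   clusters), `by_individual` (individuals x clusters),
#'   `individual_condition` lookup, `k_min`.
#' @export
count_cube <- function(cells, k_min = NULL) {
  stopifnot(all(c("individual_id", "condition", "cluster") %in% names(cells)))
  clusters <- unique(cells$cluster)
  num <- suppressWarnings(as.integer(clusters[clusters != "UC"]))
  lev <- c(as.character(sort(num)), if ("UC" %in% clusters) "UC")
  cl <- factor(cells$cluster, levels = lev)
  by_disease <- table(cells$condition, cl)
  by_individual <- table(cells$individual_id, cl)
  ic <- unique(cells[, c("individual_id", "condition")])
  structure(
    list(
      by_disease = unclass(by_disease),
      by_individual = unclass(by_individual),
      individual_condition = setNames(ic$condition, ic$individual_id),
      k_min = k_min
    ),
    class = "count_cube"
  )
}

#' Enrichment profiles from a count cube
#'
#' * `by_disease`: `K[d,h] / K_min`, the fraction of a condition's
#'   balanced cell total falling in each cluster (columns over clusters
#'   sum to 1 per condition when all clusters are included).
#' * `by_cluster`: `K[d,h] / K_h`, the disease composition of each
#'   cluster (rows over conditions sum to 1).
#' * `by_individual`: `K[i,h] / K_i`, each individual's cluster
#'   composition (rows sum to 1). Individuals with zero cells are
#'   dropped with a warning.
#'
#' @param counts a [count_cube()].
#' @param kind which normalization to apply.
#' @return Numeric matrix of the requested profile.
#' @export
enrichment <- function(counts, kind = c("by_individual", "by_disease", "by_cluster")) {
  kind <- match.arg(kind)
  stopifnot(inherits(counts, "count_cube"))
  if (kind == "by_individual") {
    K <- counts$by_individual
    tot <- rowSums(K)
    if (any(tot == 0)) {
      warning("dropping individual(s) with zero cells: ",
              paste(rownames(K)[tot == 0], collapse = ", "))
      K <- K[tot > 0, , drop = FALSE]
      tot <- tot[tot > 0]
    }
    return(K / tot)
  }
  K <- counts$by_disease
  if (kind == "by_cluster") {
    Kh <- colSums(K)
    if (any(Kh == 0)) {
      K <- K[, Kh > 0, drop = FALSE]
      Kh <- Kh[Kh > 0]
    }
    return(t(t(K) / Kh))
  }
  # by_disease: normalize each condition by K_min (the balanced total);
  # fall back to the observed condition totals when no K_min is carried
  denom <- if (!is.null(counts$k_min)) rep(counts$k_min, nrow(K)) else rowSums(K)
  K / denom
}

#' Drop patients with too few cells
#'
#' @param profiles individual-level enrichment matrix (rows =
#'   individuals).
#' @param cell_counts named per-individual total cell counts.
#' @param min_cells exclusion threshold; individuals with strictly
#'   fewer cells are dropped.
#' @return The filtered matrix, with attribute `"excluded"` listing the
#'   dropped individuals.
#' @export
filter_low_count_patients <- function(profiles, cell_counts, min_cells = 100) {
  ids <- rownames(profiles)
  stopifnot(!is.null(ids), all(ids %in% names(cell_counts)))
  drop <- ids[cell_counts[ids] < min_cells]
  keep <- setdiff(ids, drop)
  if (length(keep) == 0) stop("all patients fall below the cell-count threshold")
  out <- profiles[keep, , drop = FALSE]
  attr(out, "excluded") <- drop
  out
}

# Fit/predict one LOPO fold; returns class probabilities for held-out.
rf_fold <- function(train_x, train_y, test_x, n_estimators, seed) {
  with_seed(seed, {
    fit <- randomForest::randomForest(
      x = train_x, y = train_y, ntree = n_estimators
    )
    list(prob = predict(fit, test_x, type = "prob"),
         importance = randomForest::importance(fit)[, "MeanDecreaseGini"])
  })
}

#' Leave-one-patient-out random-forest prediction
#'
#' For every patient, a random forest (default 10 trees) is trained on
#' all other patients' enrichment profiles and predicts the held-out
#' patient's condition. Metrics are computed from the pooled
#' out-of-fold predictions.
#'
#' @param profiles individual-level enrichment matrix (rows named by
#'   individual).
#' @param labels named (or aligned) condition labels.
#' @param n_estimators number of trees.
#' @param seed RNG seed.
#' @param keep_models keep per-fold importances (needed by
#'   [cluster_importance()]).
#' @return list of class `lopo_result`: `predicted`, `truth`,
#'   `probabilities`, `confusion`, `balanced_accuracy`,
#'   `per_class_recall`, `auroc` (binary: pooled-probability AROC;
#'   multiclass: one-vs-rest AROCs), `fold_importances`.
#' @export
lopo_predict <- function(profiles, labels, n_estimators = 10, seed = 1,
                         keep_models = TRUE) {
  profiles <- as.matrix(profiles)
  n <- nrow(profiles)
  if (is.null(names(labels))) names(labels) <- rownames(profiles)
  labels <- factor(labels[rownames(profiles)])
  if (any(table(labels) < 2)) stop("need at least 2 patients per class")
  classes <- levels(labels)
  prob <- matrix(NA_real_, n, length(classes),
                 dimnames = list(rownames(profiles), classes))
  imps <- matrix(NA_real_, n, ncol(profiles),
                 dimnames = list(rownames(profiles), colnames(profiles)))
  # degenerate cohort: every profile identical (e.g. all cells UC).
  # There is nothing to split on, so each fold predicts its training
  # class frequencies (randomForest itself cannot fit constant input).
  if (all(apply(profiles, 2, function(col) var(col) == 0))) {
    warning("enrichment profiles are constant across patients; ",
            "falling back to training class frequencies")
    for (i in seq_len(n)) {
      prob[i, ] <- as.numeric(table(labels[-i])[classes]) / (n - 1)
      if (keep_models) imps[i, ] <- 0
    }
    return(finalize_lopo(prob, labels, classes, imps, keep_models))
  }
  for (i in seq_len(n)) {
    train_y <- droplevels(labels[-i])
    if (length(levels(train_y)) < length(classes)) {
      warning("fold ", rownames(profiles)[i],
              " skipped: a class is absent from its training set")
      next
    }
    fold <- rf_fold(profiles[-i, , drop = FALSE], labels[-i],
                    profiles[i, , drop = FALSE], n_estimators,
                    derive_seed(seed, paste0("fold_", i)))
    prob[i, colnames(fold$prob)] <- fold$prob[1, ]
    if (keep_models) imps[i, ] <- fold$importance
  }
  finalize_lopo(prob, labels, classes, imps, keep_models)
}

# pooled out-of-fold metrics shared by the regular and degenerate paths
finalize_lopo <- function(prob, labels, classes, imps, keep_models) {
  done <- !is.na(prob[, 1])
  predicted <- factor(classes[max.col(prob[done, , drop = FALSE], "first")],
                      levels = classes)
  truth <- labels[done]
  confusion <- table(truth = truth, predicted = predicted)
  recall <- diag(confusion) / rowSums(confusion)
  auroc <- tryCatch({
    if (length(classes) == 2) {
      as.numeric(pROC::auc(pROC::roc(
        response = truth, predictor = prob[done, classes[2]],
        levels = classes, direction = "<", quiet = TRUE
      )))
    } else {
      vapply(classes, function(cl) {
        as.numeric(pROC::auc(pROC::roc(
          response = factor(truth == cl, levels = c(FALSE, TRUE)),
          predictor = prob[done, cl], direction = "<", quiet = TRUE
        )))
      }, numeric(1))
    }
  }, error = function(e) NA_real_)
  structure(
    list(
      predicted = predicted, truth = truth,
      probabilities = prob[done, , drop = FALSE],
      confusion = confusion,
      balanced_accuracy = mean(recall),
      per_class_recall = recall,
      auroc = auroc,
      fold_importances = if (keep_models) imps[done, , drop = FALSE] else NULL
    ),
    class = "lopo_result"
  )
}

#' Permutation null for the LOPO balanced accuracy
#'
#' Permutes condition labels across patients and recomputes the full
#' leave-one-patient-out balanced accuracy for each permutation;
#' reports the add-one empirical p-value
#' `p = (1 + #\{null >= observed\}) / (1 + n_perm)`.
#'
#' @param profiles,labels,n_estimators as in [lopo_predict()].
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed.
#' @return list with `observed`, `null` (numeric vector), `p_value`.
#' @export
permutation_test <- function(profiles, labels, n_perm = 200, seed = 1,
                             n_estimators = 10) {
  stopifnot(n_perm >= 100)
  profiles <- as.matrix(profiles)
  if (is.null(names(labels))) names(labels) <- rownames(profiles)
  observed <- lopo_predict(profiles, labels, n_estimators = n_estimators,
                           seed = seed, keep_models = FALSE)$balanced_accuracy
  null <- with_seed(derive_seed(seed, "perm"), {
    vapply(seq_len(n_perm), function(b) {
      perm <- setNames(sample(labels[rownames(profiles)]), rownames(profiles))
      ok <- all(table(perm) >= 2)
      if (!ok) return(NA_real_)
      suppressWarnings(
        lopo_predict(profiles, perm, n_estimators = n_estimators,
                     seed = derive_seed(seed, paste0("perm_", b)),
                     keep_models = FALSE)$balanced_accuracy
      )
    }, numeric(1))
  })
  null <- null[!is.na(null)]
  p <- (1 + sum(null >= observed)) / (1 + length(null))
  list(observed = observed, null = null, p_value = p)
}

#' Mean Gini importance per cluster across LOPO folds
#'
#' @param lopo a [lopo_predict()] result with `keep_models = TRUE`.
#' @param conf_level confidence level for the across-fold interval.
#' @return `data.frame` with `cluster`, `mean_importance`, `sd`, and
#'   normal-approximation confidence bounds across folds.
#' @export
cluster_importance <- function(lopo, conf_level = 0.95) {
  stopifnot(inherits(lopo, "lopo_result"), !is.null(lopo$fold_importances))
  imp <- lopo$fold_importances
  m <- colMeans(imp)
  s <- apply(imp, 2, sd)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  half <- z * s / sqrt(nrow(imp))
  data.frame(
    cluster = colnames(imp),
    mean_importance = as.numeric(m),
    sd = as.numeric(s),
    ci_lo = as.numeric(pmax(0, m - half)),
    ci_hi = as.numeric(m + half),
    row.names = NULL
  )
}
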