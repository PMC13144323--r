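make_cells <- function() {
  # 3 conditions x 2 individuals, hand-countable cluster assignments
  data.frame(
    individual_id = rep(c("h1", "h2", "p1", "p2", "d1", "d2"), each = 10),
    condition = rep(c("healthy", "prediabetic", "diabetic"), each = 20),
    cluster = c(rep("1", 10), rep(c("1", "2"), 5),
                rep("2", 10), rep(c("2", "UC"), 5),
                rep("3", 10), rep(c("3", "1"), 5)),
    stringsAsFactors = FALSE
  )
}

test_that("enrichment normalizations hold exactly", {
  cells <- make_cells()
  cube <- count_cube(cells, k_min = 20)
  by_ind <- enrichment(cube, "by_individual")
  expect_true(all(abs(rowSums(by_ind) - 1) < 1e-12))
  by_cl <- enrichment(cube, "by_cluster")
  expect_true(all(abs(rowSums(t(by_cl)) - 1) < 1e-12)) # per-cluster sums over conditions
  by_dis <- enrichment(cube, "by_disease")
  expect_true(all(abs(rowSums(by_dis) - 1) < 1e-12))   # K_min-normalized per condition
  # hand-checked values
  expect_equal(unname(by_ind["h1", "1"]), 1)           # one-hot individual
  expect_equal(unname(by_dis["diabetic", "3"]), 15 / 20)
  # direct division example
  cube2 <- count_cube(data.frame(
    individual_id = "x", condition = "only",
    cluster = rep(c("1", "2", "3"), c(6, 3, 1))), k_min = 10)
  expect_equal(unname(enrichment(cube2, "by_disease")[1, ]), c(0.6, 0.3, 0.1))
  expect_equal(unname(enrichment(cube2, "by_cluster")[1, ]), c(1, 1, 1))
})

test_that("UC is carried as a regular cluster column", {
  cube <- count_cube(make_cells())
  expect_true("UC" %in% colnames(cube$by_individual))
  expect_equal(sum(cube$by_individual[, "UC"]), 5)
})

test_that("low-count patient filtering uses the strict boundary", {
  prof <- matrix(0.25, 3, 4,
                 dimnames = list(c("a", "b", "c"), paste0("c", 1:4)))
  counts <- c(a = 99, b = 100, c = 300)
  kept <- filter_low_count_patients(prof, counts, min_cells = 100)
  expect_equal(rownames(kept), c("b", "c"))
  expect_equal(attr(kept, "excluded"), "a")
  expect_identical(filter_low_count_patients(prof, counts, min_cells = 50),
                   structure(prof, excluded = character(0)))
  expect_error(filter_low_count_patients(prof, counts, min_cells = 1000),
               "all patients")
})

test_that("LOPO separates disjoint one-hot profiles perfectly", {
  sp <- separable_profiles(n_per_class = 6, seed = 3)
  res <- lopo_predict(sp$profiles, sp$labels, seed = 2)
  expect_equal(res$balanced_accuracy, 1.0)
  expect_equal(sum(res$confusion), 12)
  expect_true(all(diag(res$confusion) == 6))
  expect_gte(res$auroc, 0.99)
  # every patient is predicted exactly once
  expect_equal(length(res$predicted), 12)
})

test_that("permuted labels fall inside their own permutation null", {
  sp <- separable_profiles(n_per_class = 5, seed = 4)
  perm_labels <- with_seed_test(9, setNames(sample(sp$labels),
                                            names(sp$labels)))
  pt <- permutation_test(sp$profiles, perm_labels, n_perm = 100, seed = 6)
  lo <- quantile(pt$null, 0.025)
  hi <- quantile(pt$null, 0.975)
  expect_gte(pt$observed, lo)
  expect_lte(pt$observed, hi)
  expect_gt(pt$p_value, 0)
  expect_lte(pt$p_value, 1)
})

test_that("a perfectly separable cohort beats its permutation null", {
  sp <- separable_profiles(n_per_class = 6, seed = 5)
  pt <- permutation_test(sp$profiles, sp$labels, n_perm = 200, seed = 8)
  expect_lte(pt$p_value, 0.01)
})

test_that("importances rank the single informative cluster first", {
  set.seed(11)
  n <- 16
  prof <- matrix(runif(n * 5), n, 5,
                 dimnames = list(sprintf("q%02d", 1:n), paste0("c", 1:5)))
  cls <- rep(c("a", "b"), each = n / 2)
  prof[cls == "b", 3] <- prof[cls == "b", 3] + 2 # cluster 3 carries the signal
  res <- lopo_predict(prof, setNames(cls, rownames(prof)), seed = 4)
  imp <- cluster_importance(res)
  expect_true(all(imp$mean_importance >= 0))
  expect_equal(imp$cluster[which.max(imp$mean_importance)], "c3")
  # label-independent profiles: no cluster dominates strongly
  prof0 <- matrix(runif(n * 5), n, 5,
                  dimnames = dimnames(prof))
  res0 <- lopo_predict(prof0, setNames(cls, rownames(prof0)), seed = 4)
  imp0 <- cluster_importance(res0)
  expect_lt(max(imp0$mean_importance) / max(1e-9, min(imp0$mean_importance)), 10)
})

test_that("reference distance statistics match the brute-force oracle", {
  set.seed(13)
  X <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 8), 20, 2))
  rs <- reference_distance_stats(X, k = 5, metric = "euclidean")
  # oracle: all-pairs loop
  md <- numeric(40)
  for (i in 1:40) {
    dd <- sqrt(colSums((t(X) - X[i, ])^2))
    md[i] <- mean(sort(dd[-i])[1:5])
  }
  expect_equal(rs$mean_distances, md, tolerance = 1e-12)
  expect_equal(rs$mu_ref, mean(md))
  expect_equal(rs$sigma_ref, sd(md))
  # two tight separated blobs: neighbor distances stay within blobs
  expect_true(all(md < 4))
  # degenerate reference errors out
  expect_error(reference_distance_stats(matrix(1, 10, 2), k = 3),
               "degenerate|zero")
})

test_that("transfer confidence follows the closed form and is monotone", {
  expect_equal(transfer_confidence(1, d = 0.3, mu_ref = 0.3, sigma_ref = 0.1),
               0.75)
  expect_equal(transfer_confidence(0.6, d = 0.2, mu_ref = 0.3, sigma_ref = 0.1),
               0.3 + 0.5 * plogis(1), tolerance = 1e-9)
  expect_equal(transfer_confidence(0.6, d = 0.2, mu_ref = 0.3, sigma_ref = 0.1),
               0.66553, tolerance = 1e-5)
  set.seed(15)
  for (rep in 1:50) {
    p <- runif(1); d <- runif(1); mu <- runif(1); s <- runif(1, 0.05, 1)
    expect_gt(transfer_confidence(p + 0.01, d, mu, s),
              transfer_confidence(p, d, mu, s))
    expect_lt(transfer_confidence(p, d + 0.01, mu, s),
              transfer_confidence(p, d, mu, s))
  }
})

test_that("kNN label transfer votes, scores, and rejects", {
  set.seed(17)
  X_ref <- rbind(matrix(rnorm(60, 0, 0.3), 30, 2),
                 matrix(rnorm(60, 5, 0.3), 30, 2))
  labs <- rep(c("lo", "hi"), each = 30)
  X_query <- rbind(matrix(rnorm(20, 0, 0.3), 10, 2),
                   matrix(rnorm(20, 5, 0.3), 10, 2),
                   matrix(50, 2, 2)) # far outliers
  tr <- transfer_labels(X_ref, labs, X_query, k = 10, threshold = 0.52,
                        metric = "euclidean")
  expect_equal(tr$predicted[1:10], rep("lo", 10))
  expect_equal(tr$predicted[11:20], rep("hi", 10))
  expect_true(all(abs(tr$prob_lo + tr$prob_hi - 1) < 1e-12))
  expect_true(all(tr$rejected[21:22])) # far outliers: compactness term -> 0
  expect_false(any(tr$rejected[1:20]))
  # single-label reference: p = 1 for every query
  tr1 <- transfer_labels(X_ref, rep("only", 60), X_query, k = 10,
                         metric = "euclidean")
  expect_true(all(tr1$vote_probability == 1))
})

test_that("independent-set evaluation meets the training operating point", {
  sp_tr <- separable_profiles(n_per_class = 8, seed = 21)
  sp_te <- separable_profiles(n_per_class = 5, seed = 22)
  res <- evaluate_independent(sp_tr$profiles, sp_tr$labels,
                              sp_te$profiles, sp_te$labels,
                              positive = "b", seed = 3)
  expect_equal(res$sensitivity, 1.0)
  expect_equal(res$specificity, 1.0)
  # exact binomial CI lower bound at 5/5 successes
  expect_equal(res$sensitivity_ci[1], (0.025)^(1 / 5), tolerance = 1e-6)
  expect_true(all(res$sensitivity_ci >= 0 & res$sensitivity_ci <= 1))
  expect_true(res$sensitivity_ci[1] <= res$sensitivity &&
                res$sensitivity <= res$sensitivity_ci[2])
})
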