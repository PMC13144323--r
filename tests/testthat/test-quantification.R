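test_that("nuclear expression matches the brute-force voxel loop", {
  set.seed(1)
  for (rep in seq_len(50)) {
    d <- c(sample(4:8, 1), sample(4:8, 1), sample(2:4, 1))
    vox <- array(sample(0:255, prod(d), replace = TRUE), d)
    mask <- array(runif(prod(d)) < 0.5, d)
    if (!any(mask)) mask[1, 1, 1] <- TRUE
    st <- image_stack(vox)
    expect_equal(nuclear_expression(st, mask), naive_expression(vox, mask),
                 tolerance = 1e-12)
  }
  # uniform intensity over any mask returns that intensity
  st <- image_stack(array(100L, c(4, 4, 2)))
  m <- array(c(TRUE, FALSE), c(4, 4, 2))
  expect_equal(nuclear_expression(st, m), 100)
  expect_equal(nuclear_expression(image_stack(array(200L, c(4, 4, 2))), m), 200)
  expect_error(nuclear_expression(st, array(FALSE, c(4, 4, 2))), "empty")
})

test_that("physical-unit dilation grows a sphere by the right radius", {
  sp <- c(0.25, 0.25, 1)
  x <- axis_coords_test(56, sp[1]) - 7
  y <- axis_coords_test(56, sp[2]) - 7
  z <- axis_coords_test(14, sp[3]) - 7
  mask <- outer(outer(x^2, y^2, "+"), z^2, "+") <= 9
  dm <- dilate_mask(mask, radius_um = 2, spacing = sp)
  expect_true(all(dm[mask]))
  r_eq <- effective_diameter(sum(dm), sp) / 2
  expect_lt(abs(r_eq - 5), max(sp))
  # zero radius is the identity; dilation strictly grows
  expect_identical(dilate_mask(mask, 0, sp), mask)
  expect_gt(sum(dm), sum(mask))
})

test_that("membrane expression densities min-max scale across the cohort", {
  expect_equal(membrane_expression_norm(c(10, 30)), c(0, 1))
  expect_equal(membrane_expression_norm(c(10, 20, 30)), c(0, 0.5, 1))
  expect_warning(out <- membrane_expression_norm(c(5, 5, 5)), "degenerate")
  expect_equal(out, c(0, 0, 0))
  # density = shell intensity over dilated volume, checked on a fixture
  cfg <- plain_config(seed = 3, noise = FALSE)
  ph <- manual_phenotype(diameter = 6)
  ph$cd25_intensity <- 90
  mc <- render_multichannel(ph, "cd25", cfg)
  mask <- attr(mc, "truth")$mask
  dens <- membrane_expression_density(mc$cd25, mask, radius_um = 2)
  dm <- dilate_mask(mask, 2, cfg$voxel_spacing)
  expect_equal(dens, sum(mc$cd25$voxels[dm]) / sum(dm), tolerance = 1e-12)
})

test_that("pooled Otsu positivity recovers a planted bimodal cohort", {
  set.seed(5)
  truth <- rep(c(FALSE, TRUE), times = c(300, 200))
  vals <- ifelse(truth, rnorm(500, 0.8, 0.06), rnorm(500, 0.2, 0.06))
  groups <- sample(c("healthy", "diabetic"), 500, replace = TRUE)
  res <- positivity_by_otsu(vals, groups)
  expect_gte(mean(res$positive == truth), 0.95)
  expect_named(res$positive_fraction, c("diabetic", "healthy"))
  expect_error(positivity_by_otsu(rep(0.4, 10)), "distinct")
  # threshold maximizes the naive between-class variance over bins
  sig_at <- naive_sigma2(vals, res$threshold)
  cand <- seq(min(vals), max(vals), length.out = 200)
  expect_gte(sig_at, max(vapply(cand, function(t) naive_sigma2(vals, t),
                                numeric(1))) - 1e-4)
})

test_that("triangle viability recovers a 9:1 live/dead mixture", {
  set.seed(6)
  x <- c(rnorm(900, 25, 5), rnorm(100, 160, 18))
  v <- viability_triangle(x)
  expect_equal(v$live_fraction, 0.9, tolerance = 0.03)
  expect_gt(v$threshold, 25)
  expect_lt(v$threshold, 160)
  # all-low cohort: the threshold lands in the upper tail, so at most a
  # few percent of a dead-free unimodal cohort are flagged
  low <- rnorm(1000, 20, 3)
  expect_gte(viability_triangle(low)$live_fraction, 0.9)
  expect_error(viability_triangle(rnorm(5)), "at least 10")
})

test_that("Hotelling T2 detects shifts and is symmetric", {
  set.seed(7)
  A <- matrix(rnorm(60), 30, 2)
  B <- matrix(rnorm(60), 30, 2)
  same <- hotelling_two_sample(A, B)
  expect_gt(same$p_value, 0.01)
  shifted <- hotelling_two_sample(A, B + 10)
  expect_lt(shifted$p_value, 1e-6)
  swapped <- hotelling_two_sample(B + 10, A)
  expect_equal(shifted$T2, swapped$T2, tolerance = 1e-12)
  expect_equal(shifted$p_value, swapped$p_value, tolerance = 1e-12)
  expect_error(hotelling_two_sample(A[1:2, ], B), "at least 3")
})

test_that("Mann-Whitney wrapper gives exact small-sample p-values", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p_value, 0.1) # 2/20 arrangements as extreme
  same <- mann_whitney(1:5, 1:5)
  expect_gt(same$p_value, 0.9)
  # exact vs normal approximation agreement at n = 30/30
  set.seed(8)
  a <- rnorm(30); b <- rnorm(30, 0.3)
  p_approx <- suppressWarnings(
    wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
  p_exact <- wilcox.test(a, b, exact = TRUE)$p.value
  expect_lt(abs(p_approx - p_exact), 0.02)
})

test_that("box-plot statistics follow the stated conventions", {
  bs <- boxplot_stats(c(1, 2, 3, 4, 100))
  expect_equal(bs$q1, 2)
  expect_equal(bs$q3, 4)
  expect_equal(bs$upper_fence, 7)
  expect_equal(bs$outliers, 100)
  flat <- boxplot_stats(rep(3, 10))
  expect_equal(flat$q1, flat$q3)
  expect_length(flat$outliers, 0)
})

test_that("compression summaries report SEMs, ellipses, and pairwise tests", {
  set.seed(9)
  conds <- c("healthy", "prediabetic", "diabetic")
  rows <- do.call(rbind, lapply(conds, function(cond) {
    shift <- switch(cond, healthy = 0, prediabetic = 3, diabetic = 8)
    do.call(rbind, lapply(1:5, function(i) {
      n <- 12
      data.frame(individual_id = paste0(cond, i), condition = cond,
                 arm = rep(c("control", "compressed"), each = n),
                 projected_area_um2 = rnorm(2 * n, 30 + shift, 2),
                 mean_intensity = rnorm(2 * n, 100 + shift, 4))
    }))
  }))
  cs <- compression_summary(rows)
  ps <- cs$patient_stats
  # SEM = sd / sqrt(n)
  one <- rows[rows$individual_id == "healthy1" & rows$arm == "control", ]
  expect_equal(ps$area_sem[ps$individual_id == "healthy1" &
                             ps$arm == "control"],
               sd(one$projected_area_um2) / sqrt(nrow(one)))
  expect_length(cs$ellipses, 6)
  expect_equal(length(cs$hotelling), 6) # 3 pairs x 2 arms
  expect_true(all(cs$hotelling >= 0 & cs$hotelling <= 1, na.rm = TRUE))
  # the strongly shifted diabetic group separates from healthy
  expect_lt(cs$hotelling[["control diabetic vs healthy"]], 0.05)
})
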