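test_that("conditional multi-Otsu rule picks the guarded threshold", {
  # three flat bands: background 30, foregrounds 100 and 200; the lower
  # multi-Otsu threshold clears the >10 guard and is selected, so the
  # background separates from both foregrounds
  set.seed(1)
  v <- c(rep(30L, 600), rep(100L, 250), rep(200L, 150))
  st <- image_stack(array(v[sample(length(v))], c(10, 10, 10)))
  th2 <- multiotsu_thresholds(st$voxels)
  sel <- select_threshold(st)
  expect_true(min(th2) > 10)
  expect_equal(sel, min(th2))
  expect_true(sel > 30 && sel <= 100)

  # a deep-dark background pushes the lower threshold under the guard,
  # which deliberately falls back to the upper threshold
  v2 <- c(rep(2L, 600), rep(100L, 250), rep(200L, 150))
  st2 <- image_stack(array(v2, c(10, 10, 10)))
  th2b <- multiotsu_thresholds(st2$voxels)
  expect_lte(min(th2b), 10)
  expect_equal(select_threshold(st2), max(th2b))

  expect_error(select_threshold(image_stack(array(7L, c(4, 4, 4)))),
               "constant")
})

test_that("multi-Otsu attains the exhaustive-search optimum on random images", {
  set.seed(42)
  for (rep in seq_len(50)) {
    # few distinct levels keep the naive exhaustive oracle exact and cheap
    levels <- sort(sample(0:255, sample(3:6, 1)))
    v <- as.integer(sample(levels, 300, replace = TRUE,
                           prob = runif(length(levels), 0.2, 1)))
    if (length(unique(v)) < 3) next
    th <- multiotsu_thresholds(v)
    got <- naive_sigma3(v, th[1], th[2])
    best <- naive_multiotsu_max(v)
    expect_equal(got, best, tolerance = 1e-9)
  }
})

test_that("6-connectivity labeling matches a flood-fill oracle", {
  # diagonal contact does not connect; face contact does
  m <- array(FALSE, c(4, 4, 2))
  m[1, 1, 1] <- TRUE; m[2, 2, 1] <- TRUE
  expect_equal(max(label_components(m)), 2)
  m[2, 1, 1] <- TRUE # bridges the two by faces
  expect_equal(max(label_components(m)), 1)

  set.seed(7)
  for (rep in seq_len(50)) {
    mask <- array(runif(12 * 12 * 6) < 0.35, c(12, 12, 6))
    got <- label_components(mask)
    want <- bfs_label(mask)
    expect_true(same_partition(got[mask], want[mask]))
    expect_true(all(got[!mask] == 0))
  }
})

test_that("effective diameter follows the equivalent-sphere closed form", {
  expect_equal(effective_diameter(1, c(1, 1, 1)), (6 / pi)^(1 / 3),
               tolerance = 1e-12)
  expect_equal(effective_diameter(10, c(2, 2, 2)),
               2 * effective_diameter(10, c(1, 1, 1)), tolerance = 1e-12)
  # digitized 3 um-radius sphere at the assay spacing
  sp <- c(0.25, 0.25, 1)
  x <- axis_coords_test(48, sp[1]) - 6
  y <- axis_coords_test(48, sp[2]) - 6
  z <- axis_coords_test(12, sp[3]) - 6
  mask <- outer(outer(x^2, y^2, "+"), z^2, "+") <= 9
  expect_lt(abs(effective_diameter(sum(mask), sp) - 6), max(sp))
})

test_that("segmentation keeps in-range nuclei and drops debris", {
  cfg <- planted_cohort_config(seed = 31, fixed = TRUE, mean_count = 2)
  ph <- sample_phenotypes(sample_cohort(cfg), cfg)
  ph$true_diameter <- c(6, 8, 3, 6)[seq_len(nrow(ph))] # plant one debris blob
  field <- render_field(ph[1:3, ], cfg)
  seg <- segment_stack(field)
  expect_equal(nrow(seg$records), 2)
  expect_true(all(seg$records$effective_diameter >= 4.5 &
                    seg$records$effective_diameter <= 13.5))
  expect_equal(seg$records$label_id, seq_len(nrow(seg$records)))
})

test_that("oversized blobs and empty stacks give zero records", {
  cfg <- plain_config(seed = 17)
  big <- manual_phenotype(diameter = 15)
  big_cfg <- cfg
  big_cfg$stack_dim <- c(96L, 96L, 24L)
  st <- render_nucleus_stack(big, big_cfg)
  expect_equal(nrow(segment_stack(st)$records), 0)

  noise_only <- with_seed_test(5, array(
    as.integer(pmin(255, pmax(0, round(rnorm(64 * 64 * 8, 30, 12))))),
    c(64, 64, 8)))
  st0 <- image_stack(noise_only)
  expect_equal(nrow(segment_stack(st0)$records), 0)
})

test_that("recovered nucleus count equals planted count on noiseless fields", {
  cfg <- plain_config(seed = 23, noise = FALSE)
  for (rep in 1:3) {
    set.seed(rep + 100)
    n <- sample(2:4, 1)
    ph <- data.frame(
      nucleus_id = paste0("F", rep, "_", seq_len(n)),
      individual_id = "I1", condition = "healthy", archetype_id = "manual",
      true_diameter = runif(n, 5, 13), true_domain_count = 0L,
      intensity = 120, stringsAsFactors = FALSE
    )
    ph$true_domain_radii <- replicate(n, numeric(0), simplify = FALSE)
    field <- render_field(ph, cfg)
    expect_equal(nrow(segment_stack(field)$records), n)
  }
})

test_that("segmentation is invariant to a uniform intensity offset", {
  cfg <- plain_config(seed = 29, noise = FALSE)
  ph <- manual_phenotype(diameter = 7, intensity = 100)
  st <- render_nucleus_stack(ph, cfg)
  headroom <- 255 - max(st$voxels)
  shift <- min(20, headroom)
  st2 <- image_stack(st$voxels + shift, st$spacing, st$channel)
  seg1 <- segment_stack(st)
  seg2 <- segment_stack(st2)
  expect_equal(seg2$threshold, seg1$threshold + shift)
  expect_equal(seg2$records$voxel_count, seg1$records$voxel_count)
})
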