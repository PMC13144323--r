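test_that("cohort sampling honors the count distribution and the seed", {
  cfg_fixed <- cohort_config(
    n_individuals = c(healthy = 3L),
    subpopulation_mixtures = list(healthy = c(small_compact = 1)),
    count_distribution = list(mean = 50, dispersion = 1, fixed = TRUE),
    seed = 4
  )
  co <- sample_cohort(cfg_fixed)
  expect_equal(nrow(co), 3)
  expect_true(all(co$n_nuclei == 50))
  expect_identical(co, sample_cohort(cfg_fixed))

  cfg_disp <- cohort_config(
    n_individuals = c(healthy = 100L),
    subpopulation_mixtures = list(healthy = c(small_compact = 1)),
    count_distribution = list(mean = 60, dispersion = 0.8, fixed = FALSE),
    seed = 4
  )
  counts <- sample_cohort(cfg_disp)$n_nuclei
  expect_gt(var(counts) / mean(counts), 1) # overdispersed beyond Poisson

  expect_error(cohort_config(count_distribution = list(mean = -1, dispersion = 1)),
               "positive")
})

test_that("rendered nuclei match their phenotype ground truth", {
  cfg <- plain_config(seed = 3, noise = FALSE)
  ph <- manual_phenotype(diameter = 6, intensity = 120)
  st <- render_nucleus_stack(ph, cfg)
  truth <- attr(st, "truth")
  inside <- st$voxels[truth$mask]
  outside <- st$voxels[!truth$mask]
  expect_length(unique(inside), 1)   # zero noise, zero foci
  expect_length(unique(outside), 1)
  expect_gt(unique(inside)[1], unique(outside)[1])

  # equivalent diameter of the rendered mask within one voxel-equivalent
  d_meas <- effective_diameter(sum(truth$mask), cfg$voxel_spacing)
  vox_equiv <- max(cfg$voxel_spacing)
  expect_lt(abs(d_meas - 6), vox_equiv)

  # oversized nucleus errors
  expect_error(render_nucleus_stack(manual_phenotype(diameter = 30), cfg),
               "larger than stack extent")
})

test_that("foci at fractional radii 0 and 1 put maxima at centroid and border", {
  cfg <- plain_config(seed = 5, noise = FALSE)
  ph <- manual_phenotype(diameter = 8, n_domains = 2, radii = c(0, 1),
                         intensity = 100)
  st <- render_nucleus_stack(ph, cfg)
  truth <- attr(st, "truth")
  foci <- truth$foci
  rr <- sqrt(rowSums(foci^2))
  expect_equal(sort(rr), c(0, 4), tolerance = 1e-9)
  # bright local maxima sit at both focus positions: the nuclear
  # centroid (radius 0) and the boundary (radius 1)
  base <- 100 + cfg$noise_model$background
  value_near <- function(pos) {
    ijk <- round(pos / cfg$voxel_spacing + 0.5)
    d <- dim(st$voxels)
    xs <- max(1, ijk[1] - 1):min(d[1], ijk[1] + 1)
    ys <- max(1, ijk[2] - 1):min(d[2], ijk[2] + 1)
    zs <- max(1, ijk[3] - 1):min(d[3], ijk[3] + 1)
    max(st$voxels[xs, ys, zs])
  }
  # nearest voxel center can sit 0.5 um off in z (1 um axial step), so
  # the observed peak is attenuated relative to the focus amplitude
  amp <- cfg$focus_contrast * 100
  expect_gt(value_near(truth$center + foci[which.min(rr), ]), base + 0.3 * amp)
  inner_boundary <- truth$center + foci[which.max(rr), ] * 0.95
  expect_gt(value_near(inner_boundary), base + 0.1 * amp)
})

test_that("rendered mask diameters track the sampled phenotypes", {
  cfg <- cohort_config(
    n_individuals = c(healthy = 1L),
    subpopulation_mixtures = list(
      healthy = c(small_compact = 0.4, large_open = 0.3, mid_peripheral = 0.3)
    ),
    count_distribution = list(mean = 100, dispersion = 1, fixed = TRUE),
    seed = 11
  )
  ph <- sample_phenotypes(sample_cohort(cfg), cfg)
  vox_equiv <- max(cfg$voxel_spacing)
  for (i in seq_len(100)) {
    st <- render_nucleus_stack(ph[i, ], cfg)
    d <- effective_diameter(sum(attr(st, "truth")$mask), cfg$voxel_spacing)
    expect_lt(abs(d - ph$true_diameter[i]), vox_equiv)
  }
  # one truth row per nucleus, counts match the cohort table
  expect_equal(nrow(ph), 100)
  expect_equal(length(unique(ph$nucleus_id)), 100)
})

test_that("stack rendering is bit-identical under a fixed config and seed", {
  cfg <- planted_cohort_config(seed = 8)
  ph <- sample_phenotypes(sample_cohort(cfg), cfg)
  a <- render_nucleus_stack(ph[1, ], cfg)
  b <- render_nucleus_stack(ph[1, ], cfg)
  expect_identical(a$voxels, b$voxels)
})

test_that("multichannel rendering covers the stain set and flags bad names", {
  cfg <- plain_config(seed = 6, noise = FALSE)
  ph <- manual_phenotype(diameter = 7, intensity = 110)
  ph$lamin_intensity <- 73
  mc <- render_multichannel(ph, c("nuclear_dye", "lamin", "cd25", "draq7"), cfg)
  truth <- attr(mc, "truth")
  # uniform lamin value recovered exactly by nuclear expression
  # (background offsets every voxel equally in the noise-free setting)
  lam <- nuclear_expression(mc$lamin, truth$mask)
  expect_equal(lam, 73 + cfg$noise_model$background, tolerance = 1e-9)
  # cd25 lives on the shell, not inside the nucleus
  expect_gt(mean(mc$cd25$voxels[truth$shell]), mean(mc$cd25$voxels[truth$mask]))
  expect_error(render_multichannel(ph, "gfp", cfg), "unknown channel")
})

test_that("draq7 live/dead mixture reproduces the planted viability", {
  cfg <- plain_config(seed = 9)
  dead <- rep(c(FALSE, TRUE), times = c(180, 20))
  vals <- vapply(seq_along(dead), function(i) {
    ph <- manual_phenotype(nucleus_id = paste0("N", i), diameter = 6)
    ph$dead <- dead[i]
    mc <- render_multichannel(ph, "draq7", cfg)
    nuclear_expression(mc$draq7, attr(mc, "truth")$mask)
  }, numeric(1))
  v <- viability_triangle(vals)
  expect_equal(v$live_fraction, 0.9, tolerance = 0.03)
})

test_that("embedding mixtures separate and degrade as configured", {
  gm0 <- generate_embedding_mixture(2, 200, 5, separation = 0, seed = 2)
  m1 <- colMeans(gm0$X[gm0$labels == 1, ])
  m2 <- colMeans(gm0$X[gm0$labels == 2, ])
  expect_lt(sqrt(sum((m1 - m2)^2)), 0.5)

  gm <- generate_embedding_mixture(4, 150, 8, separation = 8, seed = 2)
  centroids <- t(vapply(1:4, function(k) colMeans(gm$X[gm$labels == k, ]),
                        numeric(8)))
  assign <- apply(gm$X, 1, function(x)
    which.min(colSums((t(centroids) - x)^2)))
  expect_equal(adjusted_rand_index(assign, gm$labels), 1.0)

  gm_zero <- generate_embedding_mixture(3, c(50, 0, 50), 5, separation = 4,
                                        seed = 3)
  expect_false(2 %in% gm_zero$labels)
  expect_error(generate_embedding_mixture(2, 10, 0, 1), "dim")
})

test_that("written cohorts round-trip through TIFF and manifest", {
  dir <- withr::local_tempdir()
  cfg <- cohort_config(
    n_individuals = c(healthy = 2L),
    subpopulation_mixtures = list(healthy = c(small_compact = 1)),
    count_distribution = list(mean = 2, dispersion = 1, fixed = TRUE),
    seed = 12
  )
  man <- write_cohort(cfg, dir)
  expect_equal(nrow(man), 4)
  expect_true(all(file.exists(file.path(dir, man$path))))
  ph <- sample_phenotypes(sample_cohort(cfg), cfg)
  st_disk <- read_stack(file.path(dir, man$path[1]), spacing = cfg$voxel_spacing)
  st_mem <- render_nucleus_stack(ph[1, ], cfg)
  expect_identical(st_disk$voxels, st_mem$voxels)
})
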