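test_that("max-z projection equals the per-pixel maximum", {
  one <- array(sample(0:255, 25), c(5, 5, 1))
  pr <- max_z_projection(one)
  expect_equal(pr$image, one[, , 1])

  two <- array(0L, c(2, 2, 2))
  two[1, 1, 1] <- 3L; two[1, 1, 2] <- 7L
  expect_equal(max_z_projection(two)$image[1, 1], 7)

  set.seed(3)
  vox <- array(sample(0:255, 6 * 5 * 4, replace = TRUE), c(6, 5, 4))
  got <- max_z_projection(vox)$image
  want <- matrix(0, 6, 5)
  for (x in 1:6) for (y in 1:5) want[x, y] <- max(vox[x, y, ])
  expect_equal(got, want)
})

test_that("dense-domain detection counts rendered foci and respects q", {
  cfg <- plain_config(seed = 13, noise = FALSE)
  ph <- manual_phenotype(diameter = 8, n_domains = 2, radii = c(0.3, 0.7),
                         intensity = 100)
  st <- render_nucleus_stack(ph, cfg)
  mask <- attr(st, "truth")$mask
  dom <- detect_dense_domains(st, mask, q = 0.9)
  expect_equal(nrow(dom), 2)

  # constant-intensity nucleus: no domains
  flat <- render_nucleus_stack(manual_phenotype(diameter = 7), cfg)
  fm <- attr(flat, "truth")$mask
  expect_equal(nrow(detect_dense_domains(flat, fm, q = 0.9)), 0)

  # raising q can only shrink the super-threshold voxel set
  v <- st$voxels[mask]
  lo <- sum(v > quantile(v, 0.80))
  hi <- sum(v > quantile(v, 0.95))
  expect_lte(hi, lo)
})

test_that("domain geometry matches analytic placements", {
  # analytic spherical mask, domains placed by hand
  sp <- c(0.25, 0.25, 1)
  x <- axis_coords_test(48, sp[1]) - 6
  y <- axis_coords_test(48, sp[2]) - 6
  z <- axis_coords_test(12, sp[3]) - 6
  mask <- outer(outer(x^2, y^2, "+"), z^2, "+") <= 2.8^2
  eq_r <- effective_diameter(sum(mask), sp) / 2
  ctr <- c(6, 6, 6)
  dom <- data.frame(
    centroid_x = ctr[1] + c(0, 0.2 * eq_r, 0.8 * eq_r),
    centroid_y = ctr[2], centroid_z = ctr[3],
    voxel_count = 10, mean_intensity = 200
  )
  g1 <- domain_geometry(dom[1, , drop = FALSE], mask, sp)
  expect_equal(unname(g1["d3"]), 0, tolerance = 0.02)
  g23 <- domain_geometry(dom[2:3, ], mask, sp)
  expect_equal(unname(g23["d3"]), 0.5, tolerance = 0.03) # median of two = mean
  # empty set defines both as 0
  g0 <- domain_geometry(dom[0, ], mask, sp)
  expect_equal(unname(g0[c("d3", "d4_um")]), c(0, 0))
})

test_that("boundary separation D4 agrees with a distance-transform oracle", {
  sp <- c(0.25, 0.25, 1)
  x <- axis_coords_test(40, sp[1]) - 5
  y <- axis_coords_test(40, sp[2]) - 5
  z <- axis_coords_test(10, sp[3]) - 5
  mask <- outer(outer(x^2, y^2, "+"), z^2, "+") <= 2.5^2
  dt <- distance_transform(!mask, sp) # distance to outside voxels
  set.seed(5)
  inner <- which(mask)
  for (i in sample(inner, 10)) {
    pos <- arrayInd(i, dim(mask))
    ctr <- (pos - 0.5) * sp
    dom <- data.frame(centroid_x = ctr[1], centroid_y = ctr[2],
                      centroid_z = ctr[3], voxel_count = 1,
                      mean_intensity = 1)
    g <- domain_geometry(dom, mask, sp)
    expect_equal(unname(g["d4_um"]), dt[i], tolerance = 1e-9)
  }
  # a domain one voxel from the boundary is within sqrt(2) in-plane steps
  bnd <- which(mask & dt <= 0.3)
  pos <- arrayInd(bnd[1], dim(mask))
  ctr <- (pos - 0.5) * sp
  g <- domain_geometry(
    data.frame(centroid_x = ctr[1], centroid_y = ctr[2], centroid_z = ctr[3],
               voxel_count = 1, mean_intensity = 1), mask, sp)
  expect_lte(unname(g["d4_um"]), 0.25 * sqrt(2) + 1e-6)
})

test_that("feature vector reproduces closed-form values on a sphere", {
  cfg <- plain_config(seed = 19, noise = FALSE)
  ph <- manual_phenotype(diameter = 6, intensity = 100)
  st <- render_nucleus_stack(ph, cfg)
  mask <- attr(st, "truth")$mask
  f <- compute_features(st, mask)
  expect_equal(f$volume_um3, 4 / 3 * pi * 27, tolerance = 0.08)
  expect_equal(f$mean_intensity, 100 + cfg$noise_model$background)
  expect_equal(f$intensity_sd, 0)
  expect_lt(f$eccentricity, 0.1)
  expect_gt(f$solidity, 0.9)
  expect_equal(f$n_dense_domains, 0)
  expect_true(all(is.finite(unlist(f))))
})

test_that("features are intensity-homogeneous and translation invariant", {
  cfg <- plain_config(seed = 37, noise = FALSE)
  ph <- manual_phenotype(diameter = 6.5, n_domains = 2, radii = c(0.4, 0.6),
                         intensity = 60) # keeps doubled foci below 8-bit clip
  st <- render_nucleus_stack(ph, cfg)
  mask <- attr(st, "truth")$mask
  f1 <- compute_features(st, mask)
  # doubling intensities doubles the mean, leaves geometry alone
  st2 <- image_stack(array(pmin(255, st$voxels * 2), dim(st$voxels)),
                     st$spacing, st$channel)
  f2 <- compute_features(st2, mask)
  expect_equal(f2$mean_intensity, 2 * f1$mean_intensity, tolerance = 0.02)
  expect_equal(f2$d3_radial, f1$d3_radial, tolerance = 1e-9)
  expect_equal(f2$d4_boundary_um, f1$d4_boundary_um, tolerance = 1e-9)
  # translation within the stack
  shifted <- render_nucleus_stack(ph, cfg, center = cfg$stack_dim *
                                    cfg$voxel_spacing / 2 + c(1, -1, 1))
  fs <- compute_features(shifted, attr(shifted, "truth")$mask)
  expect_equal(fs$volume_um3, f1$volume_um3, tolerance = 0.02)
  expect_equal(fs$d3_radial, f1$d3_radial, tolerance = 0.12)
})

test_that("D3 recovers the planted radial placement ordering", {
  cfg <- plain_config(seed = 41, noise = FALSE)
  set.seed(41)
  radii <- runif(60, 0.05, 0.9)
  d3 <- vapply(seq_along(radii), function(i) {
    ph <- manual_phenotype(nucleus_id = paste0("R", i), diameter = 8,
                           n_domains = 2, radii = rep(radii[i], 2),
                           intensity = 100)
    st <- render_nucleus_stack(ph, cfg)
    compute_features(st, attr(st, "truth")$mask)$d3_radial
  }, numeric(1))
  expect_gt(cor(radii, d3, method = "spearman"), 0.9)
})

test_that("features stay finite over random synthetic nuclei (fuzz)", {
  cfg <- planted_cohort_config(seed = 43, fixed = TRUE, mean_count = 5)
  ph <- sample_phenotypes(sample_cohort(cfg), cfg)
  for (i in seq_len(min(40, nrow(ph)))) {
    st <- render_nucleus_stack(ph[i, ], cfg)
    seg <- segment_stack(st)
    if (nrow(seg$records) == 0) next
    f <- compute_features(st, seg$labels == seg$records$label_id[1])
    expect_true(all(is.finite(unlist(f))))
    expect_gte(f$d3_radial, 0)
    expect_lte(f$dense_chromatin_fraction, 1)
  }
})
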