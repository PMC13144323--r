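# Seeded synthetic imaging cohorts. The generator emulates the structure
# the downstream analysis assumes: per-individual nucleus-count imbalance
# (negative-binomial), three disease conditions with distinct mixtures of
# nuclear phenotype archetypes (size, dense-domain count and radial
# placement, intensity), Poisson photon noise with Gaussian read noise,
# and 8-bit quantization at the assay's confocal voxel geometry.

#' Default nuclear phenotype archetypes
#'
#' Three archetypes spanning the morphology range of PBMC nuclei
#' (roughly 6-9 um): a small compact nucleus with few central dense
#' domains, a large open nucleus with many peripheral domains, and an
#' intermediate form. Diameters sit well inside the detectable
#' (4.5, 13.5) um window.
#'
#' @return Named list of archetype parameter lists.
#' @export
default_archetypes <- function() {
  list(
    small_compact = list(
      diameter_um = 6.0, diameter_sd_um = 0.35, n_domains = 2L,
      domain_radial_bias = 0.30, intensity_mean = 120, intensity_sd = 10
    ),
    large_open = list(
      diameter_um = 8.5, diameter_sd_um = 0.45, n_domains = 5L,
      domain_radial_bias = 0.75, intensity_mean = 95, intensity_sd = 10
    ),
    mid_peripheral = list(
      diameter_um = 7.0, diameter_sd_um = 0.35, n_domains = 3L,
      domain_radial_bias = 0.60, intensity_mean = 110, intensity_sd = 10
    )
  )
}

#' Configuration of a synthetic imaging cohort
#'
#' The defaults reproduce the study conditions the pipeline was designed
#' for: three disease stages (healthy, prediabetic, diabetic) with
#' 18/21/14 individuals, strongly imbalanced per-individual nucleus
#' counts, and per-condition mixtures of the phenotype archetypes in
#' which the large-nucleus archetype is enriched in the diabetic
#' condition.
#'
#' @param n_individuals named integer vector, individuals per condition.
#' @param count_distribution list with `mean`, `dispersion` (negative
#'   binomial size; smaller means more overdispersed) and `fixed`
#'   (logical; `TRUE` makes every individual contribute exactly `mean`
#'   nuclei, a degenerate mode used in tests).
#' @param archetypes named list of archetype parameters, see
#'   [default_archetypes()].
#' @param subpopulation_mixtures named list (one per condition) of
#'   probability vectors over archetypes; each must sum to 1.
#' @param noise_model list with `photon_scale` (Poisson gain; 0 disables
#'   photon noise), `read_sd` (Gaussian read noise, gray levels) and
#'   `background` (additive offset, gray levels).
#' @param voxel_spacing `(dx, dy, dz)` in um.
#' @param stack_dim stack extent in voxels `(nx, ny, nz)`.
#' @param focus_sigma_um isotropic Gaussian width of a rendered dense
#'   chromatin focus, um.
#' @param focus_contrast focus amplitude relative to the nuclear base
#'   intensity.
#' @param seed master seed; fully determines the cohort.
#' @return A validated `cohort_config` object.
#' @export
cohort_config <- function(
    n_individuals = c(healthy = 18L, prediabetic = 21L, diabetic = 14L),
    count_distribution = list(mean = 900, dispersion = 1.2, fixed = FALSE),
    archetypes = default_archetypes(),
    subpopulation_mixtures = list(
      healthy     = c(small_compact = 0.60, large_open = 0.10, mid_peripheral = 0.30),
      prediabetic = c(small_compact = 0.40, large_open = 0.20, mid_peripheral = 0.40),
      diabetic    = c(small_compact = 0.25, large_open = 0.50, mid_peripheral = 0.25)
    ),
    noise_model = list(photon_scale = 0.5, read_sd = 2, background = 8),
    voxel_spacing = c(0.25, 0.25, 1),
    stack_dim = c(64L, 64L, 20L),
    focus_sigma_um = 0.4,
    focus_contrast = 0.8,
    seed = 1L) {
  stopifnot(length(n_individuals) >= 1, all(n_individuals >= 1))
  if (is.null(names(n_individuals))) stop("n_individuals must be named by condition")
  if (count_distribution$mean <= 0 || count_distribution$dispersion <= 0)
    stop("count distribution parameters must be positive")
  if (!setequal(names(subpopulation_mixtures), names(n_individuals)))
    stop("subpopulation_mixtures must cover exactly the conditions")
  for (cond in names(subpopulation_mixtures)) {
    mix <- subpopulation_mixtures[[cond]]
    if (abs(sum(mix) - 1) > 1e-8)
      stop("mixture for condition '", cond, "' must sum to 1")
    if (!all(names(mix) %in% names(archetypes)))
      stop("mixture for condition '", cond, "' names unknown archetypes")
  }
  for (a in names(archetypes)) {
    d <- archetypes[[a]]$diameter_um
    if (d <= 4.5 || d >= 13.5)
      stop("archetype '", a, "' diameter must lie inside the detectable (4.5, 13.5) um window")
  }
  structure(
    list(
      n_individuals = n_individuals,
      count_distribution = count_distribution,
      archetypes = archetypes,
      subpopulation_mixtures = subpopulation_mixtures,
      noise_model = noise_model,
      voxel_spacing = as.numeric(voxel_spacing),
      stack_dim = as.integer(stack_dim),
      focus_sigma_um = focus_sigma_um,
      focus_contrast = focus_contrast,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' Sample per-individual nucleus counts for a cohort
#'
#' Draws the number of imaged nuclei per individual from the configured
#' negative-binomial distribution (truncated at 1), reproducing the
#' heavy per-individual count imbalance of real imaging cohorts. With
#' `count_distribution$fixed = TRUE`, every individual gets exactly the
#' (rounded) mean.
#'
#' @param config a [cohort_config()].
#' @return `data.frame` with `individual_id`, `condition`, `n_nuclei`.
#' @export
sample_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cd <- config$count_distribution
  with_seed(derive_seed(config$seed, "cohort"), {
    rows <- lapply(names(config$n_individuals), function(cond) {
      n <- config$n_individuals[[cond]]
      ids <- sprintf("%s_%02d", toupper(substr(cond, 1, 2)), seq_len(n))
      counts <- if (isTRUE(cd$fixed)) {
        rep(as.integer(round(cd$mean)), n)
      } else {
        pmax(1L, rnbinom(n, size = cd$dispersion, mu = cd$mean))
      }
      data.frame(
        individual_id = ids, condition = cond, n_nuclei = as.integer(counts),
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, rows)
  })
}

#' Sample per-nucleus phenotype ground truth
#'
#' For every nucleus in the cohort table, draws an archetype from the
#' condition's mixture and realizes its phenotype: true diameter
#' (Gaussian around the archetype mean, clipped into the detectable
#' window), dense-domain count, fractional radial domain positions
#' (Beta-distributed around the archetype's radial bias) and base
#' intensity.
#'
#' @param cohort output of [sample_cohort()].
#' @param config the [cohort_config()].
#' @return `data.frame` (one row per nucleus) with a list column
#'   `true_domain_radii`.
#' @export
sample_phenotypes <- function(cohort, config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(derive_seed(config$seed, "phenotypes"), {
    out <- vector("list", nrow(cohort))
    for (r in seq_len(nrow(cohort))) {
      n <- cohort$n_nuclei[r]
      cond <- cohort$condition[r]
      mix <- config$subpopulation_mixtures[[cond]]
      arch_ids <- sample(names(mix), n, replace = TRUE, prob = mix)
      diam <- numeric(n); dom_n <- integer(n); inten <- numeric(n)
      radii <- vector("list", n)
      for (j in seq_len(n)) {
        a <- config$archetypes[[arch_ids[j]]]
        diam[j] <- min(13.4, max(4.6, rnorm(1, a$diameter_um, a$diameter_sd_um)))
        dom_n[j] <- a$n_domains
        inten[j] <- max(20, rnorm(1, a$intensity_mean, a$intensity_sd))
        radii[[j]] <- if (dom_n[j] > 0) {
          kappa <- 8
          b <- a$domain_radial_bias
          rbeta(dom_n[j], 1 + b * kappa, 1 + (1 - b) * kappa)
        } else numeric(0)
      }
      df <- data.frame(
        nucleus_id = sprintf("%s_%04d", cohort$individual_id[r], seq_len(n)),
        individual_id = cohort$individual_id[r],
        condition = cond,
        archetype_id = arch_ids,
        true_diameter = diam,
        true_domain_count = dom_n,
        intensity = inten,
        stringsAsFactors = FALSE
      )
      df$true_domain_radii <- radii
      out[[r]] <- df
    }
    do.call(rbind, out)
  })
}

# Noise-free signal and mask for one nucleus rendered into a volume of
# dimension `dims` centered at physical position `center` (um).
render_signal <- function(phenotype, config, dims, center, seed) {
  sp <- config$voxel_spacing
  r <- phenotype$true_diameter / 2
  extent <- dims * sp
  if (2 * r > min(extent))
    stop("nucleus (", round(2 * r, 2), " um) larger than stack extent")
  cx <- axis_coords(dims[1], sp[1]) - center[1]
  cy <- axis_coords(dims[2], sp[2]) - center[2]
  cz <- axis_coords(dims[3], sp[3]) - center[3]
  d2 <- outer(outer(cx^2, cy^2, "+"), cz^2, "+")
  mask <- d2 <= r^2
  signal <- ifelse(mask, phenotype$intensity, 0)
  radii <- phenotype$true_domain_radii
  if (is.list(radii)) radii <- radii[[1]]
  foci <- NULL
  if (length(radii) > 0) {
    foci <- with_seed(seed, {
      u <- matrix(rnorm(3 * length(radii)), ncol = 3)
      u <- u / sqrt(rowSums(u^2))
      u * (radii * r) # positions relative to nucleus center
    })
    amp <- config$focus_contrast * phenotype$intensity
    s2 <- config$focus_sigma_um^2
    for (f in seq_len(nrow(foci))) {
      fd2 <- outer(outer((cx - foci[f, 1])^2, (cy - foci[f, 2])^2, "+"),
                   (cz - foci[f, 3])^2, "+")
      signal <- signal + amp * exp(-fd2 / (2 * s2))
    }
    signal[!mask] <- 0
  }
  list(signal = signal, mask = mask, foci = foci)
}

# Apply the configured noise model and 8-bit quantization to a clean
# signal array.
apply_noise <- function(signal, config, seed) {
  nm <- config$noise_model
  with_seed(seed, {
    x <- signal
    if (nm$photon_scale > 0) {
      x <- rpois(length(x), lambda = as.vector(x) * nm$photon_scale) / nm$photon_scale
      x <- array(x, dim(signal))
    }
    x <- x + nm$background
    if (nm$read_sd > 0) {
      x <- x + array(rnorm(length(x), 0, nm$read_sd), dim(signal))
    }
    array(as.integer(pmin(255, pmax(0, round(x)))), dim(signal))
  })
}

#' Render a single nucleus into an 8-bit image stack
#'
#' Renders an ellipsoidal (spherical in physical units) nucleus of the
#' phenotype's true diameter at the stack center, adds Gaussian dense
#' chromatin foci at the phenotype's fractional radial positions, then
#' applies Poisson photon noise, additive background, Gaussian read
#' noise, and 8-bit quantization.
#'
#' @param phenotype one row of [sample_phenotypes()] output (or a list
#'   with the same fields).
#' @param config the [cohort_config()].
#' @param center optional physical center (um); default stack center.
#' @return An [image_stack] with an attribute `"truth"` holding the
#'   noise-free mask and focus positions.
#' @export
render_nucleus_stack <- function(phenotype, config, center = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.data.frame(phenotype)) phenotype <- as.list(phenotype[1, ])
  if (phenotype$true_diameter <= 0) stop("phenotype diameter must be positive")
  dims <- config$stack_dim
  sp <- config$voxel_spacing
  if (is.null(center)) center <- dims * sp / 2
  seed0 <- derive_seed(config$seed, paste0("render_", phenotype$nucleus_id))
  rs <- render_signal(phenotype, config, dims, center, seed0)
  vox <- apply_noise(rs$signal, config, derive_seed(seed0, "noise"))
  out <- image_stack(vox, spacing = sp, channel = "nuclear_dye")
  attr(out, "truth") <- list(mask = rs$mask, foci = rs$foci, center = center)
  out
}

#' Render several non-touching nuclei into one field of view
#'
#' Places each phenotype on a regular grid with guaranteed physical
#' margins so that nuclei never touch (the segmentation stage has no
#' splitting step), then applies the shared noise model once.
#'
#' @param phenotypes `data.frame` of phenotype rows.
#' @param config the [cohort_config()].
#' @param margin_um minimal gap between nuclear surfaces, um.
#' @return An [image_stack] with `"truth"` attribute carrying per-nucleus
#'   centers and the union mask.
#' @export
render_field <- function(phenotypes, config, margin_um = 2) {
  stopifnot(inherits(config, "cohort_config"))
  n <- nrow(phenotypes)
  sp <- config$voxel_spacing
  cell <- max(phenotypes$true_diameter) + margin_um
  ncol_grid <- ceiling(sqrt(n))
  nrow_grid <- ceiling(n / ncol_grid)
  nx <- ceiling(ncol_grid * cell / sp[1])
  ny <- ceiling(nrow_grid * cell / sp[2])
  nz <- max(config$stack_dim[3], ceiling((max(phenotypes$true_diameter) + 2) / sp[3]))
  dims <- c(nx, ny, nz)
  signal <- array(0, dims)
  mask <- array(FALSE, dims)
  centers <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    gx <- (i - 1) %% ncol_grid
    gy <- (i - 1) %/% ncol_grid
    center <- c((gx + 0.5) * cell, (gy + 0.5) * cell, dims[3] * sp[3] / 2)
    seed_i <- derive_seed(config$seed, paste0("field_", phenotypes$nucleus_id[i]))
    ph <- as.list(phenotypes[i, ])
    rs <- render_signal(ph, config, dims, center, seed_i)
    signal <- signal + rs$signal
    mask <- mask | rs$mask
    centers[i, ] <- center
  }
  vox <- apply_noise(signal, config, derive_seed(config$seed, "field_noise"))
  out <- image_stack(vox, spacing = sp, channel = "nuclear_dye")
  attr(out, "truth") <- list(mask = mask, centers = centers,
                             nucleus_id = phenotypes$nucleus_id)
  out
}

#' Render co-registered multi-channel stacks for one nucleus
#'
#' Supported channels: `nuclear_dye` (chromatin with dense foci),
#' `draq7` (uniform in-nucleus; bright when the cell is dead), `lamin`
#' and `h3k9me3` (nuclear stains), and `cd25` (a membrane shell around
#' the nucleus). Per-channel ground-truth mean intensities are recorded
#' in the `"truth"` attribute.
#'
#' @param phenotype one phenotype row; an optional logical field `dead`
#'   switches the draq7 level, and optional fields `<channel>_intensity`
#'   override the defaults in `channel_levels`.
#' @param channels character vector of channel names.
#' @param config the [cohort_config()].
#' @param channel_levels named list of default intensities.
#' @return Named list of [image_stack]s with a `"truth"` attribute.
#' @export
render_multichannel <- function(
    phenotype, channels, config,
    channel_levels = list(lamin = 120, h3k9me3 = 90, cd25 = 110,
                          draq7_live = 12, draq7_dead = 150)) {
  stopifnot(inherits(config, "cohort_config"))
  known <- c("nuclear_dye", "draq7", "lamin", "h3k9me3", "cd25")
  bad <- setdiff(channels, known)
  if (length(bad) > 0) stop("unknown channel name(s): ", paste(bad, collapse = ", "))
  if (is.data.frame(phenotype)) phenotype <- as.list(phenotype[1, ])
  dims <- config$stack_dim
  sp <- config$voxel_spacing
  center <- dims * sp / 2
  seed0 <- derive_seed(config$seed, paste0("mc_", phenotype$nucleus_id))
  rs <- render_signal(phenotype, config, dims, center, seed0)
  mask <- rs$mask
  r <- phenotype$true_diameter / 2
  cx <- axis_coords(dims[1], sp[1]) - center[1]
  cy <- axis_coords(dims[2], sp[2]) - center[2]
  cz <- axis_coords(dims[3], sp[3]) - center[3]
  d2 <- outer(outer(cx^2, cy^2, "+"), cz^2, "+")
  shell_um <- 0.75
  shell <- d2 > r^2 & d2 <= (r + shell_um)^2

  level_for <- function(chan, default) {
    key <- paste0(chan, "_intensity")
    if (!is.null(phenotype[[key]])) phenotype[[key]] else default
  }
  out <- list()
  truth <- list(mask = mask, shell = shell, mean_intensity = list())
  for (chan in channels) {
    sig <- switch(
      chan,
      nuclear_dye = rs$signal,
      draq7 = {
        lvl <- if (isTRUE(phenotype$dead)) {
          level_for("draq7_dead", channel_levels$draq7_dead)
        } else {
          level_for("draq7_live", channel_levels$draq7_live)
        }
        ifelse(mask, lvl, 0)
      },
      lamin = ifelse(mask, level_for("lamin", channel_levels$lamin), 0),
      h3k9me3 = {
        base <- level_for("h3k9me3", channel_levels$h3k9me3)
        # heterochromatin mark concentrates in the dense foci
        foci_part <- rs$signal - ifelse(mask, phenotype$intensity, 0)
        ifelse(mask, 0.4 * base, 0) + foci_part * (base / phenotype$intensity)
      },
      cd25 = ifelse(shell, level_for("cd25", channel_levels$cd25), 0)
    )
    vox <- apply_noise(sig, config, derive_seed(seed0, paste0("noise_", chan)))
    out[[chan]] <- image_stack(vox, spacing = sp, channel = chan)
    region <- if (chan == "cd25") shell else mask
    truth$mean_intensity[[chan]] <- sum(sig[region]) / sum(region)
  }
  attr(out, "truth") <- truth
  out
}

#' Gaussian-mixture feature matrices with known labels
#'
#' Samples `n_per_component` points per component in `dim` dimensions
#' with unit within-component standard deviation; component means sit on
#' scaled coordinate axes so that every pair of means is at least
#' `separation` within-component standard deviations apart. The test
#' harness for the clustering stack.
#'
#' @param n_components number of mixture components (must be `<= dim`).
#' @param n_per_component points per component (scalar or vector; zeros
#'   allowed).
#' @param dim feature dimensionality.
#' @param separation distance between component means in units of the
#'   within-component standard deviation.
#' @param seed RNG seed.
#' @return list with `X` (numeric matrix) and `labels` (integer vector).
#' @export
generate_embedding_mixture <- function(n_components, n_per_component, dim,
                                       separation, seed = 1) {
  if (dim < 1) stop("dim must be at least 1")
  if (n_components > dim)
    stop("n_components must not exceed dim (means are placed on coordinate axes)")
  n_per <- rep(n_per_component, length.out = n_components)
  means <- matrix(0, n_components, dim)
  for (j in seq_len(n_components)) means[j, j] <- separation
  with_seed(seed, {
    labels <- rep(seq_len(n_components), n_per)
    X <- matrix(rnorm(sum(n_per) * dim), ncol = dim)
    X <- X + means[labels, , drop = FALSE]
    list(X = X, labels = labels)
  })
}

#' Write a full synthetic cohort to disk
#'
#' Generates the cohort, renders every nucleus as a multi-page 8-bit
#' TIFF, and writes a manifest (`nucleus_id`, `individual_id`,
#' `condition`, `path`), the phenotype ground truth, and the config as
#' YAML.
#'
#' @param config a [cohort_config()].
#' @param dir output directory (created if missing).
#' @return The manifest `data.frame`, invisibly.
#' @export
write_cohort <- function(config, dir) {
  stopifnot(inherits(config, "cohort_config"))
  dir.create(file.path(dir, "stacks"), recursive = TRUE, showWarnings = FALSE)
  cohort <- sample_cohort(config)
  phen <- sample_phenotypes(cohort, config)
  paths <- character(nrow(phen))
  for (i in seq_len(nrow(phen))) {
    st <- render_nucleus_stack(phen[i, ], config)
    paths[i] <- file.path("stacks", paste0(phen$nucleus_id[i], ".tif"))
    write_stack(st, file.path(dir, paths[i]))
  }
  manifest <- data.frame(
    nucleus_id = phen$nucleus_id,
    individual_id = phen$individual_id,
    condition = phen$condition,
    path = paths,
    stringsAsFactors = FALSE
  )
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  truth <- phen
  truth$true_domain_radii <- vapply(
    phen$true_domain_radii, function(r) paste(signif(r, 6), collapse = ";"), ""
  )
  write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  cfg <- config
  cfg$archetypes <- lapply(cfg$archetypes, as.list)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(manifest)
}
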