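# Shared small-scale cohort fixtures, generated in code at test time.

# two-condition imaging cohort with a planted mixture-weight difference
# (large_open archetype: 0.2 vs 0.55)
planted_cohort_config <- function(seed = 21, fixed = FALSE, mean_count = 45) {
  cohort_config(
    n_individuals = c(healthy = 6L, diabetic = 6L),
    subpopulation_mixtures = list(
      healthy = c(small_compact = 0.80, large_open = 0.20),
      diabetic = c(small_compact = 0.45, large_open = 0.55)
    ),
    count_distribution = list(mean = mean_count, dispersion = 5, fixed = fixed),
    seed = seed
  )
}

# single-archetype config for deterministic rendering checks
plain_config <- function(seed = 1, noise = TRUE, archetype = "small_compact") {
  arch <- default_archetypes()[archetype]
  mix <- setNames(list(setNames(1, archetype)), "healthy")
  cohort_config(
    n_individuals = c(healthy = 1L),
    subpopulation_mixtures = mix,
    archetypes = arch,
    count_distribution = list(mean = 4, dispersion = 1, fixed = TRUE),
    noise_model = if (noise) list(photon_scale = 0.5, read_sd = 2, background = 8)
                  else list(photon_scale = 0, read_sd = 0, background = 10),
    seed = seed
  )
}

# a hand-built phenotype row (bypasses sampling)
manual_phenotype <- function(nucleus_id = "N1", diameter = 6, n_domains = 0,
                             radii = numeric(0), intensity = 120) {
  list(nucleus_id = nucleus_id, individual_id = "I1", condition = "healthy",
       archetype_id = "manual", true_diameter = diameter,
       true_domain_count = n_domains, intensity = intensity,
       true_domain_radii = radii)
}

# separable per-individual enrichment profiles for two classes
separable_profiles <- function(n_per_class = 6, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  prof <- matrix(0, n, 4,
                 dimnames = list(sprintf("p%02d", seq_len(n)),
                                 paste0("c", 1:4)))
  cls <- rep(c("a", "b"), each = n_per_class)
  for (i in seq_len(n)) {
    w <- runif(4, 0, 0.05)
    hot <- if (cls[i] == "a") 1 else 3
    w[hot] <- 1
    prof[i, ] <- w / sum(w)
  }
  list(profiles = prof, labels = setNames(cls, rownames(prof)))
}
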