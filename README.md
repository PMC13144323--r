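# chromacyte

Chromatin-state morphometry and patient-level prediction from 3D
fluorescence imaging of immune-cell (PBMC) nuclei.

Routine monitoring of immune dysfunction — for instance across the
healthy → prediabetic → diabetic progression of Type 2 diabetes — is
costly with single-cell sequencing or proteomics. Imaging the chromatin
of blood-derived PBMC nuclei is cheap and fast, but turning image
stacks into patient-level calls requires a careful numerical chain.
`chromacyte` implements that chain end to end, for scientists analyzing
nuclear-dye image stacks and for method developers who need every step
testable without access to an imaging archive:

1. **Segmentation** — 3-class multi-Otsu on the 8-bit 3D histogram with
   the conditional rule *t = t₁ if t₁ > 10 else t₂* (t₁ ≤ t₂),
   6-connected component labeling, and equivalent-sphere diameter
   filtering to [4.5, 13.5] μm.
2. **Features** — nuclear morphometrics plus dense-chromatin domain
   geometry: D3 = median ‖domain − nuclear centroid‖ / equivalent
   radius, D4 = median distance from domain centroids to the nuclear
   boundary (μm).
3. **VAE embedding** — a convolutional variational autoencoder (4
   conv + batch-norm + activation layers per coder) on 128×128 max-Z
   projections, trained to minimize ‖D(E(x)) − x‖² + λ·KL(q(z|x) ‖
   N(0, I)) with the training set rotating between disease conditions
   every 20 epochs. Written in plain R linear algebra; no GPU, no
   external deep-learning stack.
4. **Class balancing** — cap per-individual counts at the condition
   mean, set K_min to the smallest capped condition total, then remove
   nuclei one at a time from the largest contributor until every
   condition totals exactly K_min.
5. **Consensus clustering** — 30 seeded Leiden runs (resolution 1.0) on
   a k = 10 Euclidean kNN graph; co-association matrix P; average-
   linkage cut of 1 − P at minimum co-association 0.8; clusters under
   30 cells relabeled **UC**; stability scored as mean ± SD ARI between
   consensus and the individual runs.
6. **Enrichment & prediction** — per-individual cluster-composition
   vectors Enrichmentᵢ = K[i,h]/Kᵢ (plus K[d,h]/K_min and K[d,h]/K_h
   views), a 10-tree random forest under leave-one-patient-out
   cross-validation with permutation nulls and Gini importances, and
   kNN label transfer with confidence
   ½·p + ½·σ((μ_ref − d)/σ_ref) and rejection below a threshold t.
7. **Quantification** — nuclear and 2 μm-dilated membrane expression,
   pooled-Otsu positivity, DRAQ7 triangle-threshold viability, box-plot
   conventions, SEMs, 1-SD ellipses, and two-sample Hotelling T².

A first-class synthetic-cohort module renders seeded 8-bit image stacks
(ellipsoidal nuclei, Gaussian dense-chromatin foci, Poisson + read
noise) with per-individual count imbalance and per-condition archetype
mixtures, so the entire pipeline runs and is verified on data with
known ground truth.

## Worked example

A small synthetic cohort (two conditions, four individuals each, with
the large-nucleus archetype enriched in the diabetic condition) through
the full pipeline:

```r
library(chromacyte)

cfg <- cohort_config(
  n_individuals = c(healthy = 4L, diabetic = 4L),
  subpopulation_mixtures = list(
    healthy  = c(small_compact = 0.85, large_open = 0.15),
    diabetic = c(small_compact = 0.30, large_open = 0.70)),
  count_distribution = list(mean = 25, dispersion = 6, fixed = FALSE),
  seed = 1)

run <- run_pipeline(pipeline_config(
  cohort     = cfg,
  clustering = clustering_config(n_runs = 10, min_cluster_size = 15),
  out_root   = "demo_run", master_seed = 14, min_cells = 10))
```

The run directory then contains `report.md`, which begins:

```
## Consensus clustering

- clusters: 45, 34, 18
- mean ARI vs individual runs: 0.9753 +/- 0.0483
- unclustered (UC) fraction: 0.2049
- iterations: 1
```

and `prediction_metrics.json`:

```json
{"balanced_accuracy": 0.875,
 "per_class_recall": {"diabetic": 1, "healthy": 0.75},
 "auroc": 0.9375, "n_patients": 8}
```

Reading: the consensus procedure found three stable nuclear-phenotype
clusters (45, 34, and 18 cells after balancing; 20% of cells were not
stably assigned and carry the UC label), the partition agrees with the
individual Leiden runs at mean ARI 0.98, and the per-patient cluster
enrichment profiles predict the held-out patient's condition with
balanced accuracy 0.875 (7 of 8 patients correct; AROC 0.94) — the
planted composition difference between the two conditions is recovered
from images alone.

Individual stages are plain functions (`segment_stack()`,
`compute_features()`, `train_vae()`/`encode()`, `balance_counts()`,
`iterate_consensus()`, `lopo_predict()`, `transfer_labels()`,
`viability_triangle()`, …); see the package vignette for the model
details and design choices. A thin command-line wrapper lives at
`inst/cli/chromacyte.R` (`simulate`, `run-all`, `report`).

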