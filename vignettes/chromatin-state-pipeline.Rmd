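---
title: "Chromatin-state morphometry of immune-cell nuclei: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromatin-state morphometry of immune-cell nuclei}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromacyte)
```

# What the pipeline computes

`chromacyte` turns 3D fluorescence stacks of stained immune-cell (PBMC)
nuclei into patient-level disease predictions. The chain is:

1. **Segmentation** — conditional multi-Otsu thresholding, 6-connected
   labeling, physical diameter filtering.
2. **Representation** — per-nucleus descriptors, either handcrafted
   morphometrics or the latent code of a convolutional variational
   autoencoder (VAE) trained on 128x128 maximum-intensity projections.
3. **Class balancing** — a four-step count-capping and trimming
   algorithm that equalizes per-condition cell totals at `K_min`.
4. **Consensus clustering** — an ensemble of seeded Leiden partitions
   on a kNN graph, merged through a co-association matrix, with
   unstable cells relabeled "UC".
5. **Enrichment and prediction** — per-individual cluster-composition
   vectors classified by a small random forest under
   leave-one-patient-out (LOPO) cross-validation, with permutation
   nulls; label transfer to independent cohorts by kNN voting with a
   confidence score.
6. **Quantification** — immunofluorescence expression statistics
   (nuclear density, 2 um membrane shells, pooled-Otsu positivity),
   DRAQ7 triangle-threshold viability, and the bivariate
   compression-assay statistics (SEMs, 1-SD ellipses, Hotelling's
   T-squared).

Because the pipeline is meant to be testable without any external
image archive, a first-class synthetic-data module generates seeded
imaging cohorts with known ground truth; every downstream stage is
validated against that truth or against independent brute-force
oracles.

# The synthetic cohort generator

The generator emulates the statistical structure the analysis relies
on, not the optics of a microscope:

* **Count imbalance.** Per-individual nucleus counts are negative
  binomial (`mean`, `dispersion` = NB size). The default mean of 900
  with dispersion 1.2 produces the severe per-individual imbalance
  typical of imaging cohorts; a degenerate `fixed` mode exists for
  deterministic tests.
* **Phenotype archetypes.** Each condition has a probability mixture
  over nuclear archetypes that differ in diameter (6, 7, 8.5 um —
  PBMC-scale, inside the detectable 4.5-13.5 um window), dense-domain
  count (2/3/5), radial domain placement (fractional radius bias
  0.3/0.6/0.75) and base intensity. The default mixtures enrich the
  large-nucleus archetype in the diabetic condition, mirroring the
  larger nuclear sizes reported for diabetic PBMCs. No quantitative
  per-condition effect sizes are established for this system, so these
  are package choices, fixed once and documented here — not calibrated
  values.
* **Rendering.** A nucleus is a sphere in physical units (an ellipsoid
  in anisotropic voxel space at 0.25 x 0.25 x 1 um spacing), dense
  chromatin foci are isotropic Gaussian blobs (sigma 0.4 um, contrast
  0.8 relative to the base intensity) placed at sampled fractional
  radii, and the noise model is Poisson photon noise (gain 0.5) plus
  additive background and Gaussian read noise, quantized to 8 bits.
* **What it does not emulate.** No point-spread function, no
  aberrations or shading, no touching nuclei (the segmentation has no
  splitting step, so fields are rendered non-touching by
  construction), no cell-cycle or staining batch effects. Passing
  tests therefore demonstrate the correctness of the computations and
  the recoverability of planted structure under idealized imaging —
  they do not certify performance on real microscope data.

# Segmentation choices

* "Effective diameter" is defined as the equivalent-sphere diameter of
  the 3D voxel volume; masks are 3D and spacing is anisotropic, so a
  2D definition would be unit-inconsistent.
* The diameter filter keeps the closed interval `[4.5, 13.5]` um
  (regions *less than* 4.5 and *greater than* 13.5 are discarded, so
  the boundary values stay).
* Multi-Otsu runs on the full 3D histogram (one bin per gray level);
  the threshold-selection guard (`min` of the two thresholds if it
  exceeds 10, else `max`) is applied exactly, with a strict
  inequality at 10.
* The foreground comparison is inclusive (`intensity >= threshold`);
  the alternative strict form differs only on boundary gray levels and
  is not separately exposed.

# Handcrafted features

The morphometric set follows the live-nucleus imaging literature's
usual descriptors, for which no single canonical list exists:
volume, projected area, equivalent diameter, intensity mean/SD/skew,
projection eccentricity and solidity, dense-domain count, the
dense-chromatin volume fraction, and the two domain-geometry
descriptors that carry most disease signal:

* **D3** — median distance from domain centroids to the nuclear
  centroid, normalized by the equivalent radius so it compares across
  nucleus sizes (an unnormalized um variant is also emitted);
* **D4** — median physical distance from domain centroids to the
  nearest outside-mask voxel.

The dense-domain detector itself has no canonical published
definition; the package uses an in-mask intensity quantile threshold
(default q = 0.85) with 6-connected components and a minimum size of 8
voxels, all config-exposed. On synthetic nuclei this detector recovers
planted focus counts exactly and planted radial orderings with
Spearman rho > 0.9.

# The VAE

Encoder and decoder each cascade four convolution + batch-norm +
activation layers (3x3 kernels; stride-2 in the encoder, nearest-
neighbor 2x upsampling in the decoder; leaky-rectifier slope 0.2; a
sigmoid output). Architecture constants the protocol leaves
open — latent dimension 32, channel widths (32, 64, 128, 256), KL
weight lambda = 1, Adam at learning rate 1e-3 — are defaults in
`vae_config()` and freely configurable. Two deliberate choices:

* **Reconstruction error is the mean (not summed) squared error**, so
  the stopping tolerance of 1e-5 has a well-defined per-pixel scale.
* **Condition rotation order is fixed** to the sorted condition labels
  (healthy, prediabetic, diabetic in this cohort's naming), switching
  every 20 epochs; the protocol fixes the fact of switching but not
  the order.

The split fractions 85.5% / 4.55% / 10% are treated as weights and
converted to integer set sizes by the largest-remainder rule (they sum
to 100.05% as printed, so exact proportions cannot all hold at once).

The implementation is plain R linear algebra (im2col gathers + BLAS
products) with hand-derived backpropagation; gradients were verified
against central finite differences to ~1e-9 relative error during
development, and the loss closed forms are pinned in the test suite.
Full-cohort training (hundreds of epochs over tens of thousands of
images) is not exercised by the tests, which instead train a reduced
model (90 FOVs, 6 epochs, channel widths 4-16) and check that
validation loss decreases and that size-differing archetypes separate
in latent space.

# Balancing

The four steps are implemented exactly: cap each individual's count at
the condition mean (the mean kept real-valued for comparison, the cap
floored to an integer count — counts are integers and the rounding is
an open choice; `round_mode = "half_even"` is available), take
`K_min` as the smallest capped condition total, then iteratively
remove one nucleus from the largest contributor (ties to the lowest
individual index) until each condition totals `K_min`. The iteration
is executed via its closed-form water-filling equivalent, which the
tests verify against a literal step-by-step simulation. Which
*particular* nuclei are dropped is not specified by the counts
algorithm; the package samples uniformly without replacement under a
seed.

Two properties one might expect do **not** hold for this algorithm and
are deliberately not asserted: it is not idempotent (capping at the
mean strictly shrinks any non-flat column, so rebalancing balanced
output trims further), and trimming can raise a column's max-min
spread from 0 to 1 (e.g. `[5, 5] -> [4, 5]`).

# Consensus clustering

Defaults follow the procedure's stated operating point: k = 10
Euclidean kNN (edges when either endpoint is in the other's neighbor
list), 30 Leiden runs (modularity objective, resolution 1.0, one seed
per run derived from the config seed), co-association matrix P,
average-linkage dendrogram on 1 - P cut at cophenetic distance
1 - 0.8. Clusters below 30 cells are relabeled "UC" and removed from
subsequent iterations (the kNN graph is rebuilt on survivors each
round). The loop stops when cluster count and size multiset repeat,
when the mean ARI between consensus and the individual runs reaches
0.8, when nothing is removable, or after 10 iterations; stability is
reported as mean +/- SD of ARI against the final iteration's runs.
One reconciliation: because stopping on ARI alone could leave
sub-minimum clusters in the output, such clusters are always reported
as UC, keeping the output contract (no non-UC cluster below the
minimum size) unconditional.

# Enrichment and prediction

Three normalizations of the cluster-count cube are exposed, with UC a
regular column: per-disease (`K[d,h] / K_min`), per-cluster
(`K[d,h] / K_h`), and per-individual (`K[i,h] / K_i`, the classifier
input). Patients with fewer than 100 cells (strict) are excluded by
default. The classifier is a 10-tree random forest evaluated
leave-one-patient-out; metrics are computed from pooled out-of-fold
predictions (pooling vs averaging is an open choice; pooling keeps
every patient weighted once). Balanced accuracy is the unweighted mean
of per-class recalls; AROC uses pooled probabilities (one-vs-rest per
class in the 3-way task). Permutation tests re-run the entire LOPO
loop per permutation (default 200) and report the add-one p-value, so
p is never exactly zero. Gini importances are averaged across folds.

Label transfer to an independent cohort uses a k = 10 cosine kNN vote;
per-label probabilities are vote fractions, and confidence is
`p/2 + sigmoid((mu_ref - d)/sigma_ref)/2` with `mu_ref`, `sigma_ref`
the mean and SD of reference-set mean neighbor distances (self-matches
excluded). Vote ties break by smaller mean distance to the tied
label's neighbors, then label order. Operating points for the
independent evaluation are chosen on training out-of-fold
probabilities to hit the target sensitivity (0.8), then frozen;
sensitivity/specificity carry exact Clopper-Pearson 95% intervals,
consistent with the wide intervals such small cohorts produce.

# Quantification

Nuclear expression is total in-mask intensity over mask volume; the
denominator defaults to voxel count (intensity per voxel) with a
physical-um^3 switch, since the unit convention is an open choice. Membrane expression integrates over the full 2 um
physically-dilated mask (the literal reading; a shell-only variant can
be built from the same primitives), then min-max scales across all
analyzed cells pooled over disease groups — matching the pooled
histogram on which the single Otsu positivity threshold is computed.
DRAQ7 marks dead cells, so viability is the fraction *below* the
triangle threshold. Box statistics use linear-interpolation quartiles
and 1.5 x IQR fences. The compression summary tests bivariate
(projected area, mean intensity) *patient means* — the figure-level
reading of the assay — with the exact-F Hotelling T-squared; its
type-I error is checked at desk scale (2,000 null simulations within
[0.03, 0.07] at nominal 0.05).

# Numerical and degenerate-input conventions

* Constant images make multi-Otsu (and Otsu) fail loudly, never
  silently return 0.
* Degenerate min-max scaling (all equal) returns 0 with a warning.
* A reference set with zero neighbor-distance spread makes
  `sigma_ref` undefined and errors.
* An empty domain set defines D3 = D4 = 0.
* kNN ties break by index; dendrogram cuts include the threshold
  (cophenetic distance `<=` 1 - min co-association).
* All stochastic steps consume seeds derived from a master seed via a
  31-bit string hash (`derive_seed`), so every stage is independently
  reproducible and results never depend on call order.

# Problem sizes used by the test suite

The suite exercises the full pipeline at sizes a laptop handles in
minutes, chosen as this package's own desk-scale study conditions: the
clustering stability check runs 1,500 cells in 10 dimensions with 30
Leiden runs; the end-to-end recovery check renders ~500 nuclei across
12 individuals and 2 conditions with a planted 0.35 mixture-weight
difference, and its null counterpart repeats a feature-level cohort 20
times; balancing conservation is fuzzed over 10,000 random count
tables; the VAE smoke run uses 90 FOVs for 6 epochs at reduced widths.

# Known limitations

* The synthetic renderer's idealizations (above) mean test results
  bound correctness, not clinical performance.
* The handcrafted feature list and the dense-domain detector are
  documented stand-ins for an external publication's set.
* The VAE at full default width is CPU-trainable but slow in plain R;
  the defaults document the intended architecture while tests use
  reduced widths.
* No watershed splitting: touching nuclei merge into (usually
  oversize, hence filtered) regions.
* The stability ARI could equally be computed against first- or
  final-iteration runs; this package uses the final iteration.
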