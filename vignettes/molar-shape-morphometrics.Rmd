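---
title: "Landmark-based shape analysis of platyrrhine lower molars: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landmark-based shape analysis of platyrrhine lower molars: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(platymorph)
```

# The analysis problem

New World monkey (platyrrhine) lower molars are digitized in occlusal view
as configurations of 15 homologous landmarks: the tips of the four main
cusps (protoconid, metaconid, hypoconid, entoconid), eight points along
the crown outline, and three points on the crests. The questions the
package addresses are (i) how molar crown *shape* — what remains after
position, size and orientation are removed — varies across extant genera,
subfamilies and families; (ii) how reliably taxa can be told apart from
molar shape alone; and (iii) where isolated fossil teeth fall relative to
the extant variation, expressed as posterior membership probabilities.

The pipeline is the classic geometric-morphometrics stack: generalized
Procrustes analysis (GPA), principal component analysis of tangent-space
coordinates, and linear discriminant analysis (LDA) of the PC scores, plus
a repeated-digitization measurement-error study.

# Standardization of raw configurations

Digitized coordinates arrive in image units with a millimetre scale
factor, from either tooth side. `apply_scale()` converts to millimetres
(and becomes a no-op afterwards, since the stored scale is reset to 1).
`standardize_side()` reflects left-side configurations onto right-side
orientation. Two details deserve note:

* **Mirror axis.** With the mesial border facing the same direction for
  both sides, left and right antimeres differ by a reflection across the
  horizontal (mesiodistal) axis, which exchanges the buccal and lingual
  sides. The implementation therefore reflects `y -> -y`.
* **Index remapping.** Reflection swaps the anatomy under each landmark
  index if landmarks were digitized by screen position: the entoconid and
  hypoconid exchange places (1, 4), as do the metaconid and protoconid
  (2, 3) and the outline points below them (6, 12), (7, 11), (8, 10),
  while the midline and crest points (5, 9, 13, 14, 15) stay fixed.
  `mirror_pairs()` ships this remap as data, and `standardize_side()`
  accepts any remap (including the identity, appropriate when landmarks
  were placed by anatomical definition regardless of orientation). The
  combined map is an involution, which the tests verify to 1e-12.

TPS input is read with a deliberately minimal dialect (`LM=`, coordinate
lines, `ID=`, `IMAGE=`, `SCALE=`); outline/curve blocks are rejected
rather than silently dropped. Because image-origin conventions vary
between digitizers, `read_tps(flip_y =)` optionally negates y on input.
Records without a `SCALE=` line default to scale 1 with a warning rather
than an error, since shape (though not any size covariate) is unaffected
after superimposition.

# Superimposition

`gpa()` implements the standard iterative least-squares superimposition:
all configurations are centered and scaled to unit centroid size, aligned
to a provisional consensus, and the consensus is recomputed (and rescaled
to unit size) until it moves by less than `tol`. Choices:

* **Partial Procrustes fit** (all specimens kept at unit centroid size)
  is the default, matching the behaviour of the widely used MorphoJ
  software; `scale_mode = "full"` additionally fits per-specimen scales.
* **Reflections are disallowed** during alignment (`allow_reflection =
  FALSE`) because tooth side is standardized beforehand; the option
  exists for diagnostic use.
* **Convergence**: `tol = 1e-8` on the root summed squared consensus
  displacement, at most 100 iterations. The objective (summed squared
  distance to the consensus) is non-increasing, which is tested. On all
  datasets exercised here convergence takes fewer than 10 iterations.
* **Orientation**: after convergence the consensus is rotated to its
  principal axes, with a deterministic sign rule (the landmark farthest
  from the centroid along the first axis gets positive x), so PC
  orientations are reproducible across runs and machines.
* **Degenerate input** (coincident landmarks, fewer than 2 shapes,
  mismatched landmark counts) is a hard error; missing landmarks are not
  estimated, since the analysis assumes complete configurations.

`procrustes_distance()` defaults to the partial Procrustes distance
(rotation-minimized distance between unit-size preshapes,
`sqrt(2 - 2s)`); `scale = "full"` and `scale = "none"` (no rescaling,
distances in raw units) are available. A numerical point that shaped the
test suite: near zero this distance has a precision floor of about
`sqrt(.Machine$double.eps)` because of the square root, so exact-recovery
tests compare superimposed coordinates rather than distances.

Tangent-space coordinates are obtained by orthogonal projection of the
aligned coordinates onto the hyperplane orthogonal to the consensus; each
specimen's stored tangent vector is its projected deviation from the
consensus. For the dispersions seen here (Procrustes distances well below
0.3) the tangent approximation is excellent; the tests check agreement
with Procrustes residuals to 1e-5 at small noise.

# Shape PCA and deformation grids

`shape_pca()` decomposes the covariance matrix of the tangent
coordinates — covariance, not correlation: shape coordinates share units,
so no column scaling is appropriate. At most `2k - 4 = 26` components are
non-null for `k = 15` 2D landmarks; percent variance is reported over the
non-null components. Eigenvector signs follow the rule that the
largest-magnitude loading coordinate is positive.

Because the PCA is centered at the *sample mean* of the tangent
coordinates (the covariance definition), the consensus — the zero tangent
deviation — projects not to the exact origin but to minus the projected
sample mean, a vector of order (dispersion)^2 that the tests bound at a
small fraction of the leading singular value. This is a real, if tiny,
asymmetry of tangent-space PCA worth knowing about when reading score
plots.

Two scopes are supported: `scope = "all"` fits the axes on every
superimposed specimen, fossils included (this is the default, since the
joint morphospace plot is the display of record); `scope = "extant"` fits
on extant specimens only and projects fossils afterwards with
`predict()`. Both give the same GPA; only the axes differ.

`warp_grid()` renders the shape change along a component as a thin-plate
spline (TPS) deformation of a rectangular lattice around the consensus
(10% margin), the classic deformation-grid display. The TPS interpolant
is exact at the landmarks and its bending energy is zero exactly when the
map is affine — both are tested, the latter against a pure shear. The
requested score must lie within 1.5x the observed score range, as grids
far outside the data are not meaningful. Score-plot ellipses drawn by
`plot.shape_pca()` are 95% *data* ellipses of each group's scores, not
confidence ellipses of the group mean; the choice is deliberate (the
display is about group dispersion and overlap) and configurable via
`ellipse_level`.

# Discriminant classification

`shape_lda()` solves the generalized eigenproblem of between-group
against pooled within-group covariance of the retained PC scores.
Classification — of training specimens and of unknowns — uses the squared
Mahalanobis distance to each group centroid under the pooled covariance,
with posteriors proportional to `prior * exp(-d^2 / 2)`; this is the
classical linear rule. Design decisions on points the underlying protocol
leaves open:

* **Number of PCs.** Default: all supplied score columns, reduced from
  the right until the pooled within-group covariance has condition number
  below 1e8, and never more than `n - g - 1` (one spare within-group
  degree of freedom, so leave-one-out refits of the same columns remain
  nonsingular). The retained count is stored in the fit and written to
  the run metadata, so any configuration-driven discrepancy is
  diagnosable. `n_pcs` overrides.
* **Priors.** Equal across groups by default. The extant sample is very
  unbalanced (over a hundred howler-monkey specimens against four
  Goeldi's marmosets), and proportional priors would let prevalence
  dominate the posteriors of unknowns; `prior = "proportional"` is
  available.
* **Cross-validation.** `loocv_pcc()` refits the model from scratch for
  every held-out specimen — no fast update formula — and the tests pin it
  against an independently coded brute-force oracle, exactly.
* **Ties** in the posterior arg-max are broken towards the first label in
  sorted order, with a warning.

`run_all_ldas()` runs the four grouping factors (family, the
eight-subfamily scheme, the five-subfamily scheme, genus) for each tooth
and collects DF1/DF2 variance shares, original and cross-validated
percent correct classification, and per-fossil posterior tables. Fossils
absent for a tooth are simply absent from that tooth's dataset and are
noted, not imputed.

# Measurement-error study

The intra-observer toolkit mirrors the usual design: a few specimens
digitized several times over several sessions.

* `repetition_distances()`: Procrustes distances over all unordered
  pairs of repetitions within each specimen, pooled mean and SD. The
  default uses unit-size shapes; `scale = "none"` gives raw-unit
  distances, since published error summaries do not always state which
  convention was used and the two differ by the centroid-size factor.
* `repeatability_mantel()`: for each repetition, the specimen-by-specimen
  Procrustes distance matrix; the summary is the mean Mantel correlation
  over all unordered pairs of repetition-specific matrices. This is the
  most direct reading of "average correlation between distance matrices
  of the repeated measurements"; the per-pair correlations are returned
  so other averages can be formed.
* `perm_manova()`: distance-based pseudo-F
  `(SS_between / (a-1)) / (SS_within / (N-a))` with the sums of squares
  derived from the pairwise distance matrix. With Euclidean distances
  this equals the classical one-way F built from per-coordinate sums of
  squares — an algebraic identity the tests verify to 1e-9, alongside a
  cross-check against an independent implementation. The grouping factor
  is `"repetition"` by default, with `"day"` available, as either reading
  of "differences among repetitions" is defensible.
* Permutation p-values throughout use the `(b + 1) / (m + 1)` convention
  (observed statistic included), which guarantees validity; permutations
  are drawn from a local RNG stream when a seed is given, leaving the
  caller's RNG state untouched.

Published error statistics of the motivating kind (a mean paired distance
near 0.13, Mantel correlations near 0.99, a vanishing pseudo-F) cannot be
recomputed without the raw repeated digitizations, which are not
deposited; the module is therefore validated by properties — the paired
distance scales linearly with the digitizing noise, the permutation
p-values are uniform under their nulls, and the pseudo-F identity holds —
rather than by reproducing printed values.

# The synthetic-data generator

`generate_dataset()` draws datasets with the statistical structure the
analysis assumes, so every stage is testable without any download:

* **Taxonomy**: the default `platyrrhine_taxonomy()` mirrors the extant
  comparative sample structure — 3 families, 8 subfamilies (one scheme)
  against 5 (the other), 18 genera, 61 species and their per-species
  specimen counts (792 specimens in total as tabulated).
* **Group effects**: each taxon at each level receives a smooth
  displacement field, built by displacing a random subset of 6–10
  landmarks and interpolating with a thin-plate spline. The field's
  similarity components (translation, rotation, rescaling) are projected
  out before it is normalized to magnitude `delta * w_level`, so `delta`
  is a genuine shape-space effect size — without the projection a large
  part of each "effect" would be removed again by the GPA, and nominally
  identical effect sizes would vary wildly in realized separation. The
  anchor subset is drawn at 6–10 landmarks (not fewer) so the fields span
  enough directions that independently drawn group effects are rarely
  near-parallel.
* **Level weights** default to family 1.0, subfamily 0.6, genus 0.35,
  species 0.2 — a fixed hierarchy of effect sizes. The scale pair was
  calibrated once and frozen at `delta = 0.08`, `sigma = 0.02` (isotropic
  per-landmark noise, unit-centroid-size shape units) so that
  subfamily-level cross-validated classification on the default
  conditions lands in the realistic 80–95% regime; the constant is
  documented here, not fitted per run.
* **Nuisance structure**: every specimen gets a random rotation,
  translation, crown size (about 5 mm), image scale, and side (30% left,
  emitted mirrored with remapped landmark order), so the reader,
  standardization and GPA are exercised end to end.
* **Fossils** are generated at a random genus centroid (default),
  interpolated between two centroids, or offset to a novel shape, and
  carry a truth recipe so classification output can be scored exactly.
* **Determinism**: all randomness flows from one seed through a local
  RNG stream; a fixed seed reproduces the dataset bit for bit.

What the generator does *not* emulate: allometry (shape–size covariation
is absent by construction), non-isotropic landmark-specific digitizing
error, integration/modularity covariance structure between landmarks,
within-genus phylogenetic structure beyond the nested mean offsets, and
observer drift across sessions. Passing tests on synthetic data therefore
demonstrate the correctness and statistical calibration of the machinery,
not that real molar data satisfy the generative assumptions.

# Problem sizes and numerical tolerances used in validation

The test suite and the acceptance script run the full default emulation
(805 configurations), a 2000-specimen isotropic-noise PCA null, a
500-specimen consensus-recovery check (noise SD 0.01, recovering the
template within Procrustes distance 0.005), a five-point
separation-to-noise grid with 20 replicate datasets of 60 specimens each
for the classification-recovery curve, 200-run uniformity checks of the
permutation p-values, and 100-replicate repetition studies per noise
level for the error-scaling law. These sizes were chosen to make
Monte-Carlo error comfortably smaller than the asserted margins while
keeping a full run in the tens of seconds. Key tolerances: 1e-9 for
algebraic identities (trace conservation, orthonormality, TPS
interpolation, pseudo-F identity), 1e-5 against the 0.1-degree rotation
grid oracle (the grid's own resolution), exact equality for the LOOCV
oracle, and Monte-Carlo-scaled bands (±5 percentage points at n = 400)
for chance-level classification.

# Known limitations

* 2D occlusal projections only; no 3D landmarks or semilandmarks.
* No allometric regression (shape on centroid size) or between-group
  PCA; the LDA operates on the plain tangent PCA scores.
* The Mahalanobis posterior model assumes a shared within-group
  covariance (linear boundaries); strongly heteroscedastic groups would
  call for quadratic or regularized variants, which are out of scope.
* Genus-level truth recovery for fossils generated at genus centroids is
  intrinsically imperfect when genus-level effects are small relative to
  noise — the posterior spreads over morphologically adjacent genera.
  This is a property of the study design, not a defect of the
  classifier, and is quantified (not assumed) by the acceptance script's
  truth-scored fossil metrics.
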