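# platymorph

Landmark-based geometric morphometrics of New World monkey (platyrrhine)
lower molars: generalized Procrustes analysis, tangent-space shape PCA
with thin-plate-spline deformation grids, linear discriminant
classification of fossil teeth against extant taxa, and a
repeated-digitization measurement-error toolkit.

## The problem

Isolated fossil molars are often all that survives of an extinct primate,
and molar crown shape carries a strong taxonomic signal. Given
two-dimensional configurations of k = 15 homologous occlusal landmarks
(four cusp tips forming the occlusal polygon, eight crown-outline points,
three crest points) digitized on first and second lower molars of extant
platyrrhines, the package answers:

* how molar **shape** varies across genera, subfamilies and families once
  position, size and orientation are removed;
* how reliably taxa can be discriminated from shape alone; and
* to which extant group an unclassified (fossil) tooth most plausibly
  belongs, with a posterior probability.

## Methods at the core

**Superimposition.** Generalized Procrustes analysis: each configuration
X_i (k x 2) is centered, scaled to unit centroid size
CS(X) = sqrt(sum_j ||x_j - x̄||²), and rotated to minimize the summed
squared distance to an iteratively refined consensus; aligned coordinates
are projected into the tangent space at the consensus. The partial
Procrustes distance between shapes is d(X, Y) = sqrt(2 − 2s), with s the
sum of sign-corrected singular values of the preshape cross-product.

**Ordination.** PCA of the covariance matrix of tangent coordinates (at
most 2k − 4 = 26 non-null components); shape change along a component is
visualized as a thin-plate-spline deformation grid, exact at the
landmarks, with zero bending energy iff the deformation is affine.

**Classification.** Canonical discriminant analysis of the PC scores at
four taxonomic levels (family, two competing subfamily schemes, genus):
the generalized eigenproblem of between- versus pooled within-group
covariance. Specimens and unknowns are assigned by Mahalanobis distance
d_g to group centroids under the pooled covariance, with posteriors
p(g | x) ∝ prior_g · exp(−d_g²/2); reliability is the percentage of
correct classification (pcc), before and after leave-one-out
cross-validation (every fold a full refit).

**Measurement error.** Paired Procrustes distances between repeated
digitizations, mean Mantel correlation between repetition-specific
distance matrices, and a permutational MANOVA pseudo-F
(SS_b/(a−1))/(SS_w/(N−a)) on tangent coordinates with label permutations.

A hierarchical synthetic-data generator (3 families / 8 subfamilies /
18 genera / 61 species with realistic sample sizes, smooth
thin-plate-spline group effects, isotropic landmark noise, random
similarity transforms and tooth sides, truth-tagged fossils) makes every
stage testable end to end; see the methods vignette
(`vignettes/molar-shape-morphometrics.Rmd`) for the model, its
parameters, and what it does and does not emulate.

## Worked example

```r
library(platymorph)

gen <- generate_dataset(synth_spec(), seed = 1)   # default study emulation
ds  <- standardize_dataset(gen$dataset)           # side + scale normalization
print(ds)
#> Shape dataset: 805 M1 configurations (792 extant, 13 fossil)
#>   63 species, 18 genera, 8 subfamilies (G), 3 families

g <- gpa(ds)                                      # Procrustes superimposition
print(g)
#> Generalized Procrustes analysis: 805 configurations, 15 landmarks
#>   partial Procrustes fit, 4 iterations (converged)
#>   total shape variation (sum of squares to consensus): 14.5494

p <- shape_pca(g)
print(p)
#> Shape PCA (all specimens): 26 non-null components
#>   PC1: 25.04%
#>   PC2: 13.65%
#>   PC3:  5.33%
#>   PC4:  4.32%
#>   PC5:  3.33%
#>   ... (21 more components)

extant <- !g$info$fossil
fit <- shape_lda(p$scores[extant, ], g$info$subfamily_G[extant])
print(fit)
#> Shape LDA: 8 groups, 792 specimens, 26 PCs retained (equal priors)
#>   DF1:  55.1% of discriminant variance
#>   DF2:  28.8% of discriminant variance
#>   original correct classification: 93.4%

loocv_pcc(fit)$pcc
#> [1] 91.03535

posterior <- predict(fit, p$scores[g$info$fossil, ])$posterior
```

Reading the output: the first two PCs carry 25.0% + 13.7% of the shape
variance — a typical picture where one dominant contrast (broad occlusal
polygon and rectangular outline versus a more quadrangular crown)
organizes the morphospace but plenty of variation remains in later
components. The eight-subfamily discriminant analysis classifies 93.4% of
specimens correctly on the training data, dropping to 91.0% under
leave-one-out cross-validation — the honest figure. The posterior matrix
gives, for each fossil, its membership probability in every subfamily;
rows sum to 1.

Plots: `plot(p, fossil_scores = p$scores[g$info$fossil, ])` draws the PC1 x PC2
morphospace with 95% data ellipses per subfamily and fossil overlays;
`plot(warp_grid(p, 1, max(p$scores[, 1])))` draws the deformation grid at
the PC1 extreme. `run_replication(run_config(synthetic = TRUE, seed = 1))`
writes the whole report bundle (variance, scores, loadings, the
classification summary table, fossil posteriors, run metadata) to CSV and
YAML.

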