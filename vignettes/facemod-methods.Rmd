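---
title: "Methods: hierarchical shape phenotyping and gene-based multivariate kernel tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical shape phenotyping and gene-based multivariate kernel tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facemod)
```

# The problem

Common-variant association studies of normal-range facial morphology leave
much of the heritable variation unexplained. One complementary strategy is
to test low-frequency coding variants (minor allele frequency below 1%) in
aggregate, gene by gene, against *multivariate* shape phenotypes rather than
single measurements. Doing that requires two pieces of machinery:

1. **Global-to-local phenotyping.** Dense homologous quasi-landmarks on each
   face are Procrustes-aligned and recursively segmented into a five-level
   binary hierarchy of 31 facial modules, each module summarized by a small
   set of principal components (PCs) of its within-segment shape variation.
2. **A multivariate gene-based test.** For each (gene, module) pair, a
   kernel score test relates the gene's weighted low-frequency variants to
   the module's PCs under four kernel combinations, and the four p-values
   are combined through a copula-calibrated minimum-p omnibus.

`facemod` implements both stages plus single-variant follow-up,
effective-number-of-tests multiplicity correction, effect-size and morph
reporting, and — because the human cohorts this design targets are under
controlled access — a synthetic cohort generator that reproduces the
statistical structure the analysis assumes, so every stage is testable
end to end.

# The synthetic cohort generator

`synth_config()` + `simulate_cohort()` generate:

* **Faces.** A regular grid of `L` quasi-landmarks embedded as a curved 3D
  patch (mm units). Shape covariance is built hierarchically: a binary tree
  over the grid (`2^d - 1` segments for depth `d`) in which every node
  contributes `deform_rank` random unit deformation fields confined to its
  landmarks, with per-individual Gaussian coefficients whose SD decays with
  level (default `1.6 * 0.85^level` mm). This realizes the assumption the
  segmentation stage relies on — landmarks within a segment co-vary more
  than landmarks across segments — and makes leaf membership a recoverable
  ground truth. Iid Gaussian landmark noise (default 0.2 mm) and a random
  per-individual rigid transform (rotation up to 15 degrees, translation,
  scale 0.9–1.1) are added so the Procrustes stage is exercised
  non-trivially.
* **Covariates.** Sex, age, height, weight, ancestry PCs, and facial
  centroid size; each with a linear effect on shape along a fixed unit
  field (defaults of a few tenths of a millimetre per SD), so that the
  residualization stage has real work to do.
* **Genotypes.** Per gene, 5 variants by default with true MAFs uniform on
  a configurable low-frequency range, dosages Binomial(2, MAF) across
  unrelated individuals, written and re-read as plain VCF 4.2.
* **Planted effects.** Carriers of at least one minor allele in a chosen
  gene are displaced along a fixed unit field confined to one segment,
  scaled by a magnitude in mm. The field is applied in each individual's
  own frame (the recorded rigid transform), so the signal survives
  alignment coherently. With identity transforms the per-carrier
  displacement norm is exactly the stated magnitude.

What the generator does **not** emulate: mesh topology and texture,
registration error (input landmarks are homologous by construction),
non-Gaussian shape variation, population stratification beyond independent
ancestry-PC effects, linkage disequilibrium between variants, and
relatedness. Passing tests therefore demonstrate the statistical machinery
under its stated assumptions, not robustness to the messiness of real
image-derived data.

# Phenotyping

**GPA.** `gpa_align()` iteratively centres, optionally scales to unit
centroid size, and rotates each configuration onto the evolving mean
(orthogonal Procrustes via SVD with reflections forbidden), stopping when
the mean moves less than `tol = 1e-10` RMS. Scale is removed during GPA
and centroid size is carried as the "facial size" covariate — this keeps
allometry adjustable downstream rather than entangled in every module.
After convergence the mean shape is rotated onto its principal axes with
signs fixed by its own third moments, so the aligned output does not
depend on the (arbitrary) frame the landmarks arrived in; every downstream
p-value is invariant to global rigid transforms of the input, which the
test suite checks end to end at `1e-6`.

**Segmentation.** Landmark similarity is the RV coefficient between the
two landmarks' `n x 3` displacement blocks — bounded in [0, 1], rotation
invariant, and 1 for duplicated landmarks. Each node's similarity matrix is
bipartitioned with the normalized Laplacian: the Fiedler vector's signs
seed a deterministic 2-means refinement on the 2D spectral embedding.
Degenerate cases have fixed, logged behaviour: disconnected graphs split
along components; an all-equal similarity matrix splits deterministically
by index. GPA is re-run inside every node before its similarity is
computed, and the recursion runs to five levels (31 segments) unless a node
drops below 8 landmarks, in which case that branch stops and the hierarchy
is flagged incomplete. Segment boundaries can be re-estimated per dataset
or frozen by passing an existing hierarchy to `phenotype_modules()` — both
workflows are supported because cohort-to-cohort transfer of boundaries is
a design decision, not something the method dictates.

**Per-module PCs.** PCA of the segment-aligned coordinates with a
deterministic sign convention; retention by parallel analysis (100
column permutations by default, 95th percentile, leading-run rule, floored
at one PC). Retained scores are then residualized on the covariates.
Because partial least squares with as many latent components as the
covariate rank coincides with least-squares projection, the residualization
is computed by QR projection; the contract — adjusted scores exactly
orthogonal to every covariate column — is asserted in tests at `1e-8`.

**Outlier screen.** Robust squared Mahalanobis distances of each module's
scores (minimum covariance determinant centre/covariance, with a logged
classical fallback if the robust estimate is singular), flagged against a
Bonferroni-style chi-square cutoff `qchisq(1 - alpha/n, K)`, with the Q-Q
pairing exported for visual review — the flagging threshold is a
convenience; the Q-Q data are the primary artifact, mirroring how such
screens are actually used.

# The gene-based kernel test

For a module with score matrix `Y` (n x K, covariate-adjusted) the null
model is an intercept-only multivariate regression (covariates may be
supplied, but adjustment normally happened at phenotyping): residuals `R`,
residual covariance `Sigma = R'R/(n - p)`, ridge-regularized only if its
condition number exceeds `1e10` (logged). Variants are weighted
`w_j = dbeta(MAF_j, 1, 25)` — the SKAT-family convention that up-weights
rarer variants — giving `Gw`. The score matrix is

```
S = Gw' R Sigma^{-1}        (m variants x K traits)
```

The four kernel statistics are quadratic forms in `S`:

| phenotype kernel | genotype kernel | Q |
|---|---|---|
| heterogeneous (identity) | SKAT | `sum(S^2)` |
| homogeneous (all-ones) | SKAT | `sum(rowSums(S)^2)` |
| heterogeneous | burden | `sum(colSums(S)^2)` |
| homogeneous | burden | `(sum(S))^2` |

Under the null, `vec(S) ~ N(0, Sigma^{-1} (x) Gw'P0Gw)` with `P0` the
covariate projector, so each Q is a mixture of 1-df chi-squares with
weights `a_i * b_l`: `a_i` the eigenvalues of `Sigma_P Sigma^{-1}`
(`Sigma_P = I` heterogeneous; all-ones — hence the single non-zero
eigenvalue `1'Sigma^{-1}1` — homogeneous) and `b_l` the eigenvalues of
`Gw'P0Gw` (SKAT) or the collapsed scalar `1'Gw'P0Gw1` (burden). The
homogeneous/heterogeneous pair is the appropriate choice when the traits
are orthogonal PCs, which is exactly what the phenotyping stage produces.

**Mixture-of-chi-square tails.** `pvalue_mixture_chisq()` prefers an exact
series expansion of the quadratic form into central chi-square tails
(scale `beta = min(lambda)`, non-negative weights summing to one, truncated
when the remaining mass is below `5e-15`); if the eigenvalues are too
spread for the series to converge within 3000 terms it falls back to
characteristic-function inversion (Imhof's integral via adaptive
quadrature), and as a last resort to non-central chi-square moment
matching. The method used is recorded per result, and p-values below
`1e-14` are flagged rather than refined.

**Omnibus.** The four p-values are combined as `T = min(p)` calibrated
under a Gaussian copula: the 4x4 correlation of probit-transformed null
p-values is estimated from `B = 500` resamples of `S` drawn directly from
its null law (equivalent to resampling residual rows from `N(0, Sigma)`,
but vectorizable), and `p_omnibus = 1 - P(all four probits <= probit(1-T))`
computed with a deterministic-seeded multivariate-normal rectangle
probability. Resample p-values use the moment-matching approximation —
only their correlation is consumed — while observed p-values always use
the exact engines. Requests with `B < 50` are refused as too unstable.
Perfect dependence gives `p = T`, independence `1 - (1-T)^4`, and the
omnibus always lies between those bounds. When the rectangle probability
cannot resolve `1 - P` (that is, below about `1e-8`), the independence
combination is reported instead — conservative by at most a factor of 4
at that magnitude.

**Known behaviour.** The omnibus is mildly conservative in the mid-range
(minP under an estimated Gaussian copula; the same behaviour is documented
for the method family), but holds its size within Monte-Carlo error at the
0.05 and 0.01 levels used for calibration — this is measured, not assumed,
by the acceptance suite on 2000 null gene tests.

# Single-variant follow-up

Variants inside genes that pass the significance threshold are tested by
reverse regression: the genotype, as an ordered categorical dosage, is
regressed on all K module PCs jointly and compared to the intercept-only
model by a likelihood-ratio test with `df = K` — i.e. the test finds the
linear combination of PCs most associated with the genotype. With two
observed genotype classes (the norm for low-frequency variants, where
heterozygotes are the only carriers) this reduces to binary logistic
regression; detected separation switches to a Jeffreys-penalized (Firth)
fit, flagged in the output. Calibration is asserted at MAC >= 10;
below that, discreteness inflates the tails — which is precisely why the
gene-based aggregate test, not the single-variant test, is the primary
discovery instrument.

# Multiplicity, effect sizes, morphs

Module phenotypes overlap (a parent shares all its landmarks with its
children), so Bonferroni over 31 modules would be too strict. The
inter-module correlation is summarized by the RV coefficient between
module score blocks, and the effective number of independent modules by
the eigenvalue rule `M_eff = sum(1(lambda >= 1) + frac(lambda))`, reported
raw and rounded half-up. The gene-level threshold is
`alpha / (n_genes * M_eff)`; at the published study's scale
(8091 genes, 19 effective modules) this is `3.3e-7` at two significant
figures. Which inter-block correlation the eigenvalue rule should consume
is genuinely open for multivariate blocks; the RV coefficient was chosen
for consistency with the segmentation machinery and is isolated in
`module_correlation()` should a user prefer another.

Effect sizes are carrier/non-carrier centroid distances in a module's PC
space; morphs export the non-carrier mean segment shape plus the
carrier-minus-non-carrier displacement field, multiplied by an
exaggeration constant (default 7) to make subtle effects visible, with the
signed normal component (protrusion positive) for colouring. Normals come
from local plane fits, oriented away from the segment centroid.

# Numerical and design choices

* Per-stage seed streams are derived by hashing the stage name into the
  master seed, so adding a stage never perturbs another's draws, and every
  run is bit-reproducible.
* PCA signs (largest |loading| positive) and GPA principal-axis signs
  (third moments) are fixed conventions; without them, the homogeneous
  kernel — which is not sign-invariant — would depend on the input frame.
* Parallel-analysis permutation count (100) and percentile (95) follow
  common practice; both are arguments.
* `MAF < 1%` is strict and `MAC >= 4` inclusive ("three or fewer minor
  alleles removed"); with small cohorts the two rules interact (at
  n = 250, only MAC = 4 can satisfy both) — the filter log makes this
  visible.
* Missing dosages are imputed to `2 * MAF` for testing; for the ordinal
  follow-up they are rounded to the nearest genotype class.
* Variants mapping to several genes contribute to each (configurable
  upstream by editing the gene map).
* Monomorphic-in-sample variants inside a gene are dropped at test time
  with a message.

# Problem sizes used by the test and acceptance suites

Desk-scale conditions were chosen so the full 31-segment hierarchy is
well-posed and the suites complete in minutes: n = 500 individuals,
L = 256 landmarks and 5 levels for segmentation, retention and
multiplicity checks; 2000 null genes (5 variants each, MAF 0.002–0.01,
`B = 500`) for type-I calibration at `alpha` 0.05 and 0.01; 100 replicates
of a 20-gene cohort (n = 500, L = 64, 3 levels, MAF 0.004–0.01) for the
planted-gene top-hit rate, with the planted magnitude fixed at 2.5 mm —
calibrated once to give roughly 80–90% power at those conditions — and
smaller cohorts for the unit tests. The synthetic leaf-level
deformation-to-noise ratio at the defaults is about 4.2, the regime in
which leaf recovery is expected to be near-perfect (adjusted Rand index
above 0.9, observed about 0.98–0.99).

# Limitations

* The mixture-chi-square null law treats the residual covariance as known;
  at `n >> K` the effect is negligible, but very small cohorts with many
  PCs will show it.
* The omnibus copula correlation is re-estimated per gene (`B = 500`);
  extremely small omnibus p-values inherit the `1e-8` rectangle-probability
  resolution and are then reported via the conservative independence bound.
* The generator's planted effects are linear mean shifts; power statements
  do not transfer to non-linear or variance effects.
* Real-data ingestion expects homologous landmarks (registration is out of
  scope) and a biallelic VCF with GT fields; multi-allelic sites are
  skipped with a message.
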