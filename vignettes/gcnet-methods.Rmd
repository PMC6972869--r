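---
title: "Genetic correlation networks and cross-phenotype tests: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic correlation networks and cross-phenotype tests: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcnet)
```

## The analysis in one paragraph

gcnet analyzes many correlated quantitative traits measured on one
genotyped cohort — the motivating case is a neuroimaging-genetics study
in which every trait is the volume of one brain region of interest (ROI)
and every subject contributes all traits. The pipeline runs a per-trait
additive-model GWAS, estimates pairwise genetic correlations between
traits from the summary statistics, organizes the traits into a weighted
network whose edges are soft-thresholded genetic correlations, extracts
modules of genetically coherent traits by topological-overlap
clustering, and then combines the per-SNP association evidence of each
module's traits with the CPASSOC statistics S_Hom and S_Het, which
account for the correlation between the traits' test statistics induced
by the shared cohort. Because the cohorts such studies use are
restricted, the package ships a seeded synthetic-cohort generator with
known genetic ground truth, so every stage is testable end to end.

## The synthetic cohort

`simulate_genotypes()` draws unrelated samples at biallelic SNPs with
per-SNP allele frequencies uniform on a range (default 0.05–0.5) and
binomial(2, MAF) dosages; there is no population structure and SNPs are
independent by default, so LD score regression reduces to an exactly
analyzable regime. An optional Gaussian-copula mode induces
block-autocorrelated dosages for experiments that need varying LD. A
`variants` template lets a second cohort reuse the first cohort's SNP
ids, alleles and population frequencies — the multi-cohort mode used to
study estimators with zero sample overlap. Passing the same seed
reproduces every table bit for bit.

`simulation_truth()` fixes the genetic architecture once: per-trait
heritability h², a positive semi-definite genetic-correlation target
matrix ρ_g, causal sets (one shared set by default), and the realized
per-SNP effect sizes, drawn from a multivariate normal whose
trait-by-trait covariance is ρ_g scaled by per-SNP effect variances
h²_k/c_k. With a shared causal set the expected genetic covariance
between traits is exactly ρ_g·√(h²_1 h²_2); with disjoint sets the
traits are genetically independent regardless of ρ_g.
`simulate_phenotypes()` adds correlated Gaussian environmental noise
(equicorrelation `env_cor` on the residual scale) and standardizes each
trait to unit sample variance; the ROI volumes the design emulates have
arbitrary units, so unit variance loses nothing and keeps h² directly
interpretable as a variance fraction. Covariates (age, sex, education,
handedness, three placeholder principal-component scores) exercise the
adjustment machinery; the PC columns are independent Gaussians, not a
stratification correction, because the genotypes carry no structure to
correct.

What the generator deliberately does not emulate: realistic LD from
reference haplotypes, allele-frequency-dependent effect sizes,
non-normal trait distributions, relatedness, and genotyping batch
effects. Tests passing on these cohorts therefore validate the
estimators' logic and calibration, not their robustness to the full
messiness of real imaging-genetics data.

## GWAS stage

Quality control retains SNPs with call rate ≥ 0.98, minor allele
frequency ≥ 0.01 (computed on the observed genotypes of the analyzed
samples), and a Hardy–Weinberg goodness-of-fit P ≥ 1e-6 from the
one-degree-of-freedom chi-square test; all thresholds are inclusive and
the QC report names the first failing rule per excluded SNP. The
association model is ordinary least squares of the trait on the A1
dosage, covariates and an intercept. Samples with a missing dosage are
casewise-deleted for that SNP only, and the recorded per-SNP sample size
reflects the deletion — mean imputation would keep n dishonest. P-values
use the standard-normal reference for the Wald statistic by default
(the large-n regime); `p_reference = "t"` gives the exact t reference.
SNPs with zero post-deletion dosage variance or a residual-free fit are
flagged rather than silently dropped, and the writer excludes them from
downstream files. The genomic-control factor is median(Z²)/0.45494 with
the chi-square median fixed at five decimals. A polygenic trait inflates
λ legitimately; the calibration claim that λ stays within 1 ± 0.1 is
made, and tested, under the global null.

## Simplified LD score regression

Heritability is estimated by ordinary least squares of the per-SNP Wald
chi-square on the LD score, h² = slope·M/mean(N); the genetic covariance
of a trait pair by the same regression with z₁z₂ as the response,
ρ_g = slope·M/√(mean N₁ · mean N₂); and r_g = ρ_g/√(h²₁h²₂).
Standard errors come from a delete-a-block jackknife over 200 contiguous
SNP blocks (⌊m/2⌋ blocks below 400 SNPs); the jackknife is applied to
the slope, with the h² point estimates held fixed in the r_g transform —
re-estimating h² inside every replicate occasionally produces
non-positive replicates that would make the jackknife undefined. This
estimator is deliberately simpler than the published method: no
iterative heteroskedasticity weights, no reference-panel LD scores, no
partitioning. It is adequate for the synthetic regimes above and is not
a substitute for the published software on real data.

Two intercept regimes exist because the synthetic default — independent
SNPs — makes every LD score exactly 1, and a free-intercept regression
on a constant regressor is singular:

* **Varying LD scores** (LD-mode cohorts): the intercept is free, as in
  the published estimator, absorbing confounding in the h² fit and
  sample overlap in the cross-trait fit.
* **Constant LD scores**: the h² intercept is constrained to its exact
  null value of 1, so the slope is mean(χ²) − 1. The cross-trait
  intercept is the sample-overlap term — the correlation of the two
  traits' statistics under the null. It is estimated from the median of
  the per-SNP products z₁z₂, inverted through the exact
  median-of-product curve of the bivariate normal (computed once by
  quadrature and cached). The median is robust to the causal minority
  of SNPs, is exactly the chi-square(1) median for a trait paired with
  itself (recovering r_g = 1 for self-pairs), and is 0 for independent
  statistics. Near zero correlation the inverse of the curve is steep,
  so the residual contamination of the median still costs on the order
  of 0.1 in ρ_g under strong polygenic signal; when two cohorts are
  known to share no samples, `intercept = "zero"` fixes the overlap
  term at 0, the analogue of the published estimator's no-intercept
  mode, and is what the package's own recovery studies use for
  disjoint cohorts.

Pairs whose estimate is NA, above 1 or below −1 — which small cohorts
produce regularly — are marked invalid by `build_rg_matrix()` and carry
an NA in the matrix; the invalid count is reported and logged. Pairs
with non-positive ĥ² are invalid by construction (the r_g denominator
is undefined), not clipped.

## The trait network

The adjacency is the power function a_ij = |r_g(ij)|^β, with a pair
zeroed when its P-value exceeds the threshold or it is invalid; the
diagonal is 0. β and the P threshold are chosen over the default grids
β ∈ {2, 4, 6, 8} and P ∈ {0.5, 0.3, 0.2, 0.1} by the scale-free
topology criterion: nodes with nonzero count connectivity k are binned
into 10 equal-width bins and log10 p(k) is regressed on log10 k; the
configuration with the largest R² among fits with a negative slope
wins. Two printed definitions of connectivity coexist in this
literature — the count of direct connections and the weighted sum
Σa_iu — and the package keeps both: the count degree drives the
scale-free fit (so the selection is invariant to β given the same
surviving edges, and ties resolve to the smaller β, then the larger
threshold — the less aggressive transformation), while the weighted
k_i enters the topological overlap formula. Grid cells whose degree
distribution is constant, or whose binned frequencies are constant, are
degenerate and excluded; if every cell is degenerate the selection
refuses and asks for manual configuration.

The topological overlap is
w_ij = (l_ij + a_ij)/(min{k_i, k_j} + 1 − a_ij) with
l_ij = Σ_{u≠i,j} a_iu a_uj, the standard convention with the adjacency
diagonal fixed at 0; w ∈ [0, 1] for any adjacency in [0, 1], w_ii = 1,
and the clustering dissimilarity is d = 1 − w. Modules come from
average-linkage hierarchical clustering on d, cut at 0.95 of the
maximum merge height. The static fractional cut is a deliberate,
simple choice (dynamic tree cut is the documented alternative); one
degenerate case is handled explicitly: when all merge heights are equal
(a perfectly uniform network) the cut would isolate every node, and the
partition returns a single module instead. Clusters smaller than 3
traits and nodes with k = 0 receive label 0; modules are numbered in
decreasing size order. The number of modules is a data outcome, not a
tuning target.

## CPASSOC statistics

For one SNP, T is the vector of Wald statistics across the module's
traits, W = diag(√n) the sample-size weights and R the correlation
matrix of the statistics under the null. The homogeneous statistic is

S_Hom = (e′(RW)⁻¹T)² / (e′(WRW)⁻¹e),

chi-square with 1 df under the null. The printed weighting enters
through (RW)⁻¹; with equal weights — the single-cohort case throughout
this package — the weights cancel exactly, and all calibration results
here are invariant to the convention. The heterogeneous statistic
S_Het maximizes the same form evaluated on the sub-vector with
|T| > τ over magnitude thresholds τ. The implementation scans the
nested top-q subsets in decreasing |T| order (q = 1..K), which visits
every subset the supremum over τ can select and, unlike a scan over
unique |T| values, also reaches the singleton when magnitudes tie
(T = (3, −3) must yield 9, not 0). The numerator of the truncated form
is read as the square of the scalar e′(R(τ)W(τ))⁻¹T(τ). Sub-matrices
that are numerically singular receive a logged 1e-8 ridge.

R is estimated as the sample correlation of per-SNP Z-scores across
traits over SNPs whose maximum |Z| is below 1.96, projected to the
nearest correlation matrix if needed. Under full sample overlap the
statistic correlation equals the phenotypic correlation; the
componentwise truncation attenuates the estimate moderately (about
0.53 observed for a true 0.6 at the default cutoff), a conservative
bias that standard practice accepts and that the tests bound
explicitly.

The S_Het null has no standard form and is calibrated by Monte Carlo:
B draws from MVN(0, R), the empirical P is (r + 1)/(B + 1), and a beta
distribution is fitted by maximum likelihood to the chi-square(1)-tail
transform of the null draws, giving a smooth map that takes over when
the empirical P hits its floor of 1/(B + 1). At K = 1 the transform is
exactly uniform and the fitted beta is close to (1, 1), a calibration
identity the tests verify. B defaults to 10,000 in the pipeline
(calibration-grade; the acceptance studies use 100,000) and the model
stores its R fingerprint so a mismatched reuse fails loudly.

The module scan intersects the module traits' summary statistics by SNP
id, aligns alleles to the first trait (sign-flipping swapped pairs,
dropping mismatches), computes both statistics per SNP and flags SNPs
whose smaller P-value is at or below the scan threshold (default 1e-7),
reporting the conventional 5e-8 genome-wide line alongside, both
inclusive.

## Pipeline, determinism and problem sizes

`run_pipeline()` chains synth → QC → GWAS → r_g → network → modules →
scans → report tables under one validated config whose defaults are the
printed settings above. Every stage writes plain tab-delimited outputs;
the manifest records per-file MD5 checksums, per-stage seeds derived
from the master seed, and timings. Re-running an identical config
reproduces identical bytes; resuming loads cached stages and recomputes
any stage whose outputs were deleted, plus its descendants. The default
synthetic study — 10 traits in three genetic blocks (within-block
ρ_g = 0.8), 5,000 SNPs, 2,000 samples, h² = 0.5, 500 shared causal
SNPs, environmental equicorrelation 0.2, two planted pleiotropic SNPs
in the first block — completes in well under a minute on one CPU and
recovers the three blocks as modules. The package's simulation studies
use 20 seeds at n = 2,000 and m = 2,000–5,000 for power and recovery,
and B = 100,000 null draws for calibration; these sizes put Monte Carlo
error comfortably inside the tolerances they are checked against.

## Known limitations

The LD score estimator is unweighted and intercept-simplified, and its
full-overlap offset is approximate under strong polygenic signal (see
above); real-data applications should use the published estimators. The
scale-free criterion is fragile on very small trait sets, where few
distinct degrees exist — the selection then refuses rather than
returning an arbitrary cell. The beta tail map extrapolates beyond the
largest null draw; P-values far below 1/(B + 1) should be read as
order-of-magnitude statements. Modules depend on the static cut height;
on flat dendrograms the partition collapses to one module by design.
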