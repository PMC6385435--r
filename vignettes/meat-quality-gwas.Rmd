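---
title: "Mixed-model GWAS and downstream inference for crossbred beef meat quality: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed-model GWAS and downstream inference for crossbred beef meat quality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models, parameter choices
and limitations. It states no empirical result beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## The problem

Meat-quality traits in crossbred beef cattle — instrumental tenderness
(Warner–Bratzler shear force, WBSF), marbling, cooking loss and sensory-panel
scores — are moderately heritable, mutually correlated, and strongly
confounded with breed composition in an admixed Angus–Brahman population.
A credible association study in such a population must (i) control the
polygenic/structure confounding with a kinship mixed model, (ii) set
multiplicity thresholds that respect the heavy local LD of a dense chip,
and (iii) move from single-marker hits to gene-level statements: which genes
carry several independent signals, which pathways are over-represented among
the genes expressed in the target tissue, and whether a cluster of hits is
one QTL or several.

## The mixed model

For each trait, after preprocessing,

y = Xb + u + e,  u ~ N(0, σ²ₐ G),  e ~ N(0, σ²ₑ I)

with X holding an intercept and the year of birth (categorical; breed
composition is deliberately *not* a fixed covariate by default — the GRM
absorbs it, and a fixed-effect version can be added via `covariates=`).
G is the VanRaden method-1 genomic relationship matrix computed from
QC-passing, mean-imputed dosages. REML estimation exploits the one-time
spectral decomposition of G: profiling σ²ₑ out leaves a one-dimensional
restricted likelihood in λ = σ²ₐ/σ²ₑ, optimized on the log scale over
[1e-5, 1e5] with `stats::optimize` (golden-section search with parabolic
refinement — bounded, derivative-free, reproducible). Negative eigenvalues
from rank-deficient G are clipped at zero; a boundary optimum is flagged,
not fatal.

The scan holds σ²ₐG + σ²ₑI fixed at the null-model estimate and tests each
marker by generalized least squares (the standard one-variance-fit
approximation): after rotating by the eigenvectors and whitening by
(λdᵢ+1)^{-1/2}, each marker is an OLS slope with a 1-df Wald chi-square.
At λ = 0 the scan *is* OLS, which the tests exploit as an exact oracle.
Exact per-marker REML refitting is available behind `per_snp_reml = TRUE`;
it is slower and changes p-values only marginally at these sample sizes.
The residual variance factor is re-estimated per marker with n − p − 1
degrees of freedom, which keeps the null raw-association rate at 5% (the
acceptance suite checks 0.05 ± 0.01 under a polygenic null).

Joint multi-SNP models reuse the same whitened regression with all of a
gene's pruned SNPs entered simultaneously; backward elimination removes the
least significant SNP while any Wald p exceeds α = 0.05, with ties broken by
larger p then larger input index so the trace is deterministic. Aliased
(collinear) SNPs are removed first. Conditional scans append the
conditioning SNP's dosage to X and re-estimate the variance components under
that null.

## Phenotype preprocessing

WBSF is analyzed on the natural-log scale (it is a positive, right-skewed
load in kg). Marbling and connective tissue get a Johnson-family
normalization: the SU family is fitted by Slifker–Shapiro quantile matching
(selection deviate z = 0.524); when the quantile geometry indicates a
bounded or lognormal shape (m·n/p² ≤ 1) or degenerate parameters, the
deterministic rank-based inverse-normal transform (Blom offsets) is used
instead. Both are strictly monotone, so raw "p ≤ 0.05" membership is
transform-stable for rank-based checks, and scan p-values are invariant to
affine rescaling of the trait (a tested property). The original tool used
for this normalization is closed-source; the quantile-matching SU fit with
an inverse-normal fallback is this package's documented equivalent.

## Multiple testing

The effective number of independent tests follows the simpleM recipe:
within consecutive windows of 133 SNPs per chromosome (the published
block-processing default; configurable), the Pearson correlation matrix of
mean-imputed dosages — the composite-LD estimate appropriate for unphased
data — is eigendecomposed, eigenvalues are clipped at zero, and the window's
M_eff is the smallest k whose leading eigenvalues reach C = 0.995 of the
total variance. The genome-wide threshold is 0.05 / ΣM_eff, and BH
adjustment uses m = M_eff rather than the marker count. Tier labels are
per trait: the arbitrary secondary threshold 1e-4 is only reported for a
trait in which no marker reaches genome-wide significance. For very small
panels 0.05/M_eff can exceed 1e-4; the secondary tier then collapses onto
the genome-wide one rather than violating the tier ordering.

## From SNPs to genes, pathways and networks

Raw associated SNPs (p ≤ 0.05, inclusive) map to genes within a symmetric,
strand-agnostic 3 kb flank; a SNP may map to several overlapping genes.
Within each gene and trait, greedy pruning keeps the most significant SNPs
that are mutually uncorrelated at dosage r² ≤ 0.3 (p-ties broken by genomic
position, then ID). The r² here is squared Pearson correlation of genotype
dosages: correlation of *p-values* is not a meaningful pruning notion for
"independent signals within a gene", and r² cannot be negative, so a
threshold stated as "± 0.3" is read as 0.3 on r².

The trait's gene list contains each background-expressed gene once per kept
SNP. This multiplicity enters the hypergeometric test's list count n and
annotated-in-list count k, while the background population N and the
per-term background count K count unique genes — only the study list is
multiplicity-expanded, never the universe. Because a repeated gene can push
k past the hypergeometric support, k is capped at min(n, K). The
over-representation tail P(X ≥ k) is the default and the reported p; the
under-representation tail is emitted alongside (`tail = "both"`) because
sparse list/term intersections can be informative in either direction, and
a `unique_genes` switch collapses multiplicity entirely. Terms annotating
fewer than 2 background genes are not tested (singletons only inflate m).
BH adjustment is per trait with m = number of tested terms. The cross-trait
overlap summary reports terms passing p_raw ≤ 0.05 in ≥ 2 traits by default
— a descriptive view; switch to adjusted p with `use_adjusted`.

The gene–trait network sets w[g, t] to the kept-SNP count; gene connectivity
is the row sum (a trait-count alternative is available via `top_genes(by =
"traits")`). Trait–trait edges carry pairwise-complete Pearson correlations
of the analysis-scale phenotypes, since the sensory traits are observed on a
subset. The top-5 genes by connectivity are forwarded to joint models for
every trait with w ≥ 2, and the 5th/6th connectivity ratio is reported as a
descriptive gap statistic.

## LD blocks

Pairwise LD from unphased genotypes uses the two-locus EM: every genotype
class except the double heterozygote contributes known haplotypes, and the
double heterozygote's cis/trans split is iterated to convergence (tolerance
1e-8 on haplotype frequencies; the EM log-likelihood is non-decreasing, a
tested invariant). Confidence bounds on |D′| evaluate the multinomial
likelihood of the EM-expected haplotype counts on a 1001-point |D′| grid at
fixed allele margins and take the 5%/95% points of the normalized mass
(Wall–Pritchard style, the standard unphased-data approximation). Blocks
follow the Gabriel rule as implemented in Haploview: a pair is strong LD if
ci_low ≥ 0.70 and ci_high ≥ 0.98, shows strong recombination evidence if
ci_high < 0.90, and a candidate run is accepted when its outermost pair is
strong and ≥ 95% of its informative pairs are strong; overlapping candidates
resolve longest-first. The "minimum 98%" strong-LD bound is the only
non-default in that rule set; all four cut-offs are arguments.

## The synthetic data generator

The generator is the package's study population. Design and defaults:

- **Genome**: 3,000 SNPs in blocks of exactly 10 on 3 chromosomes. Constant
  block length keeps generating boundaries known to the block-detection
  tests. SNP spacing 1 kb; 4 kb gaps between blocks inside a gene, 20 kb
  between genes, so the 3 kb assignment flank is unambiguous.
- **LD**: per block, founder haplotypes arise from an infinite-sites
  genealogy (each SNP mutates exactly once), so every within-block pair
  satisfies the four-gamete condition — |D′| = 1, as in recombination-free
  haplotype blocks. Each founder population (Angus, Brahman) samples 4 pool
  haplotypes with Balding–Nichols-style Dirichlet weights at Fst 0.15; pool
  size controls within-block r² (pool size 2 forces |r| = 1). Gametes pick a
  population by the group's admixture proportion (0.9, 0.72, 0.625, 0.5,
  0.3, 0.1 Angus across the six groups) and recombine freely at block
  boundaries, so between-block LD is admixture background only.
- **Traits**: on a unit-variance latent scale, y = year effect + QTL effects
  + polygenic value + residual. Polygenic values are drawn from the realized
  GRM (rescaled to mean diagonal 1) with heritabilities 0.50/0.47/0.17 for
  marbling/tenderness/WBSF — the published estimates for this population —
  and 0.30/0.25/0.25/0.10 for cooking loss, juiciness, connective tissue and
  flavor, values chosen once from the beef-cattle literature range since no
  population-specific estimates exist. The polygenic correlation matrix is
  identity except rg(WBSF, tenderness) = −0.97; a −0.40 residual correlation
  between the same pair mimics shared steak handling.
- **QTLs**: three planted genes, each spanning 3 LD blocks, each carrying 3
  causal SNPs (one per block, the most common SNP of the block) acting
  pleiotropically on marbling, cooking loss and juiciness at 5% of
  phenotypic variance per gene–trait pair. Planting QTLs off WBSF/tenderness
  keeps their realized genetic correlation at the configured −0.97 (QTL
  variance specific to one trait of the pair would dilute it). The
  multi-trait, multi-block pattern is exactly what the connectivity ranking
  and joint models are meant to flag.
- **Observed scales**: WBSF is emitted as six core peak loads averaging to a
  lognormal with mean 4.30 kg and SD 1.15; marbling as a rounded lognormal
  score with mean 425.6 and SD 90.0 clamped to 100–999; cooking loss via
  thaw/cooked weights reproducing mean 23.25%, SD 5.74; sensory traits as
  means of 9 panelists' integer scores on 1–8 scales (tenderness 5.28 ± 0.84,
  juiciness 5.01 ± 0.76, connective tissue 5.81 ± 0.83, flavor 5.56 ± 0.46),
  recorded for a random 495-animal subset.
- **Annotation**: 100 genes tile the blocks (planted genes get 3 blocks,
  others 1, separated by intergenic blocks); a 60-term GO vocabulary with
  1 + Poisson(2) random terms per gene; the planted term annotates every
  causal gene plus 8% of the rest — a realistically sized pathway. With a
  much smaller planted pathway the term saturates (every carrier is in the
  list, k = K) and chance terms sharing two causal genes can outrank it;
  with a much larger one the signal dilutes. The tissue background holds all
  causal genes plus 90% of the others.

What the generator does *not* emulate: realistic bovine demography or map
distances, genotyping error, family pedigree structure (the LD population's
196 families appear only as a sample size), selection, dominance or
epistasis, GO-graph structure (no term propagation), or gene-length biases.
Consequently, passing tests demonstrate that the statistical machinery
recovers the structures it targets under its own assumptions — not that it
is robust to, e.g., cryptic relatedness beyond admixture or annotation
biases in real data.

## Numerical choices and degenerate inputs

- REML: eigenvalues clipped at 0; λ at the lower search bound is reported as
  σ²ₐ = 0; design matrices are reduced to full column rank by pivoted QR.
- Scan: markers collinear with the covariates (whitened residual sum of
  squares ≤ 10⁻¹⁰ n) get NA p with reason "collinear"; p-values are floored
  at the smallest positive double so they stay in (0, 1].
- M_eff: single-variant windows contribute 1 without decomposition;
  monomorphic variants are a QC error, not silently tolerated.
- EM: non-convergence at 1,000 iterations is flagged, with the last iterate
  returned; zero-variance margins are errors at the CI stage.
- Pruning: zero-variance dosage columns correlate with nothing and are kept
  as "uncorrelated by convention" (they cannot occur after QC).
- Hypergeometric: multiplicity-capped k (see above); inconsistent counts
  error out rather than returning NaN.

## Problem sizes in the shipped analyses

The numbered analysis scripts and the acceptance machinery run at the study
scale — 672 animals, a 3,000-SNP panel (the 221k-marker chip scaled down
while keeping ~10-SNP LD blocks), 20 replicates for heritability recovery,
10 for the end-to-end and block-recovery checks, 5 for null calibration.
These sizes were chosen so a full run completes in minutes on one CPU while
keeping the Monte Carlo error of each checked quantity well inside its
stated tolerance.

## Known limitations

- The one-variance-fit scan slightly misestimates per-marker variance for
  markers of large effect (the usual EMMAX caveat); the joint models inherit
  the same approximation.
- Heritability estimates for the sensory traits are attenuated relative to
  their latent-scale generating values by panel-score rounding/clamping and
  the 495-animal subset; the acceptance targets therefore use marbling and
  WBSF, which are free of that attenuation.
- The Johnson SU fit uses four quantiles only; heavy-tailed data with n in
  the low hundreds can fall back to the inverse-normal transform.
- Enrichment treats GO terms as flat sets; genes annotated only to parents
  of the planted term contribute nothing.
- D′ confidence bounds treat EM-expected haplotype counts as observed
  (the standard Haploview approximation); with many double heterozygotes the
  bounds are slightly anti-conservative.
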