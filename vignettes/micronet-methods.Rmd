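---
title: "micronet: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{micronet: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

micronet links a latent micronutrient phenotype to genetic variation through
a metabolic/protein-interaction network. This vignette documents the models
behind each stage, the tunable parameters and why their defaults are what
they are, what the synthetic-cohort generator does and does not emulate, and
the numerical choices that a maintainer would otherwise have to reverse
engineer from the code.

## The analysis in one paragraph

Repeated metabolite assessments are averaged per subject and summarized by
principal component analysis; the first component (met_PC1) is the
quantitative phenotype. Genotypes pass four quality-control filters, then
each surviving SNP is tested against met_PC1 with a generalized estimating
equation that respects sibling clustering. Nominal SNP p-values are
aggregated to gene level with a Monte-Carlo null that respects local linkage
disequilibrium. The gene interaction network is reduced to its largest
connected component and partitioned into topological modules by spin-glass
simulated annealing. Modules are tested for hypergeometric
overrepresentation of (a) the significant genes and (b) a curated
micronutrient-neighborhood gene list; a module significant in both is a
"micronutrient system". Significant genes are also tested against QTL-window
gene sets, and plasma proteins are screened against met_PC1 by robust
regression.

## Latent metabolite phenotype

`average_assessments()` takes per-subject means over however many
assessments are available (the generator produces three). `compute_met_pc()`
z-scores the metabolite columns before the eigendecomposition: the panel
mixes assay units (plasma vitamins, erythrocyte SAM/SAH ratio, homocysteine)
whose variances are incommensurable, so covariance-scale PCA would let the
most variable assay dominate. Subjects with any missing metabolite are
excluded rather than imputed; at the cohort sizes this package targets
(tens to low hundreds), imputation would inject structure the downstream
association tests could not distinguish from signal.

The sign of a principal component is arbitrary, so component 1 is anchored:
the loading of a named anchor metabolite (default vitamin E) is forced
non-negative, making "high met_PC1" mean "higher vitamin E, thiamine,
pyridoxal" under the generator's default loadings. The SAM/SAH ratio enters
as a single column, not two.

## Genotype quality control

Four filters run in a fixed order, and the QC report attributes each removed
SNP to the first filter that removed it, so removal counts plus survivors
always partition the input:

1. **Call quality** (default threshold 0.7): a SNP is removed when *any*
   present call falls below the threshold. A mean-quality mode is available;
   the any-call rule is the default because the next filter already demands
   complete genotyping, so a single unreliable call is disqualifying.
2. **Completeness**: any missing call removes the SNP.
3. **Minor allele frequency** < 0.1, computed after completeness so every
   SNP has the same denominator.
4. **Hardy-Weinberg**: the exact conditional test (probability of
   heterozygote counts at most as probable as the observed one, given the
   allele counts), not the chi-square approximation — the intended cohorts
   are far too small for the asymptotic test. The significance level is not
   something the QC literature fixes; the default is 0.001, configurable.

## Per-SNP association

`fit_gee_snp()` is a Gaussian GEE with identity link and independence
working correlation: the point estimate is exactly ordinary least squares of
met_PC1 on minor-allele count plus age, sex and diet-quality score, and the
uncertainty comes from the cluster-robust sandwich over sibling clusters.
Additive (0/1/2) coding is the default; a genotype-class (2-df) mode exists
for the common display of per-genotype boxplots.

Small-sample inference is the one place the package departs from the
textbook GEE recipe. With ~100 clusters of size 1-3, the unadjusted
sandwich z-test is measurably anti-conservative: the package's own
calibration test (1,000 null SNPs, n = 200, family random effect) puts its
type-I error near 0.065-0.07 at nominal 0.05. `fit_gee_snp()` therefore
applies the standard CR1 adjustment — the meat is scaled by
G/(G-1) x (n-1)/(n-k) — and refers the Wald statistic to t with G-1 degrees
of freedom (F(q, G-1) for the 2-df coding). The same calibration test then
measures ~0.057, inside the acceptance band. With singleton clusters this
reduces to a heteroskedasticity-robust t-test; below two clusters the code
falls back to the model-based covariance with a warning. BH correction is
applied over all tested SNPs (NA results excluded from the family size).

## Gene-level aggregation

The gene statistic is `sum(qchisq(1 - p, df = 1))` over the member SNPs'
nominal p-values. Membership is positional: a SNP belongs to every gene
whose interval, extended by a flank (default 50 kb per side, the gene-based
testing convention; 0 restricts to gene bodies), contains it. The null
distribution is simulated as `colSums(Z^2)` with `Z ~ MVN(0, R)`, where R is
the Pearson correlation of minor-allele counts estimated from the study
genotypes themselves — matching the in-cohort design rather than a reference
panel. R is repaired to positive semidefinite by clipping eigenvalues at
1e-8 and rescaling the diagonal to 1, then Cholesky-factorized with a 1e-10
ridge for numerical safety.

The Monte-Carlo p uses the add-one estimator `(1 + exceedances) / (1 + n)`,
so p is never zero and is floored at `1/(n+1)`. The schedule is adaptive:
stages (package default 1e3 → 1e4 → 1e6) escalate while the running estimate
is below `10 / n`, so only promising genes pay for precision. The pipeline
default caps the schedule at 1e5: at the default network size (≈1,000 genes)
a floor of 1e-5 resolves BH significance at q < 0.1 with two orders of
margin, and the cap keeps a full run interactive. Simulation happens in
200,000-row slabs to bound memory. BH runs over all genes with at least one
tested SNP; genes reaching q < 0.1 are the "significant genes".

## Network modules

The interaction network is undirected and unweighted; loading deduplicates
edges and drops self-loops. All module analyses operate on the largest
connected component (size ties broken toward the component containing the
lexicographically smallest gene id, for determinism).

`spinglass_partition()` minimizes the spin-glass Hamiltonian

H(σ) = − Σ_{i<j} (A_ij − γ k_i k_j / 2m) δ(σ_i, σ_j)

by single-node-move simulated annealing (Rcpp kernel) with geometric
cooling. At γ = 1 this is equivalent to maximizing Newman-Girvan modularity
up to a partition-independent constant, which the test suite asserts.
Defaults: 100 spin states (an upper bound on module count, not a target —
empty states are dropped and modules relabeled by decreasing size), starting
temperature chosen from the mean |ΔH| of 200 random proposals so initial
acceptance is near one half, cooling factor 0.99 per sweep, stop when a full
sweep below T = 0.01 accepts no energy-changing move, then a deterministic
greedy polish until no single-node move improves H. Zero-cost shuffles are
accepted during annealing (they help exploration) but do not count as
progress, so cooling terminates. Five independently seeded restarts are run
and the minimum-H configuration kept. The module count is data-dependent
output — the partitioner makes no attempt to hit any particular number.

## Enrichment

All overrepresentation tests are exact upper-tail hypergeometric
probabilities, `P(X ≥ k)`. The universe for module tests is the LCC node
set, because the modules partition exactly that set; a "genes with at least
one tested SNP" universe is available. BH families are per analysis —
the modules for the met_PC1 test, the modules again (separately) for the
neighborhood test, the QTL phenotypes for the QTL test — and are never
pooled. Thresholds: q < 0.1 for module enrichment, q < 0.15 for QTL
phenotypes. A module significant in both module analyses is flagged a
micronutrient system.

QTL gene sets contain every gene whose interval intersects a phenotype's
QTL interval expanded by 1 Mbp on both sides; genes hit by several windows
of the same phenotype count once. On disk, gene and QTL intervals are BED
(0-based half-open); internally everything is 1-based inclusive, and the
conversion is tested explicitly.

## Protein screen

Each protein is regressed on met_PC1 by Huber M-estimation (tuning 1.345,
MAD scale, IRLS to 1e-8, 200-iteration guard) — aptamer panels are
heavy-tailed, and a bisquare option exists. Abundances are log2-transformed
by default. "Corrected p < 0.1" is implemented as BH q < 0.1. Significant
proteins are clustered by average linkage on correlation distance (1 − r);
the two top-level branches are reported, with each branch's plasma/membrane
fraction when a location annotation is supplied. No covariate adjustment is
applied: the screen is deliberately the bivariate association.

## The synthetic-cohort generator

The generator exists so that every stage is testable against planted truth.
What it emulates, and the defaults (chosen once, before any results were
inspected):

- **Cohort**: 200 subjects in 100 sibling clusters of sizes 1-3. Age 6-14
  years, a 0/1 sex, and a diet-quality index ~ N(55, 12) truncated to
  (10, 95).
- **Genotypes**: 5,000 SNPs in 10-SNP LD blocks. Haplotypes come from an
  equicorrelated Gaussian copula (latent r = 0.8) thresholded at allele
  frequencies drawn U(0.1, 0.5); each family has four parental haplotypes
  per block and each child inherits one maternal and one paternal haplotype
  independently per block, so siblings share each parental haplotype with
  probability 1/2 per block. Minor-allele orientation happens after
  simulation (ties at 0.5 keep the alternate allele minor) so the QC path is
  exercised. Per-call quality is U(0.7, 1) except a 0.001 fraction at
  U(0, 0.7); 0.001 of calls are missing — consistent with the >98% array
  call rates the QC stage is designed around.
- **Genome/network layout**: 1,000 genes, 20 kb bodies at 200 kb spacing on
  one chromosome (so 50 kb flanks never bridge neighbouring genes), assigned
  to 10 modules in contiguous genomic runs. Contiguity emulates the genomic
  clustering of functionally related genes, and keeps LD between
  neighbouring genes mostly within one module — the regime the planted
  power design assumes. The graph is a stochastic block model
  (p_in = 0.08, p_out = 0.004).
- **Phenotype**: 12 causal genes in module 3, each contributing its 5 SNPs
  at 0.5 SD per minor allele; the latent factor adds small age and sex
  effects plus unit noise and is standardized. Eight metabolites load on it
  with signs mirroring the reported pattern (vitamin E, thiamine, pyridoxal
  positive; vitamin A, homocysteine, SAM/SAH negative; vitamin D and
  riboflavin weak) and noise SD 0.8, a combination whose a-priori PC1 share
  is ≈ 0.4. Three assessments per subject add noise at 0.3 x the
  metabolite SD.
- **Proteins**: 1,000 analytes, 50 carrying 0.8 x latent on the log2 scale,
  all with t(3) noise (heavy tails are what the robust screen is for);
  stored abundances are 2^log2.
- **Neighborhood and QTL**: a 60-gene neighborhood list with 60% inside the
  causal module; 36 QTL phenotypes, one planted with windows near 80% of
  the causal genes, the rest random.

All randomness flows from one root seed: stage s uses
`(seed + 104729 * s) mod (2^31 - 1)` (`substream_seed()`), so changing the
number of draws in one stage never perturbs another, and a fixed seed gives
byte-identical output.

What the generator does **not** emulate: realistic human LD maps or
recombination hotspots, ancestry/admixture structure, imputation artifacts,
genotyping batch effects, assay drift between assessments, or scale-free
degree structure in the interaction network. Passing tests on synthetic data
therefore demonstrate that the machinery is correct and calibrated under the
stated statistical structure — not that any particular biological finding on
real data would replicate.

## Problem sizes used by the tests and acceptance script

The acceptance script runs one end-to-end study at the full generator
defaults (200 x 5,000, 1,000-gene network, 1,000 proteins, 36 QTL
phenotypes), which takes well under a minute. The test suite uses the full
defaults where the property demands them (end-to-end dual-enrichment and
recovery checks across 10 seeds) and smaller instances — 60-150 subjects,
100-1,000 SNPs, 30-200-gene networks — for unit-level properties, where the
quantities being checked (exact equalities, closed forms, calibration bands)
do not depend on scale. Monte-Carlo checks state their tolerance as
multiples of the binomial standard error at the simulation size used.

## Known limitations

- The GEE inference is cluster-robust but still asymptotic in the number of
  clusters; below ~30 clusters the CR1/t correction is a mitigation, not a
  cure, and a wild cluster bootstrap would be the next step.
- In-cohort LD estimates for very small cohorts are noisy; the PSD repair
  keeps the simulation valid but cannot recover information that is not
  there.
- The spin-glass optimizer is stochastic; with a fixed seed it is exactly
  reproducible, but different seeds can split or merge borderline modules
  (the suite checks cross-seed agreement at ARI ≥ 0.8 on block-model
  fixtures, not identity).
- Gene membership is purely positional; a SNP in two flanked genes counts
  in both, and no attempt is made to apportion it.
- The protein screen models a single phenotype with no covariates, by
  design; confounding by age or sex is not addressed there.
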