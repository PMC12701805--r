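---
title: "Models and methods in pleioscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in pleioscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`pleioscan` chains the statistical machinery of an integrative
quantitative-genetics study — mixed-model GWAS, multi-trait meta-analysis,
haplotype-based selection scans, cis-eQTL mapping, TWAS, colocalization,
SMR, annotation enrichment, and methylome feature calling — and ships a
synthetic-cohort generator with a ground-truth manifest so the whole chain
is testable without external data. This vignette explains the models, the
parameters that matter, the numerical choices, and what the synthetic
design does and does not establish about real data.

## The synthetic cohort

`simulate_cohort()` builds a diploid cohort from a founder haplotype pool.
Founder alleles follow a first-order Markov chain along each chromosome: the
allele at a site copies the founder's previous allele with probability
`exp(-d / ld_scale_bp)` (default 25 kb) and is otherwise a fresh draw at the
site's base frequency. Individuals are recombinant mosaics of founder draws
with a per-bp switch probability (`recomb_rate_per_bp`, default 2e-8,
roughly the 1 cM/Mb scale of livestock genomes). This gives tunable LD decay
and long shared haplotypes without a coalescent dependency. The founder pool
defaults to 120 haplotypes: extended-haplotype homozygosity among carriers
of an allele at frequency q plateaus near 1/(H·q), and the pool must be
large enough for that plateau to fall below the EHH integration cutoff
(0.05) at mid frequencies, or no core would ever finish integrating.

The partial sweep is planted by choosing the low-frequency variant nearest
the configured core position, assigning its derived allele to one founder,
and giving a calibrated fraction of haplotypes that founder's alleles over a
tract around the core with exponentially distributed one-sided lengths
(mean `half_width_bp`, default 200 kb). Exponential tract lengths mimic the
decaying shared-haplotype lengths of a recent sweep and — unlike copying a
fixed interval — keep distal variants polymorphic, which is what gives iHS
its contrast. The realized core frequency is binomial around the target.

Traits follow y = Σ x_k β_k + ε per trait, with effects for a shared
pleiotropic causal block (default 3 causal variants, the first given the
largest same-sign effect across traits) and a polygenic background (default
50 variants), drawn with cross-trait correlation `trait_corr` (default
exchangeable 0.4 over 5 traits). The genetic component is rescaled so each
trait's Var(g)/Var(total) equals `trait_h2` (default 0.4), then categorical
farm and sex effects are added and recorded. When `mechanism_gene = TRUE`
the strongest block variant is also the planted cis-eQTL (|log2 effect| = 1)
of its nearest gene, creating a complete variant → expression → multi-trait
chain for end-to-end recovery checks.

Expression is generated on the log2(TPM+1) scale — baseline + eQTL effect ×
dosage + hidden-factor term + Gaussian noise (sd 0.5) — and back-transformed
with the same pseudocount the aFC estimator uses. The methylome is a random
genome with planted CpG-dense islands whose CpGs are hypomethylated
(beta-distributed levels, mean 0.05 in islands vs 0.85 background, binomial
counts at Poisson coverage, mean 20×).

What the generator does *not* emulate: realistic demography or coalescent
genealogies, genotyping error, allele-frequency spectra skewed toward rare
variants, trans-regulation, cell-type mixture in expression, or non-CpG
methylation. Passing tests therefore demonstrate correctness of the
statistical machinery under a known generative model, not robustness to
every artifact of real data.

## Association stages

The GRM follows the standard allele-frequency-standardized form
K = (1/m) Σ (x−2p)(x−2p)′/(2p(1−p)). REML for the single-component model
rotates phenotype and covariates by the eigenvectors of K and maximizes the
restricted likelihood in log λ (λ = σ²ₐ/σ²ₑ) by bracketed scalar
optimization on [−12, 12]; the λ → 0 boundary is always evaluated and
reported with a flag when it wins, and a GRM with no eigenvalue spread
(e.g. K = I) is flagged unidentifiable rather than fitted. The scan reuses
the null-model variance components for every variant (the MLMA convention),
making the scan a single rotation plus per-variant weighted regressions.
Leave-one-chromosome-out GRMs are not the default; the conditional analysis
appends the target variant's dosage to the covariates and refuses collinear
targets by name.

The multi-trait statistic refers t′V⁻¹t to χ² with df = n_traits. V is the
Pearson correlation of signed t-values over all variants (an option
restricts to |t| < 2 variants, since shared true signals can inflate V).
Near-singular V (condition number above 1e6) is shrunk linearly toward the
identity with weight 0.05; a fixed V can be supplied, which is how the
identity-reduction checks are expressed. Significance uses Bonferroni
0.05/M over the variants tested.

Gene-based tests operate on gene-body ± 50 kb windows with LD taken from
the analysis cohort itself. SNP-wise Mean sums 1-df quantile transforms of
the member p-values and calibrates against Σλχ²₁ by Satterthwaite moment
matching (exact when all λ = 1); eigenvalues are clipped at zero. SNP-wise
Top uses seeded Monte-Carlo MVN draws through a PSD-safe eigen factor of R,
with the (1+k)/(B+1) estimator and its 1/(B+1) floor. The two models are
combined by Bonferroni (aggregated p = min(1, 2·min)), a deliberately
transparent and conservative stand-in for aggregation rules that published
tools do not document; the genome-wide threshold is 0.05/n_genes.

## Sweep scan

EHH among the carriers of a core allele is the probability that two random
carriers are identical at every marker between the core and the query
marker, computed by incremental group refinement (Σ C(n_h,2)/C(n,2)). iHH
integrates EHH over physical distance by the trapezoid rule outward in both
directions until EHH < 0.05; cores are skipped — not truncated — when a gap
exceeds 800 kb or the chromosome ends first. The walk is compiled (Rcpp),
as the field's EHH implementations are, and the R-level `ehh()` is kept as
an oracle-checkable reference. Standardization z-scores uniHS within 100
equal-width derived-allele-frequency bins, merging bins with fewer than two
scores into their nearest occupied neighbor so the procedure is
deterministic. Candidate windows are the top 1% (floor of 0.01 × windows
with ≥1 scored SNP, ranked with first-tie-wins) of non-overlapping 50-kb
tiles by mean |iHS| that also hold strictly more than 10 SNPs; the top-1%
cut is applied before the SNP-count filter. Window-based top-percent rules
presume a genome with many windows; the replicate tests use 10-Mb
chromosomes (~400 windows) for exactly this reason.

## cis-eQTL mapping

Genes pass the expression filter with TPM ≥ 0.1 in ≥ 20% of samples (both
boundaries inclusive). Normalization quantile-normalizes sample columns to
a common distribution and then inverse-normal transforms each gene with the
Blom offset (rank − 3/8)/(n + 1/4), average ranks on ties. Quantile
normalization can itself introduce cross-sample ties, so the marginals are
exact normal scores only in the tie-free case; the tests assert exactness
there and closeness after quantile normalization. Hidden covariates are the
top principal components of the sample × gene matrix (deterministic sign
convention; default 10, following the observation that factor-model
covariates plateau around ten in muscle-scale data), plus two genotype PCs.

The nominal scan residualizes expression and dosage on the covariates and
tests the slope with df = n − 2 − n_covariates inside a 1-Mb TSS window.
The permutation pass permutes the residualized phenotype (re-residualizing
each draw), records per-permutation minimum p, fits Beta(a,b) by
Nelder-Mead maximum likelihood with a method-of-moments fallback, and
reports both the beta-interpolated empirical p and the direct count
estimator. A fixed 1000 permutations replaces adaptive schedules for
determinism; the beta approximation supplies resolution below 1/1001.
eGenes are called by Benjamini-Hochberg at FDR ≤ 0.05 on the empirical
p-values; the largest significant empirical p becomes the global cutoff and
each gene's nominal threshold is its beta quantile at that cutoff.
Independent signals come from forward conditioning with a backward
refinement pass, stopping at the per-gene threshold. aFC is the
linear-scale estimator log2(1 + 2β/μ), capped at log2(100) ≈ 6.64 and
flagged undefined when the reference-homozygote mean is non-positive. π1
estimates π0 on the λ grid 0.05…0.95 with a df-3 smoothing spline
extrapolated to λ → 1.

## TWAS

Genes are screened by cis-variant REML heritability with a likelihood-ratio
test against σ²ₐ = 0 under the ½χ²₀ + ½χ²₁ boundary null (retain h² > 0 and
p ≤ 0.05; at least 10 cis variants required). Weights are trained on
standardized dosages under four models — single best eQTL, ridge with the
BLUP penalty m(1−h²)/h², lasso, and elastic net (mixing 0.5) with inner-CV
penalties — and scored by outer 5-fold cross-validation with seeded fold
assignment. Accuracy is the pooled held-out predictive R²
(1 − SS_res/SS_tot, small-sample adjusted). Predictive R² rather than
squared correlation is a deliberate choice: squared correlation is
non-negative by construction, so a marginal-best-eQTL model would
essentially never be droppable on pure-noise genes, while predictive R²
goes negative exactly when a model predicts worse than the mean — which is
the behavior the drop rule (all models ≤ 0) needs. Association regresses
the trait on predicted expression plus covariates at the individual level
(the synthetic design provides individual data), with BH across genes.

## Colocalization, SMR, enrichment

Colocalization uses Wakefield log-ABFs, ½[log(1−r) + r·z²] with
r = W/(se² + W) and prior sd 0.15 for both quantitative datasets, and
prior-weighted sums over single- and paired-variant configurations
(p1 = p2 = 1e-4, p12 = 1e-5) evaluated with log-sum-exp; PP.H3's
off-diagonal sum is computed by log-space subtraction. The posteriors are
tested against a literal configuration enumeration to 1e-10. SMR uses the
top cis-eQTL as instrument: T = z_g²z_e²/(z_g²+z_e²) on χ²₁, b_xy = β_g/β_e,
BH across genes. HEIDI-style heterogeneity filtering is out of scope.

Enrichment permutes candidate sets against the tested universe within
2%-MAF bins (frequency matching defaults on, since both GWAS hits and
eQTLs are frequency-biased). The two-sided empirical p uses the mid-p tie
convention — ties between permuted and observed deviations carry half
weight — because the overlap statistic is discrete and counting ties as
extreme makes the null visibly super-uniform; mid-p restores calibration
while keeping the 1/(n_perm+1) floor, and a completely degenerate null
(every permutation equal to the observation) reports p = 1. TAD
co-occurrence keeps a conservative one-sided count, rebuilding every pair
at a random gene with a distance-matched variant (±10 kb, doubled on
failure).

## Methylome

CpG islands: 500-bp windows at 100-bp steps, marked at GC ≥ 0.55 and
ObsCpG/ExpCpG ≥ 0.65 with Exp = #C·#G/L (inclusive thresholds, N as
non-GC), merged, then trimmed in 10-bp steps from both ends until the whole
region passes at length ≥ 500 or is discarded. Experimental support demands
≥5 CpGs at coverage strictly above 5 with coverage-weighted methylation
below 0.30 in at least one sample. HMRs come from a two-state beta-binomial
HMM on (methylated, coverage) pairs at ≥10× sites: fixed initialization
(state means 0.1 and 0.8, self-transitions 0.9), Baum-Welch with numerical
emission updates accepted only when they improve the expected complete-data
log-likelihood (a generalized EM step, so the observed log-likelihood is
non-decreasing — asserted in tests), tolerance 1e-4, at most 100
iterations, posterior decoding, and a 10-kb desert rule splitting runs at
larger CpG gaps. Multi-sample tracks merge by interval union; pooling
counts before calling is possible but union is the default.

## Problem sizes and determinism

Default study conditions: 300 individuals, 2 chromosomes × 1500 variants on
5 Mb, 5 traits at h² = 0.4, 60 genes (40% with eQTLs) over 200 expression
samples, 4000 CpGs with 6 planted islands. Sweep-recovery replicates use
150 individuals and 2 × 4000 variants on 10-Mb chromosomes; the end-to-end
demonstration uses 1000 individuals. Every stochastic stage derives its
seed from the master seed and a stage label, so toggling one stage never
shifts another's stream and a config reproduces its bundle byte for byte.

## Known limitations

Single-component REML only (no multi-GRM or dominance); no LOCO default;
COJO-style joint selection is not reproduced (conditioning only);
fine-mapping posteriors (DAP-G-style) are replaced by stepwise conditional
signals; colocalization assumes at most one causal variant per dataset per
region; the sweep scan uses physical distance (no genetic map) and skips —
rather than truncates — undecayed cores; the HMM fixes its initialization
rather than using random restarts, trading global-optimum guarantees for
reproducibility.
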