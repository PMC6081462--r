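---
title: "brainchrom: models, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{brainchrom: models, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical machinery: the
models each stage assumes, the tunable parameters and their defaults,
what the synthetic-data generator does and does not emulate, the
numerical choices, and the known limitations. Nothing here states an
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## What the package is for

Case–control chromatin accessibility studies of postmortem brain tissue
ask four connected questions: which genomic regions are open; whether
openness differs with diagnosis or with biological covariates such as
age at death and postmortem interval (PMI); which common variants alter
local accessibility (cQTLs) and whether they also alter gene expression;
and whether trait heritability concentrates in open chromatin. The
package implements one coherent path through all four, shaped around
fixed-width peaks (300 bp about a summit), a peaks × samples
negative-binomial count matrix, and summary-statistic integration.

Because the real cohort (≈288 DLPFC samples with genotypes) is
controlled-access, all empirical claims made by the tests are claims
about synthetic data with known ground truth. That is the honest scope:
the tests demonstrate that the estimators are calibrated and recover
their generating parameters under the stated model, not that any
particular biological result replicates.

## The synthetic study generator

The generator is first-class, tested code; its defaults are the study
conditions every downstream test inherits.

**Genome.** `simulateGenome()` builds n autosomes plus chrX and chrY
(chrY at half length), a TSS catalogue with expression-quartile labels,
a mappability track (~95% of the genome) and a blacklist (default 2%).
All tracks are merged GRanges within chromosome bounds.

**Genotypes.** `simulateGenotypes()` uses a block-exchangeable
latent-haplotype construction: within each block of consecutive SNPs,
each of the two haplotypes follows an AR(1) latent Gaussian
(autocorrelation 0.9) thresholded at the allele-frequency quantile.
Pairwise r² therefore decays geometrically with intra-block distance and
is ≈0 across blocks. This is deliberately not a coalescent: it is
sufficient to give LD scores and cis windows realistic structure at desk
scale, and it is cheap. Per-SNP MAF is uniform on [0.05, 0.5] by
default.

**Counts.** `simulateCounts()` draws negative-binomial counts with
log mean = peak baseline + per-sample library offset (log-normal,
SD 0.3; `libSizeSD = 0` gives the equal-offset Poisson-limit setting
used by the calibration test) + diagnosis/age/PMI effects + a cQTL
dosage term. Dispersion defaults to 0.2, mean depth to 50 reads per
peak. chrY peaks are male-only: female chrY counts are fixed at zero,
which is what makes the male-only differential route exercisable.
Fragment placements (`simulateFragments()`) put in-peak fragment
midpoints on a triangular density peaking at the summit — the
center-concentrated signal the peak-width heritability experiment needs
— and background fragments uniformly over the mappable track.

**GWAS summary statistics.** `simulateGWAS()` draws per-SNP
standardized effects with variance Σ_c τ_c a_jc and forms marginal
z-scores through the reference panel's LD as z = √N·(R β) + ε, where R
is the panel correlation matrix banded to the LD window and ε = Xᵀu/√(n−1)
has exactly the panel's LD correlation. Two consequences matter and are
assumed by the tests:

* banding the signal term to the window is essential — the sampling
  noise of panel correlations at genome distance (entries of order
  1/√n_ref) would otherwise inflate every χ² by a large constant;
  within the window the same noise is absorbed by the regression
  intercept, exactly as LD-score regression intends;
* ε lives in the panel's n_ref-dimensional column space, so the mean
  χ² over M SNPs fluctuates with effective standard error √(2/n_ref),
  not sd/√M. The null-calibration test uses this SE.

The reference panel for heritability experiments is 288 samples — the
cohort scale of the study design the package emulates.

**Allelic reads.** For every SNP inside a peak, each heterozygote
contributes alt ~ Binomial(depth, p) with logit(p) equal to the cQTL
effect for truth pairs and 0 otherwise. Homozygotes emit no record;
truth SNPs outside any peak are skipped with a counted warning.

**What the generator does not emulate:** sequence content, read-level
error, imputation uncertainty, fine-scale recombination, population
structure beyond exchangeable blocks, cell-type composition, or any
coupling between metadata covariates and counts beyond the explicit
linear terms. Passing tests therefore say nothing about robustness to
those features of real data.

## Peak matrix construction

* **Merging** (`mergePeaks()`): union of per-sample intervals; unions
  with support < 2 samples are dropped; the consensus summit is the
  floor of the median of contributing summits (a tie — an even count
  with a .5 median — rounds to the lower coordinate, a documented
  convention), and each region becomes one 300-bp peak about it.
  Merging is idempotent.
* **Quantification** (`quantifyPeaks()`): fragments are extended to
  300 bp from their start; ≥1 bp overlap counts; intervals are BED
  0-based half-open on disk and GRanges 1-based closed in memory.
* **TMM** (`tmmFactors()`): reference = the sample whose
  75th-percentile count fraction is closest to the mean (overridable);
  trim 30% on M and 5% on A (rank-based, ties kept); inverse
  asymptotic-variance weights (N−y)/(Ny) per sample; factors rescaled
  to geometric mean 1 (enforced by the `ChromAccExperiment` validity
  check at 10⁻⁹). The test suite checks the factors against both a
  brute-force trimmed weighted mean and edgeR's implementation.
* **Shuffle QC** (`shuffleEnrichment()`): shuffled peaks are placed by
  rejection sampling over the cumulative length of the allowed space
  (mappable minus blacklist minus excluded regions), non-overlapping
  with each other. The per-peak enrichment denominator — the median
  shuffled-peak read count — is floored at 0.5 reads so low-depth
  samples keep a defined ratio.
* **Replicate concordance**: the statistic is mean within-pair Spearman
  minus mean between-pair Spearman; the null reassigns pair membership
  across all samples, and a permutation that recreates the observed
  pairing is redrawn, so perfect replicates attain the floor
  1/(1+n_perm).
* **TSS annotation**: distance is peak center to nearest TSS, signed by
  TSS strand (positive = downstream); class boundaries are closed at
  5,000 and 25,000 bp. Only TSS positions exist in the model, so the
  orientation flags are upstream/downstream; a within-gene call would
  need gene extents the layout does not carry.

## Covariate selection

The screen drops invariant variables, >5% missingness, and categoricals
with >30 levels; `diagnosis` and `sex` are protected. Imputation is
median (numeric) or frequency-sampled (categorical) — deliberately
simpler than tree-based imputation, since downstream stages only need
completeness; the substitution is recorded in the selection log.

Selection iterates: PCA of the residualized log₂ CPM matrix (centered,
unscaled, 0.5 pseudocount); each candidate regressed on each of the top
20 PCs; stop when no pair passes Bonferroni α/(n_vars × n_PCs);
otherwise select by (1) assay-technical tag, (2) largest variance
explained on the best PC, (3) fewest parameters, (4) lexicographic —
the last tie-break exists to make selection deterministic and
order-invariant. Whether the original procedure regressed PCs on
variables singly or jointly is not knowable from its description;
separate simple regressions are implemented. A hard cap of 25 iterations
bounds runtime; if, at convergence, a remaining candidate is numerically
in the span of the selected design, the status is `"collinearity"`,
mirroring variables that can never be resolved.

## Differential accessibility

`fitNBPeak()` is an IRLS maximum-likelihood NB GLM at fixed dispersion
(var = μ + αμ²), Wald statistic β/se against a standard normal.
Dispersion (`estimateDispersion()`) is method-of-moments on Poisson
fitted means, floored at 10⁻⁸, shrunk 50/50 toward a lowess
mean–dispersion trend — a fixed-weight simplification of empirical-Bayes
curves, chosen for transparency. Offsets default to
log(lib_size × TMM factor); a DESeq-style median-of-ratios offset is
selectable (`sizeFactor = "median-ratio"`) because the two conventions
genuinely differ and the choice should be visible.

Routing: autosomes use the full model; chrX is fit per sex stratum
(sex dropped within stratum, aliased columns pruned) and combined by
inverse-variance weighting; when one stratum has fewer than 3 samples or
fails to converge, the other is used alone with a warning. chrY is
males-only. BH FDR is applied across each scan; Storey's estimator is
reserved for the cQTL module, matching the provenance of each
correction.

## cQTL mapping

The cis window is anchored at the **peak center** with the boundary
**inclusive** at exactly `window` bp (5 kb default) — the anchoring was
an open choice and is fixed here. Covariates (10 phenotype PCs computed
from the log-normalized matrix before any residualization, plus
ancestry PCs) are residualized out of phenotype and dosage once, not
re-fit per SNP. The phenotype default is log₂ TMM-CPM; a rank-normal
transform is available via `rankNormal()`.

Permutation adjustment fits Beta(a, b) to the per-permutation minimum
nominal p by maximum likelihood: method-of-moments start, Newton steps
on the digamma score equations, tolerance 10⁻⁸, 100 iterations, and a
halving guard against leaving the positive orthant; a degenerate
permutation distribution falls back to the empirical permutation p with
a flag. The effective-degrees-of-freedom refinement that fastQTL applies
to the nominal p is **not** implemented — the Beta fit is applied to the
raw permutation minima — a documented divergence that the
adjusted-vs-empirical envelope test (0.2× to 5×) bounds in practice.
With K independent cis SNPs the null minimum is Beta(1, K), which is the
recovery oracle used in acceptance.

The diagnosis interaction model adds dosage × diagnosis and permutes
diagnosis labels (exact p = (1+#{≥obs})/(1+n_perm), 10,000 permutations
by default). Allelic imbalance uses alt-fraction histograms on bins
0–0.1, …, 0.9–1 (right-closed; the binning was unspecified upstream) and
a Pearson χ² between cQTL and non-cQTL heterozygote records; concordance
is the fraction of cQTL SNPs whose mean alt fraction deviates from 0.5
on the side of the alt-allele effect.

`storeyQvalue()` estimates π0 on λ = 0.05…0.95 (step 0.05) with a cubic
smoothing spline evaluated at the last grid point, clipped to (0, 1];
q = π0 × BH. Below 100 p-values it falls back to π0 = 1 (pure BH) with a
warning; forcing π0 = 1 reproduces `bhFDR()` exactly, which the suite
asserts as a cross-module identity.

## Integration and colocalization

The cQTL–eQTL sharing fraction is π1 = 1 − π0 of the matched eQTL
p-values, with one p kept per gene at random or — to bracket the
estimate — the most or least significant. Direction concordance is an
exact two-sided binomial test against 0.5.

Colocalization uses Wakefield log ABFs with effect-prior SD 0.15 for
quantitative traits and 0.2 for case–control log-odds (the conventional
defaults; the upstream analysis does not print its priors), and priors
p1 = p2 = 10⁻⁴, p12 = 10⁻⁵. All configuration sums are log-sum-exp; the
H3 term is computed as log(S1·S2 − S12) via a guarded log-difference,
since z-scores of GWAS scale overflow linear space. When a trait arrives
as z-scores only, the standardized-trait approximation β = z/√N,
se = 1/√N is applied (N from the data, default 10⁴) — with se pinned at
1 the 0.15² prior would be vacuously small. A 2-SNP exhaustive
enumeration oracle pins the combinatorics to 10⁻¹².

## Partitioned heritability

LD scores use a fixed 1 Mb window (a stand-in for 1 cM — the synthetic
genome has no genetic map), the small-sample adjustment
r²_adj = r² − (1−r²)/(n−2), and include the self term. The regression of
χ² on N·ℓ(j,c) uses one-step heteroskedasticity weights
1/max(ℓ_base, 1) (no iterative reweighting — a documented simplification
of full LDSC weighting), 20 contiguous jackknife blocks at desk scale
(200 would be used at genome scale), coefficient z = τ̂/SE_jack(τ̂), and
an enrichment p from the jackknife-t of (enrichment − 1). The base
category's enrichment is exactly 1 by construction. The full 53-category
baseline is replaced by a small configurable set (base, peak, ±500 bp
companion, optional conserved and GWA-locus columns); the companion
annotation exists to absorb boundary-adjacent signal that would
otherwise bias the focal peak estimate upward, and it is built as the
padded interval minus the peak. The width experiment rebuilds the peak
annotation at 100 bp–10 kb about the summit (clipped at chromosome
bounds, counted) and reuses one streamed LD pass over all widths.

## Pipeline

`runPipeline()` takes a YAML/list config validated before any stage
runs, derives per-stage seeds deterministically from one master seed,
writes TSVs per stage plus a manifest of md5 hashes, and
`pipelineReport()` assembles the cohort association table, significant
counts at 5% FDR, cQTL locality fractions (in own peak; within ±2 kb of
center) and the enrichment table, listing any missing stage instead of
failing. All on-disk coordinates are BED 0-based half-open; 1-based
inclusive coordinates are converted on ingest.

## Problem sizes used by the tests

The suite runs at deliberately small scale, chosen as the smallest sizes
at which each statistical claim is decidable: unit fixtures of tens of
peaks and samples; calibration suites of 200 peaks × 200 samples × 1000
permutations; a 5,000-peak differential scan with 100 injected effects
at n = 50/50; heritability recovery on 20,000 SNPs with a 288-sample
panel and N = 50,000 GWAS draws repeated 100×; a 12,000-SNP width
series. The full-study default (288 × 5,000 × 20,000) runs in minutes
through `runPipeline()`.

## Known limitations

* The NB dispersion shrinkage is fixed-weight, not empirical-Bayes; at
  very low replication the Wald tests can be mildly anticonservative.
* The Beta adjustment omits fastQTL's effective-df refinement of the
  nominal p; for strongly dependent cis SNP sets the adjusted p is an
  approximation whose quality the envelope test only bounds.
* LD scores from a 288-sample panel carry errors-in-variables noise that
  attenuates τ̂ slightly; jackknife coverage in the acceptance suite
  quantifies the net effect rather than correcting it.
* The covariate-count coupling strengths in the generator are free
  parameters — the upstream description does not characterize them — so
  selection-depth results on synthetic data do not predict the number of
  covariates a real cohort needs.
* The sharing estimate π1 inherits the variance of the Storey estimator;
  bracketing with most/least-significant eQTL selection is the intended
  use.
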