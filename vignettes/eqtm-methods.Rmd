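---
title: "Methods: models, parameters and design choices in eqtmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in eqtmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eqtmr)
```

This vignette is the package's account of its statistical machinery: the
models behind each stage, the parameters that matter and their defaults,
what the synthetic cohort generator does and does not emulate, and the
choices made where the design was genuinely open.

## Differential methylation

Each CpG is tested with ordinary least squares of its methylation level on
an intercept, a case/control indicator, and covariates (age in years, sex,
and five of the six blood cell fractions — the six sum to one, so the
granulocyte fraction is the dropped reference to keep the design full
rank). The group coefficient's two-sided *t* test and Benjamini–Hochberg
FDR across CpGs give the DMP calls.

Two response scales are supported. The default is the β scale (methylation
fraction in [0, 1]), which keeps effect sizes directly interpretable as
methylation differences; the M-value scale, M = log₂(β/(1−β)) after
clipping β to [10⁻⁶, 1−10⁻⁶], is available through `design_spec()` and has
better variance homogeneity near the boundaries. Whatever the test scale,
`delta_beta` is always the β-scale adjusted group coefficient so that
hypo/hyper labels stay interpretable.

We use plain OLS rather than empirical-Bayes moderated *t* statistics. At
the cohort sizes this package targets (about sixty samples) the residual
degrees of freedom are large enough that moderation changes little, and
the unmoderated statistic has an exact finite-sample reference
distribution, which the test suite exploits by checking every fit against
a normal-equations oracle.

**Degenerate CpGs.** A CpG with zero residual variance (for example, a
probe stuck at one value) carries no usable *t* statistic. Its p-value and
FDR are set to `NA`, it is excluded from the FDR denominator, and it is
flagged in the `degenerate` column rather than silently dropped.

**Cell-fraction deconvolution.** `estimate_cell_fractions()` projects each
bulk profile over marker CpGs onto reference cell-type profiles by least
squares under *f* ≥ 0 and Σ*f* ≤ 1. With six cell types the constrained
quadratic program is solved exactly by enumerating active sets (at most
2⁷ small KKT systems per sample), which is deterministic and avoids an
iterative solver dependency. The reference panel must have at least as
many markers as cell types and full column rank.

## Region calling and evidence combination

A DMR is a maximal run of consecutively FDR-significant CpGs in which
every adjacent pair lies within `max_gap` = 1000 nt, with at least
`min_cpgs` = 2 members. "Consecutively significant" is read strictly: an
intervening non-significant panel CpG breaks the run, as does a gap above
1000 nt. Kernel-smoothed region statistics (bandwidth-weighted per-CpG
test statistics, as array-centric DMR callers use) are deliberately not
reproduced: the two-CpG/1000-nt criterion is the operative rule here, and
the strict scan is fully auditable — the test suite checks it against an
exhaustive window enumerator on hundreds of random panels.

Region evidence is summarised with Stouffer's method,
Z = Σᵢ Φ⁻¹(1 − pᵢ)/√n. Member p-values enter one-sidedly, oriented by the
sign of each member's `delta_beta` relative to the region's dominant
direction, so members shifting the opposite way *cancel* rather than
reinforce; a region with exactly balanced opposing members has Z = 0.
Mixed-sign regions are retained but flagged. Whether published region
ranks of this kind derive from a kernel-statistic hybrid is not
recoverable in general; the plain Stouffer above is this package's
documented statistic. Member p-values of exactly 0 or 1 are clipped to
10⁻¹⁵ and flagged.

Region coordinates are the first and last member positions, 1-based
inclusive; `dmr_to_bed()` converts to 0-based half-open BED and back.
Duplicate positions are resolved by stable input order and logged.

The two FDR cuts are deliberate: 0.05 for the primary genome-wide scan,
and a relaxed 0.1 for the region set feeding the eQTM stage, where the
subsequent per-pair permutation test provides the error control.

## Expression processing and the differential-expression surrogate

Genes with a non-zero count in at least ⌈0.9·n⌉ samples are kept
(inclusive boundary). Size factors are median-of-ratios over genes
non-zero in every sample, rescaled to geometric mean one, with a
total-count fallback (logged) when no gene qualifies. Expression is
log₂(count/size factor + 1); the pseudocount of 1 keeps zeros at zero.

Differential expression is per-gene OLS on this log scale with the same
covariates as the methylation model — a surrogate for a negative-binomial
analysis with dispersion shrinkage. The simplification is justified by
what the step must deliver in this workflow: at a 12-vs-51 design the
expected outcome is a *null* FDR list, so the surrogate's fidelity
requirement is type-I control, which OLS on log counts provides at these
sample sizes (verified by simulation in the test suite). Users needing
shrinkage-based DE for other purposes should run a dedicated tool; the
eQTM stage only consumes the expression-direction sign.

Whether counts should be normalized before the log transform in the eQTM
correlation is ambiguous in the field; the default here normalizes (so
library size cannot masquerade as a methylation–expression association),
and the raw-count route remains available by passing unnormalized values.

## Co-expression networks

Signed adjacency aᵢⱼ = ((1 + r)/2)^β with β = 6 (the conventional default
for signed networks; no scale-free fit index is computed since β is taken
as given). The signed-hybrid form max(r, 0)^β is available as an option
since "signed network" is used ambiguously in the field's vocabulary.
Topological overlap uses the standard formula with connectivity k = row
sums minus the diagonal.

Module detection is average-linkage hierarchical clustering on 1 − TOM
with a *fixed-height* cut (`cut_height` = 0.95, `min_module_size` = 10),
clusters below the size floor relabelled 0 — the grey/unassigned
convention. This replaces dynamic tree cutting: it is deterministic, has
two transparent parameters, and recovers planted block structure exactly
(Rand index 1.0 in the recovery tests). The price is less adaptivity on
nested or uneven module structures, which is acceptable for this
pipeline's purpose and stated openly.

Module eigengenes are the first principal component of the per-gene
z-scored member submatrix, scaled to unit variance, with sign fixed so the
mean correlation with member profiles is positive (a stated convention;
other tools align to average expression instead). Eigengene–trait
association is a Pearson correlation with the case indicator and a
two-sided *t* reference on n − 2 df. Overrepresentation uses the
hypergeometric upper tail with the network genes as the population, sets
intersected with the background first.

## The cis-eQTM engine

For each region×gene pair the per-sample summary is the *median* β over
member CpGs (midpoint mean for even counts), a robust choice against a
single noisy probe. Its Pearson correlation with the gene's log₂
normalized expression over all samples is the primary statistic — the
combined-cohort correlation, with the per-group correlations reported as
descriptive decomposition only (no group-difference test is performed).

Inference is resampling-based throughout:

* **Bootstrap CI** — samples resampled with replacement as pairs, the
  correlation recomputed per replicate, percentile interval at 2.5/97.5%.
  Default 100,000 replicates. Replicates where a resampled vector is
  constant are redrawn (up to five rounds), then dropped with a warning;
  more than half degenerate is an error.
* **Permutation p** — the expression vector is permuted against the
  methylation vector, which is exact under exchangeability of the pairing,
  and p = (1 + #{|r_perm| ≥ |r_obs|})/(n_perm + 1): the add-one estimator
  never returns zero. Default 10,000 permutations. How a published
  "resampling" null was constructed is often ambiguous (label permutation,
  null bootstrap, or parametric); permutation of the pairing is this
  package's choice because it is the one with an exactness guarantee, and
  the alternative is a one-line swap in the config.

Pairs are significant at unadjusted p < 0.05: the region-level scan
already applied FDR control upstream, and the handful of pairs tested
per run does not warrant a second correction — BH-adjusted q-values are
available via `include_q = TRUE` for users who prefer them.

Multi-gene regions fan out to one record per annotated gene; regions
whose genes were filtered out are preserved in a drop log; intergenic
regions may be matched to the nearest TSS within 100 kb (flagged as such).
Feature labels use a most-specific-first rule — upstream-window or 5′UTR
membership ⇒ Promoter, else first exon ⇒ 1st exon, else body/3′UTR ⇒ Gene
body, else Intergenic — and the expression direction comes from the sign
of the adjusted group effect, falling back to the raw group mean
difference when the adjusted effect is exactly zero, and to the label
`none` on an exact tie (a direction is never asserted from a zero).

## The synthetic cohort generator

`generate_cohort()` draws, per CpG, an M-scale linear model: a trimodal
baseline (hypo/hemi/hyper-methylated compartments), a group shift obtained
by mapping the requested β-scale `delta_beta` through the logit at that
CpG's baseline, an optional cell-composition confound (per-CpG Gaussian
loadings on standardized Dirichlet cell fractions, with a group tilt in
the granulocyte concentration so the confound is correlated with case
status), and Gaussian noise (default SD 0.5 M-units), inverse-logit mapped
back to [0, 1]. Counts are negative binomial with variance μ + φμ²
(default φ = 0.15) around a wide log-normal baseline with a low-expression
tail. For planted eQTM pairs the gene's log₂ mean absorbs the region's
standardized median β with coefficient b = √v·ρ/√(1−ρ²), where v is the
delta-method variance of log₂(count+1) under the NB noise — solved once,
not iterated — so the realized correlation targets ρ; unattainable ρ given
the noise settings is rejected with a diagnostic. The default design is 12
cases vs 51 controls with case ages centred lower than controls, matching
the cohort structure this kind of study reports, at a desk-scale panel of
20,000 CpGs and 2,000 genes.

A single global seed expands into independent per-stream seeds
(demographics, genomic map, methylation, counts), so adding one stream
never perturbs another and identical configs are byte-reproducible.

What the generator does **not** emulate: probe chemistry and array
artefacts (Type I/II design, batch, slide position), the fine bimodal
shape and spatial co-methylation of real arrays, sequencing depth
gradients and gene-length effects in counts, mean–dispersion trends, and
linkage between neighbouring genes. Consequently, passing recovery tests
demonstrate the *statistical* correctness of the pipeline under its
stated model — calibrated error rates, unbiased recovery of planted
effects — not robustness to array- or sequencing-specific artefacts,
which real-data preprocessing must handle upstream.

## Problem sizes and numerical settings

The test and acceptance runs use sizes chosen to make Monte Carlo noise
small relative to the margins being checked while keeping a laptop-scale
footprint: 1000 null datasets for permutation type-I error (n = 63,
999 permutations) and bootstrap coverage (ρ = 0.5, 2000 replicates),
200 generator seeds for eQTM power at ρ = 0.4, 20 seeds at 4000 CpGs for
region-level DMR recovery, and 50 seeds for trait-module detection.
Observed values at these sizes: per-CpG type-I ≈ 0.05, permutation type-I
≈ 0.03–0.06, coverage ≈ 93–94% (percentile intervals for a correlation
run slightly anti-conservative at n = 63; this is a known property of the
percentile method, not an implementation artefact), power ≈ 88%, DMR
sensitivity ≈ 0.96, block recovery Rand index 1.0.

Numerical conventions collected in one place: β clipping at 10⁻⁶ for the
M transform; Stouffer input clipping at 10⁻¹⁵; zero-residual-variance
tests excluded from FDR with `NA`; matrices persisted at full precision
(`%.17g`, round trip lossless to 10⁻¹²); position ties resolved by stable
input order; all resampling seeded and reproducible.

## Known limitations

* The DE stage is a calibration-focused surrogate, not a shrinkage
  estimator; its fold-change estimates are noisy for low counts.
* The fixed-height module cut requires structure with a clear
  between-module dissimilarity gap; nested modules merge or vanish.
* The permutation null tests exchangeability of the pairing, i.e. the
  no-association hypothesis; it does not adjust the eQTM correlation for
  covariates (associations driven by a shared confounder are not
  distinguished — the covariate-adjusted DMR screen upstream is the
  mitigation).
* Group-specific correlations at 12 cases are descriptive; their
  sampling error is large, which is why no case/control difference test
  is offered.
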