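---
title: "Choosing and validating RT-qPCR reference genes with refstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Choosing and validating RT-qPCR reference genes with refstab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refstab)
```

## The problem

Relative quantification by RT-qPCR stands or falls with the reference
(housekeeping) genes used for normalization. A reference gene that itself
shifts between experimental conditions — the classic offenders being *ACTB*
and *GAPDH* during cell differentiation — silently distorts every fold
change computed against it, and can attenuate or even invert a real effect.
refstab implements the standard validation workflow used in livestock and
cell-culture transcriptomics: screen candidates from RNA-seq, measure them
by RT-qPCR across the conditions of interest, score their stability with
several independent algorithms, aggregate the rankings, and demonstrate the
consequences of the choice on target genes. The motivating design is a
muscle-satellite-cell experiment with a proliferation phase (GM) and two
differentiation time points (DM1, DM5), each with three biological and
three technical replicates, but nothing in the package is specific to that
layout.

## Data model and preprocessing

The central container is the `cq_table`: a genes × samples matrix of
quantification cycles (Cq) plus metadata (`sample_id`, `group`, `bio_rep`,
`tech_rep`). Validation is strict — unique gene symbols, Cq in (0, 45],
metadata covering every column — because every downstream algorithm assumes
a complete rectangular panel.

Two preprocessing decisions are built in:

* **Technical replicates are averaged (arithmetic mean on the Cq scale)
  before any stability analysis.** All stability algorithms model one
  observation per biological sample; feeding them wells would overweight
  technical noise and pseudo-replicate the design. Triplicates whose SD
  exceeds 0.5 cycles (configurable) are flagged for QC but not dropped
  automatically.
* **Missing Cq values are a hard error by default.** The optional
  complete-case mode drops an affected sample from *every* gene, never
  imputes: an imputed Cq would enter the pairwise statistics of all genes
  at once and bias them in a correlated way.

Relative quantities use the conventional transformation
`Q = 2^-(Cq - Cq_min)` per gene, so each gene's most abundant sample sits
at Q = 1 exactly. Q is scale-free per gene: adding a constant to a gene's
Cq (a primer-efficiency or threshold offset) leaves Q untouched. Measured
amplification efficiencies are *not* folded into Q; the classical base-2
convention is used throughout, with efficiency fits serving as an assay QC
gate (default acceptance band 90–110%, flag-only).

## The four stability algorithms

**geNorm.** For genes j, k the pairwise variation
`V_jk = SD_s[log2(Q_j(s)/Q_k(s))]` and the stability measure
`M_j = mean_k V_jk`. Stepwise exclusion removes the worst gene (largest M
on the surviving set) until two remain; the last pair cannot be separated
by geNorm (their two-gene M values are equal), so ranks 1–2 are ordered by
full-panel M, ties by gene symbol — the tie rule is recorded in the result
trace. The optimal number of references comes from
`V_{n/n+1} = SD_s[log2(NF_n/NF_{n+1})]`, where `NF_n` is the per-sample
geometric mean of the n most stable genes; the smallest n with
`V_{n/n+1} < 0.15` (strict) is recommended.

**NormFinder-style decomposition.** On `y = log2 Q`, samples are centered
by their per-sample gene mean, which removes loading effects exactly. The
naive within-group variances of centered values are biased
(`E[s²_ig] = σ²_ig (1 − 2/k) + σ̄²_g/k` for k genes, a direct consequence
of the centering); the implementation inverts this relation, clamps
estimates at zero, adds a moment estimator of the intergroup variance, and
shrinks the per-group differences before combining both components into
the stability value ρ (lower = better). The published tool's exact
estimator varies in the third decimal across implementations, so refstab's
guarantees are stated as invariants (exact loading invariance) and
parameter recovery (unbiased intragroup-variance estimates), both enforced
in the test suite, rather than as agreement with any one binary.
With fewer than two groups the pooled SD is used (ungrouped mode).

**BestKeeper.** Descriptive statistics on the *raw Cq scale*: per-gene
mean Cq, dispersion (sample SD by default, mean absolute deviation behind
an option as in the original spreadsheet), CV = 100·SD/mean, and the
Pearson correlation with the BestKeeper index (per-sample geometric mean
Cq). Ranking is by SD with CV and gene symbol as tie-breaks; the
correlation is reported but deliberately kept out of the ranking key —
on published panels the printed order follows SD alone, including pairs
where the CV order would disagree.

**Comparative ΔCt.** The mean over partner genes of
`SD_s(Cq_j − Cq_k)`, ranked ascending. Algebraically this equals the
full-panel geNorm M (Q anchors each gene by a per-gene constant that
cancels in differences), which the tests assert to 1e-9; it is kept as a
separate code path and method because four-method consensus tools treat it
as an independent vote on the raw Cq scale.

## Consensus and validation

Per-method ranks are aggregated by their geometric mean — with m methods,
`(∏ ranks)^(1/m)` — reported at full precision and rounded to two decimals
in outputs. The comprehensive rank is the ascending order of the mean
rank, ties broken by the gene's best single-method rank, then gene symbol.
The arithmetic mean is not offered as a default because rank products, not
sums, are the convention of comprehensive-ranking tools; permutation of
method order provably leaves the result unchanged and the tests check it.

Validation uses `2^-ΔΔCt`: `ΔCt = Cq_target − mean(Cq_refs)` per sample,
referenced to the calibrator group's mean ΔCt. Multi-reference
normalization averages reference Cq arithmetically per sample, equivalent
to the geometric mean of reference quantities on the linear scale. By
construction the calibrator group's *geometric* mean fold change is
exactly 1 (its arithmetic mean exceeds 1 by Jensen's inequality; the
package asserts the exact geometric identity). Group comparison runs a
one-way ANOVA of fold changes with Tukey HSD pairwise labels at 0.05/0.01.
Tukey HSD is used instead of Duncan's multiple range test: it is the
standard familywise-error-controlling choice, and only the qualitative
significance pattern — a real difference visible under a stable
normalizer, masked under an unstable one — is part of the package's
contract.

## The synthetic-data generator

Raw per-well Cq data for published reference-gene studies are rarely
available, so the generator is a first-class module with recorded ground
truth, not a test fixture. Its model is deliberately minimal:

```
Cq[g, well] = base_g + group_effect[g, group(well)] + loading_well + eps
```

with `eps ~ N(0, noise_sd²)` and a loading effect `~ N(0, loading_sd²)`
shared by all genes in a well. Group effects are additive on the Cq scale
(multiplicative on abundance), which is how stage-specific regulation
manifests; the shared loading term is precisely the variation that
reference-gene normalization exists to remove, making the cancellation
invariants exact rather than approximate. Defaults: noise SD 0.15 cycles
(typical technical noise), loading SD 0.3 cycles, baseline Cq uniform in
[15.3, 20.7] — the range reported for abundant transcripts in
muscle-satellite-cell panels.

`simulate_paper_like_panel()` emulates the motivating design: 10 genes ×
3 phases × 3 biological × 3 technical replicates, with eight truly stable
genes, a GAPDH-like gene shifting up to 0.8 cycles and an ACTB-like gene
shifting up to 2.4 cycles across differentiation. What the generator does
*not* emulate: amplification-efficiency differences between genes,
inter-plate effects, heteroscedastic noise at high Cq, or outlier wells.
Passing recovery tests on this panel therefore demonstrates that the
algorithms rank designed instability correctly under realistic noise — not
that any particular real dataset would yield the same gene ordering.

`simulate_fpkm_matrix()` pins each gene's realized sample mean and CV
exactly (by standardizing the drawn shape and rescaling), so the screening
truth — exactly `n_candidates` genes satisfying mean FPKM > 100 and
CV < 10% — is guaranteed rather than probable. The construction stays
positive only while `CV × sqrt(n−1) < 100`, which bounds the violator CVs;
infeasible parameter combinations error out.

## Numerical choices and test scale

* SD uses the n−1 denominator everywhere, matching the conventions of the
  published stability tools.
* Pairwise SD matrices are computed from the sample covariance matrix
  (`sd(a_j − a_k)² = var_j + var_k − 2 cov_jk`) with tiny negative
  round-off clamped to zero; tests verify equality with explicit
  double-loop recomputation to 1e-9.
* All argmax/argmin tie-breaks are lexicographic on the gene symbol in the
  C locale, and every ranking records its tie rule, so results are
  platform-independent and reproducible byte-for-byte.
* Variance estimates in the NormFinder decomposition are clamped at zero;
  shrinkage factors are defined as 0 when their denominator vanishes.
* Statistical guarantees are checked at deliberately modest problem sizes
  chosen to make the checks sharp but quick: 100 random 5-gene × 6-sample
  panels for oracle equivalence, 100 seeded study-like panels for
  consensus recovery, and 200 replicates at 10 genes × 2 groups × 10
  biological samples for intragroup-variance recovery (tolerance 15%).

## Known limitations

* No efficiency-corrected quantification (`(1+E)^-ΔCq`) in the default
  path; the base-2 convention is assumed throughout.
* BestKeeper's pairwise regressions and p-values are out of scope; only
  the descriptive statistics and index correlation are computed.
* The comparative ΔCt method duplicates geNorm's ordering by construction
  on complete panels; its value is interpretability and compatibility with
  four-method consensus conventions, not independent information.
* Instrument-native plate exports and melting-curve QC are not parsed;
  inputs are plain wide CSV/TSV tables.
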