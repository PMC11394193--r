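# refstab

Validation of RT-qPCR reference (housekeeping) genes: candidate screening
from RNA-seq, four stability algorithms, consensus ranking, and
ΔΔCt-based demonstration of what an unstable normalizer does to target
genes.

## Why

Every RT-qPCR fold change is computed *relative to* one or more reference
genes assumed stable across conditions. That assumption routinely fails —
*ACTB* and *GAPDH*, the traditional defaults, are regulated during cell
differentiation in many systems — and a shifting reference silently
distorts or masks real expression changes. The accepted remedy is to
validate a panel of candidates empirically before using any of them.
refstab packages that workflow for designs such as muscle-satellite-cell
proliferation/differentiation experiments (groups GM, DM1, DM5 with
biological and technical replicates), with a ground-truth synthetic
generator so every stage is testable without access to raw instrument
data.

## What it computes

Given a genes × samples Cq table, with `Q = 2^-(Cq - Cq_min)` per gene:

* **geNorm** — pairwise variation `V_jk = SD_s[log2(Q_j/Q_k)]`, stability
  `M_j = mean_k V_jk`, stepwise-exclusion ranking, and the pairwise
  variation `V_{n/n+1}` of normalization factors (geometric means of the
  top-n genes) with the `< 0.15` rule for the optimal number of
  references.
* **NormFinder-style** — variance decomposition of log2 Q into intragroup
  variance and shrunken intergroup differences after exact sample
  centering; stability value ρ per gene.
* **BestKeeper** — mean, SD, CV on raw Cq plus Pearson correlation with
  the per-sample geometric-mean index; ranked by SD.
* **Comparative ΔCt** — mean SD of pairwise Cq differences.
* **Consensus** — geometric mean of the per-method ranks,
  `(∏ ranks)^(1/m)`, with a deterministic comprehensive ordering.
* **Validation** — `2^-ΔΔCt` fold changes of target genes against chosen
  references (single or combined), one-way ANOVA across groups and Tukey
  HSD pairwise labels.
* **Screening** — candidate selection from an FPKM matrix by
  mean FPKM > 100 and CV < 10%, ascending CV.

## Worked example

Simulate the bundled study-like design — 10 genes, 3 culture phases × 3
biological × 3 technical replicates, eight genes truly stable, a
GAPDH-like gene with a moderate differentiation shift and an ACTB-like
gene with a large one — then run the full pipeline:

```r
library(refstab)
sim <- simulate_paper_like_panel(seed = 7)
col <- collapse_technical_replicates(sim$table)   # wells -> 9 biological samples
q   <- relative_quantity(col$table)
g   <- genorm(q)
res <- comprehensive_ranking(list(g, normfinder_stability(q),
                                  bestkeeper(col$table),
                                  delta_ct_method(col$table)))
res[, c("gene", "mean_rank_2dp", "comprehensive_rank")]
#>      gene mean_rank_2dp comprehensive_rank
#> 1   HSPA9          2.34                  1
#> 2    YBX1          2.34                  2
#> 3  RPS15A          2.63                  3
#> ...
#> 9   GAPDH          9.00                  9
#> 10   ACTB         10.00                 10
```

The eight designed-stable genes occupy ranks 1–8; the two genes with
built-in group effects land exactly where their effect sizes put them.
The V curve says two references suffice:

```r
head(g$v$v, 3); g$v$optimal_n
#>   n          v below_threshold
#> 1 2 0.02300663            TRUE
#> 2 3 0.01715823            TRUE
#> 3 4 0.01534937            TRUE
#> [1] 2
```

V2/3 = 0.023 < 0.15, so the top two genes form an adequate normalization
factor. Normalizing a shifting gene by two stable ones then exposes its
regulation as fold changes:

```r
fc <- ddct_fold_change(col$table, "GAPDH", c("RPL14", "RPS15A"), "GM")
compare_normalizations(fc)[[1]]$groups
#>   group n mean_fold        sem
#> 1   DM1 3 0.7573202 0.03011647
#> 2   DM5 3 0.5976082 0.01302532
#> 3    GM 3 1.0008116 0.02843578
```

GAPDH expression falls to ~0.6× by differentiation day 5 relative to the
proliferation phase — exactly the built-in effect, and exactly why it
should not be used as a reference here.

A thin command-line wrapper over the same functions lives at
`inst/scripts/refstab.R` (subcommands `simulate`, `screen`, `efficiency`,
`evaluate`, `validate`).

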