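# panelqc

Identity quality control for cultured cell-therapy products by gene-panel
expression correlation.

Mesenchymal stem cells (MSCs) have no single surface marker that separates,
say, synovium-derived MSCs from bone-marrow- or adipose-derived MSCs, let
alone from fibroblasts. `panelqc` implements a panel-based alternative: the
identity of a cell lot is scored as the coefficient of determination between
its log-TPM expression profile and a median reference profile, restricted to
a curated panel of MSC-associated genes. Because between-cell-type divergence
concentrates in those genes, the panel amplifies differences that are diluted
away in whole-transcriptome comparisons.

## The statistic and the decision rule

For a query sample *q* and reference profile *m* (per-gene median log₂ TPM
across reference lots), over panel gene set *G*:

- **Identity score** — R² = cor(q_G, m_G)², the squared Pearson correlation
  of log₂ TPM values (an identity-line variant is available via
  `mode = "identity_line"`).
- **Discrimination** — %CV = |(R²_self − R²_other) / R²_self| × 100, the
  relative deviation of a compared population's score from the reference's
  own score.
- **Detection power** — CV_panel / CV_comparator for the same comparison
  under a comparator gene set (a seeded random panel of equal size, or all
  genes). Values > 1 mean the curated panel discriminates better.
- **Thresholds** — the target-MSC lower bound is mean + SD of the
  other-tissue-MSC scores (3-decimal reporting precision); the non-MSC upper
  bound is the maximum observed non-MSC score. Samples classify as
  `target_msc` (≥ lower bound), `non_msc_like` (≤ upper bound) or
  `other_msc_zone` in between.

Upstream, the package implements the matching preprocessing: Phred
cumulative-sum read trimming (error-probability limit 0.05), RPKM → TPM
normalization, and log₂ transformation with zeros imputed at half the
minimum positive TPM so absent expression stays informative.

## Worked example

Thresholds derived from published other-MSC scores (0.821, 0.786, 0.821)
and non-MSC scores:

```r
library(panelqc)
th <- derive_thresholds(c(0.821, 0.786, 0.821),
                        c(0.699, 0.720, 0.462, 0.132, 0.100))
th
#> threshold_set: target MSC at R^2 >= 0.829, non-MSC at <= 0.720
#>   other-MSC mean 0.809, SD 0.020 (x1)
```

A full in-silico study — ten cell types (one target MSC with four lots,
three other-tissue MSC types, six non-MSC populations), 4400 genes with a
200-gene curated panel:

```r
sim <- simulate_dataset(sim_config(seed = 42))
qc  <- run_panel_qc(sim$counts, sim$panel)
qc
#> panel_qc on 200 panel genes, target 'SyMSC' (median of 4 lots)
#> threshold_set: target MSC at R^2 >= 0.834, non-MSC at <= 0.722
#>   other-MSC mean 0.825, SD 0.009 (x1)
#> decisions by role:
#>             non_msc_like other_msc_zone target_msc
#>   non_msc              6              0          0
#>   other_msc            0              9          0
#>   target               0              0          4
```

Every lot lands in the zone its biology dictates. Benchmarking the curated
panel against a random gene set of equal size shows the panel's
discrimination advantage (`power` = CV_panel / CV_random):

```r
rand <- sample_random_panel(rownames(sim$counts$values), 200, seed = 43)
bm <- benchmark_gene_sets(qc$logtpm, sim$panel, "SyMSC_L1", "SyMSC",
                          comparators = list(random = rand))
#>    cell_type r2_panel cv_panel r2_random cv_random power
#> 2       BMSC    0.826       17     0.954         4  4.72
#> 7         WP    0.720       27     0.923         7  4.16
#> 9      Tcell    0.418       58     0.876        11  5.07
#> ...
```

The random set sees every population as fairly similar to the target
(R² ≥ 0.88) while the panel separates other-tissue MSCs (≈ 0.82) from
fibroblast-like and blood populations (0.42–0.72).

A command-line wrapper covers the same flows
(`exec/panelqc trim|quantify|panel|qc|simulate`).

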