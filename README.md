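# cernaflow

Integrative multi-cohort differential expression and circRNA–miRNA–mRNA
(ceRNA) network discovery in R.

Single case/control expression microarrays replicate poorly across
platforms and cohorts. `cernaflow` implements the integrative strategy used
in multi-dataset transcriptomics (e.g. of asthmatic airway epithelium):

1. **Robust DEGs.** Per-dataset two-group differential expression with an
   empirical-Bayes moderated t (variance shrinkage via method-of-moments on
   log variances with trigamma inversion), then cross-dataset integration
   with the **Robust Rank Aggregation (RRA)** statistic. For an item with
   sorted normalized ranks `r_(1) ≤ … ≤ r_(m)` across `m` lists,
   `β_k = P(U_(k) ≤ r_(k)) = Σ_{j≥k} C(m,j) r_(k)^j (1−r_(k))^(m−j)`,
   `ρ = min_k β_k`, and the reported score is the Bonferroni-corrected
   `min(1, m·ρ)`. Robust DEGs: score < 0.05 and |mean log2FC| > 0.5.
2. **Hubs and complexes.** A confidence-filtered interaction network
   (STRING-style edge lists, confidence > 0.4) induced on the robust DEGs;
   dense complexes via an MCODE implementation (neighborhood k-core vertex
   weighting, seeded growth, 2-core haircut); hub genes by re-aggregating
   the top-50 lists of **ten centralities** (MCC, DMNC, MNC, Degree, EPC,
   BottleNeck, EcCentricity, harmonic Closeness, Radiality, Betweenness)
   with the same RRA score.
3. **ceRNA network.** miRNA→mRNA pairs predicted by all three target
   sources, validated against differentially expressed miRNAs under the
   sponge direction constraint (miRNA opposite to target), circRNAs
   attached through their miRNA partners, and only circRNAs covering
   *every* remaining mRNA retained; the tripartite network is ranked by
   Maximal Clique Centrality.

Seeded synthetic-data generators (`simulate_expression_datasets()`,
`simulate_ppi()`, `simulate_cerna_tables()`) produce every pipeline input
with planted ground truth, so each stage and the end-to-end run are
testable offline. `run_pipeline()` orchestrates all six stages with a
validated config, per-stage seeds, logs, and an MD5-hashed artifact
manifest.

## Worked example

Five synthetic case/control datasets (1000 shared genes, 20 + 20 samples,
50 up + 50 down planted genes at effect 1.0) integrated into robust DEGs:

```r
library(cernaflow)
library(dplyr)

sim  <- simulate_expression_datasets(seed = 1)
fits <- lapply(sim$datasets, moderated_t_test)
degs <- lapply(fits, filter_degs)                       # ranked up/down lists
universes <- vapply(fits, function(f) nrow(f$table), numeric(1))
lfc  <- bind_rows(lapply(fits, function(f)
  tibble::tibble(item = f$table$gene, log2fc = f$table$log2fc)))

robust <- select_robust(
  rra_aggregate(lapply(degs, `[[`, "up"),   universes, lfc),
  rra_aggregate(lapply(degs, `[[`, "down"), universes, lfc)
)
head(robust, 5)
#> # A tibble: 5 × 5
#>   item           rho         score mean_lfc direction
#>   <chr>        <dbl>         <dbl>    <dbl> <chr>
#> 1 GENE00180 9.11e-10 0.00000000455    -1.30 down
#> 2 GENE00067 2.43e- 8 0.000000121     -1.15 down
#> 3 GENE00570 2.43e- 8 0.000000121      1.07 up
#> 4 GENE00014 3.47e- 8 0.000000174     -1.09 down
#> 5 GENE00851 5.68e- 8 0.000000284      1.13 up
mean(c(sim$truth$up, sim$truth$down) %in% robust$item)
#> [1] 0.97
```

The small scores read as Bonferroni-corrected order-statistic p-values: a
gene near the top of all five fold-change rankings is wildly unlikely under
the permutation null, and 97% of the planted genes are recovered.

The shipped curated table of 45 validated miRNA–hub-gene pairs from
asthmatic bronchial epithelium drives the circRNA-attachment rule: *CST4*
and *CTSG* each depend on a single miRNA with no circRNA partner, so 12 of
the 14 mRNAs survive:

```r
pairs <- read_validated_pairs(
  system.file("extdata", "asthma_hub_mirna_pairs.tsv", package = "cernaflow"))
supported <- setdiff(unique(pairs$mirna), c("hsa-miR-1293", "hsa-miR-3664-5p"))
att <- attach_circrnas(pairs, tibble::tibble(circrna = "hsa_circ_x", mirna = supported))
nrow(pairs); length(att$kept_mrnas); att$dropped_mrnas
#> [1] 45
#> [1] 12
#> [1] "CST4" "CTSG"
```

And the full ceRNA assembly on planted synthetic tables keeps exactly the
planted triplets while every single-rule decoy is filtered out:

```r
ce  <- simulate_cerna_tables(seed = 1)
net <- assemble_cerna(ce$targets, ce$demis, ce$truth$mrna_dirs, ce$circ)
net
#> <cerna_network> 3 circRNAs, 5 miRNAs, 5 mRNAs; 20 edges
rank_cerna_mcc(net, top = 5)
#> [1] "hsa_circ_S0001" "hsa_circ_S0002" "hsa_circ_S0003" "hsa-miR-S001"
#> [5] "hsa-miR-S002"
```

`autoplot()` methods render volcano plots (`de_fit`), score lollipops
(`rra_result`), and the tripartite network (`cerna_network`); `tidy()` and
`glance()` give broom-style views of every fitted object.

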