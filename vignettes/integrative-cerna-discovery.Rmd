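---
title: "Integrative rank-aggregation discovery of circRNA-miRNA-mRNA networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative rank-aggregation discovery of circRNA-miRNA-mRNA networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cernaflow)
```

## The analysis problem

A single case/control expression microarray rarely supports firm conclusions:
platforms differ, cohorts are small, and per-dataset differentially expressed
gene (DEG) lists replicate poorly. `cernaflow` implements the integrative
strategy used in multi-cohort transcriptomics of airway epithelium: several
independent case/control datasets over a shared gene space are combined
through the Robust Rank Aggregation (RRA) order-statistic score into *robust*
DEGs; these seed a protein-protein interaction (PPI) subnetwork whose hub
genes are called by re-aggregating ten topological centralities with the same
RRA statistic; and the hubs anchor a competing-endogenous-RNA (ceRNA) network
in which circular RNAs sponge the miRNAs that repress the hub mRNAs.

## The RRA statistic

Each of $m$ input lists ranks items (genes) best-first within a universe of
size $N$; the item at position $i$ has normalized rank $r = i/N \in (0, 1]$.
Under the null that a gene is exchangeable with the rest of its universe, its
normalized ranks across lists behave like $m$ independent uniforms. For the
sorted rank vector $r_{(1)} \le \dots \le r_{(m)}$ (missing entries
substituted by the worst rank, $r = 1$),

$$\beta_k = P\!\left(U_{(k)} \le r_{(k)}\right)
  = \sum_{j=k}^{m} \binom{m}{j} r_{(k)}^j (1 - r_{(k)})^{m-j},$$

the upper binomial tail, is the probability that the $k$-th order statistic
of $m$ uniforms falls at or below the observed value. The score
$\rho = \min_k \beta_k$ picks the strongest order-statistic signal, and the
reported score is the Bonferroni-corrected $\min(1, m\rho)$ — a valid p-value
upper bound because the minimum ranges over $m$ statistics. Small scores mean
"consistently near the top of every list". Both $\rho$ and the corrected
score are reported because published applications print the corrected value
without naming it.

Design choices worth knowing:

* **Missing items take the worst rank** ($r = 1$). This is conservative — an
  item absent from a platform is treated as maximally unimpressive there.
  The original R implementation of this statistic handles partial lists
  slightly differently; numerical equality with it on partial lists is not
  claimed, and the package's tests pin this implementation against exact
  order-statistic (Beta) probabilities and a Monte-Carlo permutation oracle
  instead.
* **Directions are aggregated separately.** Up-lists are ranked by
  descending log2 fold change, down-lists by ascending; a gene passing both
  directional aggregations indicates corrupt input and raises an error
  rather than a silent choice.
* **`mean_lfc`** is the arithmetic mean of per-dataset log2 fold changes
  over the datasets measuring the gene; robust DEGs require corrected score
  < 0.05 and |mean log2FC| > 0.5 (both strict, matching the published
  cutoffs).

## Differential expression

Per dataset, `moderated_t_test()` computes an empirical-Bayes moderated t:
the per-gene pooled variance $s^2_g$ on $df = n_1 + n_2 - 2$ degrees of
freedom is shrunk toward a prior variance $s_0^2$ with prior degrees of
freedom $d_0$,

$$\tilde{s}^2_g = \frac{d_0 s_0^2 + df\, s^2_g}{d_0 + df}, \qquad
  t_g = \frac{\Delta_g}{\tilde{s}_g \sqrt{1/n_1 + 1/n_2}},$$

with a Student-$t$ reference on $d_0 + df$ degrees of freedom. The
hyperparameters come from the classical method of moments on
$e_g = \log s^2_g - \psi(df/2) + \log(df/2)$: the excess of $\mathrm{var}(e)$
over $\psi'(df/2)$ identifies $d_0$ through a trigamma inversion (monotone
Newton iteration, `trigamma_inverse()`), and the mean of $e$ identifies
$s_0^2$. Two degenerate regimes are handled explicitly:

* **Literally identical variances** (`var(e) = 0`): complete shrinkage with
  $s_0^2$ equal to the common variance, so the moderated t *equals* the
  ordinary pooled t — no information exists to shrink with, and the
  statistic degrades gracefully.
* **Non-positive moment excess with spread variances**: sampling noise, not
  degeneracy; $d_0 = \infty$ with the bias-corrected $s_0^2 = \exp(\bar e)$
  and a standard normal reference. The distinction matters: shrinking to the
  uncorrected geometric mean would be biased low by
  $\exp(\psi(df/2) - \log(df/2))$ and inflate the null type-I rate by
  several percent, which the calibration test would catch.

DEG calls use raw p < 0.05 and |log2FC| > 0.5 with *strict* inequalities, as
published; no multiplicity adjustment is applied at the per-dataset stage
because the cross-dataset RRA score carries the error control. The same code
path serves miRNA matrices.

## PPI network, MCODE, and the hub ensemble

`load_edge_list()` reads STRING-style edge dumps (0-1 or 0-1000 score
scales auto-detected), keeps confidence strictly above 0.4 by default,
merges duplicates keeping the maximum, and drops self-loops.
`induce_on_genes()` restricts to the robust DEGs and hides disconnected
nodes.

**MCODE** (`mcode_find_clusters()`) scores each node by the highest k-core
of its open neighborhood — `weight = k × density` of that core — then grows
clusters from unvisited seeds in decreasing weight order, admitting
neighbors within `node_score_cut = 0.2` of the seed weight, applying a
2-core haircut, and discarding clusters that fail the `k_core = 2` gate.
Parameters default to the Cytoscape plugin defaults (degree cutoff 2, no
fluff). Two behaviors are intentional: nodes examined but not admitted
remain available to seed later clusters, and returned node sets are
disjoint. On planted-clique benchmarks one clique member can be lost when
background edges dilute its neighborhood core (its weight falls below the
growth threshold), and one adjacent background node can be gained when it
genuinely joins the near-clique; the recovery tests allow exactly that
one-node slack.

**The hub ensemble** computes ten centralities (`centrality()`): Degree,
Betweenness (Brandes, unnormalized), harmonic Closeness (reciprocal distance
sum, finite on disconnected graphs), reciprocal EcCentricity, Radiality,
MCC (sum of $(|C|-1)!$ over maximal cliques through the node), MNC and DMNC
(size, and $|E|/|V|^{1.7}$, of the largest neighbor-subgraph component),
BottleNeck (per-root lexicographic BFS trees; a node scores when its proper
descendant count exceeds $|V|/4$), and EPC (mean reachable-node count over
seeded random edge-percolation subgraphs, keep probability 0.5, 1000
iterations by default). Deterministic tie-breaks are fixed everywhere
(lexicographic BFS parents; ties in `top_k_list()` resolved by node id) so
runs are reproducible; EPC takes an explicit seed and restores the caller's
RNG state. Every deterministic centrality is pinned against an independent
brute-force oracle on all 996 connected graphs with up to 7 nodes (one per
isomorphism class, enumerated by vertex augmentation with canonical forms),
and EPC against its exact edge-subset expectation within Monte-Carlo error.

Per-method top-50 lists are re-aggregated with RRA over a universe equal to
the network order; hubs are nodes with corrected score < 0.05 (the
published analysis reports 19 hubs without stating a cut; 0.05 is this
package's documented choice, exposed in the config). A caveat the synthetic
benchmarks make explicit: the five shortest-path centralities reward global
connectors, so the ensemble does not guarantee that every member of a dense
planted clique is called a hub — density-driven methods rank the clique
exactly, but the Bonferroni-corrected minimum favors nodes that are decent
in *all* ten lists over nodes that are excellent in five.

## ceRNA assembly

Four filters, in order, each a pure function of tables:

1. `intersect_three_dbs()`: keep (miRNA, mRNA) pairs predicted by all three
   target sources (exactly three sources are required).
2. `validate_directions()`: a sponge-regulated target moves opposite to its
   miRNA, so pairs are kept only when the miRNA's differential-expression
   direction opposes the mRNA's; miRNAs absent from the DE table drop out.
3. `attach_circrnas()`: an mRNA survives only if at least one of its
   validated miRNAs has a circRNA partner.
4. `coverage_filter()`: a circRNA is retained only if it can regulate
   *every* surviving mRNA through its miRNA partners. "Every remaining
   mRNA" means the post-attachment kept set, computed once — a single
   cross-linking pass, not a fixed-point iteration — and coverage counts
   only validated pairs, not raw predictions.

`build_cerna_network()` assembles the tripartite graph (miRNA nodes must
link both a retained circRNA and a kept mRNA) and asserts its invariants:
classes partition the nodes, only circ-mi and mi-mRNA edges exist, and
every mRNA is reachable from a circRNA. `rank_cerna_mcc()` ranks the result
by MCC viewed as a plain graph; on a triangle-free tripartite graph MCC
reduces to degree, which the tests exploit.

The package ships a 45-pair curated table of validated miRNA-hub-gene
relationships from asthmatic bronchial epithelium
(`inst/extdata/asthma_hub_mirna_pairs.tsv`, 14 mRNAs, slash-separated miRNA
lists) as a worked example: two genes (*CST4*, *CTSG*) each depend on a
single miRNA with no circRNA partner, so the attachment rule leaves 12 mRNA
nodes.

## Enrichment

`ora()` is the hypergeometric upper tail $P(X \ge k)$ for a query of size
$n$ overlapping $k$ of a set's $K$ members in a universe of $N$ measured
genes, with Benjamini-Hochberg q-values across the tested sets. The
universe is caller-supplied (the measured platform genes, not the genome) —
standard ORA practice. Raw p < 0.05 marks significance to mirror the
published analysis; q is always emitted alongside.

## What the synthetic generators emulate — and what they do not

`simulate_expression_datasets()` emulates the five-cohort case/control
design: a shared gene space of 1000 genes, per-gene baselines
$\mathcal{N}(7, 1)$ on the log2 scale, i.i.d. within-group noise
$\sigma = 1$, 20 + 20 samples per dataset, 50 up + 50 down planted genes
shifted by ±1.0 in cases wherever measured, and 10% of genes missing per
dataset to emulate platform differences. These defaults are the package's
study conditions: effect 1.0 at $n = 20$ per arm gives per-dataset power
high enough that five-dataset RRA recall of planted genes exceeds 0.9,
mirroring the regime in which the integrative method is useful. Noise is
Gaussian and intensity-independent because the moderated t assumes
approximate normality on the log2 scale; the generators deliberately omit
batch effects, probe saturation, correlated genes, and intensity-dependent
variance, so passing tests demonstrate correctness of the statistics, not
robustness to microarray artifacts.

`simulate_ppi()` plants complete cliques (sizes 6 and 5 by default) in an
Erdős–Rényi background ($n = 60$, $p = 0.05$); every non-clique pair,
including clique-to-background wiring, uses the same edge probability, so
$p = 0$ degenerates to the bare cliques. Within-clique confidences are
drawn from $U(0.7, 1)$, others from $U(0.2, 0.9)$.

`simulate_cerna_tables()` plants full (circRNA, miRNA, mRNA) triplets —
present in all three target sources, direction-consistent, with planted
circRNAs covering all planted mRNAs — plus decoys that each violate exactly
one rule: missing from one source, same-direction miRNA, or circRNA
covering a strict subset. One-rule decoys make per-filter failure
attribution possible in the tests. Background rows never reach three
sources, so they cannot leak into the intersection.

All generators are pure functions of their parameters and seed
(`withr::with_seed`), leaving the caller's RNG untouched.

## The pipeline

`run_pipeline(pipeline_config(...))` executes de → rra → network → hubs →
cerna → enrich, writing each stage's TSV/JSON artifacts, a log, and a
manifest with MD5 content hashes; identical configs yield byte-identical
artifacts. One global seed is fanned out to the stochastic stages by fixed
offsets so any stage can be reproduced in isolation. Configs are validated
up front — unknown fields and out-of-range thresholds are rejected by name,
and in file-driven mode all input files are checked before any stage runs.
In synthetic mode the generators are coupled: interaction cliques are
planted on planted DE genes and ceRNA mRNAs on detected hubs, so the
six stages exercise each other end to end. In file-driven mode, target
predictions are restricted to the detected hub genes before validation,
matching how the predictions are generated in practice.

## Numerical choices and limitations

* Strict inequalities at every published threshold (the sources write ">").
* Probe collapsing: probes mapping to zero or multiple symbols (separators
  `///`, `;`, `,`) are eliminated before per-symbol averaging; collapsing
  is idempotent.
* The log2 heuristic (transform when the maximum exceeds 30) and the
  outlier rule (mean inter-sample correlation more than 3 scaled MADs below
  the median; constant samples always flagged) are deterministic,
  parameter-light stand-ins for manual per-dataset curation; the outlier
  threshold is exposed. When the MAD of the mean correlations is exactly
  zero only constant samples are flagged.
* p-values are floored at the smallest positive double, never 0.
* Scores reported by RRA include both `rho` and the corrected score;
  equality with other implementations on partial lists is not claimed.
* Test problem sizes — 996-graph centrality sweep, 10,000-draw Monte-Carlo
  oracles, 5 × 1000-gene end-to-end recovery — were chosen so the whole
  suite completes in a few minutes on one core while keeping Monte-Carlo
  bounds at 3 standard errors.
* The published full-scale composition (127 robust DEGs, 19 hubs, a
  77-node/114-edge PPI, a 3/27/12 ceRNA network) depends on specific
  versions of GEO series, STRING, and target/circRNA databases; reproducing
  it requires those downloads and is out of scope here. The shipped
  worked example reproduces the one piece of in-table arithmetic that is
  version-independent: 45 validated pairs reduce to 12 mRNA nodes after the
  circRNA-support exclusion.
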