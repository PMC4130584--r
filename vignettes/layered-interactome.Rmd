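---
title: "Methods: layered interactome enrichment and annotation grouping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: layered interactome enrichment and annotation grouping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis

`layint` asks a compartment-aware question of a two-condition expression
experiment: *which biological processes differ between the conditions, and in
which subcellular compartment do they act?* The answer is assembled in six
stages, each exported on its own and driven together by `layint()` /
`run_pipeline()`:

1. **Differential expression.** Each gene is tested with a two-sided,
   pooled-variance (equal-variance) Student's t test between the two
   condition groups; genes with raw `p < alpha_de` (default 0.05) are kept.
   No multiplicity correction is applied here — family-wise control enters
   later, at the annotation-term level, which mirrors how this style of
   analysis is practised: the DE filter is a screen, not an inference.
2. **Direction clustering.** DE genes are split into an up- and a
   down-regulated cluster by deterministic 2-medoid partitioning of their
   standardized (per-gene z-score) profiles under correlation distance.
   "Up" always means higher in the first condition level (the reference
   group). Genes whose profile does not correlate positively with their own
   cluster centroid are left `unclustered` and excluded from direction
   bookkeeping downstream — the analogue of expression clusterers that
   refuse to place incoherent profiles.
3. **Network assembly.** A weighted functional-coupling edge list is
   restricted to edges whose both endpoints are DE genes; self-loops are
   dropped, duplicate unordered pairs collapse to their maximum confidence,
   then components smaller than `min_component_size` (default 5) are removed
   and only the largest component is kept.
4. **Layering.** Every node is placed in one of three strata — plasma
   membrane, cytoplasm, nucleus — from its localization record; nodes
   without a record inherit the majority layer of the annotated nodes at
   minimal hop distance.
5. **Per-layer over-representation.** Each catalog term is tested in each
   layer with the upper-tail hypergeometric against a background gene set,
   Bonferroni-corrected within the layer.
6. **Kappa grouping.** Significant terms are linked when the Cohen's kappa
   of their hit-gene memberships exceeds 0.3 and merged into annotation
   groups labelled by their most significant up- and/or down-regulated
   member term.

Optionally, `extract_seed_network()` pulls the one-hop neighborhood of
chosen seed genes from the interactome, tiering neighbors by how many seeds
they touch ("core" = all of them).

## Statistical details and conventions

**t test.** Pooled variance, `nA + nB − 2` degrees of freedom. Degenerate
inputs get a fixed convention: zero pooled variance with equal group means
gives `t = 0, p = 1`; with unequal means, `p = 0`. This keeps noiseless
fixtures well-defined.

**Direction clustering.** The two medoids are seeded from the genes with the
largest and smallest mean difference, making the partition deterministic;
medoid updates minimise within-cluster distance sums with ties broken by
index. A cluster is labelled up or down by the sign of its centroid's mean
contrast (reference minus other group). The unclustered rule fires when a
gene's correlation with its own centroid is at or below `cluster_floor`
(default 0). This 2-medoid scheme deliberately replaces a heavier
graph-theoretic clusterer: the only observable the pipeline consumes is the
up/down split plus a possible unclustered remainder, and the lightweight
substitute reproduces exactly that (the substitution is recorded in the
control object).

**Hypergeometric tail.** `P(X ≥ x)` is summed in log space from binomial
coefficients (`lchoose` + log-sum-exp), so small p-values at large
backgrounds do not underflow; the test suite checks it against exhaustive
enumeration (every parameter combination with background ≤ 12) and against
`phyper`. Terms with fewer than `min_hits = 2` hits are not tested and do
not count toward the Bonferroni family size `m`; `m` is the number of terms
actually tested in that layer.

**The EASE-style variant and null control.** The plain tail with the
`min_hits` filter has a known weakness in the *tiny-layer regime*: when only
a handful of false-positive DE genes survive the component filter, very few
terms reach 2 hits, so `m` shrinks to 1–3 while a 2-hit term can still have
`p_raw ≈ 0.01` — and null runs can report spurious groups. The EASE-style
option (`ease = TRUE`, which scores `x − 1` hits) is provided exactly for
this regime and restores the expectation that null runs report no groups;
the test suite verifies both the term-level null control of the default
variant (fraction of layer × term tests called significant stays below
alpha) and the zero-group property of the EASE variant. The report always
echoes which variant produced it.

**Kappa.** With contingency counts `a, b, c, d` over a reference set of size
`N`, `po = (a + d)/N`, `pe = ((a+b)(a+c) + (c+d)(b+d))/N²`, and
`kappa = (po − pe)/(1 − pe)`; when both memberships are constant (`pe = 1`)
the convention is 1 for identical memberships and 0 otherwise. The reference
set is the **layer's DE genes**, not the whole background: the binary
gene–term matrix the statistic is built on only contains the analysed
cluster's genes, and using the full background would inflate the chance
agreement term `d` and with it every kappa.

**Grouping.** Initial groups are closed kappa-neighborhoods; the merge step
repeatedly fuses the pair of groups sharing the largest fraction of the
smaller group's terms (threshold `share_threshold = 0.5`), with ties broken
by the lexicographically smallest combined member list, so the fixed point
is unique and independent of input order. Groups never span layers. The
direction of a term is up when at least `pct_up_threshold = 60%` of its hit
genes are up-regulated (down symmetrically, otherwise mixed); the group
direction applies the same rule to the pooled (union) hit genes.

**Layer propagation.** "Closest neighbors" is read literally: minimal BFS
hop distance to any annotated node, majority vote among the annotated nodes
at that distance, ties broken by the layer priority order (default plasma
membrane, cytoplasm, nucleus). Multi-localized genes resolve by the same
priority list. Genes whose only localizations map outside the three strata
(e.g. mitochondrion) are treated as unannotated and propagated — the
three-layer model has no fourth stratum.

**Rounding.** Layer percentages are rounded half-up to one decimal (base
R's banker's rounding would round 36.65 to 36.6 or 36.7 depending on
parity, which makes printed tables irreproducible).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha_de` | 0.05 | raw t-test cut for the DE screen |
| `alpha_terms` | 0.05 | Bonferroni-adjusted cut for terms |
| `min_confidence` | 0 | edge confidence floor (no cut; coupling databases ship pre-thresholded links) |
| `min_component_size` | 5 | smallest component kept |
| `keep_largest_only` | TRUE | retain only the largest component |
| `kappa_threshold` | 0.3 | strict lower edge bound on kappa |
| `share_threshold` | 0.5 | merge rule: shared fraction of the smaller group |
| `pct_up_threshold` | 0.6 | direction call on hit-gene proportions |
| `min_hits` | 2 | smallest testable term overlap |
| `background` | all matrix genes | conservative over-representation background |

Both component-filter behaviours (size floor and largest-only) are exposed
separately because the two are not equivalent and either reading of "remove
small components / keep the largest" may be wanted.

## The synthetic generator

`simulate_dataset()` emulates the full input context — expression matrix,
functional-coupling edge list, localization records, GMT term catalog —
with planted ground truth so every downstream stage is testable without any
external database. Defaults, chosen once as a realistic small experiment:
400 genes, 6 replicates per condition, 25% DE genes shifted by 3
within-group standard deviations (a strong microarray effect; per-gene
two-sample t power at this noncentrality exceeds 0.99), equal up/down split,
equal layer proportions with 10% unannotated genes, a 60-term catalog with
one planted up-regulated cytoplasm term of 8 genes, Erdős–Rényi background
edges at density 0.05 plus a dense (0.8) module over each planted term's
genes, and isolated nodes rescued by one edge to a random module node. All
randomness flows from `rng_seed`; identical configs reproduce identical
outputs.

What it does **not** emulate: probe-level structure, normalisation and batch
effects, scale-free degree distributions, correlated gene-gene noise, or
annotation bias in real GO/KEGG catalogs. Passing the planted-recovery tests
therefore demonstrates that the pipeline's logic is correct and calibrated
under idealised noise, not that any particular biological dataset will
reproduce a published table.

## Problem sizes used by the test suite

The suite runs the full pipeline on 400-gene simulations (200 seeded
replicates for planted recovery), 1000-gene null simulations for the DE
binomial check, 100-replicate null enrichment for family-wise control, and
exhaustive oracles at desk scale (backgrounds ≤ 12 for enumeration, graphs
≤ 20 nodes for seed networks). These sizes were picked so the whole suite
exercises every claim in well under a minute of simulation time while
keeping Monte-Carlo standard errors far below the asserted margins.

## Design choices where the design was open

- **Config files are YAML** (`run_pipeline("config.yaml")`): a plain
  key-value format with a reader in the standard R toolchain; the full
  config is echoed into the report so every threshold is reproducible.
- **Duplicate edges keep the maximum confidence** — conservative retention
  of the strongest evidence for a pair.
- **Component ties** go to the component containing the lexicographically
  smallest node id, purely for deterministic output.
- **Joint testing per layer** (not separate up/down gene lists), with
  per-term direction percentages; grouped results still present one
  direction per term, and a split analysis can be emulated by passing a
  direction-filtered background.
- **Seeds for subnetworks** may be given explicitly or as `term:<id>`,
  resolving to the network's genes annotated to that term.

## Limitations

- The percentage table tolerates only the three canonical strata; secreted
  or organellar proteins are propagated into them.
- Kappa grouping is within-layer by construction; cross-compartment
  processes appear as separate groups.
- One-hop seed networks only; no multi-hop expansion or regulatory
  direction inference.
- The DE screen is a raw-p filter; its gene counts are not comparable
  across platforms or preprocessing pipelines, and no attempt is made to
  reproduce any particular study's DE totals.
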