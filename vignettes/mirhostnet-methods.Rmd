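---
title: "Methods: tissue-specific functional association between intronic miRNAs and their host genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tissue-specific functional association between intronic miRNAs and their host genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirhostnet)
```

## The question the pipeline asks

Roughly two thirds of human microRNA genes sit inside introns of
protein-coding "host" genes and are often co-transcribed with them.
When the host gene is genetically associated with cardiovascular
disease (canonical examples: CDH13 hosting miR-3182, SLC12A3 hosting
miR-6863, CKAP5 hosting miR-5582), a natural hypothesis is that the
intronic miRNA participates in the same cellular program: its targets
should be functionally close to the host gene, in the tissues where
that program runs.

`mirhostnet` operationalizes this as a sequence of testable steps:

1. **Target integration.** Predicted targets from two prediction
   algorithms are combined by *union* (predictors have high
   false-negative rates, so intersection would discard most true
   targets). Targets of two mature forms of one locus are pooled the
   same way, and experimentally validated interactions from up to three
   databases are pooled into an annotation flag that never gates the
   analysis. A host gene predicted as a target of its own intronic
   miRNA is detected and, per configuration, flagged or removed.
2. **Association filtering.** For each tissue, every gene carries a
   network-association score to the host gene (a posterior-probability
   style score from a tissue-specific functional gene network, the
   NetWAS score). Genes passing an explicit criterion — strictly above
   a configured threshold — form the *host-associated set* of size
   $N$. The filtered target set is the intersection of the integrated
   targets with this set.
3. **Fractional ranks.** Raw scores from different tissue networks are
   not comparable, so each score is replaced by its fractional rank:
   rank divided by $N$, ties averaged, mapping scores to $(0, 1]$ with
   the best gene at 1. The mean fractional rank is exactly
   $(N+1)/2N$, and the transform is invariant under any strictly
   increasing rescaling of the scores — which is the point.
4. **Overlap test.** Whether targets are over- or under-represented
   among host-associated genes is a hypergeometric test: universe $G$
   (all genes scored in the tissue, host excluded), $K$ associated
   genes, $n$ targets, overlap $k$. Depletion is $P(X \le k)$,
   enrichment $P(X \ge k)$, two-sided doubles the smaller tail. Tails
   are evaluated in log space so that p-values near $10^{-22}$ remain
   meaningful.
5. **Score comparison.** Fractional ranks of filtered targets are
   compared with the ranks of all host-associated genes using a
   two-sample rank-sum (Mann–Whitney) test. The exact null is used
   when both groups have at most 10 observations and no ties; the
   tie-corrected normal approximation otherwise. Groups smaller than
   `min_n` (default 3) produce an explicit "no test performed, too few
   data" record rather than an unreliable p-value. Stars are assigned
   at p < 0.05, p < 1e-5, p < 1e-10.
6. **Centrality.** On the tissue interaction graph (edges kept at or
   above a weight threshold, every scored gene a node, isolated nodes
   allowed), degree is standardized to a percentage of the maximum
   possible degree, $\mathrm{deg}/(|V|-1) \times 100$, and betweenness
   is the shortest-path form normalized by $(|V|-1)(|V|-2)/2$. The
   comparison asks, one-sided by default, whether host-interacting
   targets are more central than the full target set.
7. **Enrichment.** The top targets (fractional rank $\ge$ `min_fr`,
   default 0.5; truncated to `top_n`, default 20; boundary ties broken
   by rank then gene symbol) are tested against a gene-set collection.
   The default mode is over-representation: per set a one-sided
   hypergeometric enrichment p, Benjamini–Hochberg q across sets. A
   preranked running-sum mode is also provided (below).

## The preranked enrichment mode

The running sum walks the ranked list (here: host-associated genes
ranked by fractional rank — the same quantity the screening stage uses)
and adds $|s_i|^p / \sum_{hits} |s_j|^p$ at gene-set hits and
$-1/(N - N_{hits})$ at misses; the enrichment score (ES) is the signed
maximum deviation, always in $[-1, 1]$. With $p = 0$ this is the
Kolmogorov–Smirnov-style statistic; the default is $p = 1$. A set
covering the entire ranked list has no misses and the statistic is
undefined; the function refuses it.

Significance uses a gene-label permutation null. Permuting scores over
genes and re-ranking is equivalent to placing the set's $N_{hits}$ hit
positions uniformly at random among the $N$ ranks, which is what is
actually sampled — one null ensemble per distinct hit count, reused
across sets of the same size. The nominal p is the same-sign null tail
with add-one smoothing; NES divides ES by the mean same-sign null
magnitude; the FDR q compares the pooled null NES tail fraction with
the observed NES tail fraction, sign-matched.

Two guards matter in practice and are worth stating plainly:

* **Minimum hits** (`min_hits`, default 5). A set overlapping the
  ranked list in one or two genes has an ES distribution so wide and so
  discrete that its normalized scores corrupt the pooled null for every
  other set. Such sets are reported with `NA` statistics and excluded
  from the pool — the same reason the classic implementation applies a
  minimum set size.
* **q-value monotonization.** The raw pooled-null FDR ratio is not
  monotone in NES: a set with the strongest NES in the collection can
  receive a larger q than a weaker set. Each set therefore reports the
  smallest FDR estimate over all same-sign rejection regions that
  contain it (a reversed cumulative minimum along the NES ordering),
  which is ordinary q-value logic.

The choice between modes is a configuration switch
(`enrichment_mode: ora | preranked`) and is stamped into the run
metadata; over-representation is the default because the natural input
after the top-20 screen is an unranked gene list.

## The synthetic-data generator

No inputs of the original analysis are redistributable, so the
generator emulates all four: predictor target tables, per-tissue
association score tables, tissue edge lists, and a GMT gene-set
collection, with ground truth recorded in a JSON sidecar.

* **Association scores** are a two-component uniform mixture split at
  the association threshold $c$: exactly
  $\mathrm{round}(f \cdot (G-1))$ genes (rounding half away from zero,
  for cross-platform reproducibility) score in $(c, 1]$, the rest in
  $[0, c)$. The components are disjoint, so ground-truth membership is
  exact and threshold-robust — a deliberate testing convenience, not a
  claim about the distribution of real network-association scores,
  about which the emulated resources publish nothing.
* **Targets** are drawn without replacement with a shared core giving
  the configured predictor overlap; host-associated genes have their
  sampling weight multiplied by `target_assoc_bias` (1 = null, below 1
  plants the overlap depletion seen in real data, above 1 plants
  enrichment). The bias is anchored to the ground truth of the *first*
  tissue, since a miRNA's predicted targets cannot depend on tissue;
  the remaining tissues behave as unbiased controls, which is exactly
  what produces a tissue-specific association pattern downstream.
* **Tissue graphs** are weighted Erdős–Rényi variants: pair
  connection probability proportional to the product of per-node
  attachment propensities (`centrality_bias` for host-associated
  targets, 1 otherwise), rescaled so the expected density stays at
  `edge_density`. This is the simplest model in which the bias has a
  provably monotone effect on expected degree. It does not produce
  scale-free degree distributions, and nothing in the generator models
  seed-sequence matching or the actual network-inference procedure —
  passing tests show the statistics recover planted structure, not
  that real tissue networks look like this.
* **Gene sets** have sizes uniform in a configured range; one
  designated set (`SET_PLANTED`) is seeded with a configured number of
  the top-ranked targets before being filled with random genes.

Every generator output is a pure function of (parameters, seed);
identical scenarios produce byte-identical files, which is what the
end-to-end determinism check exercises through the command-line
interface.

## Numerical and design choices

* **Association criterion.** The emulated resources publish no cutoff
  for "interacting with the host gene", so the threshold is mandatory
  in configurations and stamped into every output. The synthetic
  default (0.5) matches the generator's mixture split, so the filter
  recovers ground truth exactly.
* **"High ranked scores (≥ 0.5)".** The screen is applied to
  fractional ranks, not raw scores — keeping the top half of the
  host-associated genes — with rank direction chosen so higher score
  means higher fractional rank. A configuration switch applies it to
  raw scores instead for sensitivity analysis.
* **Rank test.** The described comparisons are between unpaired groups
  of unequal size, for which a signed-rank (paired) test is undefined;
  the two-sample rank-sum test is the default, and a paired mode
  exists but refuses unequal lengths.
* **Test universe.** $G$ is the set of genes scored in the tissue's
  association vector, host excluded; the over-representation universe
  defaults to the same set. Both are recorded in outputs.
* **Discreteness of the overlap test.** At small expected overlaps the
  hypergeometric test is conservative: at $G \approx 2000$, $K = 200$,
  $n = 150$ its exact attainable size at $\alpha = 0.05$ is 0.026, and
  the calibration test pins the Monte-Carlo rejection rate to that
  exact size rather than to the nominal 5%.
* **Determinism.** Sub-seeds for each generator component are derived
  arithmetically from the scenario seed (kept below $2^{31}$);
  boundary ties in top-target selection and in ranked-list ordering are
  broken by gene symbol.

## Problem sizes used by the test suite

The suite verifies oracle equivalence exhaustively where enumeration is
cheap (all feasible hypergeometric configurations to $G = 30$; all
rank-sum group sizes to 6; 100 random graphs of up to 10 nodes against
full geodesic enumeration) and uses simulations at the dimensions the
planted-effect checks are stated at: null calibration and depletion
power at $G = 2000$, $K = 200$, $n = 150$ (1000 and 200 replicates);
centrality recovery at 500 genes, density 0.02, bias 5 (100 seeds);
planted-set recovery with 15 of the top 20 targets in a 500-set
collection (50 seeded runs, 500 permutations). These sizes were chosen
as the smallest at which the planted effects are unambiguous.

## Limitations

* Gene identity is by uppercased symbol; no identifier mapping is
  attempted, which suits the synthetic universe and symbol-level dumps
  but not mixed-identifier inputs.
* Betweenness treats the graph as unweighted (the interaction
  skeleton); weighted-geodesic betweenness, closeness and eigenvector
  centrality are out of scope.
* The preranked FDR is permutation-based and shares the known
  coarseness of pooled-null estimates at modest permutation counts;
  p-values below $1/(n_{perm}+1)$ are not attainable.
* Conclusions from synthetic runs are statements about the generator's
  planted structure. Real predictor dumps, association score files and
  gene-set collections can be substituted through the same readers and
  configuration, but no claims about real cardiovascular biology follow
  from the tests shipped here.
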