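# mirhostnet

Many human microRNA genes are intronic: they sit inside an intron of a
protein-coding "host" gene and are frequently co-transcribed with it.
When the host gene is genetically associated with cardiovascular
disease — CDH13 (hosting miR-3182), SLC12A3 (miR-6863) and CKAP5
(miR-5582) are the canonical trio — the question is whether the miRNA's
targets are functionally tied to the host gene, and in which tissues.
`mirhostnet` is an R package for systems biologists that turns this
question into a reproducible pipeline over tissue-specific functional
gene networks.

## What the pipeline computes

For a (host gene, intronic miRNA) pair and a panel of tissue networks:

1. **Integrate targets** — union of the prediction tables of two
   algorithms (union, not intersection: predictors have high
   false-negative rates), union across two mature forms of a locus,
   and a pooled validated-interaction flag from up to three databases.
2. **Filter by host association** — keep targets whose network
   association score to the host gene (NetWAS-style posterior score)
   passes an explicit per-run criterion in that tissue. With the
   host-associated set of size *N*, each score is replaced by its
   **fractional rank** (rank / *N*, ties averaged, values in (0, 1],
   mean exactly (*N*+1)/2*N*) so tissues become comparable.
3. **Test the overlap** — hypergeometric test of the target /
   associated-set overlap *k* against drawing *n* targets from *G*
   genes with *K* associated: depletion tail P(X ≤ k), enrichment
   P(X ≥ k), computed in log space.
4. **Compare score and centrality distributions** — two-sample
   rank-sum (Mann–Whitney) tests: filtered targets vs. all associated
   genes on fractional ranks, and host-interacting targets vs. all
   targets on standardized degree (deg/(|V|−1) × 100) and normalized
   betweenness on the tissue graph. Groups below `min_n` produce an
   explicit "no test performed" record.
5. **Select and enrich top targets** — fractional rank ≥ 0.5, top 20,
   tested against a GMT gene-set collection by over-representation
   (hypergeometric + Benjamini–Hochberg FDR) or by preranked
   running-sum enrichment with a gene-label permutation null and
   sign-matched NES-based FDR.
6. **Summarize tissue specificity** — in how many tissues each
   filtered target appears, plus the pairwise tissue overlap matrix.

A synthetic-data generator emulates every input (predictor tables,
association scores, tissue edge lists, gene sets) with controlled
planted structure — overlap depletion/enrichment, centrality elevation
of host-associated targets, one enriched gene set — and writes the
ground truth beside the data, so the whole pipeline is testable without
any external downloads.

## Worked example

```r
library(mirhostnet)

scenario <- synthetic_scenario(
  n_genes = 600, host_gene = "CDH13", mirna_id = "hsa-miR-3182",
  n_targets_per_predictor = 80, target_assoc_bias = 0.3,
  centrality_bias = 6, edge_density = 0.03, n_gene_sets = 100,
  seed = 42)
simulate_scenario(scenario, "scenario42")
res <- run_full_analysis("scenario42/analysis_config.yaml", "report42")

res$per_tissue$cardiac_muscle$overlap
#> Hypergeometric overlap test (depletion): k = 5, expected = 12.02
#>   (G = 599, K = 60, n = 120), p = 0.008935
res$per_tissue$cardiac_muscle$centrality$degree
#> Rank comparison (greater): W = 587.5, p = 0.0001402 * (n = 5 vs 120)
res$specificity
#> Tissue specificity of 42 filtered targets
#>   tissues-per-target histogram: 1:32  2:9  3:1  4:0  5:0
```

Reading the output: in the cardiac-muscle network only 5 of the 120
predicted targets are associated with the host gene where 12 were
expected at random — the planted overlap depletion (`target_assoc_bias
= 0.3`), detected at p ≈ 0.009. Those 5 host-interacting targets are
markedly more central than the target set as a whole (one-sided
rank-sum p ≈ 1.4e-4, the planted `centrality_bias = 6`). Most filtered
targets appear in a single tissue network, the tissue-specific pattern
the histogram summarizes. `report42/` holds the same results as TSV
tables plus `run_metadata.json` with every threshold stamped in; runs
with the same config and seed are byte-identical.

The command-line wrapper drives the same functions:

```sh
Rscript inst/cli/mirhostnet.R simulate --config scenario.yaml --out data/ --seed 42
Rscript inst/cli/mirhostnet.R run --config data/analysis_config.yaml --out report/
Rscript inst/cli/mirhostnet.R enrich --mode ora --gmt sets.gmt \
    --query top_targets.txt --universe universe.txt --out enrichment.tsv
```

The YAML analysis config (written for you by `simulate`) names the
host/miRNA pair, the tissue panel, all input paths, and the thresholds:
`association_threshold` (mandatory), `min_fr`, `top_n`, `min_n`,
`edge_weight_threshold`, `overlap_alternative`,
`centrality_alternative`, `enrichment_mode`, `n_perm`, `seed`.

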