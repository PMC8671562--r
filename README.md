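# synoclone

Paired single-cell transcriptome + TCR repertoire analysis of sorted
T-cell populations (e.g. regulatory T cells) sampled from two tissue
compartments — peripheral blood (PB) and synovial fluid (SF).  The
package is aimed at analysts working with CellRanger-style outputs
(Matrix Market count matrices, `filtered_contig_annotations.csv`) who
need the downstream statistics of a clonality study: which T-cell clones
are expanded, whether they are enriched in the inflamed joint, and how
their transcriptional states distribute across clusters.

## What it computes

* **Quality control** — removal of cells with >10% mitochondrial UMIs,
  <250 or >4000 detected genes, >25,000 UMIs, no CD3-complex transcript,
  or TCR multiplet chains (>1 β or >2 α); boundary values are kept, and a
  PsA preset (500–3500 genes, CD4/CD8 co-expressors removed) is included.
* **Hashtag demultiplexing** — per-tag negative-binomial background fit
  (method of moments) with the positivity threshold at the distribution's
  99th quantile; cells positive for one tag are singlets, for two or more
  doublets, for none negatives.
* **Clonotypes** — a clone is the set of cells with identical α- and
  β-chain CDR3 nucleotide sequences.  For each clone with ≥ 3 cells in
  either compartment, enrichment is tested with a two-sided Fisher's
  exact test on

  ```
  [[ n_SF,  total_SF − n_SF ],
   [ n_PB,  total_PB − n_PB ]]
  ```

  (totals = clonotyped cells per compartment), with Benjamini–Hochberg
  correction across eligible clones; significance at adjusted p ≤ 0.05.
* **Expression statistics** — counts-per-10k `log1p` normalization;
  two-sided Wilcoxon rank-sum differential expression (exact for small
  groups, tie-corrected normal approximation otherwise) with Bonferroni
  correction and a 10% detection floor; log fold change
  `ln(mean(expm1 A)+1) − ln(mean(expm1 B)+1)` with ±0.25 reporting cut;
  gene-module scores against expression-matched control genes; pairwise
  Spearman co-expression; and a pooled two-proportion z-test of cluster
  composition between compartments.
* **Synthetic data** — a seeded, truth-labelled generator
  (`sim_config()` / `generate_dataset()`) emulating clustered NB
  expression, mitochondrial genes, hashtag counts with doublets, and a
  clone-size distribution with planted compartment-biased expansions, so
  the whole pipeline is testable without any external dataset.

## Worked example

```r
library(synoclone)

cfg <- sim_config(seed = 1)        # 2500 cells, 10 planted SF-biased clones
ds  <- generate_dataset(cfg)
dir <- tempfile(); write_dataset(ds, dir)
writeLines(ds$truth$module_genes, file.path(dir, "module.txt"))

res <- run_pipeline(list(
  expression  = file.path(dir, "expression"),
  contigs     = file.path(dir, "contigs.csv"),
  meta        = file.path(dir, "meta.tsv"),
  hto         = file.path(dir, "hto"),
  module_file = file.path(dir, "module.txt"),
  out_dir     = file.path(dir, "out"),
  seed        = 1))

res$manifest
#>            stage n_in n_out seed
#> 1  qc_expression 2500  2374    1
#> 2      hto_demux 2374  2225    1
#> 3   cd3_tcr_gate 2225  2180    1
#> 4    clonotyping 2180  2180    1
#> 5     enrichment 2041    10    1
#> 6    de_sf_vs_pb 2180   897    1
#> 7   module_score 2180  2180    1
#> 8 cluster_z_test 2180     4    1
```

The manifest is the audited cell funnel: 2,500 simulated cells, 2,374
surviving expression QC, 2,225 hashtag singlets, 2,180 after CD3 gating
and TCR-multiplet removal; 10 clones reach the ≥3-cell eligibility rule
and 897 genes pass the 10% detection floor for SF-vs-PB differential
expression.  The enrichment table ranks clones by Fisher p-value:

```r
head(res$enrichment[, c("n_pb", "n_sf", "odds_ratio", "p", "p_adj",
                        "significant", "enriched_in")], 4)
#>   n_pb n_sf odds_ratio        p    p_adj significant enriched_in
#> 1    2   28      14.58 3.30e-07 3.30e-06        TRUE          SF
#> 2    1   23      23.87 1.18e-06 5.88e-06        TRUE          SF
#> 3    5   31       6.46 5.46e-06 1.82e-05        TRUE          SF
#> 4    2   15       7.72 1.16e-03 2.91e-03        TRUE          SF
```

Each such row is one clone: `n_pb`/`n_sf` are its member counts per
compartment, and a significant SF-enriched row is a clonal expansion
concentrated in the joint.  Here the top clones recover the planted
SF-biased expansions (members land in SF with probability 0.9 by
construction).

## Documentation

The methods vignette (`vignettes/treg-compartment-analysis.Rmd`) gives
the full account: model assumptions, parameter defaults and their
rationale, numerical conventions (tie handling, boundary semantics,
exactness switchovers), what the synthetic generator does and does not
emulate, and known limitations — in particular the power floor of
Fisher's exact test for clones of 3–5 cells.
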