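---
title: "Clonal and transcriptional analysis of T cells across blood and synovial fluid"
author: "synoclone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clonal and transcriptional analysis of T cells across blood and synovial fluid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synoclone)
```

# The analysis problem

Regulatory T cells (Tregs) sampled from an inflamed joint and from the
matching peripheral blood can be profiled in the same experiment with
paired 5' single-cell RNA-seq and single-cell TCR-seq, with a hashtag
oligo (HTO) marking each sorted population before pooling.  `synoclone`
implements the downstream computational pipeline for such a design:

1. cell-level quality control (QC),
2. hashtag demultiplexing with a negative-binomial background threshold,
3. clonotype calling from paired alpha/beta CDR3 nucleotide sequences,
4. per-clone compartment-enrichment testing (two-sided Fisher's exact
   test with Benjamini–Hochberg correction),
5. clonal fate mapping across externally supplied transcriptional
   clusters, and
6. the supporting expression statistics: library-size `log1p`
   normalization, Wilcoxon rank-sum differential expression with
   Bonferroni correction, gene-module scoring against expression-matched
   controls, pairwise Spearman co-expression, and a two-proportion
   z-test of cluster composition between compartments.

Upstream steps — alignment and quantification, normalization-based
integration, dimensionality reduction and clustering — are out of scope;
cluster labels enter the pipeline as plain metadata.

A truth-labelled synthetic data generator (`sim_config()`,
`generate_dataset()`) is a first-class component: every downstream stage
can be validated against planted ground truth without any external
download.

# Quality control

`compute_qc_metrics()` works on the raw count matrix.  A cell is removed
when any of the following holds (AS preset):

* mitochondrial UMI fraction > 10% (genes identified by the `MT-` id
  prefix),
* fewer than 250 or more than 4,000 detected genes,
* more than 25,000 total UMIs,
* no transcript from any CD3-complex gene (*CD3E*, *CD3D*, *CD3G*),
* TCR multiplet: more than 1 distinct productive beta chain or more than
  2 distinct productive alpha chains.

The PsA preset tightens the gene bounds to 500–3,500 and additionally
removes cells co-expressing *CD4* together with *CD8A* or *CD8B* (the
sorting strategy for that dataset makes such cells suspect doublets).

Three deliberate readings are worth stating:

* **Boundary semantics.**  The removal rules are written as strict
  inequalities, so boundary cells — exactly 250 genes, exactly 10%
  mitochondrial UMIs, exactly 25,000 UMIs — are *kept*.
* **Chain counting.**  Multiplet rules count distinct productive
  `(chain, CDR3-nt)` pairs; duplicate contigs of the same chain are
  assembly redundancy, not extra chains.
* **CD14 purge.**  An upstream monocyte-cluster purge is replaced by a
  direct rule (`drop_cd14 = TRUE` removes cells with any *CD14* counts),
  since clustering is outside the package's scope.

The mitochondrial fraction is computed on the raw matrix before any gene
filtering; nothing in the procedure is sensitive to that ordering for
the data the package targets, but it is fixed here for reproducibility.

Exclusions are attributed to the *first* failing rule in a fixed order
(mito, low genes, high genes, high UMI, CD3, multi-beta, multi-alpha,
CD4/CD8, CD14) so that per-rule counts plus kept cells always sum to the
number of input cells — the cell funnel in the run manifest is exactly
auditable.

# Hashtag demultiplexing

Each hashtag's counts are modelled as negative binomial over background
cells; the positivity threshold is the smallest integer `k` whose CDF
reaches the 0.99 quantile, computed by direct term-by-term summation of
the mass function.  The fit is method-of-moments (`mu` = sample mean,
`size = mu^2 / (s^2 - mu)`), falling back to Poisson when the sample
variance does not exceed the mean.  A cell is *positive* for a tag when
its count strictly exceeds the tag's threshold; one positive tag makes a
singlet, two or more a doublet, none a negative.  With a single hashtag
only singlet/negative are possible.

**Background selection.**  Cells are clustered by k-means
(k = number of tags + 1) on CLR-transformed counts (`ln(count + 1)`
centred per cell across tags; the CLR is used only for selection, never
for thresholding).  For tag *t* the background is accumulated from the
clusters in increasing order of their mean CLR value for *t* until at
least 20 cells are available, never touching the highest (positive)
cluster.  Two design points came out of validation on synthetic data:

* Taking the *complement of the top cluster* as background is fragile:
  doublets that carry tag *t* as their second tag fall outside the top
  cluster, contaminate the background, and inflate the moment-fit
  variance so much that the threshold swallows true signal.  Anchoring
  the background at the most-negative clusters (the behaviour of the
  widely used HTODemux implementation) avoids this.
* The lowest cluster alone can be a tiny doublet cluster; accumulating
  clusters upward keeps the background clean *and* large enough for a
  stable fit.  If clustering degenerates entirely, the fallback takes
  cells at or below the tag's 90th count percentile — adequate only
  when positives are rarer than 10%, which is why it is a last resort.

# Clonotypes and compartment enrichment

A clonotype is the set of cells with identical TCR alpha- and beta-chain
CDR3 *nucleotide* sequences; the clone key is the sorted distinct alpha
list joined to the sorted distinct beta list, so clone identity is
independent of contig row order.  Cells without a beta chain are never
clonotyped.  Two modes handle chain multiplets:

* `joint_gex` (joint expression + clonality analyses): cells with more
  than 1 beta or more than 2 alphas are multiplets and are excluded.
* `clonality_table` (repertoire accounting): multi-beta cells are kept,
  each full chain multiset forming its own clone, because alpha/beta
  pairing cannot be deduced for them.

For each clone with at least `min_cells = 3` cells in *either*
compartment (`max(n_pb, n_sf) >= 3`; the alternative total-count reading
is available as `eligibility = "total"`), the proportion of cells
belonging to the clone is compared between compartments with a
two-sided Fisher's exact test on
`[[n_sf, total_sf - n_sf], [n_pb, total_pb - n_pb]]`.  The totals are
all *clonotyped* cells per compartment: the tested proportion is only
defined over cells that have a clone.  The two-sided p-value uses the
point-probability rule — the sum of all hypergeometric point
probabilities not exceeding the observed one, with a `1e-7` relative
tie tolerance, matching the convention of R's `fisher.test` — and
`bh_adjust()` implements the Benjamini–Hochberg step-up across the
eligible clones only.  A clone is *significant* at adjusted p ≤ 0.05.

Clone members can then be mapped onto transcriptional clusters
(`clone_cluster_distribution()`, with a purely descriptive
hypergeometric over-representation score) and a clone's CD4/CD8 lineage
is called by majority vote over members on normalized *CD4* vs
*CD8A + CD8B* expression, abstaining on ties.

# Expression statistics

* **Normalization** — `ln(1 + count * 10000 / cell_total)`; counts per
  10k before `log1p` is the convention of the tooling that defined the
  ±0.25 log-fold-change reporting cut used below.  Raw `ln(count + 1)`
  is available with `scale_total = NULL`.
* **Differential expression** — Wilcoxon rank-sum on normalized values,
  two-sided, average ranks for ties; genes are tested when detected in
  at least 10% of either group; the log fold change is
  `ln(mean(expm1(A)) + 1) - ln(mean(expm1(B)) + 1)` (natural log);
  Bonferroni multiplies by the total gene count of the matrix (not just
  the tested genes), switchable via `m_total`.  Both test names in the
  upstream description resolve to Wilcoxon in every figure they
  annotate, so Wilcoxon is the implemented test; an NB-GLM variant is
  out of scope.
* **Exactness** — for group sizes up to 8 per side the p-value is exact:
  a dynamic program over the multiset of doubled average ranks counts
  all labellings whose rank-sum deviates from the permutation-null mean
  by at least the observed deviation (symmetric-deviation two-sided
  rule, valid under ties).  Larger groups use the normal approximation
  with tie-corrected variance and no continuity correction; at 50 cells
  per group the two agree to within 0.01.
* **Reporting** — `report_filter()` keeps `|logFC|` strictly above 0.25,
  flags adjusted p < 0.05, and can drop TCR variable-chain genes
  (TRAV/TRBV/TRAJ/TRBJ prefixes), which are trivially "differential"
  whenever groups were defined by their TCR.
* **Module scores** — genes are binned into 24 equal-occupancy bins by
  average normalized expression; each module gene draws 100 control
  genes (with replacement, seeded) from its own bin; the per-cell score
  is the module mean minus the control-draw mean.  Bin count and
  control count are the published defaults of the tool that popularised
  the procedure.  Under an exchangeable null the score is centred on
  zero.
* **Cluster composition** — per cluster, the fraction of PB cells in the
  cluster is compared with the fraction of SF cells by the pooled
  two-proportion z statistic, two-sided, with no continuity and no
  multiplicity correction (mirroring how such per-cluster annotations
  are conventionally reported); `z^2` equals the uncorrected 1-df
  chi-square statistic of the corresponding 2x2 table.
* **Co-expression** — average-rank Spearman rho per gene pair;
  zero-variance genes yield `NA` against every partner while the
  diagonal is 1 by definition.

# The synthetic data generator

`generate_dataset()` produces an expression matrix, metadata, contigs,
hashtag counts and a truth table with the statistical structure the
pipeline assumes:

* **Expression** — negative binomial counts (dispersion `size = 2`,
  i.e. variance `mu + mu^2/2`), baseline gene means log-normal
  (`ln mu ~ N(ln 0.4, 1.2^2)`, a right-skewed mean distribution typical
  of droplet data), cells assigned uniformly to `n_clusters = 4`
  clusters, each cluster's marker genes elevated `marker_fold = 4`-fold,
  and one cluster carrying a 20-gene module elevated
  `module_fold = 2`-fold.  Mitochondrial (`MT-` prefixed) gene means are
  scaled so a clean cell sits near a 5% mitochondrial fraction.  CD3
  genes are expressed at means high enough that CD3-negative droplets
  are rare (a per-mille, as in sorted T-cell data).
* **Repertoire** — each background cell is a singleton clone with its
  own random in-frame CDR3 pair (uniform codons, lengths 30–60 nt in
  multiples of 3; no V/J grammar, since enrichment statistics depend
  only on string identity).  `n_expanded_clones = 10` planted clones
  have sizes `1 + Geometric(1/mean)` with `expanded_size_mean = 20`
  (memoryless heavy tail standing in for expansion skew; no
  repertoire-level law is prescribed by the data the package emulates)
  and each member lands in synovial fluid with probability
  `sf_bias = 0.9` (0.5 is the null).
* **Hashing** — 2 hashtags by default: the minimal pooled-lane design in
  which the hashtag both identifies the tagged population and lets
  cross-tag doublets be flagged.  Counts are NB with mean 200 on a
  cell's own tag(s) and 4 elsewhere (50x separation, dispersion 10);
  `doublet_rate = 5%` of cells carry signal on two tags.
* **QC violations** — controlled fractions of cells are made to violate
  each QC rule (high mito, near-empty, saturated, high-UMI, extra beta
  chain).  Truth flags are derived from the *realized* per-cell metrics
  against the standard thresholds, so the truth table is always
  consistent with the emitted data even when a small gene universe makes
  a rule (e.g. > 4,000 genes) unreachable.
* **Determinism** — one seed per dataset; each generator component
  derives its own sub-seed from a component name, so adding or
  reordering components never perturbs the random stream of the others.
  Identical config + seed reproduces every file byte for byte.

What the generator does *not* emulate: ambient RNA, batch effects,
dropout beyond NB sparsity, UMI saturation, V(D)J recombination biology,
or doublet expression profiles.  Passing tests therefore demonstrate the
statistical machinery on data satisfying the model's assumptions, not
robustness to every artefact of real droplet data.

# Validation strategy and problem sizes

The test suite validates each statistical primitive against an
independent oracle: Fisher p-values against brute-force enumeration over
all 2x2 tables with total at most 40; BH against an independent step-up
implementation on 1,000 random vectors; exact Wilcoxon p-values against
full labelling enumeration for all group sizes up to 8, and the normal
approximation against the exact dynamic program at 50 cells per group;
NB quantiles against R's quantile functions on a (mu, size) grid.
Pipeline-level properties run on seeded synthetic replicates: 200 null
repertoires (~1,600 cells, ~95 eligible clones each) for
false-discovery control, 50 seeds for clone recovery (2,500 cells) and
module-score ranking (300 cells, 400 genes), and 20 seeds (500 cells)
for demultiplexing accuracy.  These sizes keep the full suite in the
minutes range while leaving each property's Monte-Carlo error well below
its margin.

# Known limitations

* Fisher-exact compartment enrichment has essentially no power for
  clones of 3–5 cells: the most extreme attainable two-sided p for an
  all-SF 3-cell clone is ~0.25, and ~0.06 for 5 cells, before any
  multiple-testing correction.  With heavy-tailed (geometric) planted
  clone sizes a substantial minority of true expansions is therefore
  undetectable in principle, and measured recovery of planted clones
  (~0.7 at mean size 20) reflects that floor, not an implementation
  defect.  Interpret small-clone non-significance as absence of
  evidence.
* The moment-fit NB threshold assumes the selected background is
  uncontaminated; the cluster-accumulation rule above makes this robust
  for well-separated hashing (50x), but heavily overloaded lanes with
  high doublet rates may need a manual threshold.
* The per-cluster z-test is reported uncorrected across clusters, as is
  conventional for composition annotations; treat the per-cluster
  p-values as descriptive.
* Clones are compared within one patient; cross-patient clone sharing is
  out of scope.

# A worked example

```{r example, eval = FALSE}
library(synoclone)

cfg <- sim_config(seed = 1)
ds <- generate_dataset(cfg)
dir <- tempfile()
write_dataset(ds, dir)
writeLines(ds$truth$module_genes, file.path(dir, "module.txt"))

res <- run_pipeline(list(
  expression = file.path(dir, "expression"),
  contigs = file.path(dir, "contigs.csv"),
  meta = file.path(dir, "meta.tsv"),
  hto = file.path(dir, "hto"),
  module_file = file.path(dir, "module.txt"),
  out_dir = file.path(dir, "out"),
  seed = 1))

res$manifest                      # the audited cell funnel
head(res$enrichment)              # per-clone Fisher/BH results
```
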