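# Shared fixture builders: everything is constructed in code.

# Small dense count matrix with named genes, as an expression matrix.
tiny_expr <- function(counts, genes = NULL, cells = NULL) {
  counts <- as.matrix(counts)
  if (is.null(genes)) genes <- sprintf("G%02d", seq_len(nrow(counts)))
  if (is.null(cells)) cells <- sprintf("cell%02d", seq_len(ncol(counts)))
  expression_matrix(counts, genes, cells)
}

# One contig row in the 10x dialect used by read_contigs().
contig_row <- function(barcode, chain, cdr3_nt, productive = TRUE,
                       umis = 5L) {
  data.frame(barcode = barcode, chain = chain,
             cdr3 = "CASS", cdr3_nt = cdr3_nt,
             v_gene = "TRBV9", j_gene = "TRBJ1-1",
             productive = productive, umis = umis,
             stringsAsFactors = FALSE)
}

contig_df <- function(...) do.call(rbind, list(...))

# Write a contig data frame as a CSV the reader understands.
write_contig_csv <- function(df, path) {
  df$productive <- ifelse(df$productive, "True", "False")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# Minimal metadata for a set of barcodes.
tiny_meta <- function(barcodes, compartment, cluster = NULL) {
  df <- data.frame(barcode = barcodes, sample_id = "S1",
                   compartment = compartment, patient = "P1",
                   stringsAsFactors = FALSE)
  if (!is.null(cluster)) df$cluster <- cluster
  df
}

# Brute-force two-sided Fisher p by enumerating all tables with the
# observed margins, using choose() only (independent of dhyper).
fisher_enum_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  if (lo == hi) return(1)
  xs <- lo:hi
  mass <- choose(m, xs) * choose(n, k - xs) / choose(m + n, k)
  pobs <- choose(m, a) * choose(n, k - a) / choose(m + n, k)
  min(1, sum(mass[mass <= pobs * (1 + 1e-7)]))
}

# Literal step-up BH oracle: adj_(i) = min_{j >= i} p_(j) * m / j.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m))
    adj[i] <- min(1, min(ps[i:m] * m / (i:m)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Exact two-sided rank-sum p by enumerating every labelling of n1 + n2
# observations (symmetric-deviation rule, average ranks).
ranksum_enum_oracle <- function(va, vb) {
  n1 <- length(va)
  ranks <- rank(c(va, vb))
  w_obs <- sum(ranks[seq_len(n1)])
  mu <- n1 * mean(ranks)
  combos <- utils::combn(length(ranks), n1)
  w_all <- apply(combos, 2, function(i) sum(ranks[i]))
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# A 12-cell fixture with one designed violation per QC rule plus boundary
# cells that must be kept.  Built entirely in code.
make_qc_fixture <- function() {
  n_genes <- 4200L
  genes <- c(sprintf("MT-G%02d", 1:5), "CD3E", "CD3D", "CD3G",
             sprintf("GENE%04d", seq_len(n_genes - 8L)))
  cells <- sprintf("cell%02d", 1:12)
  m <- matrix(0L, n_genes, 12L, dimnames = list(genes, cells))
  fill <- function(cell, n_detected, total, mito = 0L, cd3 = 1L) {
    m[, cell] <<- 0L
    m["CD3E", cell] <<- cd3
    if (mito > 0) m[1:5, cell] <<- c(mito, 0L, 0L, 0L, 0L)
    rest <- total - mito - cd3
    n_rest <- n_detected - (cd3 > 0) - (mito > 0)
    base <- rest %/% n_rest
    extra <- rest %% n_rest
    counts <- rep(base, n_rest)
    if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
    m[8L + seq_len(n_rest), cell] <<- counts
  }
  fill("cell01", 1000L, 8000L, mito = 0L)          # clean keeper
  fill("cell02", 1000L, 8000L, mito = 960L)        # mito 12% -> removed
  fill("cell03", 249L, 2000L)                      # 249 genes -> removed
  fill("cell04", 4001L, 9000L)                     # 4001 genes -> removed
  fill("cell05", 1000L, 25001L)                    # 25001 UMI -> removed
  fill("cell06", 1000L, 8000L, cd3 = 0L)           # CD3-null -> removed
  fill("cell07", 1000L, 8000L)                     # 2-beta multiplet below
  fill("cell08", 250L, 2000L)                      # boundary: kept
  fill("cell09", 1000L, 25000L)                    # boundary: kept
  fill("cell10", 1000L, 10000L, mito = 1000L)      # boundary mito 10%: kept
  fill("cell11", 4000L, 9000L)                     # boundary: kept
  fill("cell12", 1000L, 8000L)                     # clean keeper
  contigs <- contig_df(
    contig_row("cell07", "TRB", "TGTGCCAAA"),
    contig_row("cell07", "TRB", "TGTGCCCCC"),
    contig_row("cell12", "TRB", "TGTGCCGGG"),
    contig_row("cell12", "TRA", "TGTGCAAAA"),
    contig_row("cell12", "TRA", "TGTGCACCC"))
  list(expr = expression_matrix(m, genes, cells), contigs = contigs)
}

# Small simulated dataset written to disk plus a ready pipeline config.
make_pipeline_fixture <- function(dir, seed = 21L, sf_bias = 0.9) {
  cfg <- sim_config(n_cells_pb = 200L, n_cells_sf = 200L, n_genes = 1000L,
                    n_expanded_clones = 6L, expanded_size_mean = 10,
                    sf_bias = sf_bias, seed = seed)
  ds <- generate_dataset(cfg)
  write_dataset(ds, dir)
  module_file <- file.path(dir, "module.txt")
  writeLines(ds$truth$module_genes, module_file)
  config <- list(
    expression = file.path(dir, "expression"),
    contigs = file.path(dir, "contigs.csv"),
    meta = file.path(dir, "meta.tsv"),
    hto = file.path(dir, "hto"),
    module_file = module_file,
    out_dir = file.path(dir, "out"),
    seed = seed)
  list(ds = ds, config = config)
}
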