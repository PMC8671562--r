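#' Configuration for the synthetic two-compartment dataset
#'
#' Builds and validates the parameter set for [generate_dataset()].  The
#' defaults describe a two-patient-style experiment: a few thousand sorted
#' T cells split between peripheral blood (PB) and synovial fluid (SF),
#' clustered negative-binomial expression with mitochondrial genes and CD3
#' / CD4 / CD8 markers, hashtag counts with doublets, and a TCR repertoire
#' of singleton background clones plus a handful of expanded clones whose
#' members preferentially land in SF.
#'
#' @param n_cells_pb,n_cells_sf Cells per compartment (defaults 1250/1250).
#' @param n_genes Total genes, including the named marker and mitochondrial
#'   genes (default 1000).
#' @param n_clusters Number of transcriptional clusters (default 4); the
#'   first cluster carries the elevated gene module.
#' @param marker_fold Expression fold for each cluster's marker genes
#'   (default 4; must be >= 1).
#' @param n_markers_per_cluster Marker genes per cluster (default 10).
#' @param module_size,module_fold Size (default 20) and elevation fold
#'   (default 2) of the planted gene module.
#' @param mito_gene_count Number of `MT-` prefixed genes (default 10).
#' @param mito_target_frac Typical mitochondrial UMI fraction for a clean
#'   cell (default 0.05).
#' @param nb_dispersion NB size parameter shared by all genes (default 2;
#'   variance `mu + mu^2/size`).
#' @param n_expanded_clones Number of planted expanded clones (default 10).
#' @param expanded_size_mean Mean clone size of expanded clones, geometric
#'   law shifted to a minimum of 1 (default 20; must be >= 3).
#' @param sf_bias Probability that an expanded-clone cell lands in SF
#'   (default 0.9; 0.5 is the null).
#' @param n_hashtags Number of hashtag oligos (default 2: one tagged
#'   population per pooled sample, the minimal design that both identifies
#'   the tagged cells and lets cross-tag doublets be flagged).
#' @param hto_signal_mean,hto_background_mean NB means for a cell's own
#'   tag(s) and for the ambient background (defaults 200 and 4).
#' @param hto_dispersion NB size for hashtag counts (default 10).
#' @param doublet_rate Fraction of cells carrying signal on two tags
#'   (default 0.05).
#' @param qc_violation_rates Named list of per-rule violation
#'   probabilities: `high_mito`, `low_genes`, `high_genes`, `high_umi`,
#'   `multi_beta` (defaults 0.02/0.02/0.01/0.01/0.02).
#' @param seed Integer seed; identical config + seed reproduces the
#'   dataset bit for bit.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_cells_pb = 1250L, n_cells_sf = 1250L,
                       n_genes = 1000L, n_clusters = 4L,
                       marker_fold = 4, n_markers_per_cluster = 10L,
                       module_size = 20L, module_fold = 2,
                       mito_gene_count = 10L, mito_target_frac = 0.05,
                       nb_dispersion = 2,
                       n_expanded_clones = 10L, expanded_size_mean = 20,
                       sf_bias = 0.9,
                       n_hashtags = 2L, hto_signal_mean = 200,
                       hto_background_mean = 4, hto_dispersion = 10,
                       doublet_rate = 0.05,
                       qc_violation_rates = list(high_mito = 0.02,
                                                low_genes = 0.02,
                                                high_genes = 0.01,
                                                high_umi = 0.01,
                                                multi_beta = 0.02),
                       seed = 1L) {
  cfg <- as.list(environment())
  probs <- c(sf_bias, doublet_rate, unlist(qc_violation_rates),
             mito_target_frac)
  if (any(probs < 0 | probs > 1))
    stop("sim_config: probabilities must lie in [0, 1]", call. = FALSE)
  if (n_cells_pb < 1 || n_cells_sf < 1 || n_genes < 1)
    stop("sim_config: sizes must be positive", call. = FALSE)
  if (marker_fold < 1)
    stop("sim_config: marker_fold must be >= 1", call. = FALSE)
  if (n_expanded_clones > 0 && expanded_size_mean < 3)
    stop("sim_config: expanded_size_mean must be >= 3", call. = FALSE)
  if (nb_dispersion <= 0 || hto_dispersion <= 0)
    stop("sim_config: dispersions must be > 0", call. = FALSE)
  n_named <- mito_gene_count + 9L +
    n_clusters * n_markers_per_cluster + module_size
  if (n_genes < n_named)
    stop("sim_config: n_genes too small for the named/marker/module genes (",
         n_named, " needed)", call. = FALSE)
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

# Deterministic per-component sub-seed so that adding or reordering
# generator components never perturbs the random stream of the others.
.sub_seed <- function(seed, key) {
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)) * 131L)
  as.integer((as.double(seed) * 7919 + h) %% (.Machine$integer.max - 1))
}

.with_seed <- function(seed, expr) {
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  expr
}

# Random in-frame CDR3 nucleotide string: length a multiple of 3 in
# [30, 60], uniform over codons.
.random_cdr3 <- function(n) {
  len <- 3L * sample(10:20, n, replace = TRUE)
  vapply(len, function(l)
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = ""),
    character(1))
}

# Minimal standard-code translation for the cosmetic cdr3_aa field.
.codon_table <- local({
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
  stats::setNames(aa, codons)
})
.translate_nt <- function(nt) {
  vapply(nt, function(s) {
    cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    paste(.codon_table[cods], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Generate a truth-labelled synthetic dataset
#'
#' Produces an expression matrix, cell metadata, TCR contigs, hashtag
#' counts and a truth table with the statistical structure the analysis
#' pipeline assumes (see [sim_config()]).  Identical config + seed yields
#' bit-identical output.  QC-violation truth flags are derived from the
#' realized per-cell metrics against the standard thresholds, so the truth
#' table is always consistent with the emitted data.
#'
#' @param config A [sim_config()] object.
#' @return A list `expr` (genes x cells counts), `meta` (cell metadata with
#'   cluster labels), `contigs` (contig data frame), `hto` (hashtags x
#'   cells counts), `truth` (list: `clones`, `cells`, `module_cluster`,
#'   `module_genes`, `seed`), `config`.
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "sim_config"))
    stop("generate_dataset: config must come from sim_config()",
         call. = FALSE)
  cfg <- config
  n_total <- cfg$n_cells_pb + cfg$n_cells_sf
  barcodes <- sprintf("CELL%06d-1", seq_len(n_total))
  compartment <- rep(c("PB", "SF"), c(cfg$n_cells_pb, cfg$n_cells_sf))

  ## ---- gene universe ------------------------------------------------
  mito_genes <- if (cfg$mito_gene_count > 0)
    sprintf("MT-G%02d", seq_len(cfg$mito_gene_count)) else character(0)
  named_genes <- c("CD3E", "CD3D", "CD3G", "CD4", "CD8A", "CD8B", "CD14",
                   "TRBV9", "TRAV1-2")
  n_special <- length(mito_genes) + length(named_genes)
  n_rest <- cfg$n_genes - n_special
  rest_genes <- sprintf("GENE%04d", seq_len(n_rest))
  genes <- c(mito_genes, named_genes, rest_genes)
  clusters <- paste0("C", seq_len(cfg$n_clusters))
  marker_idx <- matrix(
    n_special + seq_len(cfg$n_clusters * cfg$n_markers_per_cluster),
    nrow = cfg$n_clusters, byrow = TRUE)
  module_idx <- n_special + cfg$n_clusters * cfg$n_markers_per_cluster +
    seq_len(cfg$module_size)
  module_genes <- genes[module_idx]
  module_cluster <- clusters[1]

  ## ---- per-gene baseline means -------------------------------------
  base_mu <- .with_seed(.sub_seed(cfg$seed, "gene-means"), {
    mu <- exp(stats::rnorm(cfg$n_genes, mean = log(0.4), sd = 1.2))
    mu
  })
  names(base_mu) <- genes
  base_mu[c("CD3E", "CD3D", "CD3G")] <- 5
  base_mu["CD4"] <- 3
  base_mu[c("CD8A", "CD8B")] <- 0.05
  base_mu["CD14"] <- 0.02
  if (length(mito_genes)) {
    other_sum <- sum(base_mu[-seq_along(mito_genes)])
    base_mu[mito_genes] <- cfg$mito_target_frac /
      (1 - cfg$mito_target_frac) * other_sum / length(mito_genes)
  }

  ## ---- cluster assignment ------------------------------------------
  cluster <- .with_seed(.sub_seed(cfg$seed, "clusters"),
                        sample(clusters, n_total, replace = TRUE))

  ## ---- expression counts -------------------------------------------
  counts <- .with_seed(.sub_seed(cfg$seed, "expression"), {
    m <- matrix(0L, cfg$n_genes, n_total)
    for (k in seq_len(cfg$n_clusters)) {
      mu_k <- base_mu
      mu_k[marker_idx[k, ]] <- mu_k[marker_idx[k, ]] * cfg$marker_fold
      if (clusters[k] == module_cluster)
        mu_k[module_idx] <- mu_k[module_idx] * cfg$module_fold
      cells_k <- which(cluster == clusters[k])
      if (!length(cells_k)) next
      m[, cells_k] <- stats::rnbinom(cfg$n_genes * length(cells_k),
                                     mu = mu_k, size = cfg$nb_dispersion)
    }
    m
  })

  ## ---- QC violations -----------------------------------------------
  rates <- cfg$qc_violation_rates
  viol <- .with_seed(.sub_seed(cfg$seed, "qc-violations"), {
    pool <- seq_len(n_total)
    pick <- function(rate) {
      n <- round(rate * n_total)
      chosen <- if (n > 0 && length(pool) >= n) sample(pool, n)
                else integer(0)
      pool <<- setdiff(pool, chosen)
      chosen
    }
    list(high_mito = pick(rates$high_mito %||% 0),
         low_genes = pick(rates$low_genes %||% 0),
         high_genes = pick(rates$high_genes %||% 0),
         high_umi = pick(rates$high_umi %||% 0),
         multi_beta = pick(rates$multi_beta %||% 0))
  })
  if (length(viol$high_mito) && length(mito_genes)) {
    # push mito fraction well above 10%
    mrows <- seq_along(mito_genes)
    counts[mrows, viol$high_mito] <- counts[mrows, viol$high_mito] * 6L + 2L
  }
  if (length(viol$low_genes)) {
    # near-empty droplets: zero all but a handful of genes
    keep_rows <- .with_seed(.sub_seed(cfg$seed, "low-genes-rows"),
                            sample(cfg$n_genes, min(40L, cfg$n_genes)))
    zero <- setdiff(seq_len(cfg$n_genes), keep_rows)
    counts[zero, viol$low_genes] <- 0L
  }
  if (length(viol$high_genes)) {
    # saturated droplets: every gene detected (only an actual violation
    # when the simulated gene universe exceeds the max-genes threshold)
    counts[, viol$high_genes] <- counts[, viol$high_genes] + 1L
  }
  if (length(viol$high_umi)) {
    counts[, viol$high_umi] <- counts[, viol$high_umi] * 40L
  }
  expr <- expression_matrix(counts, genes, barcodes)

  ## ---- TCR repertoire ----------------------------------------------
  tcr <- .with_seed(.sub_seed(cfg$seed, "tcr"), {
    sizes <- if (cfg$n_expanded_clones > 0)
      1L + stats::rgeom(cfg$n_expanded_clones,
                        prob = 1 / (cfg$expanded_size_mean))
    else integer(0)
    if (sum(sizes) > n_total)
      stop("generate_dataset: expanded-clone cells (", sum(sizes),
           ") exceed total cells (", n_total, ")", call. = FALSE)
    pb_pool <- sample(which(compartment == "PB"))
    sf_pool <- sample(which(compartment == "SF"))
    clone_of <- integer(n_total)   # 0 = background singleton
    for (i in seq_along(sizes)) {
      for (j in seq_len(sizes[i])) {
        want_sf <- stats::runif(1) < cfg$sf_bias
        if (want_sf && length(sf_pool)) {
          clone_of[sf_pool[1]] <- i; sf_pool <- sf_pool[-1]
        } else if (!want_sf && length(pb_pool)) {
          clone_of[pb_pool[1]] <- i; pb_pool <- pb_pool[-1]
        } else if (length(sf_pool)) {
          clone_of[sf_pool[1]] <- i; sf_pool <- sf_pool[-1]
        } else {
          clone_of[pb_pool[1]] <- i; pb_pool <- pb_pool[-1]
        }
      }
    }
    n_bg <- sum(clone_of == 0L)
    n_clones <- cfg$n_expanded_clones + n_bg
    repeat {
      cdr3_a <- .random_cdr3(n_clones)
      cdr3_b <- .random_cdr3(n_clones)
      if (!anyDuplicated(paste(cdr3_a, cdr3_b))) break
    }
    clone_full <- clone_of
    clone_full[clone_of == 0L] <- cfg$n_expanded_clones +
      seq_len(n_bg)
    list(clone_of = clone_full, expanded = clone_of > 0L,
         cdr3_a = cdr3_a, cdr3_b = cdr3_b, sizes = sizes)
  })

  contigs <- .with_seed(.sub_seed(cfg$seed, "contigs"), {
    cl <- tcr$clone_of
    v_a <- sprintf("TRAV%d", sample(1:40, length(tcr$cdr3_a), TRUE))
    j_a <- sprintf("TRAJ%d", sample(1:50, length(tcr$cdr3_a), TRUE))
    v_b <- sprintf("TRBV%d", sample(1:30, length(tcr$cdr3_b), TRUE))
    j_b <- sprintf("TRBJ%d-%d", sample(1:2, length(tcr$cdr3_b), TRUE),
                   sample(1:6, length(tcr$cdr3_b), TRUE))
    df <- rbind(
      data.frame(barcode = barcodes, chain = "TRA",
                 cdr3 = .translate_nt(tcr$cdr3_a[cl]),
                 cdr3_nt = tcr$cdr3_a[cl],
                 v_gene = v_a[cl], j_gene = j_a[cl],
                 productive = TRUE,
                 umis = 1L + stats::rnbinom(n_total, mu = 6, size = 2),
                 stringsAsFactors = FALSE),
      data.frame(barcode = barcodes, chain = "TRB",
                 cdr3 = .translate_nt(tcr$cdr3_b[cl]),
                 cdr3_nt = tcr$cdr3_b[cl],
                 v_gene = v_b[cl], j_gene = j_b[cl],
                 productive = TRUE,
                 umis = 1L + stats::rnbinom(n_total, mu = 8, size = 2),
                 stringsAsFactors = FALSE))
    if (length(viol$multi_beta)) {
      extra_nt <- .random_cdr3(length(viol$multi_beta))
      df <- rbind(df, data.frame(
        barcode = barcodes[viol$multi_beta], chain = "TRB",
        cdr3 = .translate_nt(extra_nt), cdr3_nt = extra_nt,
        v_gene = sprintf("TRBV%d", sample(1:30, length(extra_nt), TRUE)),
        j_gene = "TRBJ1-1", productive = TRUE,
        umis = 1L + stats::rnbinom(length(extra_nt), mu = 8, size = 2),
        stringsAsFactors = FALSE))
    }
    df <- df[order(df$barcode, df$chain, df$cdr3_nt, method = "radix"), ,
             drop = FALSE]
    rownames(df) <- NULL
    df
  })

  ## ---- hashtag counts ----------------------------------------------
  hto_truth <- .with_seed(.sub_seed(cfg$seed, "hto"), {
    tags <- sprintf("HTO%d", seq_len(cfg$n_hashtags))
    true_tag <- sample(tags, n_total, replace = TRUE)
    is_doublet <- stats::runif(n_total) < cfg$doublet_rate
    second <- vapply(seq_len(n_total), function(i) {
      if (!is_doublet[i] || cfg$n_hashtags < 2) return(NA_character_)
      sample(setdiff(tags, true_tag[i]), 1)
    }, character(1))
    m <- matrix(stats::rnbinom(cfg$n_hashtags * n_total,
                               mu = cfg$hto_background_mean,
                               size = cfg$hto_dispersion),
                cfg$n_hashtags, n_total, dimnames = list(tags, barcodes))
    sig <- function(n) stats::rnbinom(n, mu = cfg$hto_signal_mean,
                                      size = cfg$hto_dispersion)
    for (t in seq_along(tags)) {
      own <- which(true_tag == tags[t] | (!is.na(second) &
                                            second == tags[t]))
      m[t, own] <- sig(length(own))
    }
    list(counts = m, true_tag = true_tag,
         true_class = ifelse(is_doublet & cfg$n_hashtags >= 2,
                             "doublet", "singlet"))
  })

  ## ---- assemble metadata and truth ---------------------------------
  meta <- data.frame(
    barcode = barcodes,
    sample_id = paste0("P1_", compartment),
    compartment = compartment,
    patient = "P1",
    cluster = cluster,
    stringsAsFactors = FALSE)

  chains <- collapse_chains(contigs)
  metrics <- compute_qc_metrics(expr, chains)
  th <- qc_thresholds("AS")
  cells_truth <- data.frame(
    barcode = barcodes,
    compartment = compartment,
    cluster = cluster,
    clone_index = tcr$clone_of,
    expanded_clone = tcr$expanded,
    true_hashtag = hto_truth$true_tag,
    true_hto_class = hto_truth$true_class,
    viol_high_mito = metrics$mito_frac > th$max_mito_frac,
    viol_low_genes = metrics$n_genes < th$min_genes,
    viol_high_genes = metrics$n_genes > th$max_genes,
    viol_high_umi = metrics$n_umi > th$max_umi,
    viol_multi_beta = metrics$n_beta > th$max_beta_chains,
    stringsAsFactors = FALSE)

  clone_ids <- paste(tcr$cdr3_a, tcr$cdr3_b, sep = "|")
  idx_by_clone <- split(seq_len(n_total), tcr$clone_of)
  clones_truth <- data.frame(
    clone_index = as.integer(names(idx_by_clone)),
    clone_id = clone_ids[as.integer(names(idx_by_clone))],
    size = lengths(idx_by_clone),
    n_pb = vapply(idx_by_clone, function(i) sum(compartment[i] == "PB"),
                  integer(1)),
    n_sf = vapply(idx_by_clone, function(i) sum(compartment[i] == "SF"),
                  integer(1)),
    expanded = as.integer(names(idx_by_clone)) <= cfg$n_expanded_clones,
    stringsAsFactors = FALSE)
  clones_truth$biased <- clones_truth$expanded & cfg$sf_bias != 0.5
  clones_truth <- clones_truth[order(clones_truth$clone_index), ,
                               drop = FALSE]
  rownames(clones_truth) <- NULL

  list(expr = expr, meta = meta, contigs = contigs,
       hto = hto_truth$counts,
       truth = list(clones = clones_truth, cells = cells_truth,
                    module_cluster = module_cluster,
                    module_genes = module_genes, seed = cfg$seed),
       config = cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Lazy iterator over independent null replicates
#'
#' For type-I-error / FDR studies: requires a null configuration
#' (`sf_bias = 0.5`, so no compartment bias is planted) and yields
#' replicate `r` generated with `seed = base_seed + r`.  Replicates are
#' generated on demand via `$get(r)`.
#'
#' @param config A [sim_config()] with `sf_bias = 0.5`.
#' @param n_reps Number of replicates (> 0).
#' @return A list with `n_reps`, `seeds`, and `get(r)` returning the r-th
#'   dataset.
#' @export
generate_null_replicates <- function(config, n_reps) {
  if (!inherits(config, "sim_config"))
    stop("generate_null_replicates: config must come from sim_config()",
         call. = FALSE)
  if (config$sf_bias != 0.5)
    stop("generate_null_replicates: null replicates require sf_bias = 0.5",
         call. = FALSE)
  if (n_reps <= 0)
    stop("generate_null_replicates: n_reps must be positive", call. = FALSE)
  seeds <- config$seed + seq_len(n_reps)
  list(n_reps = as.integer(n_reps), seeds = seeds,
       get = function(r) {
         stopifnot(r >= 1, r <= n_reps)
         cfg <- config
         cfg$seed <- seeds[r]
         generate_dataset(cfg)
       })
}

#' Write a generated dataset to disk in the standard formats
#'
#' Emits exactly the formats the readers consume: the expression matrix as
#' a Matrix Market triplet (`expression/`), contigs as a 10x-style CSV,
#' metadata and truth tables as TSV, hashtag counts as a second MTX
#' triplet (`hto/`), and the generating configuration as YAML.
#'
#' @param dataset Output of [generate_dataset()].
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression(dataset$expr, file.path(dir, "expression"))
  ct <- dataset$contigs
  ct$productive <- ifelse(ct$productive, "True", "False")
  utils::write.csv(ct, file.path(dir, "contigs.csv"), row.names = FALSE,
                   quote = FALSE)
  write_table(dataset$meta, file.path(dir, "meta.tsv"))
  write_expression(dataset$hto, file.path(dir, "hto"))
  write_table(dataset$truth$clones, file.path(dir, "truth_clones.tsv"))
  write_table(dataset$truth$cells, file.path(dir, "truth_cells.tsv"))
  cfg <- unclass(dataset$config)
  yaml::write_yaml(cfg, file.path(dir, "sim_config.yaml"))
  invisible(dir)
}
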