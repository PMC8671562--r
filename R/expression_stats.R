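#' Library-size normalized log expression
#'
#' Scales each cell to `scale_total` counts and applies the natural
#' `log1p`: `value = ln(1 + count * scale_total / cell_total)`.  Zero
#' counts map exactly to zero and sparsity is preserved.  Setting
#' `scale_total = NULL` skips library-size scaling and returns raw
#' `ln(count + 1)`.
#'
#' @param mat Expression matrix (genes x cells) of counts.
#' @param scale_total Per-cell count target (default 10,000), or `NULL`
#'   for unscaled `log1p`.
#' @return A `dgCMatrix` of normalized values with attribute
#'   `scale_total`.
#' @export
normalize_counts <- function(mat, scale_total = 10000) {
  mat <- methods::as(methods::as(mat, "generalMatrix"), "CsparseMatrix")
  if (is.null(scale_total)) {
    mat@x <- log1p(mat@x)
    attr(mat, "scale_total") <- NA_real_
    return(mat)
  }
  totals <- Matrix::colSums(mat)
  if (any(totals == 0))
    stop("normalize_counts: cell(s) with zero total counts (",
         paste(utils::head(colnames(mat)[totals == 0], 3), collapse = ", "),
         "); run QC filtering first", call. = FALSE)
  # scale columns: entry j of @x belongs to the column found via @p
  col_of <- rep.int(seq_len(ncol(mat)), diff(mat@p))
  mat@x <- log1p(mat@x * scale_total / totals[col_of])
  attr(mat, "scale_total") <- scale_total
  mat
}

# Exact two-sided rank-sum p-value by dynamic programming over the
# multiset of (doubled, so integer) average ranks.  Counts the subsets of
# size n1 whose rank sum deviates from its permutation-null expectation by
# at least the observed deviation.  Handles ties; valid for any group
# sizes, at a cost growing with n1 * (sum of ranks).
.ranksum_exact_p <- function(r2, n1, w2) {
  S <- sum(r2)
  f <- matrix(0, S + 1L, n1 + 1L)
  f[1L, 1L] <- 1
  for (r in r2) {
    if (r == 0L) next
    f[(r + 1L):(S + 1L), 2L:(n1 + 1L)] <-
      f[(r + 1L):(S + 1L), 2L:(n1 + 1L)] + f[1L:(S - r + 1L), 1L:n1]
  }
  counts <- f[, n1 + 1L]
  mu2 <- n1 * S / length(r2)
  dev <- abs(seq.int(0L, S) - mu2)
  sum(counts[dev >= abs(w2 - mu2) - 1e-9]) / sum(counts)
}

# Normal-approximation two-sided rank-sum p with tie-corrected variance,
# no continuity correction.
.ranksum_normal_p <- function(ranks, n1, w) {
  N <- length(ranks)
  n2 <- N - n1
  mu <- n1 * (N + 1) / 2
  ties <- table(ranks)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  v <- n1 * n2 / 12 * ((N + 1) - tie_term)
  if (v <= 0) return(1)
  2 * stats::pnorm(-abs(w - mu) / sqrt(v))
}

#' Wilcoxon rank-sum differential expression between two cell groups
#'
#' For every gene detected in at least `min_pct` of cells in one of the
#' groups, computes a two-sided Wilcoxon rank-sum p-value on the
#' normalized values (average ranks for ties; exact enumeration when both
#' groups have at most `exact_max` cells, otherwise a normal approximation
#' with tie-corrected variance), the log fold change
#' `ln(mean(expm1(A)) + 1) - ln(mean(expm1(B)) + 1)`, the detection
#' fractions, and a Bonferroni-adjusted p-value over `m_total` tests
#' (default: all genes in the matrix, matching the convention that
#' correction spans the whole transcriptome rather than only the genes
#' passing the detection floor).
#'
#' @param norm Normalized matrix from [normalize_counts()].
#' @param cells_a,cells_b Disjoint barcode vectors, each of at least 3
#'   cells.
#' @param min_pct Detection floor: test genes with
#'   `max(pct_a, pct_b) >= min_pct` (default 0.10).
#' @param m_total Bonferroni denominator (default `nrow(norm)`).
#' @param exact_max Use the exact null distribution when both group sizes
#'   are at most this (default 8); set to `Inf` to force exact mode.
#' @return Data frame `gene`, `log_fc`, `pct_a`, `pct_b`, `p`, `p_adj`,
#'   ordered by ascending `p` then gene id.
#' @export
wilcoxon_de <- function(norm, cells_a, cells_b, min_pct = 0.10,
                        m_total = nrow(norm), exact_max = 8L) {
  if (length(intersect(cells_a, cells_b)))
    stop("wilcoxon_de: groups overlap", call. = FALSE)
  if (length(cells_a) < 3L || length(cells_b) < 3L)
    stop("wilcoxon_de: each group needs at least 3 cells", call. = FALSE)
  missing <- setdiff(c(cells_a, cells_b), colnames(norm))
  if (length(missing))
    stop("wilcoxon_de: barcode(s) not in matrix: ",
         paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
  A <- as.matrix(norm[, cells_a, drop = FALSE])
  B <- as.matrix(norm[, cells_b, drop = FALSE])
  n1 <- ncol(A); n2 <- ncol(B)
  pct_a <- rowMeans(A > 0)
  pct_b <- rowMeans(B > 0)
  tested <- which(pmax(pct_a, pct_b) >= min_pct)
  exact <- n1 <= exact_max && n2 <= exact_max
  res <- lapply(tested, function(g) {
    va <- A[g, ]; vb <- B[g, ]
    ranks <- rank(c(va, vb))
    w <- sum(ranks[seq_len(n1)])
    p <- if (exact) {
      .ranksum_exact_p(as.integer(round(2 * ranks)), n1,
                       as.integer(round(2 * w)))
    } else .ranksum_normal_p(ranks, n1, w)
    lfc <- log(mean(expm1(va)) + 1) - log(mean(expm1(vb)) + 1)
    c(lfc, p)
  })
  res <- do.call(rbind, res)
  out <- data.frame(
    gene = rownames(norm)[tested],
    log_fc = if (length(tested)) res[, 1] else numeric(0),
    pct_a = pct_a[tested],
    pct_b = pct_b[tested],
    p = if (length(tested)) res[, 2] else numeric(0),
    stringsAsFactors = FALSE)
  out$p_adj <- pmin(1, out$p * m_total)
  out <- out[order(out$p, out$gene, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter a differential-expression table for reporting
#'
#' Keeps genes with `|log_fc|` strictly greater than `log_fc_cut`, flags
#' significance at adjusted p strictly below `alpha`, and optionally
#' removes TCR variable-chain genes (ids starting TRAV/TRBV/TRAJ/TRBJ), as
#' is conventional when the groups being compared were themselves defined
#' by their TCR.
#'
#' @param results Output of [wilcoxon_de()].
#' @param log_fc_cut Fold-change cut (default 0.25, natural log).
#' @param alpha Significance level on `p_adj` (default 0.05).
#' @param drop_tcr_genes Remove TCR variable-chain genes.
#' @return Filtered data frame with an added logical `significant` column.
#' @export
report_filter <- function(results, log_fc_cut = 0.25, alpha = 0.05,
                          drop_tcr_genes = FALSE) {
  out <- results[abs(results$log_fc) > log_fc_cut, , drop = FALSE]
  if (drop_tcr_genes)
    out <- out[!grepl("^TR[AB][VJ]", out$gene), , drop = FALSE]
  out$significant <- out$p_adj < alpha
  rownames(out) <- NULL
  out
}

#' Gene-module score with expression-matched controls
#'
#' Per-cell score of a gene set relative to expression-matched control
#' genes: all genes are binned into `n_bins` of equal size by their average
#' normalized expression across cells; for each module gene, `n_ctrl`
#' control genes are drawn (with replacement, using `seed`) from the same
#' bin; the score is the mean normalized expression of the module genes
#' minus the mean over all control draws.  Under an exchangeable null the
#' score is centred on zero.
#'
#' @param norm Normalized matrix from [normalize_counts()].
#' @param module_genes Character vector of module gene ids; ids absent from
#'   the matrix are dropped with a warning; an empty module is an error.
#' @param n_bins Number of average-expression bins (default 24).
#' @param n_ctrl Control draws per module gene (default 100).
#' @param seed Seed for the control draws.
#' @return Named numeric vector of per-cell scores (names = barcodes) with
#'   attributes `module_genes`, `n_bins`, `n_ctrl`, `seed`.
#' @export
module_score <- function(norm, module_genes, n_bins = 24L, n_ctrl = 100L,
                         seed = 1L) {
  present <- intersect(module_genes, rownames(norm))
  absent <- setdiff(module_genes, present)
  if (length(absent))
    warning("module_score: dropping ", length(absent),
            " module gene(s) absent from the matrix", call. = FALSE)
  if (!length(present))
    stop("module_score: no module genes present in the matrix",
         call. = FALSE)
  n_bins <- min(n_bins, nrow(norm))
  avg <- Matrix::rowMeans(norm)
  # equal-occupancy bins on the rank of the average expression
  bin <- ceiling(rank(avg, ties.method = "first") * n_bins / length(avg))
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  ctrl <- unlist(lapply(present, function(g) {
    pool <- which(bin == bin[[match(g, rownames(norm))]])
    pool[sample.int(length(pool), n_ctrl, replace = TRUE)]
  }))
  module_mean <- Matrix::colMeans(norm[present, , drop = FALSE])
  ctrl_mean <- Matrix::colMeans(norm[ctrl, , drop = FALSE])
  score <- as.numeric(module_mean - ctrl_mean)
  names(score) <- colnames(norm)
  attributes(score) <- c(attributes(score),
                         list(module_genes = present, n_bins = n_bins,
                              n_ctrl = n_ctrl, seed = seed))
  score
}

#' Two-proportion z-test of cluster composition between compartments
#'
#' For each cluster, compares the fraction of PB cells falling in the
#' cluster with the fraction of SF cells falling in it, using the pooled
#' two-proportion z statistic
#' `z = (x1/n1 - x2/n2) / sqrt(phat (1 - phat) (1/n1 + 1/n2))` with
#' `phat = (x1 + x2)/(n1 + n2)`, two-sided normal p-value, no continuity
#' correction and no multiplicity correction.
#'
#' @param meta Cell metadata with `compartment` (PB/SF) and `cluster` for
#'   every cell.
#' @return Data frame `cluster`, `n_pb`, `n_sf`, `prop_pb`, `prop_sf`,
#'   `z`, `p`, one row per cluster present.
#' @export
cluster_compartment_test <- function(meta) {
  if (is.null(meta$cluster) || any(is.na(meta$cluster)))
    stop("cluster_compartment_test: every cell needs a cluster label",
         call. = FALSE)
  n1 <- sum(meta$compartment == "PB")
  n2 <- sum(meta$compartment == "SF")
  clusters <- sort(unique(as.character(meta$cluster)), method = "radix")
  rows <- lapply(clusters, function(cl) {
    x1 <- sum(meta$cluster == cl & meta$compartment == "PB")
    x2 <- sum(meta$cluster == cl & meta$compartment == "SF")
    if (x1 + x2 == 0L) {
      warning("cluster_compartment_test: cluster ", cl,
              " has no cells; skipped", call. = FALSE)
      return(NULL)
    }
    phat <- (x1 + x2) / (n1 + n2)
    se <- sqrt(phat * (1 - phat) * (1 / n1 + 1 / n2))
    z <- if (se > 0) (x1 / n1 - x2 / n2) / se else 0
    data.frame(cluster = cl, n_pb = x1, n_sf = x2,
               prop_pb = x1 / n1, prop_sf = x2 / n2,
               z = z, p = 2 * stats::pnorm(-abs(z)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pairwise Spearman correlation of selected genes
#'
#' Average-rank Spearman rho for every gene pair across cells.  The
#' diagonal is 1 by definition; a zero-variance gene has undefined rho
#' with every other gene, reported as `NA`.
#'
#' @param norm Normalized matrix from [normalize_counts()].
#' @param genes Gene ids to correlate (at least 2, present in the matrix);
#'   requires at least 3 cells.
#' @return Symmetric matrix of rho values with the genes as dimnames.
#' @export
spearman_pairs <- function(norm, genes) {
  missing <- setdiff(genes, rownames(norm))
  if (length(missing))
    stop("spearman_pairs: gene(s) not in matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (ncol(norm) < 3L)
    stop("spearman_pairs: need at least 3 cells", call. = FALSE)
  x <- t(as.matrix(norm[genes, , drop = FALSE]))
  rho <- suppressWarnings(stats::cor(x, method = "spearman"))
  diag(rho) <- 1
  rho
}
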