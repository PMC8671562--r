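test_that("normalization matches the ln(1 + count * scale / total) rule", {
  m <- tiny_expr(matrix(c(1, 1, 2), ncol = 1))
  norm <- normalize_counts(m, scale_total = 10000)
  expect_equal(as.numeric(norm[, 1]),
               c(log(2501), log(2501), log(5001)))
  # scale invariance: doubling every count in a cell changes nothing
  norm2 <- normalize_counts(tiny_expr(matrix(c(2, 2, 4), ncol = 1)))
  expect_equal(as.matrix(norm), as.matrix(norm2), ignore_attr = TRUE)
  # zeros map to zeros (sparsity preserved)
  m3 <- tiny_expr(matrix(c(0, 5, 0, 3), 2))
  expect_equal(Matrix::nnzero(normalize_counts(m3)), 2)
  # zero-total cell is a data error pointing at QC
  expect_error(normalize_counts(tiny_expr(matrix(c(1, 0), 1))), "QC")
})

test_that("identical groups give log_fc 0 and p 1 everywhere", {
  set.seed(1)
  m <- tiny_expr(matrix(rpois(80, 5), 8, 10))
  dup <- cbind(as.matrix(m), as.matrix(m))
  colnames(dup) <- c(paste0("a", 1:10), paste0("b", 1:10))
  normd <- normalize_counts(tiny_expr(dup, genes = rownames(m),
                                      cells = colnames(dup)))
  resd <- wilcoxon_de(normd, paste0("a", 1:10), paste0("b", 1:10),
                      min_pct = 0, exact_max = 0)
  expect_equal(resd$log_fc, rep(0, nrow(resd)))
  expect_equal(resd$p, rep(1, nrow(resd)))
})

test_that("exact p equals full labelling enumeration (n = 4 + 4)", {
  set.seed(23)
  for (i in 1:20) {
    va <- sample(0:4, 4, replace = TRUE) + stats::runif(4) * (i %% 2)
    vb <- sample(0:6, 4, replace = TRUE) + stats::runif(4) * (i %% 2)
    m <- tiny_expr(matrix(c(va, vb), 1), genes = "G1",
                   cells = sprintf("c%d", 1:8))
    res <- wilcoxon_de(normalize_counts(m, scale_total = NULL),
                       sprintf("c%d", 1:4), sprintf("c%d", 5:8),
                       min_pct = 0)
    ora <- ranksum_enum_oracle(log1p(va), log1p(vb))
    expect_equal(res$p, ora, tolerance = 1e-12,
                 info = paste(c(va, vb), collapse = ","))
  }
})

test_that("swapping group labels negates log_fc and preserves p", {
  set.seed(9)
  m <- tiny_expr(matrix(rpois(200, 4), 10, 20))
  norm <- normalize_counts(m)
  a <- colnames(m)[1:10]; b <- colnames(m)[11:20]
  r1 <- wilcoxon_de(norm, a, b, min_pct = 0)
  r2 <- wilcoxon_de(norm, b, a, min_pct = 0)
  r2 <- r2[match(r1$gene, r2$gene), ]
  expect_equal(r1$log_fc, -r2$log_fc)
  expect_equal(r1$p, r2$p)
  expect_equal(r1$pct_a, r2$pct_b)
})

test_that("the 10% detection floor removes rarely expressed genes", {
  m <- matrix(0, 2, 40)
  m[1, c(1, 21)] <- 5      # 5% in both groups: not tested
  m[2, 1:40] <- rpois(40, 3) + 1
  e <- tiny_expr(m)
  res <- wilcoxon_de(normalize_counts(e), colnames(e)[1:20],
                     colnames(e)[21:40], min_pct = 0.10, exact_max = 0)
  expect_false("G01" %in% res$gene)
  expect_true("G02" %in% res$gene)
  # Bonferroni uses the full gene count of the matrix by default
  expect_equal(res$p_adj, pmin(1, res$p * 2))
})

test_that("overlapping or undersized groups are data errors", {
  m <- tiny_expr(matrix(rpois(40, 4) + 1, 4, 10))
  norm <- normalize_counts(m)
  expect_error(wilcoxon_de(norm, colnames(m)[1:5], colnames(m)[5:9]),
               "overlap")
  expect_error(wilcoxon_de(norm, colnames(m)[1:2], colnames(m)[3:9]),
               "at least 3")
})

test_that("report filter applies strict cuts and TCR-gene removal", {
  res <- data.frame(
    gene = c("TIGIT", "TRBV9", "KLRB1", "FOXP3"),
    log_fc = c(0.30, 0.80, -0.26, 0.25),
    pct_a = 0.5, pct_b = 0.5,
    p = c(1e-4, 1e-6, 1e-3, 0.2), p_adj = c(0.01, 1e-4, 0.04, 1),
    stringsAsFactors = FALSE)
  out <- report_filter(res)
  expect_setequal(out$gene, c("TIGIT", "TRBV9", "KLRB1"))  # 0.25 strict
  expect_true(all(out$significant[out$gene %in% c("TIGIT", "TRBV9")]))
  out2 <- report_filter(res, drop_tcr_genes = TRUE)
  expect_false("TRBV9" %in% out2$gene)
  expect_equal(nrow(report_filter(res[0, ])), 0L)
})

test_that("module score is zero under constant expression, reproducible", {
  m <- tiny_expr(matrix(3, 50, 12))
  norm <- normalize_counts(m)
  s <- module_score(norm, rownames(m)[1:5], seed = 4)
  expect_equal(as.numeric(s), rep(0, 12))
  set.seed(1)
  m2 <- tiny_expr(matrix(rpois(50 * 12, 4), 50, 12))
  n2 <- normalize_counts(m2)
  s1 <- module_score(n2, rownames(m2)[1:5], seed = 4)
  s2 <- module_score(n2, rownames(m2)[1:5], seed = 4)
  expect_identical(s1, s2)
  expect_warning(module_score(n2, c(rownames(m2)[1], "NOPE"), seed = 1),
                 "absent")
  expect_error(suppressWarnings(module_score(n2, c("NOPE1", "NOPE2"),
                                             seed = 1)),
               "no module genes")
})

test_that("planted module elevation ranks its cluster first", {
  cfg <- sim_config(n_cells_pb = 150, n_cells_sf = 150, n_genes = 400,
                    module_fold = 2, seed = 42)
  ds <- generate_dataset(cfg)
  keep <- Matrix::colSums(ds$expr) > 0
  norm <- normalize_counts(ds$expr[, keep])
  s <- module_score(norm, ds$truth$module_genes, seed = 42)
  means <- tapply(s, ds$meta$cluster[match(names(s), ds$meta$barcode)],
                  mean)
  expect_equal(names(which.max(means)), ds$truth$module_cluster)
})

test_that("cluster compartment z-test matches its closed form", {
  meta <- tiny_meta(sprintf("c%03d", 1:200),
                    rep(c("PB", "SF"), each = 100),
                    cluster = c(rep("C1", 30), rep("C2", 70),
                                rep("C1", 60), rep("C2", 40)))
  res <- cluster_compartment_test(meta)
  # closed-form oracle for C1: x1=30 n1=100, x2=60 n2=100
  phat <- 90 / 200
  z <- (0.3 - 0.6) / sqrt(phat * (1 - phat) * (1 / 100 + 1 / 100))
  expect_equal(res$z[res$cluster == "C1"], z)
  expect_equal(res$p[res$cluster == "C1"], 2 * pnorm(-abs(z)))
  # z^2 equals the uncorrected 1-df chi-square statistic
  tab <- matrix(c(30, 70, 60, 40), 2, byrow = TRUE)
  chi <- suppressWarnings(chisq.test(tab, correct = FALSE))$statistic
  expect_equal(res$z[res$cluster == "C1"]^2, unname(chi))
  # equal proportions: z = 0, p = 1
  meta2 <- tiny_meta(sprintf("d%02d", 1:40), rep(c("PB", "SF"), 20),
                     cluster = rep(c("A", "B"), each = 20))
  res2 <- cluster_compartment_test(meta2)
  expect_equal(res2$z, c(0, 0))
  expect_equal(res2$p, c(1, 1))
})

test_that("Spearman pairs: identity, monotone pairs, ties, zero variance", {
  x <- c(1, 3, 2, 7, 5, 5, 0, 9, 4, 6)
  m <- rbind(A = x, B = exp(x), C = c(2, 1, 4, 3, 6, 5, 8, 7, 9, 10),
             D = rep(2, 10))
  e <- tiny_expr(m, genes = rownames(m))
  norm <- normalize_counts(e, scale_total = NULL)
  rho <- spearman_pairs(norm, c("A", "B", "C", "D"))
  expect_equal(rho["A", "A"], 1)
  expect_equal(rho["A", "B"], 1)   # monotone transform
  # oracle: Pearson correlation of average ranks
  r_ac <- cor(rank(x), rank(m["C", ]))
  expect_equal(rho["A", "C"], r_ac)
  expect_true(is.na(rho["A", "D"]))   # zero-variance gene
  expect_equal(rho["D", "D"], 1)      # self-correlation defined as 1
})
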