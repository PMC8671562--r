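test_that("chain collapse keeps distinct productive CDR3s only", {
  contigs <- contig_df(
    contig_row("c1", "TRB", "TGTAAA"),
    contig_row("c1", "TRB", "TGTAAA"),                      # duplicate
    contig_row("c2", "TRA", "TGTCCC"),
    contig_row("c2", "TRA", "TGTGGG", productive = FALSE))  # ignored
  ch <- collapse_chains(contigs)
  expect_equal(ch$n_beta[ch$barcode == "c1"], 1L)
  expect_equal(ch$betas[ch$barcode == "c1"], "TGTAAA")
  expect_equal(ch$n_alpha[ch$barcode == "c2"], 1L)
  # cell with no productive contigs is absent entirely
  only_bad <- contig_row("c3", "TRA", "TGTTTT", productive = FALSE)
  expect_false("c3" %in% collapse_chains(rbind(contigs, only_bad))$barcode)
})

test_that("clonotype keys group cells with identical chain sets", {
  contigs <- contig_df(
    contig_row("c1", "TRA", "TGTGCAAAA"), contig_row("c1", "TRB", "TGTGCCAAA"),
    contig_row("c2", "TRB", "TGTGCCAAA"), contig_row("c2", "TRA", "TGTGCAAAA"),
    contig_row("c3", "TRA", "TGTGCAAAA"))          # alpha only: excluded
  ct <- call_clonotypes(collapse_chains(contigs), mode = "joint_gex")
  expect_equal(nrow(ct$clones), 1L)
  expect_equal(ct$clones$n_cells, 2L)
  expect_setequal(ct$assignments$barcode, c("c1", "c2"))
  expect_equal(unique(ct$assignments$clone_id), "TGTGCAAAA|TGTGCCAAA")
})

test_that("multiplet handling differs by mode as specified", {
  two_beta <- contig_df(
    contig_row("m1", "TRB", "TGTAAA"), contig_row("m1", "TRB", "TGTCCC"),
    contig_row("m1", "TRA", "TGTGGG"))
  two_alpha <- contig_df(
    contig_row("a1", "TRA", "TGTAAA"), contig_row("a1", "TRA", "TGTCCC"),
    contig_row("a1", "TRB", "TGTGGG"))
  ch <- collapse_chains(rbind(two_beta, two_alpha))
  joint <- call_clonotypes(ch, mode = "joint_gex")
  expect_false("m1" %in% joint$assignments$barcode)   # >1 beta excluded
  expect_true("a1" %in% joint$assignments$barcode)    # 2 alphas allowed
  expect_equal(joint$assignments$clone_id[joint$assignments$barcode == "a1"],
               "TGTAAA;TGTCCC|TGTGGG")
  tab <- call_clonotypes(ch, mode = "clonality_table")
  expect_true("m1" %in% tab$assignments$barcode)      # own multi-beta clone
  expect_equal(tab$assignments$clone_id[tab$assignments$barcode == "m1"],
               "TGTGGG|TGTAAA;TGTCCC")
})

test_that("clone calling is invariant to contig row order", {
  set.seed(11)
  contigs <- contig_df(
    contig_row(rep(sprintf("c%02d", 1:12), each = 2),
               rep(c("TRA", "TRB"), 12),
               paste0("TGT", rep(c("AAA", "CCC", "GGG"), 8))))
  ct1 <- call_clonotypes(collapse_chains(contigs))
  ct2 <- call_clonotypes(collapse_chains(contigs[sample(nrow(contigs)), ]))
  expect_identical(ct1$assignments[order(ct1$assignments$barcode), ],
                   ct2$assignments[order(ct2$assignments$barcode), ])
  expect_identical(ct1$clones, ct2$clones)
})

test_that("two-sided Fisher matches hand enumeration on anchor tables", {
  # margins (3,3)/(3,3): masses {1,9,9,1}/20; two-sided sum = 2/20
  expect_equal(fisher_two_sided(matrix(c(3, 0, 0, 3), 2, 2)), 0.1)
  # degenerate margins
  expect_equal(fisher_two_sided(matrix(0, 2, 2)), 1)
  expect_equal(fisher_two_sided(matrix(c(5, 0, 3, 0), 2, 2)), 1)
})

test_that("Fisher equals the enumeration oracle on random small tables", {
  set.seed(202)
  for (i in 1:300) {
    tab <- matrix(rmultinom(1, sample(0:40, 1), prob = runif(4)), 2, 2)
    p_pkg <- fisher_two_sided(tab)
    p_ora <- fisher_enum_oracle(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    expect_equal(p_pkg, p_ora, tolerance = 1e-12,
                 info = paste(tab, collapse = ","))
  }
})

test_that("BH step-up on anchors, and elementwise dominance", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(bh_adjust(0.03), 0.03)
  set.seed(5)
  p <- runif(50)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  # adjusting already-adjusted values never decreases them
  expect_true(all(bh_adjust(adj) >= adj))
  # order-preserving on sorted input
  expect_true(all(diff(bh_adjust(sort(p))) >= -1e-15))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH agrees with the literal step-up oracle on random vectors", {
  set.seed(77)
  for (i in 1:50) {
    p <- runif(sample(1:200, 1))
    expect_equal(bh_adjust(p), bh_stepup_oracle(p), tolerance = 1e-14)
  }
})

test_that("enrichment eligibility and table construction are exact", {
  # 9 clonotyped cells: clone A = 3 SF cells; 6 SF cells and 3 PB cells
  # total.  Table [[3, 3], [0, 3]]: enumeration oracle value.
  barcodes <- sprintf("c%d", 1:9)
  assignments <- data.frame(
    barcode = barcodes,
    clone_id = c("A", "A", "A", "b1", "b2", "b3", "b4", "b5", "b6"),
    stringsAsFactors = FALSE)
  meta <- tiny_meta(barcodes, c(rep("SF", 6), rep("PB", 3)))
  res <- test_clone_enrichment(assignments, meta, min_cells = 3)
  expect_equal(nrow(res), 1L)   # only clone A is eligible
  expect_equal(res$clone_id, "A")
  expect_equal(res$n_sf, 3L); expect_equal(res$n_pb, 0L)
  expect_equal(res$p, fisher_enum_oracle(3, 3, 0, 3), tolerance = 1e-12)
  expect_equal(res$enriched_in, "SF")
})

test_that("a clone below the >=3 rule in both compartments is not tested", {
  barcodes <- sprintf("c%d", 1:104)
  assignments <- data.frame(
    barcode = barcodes,
    clone_id = c("A", "A", "A", "A", sprintf("s%03d", 5:104)),
    stringsAsFactors = FALSE)
  meta <- tiny_meta(barcodes, rep(c("PB", "SF"), 52))
  # clone A: 2 PB + 2 SF -> max(n_pb, n_sf) = 2 < 3 -> ineligible
  res <- test_clone_enrichment(assignments, meta, min_cells = 3)
  expect_false("A" %in% res$clone_id)
  # under "total" eligibility it becomes eligible
  res2 <- test_clone_enrichment(assignments, meta, min_cells = 3,
                                eligibility = "total")
  expect_true("A" %in% res2$clone_id)
})

test_that("a clone at equal compartment fractions has p = 1", {
  barcodes <- sprintf("c%d", 1:200)
  assignments <- data.frame(
    barcode = barcodes,
    clone_id = c(rep("A", 3), sprintf("p%03d", 4:100),
                 rep("A", 3), sprintf("s%03d", 104:200)),
    stringsAsFactors = FALSE)
  meta <- tiny_meta(barcodes, rep(c("PB", "SF"), each = 100))
  res <- test_clone_enrichment(assignments, meta)
  expect_equal(res$p[res$clone_id == "A"], 1, tolerance = 1e-9)
})

test_that("missing compartment label is reported with the barcode", {
  assignments <- data.frame(barcode = c("c1", "ghost"),
                            clone_id = c("A", "A"),
                            stringsAsFactors = FALSE)
  meta <- tiny_meta("c1", "PB")
  expect_error(test_clone_enrichment(assignments, meta), "ghost")
})

test_that("clone-to-cluster distribution fractions and unlabelled bucket", {
  barcodes <- sprintf("c%02d", 1:11)
  assignments <- data.frame(barcode = barcodes[1:10],
                            clone_id = "A", stringsAsFactors = FALSE)
  meta <- tiny_meta(barcodes, rep("SF", 11),
                    cluster = c(rep("C1", 5), rep("C2", 3), rep("C3", 2),
                                "C1"))
  d <- clone_cluster_distribution(assignments, meta)
  expect_equal(d$fraction[d$cluster == "C1"], 0.5)
  expect_equal(d$fraction[d$cluster == "C2"], 0.3)
  expect_equal(d$fraction[d$cluster == "C3"], 0.2)
  # clone wholly in one cluster -> mass 1
  a2 <- data.frame(barcode = barcodes[1:5], clone_id = "B",
                   stringsAsFactors = FALSE)
  d2 <- clone_cluster_distribution(a2, meta)
  expect_equal(d2$fraction, 1)
  expect_equal(d2$cluster, "C1")
  # member without a cluster label lands in "unlabelled"
  meta$cluster[1] <- NA
  d3 <- clone_cluster_distribution(assignments, meta)
  expect_true("unlabelled" %in% d3$cluster)
  expect_true(is.na(d3$p_overrep[d3$cluster == "unlabelled"]))
})

test_that("lineage classification by majority vote over members", {
  norm <- tiny_expr(rbind(CD4 = c(2, 2, 2, 0, 0, 0),
                          CD8A = c(0, 0, 1, 0, 0, 0),
                          CD8B = c(0, 0, 3, 0, 0, 0)),
                    genes = c("CD4", "CD8A", "CD8B"))
  a <- data.frame(barcode = colnames(norm)[c(1, 2, 3, 4)],
                  clone_id = c("X", "X", "X", "X"),
                  stringsAsFactors = FALSE)
  # members: CD4, CD4, CD8 (4 > 2? no: cd8 = 4 > cd4 = 2), abstain
  res <- classify_clone_lineage(a, norm)
  expect_equal(res$lineage, "CD4")   # 2 CD4 vs 1 CD8
  # all-zero members -> unassigned
  a2 <- data.frame(barcode = colnames(norm)[4:6], clone_id = "Z",
                   stringsAsFactors = FALSE)
  expect_equal(classify_clone_lineage(a2, norm)$lineage, "unassigned")
})
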