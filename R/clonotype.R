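#' Collapse contigs into per-cell chain sets
#'
#' For each cell barcode, collects the distinct productive TRA and TRB CDR3
#' nucleotide sequences.  Non-productive contigs are ignored and duplicate
#' contigs of the same chain (assembly redundancy) collapse to one entry.
#' Chain lists are sorted lexicographically (C collation) so that the
#' resulting keys are independent of contig row order.
#'
#' @param contigs Contig data frame as returned by [read_contigs()].
#' @return A data frame with one row per barcode that has at least one
#'   productive chain: `barcode`, `alphas` and `betas` (each a `;`-joined
#'   sorted list of distinct CDR3 nucleotide sequences, `""` if none),
#'   `n_alpha`, `n_beta`.
#' @export
collapse_chains <- function(contigs) {
  prod <- contigs[contigs$productive &
                    contigs$chain %in% c("TRA", "TRB"), , drop = FALSE]
  if (nrow(prod) == 0L)
    return(data.frame(barcode = character(0), alphas = character(0),
                      betas = character(0), n_alpha = integer(0),
                      n_beta = integer(0), stringsAsFactors = FALSE))
  join_sorted <- function(x) {
    x <- sort(unique(x), method = "radix")
    paste(x, collapse = ";")
  }
  count_distinct <- function(x) length(unique(x))
  barcodes <- sort(unique(prod$barcode), method = "radix")
  a <- split(prod$cdr3_nt[prod$chain == "TRA"],
             factor(prod$barcode[prod$chain == "TRA"], levels = barcodes))
  b <- split(prod$cdr3_nt[prod$chain == "TRB"],
             factor(prod$barcode[prod$chain == "TRB"], levels = barcodes))
  data.frame(
    barcode = barcodes,
    alphas  = vapply(a, join_sorted, character(1)),
    betas   = vapply(b, join_sorted, character(1)),
    n_alpha = vapply(a, count_distinct, integer(1)),
    n_beta  = vapply(b, count_distinct, integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Call clonotypes from per-cell chain sets
#'
#' A clonotype is the set of cells carrying identical TCR alpha- and
#' beta-chain CDR3 nucleotide sequences.  The clone key is the sorted
#' alpha list joined to the sorted beta list with `"|"`.  Cells lacking a
#' beta chain are excluded from clonotyping in both modes.
#'
#' Two modes reflect the two uses of clonotypes:
#' \describe{
#'   \item{`"joint_gex"`}{for joint expression + clonality analysis of the
#'     same cells: droplets with more than one beta chain or more than two
#'     alpha chains are considered multiplets and excluded before keying.}
#'   \item{`"clonality_table"`}{for repertoire tables: multi-beta droplets
#'     are retained; because alpha/beta pairing cannot be deduced for them,
#'     each full chain multiset is treated as a single clone.}
#' }
#'
#' @param chains Output of [collapse_chains()].
#' @param mode `"joint_gex"` or `"clonality_table"`.
#' @return A list with `assignments` (data frame `barcode`, `clone_id`) and
#'   `clones` (data frame `clone_id`, `n_cells`, ordered by decreasing size
#'   then clone id).
#' @export
call_clonotypes <- function(chains, mode = c("joint_gex", "clonality_table")) {
  mode <- match.arg(mode)
  keep <- chains$n_beta >= 1L
  if (mode == "joint_gex")
    keep <- keep & chains$n_beta <= 1L & chains$n_alpha <= 2L
  cc <- chains[keep, , drop = FALSE]
  clone_id <- paste(cc$alphas, cc$betas, sep = "|")
  assignments <- data.frame(barcode = cc$barcode, clone_id = clone_id,
                            stringsAsFactors = FALSE)
  tab <- table(clone_id)
  clones <- data.frame(clone_id = names(tab),
                       n_cells = as.integer(tab),
                       stringsAsFactors = FALSE)
  clones <- clones[order(-clones$n_cells, clones$clone_id,
                         method = "radix"), , drop = FALSE]
  rownames(clones) <- NULL
  list(assignments = assignments, clones = clones)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value under the point-probability ("minimum
#' likelihood") rule: the sum of hypergeometric point probabilities, over
#' all tables with the observed margins, that do not exceed the observed
#' table's point probability times `(1 + 1e-7)` (relative tie tolerance).
#' Degenerate margins give p = 1.
#'
#' @param tab A 2x2 matrix (or length-4 vector, row-major) of non-negative
#'   integer counts.
#' @return The two-sided p-value, clamped to `[0, 1]`.
#' @export
fisher_two_sided <- function(tab) {
  x <- as.integer(tab)
  if (length(x) != 4L || any(x < 0))
    stop("fisher_two_sided: need a 2x2 table of non-negative integers",
         call. = FALSE)
  if (is.matrix(tab)) {
    a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  } else {
    a <- x[1]; b <- x[2]; cc <- x[3]; d <- x[4]
  }
  m <- a + b; n <- cc + d; k <- a + cc
  lo <- max(0, k - n); hi <- min(k, m)
  if (lo == hi) return(1)
  xs <- lo:hi
  px <- stats::dhyper(xs, m, n, k)
  pobs <- stats::dhyper(a, m, n, k)
  p <- sum(px[px <= pobs * (1 + 1e-7)])
  min(max(p, 0), 1)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR adjustment: with p-values sorted ascending,
#' `adj_(i) = min over j >= i of p_(j) * m / j`, capped at 1, returned in
#' the original input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("bh_adjust: p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(p[o] * m / seq.int(m, 1)))
  adj[order(o)]
}

#' Test per-clone compartment enrichment
#'
#' For every clone with at least `min_cells` cells in either compartment
#' (`eligibility = "either"`, the default: `max(n_pb, n_sf) >= min_cells`;
#' `"total"` uses `n_pb + n_sf >= min_cells`), the proportion of cells
#' belonging to the clone is compared between SF and PB with a two-sided
#' Fisher's exact test on the table
#' `[[n_sf, total_sf - n_sf], [n_pb, total_pb - n_pb]]`, where the totals
#' are all clonotyped cells per compartment.  P-values are
#' Benjamini-Hochberg adjusted across the eligible clones only; a clone is
#' flagged significant when the adjusted p-value is at most `alpha`.
#'
#' @param assignments Clone assignments (`barcode`, `clone_id`), e.g.
#'   `call_clonotypes(...)$assignments`.
#' @param meta Cell metadata with `barcode` and `compartment` (PB/SF).
#' @param min_cells Eligibility threshold (default 3).
#' @param alpha Significance level on the adjusted p-value (default 0.05).
#' @param eligibility `"either"` or `"total"`; see above.
#' @return Data frame with one row per eligible clone: `clone_id`, `n_pb`,
#'   `n_sf`, `total_pb`, `total_sf`, `odds_ratio` (sample odds ratio of the
#'   table), `p`, `p_adj`, `significant`, `enriched_in`; ordered by
#'   ascending `p`, then clone id.
#' @export
test_clone_enrichment <- function(assignments, meta, min_cells = 3,
                                  alpha = 0.05,
                                  eligibility = c("either", "total")) {
  eligibility <- match.arg(eligibility)
  idx <- match(assignments$barcode, meta$barcode)
  if (anyNA(idx) || anyNA(meta$compartment[idx])) {
    bad <- assignments$barcode[is.na(idx) | is.na(meta$compartment[idx])]
    stop("test_clone_enrichment: no compartment label for barcode(s): ",
         paste(utils::head(bad, 3), collapse = ", "), call. = FALSE)
  }
  comp <- meta$compartment[idx]
  total_pb <- sum(comp == "PB")
  total_sf <- sum(comp == "SF")
  cl <- factor(assignments$clone_id)
  n_pb <- as.integer(tapply(comp == "PB", cl, sum))
  n_sf <- as.integer(tapply(comp == "SF", cl, sum))
  res <- data.frame(clone_id = levels(cl), n_pb = n_pb, n_sf = n_sf,
                    stringsAsFactors = FALSE)
  eligible <- if (eligibility == "either") pmax(n_pb, n_sf) >= min_cells
              else (n_pb + n_sf) >= min_cells
  res <- res[eligible, , drop = FALSE]
  if (nrow(res) == 0L) {
    return(data.frame(clone_id = character(0), n_pb = integer(0),
                      n_sf = integer(0), total_pb = integer(0),
                      total_sf = integer(0), odds_ratio = numeric(0),
                      p = numeric(0), p_adj = numeric(0),
                      significant = logical(0),
                      enriched_in = character(0),
                      stringsAsFactors = FALSE))
  }
  res$total_pb <- total_pb
  res$total_sf <- total_sf
  res$odds_ratio <- (res$n_sf * (total_pb - res$n_pb)) /
                    ((total_sf - res$n_sf) * res$n_pb)
  res$p <- vapply(seq_len(nrow(res)), function(i) {
    fisher_two_sided(matrix(c(res$n_sf[i], total_sf - res$n_sf[i],
                              res$n_pb[i], total_pb - res$n_pb[i]),
                            2, 2, byrow = TRUE))
  }, numeric(1))
  res$p_adj <- bh_adjust(res$p)
  res$significant <- res$p_adj <= alpha
  frac_sf <- res$n_sf / total_sf
  frac_pb <- res$n_pb / total_pb
  res$enriched_in <- ifelse(frac_sf > frac_pb, "SF",
                            ifelse(frac_pb > frac_sf, "PB", NA_character_))
  res <- res[order(res$p, res$clone_id, method = "radix"), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Distribution of clone members across transcriptional clusters
#'
#' Counts each clone's members per cluster label, with fractions, and a
#' descriptive hypergeometric over-representation p-value per (clone,
#' cluster): the upper tail probability of drawing at least the observed
#' number of that cluster's cells when sampling `clone size` cells without
#' replacement from all labelled cells.  The score is reported, not
#' thresholded.  Members lacking a cluster label are counted under
#' `"unlabelled"`.
#'
#' @param assignments Clone assignments (`barcode`, `clone_id`).
#' @param meta Cell metadata with `barcode` and `cluster`.
#' @param clone_ids Optional subset of clones to tabulate (default: all).
#' @return Data frame `clone_id`, `cluster`, `n`, `fraction`,
#'   `p_overrep` (NA for `"unlabelled"`).
#' @export
clone_cluster_distribution <- function(assignments, meta, clone_ids = NULL) {
  if (!is.null(clone_ids))
    assignments <- assignments[assignments$clone_id %in% clone_ids, ,
                               drop = FALSE]
  cluster <- meta$cluster[match(assignments$barcode, meta$barcode)]
  cluster[is.na(cluster) | cluster == ""] <- "unlabelled"
  pop_cluster <- meta$cluster
  pop_cluster[is.na(pop_cluster) | pop_cluster == ""] <- "unlabelled"
  pop <- table(pop_cluster)
  n_pop <- sum(pop)
  parts <- lapply(split(cluster, assignments$clone_id), function(cl) {
    tab <- table(cl)
    data.frame(cluster = names(tab), n = as.integer(tab),
               fraction = as.integer(tab) / length(cl),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  out$clone_id <- rep(names(parts), vapply(parts, nrow, integer(1)))
  rownames(out) <- NULL
  k <- out$n
  size <- stats::ave(out$n, out$clone_id, FUN = sum)
  m <- as.integer(pop[out$cluster])
  out$p_overrep <- stats::phyper(k - 1, m, n_pop - m, size,
                                 lower.tail = FALSE)
  out$p_overrep[out$cluster == "unlabelled"] <- NA_real_
  out[c("clone_id", "cluster", "n", "fraction", "p_overrep")]
}

#' Classify clone lineage (CD4 vs CD8) by majority vote
#'
#' Each member cell is CD8-like if its normalized `CD8A + CD8B` expression
#' exceeds `CD4`, CD4-like if the reverse, and abstains on a tie (including
#' all-zero).  The clone lineage is the majority over non-abstaining
#' members; a tie (or no votes) yields `"unassigned"`.
#'
#' @param assignments Clone assignments (`barcode`, `clone_id`).
#' @param norm Normalized expression matrix (genes x cells) containing
#'   `CD4`, `CD8A`, `CD8B` rows (missing genes are treated as zero with a
#'   warning).
#' @return Data frame `clone_id`, `lineage` (`"CD4"`, `"CD8"` or
#'   `"unassigned"`).
#' @export
classify_clone_lineage <- function(assignments, norm) {
  get_row <- function(g) {
    if (g %in% rownames(norm)) as.numeric(norm[g, assignments$barcode])
    else {
      warning("classify_clone_lineage: gene ", g,
              " absent; treated as zero", call. = FALSE)
      numeric(nrow(assignments))
    }
  }
  cd4 <- get_row("CD4")
  cd8 <- get_row("CD8A") + get_row("CD8B")
  vote <- ifelse(cd8 > cd4, "CD8", ifelse(cd4 > cd8, "CD4", NA))
  lineage <- vapply(split(vote, assignments$clone_id), function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return("unassigned")
    n4 <- sum(v == "CD4"); n8 <- sum(v == "CD8")
    if (n4 > n8) "CD4" else if (n8 > n4) "CD8" else "unassigned"
  }, character(1))
  data.frame(clone_id = names(lineage), lineage = unname(lineage),
             stringsAsFactors = FALSE)
}
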