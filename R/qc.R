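#' Quality-control thresholds
#'
#' Returns the cell-filtering thresholds used for the two dataset presets.
#' Removal criteria are strict inequalities (a cell is removed when it
#' exceeds, never when it equals, a bound), so boundary cells — exactly
#' 10\% mitochondrial UMIs, exactly `min_genes` genes, exactly `max_umi`
#' UMIs — are kept.
#'
#' \describe{
#'   \item{`"AS"`}{mito > 0.10, genes < 250 or > 4000, UMI > 25000, CD3
#'     gating on CD3E/CD3D/CD3G, multiplets with > 1 beta or > 2 alpha
#'     chains.}
#'   \item{`"PsA"`}{as AS but genes < 500 or > 3500, plus removal of cells
#'     co-expressing CD4 and CD8 (CD8A or CD8B).}
#' }
#'
#' @param preset `"AS"` or `"PsA"`.
#' @param ... Named overrides of individual fields.
#' @return A list of thresholds (class `qc_thresholds`).
#' @export
qc_thresholds <- function(preset = c("AS", "PsA"), ...) {
  preset <- match.arg(preset)
  th <- list(
    preset = preset,
    max_mito_frac = 0.10,
    min_genes = if (preset == "PsA") 500L else 250L,
    max_genes = if (preset == "PsA") 3500L else 4000L,
    max_umi = 25000L,
    cd3_genes = c("CD3E", "CD3D", "CD3G"),
    max_beta_chains = 1L,
    max_alpha_chains = 2L,
    exclude_cd4_cd8 = preset == "PsA")
  over <- list(...)
  bad <- setdiff(names(over), names(th))
  if (length(bad))
    stop("qc_thresholds: unknown field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  th[names(over)] <- over
  if (th$min_genes >= th$max_genes)
    stop("qc_thresholds: min_genes must be < max_genes", call. = FALSE)
  if (th$max_mito_frac < 0 || th$max_mito_frac > 1)
    stop("qc_thresholds: max_mito_frac must be in [0, 1]", call. = FALSE)
  structure(th, class = "qc_thresholds")
}

#' Per-cell quality-control metrics
#'
#' Computes, on the raw count matrix, the mitochondrial UMI fraction
#' (mitochondrial genes identified by id prefix, default `"MT-"`), the
#' number of detected genes (count > 0), the total UMI count, CD3
#' positivity (any of CD3E/CD3D/CD3G detected) and, when chain evidence is
#' supplied, the number of distinct productive alpha and beta CDR3
#' sequences per cell.  Cells with zero total UMIs get a mitochondrial
#' fraction of 0.
#'
#' @param mat Expression matrix (genes x cells), see [expression_matrix()].
#' @param chains Optional output of [collapse_chains()]; cells without
#'   chain evidence get `n_alpha = n_beta = 0`.
#' @param mito_prefix Prefix identifying mitochondrial gene ids.
#' @param cd3_genes Gene ids defining CD3 positivity.
#' @return Data frame `barcode`, `mito_frac`, `n_genes`, `n_umi`,
#'   `cd3_positive`, `n_alpha`, `n_beta` (cells in matrix column order).
#' @export
compute_qc_metrics <- function(mat, chains = NULL, mito_prefix = "MT-",
                               cd3_genes = c("CD3E", "CD3D", "CD3G")) {
  n_umi <- Matrix::colSums(mat)
  n_genes <- Matrix::colSums(mat > 0)
  mito <- startsWith(rownames(mat), mito_prefix)
  if (!any(mito)) {
    warning("compute_qc_metrics: no gene id matches prefix '", mito_prefix,
            "'; mito_frac set to 0 for all cells", call. = FALSE)
    mito_frac <- rep(0, ncol(mat))
  } else {
    mito_umi <- Matrix::colSums(mat[mito, , drop = FALSE])
    mito_frac <- ifelse(n_umi > 0, mito_umi / n_umi, 0)
  }
  cd3 <- intersect(cd3_genes, rownames(mat))
  cd3_positive <- if (length(cd3))
    Matrix::colSums(mat[cd3, , drop = FALSE]) > 0
  else rep(FALSE, ncol(mat))
  metrics <- data.frame(
    barcode = colnames(mat),
    mito_frac = as.numeric(mito_frac),
    n_genes = as.integer(n_genes),
    n_umi = as.numeric(n_umi),
    cd3_positive = as.logical(cd3_positive),
    n_alpha = 0L, n_beta = 0L,
    stringsAsFactors = FALSE)
  if (!is.null(chains)) {
    idx <- match(metrics$barcode, chains$barcode)
    metrics$n_alpha <- ifelse(is.na(idx), 0L, chains$n_alpha[idx])
    metrics$n_beta <- ifelse(is.na(idx), 0L, chains$n_beta[idx])
  }
  metrics
}

# Fixed first-failure attribution order for the exclusion log.
.qc_rule_order <- c("mito", "low_genes", "high_genes", "high_umi",
                    "cd3_negative", "multi_beta", "multi_alpha",
                    "cd4_cd8_coexpr", "cd14_positive")

#' Apply quality-control filters
#'
#' A cell is kept iff it passes every rule: `mito_frac <= max_mito_frac`,
#' `min_genes <= n_genes <= max_genes`, `n_umi <= max_umi`, CD3 positive,
#' `n_beta <= max_beta_chains`, `n_alpha <= max_alpha_chains`; under the
#' PsA preset additionally not co-expressing CD4 with CD8A/CD8B, and with
#' `drop_cd14 = TRUE` additionally `CD14 == 0`.  Exclusions are attributed
#' to the first failing rule in a fixed order (mito, low genes, high genes,
#' high UMI, CD3, multi-beta, multi-alpha, CD4/CD8, CD14), so per-rule
#' counts plus kept cells always sum to the total.
#'
#' @param metrics Output of [compute_qc_metrics()].
#' @param thresholds A [qc_thresholds()] object.
#' @param mat Expression matrix; required only for the CD4/CD8 and CD14
#'   rules.
#' @param drop_cd14 Remove cells with any CD14 counts (replaces an upstream
#'   cluster-level monocyte purge with a direct gene rule).
#' @return A list: `keep` (named logical per barcode), `excluded_by`
#'   (named integer, first-failure counts per rule), `n_kept`.
#' @export
apply_qc_filters <- function(metrics, thresholds = qc_thresholds("AS"),
                             mat = NULL, drop_cd14 = FALSE) {
  th <- thresholds
  n <- nrow(metrics)
  fails <- list(
    mito = metrics$mito_frac > th$max_mito_frac,
    low_genes = metrics$n_genes < th$min_genes,
    high_genes = metrics$n_genes > th$max_genes,
    high_umi = metrics$n_umi > th$max_umi,
    cd3_negative = !metrics$cd3_positive,
    multi_beta = metrics$n_beta > th$max_beta_chains,
    multi_alpha = metrics$n_alpha > th$max_alpha_chains,
    cd4_cd8_coexpr = rep(FALSE, n),
    cd14_positive = rep(FALSE, n))
  if (isTRUE(th$exclude_cd4_cd8)) {
    if (is.null(mat) || !all(c("CD4") %in% rownames(mat)) ||
        !any(c("CD8A", "CD8B") %in% rownames(mat))) {
      warning("apply_qc_filters: CD4/CD8 genes unavailable; ",
              "co-expression rule skipped", call. = FALSE)
    } else {
      bc <- metrics$barcode
      cd4 <- as.numeric(mat["CD4", bc])
      cd8 <- numeric(n)
      for (g in c("CD8A", "CD8B"))
        if (g %in% rownames(mat)) cd8 <- cd8 + as.numeric(mat[g, bc])
      fails$cd4_cd8_coexpr <- cd4 > 0 & cd8 > 0
    }
  }
  if (isTRUE(drop_cd14)) {
    if (is.null(mat) || !"CD14" %in% rownames(mat)) {
      warning("apply_qc_filters: CD14 not in matrix; rule skipped",
              call. = FALSE)
    } else {
      fails$cd14_positive <- as.numeric(mat["CD14", metrics$barcode]) > 0
    }
  }
  fail_mat <- do.call(cbind, fails[.qc_rule_order])
  keep <- rowSums(fail_mat) == 0L
  first_fail <- apply(fail_mat, 1L, function(f)
    if (any(f)) .qc_rule_order[which(f)[1]] else NA_character_)
  excluded_by <- vapply(.qc_rule_order,
                        function(r) sum(first_fail == r, na.rm = TRUE),
                        integer(1))
  names(keep) <- metrics$barcode
  list(keep = keep, excluded_by = excluded_by, n_kept = sum(keep))
}

#' PsA-variant quality filter
#'
#' Convenience wrapper applying the PsA preset (gene bounds 500–3500 and
#' removal of CD4/CD8 co-expressing cells) to a matrix and its metrics.
#'
#' @inheritParams apply_qc_filters
#' @return As [apply_qc_filters()].
#' @export
apply_psa_filters <- function(metrics, mat) {
  apply_qc_filters(metrics, qc_thresholds("PsA"), mat = mat)
}
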