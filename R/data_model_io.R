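#' Construct a validated expression matrix
#'
#' An expression matrix in this package is a sparse `dgCMatrix` of
#' non-negative integer UMI counts with genes as rows and cell barcodes as
#' columns.  Row and column names carry the identifiers and must be unique.
#'
#' @param counts A matrix or sparse Matrix of non-negative counts
#'   (genes x cells).
#' @param gene_ids Character vector of unique gene identifiers, one per row.
#' @param cell_barcodes Character vector of unique cell barcodes, one per
#'   column.
#' @return A `dgCMatrix` with `gene_ids` as rownames and `cell_barcodes` as
#'   colnames.
#' @export
expression_matrix <- function(counts, gene_ids, cell_barcodes) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  if (nrow(counts) != length(gene_ids))
    stop("expression_matrix: ", nrow(counts), " rows but ",
         length(gene_ids), " gene ids", call. = FALSE)
  if (ncol(counts) != length(cell_barcodes))
    stop("expression_matrix: ", ncol(counts), " columns but ",
         length(cell_barcodes), " cell barcodes", call. = FALSE)
  if (anyDuplicated(gene_ids))
    stop("expression_matrix: duplicate gene ids", call. = FALSE)
  if (anyDuplicated(cell_barcodes))
    stop("expression_matrix: duplicate cell barcodes", call. = FALSE)
  if (length(counts@x) && any(counts@x < 0))
    stop("expression_matrix: negative counts", call. = FALSE)
  dimnames(counts) <- list(as.character(gene_ids),
                           as.character(cell_barcodes))
  counts
}

#' Read a CellRanger-style Matrix Market count matrix
#'
#' Reads the `matrix.mtx` / `features.tsv` / `barcodes.tsv` triplet layout.
#' The features file may have one column (gene id) or the CellRanger three
#' (id, symbol, type), in which case the symbol column is used as the gene
#' identifier.  Sidecar line counts are checked against the declared matrix
#' dimensions and any mismatch is reported with the offending file name.
#' Cells and genes are returned in file order, never reordered.
#'
#' @param mtx_path Path to the Matrix Market file.
#' @param features_path Path to the features/genes sidecar (TSV).
#' @param barcodes_path Path to the barcodes sidecar (one per line).
#' @return A genes x cells `dgCMatrix`; see [expression_matrix()].
#' @export
read_expression <- function(mtx_path, features_path, barcodes_path) {
  for (p in c(mtx_path, features_path, barcodes_path))
    if (!file.exists(p)) stop("read_expression: no such file: ", p,
                              call. = FALSE)
  m <- Matrix::readMM(mtx_path)
  if (!methods::is(m, "dMatrix")) m <- m * 1  # pattern/logical MTX
  feat <- utils::read.delim(features_path, header = FALSE,
                            colClasses = "character")
  gene_ids <- if (ncol(feat) >= 2) feat[[2]] else feat[[1]]
  barcodes <- readLines(barcodes_path)
  if (nrow(m) != length(gene_ids))
    stop("read_expression: ", mtx_path, " declares ", nrow(m),
         " genes but ", features_path, " has ", length(gene_ids),
         " lines", call. = FALSE)
  if (ncol(m) != length(barcodes))
    stop("read_expression: ", mtx_path, " declares ", ncol(m),
         " cells but ", barcodes_path, " has ", length(barcodes),
         " lines", call. = FALSE)
  if (length(m@x) && any(m@x < 0))
    stop("read_expression: negative entry in ", mtx_path, call. = FALSE)
  expression_matrix(m, gene_ids, barcodes)
}

#' Write a count matrix in Matrix Market triplet layout
#'
#' Inverse of [read_expression()]: writes `matrix.mtx`, a one-column
#' `features.tsv` and `barcodes.tsv` into `dir`.
#'
#' @param mat A genes x cells count matrix with dimnames.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the three paths written.
#' @export
write_expression <- function(mat, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("matrix.mtx", "features.tsv", "barcodes.tsv"))
  m <- methods::as(methods::as(Matrix::Matrix(mat, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  Matrix::writeMM(m, paths[1])
  writeLines(rownames(mat) %||% character(0), paths[2])
  writeLines(colnames(mat) %||% character(0), paths[3])
  invisible(paths)
}

.contig_required_cols <- c("barcode", "chain", "cdr3", "cdr3_nt",
                           "v_gene", "j_gene", "productive", "umis")

#' Read a 10x-style filtered contig annotation table
#'
#' Parses the CSV dialect of `filtered_contig_annotations.csv`.  The
#' `productive` column is interpreted as TRUE for the values
#' `"True"/"true"/"TRUE"` and FALSE otherwise.  Rows whose chain is neither
#' TRA nor TRB (e.g. "Multi") are dropped; the number dropped is reported
#' via a message and attached as attribute `n_dropped`.
#'
#' @param csv_path Path to the contig CSV.
#' @return A data frame with columns `barcode, chain, cdr3, cdr3_nt, v_gene,
#'   j_gene, productive, umis`, one row per retained contig.
#' @export
read_contigs <- function(csv_path) {
  if (!file.exists(csv_path))
    stop("read_contigs: no such file: ", csv_path, call. = FALSE)
  df <- utils::read.csv(csv_path, colClasses = "character")
  missing <- setdiff(.contig_required_cols, names(df))
  if (length(missing))
    stop("read_contigs: missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df <- df[.contig_required_cols]
  keep <- df$chain %in% c("TRA", "TRB")
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message("read_contigs: dropped ", n_dropped,
            " contig(s) with chain outside {TRA, TRB}")
  df <- df[keep, , drop = FALSE]
  df$productive <- df$productive %in% c("True", "true", "TRUE")
  df$umis <- as.integer(df$umis)
  rownames(df) <- NULL
  attr(df, "n_dropped") <- n_dropped
  df
}

#' Write a result table as TSV
#'
#' Tab-separated UTF-8 with a header row.  Floating point values are
#' serialised with 15 significant digits so that re-runs are diffable.
#' Optional comment lines (prefixed `#`) can carry provenance such as the
#' seed and config hash.
#'
#' @param df A data frame; all records share its schema.
#' @param path Output path.
#' @param comments Optional character vector of comment lines written (with
#'   a leading `"# "`) before the header.
#' @return Invisibly, `path`.
#' @export
write_table <- function(df, path, comments = NULL) {
  df <- as.data.frame(df)
  if (nrow(df) == 0L) {
    fmt <- matrix(character(0), 0L, ncol(df))
  } else {
    fmt <- vapply(df, function(col) {
      if (is.double(col)) sprintf("%.15g", col)
      else if (is.logical(col)) ifelse(col, "TRUE", "FALSE")
      else as.character(col)
    }, FUN.VALUE = character(nrow(df)))
    if (nrow(df) == 1L) fmt <- matrix(fmt, nrow = 1L)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- c(if (length(comments)) paste0("# ", comments),
             paste(names(df), collapse = "\t"),
             if (nrow(df)) apply(fmt, 1L, paste, collapse = "\t"))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a TSV written by [write_table()] (comment lines skipped)
#' @param path Path to the TSV.
#' @return A data frame.
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Validate a per-cell metadata table
#'
#' Checks the contract for cell metadata: unique barcodes and a compartment
#' label that is exactly one of `"PB"` or `"SF"` for every cell.  An
#' optional `cluster` column carries externally supplied cluster labels.
#'
#' @param meta A data frame with at least `barcode`, `sample_id`,
#'   `compartment`, `patient` columns.
#' @return `meta`, invisibly, after validation.
#' @export
validate_cell_meta <- function(meta) {
  req <- c("barcode", "sample_id", "compartment", "patient")
  missing <- setdiff(req, names(meta))
  if (length(missing))
    stop("cell metadata: missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (anyDuplicated(meta$barcode))
    stop("cell metadata: duplicate barcodes", call. = FALSE)
  bad <- !meta$compartment %in% c("PB", "SF")
  if (any(bad))
    stop("cell metadata: compartment must be PB or SF; offending barcode(s): ",
         paste(utils::head(meta$barcode[bad], 3), collapse = ", "),
         call. = FALSE)
  invisible(meta)
}
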