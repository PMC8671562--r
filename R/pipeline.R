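#' Validate a pipeline configuration
#'
#' Checks a configuration list (or YAML file) for the end-to-end pipeline.
#' Every problem found is reported as one message naming the field, its
#' value and the violated constraint; an empty return value means the
#' config is valid.
#'
#' @param config A configuration list, or the path to a YAML file holding
#'   one.  Recognised fields: `expression` (dir with
#'   matrix.mtx/features.tsv/barcodes.tsv), `contigs` (CSV path), `meta`
#'   (TSV path), optional `hto` (dir), `out_dir`, `qc_preset` (AS/PsA),
#'   `drop_cd14`, `demux_quantile`, `clonotype_mode`, `min_cells`,
#'   `alpha`, `min_pct`, `log_fc_cut`, `module_file`, `seed`.
#' @return Character vector of error messages (length 0 when valid).
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) return(paste("config file not found:", config))
    config <- yaml::read_yaml(config)
  }
  errs <- character(0)
  add <- function(msg) errs <<- c(errs, msg)
  need_file <- function(field, path) {
    if (is.null(path)) add(paste0(field, ": missing (required)"))
    else if (!file.exists(path)) add(paste0(field, " = '", path,
                                            "': file does not exist"))
  }
  if (is.null(config$expression)) add("expression: missing (required)")
  else for (f in c("matrix.mtx", "features.tsv", "barcodes.tsv"))
    need_file(paste0("expression/", f), file.path(config$expression, f))
  need_file("contigs", config$contigs)
  need_file("meta", config$meta)
  if (!is.null(config$hto))
    for (f in c("matrix.mtx", "features.tsv", "barcodes.tsv"))
      need_file(paste0("hto/", f), file.path(config$hto, f))
  alpha <- config$alpha %||% 0.05
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    add(paste0("alpha = ", alpha, ": must lie in (0, 1)"))
  q <- config$demux_quantile %||% 0.99
  if (!is.numeric(q) || q <= 0 || q >= 1)
    add(paste0("demux_quantile = ", q, ": must lie in (0, 1)"))
  mc <- config$min_cells %||% 3
  if (!is.numeric(mc) || mc < 1)
    add(paste0("min_cells = ", mc, ": must be >= 1"))
  mode <- config$clonotype_mode %||% "joint_gex"
  if (!mode %in% c("joint_gex", "clonality_table"))
    add(paste0("clonotype_mode = '", mode,
               "': must be joint_gex or clonality_table"))
  preset <- config$qc_preset %||% "AS"
  if (!preset %in% c("AS", "PsA"))
    add(paste0("qc_preset = '", preset, "': must be AS or PsA"))
  if (!is.null(config$module_file) && !file.exists(config$module_file))
    add(paste0("module_file = '", config$module_file, "': file does not exist"))
  errs
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages end to end in the order: expression QC
#' (mitochondrial / gene-count / UMI rules), hashtag demultiplexing
#' (doublet and negative removal, when hashtag counts are provided), CD3
#' gating and TCR-multiplet exclusion, clonotype calling, per-clone
#' compartment enrichment, normalization, SF-vs-PB differential
#' expression, optional module scoring, and the per-cluster compartment
#' z-test (when cluster labels are present).  Writes one TSV per stage
#' plus a run manifest with per-stage in/out cell counts, so the cell
#' funnel is auditable; every output carries the seed and the config hash
#' in a comment header.  Identical config + seed produces a byte-identical
#' bundle.
#'
#' @param config Configuration list or YAML path; see [validate_config()].
#' @return Invisibly, a list of the in-memory stage results plus
#'   `out_dir`.
#' @export
run_pipeline <- function(config) {
  config_path <- NULL
  if (is.character(config)) {
    config_path <- config
    config <- yaml::read_yaml(config)
  }
  errs <- validate_config(config)
  if (length(errs))
    stop("run_pipeline: invalid config:\n  ",
         paste(errs, collapse = "\n  "), call. = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_hash <- if (!is.null(config_path)) {
    unname(tools::md5sum(config_path))
  } else {
    # hash the analysis parameters; the output location is not part of
    # the analysis identity
    tmp <- tempfile(fileext = ".yaml")
    yaml::write_yaml(config[setdiff(names(config), "out_dir")], tmp)
    h <- unname(tools::md5sum(tmp))
    unlink(tmp)
    h
  }
  hdr <- paste0("synoclone pipeline; seed=", seed, "; config_md5=", cfg_hash)
  manifest <- list()
  note <- function(stage, n_in, n_out)
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, n_in = n_in, n_out = n_out, stringsAsFactors = FALSE)

  ## ---- load ---------------------------------------------------------
  expr <- read_expression(file.path(config$expression, "matrix.mtx"),
                          file.path(config$expression, "features.tsv"),
                          file.path(config$expression, "barcodes.tsv"))
  contigs <- read_contigs(config$contigs)
  meta <- validate_cell_meta(read_table_tsv(config$meta))

  ## ---- stage 1: expression QC --------------------------------------
  chains <- collapse_chains(contigs)
  metrics <- compute_qc_metrics(expr, chains)
  th <- qc_thresholds(config$qc_preset %||% "AS")
  expr_rules <- qc_thresholds(th$preset,
                              cd3_genes = character(0),
                              max_beta_chains = .Machine$integer.max,
                              max_alpha_chains = .Machine$integer.max,
                              exclude_cd4_cd8 = FALSE)
  m1 <- metrics
  m1$cd3_positive <- TRUE   # CD3/TCR rules applied after demultiplexing
  qc1 <- apply_qc_filters(m1, expr_rules, mat = expr,
                          drop_cd14 = isTRUE(config$drop_cd14))
  kept1 <- metrics$barcode[qc1$keep]
  note("qc_expression", nrow(metrics), length(kept1))
  write_table(metrics, file.path(out_dir, "metrics.tsv"), comments = hdr)

  ## ---- stage 2: hashtag demultiplexing -----------------------------
  kept2 <- kept1
  demux <- NULL
  if (!is.null(config$hto)) {
    hto <- read_expression(file.path(config$hto, "matrix.mtx"),
                           file.path(config$hto, "features.tsv"),
                           file.path(config$hto, "barcodes.tsv"))
    demux <- demux_hashtags(hto[, kept1, drop = FALSE],
                            q = config$demux_quantile %||% 0.99,
                            seed = seed)
    kept2 <- demux$barcode[demux$class == "singlet"]
    write_table(demux, file.path(out_dir, "demux.tsv"), comments = hdr)
  }
  note("hto_demux", length(kept1), length(kept2))

  ## ---- stage 3: CD3 gating + TCR multiplet exclusion ---------------
  m3 <- metrics[metrics$barcode %in% kept2, , drop = FALSE]
  gate_rules <- qc_thresholds(th$preset, max_mito_frac = 1,
                              min_genes = 0L,
                              max_genes = .Machine$integer.max,
                              max_umi = Inf)
  qc3 <- apply_qc_filters(m3, gate_rules, mat = expr)
  kept3 <- m3$barcode[qc3$keep]
  note("cd3_tcr_gate", length(kept2), length(kept3))

  ## ---- stage 4: clonotyping + enrichment ---------------------------
  chains_kept <- chains[chains$barcode %in% kept3, , drop = FALSE]
  ct <- call_clonotypes(chains_kept,
                        mode = config$clonotype_mode %||% "joint_gex")
  note("clonotyping", length(kept3), nrow(ct$assignments))
  write_table(merge(ct$assignments, ct$clones, by = "clone_id",
                    sort = TRUE),
              file.path(out_dir, "clones.tsv"), comments = hdr)
  enrich <- test_clone_enrichment(ct$assignments, meta,
                                  min_cells = config$min_cells %||% 3,
                                  alpha = config$alpha %||% 0.05)
  note("enrichment", nrow(ct$clones), nrow(enrich))
  write_table(enrich, file.path(out_dir, "enrichment.tsv"), comments = hdr)

  ## ---- stage 5: normalization + SF-vs-PB DE ------------------------
  expr_kept <- expr[, kept3, drop = FALSE]
  norm <- normalize_counts(expr_kept)
  comp <- meta$compartment[match(kept3, meta$barcode)]
  de <- NULL
  if (sum(comp == "SF") >= 3 && sum(comp == "PB") >= 3) {
    de <- wilcoxon_de(norm, kept3[comp == "SF"], kept3[comp == "PB"],
                      min_pct = config$min_pct %||% 0.10)
    write_table(de, file.path(out_dir, "de_sf_vs_pb.tsv"), comments = hdr)
  }
  note("de_sf_vs_pb", length(kept3), if (is.null(de)) 0L else nrow(de))

  ## ---- stage 6: module scoring -------------------------------------
  scores <- NULL
  if (!is.null(config$module_file)) {
    module_genes <- readLines(config$module_file)
    module_genes <- module_genes[nzchar(module_genes)]
    scores <- module_score(norm, module_genes, seed = seed)
    write_table(data.frame(barcode = names(scores), score = scores,
                           stringsAsFactors = FALSE),
                file.path(out_dir, "scores.tsv"), comments = hdr)
  }
  note("module_score", length(kept3),
       if (is.null(scores)) 0L else length(scores))

  ## ---- stage 7: cluster compartment z-test -------------------------
  ztest <- NULL
  meta_kept <- meta[match(kept3, meta$barcode), , drop = FALSE]
  if (!is.null(meta_kept$cluster) && !any(is.na(meta_kept$cluster))) {
    ztest <- cluster_compartment_test(meta_kept)
    write_table(ztest, file.path(out_dir, "cluster_compartment.tsv"),
                comments = hdr)
  }
  note("cluster_z_test", length(kept3),
       if (is.null(ztest)) 0L else nrow(ztest))

  manifest_df <- do.call(rbind, manifest)
  manifest_df$seed <- seed
  write_table(manifest_df, file.path(out_dir, "manifest.tsv"),
              comments = hdr)
  writeLines(kept3, file.path(out_dir, "kept.txt"))

  invisible(list(metrics = metrics, demux = demux, kept = kept3,
                 clonotypes = ct, enrichment = enrich, de = de,
                 scores = scores, cluster_test = ztest,
                 manifest = manifest_df, out_dir = out_dir))
}
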