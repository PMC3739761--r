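## End-to-end orchestration: simulate (or ingest) -> threshold -> DE ->
## clustering -> prioritization -> isoforms -> enrichment -> qPCR, with a
## run manifest (parameters, seeds, output checksums) so reruns are
## verifiably bitwise identical.

#' Default pipeline configuration
#'
#' Returns the full parameter block of [run_pipeline()]; override any
#' subset via `...` or supply a YAML file with the same structure through
#' [read_pipeline_config()].
#'
#' @param ... named overrides of the defaults.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    simulate = list(),             # sim_config() overrides; NULL disables
    inputs = NULL,                 # list(matrix, metadata, edges, annotation, gmt, ct_table)
    target_reliability = 0.99,
    grid = list(from = 0.001, to = 10, length.out = 50),
    floor = NULL,                  # NULL: use the selected threshold
    fc_cutoff = 2, p_cutoff = 0.05,
    fraction = 0.10, log_base = 2, separate_directions = FALSE,
    k = 9, m = 1.25, min_fc = 2, top_n = 3000,
    n_perm = 1000, weight_p = 1,
    switch_margin = 1,
    qpcr_contrast = NULL)          # NULL: first injured stage vs control
  over <- list(...)
  cfg <- utils::modifyList(cfg, over)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys mirror [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  do.call(pipeline_config, yaml::read_yaml(path))
}

validate_pipeline_config <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$simulate) && is.null(config$inputs))
    stop("config needs either a `simulate` block or an `inputs` block")
  if (!is.null(config$inputs)) {
    need <- c("matrix", "metadata", "edges")
    miss <- setdiff(need, names(config$inputs))
    if (length(miss))
      stop("inputs block lacks: ", paste(miss, collapse = ", "))
    paths <- intersect(names(config$inputs),
                       c("matrix", "metadata", "edges", "annotation",
                         "gmt", "ct_table"))
    for (nm in paths) {
      p <- config$inputs[[nm]]
      if (!is.null(p) && !file.exists(p))
        stop("input path does not exist: ", nm, " = ", p)
    }
  }
  invisible(config)
}

#' Run the full analysis pipeline
#'
#' Executes every stage in dependency order on either a simulated input
#' bundle (ground truth retained in the result) or user-supplied files,
#' writes each stage's tables to `outdir`, logs gene counts after each
#' filter, and finishes with a manifest recording parameters, seeds and an
#' md5 checksum of every output, so that rerunning the same configuration
#' reproduces the outputs bitwise.
#'
#' @param config a [pipeline_config()] (or YAML path).
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with every stage result (`study`, `threshold`,
#'   `de`, `venn`, `clustering`, `candidates`, `isoforms`, `enrichment`,
#'   `qpcr`, `truth` when simulated, `manifest`).
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = tempfile("run")) {
  if (is.character(config)) config <- read_pipeline_config(config)
  validate_pipeline_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  failed_marker <- file.path(outdir, "FAILED")
  if (file.exists(failed_marker)) unlink(failed_marker)
  outputs <- character(0)
  emit <- function(tab, name) {
    path <- file.path(outdir, name)
    write_tsv(tab, path)
    outputs <<- c(outputs, path)
    path
  }
  res <- list()
  stage <- "setup"
  on.exit({
    if (!is.null(stage)) {
      writeLines(paste("failed at stage:", stage), failed_marker)
    }
  })

  ## ---- ingest or simulate -------------------------------------------
  stage <- "simulate/ingest"
  bundle <- NULL
  if (!is.null(config$simulate)) {
    sim_args <- utils::modifyList(config$simulate, list(seed = config$seed))
    bundle <- simulate_all(do.call(sim_config, sim_args))
    study <- bundle$study
    edges <- bundle$network$edges
    annotation <- bundle$annotation
    gene_sets <- bundle$gene_sets
    ct_table <- bundle$ct_table
    iso_study <- bundle$isoforms$study
    res$truth <- bundle$truth
    message("simulate: ", nrow(study$values), " genes, ",
            ncol(study$values), " samples")
  } else {
    inp <- config$inputs
    study <- read_expression_matrix(inp$matrix, inp$metadata)
    edges <- read_edge_list(inp$edges)
    annotation <- if (!is.null(inp$annotation)) read_annotation(inp$annotation)
    gene_sets <- if (!is.null(inp$gmt)) read_gmt(inp$gmt)
    ct_table <- if (!is.null(inp$ct_table)) {
      ct <- read_tsv_checked(inp$ct_table)
      attr(ct, "housekeeping") <- inp$housekeeping
      ct
    }
    iso_study <- NULL
    message("ingest: ", nrow(study$values), " genes, ",
            ncol(study$values), " samples")
  }
  res$study <- study
  write_expression_matrix(study, file.path(outdir, "expression.tsv"),
                          file.path(outdir, "samples.tsv"))
  outputs <- c(outputs, file.path(outdir, c("expression.tsv", "samples.tsv")))

  ## ---- detection threshold ------------------------------------------
  stage <- "threshold"
  floor_val <- config$floor
  if (!is.null(study$ci_lo)) {
    calls <- label_reliability(study)
    grid <- do.call(default_grid, config$grid)
    curve <- detection_curve(calls, grid)
    sel <- select_threshold(curve, config$target_reliability)
    res$threshold <- list(curve = curve, selection = sel)
    emit(curve, "detection_curve.tsv")
    emit(data.frame(threshold = sel$threshold, reliability = sel$reliability,
                    fn_rate = sel$fn_rate), "threshold.tsv")
    if (is.null(floor_val)) floor_val <- sel$threshold
    message(sprintf("threshold: %.4g FPKM (reliability %.4f)",
                    sel$threshold, sel$reliability))
  } else if (is.null(floor_val)) {
    floor_val <- 0.1
    message("threshold: no CI bounds; flooring at default 0.1 FPKM")
  }
  floored <- floor_fpkm(study, floor_val)

  ## ---- differential expression --------------------------------------
  stage <- "differential_expression"
  stages_inj <- study$stages[-1]
  de_tables <- lapply(stages_inj, function(s) {
    de <- call_de(floored, c(s, study$stages[1]),
                  fc_cutoff = config$fc_cutoff, p_cutoff = config$p_cutoff)
    emit(de, paste0("de_", s, "_vs_", study$stages[1], ".tsv"))
    message(sprintf("de %s vs %s: %d significant (%d up, %d down)",
                    s, study$stages[1], sum(de$significant),
                    sum(de$direction == "up"), sum(de$direction == "down")))
    de
  })
  names(de_tables) <- paste0(stages_inj, "_vs_", study$stages[1])
  res$de <- de_tables
  if (length(de_tables) >= 2) {
    venn <- venn_partition(de_tables[[1]], de_tables[[2]])
    res$venn <- venn
    emit(venn$counts, "venn_counts.tsv")
  }

  ## ---- trajectory clustering ----------------------------------------
  stage <- "clustering"
  varying <- select_varying_genes(floored, config$min_fc)
  message("clustering: ", length(varying), " genes vary > ",
          config$min_fc, "-fold across stages")
  res$clustering <- NULL
  if (length(varying) > config$k) {
    prof <- standardize_profiles(stage_means(floored)[varying, , drop = FALSE])
    cm <- fuzzy_cmeans(prof, k = config$k, m = config$m, seed = config$seed)
    res$clustering <- cm
    emit(data.frame(gene_id = rownames(prof), cluster = cm$cluster,
                    round(cm$membership, 6)), "cluster_membership.tsv")
    emit(data.frame(cluster = seq_len(config$k), round(cm$centers, 6)),
         "cluster_centers.tsv")
  }
  dend <- hierarchical_samples(study, top_n = config$top_n)
  res$dendrogram <- dend
  res$replicate_correlation <- replicate_correlation(study)
  emit(data.frame(sample_id = rownames(res$replicate_correlation),
                  round(res$replicate_correlation, 6)),
       "replicate_correlation.tsv")

  ## ---- network prioritization ---------------------------------------
  stage <- "prioritization"
  first_de <- de_tables[[1]]
  ranked <- prioritize_genes(first_de, edges, annotation,
                             fraction = config$fraction,
                             separate_directions = config$separate_directions,
                             fc_cutoff = config$fc_cutoff,
                             log_base = config$log_base)
  res$candidates <- ranked
  if (config$separate_directions) {
    emit(ranked$up, "candidates_up.tsv")
    emit(ranked$down, "candidates_down.tsv")
    message("prioritization: ", nrow(ranked$up), " up / ",
            nrow(ranked$down), " down candidates ranked")
  } else {
    emit(ranked, "candidates.tsv")
    message("prioritization: ", nrow(ranked), " candidates ranked")
  }

  ## ---- isoform analysis ---------------------------------------------
  stage <- "isoforms"
  if (!is.null(iso_study)) {
    prof <- isoform_profiles(iso_study, threshold = floor_val,
                             margin = config$switch_margin)
    res$isoforms <- prof
    emit(prof, "isoform_profiles.tsv")
    cnt <- count_expressed_isoforms(iso_study, threshold = floor_val)
    emit(cnt$histogram, "isoforms_per_gene.tsv")
    message("isoforms: ", sum(prof$switch), " switch gene(s) detected")
  }

  ## ---- enrichment -----------------------------------------------------
  stage <- "enrichment"
  if (!is.null(gene_sets)) {
    ranked_list <- rank_by_fold_change(first_de)
    gsea <- gsea_permutation(ranked_list, gene_sets, n_perm = config$n_perm,
                             weight_p = config$weight_p,
                             seed = derive_seed(config$seed, 11L))
    res$enrichment <- gsea
    emit(gsea[, setdiff(names(gsea), "leading_edge")], "gsea.tsv")
    detected <- first_de$gene_id[first_de$mean_treated >= floor_val |
                                   first_de$mean_control >= floor_val]
    query <- first_de$gene_id[first_de$significant]
    if (length(query)) {
      fisher <- fisher_enrichment(intersect(query, detected), gene_sets,
                                  detected)
      res$fisher <- fisher
      emit(fisher, "fisher.tsv")
    }
    message("enrichment: ", sum(gsea$q_value < 0.25), " set(s) at q < 0.25")
  }

  ## ---- qPCR concordance ----------------------------------------------
  stage <- "qpcr"
  if (!is.null(ct_table)) {
    ctr <- if (is.null(config$qpcr_contrast))
      c(stages_inj[1], study$stages[1]) else config$qpcr_contrast
    folds <- qpcr_fold_changes(ct_table, ctr)
    expr_fc <- do.call(rbind, lapply(de_tables, function(d)
      d[, c("gene_id", "contrast", "log2_fc")]))
    conc <- qpcr_concordance(folds, expr_fc)
    res$qpcr <- list(folds = folds, concordance = conc)
    emit(folds, "qpcr_folds.tsv")
    emit(conc$table, "qpcr_concordance.tsv")
    message(sprintf("qpcr: Pearson %.3f over %d pairs",
                    conc$pearson, conc$n_pairs))
  }

  ## ---- manifest -------------------------------------------------------
  stage <- "manifest"
  manifest <- list(
    seed = config$seed,
    parameters = config[setdiff(names(config), c("inputs", "simulate"))],
    simulated = !is.null(config$simulate),
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(sort(unique(outputs)))),
      basename(sort(unique(outputs))))))
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  res$manifest <- manifest
  stage <- NULL
  invisible(res)
}
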