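## Relative qPCR quantification by the 2^-ddCt method and concordance of
## qPCR fold changes with expression-derived fold changes.

#' Fold change from Ct values by the 2^-ddCt method
#'
#' Technical replicate Ct values are averaged per gene and sample; dCt =
#' mean Ct(gene) - mean Ct(housekeeping) per sample, averaged across the
#' biological replicates of each stage; ddCt = dCt(treated) - dCt(control);
#' fold change = 2^(-ddCt) (amplification efficiency fixed at 2, the
#' method's assumption). Adding a constant to every Ct of a sample (a plate
#' offset) cancels exactly.
#'
#' @param ct_table long data frame with columns `gene_id`, `sample_id`,
#'   `stage`, `ct` (technical replicates as repeated rows), e.g. from
#'   [simulate_qpcr()].
#' @param gene gene to quantify.
#' @param contrast character vector `c(treated, control)` of stage labels.
#' @param housekeeping housekeeping gene id; defaults to the table's
#'   `housekeeping` attribute.
#' @return list with `ddct`, `fold`, `dct_treated`, `dct_control`, and
#'   `per_replicate` (per biological replicate 2^-ddCt values against the
#'   mean control dCt, whose sd is a simple error estimate).
#' @export
delta_delta_ct <- function(ct_table, gene, contrast,
                           housekeeping = attr(ct_table, "housekeeping")) {
  stopifnot(length(contrast) == 2)
  if (is.null(housekeeping)) stop("housekeeping gene id required")
  if (any(ct_table$ct <= 0)) stop("Ct values must be positive")
  sub <- ct_table[ct_table$stage %in% contrast, , drop = FALSE]
  for (s in contrast) {
    have <- unique(sub$gene_id[sub$stage == s])
    if (!gene %in% have) stop("gene ", gene, " not measured in stage ", s)
    if (!housekeeping %in% have)
      stop("housekeeping gene ", housekeeping, " missing in stage ", s)
  }
  ## mean over technical replicates per gene x sample
  mean_ct <- stats::aggregate(ct ~ gene_id + sample_id + stage, data = sub,
                              FUN = mean)
  dct_of <- function(stage) {
    g <- mean_ct[mean_ct$gene_id == gene & mean_ct$stage == stage, ]
    h <- mean_ct[mean_ct$gene_id == housekeeping & mean_ct$stage == stage, ]
    d <- g$ct - h$ct[match(g$sample_id, h$sample_id)]
    if (anyNA(d)) stop("housekeeping gene ", housekeeping,
                       " missing in a sample of stage ", stage)
    d
  }
  dct_t <- dct_of(contrast[1])
  dct_c <- dct_of(contrast[2])
  ddct <- mean(dct_t) - mean(dct_c)
  list(ddct = ddct, fold = 2^(-ddct),
       dct_treated = mean(dct_t), dct_control = mean(dct_c),
       per_replicate = 2^(-(dct_t - mean(dct_c))))
}

#' qPCR fold changes for a panel of genes
#'
#' @inheritParams delta_delta_ct
#' @param genes genes to quantify; defaults to all non-housekeeping genes
#'   in the table.
#' @return data frame: `gene_id`, `contrast`, `ddct`, `fold`, `log2_fold`,
#'   `fold_sd` (sd of per-replicate 2^-ddCt).
#' @export
qpcr_fold_changes <- function(ct_table, contrast, genes = NULL,
                              housekeeping = attr(ct_table, "housekeeping")) {
  if (is.null(genes))
    genes <- setdiff(unique(ct_table$gene_id), housekeeping)
  rows <- lapply(genes, function(g) {
    r <- delta_delta_ct(ct_table, g, contrast, housekeeping)
    data.frame(gene_id = g, contrast = contrast_label(contrast),
               ddct = r$ddct, fold = r$fold, log2_fold = -r$ddct,
               fold_sd = stats::sd(r$per_replicate),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Concordance of qPCR and expression-derived fold changes
#'
#' Pearson and Spearman correlations of log2 fold changes, the fraction of
#' gene x contrast pairs whose fold changes agree in sign, and a
#' side-by-side table.
#'
#' @param qpcr data frame with `gene_id`, `contrast`, `log2_fold` (from
#'   [qpcr_fold_changes()]).
#' @param expression data frame with `gene_id`, `contrast`, `log2_fc`
#'   (e.g. stacked [call_de()] tables).
#' @return list with `pearson`, `spearman`, `sign_agreement`, `n_pairs`,
#'   and `table` (per-pair side-by-side log2 fold changes).
#' @export
qpcr_concordance <- function(qpcr, expression) {
  merged <- merge(qpcr[, c("gene_id", "contrast", "log2_fold")],
                  expression[, c("gene_id", "contrast", "log2_fc")],
                  by = c("gene_id", "contrast"))
  if (nrow(merged) < 3)
    stop("need at least 3 shared gene x contrast pairs; got ", nrow(merged))
  list(pearson = stats::cor(merged$log2_fold, merged$log2_fc),
       spearman = stats::cor(merged$log2_fold, merged$log2_fc,
                             method = "spearman"),
       sign_agreement = mean(sign(merged$log2_fold) == sign(merged$log2_fc)),
       n_pairs = nrow(merged),
       table = merged)
}
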