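## Differential-expression calling on floored FPKM values: replicate-mean
## fold change, unpaired two-sided t-test (pooled variance by default), the
## "fold change > 2 and p < 0.05" significance rule, Venn partitioning of
## two stage contrasts, and top-fraction selection for network seeding.

contrast_label <- function(contrast) paste0(contrast[1], "_vs_", contrast[2])

#' Per-gene fold change between two stages
#'
#' FC = mean(FPKM in `contrast[1]` replicates) / mean(FPKM in `contrast[2]`
#' replicates). The study should already be floored (see [floor_fpkm()]) so
#' that near-zero denominators cannot inflate ratios.
#'
#' @param study a (floored) [expression_study()].
#' @param contrast character vector `c(treated, control)`.
#' @return data frame with columns `gene_id`, `mean_treated`,
#'   `mean_control`, `fc`, `log2_fc`.
#' @export
fold_change <- function(study, contrast) {
  stopifnot(inherits(study, "expression_study"), length(contrast) == 2)
  a <- stage_samples(study, contrast[1])
  b <- stage_samples(study, contrast[2])
  ma <- rowMeans(study$values[, a, drop = FALSE])
  mb <- rowMeans(study$values[, b, drop = FALSE])
  fc <- ma / mb
  data.frame(gene_id = rownames(study$values),
             mean_treated = ma, mean_control = mb,
             fc = fc, log2_fc = log2(fc),
             row.names = NULL, stringsAsFactors = FALSE)
}

## two-sided unpaired t-test p-value with explicit degenerate handling
t_test_p <- function(x, y, var_equal = TRUE) {
  if (stats::sd(x) < 1e-12 && stats::sd(y) < 1e-12) {
    if (abs(mean(x) - mean(y)) < 1e-12) return(1)
    warning("zero within-group variance with differing means; p set to 0")
    return(0)
  }
  stats::t.test(x, y, var.equal = var_equal)$p.value
}

#' Per-gene unpaired two-sided t-test between two stages
#'
#' Student's pooled-variance test by default (the classic unpaired t-test,
#' sensible at 2-3 replicates per group); Welch's and log2-scale variants
#' are available. Degenerate genes (zero variance in both groups) get p = 1
#' when the means agree and p = 0 with a warning otherwise.
#'
#' @param study an [expression_study()].
#' @param contrast character vector `c(treated, control)`.
#' @param var_equal pooled-variance Student test if `TRUE`, Welch otherwise.
#' @param log_scale test on `log2(FPKM + 1e-8)` instead of raw FPKM.
#' @return named numeric vector of p-values, one per gene.
#' @export
de_t_test <- function(study, contrast, var_equal = TRUE, log_scale = FALSE) {
  stopifnot(inherits(study, "expression_study"))
  a <- stage_samples(study, contrast[1])
  b <- stage_samples(study, contrast[2])
  if (length(a) < 2 || length(b) < 2)
    stop("t-test needs at least 2 replicates per stage")
  xa <- study$values[, a, drop = FALSE]
  xb <- study$values[, b, drop = FALSE]
  if (log_scale) {
    xa <- log2(xa + 1e-8)
    xb <- log2(xb + 1e-8)
  }
  p <- vapply(seq_len(nrow(xa)),
              function(i) t_test_p(xa[i, ], xb[i, ], var_equal),
              numeric(1))
  stats::setNames(p, rownames(study$values))
}

#' Call differentially expressed genes for one stage contrast
#'
#' A gene is significant iff its fold change exceeds `fc_cutoff` in either
#' direction (`fc > fc_cutoff` or `fc < 1/fc_cutoff`) and its t-test
#' p-value is below `p_cutoff`. No multiple-testing correction enters the
#' call (the selection rule is on raw p), but BH-adjusted q-values are
#' reported alongside for transparency.
#'
#' @param study a floored [expression_study()].
#' @param contrast character vector `c(treated, control)`.
#' @param fc_cutoff fold-change cutoff (> 1).
#' @param p_cutoff p-value cutoff.
#' @inheritParams de_t_test
#' @return data frame of class `de_result` with one row per gene:
#'   `gene_id`, `contrast`, `mean_treated`, `mean_control`, `fc`,
#'   `log2_fc`, `direction` (`up`/`down`/`flat`), `p_value`, `q_value`,
#'   `significant`.
#' @export
call_de <- function(study, contrast, fc_cutoff = 2, p_cutoff = 0.05,
                    var_equal = TRUE, log_scale = FALSE) {
  stopifnot(fc_cutoff >= 1)
  fc <- fold_change(study, contrast)
  p <- de_t_test(study, contrast, var_equal = var_equal, log_scale = log_scale)
  beyond <- fc$fc > fc_cutoff | fc$fc < 1 / fc_cutoff
  sig <- beyond & p < p_cutoff
  out <- data.frame(
    gene_id = fc$gene_id, contrast = contrast_label(contrast),
    mean_treated = fc$mean_treated, mean_control = fc$mean_control,
    fc = fc$fc, log2_fc = fc$log2_fc,
    direction = ifelse(!sig, "flat", ifelse(fc$log2_fc > 0, "up", "down")),
    p_value = unname(p), q_value = stats::p.adjust(p, "BH"),
    significant = sig, row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("de_result", "data.frame")
  out
}

#' Venn partition of two differential-expression contrasts
#'
#' Partitions the up- and down-regulated gene sets of two contrasts over
#' the same gene universe into exclusives and intersections, with counts.
#'
#' @param de_a,de_b `de_result` tables from [call_de()] over the same gene
#'   universe.
#' @return list of class `venn_partition` with per-direction gene sets
#'   (`a_only`, `b_only`, `shared`, `a`, `b`, `union`) and a `counts` data
#'   frame.
#' @export
venn_partition <- function(de_a, de_b) {
  if (!setequal(de_a$gene_id, de_b$gene_id))
    stop("the two contrasts cover different gene universes")
  part_dir <- function(dir) {
    a <- de_a$gene_id[de_a$significant & de_a$direction == dir]
    b <- de_b$gene_id[de_b$significant & de_b$direction == dir]
    list(a = a, b = b,
         shared = intersect(a, b),
         a_only = setdiff(a, b), b_only = setdiff(b, a),
         union = union(a, b))
  }
  out <- list(up = part_dir("up"), down = part_dir("down"),
              contrasts = c(de_a$contrast[1], de_b$contrast[1]))
  all_a <- de_a$gene_id[de_a$significant]
  all_b <- de_b$gene_id[de_b$significant]
  out$any <- list(a = all_a, b = all_b, shared = intersect(all_a, all_b),
                  a_only = setdiff(all_a, all_b),
                  b_only = setdiff(all_b, all_a), union = union(all_a, all_b))
  out$counts <- do.call(rbind, lapply(c("up", "down", "any"), function(d) {
    p <- out[[d]]
    data.frame(direction = d, n_a = length(p$a), n_b = length(p$b),
               n_shared = length(p$shared), n_a_only = length(p$a_only),
               n_b_only = length(p$b_only), n_union = length(p$union))
  }))
  class(out) <- "venn_partition"
  out
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("Venn partition of", x$contrasts[1], "vs", x$contrasts[2], "\n")
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' Select the top fraction of up/down-regulated genes
#'
#' Among significant genes of each direction, keeps the
#' `ceiling(fraction * count)` genes with the largest |log2 fold change|
#' (largest log2 FC for up, most negative for down). Ties are broken by
#' gene id so the selection is deterministic.
#'
#' @param de a `de_result` table from [call_de()].
#' @param fraction fraction in (0, 1] of each direction's significant genes.
#' @return list with character vectors `up` and `down`.
#' @export
select_top_fraction <- function(de, fraction = 0.10) {
  stopifnot(fraction > 0, fraction <= 1)
  pick <- function(dir) {
    sub <- de[de$significant & de$direction == dir, , drop = FALSE]
    if (!nrow(sub)) {
      warning("no significant ", dir, "-regulated genes")
      return(character(0))
    }
    score <- if (dir == "up") -sub$log2_fc else sub$log2_fc
    sub$gene_id[order(score, sub$gene_id)][seq_len(ceiling(fraction * nrow(sub)))]
  }
  list(up = pick("up"), down = pick("down"))
}
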