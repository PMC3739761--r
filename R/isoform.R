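## Isoform-level summaries: expressed-isoform counts per gene and stage,
## major-isoform identification, switch detection between stages, and
## one-way ANOVA of isoform expression across stages.

iso_map_of <- function(study) {
  if (!identical(study$feature_kind, "isoform") || is.null(study$isoform_map))
    stop("an isoform-level study with an isoform-to-gene map is required")
  study$isoform_map
}

#' Count expressed isoforms per gene and stage
#'
#' An isoform counts as expressed in a stage when its stage-mean FPKM is at
#' or above the detection threshold (the same global threshold used at the
#' gene level).
#'
#' @param study isoform-level [expression_study()].
#' @param threshold expression threshold in FPKM.
#' @return list with `counts` (data frame: `gene_id`, one column per stage,
#'   `max_isoforms` annotated), `histogram` (data frame of annotated
#'   isoforms-per-gene tallies), and `multi_isoform` (per stage, the number
#'   of genes with more than one isoform expressed in that stage; the
#'   `all_stages` entry counts genes with more than one isoform expressed
#'   in every stage).
#' @export
count_expressed_isoforms <- function(study, threshold = 0.1) {
  map <- iso_map_of(study)
  sm <- stage_means(study)
  expressed <- sm >= threshold
  gene <- factor(map$gene_id[match(rownames(sm), map$isoform_id)])
  counts <- apply(expressed, 2, function(e) tapply(e, gene, sum))
  counts <- as.data.frame(counts)
  counts <- data.frame(gene_id = rownames(counts), counts,
                       row.names = NULL, check.names = FALSE)
  n_iso <- as.vector(table(gene)[as.character(counts$gene_id)])
  counts$annotated <- n_iso
  hist <- as.data.frame(table(n_isoforms = n_iso), stringsAsFactors = FALSE)
  names(hist) <- c("n_isoforms", "n_genes")
  hist$n_isoforms <- as.integer(hist$n_isoforms)
  per_stage <- colSums(counts[, study$stages, drop = FALSE] > 1)
  multi <- c(as.list(per_stage),
             all_stages = sum(apply(counts[, study$stages, drop = FALSE] > 1,
                                    1, all)))
  list(counts = counts, histogram = hist, multi_isoform = multi)
}

#' Major isoform of each gene per stage
#'
#' The isoform with the largest stage-mean FPKM; exact ties resolve to the
#' lexicographically smallest isoform id and are flagged. Genes with no
#' expressed isoform in a stage get `NA` with a flag.
#'
#' @param study isoform-level [expression_study()].
#' @param threshold minimum stage-mean FPKM for an isoform to count as
#'   expressed.
#' @return data frame: `gene_id`, `stage`, `major_isoform`, `major_fpkm`,
#'   `tie`, `undefined`.
#' @export
major_isoform <- function(study, threshold = 0.1) {
  map <- iso_map_of(study)
  sm <- stage_means(study)
  iso_by_gene <- split(map$isoform_id, map$gene_id)
  genes <- names(iso_by_gene)
  rows <- lapply(genes, function(g) {
    iso <- sort(iso_by_gene[[g]])
    sub <- sm[iso, , drop = FALSE]
    do.call(rbind, lapply(colnames(sub), function(s) {
      v <- sub[, s]
      if (all(v < threshold))
        return(data.frame(gene_id = g, stage = s, major_isoform = NA_character_,
                          major_fpkm = NA_real_, tie = FALSE, undefined = TRUE))
      best <- max(v)
      hits <- iso[v == best]
      data.frame(gene_id = g, stage = s, major_isoform = hits[1],
                 major_fpkm = best, tie = length(hits) > 1, undefined = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Detect major-isoform switches across the time course
#'
#' A gene switches when its major isoform differs between at least two
#' stages; the earliest such stage pair (in stage order) is reported. An
#' optional margin requires the new major isoform to exceed the displaced
#' one by at least `margin`-fold in the later stage, guarding against
#' noise-driven flips; `margin = 1` reproduces the plain rule.
#'
#' @param majors data frame from [major_isoform()], or an isoform-level
#'   study (in which case majors are computed first).
#' @param margin fold-ratio the incoming major must reach over the outgoing
#'   one (>= 1).
#' @param threshold passed to [major_isoform()] when `majors` is a study.
#' @return data frame: `gene_id`, `switch`, `stage_from`, `stage_to`,
#'   `major_from`, `major_to`.
#' @export
detect_switch <- function(majors, margin = 1, threshold = 0.1) {
  stopifnot(margin >= 1)
  study <- NULL
  if (inherits(majors, "expression_study")) {
    study <- majors
    majors <- major_isoform(study, threshold = threshold)
  }
  sm <- if (!is.null(study)) stage_means(study)
  stages <- unique(majors$stage)
  by_gene <- split(seq_len(nrow(majors)), majors$gene_id)
  genes <- names(by_gene)
  out <- lapply(genes, function(g) {
    sub <- majors[by_gene[[g]], , drop = FALSE]
    sub <- sub[!sub$undefined, , drop = FALSE]
    sub <- sub[match(stages, sub$stage), , drop = FALSE]
    sub <- sub[!is.na(sub$gene_id), , drop = FALSE]
    res <- data.frame(gene_id = g, switch = FALSE, stage_from = NA_character_,
                      stage_to = NA_character_, major_from = NA_character_,
                      major_to = NA_character_, stringsAsFactors = FALSE)
    if (nrow(sub) < 2) return(res)
    for (i in seq_len(nrow(sub) - 1)) {
      for (j in seq(i + 1, nrow(sub))) {
        if (sub$major_isoform[i] != sub$major_isoform[j]) {
          if (margin > 1 && !is.null(sm)) {
            old_in_later <- sm[sub$major_isoform[i], sub$stage[j]]
            if (sub$major_fpkm[j] < margin * old_in_later) next
          }
          res$switch <- TRUE
          res$stage_from <- sub$stage[i]; res$stage_to <- sub$stage[j]
          res$major_from <- sub$major_isoform[i]
          res$major_to <- sub$major_isoform[j]
          return(res)
        }
      }
    }
    res
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' One-way fixed-effects ANOVA across stages
#'
#' Standard one-way ANOVA of replicate values grouped by stage, as used to
#' test whether an isoform's expression changes over the injury course.
#' Degenerate inputs are resolved by convention: all values identical gives
#' p = 1; zero within-group variance with differing group means gives p = 0
#' with a warning.
#'
#' @param values numeric vector of replicate measurements.
#' @param group stage labels, same length as `values` (>= 2 stages, >= 2
#'   replicates in at least one stage).
#' @return list with `f` and `p`.
#' @export
anova_across_stages <- function(values, group) {
  group <- factor(group)
  if (nlevels(group) < 2) stop("need at least 2 stages")
  if (length(values) - nlevels(group) < 1)
    stop("need at least 2 replicates in at least one stage")
  gm <- tapply(values, group, mean)
  within_ss <- sum((values - gm[group])^2)
  if (within_ss < 1e-24) {
    if (stats::var(values) < 1e-24) return(list(f = 0, p = 1))
    warning("zero within-group variance with differing means; p set to 0")
    return(list(f = Inf, p = 0))
  }
  fit <- stats::anova(stats::lm(values ~ group))
  list(f = fit[["F value"]][1], p = fit[["Pr(>F)"]][1])
}

#' Per-isoform ANOVA across stages for a whole study
#'
#' @param study isoform-level [expression_study()].
#' @return data frame: `isoform_id`, `gene_id`, `f`, `p`.
#' @export
isoform_anova <- function(study) {
  map <- iso_map_of(study)
  group <- study$samples$stage
  res <- t(vapply(rownames(study$values), function(i) {
    a <- anova_across_stages(study$values[i, ], group)
    c(a$f, a$p)
  }, numeric(2)))
  data.frame(isoform_id = rownames(study$values),
             gene_id = map$gene_id[match(rownames(study$values), map$isoform_id)],
             f = res[, 1], p = res[, 2],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-gene isoform profile table
#'
#' Convenience wrapper combining expressed-isoform counts, major isoforms
#' and switch calls into one table per gene.
#'
#' @param study isoform-level [expression_study()].
#' @param threshold expressed-isoform threshold (FPKM).
#' @param margin switch margin (see [detect_switch()]).
#' @return data frame with one row per gene: annotated and per-stage
#'   expressed isoform counts, per-stage major isoform, switch call.
#' @export
isoform_profiles <- function(study, threshold = 0.1, margin = 1) {
  cnt <- count_expressed_isoforms(study, threshold)
  majors <- major_isoform(study, threshold)
  sw <- detect_switch(if (margin > 1) study else majors,
                      margin = margin, threshold = threshold)
  wide <- stats::reshape(majors[, c("gene_id", "stage", "major_isoform")],
                         idvar = "gene_id", timevar = "stage",
                         direction = "wide")
  names(wide) <- sub("^major_isoform\\.", "major_", names(wide))
  out <- merge(cnt$counts, wide, by = "gene_id")
  merge(out, sw, by = "gene_id")
}
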