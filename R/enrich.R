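## Two enrichment engines: Fisher/hypergeometric over-representation of a
## query gene set against a collection, and a rank-based weighted
## Kolmogorov-Smirnov enrichment score with a gene-label permutation null.

#' Fisher over-representation of gene sets in a query
#'
#' One-sided hypergeometric upper-tail test per set (classical Fisher exact
#' over-representation), with BH correction across sets. Sets are
#' intersected with the universe first.
#'
#' @param query character vector of genes (must lie in `universe`).
#' @param sets named list of gene sets.
#' @param universe background genes, typically all genes passing the
#'   detection threshold.
#' @return data frame: `set`, `overlap`, `set_size`, `query_size`,
#'   `universe_size`, `odds_ratio`, `p_value`, `q_value`.
#' @export
fisher_enrichment <- function(query, sets, universe) {
  if (!length(universe)) stop("empty universe")
  if (!length(query)) stop("empty query")
  universe <- unique(universe)
  query <- unique(query)
  if (length(setdiff(query, universe)))
    stop("query gene(s) outside the universe")
  n <- length(universe)
  q_n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], universe)
    k <- length(intersect(s, query))
    m <- length(s)
    p <- if (m == 0) 1 else
      stats::phyper(k - 1, m, n - m, q_n, lower.tail = FALSE)
    ## odds ratio of the 2x2 table (query x set membership)
    a <- k; b <- q_n - k; c_ <- m - k; d <- n - m - b
    or <- (a * d) / max(b * c_, .Machine$double.eps)
    data.frame(set = nm, overlap = k, set_size = m, query_size = q_n,
               universe_size = n, odds_ratio = or, p_value = min(p, 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, "BH")
  rownames(out) <- NULL
  out
}

#' Rank genes by fold change for enrichment analysis
#'
#' @param de `de_result` table from [call_de()] (or any data frame with
#'   `gene_id` and `log2_fc`).
#' @return data frame `gene_id`, `metric` (log2 fold change), sorted by
#'   decreasing metric with gene-id tie-break.
#' @export
rank_by_fold_change <- function(de) {
  if (anyNA(de$log2_fc)) stop("log2_fc must be available for every gene")
  ord <- order(-de$log2_fc, de$gene_id)
  data.frame(gene_id = de$gene_id[ord], metric = de$log2_fc[ord],
             row.names = NULL, stringsAsFactors = FALSE)
}

## core running-sum statistic on a pre-ranked list; `hit` is a logical
## vector along the ranking
running_score <- function(metric, hit, weight_p = 1) {
  n <- length(metric)
  n_hit <- sum(hit)
  if (n_hit == 0) stop("gene set does not intersect the ranked list")
  if (n_hit == n) stop("gene set covers the entire ranked list")
  w <- abs(metric)^weight_p
  inc <- numeric(n)
  inc[hit] <- w[hit] / sum(w[hit])
  inc[!hit] <- -1 / (n - n_hit)
  if (sum(w[hit]) == 0) inc[hit] <- 1 / n_hit   # all-zero metrics degrade to p = 0
  cumsum(inc)
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list accumulating a running sum: genes in the set
#' ("hits") increment it by their |metric|^p share of the in-set weight,
#' genes outside decrement it by 1/(N - N_set). The enrichment score is the
#' signed maximum deviation of this running sum from zero; for a randomly
#' scattered set it is near zero, for a set concentrated at the top it
#' approaches +1.
#'
#' @param ranked data frame from [rank_by_fold_change()] (columns
#'   `gene_id`, `metric`, already sorted).
#' @param set character vector of gene ids.
#' @param weight_p weight exponent p; 0 gives the classic unweighted KS
#'   statistic, 1 the standard weighted statistic.
#' @return list of class `es_result` with `es`, `running` (the full curve),
#'   `hit_index`, and `leading_edge` (set genes at or before the extremum
#'   for positive ES, at or after it for negative ES).
#' @export
enrichment_score <- function(ranked, set, weight_p = 1) {
  hit <- ranked$gene_id %in% set
  running <- running_score(ranked$metric, hit, weight_p)
  i_max <- which.max(abs(running))
  es <- running[i_max]
  leading <- if (es >= 0) ranked$gene_id[seq_len(i_max)][hit[seq_len(i_max)]]
  else ranked$gene_id[seq(i_max, length(hit))][hit[seq(i_max, length(hit))]]
  structure(list(es = es, running = running, hit_index = which(hit),
                 leading_edge = leading, weight_p = weight_p),
            class = "es_result")
}

#' @export
print.es_result <- function(x, ...) {
  cat(sprintf("enrichment score %.4f (%d hits, %d leading-edge gene(s))\n",
              x$es, length(x$hit_index), length(x$leading_edge)))
  invisible(x)
}

#' Permutation null, normalized ES and nominal p for gene sets
#'
#' Gene-label permutation: null scores come from random gene sets of the
#' same size drawn from the ranked list (phenotype permutation is
#' degenerate at 2-3 replicates per stage). NES divides ES by the mean
#' |null ES| of the same sign; the nominal p is the fraction of same-sign
#' null scores at least as extreme, floored at 1/(n_perm + 1) so it is
#' never exactly zero; FDR q-values are BH across the queried sets.
#'
#' @param ranked ranked list from [rank_by_fold_change()].
#' @param sets named list of gene sets to score.
#' @param n_perm number of permutations (>= 100).
#' @param weight_p weight exponent (see [enrichment_score()]).
#' @param seed integer seed for the permutation draw.
#' @return data frame of class `gsea_result`: `set`, `size`, `es`, `nes`,
#'   `p_value`, `q_value`, `n_perm`, `leading_edge` (comma-separated).
#' @export
gsea_permutation <- function(ranked, sets, n_perm = 1000, weight_p = 1,
                             seed = 1L) {
  if (n_perm < 100) stop("use at least 100 permutations")
  set.seed(as.integer(seed))
  n <- nrow(ranked)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], ranked$gene_id)
    es_obs <- enrichment_score(ranked, s, weight_p)
    size <- length(s)
    null_es <- vapply(seq_len(n_perm), function(i) {
      hit <- logical(n)
      hit[sample.int(n, size)] <- TRUE
      r <- running_score(ranked$metric, hit, weight_p)
      r[which.max(abs(r))]
    }, numeric(1))
    same <- null_es[sign(null_es) == sign(es_obs$es)]
    p <- if (length(same)) (sum(abs(same) >= abs(es_obs$es)) + 1) / (length(same) + 1)
    else 1 / (n_perm + 1)
    nes <- if (length(same)) es_obs$es / mean(abs(same)) else NA_real_
    data.frame(set = nm, size = size, es = es_obs$es, nes = nes,
               p_value = p, n_perm = n_perm,
               leading_edge = paste(es_obs$leading_edge, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, "BH")
  out <- out[, c("set", "size", "es", "nes", "p_value", "q_value",
                 "n_perm", "leading_edge")]
  rownames(out) <- NULL
  class(out) <- c("gsea_result", "data.frame")
  out
}
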