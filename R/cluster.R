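## Expression-trajectory clustering across stages (fuzzy c-means on
## z-scored stage-mean profiles) and sample-level QC clustering
## (complete-linkage on 1 - Pearson over the most variable genes).

#' Select genes whose expression varies across stages
#'
#' Keeps genes whose floored stage means change more than `min_fc`-fold
#' between at least two stages, i.e. `max(stage mean) / min(stage mean) >
#' min_fc`.
#'
#' @param study a floored [expression_study()].
#' @param min_fc minimum between-stage fold change.
#' @return character vector of gene ids.
#' @export
select_varying_genes <- function(study, min_fc = 2) {
  m <- stage_means(study)
  lo <- apply(m, 1, min)
  hi <- apply(m, 1, max)
  rownames(m)[hi / lo > min_fc]
}

#' Z-score expression profiles gene-wise
#'
#' Subtracts each gene's mean across stages and divides by its population
#' standard deviation (denominator n, so a 3-stage profile `(1, 2, 3)` maps
#' exactly to `(-1.22..., 0, 1.22...) / 1` with sd computed over n). The
#' result is invariant to affine transforms `a * x + b` (a > 0) of a
#' profile.
#'
#' @param profiles genes x stages matrix (e.g. from [stage_means()]).
#' @return matrix of the same shape with zero mean and unit population sd
#'   per row.
#' @export
standardize_profiles <- function(profiles) {
  profiles <- as.matrix(profiles)
  if (ncol(profiles) < 2) stop("need at least 2 stages to standardize")
  mu <- rowMeans(profiles)
  centered <- profiles - mu
  sd_pop <- sqrt(rowMeans(centered^2))
  if (any(sd_pop < 1e-12))
    stop("constant profile(s) cannot be standardized; filter with ",
         "select_varying_genes() first: ",
         paste(utils::head(rownames(profiles)[sd_pop < 1e-12], 5), collapse = ", "))
  centered / sd_pop
}

## k-means++-style seeding: first center uniform, then each new center
## drawn with probability proportional to squared distance to the nearest
## chosen center
seed_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k)[-1]) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j, ] <- x[sample.int(n, 1, prob = prob), ]
    d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x), byrow = TRUE))^2))
  }
  centers
}

#' Fuzzy c-means clustering of trajectory profiles
#'
#' Classic alternating optimization of the fuzzy c-means objective
#' `J = sum_ij u_ij^m ||x_i - c_j||^2`: memberships from inverse squared
#' distances with fuzzifier exponent `m`, centers as membership-weighted
#' means. Initialization is k-means++-style seeding from `seed`, so results
#' are deterministic given the seed. Iteration stops when the objective
#' decreases by less than `tol` or after `max_iter` sweeps.
#'
#' @param x numeric matrix of profiles (rows clustered), typically
#'   standardized stage means.
#' @param k number of clusters (>= 2, < nrow(x)).
#' @param m fuzzifier (> 1); 1.25 suits z-scored trajectory profiles.
#' @param seed integer seed for the initialization.
#' @param nstart number of restarts from different seedings; the run with
#'   the lowest final objective is returned (restart r uses seed + r - 1).
#' @param max_iter,tol iteration controls.
#' @return object of class `fuzzy_cmeans`: list with `centers` (k x
#'   stages), `membership` (rows x k, each row summing to 1), `cluster`
#'   (hard argmax assignment), `objective` (per-iteration trace), `k`, `m`.
#' @export
fuzzy_cmeans <- function(x, k = 9, m = 1.25, seed = 1L, nstart = 3,
                         max_iter = 500, tol = 1e-9) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k >= n) stop("k must be smaller than the number of profiles")
  if (k < 2) stop("k must be at least 2")
  if (m <= 1) stop("fuzzifier m must exceed 1")
  if (nstart > 1) {
    runs <- lapply(seq_len(nstart), function(r)
      fuzzy_cmeans(x, k = k, m = m, seed = as.integer(seed) + r - 1L,
                   nstart = 1, max_iter = max_iter, tol = tol))
    finals <- vapply(runs, function(r) r$objective[length(r$objective)],
                     numeric(1))
    best <- runs[[which.min(finals)]]
    best$seed <- seed
    return(best)
  }
  set.seed(as.integer(seed))
  centers <- seed_centers(x, k)
  obj <- numeric(0)
  u <- NULL
  for (iter in seq_len(max_iter)) {
    d2 <- outer(rowSums(x^2), rep(1, k)) - 2 * x %*% t(centers) +
      outer(rep(1, n), rowSums(centers^2))
    d2 <- pmax(d2, 0)
    zero <- d2 < 1e-12
    u <- (1 / pmax(d2, 1e-12))^(1 / (m - 1))
    u <- u / rowSums(u)
    hit <- rowSums(zero) > 0
    if (any(hit)) {                       # profile sits on a center
      u[hit, ] <- 0
      u[hit, ] <- zero[hit, , drop = FALSE] / rowSums(zero[hit, , drop = FALSE])
    }
    um <- u^m
    obj <- c(obj, sum(um * d2))
    centers_new <- (t(um) %*% x) / colSums(um)
    if (length(obj) >= 2 && obj[length(obj) - 1] - obj[length(obj)] < tol) {
      centers <- centers_new
      break
    }
    centers <- centers_new
  }
  colnames(centers) <- colnames(x)
  dimnames(u) <- list(rownames(x), paste0("cluster_", seq_len(k)))
  structure(list(centers = centers, membership = u,
                 cluster = max.col(u, ties.method = "first"),
                 objective = obj, k = k, m = m, seed = seed),
            class = "fuzzy_cmeans")
}

#' @export
print.fuzzy_cmeans <- function(x, ...) {
  cat(sprintf("fuzzy c-means: %d profiles, k = %d, m = %.2f, %d iteration(s), objective %.4g\n",
              nrow(x$membership), x$k, x$m, length(x$objective),
              x$objective[length(x$objective)]))
  invisible(x)
}

#' Hierarchical clustering of samples for quality control
#'
#' Ranks genes by variance across samples, keeps the `top_n` most variable,
#' and agglomerates samples by complete linkage on the distance
#' `1 - Pearson correlation`. Samples are ordered by id before clustering
#' so the dendrogram is invariant to input column order.
#'
#' @param study an [expression_study()].
#' @param top_n number of most-variable genes to use.
#' @return list of class `sample_dendrogram` with `hclust` (a
#'   [stats::hclust()] tree), `dist` (the correlation distance matrix) and
#'   `genes_used`.
#' @export
hierarchical_samples <- function(study, top_n = 3000) {
  stopifnot(inherits(study, "expression_study"))
  if (ncol(study$values) < 3) stop("need at least 3 samples to cluster")
  v <- study$values[, order(colnames(study$values)), drop = FALSE]
  vars <- apply(v, 1, stats::var)
  keep <- rownames(v)[order(-vars, rownames(v))][seq_len(min(top_n, nrow(v)))]
  sub <- v[keep, , drop = FALSE]
  sds <- apply(sub, 2, stats::sd)
  if (any(sds < 1e-12))
    stop("constant sample(s): ", paste(colnames(sub)[sds < 1e-12], collapse = ", "))
  d <- stats::as.dist(1 - stats::cor(sub))
  hc <- stats::hclust(d, method = "complete")
  structure(list(hclust = hc, dist = d, genes_used = keep),
            class = "sample_dendrogram")
}

#' @export
print.sample_dendrogram <- function(x, ...) {
  cat(sprintf("complete-linkage sample dendrogram over %d genes\n",
              length(x$genes_used)))
  print(x$hclust)
  invisible(x)
}

#' Pairwise Pearson correlation of samples
#'
#' @param study an [expression_study()].
#' @return symmetric sample x sample correlation matrix with unit diagonal;
#'   entries involving a zero-variance sample are `NA` with a warning.
#' @export
replicate_correlation <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  if (ncol(study$values) < 2) stop("need at least 2 samples")
  sds <- apply(study$values, 2, stats::sd)
  if (any(sds < 1e-12))
    warning("zero-variance sample(s) give undefined correlations: ",
            paste(colnames(study$values)[sds < 1e-12], collapse = ", "))
  r <- suppressWarnings(stats::cor(study$values))
  diag(r) <- 1
  r
}
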