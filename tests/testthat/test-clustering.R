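test_that("varying-gene selection applies the max/min stage-mean rule", {
  means <- matrix(c(1, 1, 1,
                    1, 1, 2.5,
                    1, 1, 2), 3, 3, byrow = TRUE,
                  dimnames = list(c("flat", "varying", "edge"),
                                  c("CTR", "D2", "D7")))
  study <- toy_study_means(means)
  expect_identical(select_varying_genes(study, 2), "varying")

  ## brute-force pairwise check on random genes
  set.seed(12)
  m <- matrix(stats::rlnorm(3000, 0, 1.5), 1000, 3,
              dimnames = list(sprintf("g%04d", 1:1000), c("CTR", "D2", "D7")))
  st <- toy_study_means(m)
  got <- select_varying_genes(st, 2)
  want <- rownames(m)[sapply(seq_len(nrow(m)), function(i) {
    any(outer(m[i, ], m[i, ], "/") > 2)
  })]
  expect_identical(got, want)
})

test_that("profile standardization uses the population sd convention", {
  z <- standardize_profiles(matrix(c(1, 2, 3), 1, 3,
                                   dimnames = list("g", NULL)))
  ## hand computation: mean 2, population sd sqrt(2/3)
  expect_equal(unname(z[1, ]), c(-1, 0, 1) / sqrt(2 / 3), tolerance = 1e-12)

  set.seed(3)
  x <- matrix(stats::rnorm(60), 20, 3, dimnames = list(paste0("g", 1:20), NULL))
  z <- standardize_profiles(x)
  expect_equal(unname(rowMeans(z)), rep(0, 20), tolerance = 1e-12)
  expect_equal(unname(rowMeans(z^2)), rep(1, 20), tolerance = 1e-12)
  ## affine invariance
  expect_equal(standardize_profiles(3.7 * x + 11), z, tolerance = 1e-9)
  expect_error(standardize_profiles(matrix(5, 2, 3,
                                           dimnames = list(c("a", "b"), NULL))),
               "constant")
})

test_that("fuzzy c-means recovers separated clouds and obeys its invariants", {
  set.seed(20)
  centers <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0))
  truth <- rep(1:3, each = 40)
  x <- centers[truth, ] + matrix(stats::rnorm(360, 0, 0.3), 120, 3)
  rownames(x) <- paste0("g", 1:120)
  cm <- fuzzy_cmeans(x, k = 3, m = 1.5, seed = 2)
  ## hard assignment recovers the clouds exactly (up to label permutation)
  tab <- table(cm$cluster, truth)
  expect_equal(sum(apply(tab, 2, max)), 120)
  expect_equal(unname(rowSums(cm$membership)), rep(1, 120), tolerance = 1e-9)
  expect_true(all(cm$membership >= 0 & cm$membership <= 1))
  expect_true(all(diff(cm$objective) <= 1e-9))

  ## deterministic given the seed
  cm2 <- fuzzy_cmeans(x, k = 3, m = 1.5, seed = 2)
  expect_identical(cm$membership, cm2$membership)

  ## objective non-increasing across random inits
  set.seed(9)
  y <- matrix(stats::rnorm(300), 100, 3, dimnames = list(paste0("p", 1:100),
                                                         NULL))
  for (s in 1:20) {
    run <- fuzzy_cmeans(y, k = 5, m = 1.25, seed = s, nstart = 1)
    expect_true(all(diff(run$objective) <= 1e-9))
  }
  expect_error(fuzzy_cmeans(y[1:4, ], k = 4), "smaller")
})

test_that("fuzzy c-means agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(77)
  x <- matrix(stats::rnorm(240), 80, 3, dimnames = list(paste0("g", 1:80),
                                                        NULL))
  own <- fuzzy_cmeans(x, k = 4, m = 1.5, seed = 5)
  ## seeding e1071 from our converged centers must not move them
  ref <- e1071::cmeans(x, centers = own$centers, m = 1.5, iter.max = 300)
  expect_equal(unname(ref$centers), unname(own$centers), tolerance = 1e-3)
})

test_that("nine planted trajectory archetypes are recovered", {
  skip_if_not_installed("mclust")
  b1 <- c(-1, 0, 1) / sqrt(2); b2 <- c(1, -2, 1) / sqrt(6)
  archetype <- function(j) {
    th <- 2 * pi * (j - 1) / 9
    sqrt(3) * (cos(th) * b1 + sin(th) * b2)
  }
  set.seed(101)
  truth <- rep(1:9, each = 100)
  x <- t(sapply(truth, function(j) archetype(j) + stats::rnorm(3, 0, 0.2)))
  rownames(x) <- paste0("g", seq_len(nrow(x)))
  cm <- fuzzy_cmeans(standardize_profiles(x), k = 9, m = 1.25, seed = 1)
  expect_gte(mclust::adjustedRandIndex(cm$cluster, truth), 0.8)
})

test_that("sample dendrograms merge replicates before stages", {
  sim <- simulate_study(sim_config(n_genes = 800, noise_sd = 0.2, seed = 30))
  dend <- hierarchical_samples(sim$study, top_n = 500)
  ## cutting into 3 groups recovers the 3 stages
  groups <- stats::cutree(dend$hclust, k = 3)
  stage_of <- sim$study$samples$stage[match(names(groups),
                                            sim$study$samples$sample_id)]
  expect_equal(length(unique(paste(groups, stage_of))), 3)

  ## duplicated sample merges first at height 0
  mat <- sim$study$values[1:100, ]
  mat <- cbind(mat, dup = mat[, 1])
  samples <- rbind(sim$study$samples,
                   data.frame(sample_id = "dup", stage = "CTR", replicate = 9))
  st <- expression_study(mat, samples)
  d2 <- hierarchical_samples(st, top_n = 100)
  first <- d2$hclust$merge[1, ]
  expect_equal(d2$hclust$height[1], 0, tolerance = 1e-12)
  merged <- d2$hclust$labels[-first]
  expect_setequal(merged, c(colnames(sim$study$values)[1], "dup"))

  ## gene order does not change the tree
  perm <- sample(rownames(sim$study$values))
  d3 <- hierarchical_samples(subset_features(sim$study, perm), top_n = 500)
  expect_equal(d3$hclust$height, dend$hclust$height, tolerance = 1e-12)
  expect_identical(d3$hclust$merge, dend$hclust$merge)
})

test_that("replicate correlations match the Pearson formula", {
  mat <- matrix(c(1, 2, 3, 3, 2, 1, 2, 2, 5), 3, 3,
                dimnames = list(paste0("g", 1:3), c("a", "b", "c")))
  st <- toy_study(mat, c("A", "B", "C"), c(1, 1, 1))
  ## one replicate per stage is fine for correlation QC
  r <- replicate_correlation(st)
  expect_equal(unname(diag(r)), c(1, 1, 1))
  expect_equal(r["A_r1", "B_r1"], -1)

  set.seed(14)
  m <- matrix(stats::rlnorm(300), 50, 6,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:6)))
  st2 <- toy_study(m, paste0("S", 1:3), c(2, 2, 2))
  r2 <- replicate_correlation(st2)
  pearson <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  for (i in 1:5) for (j in (i + 1):6)
    expect_equal(unname(r2[i, j]), pearson(m[, i], m[, j]), tolerance = 1e-12)
})
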