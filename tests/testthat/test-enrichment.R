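test_that("Fisher enrichment equals the exhaustive hypergeometric tail", {
  ## saturated case: query = set = universe
  uni <- paste0("g", 1:10)
  res <- fisher_enrichment(uni, list(S = uni), uni)
  expect_equal(res$overlap, 10)
  expect_equal(res$p_value, 1)

  ## exhaustive enumeration oracle: P(X >= k) by direct combinatorial sum
  tail_sum <- function(k, m, n, q) {
    ks <- k:min(m, q)
    sum(choose(m, ks) * choose(n - m, q - ks)) / choose(n, q)
  }
  set.seed(47)
  for (i in 1:100) {
    n <- sample(10:60, 1)
    uni <- sprintf("u%03d", 1:n)
    m <- sample(1:n, 1)
    q <- sample(1:n, 1)
    s <- sample(uni, m)
    query <- sample(uni, q)
    res <- fisher_enrichment(query, list(S = s), uni)
    k <- length(intersect(s, query))
    expect_equal(res$overlap, k)
    expect_equal(res$p_value, tail_sum(k, m, n, q), tolerance = 1e-12)
  }

  ## spec'd worked case: 5 of a 10-gene set hit by a 10-gene query in 100
  res2 <- fisher_enrichment(sprintf("u%03d", 1:10),
                            list(S = sprintf("u%03d", 6:15)),
                            sprintf("u%03d", 1:100))
  expect_equal(res2$overlap, 5)
  expect_equal(res2$p_value, tail_sum(5, 10, 100, 10), tolerance = 1e-12)

  expect_error(fisher_enrichment(character(0), list(S = "a"), uni), "query")
  expect_error(fisher_enrichment("u001", list(S = "a"), character(0)),
               "universe")
})

test_that("fold-change ranking is a deterministic descending sort", {
  de <- data.frame(gene_id = c("g1", "g2", "g3"), log2_fc = c(2, -1, 0))
  r <- rank_by_fold_change(de)
  expect_equal(r$gene_id, c("g1", "g3", "g2"))
  r2 <- rank_by_fold_change(de[3:1, ])
  expect_identical(r, r2)

  set.seed(58)
  for (i in 1:50) {
    de <- data.frame(gene_id = sprintf("g%03d", sample(1:200)),
                     log2_fc = stats::rnorm(200))
    r <- rank_by_fold_change(de)
    ord <- order(-de$log2_fc, de$gene_id)
    expect_identical(r$gene_id, de$gene_id[ord])
  }
})

test_that("the running-sum ES matches a hand-walk oracle", {
  ## single-gene set at the top of the list scores exactly 1
  r10 <- data.frame(gene_id = paste0("g", 1:10), metric = rep(1, 10))
  expect_equal(enrichment_score(r10, "g1")$es, 1)
  ## ... and at the bottom the misses walk the sum to -1 first
  expect_equal(enrichment_score(r10, "g10")$es,
               walk_es(r10$metric, r10$gene_id == "g10"))
  expect_equal(enrichment_score(r10, "g10")$es, -1)

  ## random sets against the independent walker, both weightings
  set.seed(66)
  ranked <- data.frame(gene_id = sprintf("g%04d", 1:300),
                       metric = sort(stats::rnorm(300), decreasing = TRUE))
  for (i in 1:50) {
    s <- sample(ranked$gene_id, sample(3:60, 1))
    hit <- ranked$gene_id %in% s
    expect_equal(enrichment_score(ranked, s)$es,
                 walk_es(ranked$metric, hit, 1), tolerance = 1e-12)
    expect_equal(enrichment_score(ranked, s, weight_p = 0)$es,
                 walk_es(ranked$metric, hit, 0), tolerance = 1e-12)
  }

  ## degenerate sets are refused
  expect_error(enrichment_score(ranked, "nope"), "intersect")
  expect_error(enrichment_score(ranked, ranked$gene_id), "entire")
})

test_that("ES agrees with an independent GSEA implementation", {
  skip_if_not_installed("fgsea")
  set.seed(81)
  ranked <- data.frame(gene_id = sprintf("g%04d", 1:500),
                       metric = sort(stats::rnorm(500, 0, 2),
                                     decreasing = TRUE))
  for (i in 1:10) {
    s <- sample(ranked$gene_id, 40)
    own <- enrichment_score(ranked, s)$es
    ref <- fgsea::calcGseaStat(stats::setNames(ranked$metric,
                                               ranked$gene_id),
                               selectedStats = which(ranked$gene_id %in% s),
                               gseaParam = 1)
    expect_equal(own, ref, tolerance = 1e-12)
  }
})

test_that("ES scale invariances hold for the two weightings", {
  set.seed(92)
  ranked <- data.frame(gene_id = sprintf("g%04d", 1:200),
                       metric = sort(stats::rnorm(200), decreasing = TRUE))
  s <- sample(ranked$gene_id, 25)
  ## p = 1: invariant under positive scalar multiplication
  scaled <- ranked; scaled$metric <- scaled$metric * 7.3
  expect_equal(enrichment_score(scaled, s)$es,
               enrichment_score(ranked, s)$es, tolerance = 1e-12)
  ## p = 0: invariant under any monotone rescaling
  mono <- ranked; mono$metric <- exp(ranked$metric)
  expect_equal(enrichment_score(mono, s, weight_p = 0)$es,
               enrichment_score(ranked, s, weight_p = 0)$es,
               tolerance = 1e-12)
})

test_that("the permutation null is deterministic, floored and honest", {
  set.seed(7)
  ranked <- data.frame(gene_id = sprintf("g%04d", 1:400),
                       metric = sort(stats::rnorm(400, 0, 1.5),
                                     decreasing = TRUE))
  planted <- ranked$gene_id[1:20]
  res <- gsea_permutation(ranked, list(top = planted), n_perm = 200, seed = 4)
  expect_gt(res$es, 0.9)
  expect_lte(res$p_value, 1 / 100)
  expect_gt(res$p_value, 0)            # estimator floor, never exactly 0
  res2 <- gsea_permutation(ranked, list(top = planted), n_perm = 200, seed = 4)
  expect_identical(res, res2)
  expect_error(gsea_permutation(ranked, list(top = planted), n_perm = 10),
               "100")
  ## leading edge lies inside the set
  le <- strsplit(res$leading_edge, ",")[[1]]
  expect_true(all(le %in% planted))
})

test_that("planted signatures score highest in their own contrast", {
  ## two signature sets planted in two different contrasts: each must get
  ## the larger NES in its own contrast
  wins <- sapply(1:3, function(s) {
    b <- simulate_all(sim_config(n_genes = 600, seed = s + 200))
    fl <- floor_fpkm(b$study, 0.1)
    sets <- b$gene_sets[c("sig_D2_vs_CTR_up", "sig_D7_vs_CTR_up")]
    nes <- sapply(c("D2", "D7"), function(st) {
      ranked <- rank_by_fold_change(call_de(fl, c(st, "CTR")))
      gsea_permutation(ranked, sets, n_perm = 150,
                       seed = s)$nes
    })
    ## rows follow the set order (D2 signature first), columns the contrasts
    nes[1, "D2"] >= nes[1, "D7"] && nes[2, "D7"] >= nes[2, "D2"]
  })
  expect_gte(sum(wins), 2)
})
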