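test_that("config validation rejects impossible settings", {
  expect_error(sim_config(frac_up = 0.7, frac_down = 0.6), "exceed 1")
  expect_error(sim_config(detection_limit = 0), "detection_limit")
  expect_error(sim_config(replicates = c(1, 3, 3)), "replicates")
  expect_error(sim_config(n_genes = 100, network = list(n_nodes = 500)),
               "n_nodes")
})

test_that("the generator is bitwise reproducible from the seed", {
  b1 <- simulate_all(sim_config(n_genes = 150, seed = 42))
  b2 <- simulate_all(sim_config(n_genes = 150, seed = 42))
  expect_identical(b1$study$values, b2$study$values)
  expect_identical(b1$study$ci_lo, b2$study$ci_lo)
  expect_identical(b1$network$edges, b2$network$edges)
  expect_identical(b1$isoforms$study$values, b2$isoforms$study$values)
  expect_identical(b1$ct_table$ct, b2$ct_table$ct)
  b3 <- simulate_all(sim_config(n_genes = 150, seed = 43))
  expect_false(identical(b1$study$values, b3$study$values))
})

test_that("zero DE fractions give an empty ground-truth DE set", {
  sim <- simulate_study(sim_config(n_genes = 100, frac_up = 0, frac_down = 0,
                                   seed = 1))
  for (ct in sim$truth$de)
    expect_true(all(ct$direction == "flat") && all(ct$log2_fc == 0))
})

test_that("DE labels are consistent with planted fold changes", {
  sim <- simulate_study(sim_config(n_genes = 400, seed = 9))
  for (ct in sim$truth$de) {
    expect_true(all((ct$log2_fc > 0) == (ct$direction == "up")))
    expect_true(all((ct$log2_fc < 0) == (ct$direction == "down")))
    expect_true(all(abs(ct$log2_fc[ct$direction != "flat"]) >= 1))
  }
  ## silent genes are never DE and have zero truth in all stages
  expect_true(all(sim$truth$stage_means[sim$truth$silent, ] == 0))
})

test_that("observed values scatter around the truth as the noise model says", {
  ## per-gene mean of observed/true ratio should sit within +-3 sd of its
  ## expectation; with log2 noise sd 0.25 and 8 samples the 3-sd band for
  ## the per-gene mean ratio is about [0.81, 1.19]
  frac_in <- sapply(1:10, function(s) {
    sim <- simulate_study(sim_config(n_genes = 2000, seed = s))
    truth <- sim$truth$stage_means[, sim$study$samples$stage]
    keep <- rowSums(truth == 0) == 0
    ratio <- rowMeans(sim$study$values[keep, ] / truth[keep, ])
    mean(ratio > 1 - 3 * 0.063 & ratio < 1 + 3 * 0.063)
  })
  expect_gt(mean(frac_in), 0.985)
})

test_that("simulated networks are connected, hub-planted and heavy-tailed", {
  cfg <- sim_config(n_genes = 100, seed = 2,
                    network = list(n_hubs = 2, hub_min_degree = 15))
  genes <- sprintf("G%05d", 1:50)
  net <- simulate_network(cfg, genes)
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE)
  expect_true(igraph::is_connected(g))
  expect_true(all(igraph::degree(g)[net$hubs] >= 15))

  ## two nodes give exactly one edge
  expect_equal(nrow(simulate_network(cfg, genes[1:2])$edges), 1)
  expect_error(simulate_network(cfg, genes[1]), "at least 2")

  ## heavier tail than Erdos-Renyi with the same edge count
  cfg0 <- sim_config(n_genes = 200, seed = 3,
                     network = list(n_hubs = 0, attach_m = 2))
  max_pa <- max_er <- numeric(20)
  for (s in 1:20) {
    cfgs <- sim_config(n_genes = 200, seed = s,
                       network = list(n_hubs = 0, attach_m = 2))
    e <- simulate_network(cfgs, sprintf("G%05d", 1:200))$edges
    gpa <- igraph::graph_from_data_frame(e, directed = FALSE)
    set.seed(s)
    ger <- igraph::sample_gnm(igraph::vcount(gpa), igraph::ecount(gpa))
    max_pa[s] <- max(igraph::degree(gpa))
    max_er[s] <- max(igraph::degree(ger))
  }
  expect_gt(mean(max_pa), mean(max_er))
})

test_that("isoform structure conserves gene totals and plants real switches", {
  cfg <- sim_config(n_genes = 250, seed = 4)
  sim <- simulate_study(cfg)
  iso <- simulate_isoforms(cfg, sim)
  ## per-sample conservation: isoform values sum to the gene value
  gene_of <- iso$study$isoform_map$gene_id[
    match(rownames(iso$study$values), iso$study$isoform_map$isoform_id)]
  agg <- rowsum(iso$study$values, gene_of)
  expect_equal(agg[rownames(sim$study$values), ], sim$study$values,
               tolerance = 1e-9)
  ## single-isoform genes carry the gene value exactly
  single <- names(iso$truth$counts)[iso$truth$counts == 1]
  i1 <- paste0(single[1], ".1")
  expect_equal(iso$study$values[i1, ], sim$study$values[single[1], ])
  ## planted switches change the true major isoform across the course
  first <- sim$truth$stages[1]; last <- tail(sim$truth$stages, 1)
  sw <- iso$truth$switch_genes
  expect_true(length(sw) > 0)
  expect_true(all(iso$truth$major[sw, first] != iso$truth$major[sw, last]))
  ## non-switch genes keep a constant true major
  non <- setdiff(rownames(iso$truth$major), sw)
  expect_true(all(iso$truth$major[non, first] == iso$truth$major[non, last]))
})

test_that("isoform count distribution matches its configuration", {
  ## default annotation puts 99% of genes at 1-5 isoforms
  frac5 <- sapply(1:10, function(s) {
    cfg <- sim_config(n_genes = 800, seed = s)
    iso <- simulate_isoforms(cfg, simulate_study(cfg))
    mean(iso$truth$counts <= 5)
  })
  expect_equal(mean(frac5), 0.99, tolerance = 0.005)
  expect_true(all(sapply(1:3, function(s) {
    cfg <- sim_config(n_genes = 300, seed = s)
    max(simulate_isoforms(cfg, simulate_study(cfg))$truth$counts) <= 12
  })))
})

test_that("simulated Ct tables encode fold changes at one cycle per 2-fold", {
  ## noiseless closed forms via a hand-built truth object
  truth <- list(stage_means = matrix(c(4, 4, 4, 4, 32, 1), 2, 3,
                                     byrow = TRUE,
                                     dimnames = list(c("gA", "gB"),
                                                     c("CTR", "D2", "D7"))),
                stages = c("CTR", "D2", "D7"),
                config = list(replicates = c(2, 2, 2)))
  cfg <- sim_config(seed = 1, qpcr = list(ct_sd = 0))
  ct <- simulate_qpcr(truth, c("gA", "gB"), cfg)
  ## gA: fold 1 (D2/CTR) -> ddCt 0, fold 1; gB: fold 8 -> ddCt -3
  rA <- delta_delta_ct(ct, "gA", c("D2", "CTR"))
  rB <- delta_delta_ct(ct, "gB", c("D2", "CTR"))
  expect_equal(rA$ddct, 0, tolerance = 1e-12)
  expect_equal(rA$fold, 1, tolerance = 1e-12)
  expect_equal(rB$ddct, -3, tolerance = 1e-12)
  expect_equal(rB$fold, 8, tolerance = 1e-12)
  ## silent genes cannot be assayed
  truth$stage_means["gB", "CTR"] <- 0
  expect_error(simulate_qpcr(truth, c("gA", "gB"), cfg), "silent")
})

test_that("raising replicate noise lowers DE sensitivity at fixed cutoffs", {
  sens <- sapply(c(0.1, 0.3, 0.6), function(nsd) {
    mean(sapply(1:3, function(s) {
      sim <- simulate_study(sim_config(n_genes = 600, noise_sd = nsd,
                                       seed = s))
      de <- call_de(floor_fpkm(sim$study, 0.1), c("D2", "CTR"))
      tr <- sim$truth$de$D2_vs_CTR
      truly <- tr$gene_id[tr$direction != "flat"]
      mean(de$significant[match(truly, de$gene_id)])
    }))
  })
  expect_true(all(diff(sens) < 0))
})
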