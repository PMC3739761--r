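test_that("network induction follows the first-neighbor growth rule", {
  edges <- normalize_edges(data.frame(from = c("A"), to = c("B")))
  net <- build_network(c("A", "B"), edges)
  expect_setequal(igraph::V(net)$name, c("A", "B"))
  expect_equal(igraph::ecount(net), 1)
  expect_equal(unname(connection_numbers(net)), c(1, 1))

  edges2 <- normalize_edges(data.frame(from = c("A", "C"), to = c("C", "D")))
  net2 <- build_network("A", edges2, include_neighbors = TRUE)
  expect_setequal(igraph::V(net2)$name, c("A", "C"))
  net3 <- build_network("A", edges2, include_neighbors = FALSE)
  ## A alone is isolated once D's bridge C is excluded
  expect_equal(igraph::vcount(net3), 0)

  expect_error(build_network("Z", edges2), "none of the focus genes")
})

test_that("connection numbers equal brute-force adjacency counts", {
  set.seed(41)
  for (i in 1:50) {
    n <- sample(5:25, 1)
    genes <- paste0("n", 1:n)
    m <- matrix(stats::runif(n * n) < 0.2, n, n)
    pairs <- which(upper.tri(m) & m, arr.ind = TRUE)
    if (!nrow(pairs)) next
    edges <- normalize_edges(data.frame(from = genes[pairs[, 1]],
                                        to = genes[pairs[, 2]]))
    focus <- sample(genes, sample(2:n, 1))
    net <- build_network(focus, edges, include_neighbors = FALSE)
    deg <- connection_numbers(net)
    for (v in names(deg)) {
      cnt <- sum((edges$from == v & edges$to %in% names(deg)) |
                   (edges$to == v & edges$from %in% names(deg)))
      expect_equal(unname(deg[v]), cnt)
    }
  }
})

test_that("the location/drug filter implements the published rule", {
  edges <- normalize_edges(data.frame(from = c("A", "A"), to = c("B", "C")))
  net <- build_network(c("A", "B", "C"), edges)
  ann <- data.frame(gene_id = c("A", "B", "C"),
                    location = c("cytoplasm", "cytoplasm", "plasma_membrane"),
                    has_drug = c(FALSE, TRUE, FALSE))
  de <- data.frame(gene_id = c("A", "B", "C"), fc = c(10, 1.5, 4),
                   log2_fc = log2(c(10, 1.5, 4)))
  cand <- filter_candidates(net, ann, de)
  ## cytoplasmic high-fold gene without drug: out; drugged gene: in
  ## regardless of location; membrane gene beyond cutoff: in
  expect_identical(cand$passes_filter[match(c("A", "B", "C"), cand$gene_id)],
                   c(FALSE, TRUE, TRUE))

  ## brute-force predicate on random annotation rows
  set.seed(63)
  locs <- c("extracellular_space", "plasma_membrane", "cytoplasm",
            "nucleus", "other")
  genes <- sprintf("r%04d", 1:300)
  ring <- normalize_edges(data.frame(from = genes,
                                     to = c(genes[-1], genes[1])))
  netr <- build_network(genes, ring)
  annr <- data.frame(gene_id = genes, location = sample(locs, 300, TRUE),
                     has_drug = stats::runif(300) < 0.3)
  der <- data.frame(gene_id = genes, fc = stats::rlnorm(300, 0, 1.5))
  der$log2_fc <- log2(der$fc)
  got <- filter_candidates(netr, annr, der)
  want <- (annr$location %in% c("plasma_membrane", "extracellular_space") &
             (der$fc > 2 | der$fc < 0.5)) | annr$has_drug
  expect_identical(got$passes_filter[match(genes, got$gene_id)], want)
})

test_that("the Relevance Index is |log FC| times degree", {
  expect_equal(relevance_index(1, 17), 0)
  expect_equal(relevance_index(5, 0), 0)
  expect_equal(relevance_index(4, 5), 10)
  expect_equal(relevance_index(0.25, 5), 10)     # symmetric in direction
  expect_equal(relevance_index(4, 5, log_base = 10), abs(log10(4)) * 5)
  expect_error(relevance_index(0, 3), "positive")
  expect_error(relevance_index(-2, 3), "positive")
})

test_that("ranking orders by RI with degree and id tie-breaks", {
  cand <- data.frame(gene_id = c("a", "b", "c"), fc = c(2^10, 2^3, 2^7),
                     log2_fc = c(10, 3, 7), connection_number = 1L,
                     location = "plasma_membrane", has_drug = FALSE,
                     passes_filter = TRUE)
  r <- rank_candidates(cand)
  expect_equal(r$gene_id, c("a", "c", "b"))
  expect_equal(r$rank, 1:3)

  ties <- data.frame(gene_id = c("z", "y", "x"), fc = 4, log2_fc = 2,
                     connection_number = c(3L, 5L, 3L),
                     location = "other", has_drug = TRUE,
                     passes_filter = TRUE)
  rt <- rank_candidates(ties)
  expect_equal(rt$gene_id, c("y", "x", "z"))

  ## monotone: raising degree at fixed FC never lowers the rank
  cand2 <- cand
  cand2$connection_number[cand2$gene_id == "b"] <- 50L
  r2 <- rank_candidates(cand2)
  expect_lte(match("b", r2$gene_id), match("b", r$gene_id))

  ## consistent relabeling leaves the ranking invariant
  relab <- setNames(sprintf("Q%s", cand$gene_id), cand$gene_id)
  cand3 <- cand
  cand3$gene_id <- unname(relab[cand$gene_id])
  r3 <- rank_candidates(cand3)
  expect_identical(unname(relab[r$gene_id]), r3$gene_id)
})

test_that("the full framework reproduces a hand-worked 12-node instance", {
  ## nodes A..L; L has no edges and J-K form a detached pair
  edges <- normalize_edges(data.frame(
    from = c("A", "A", "A", "A", "B", "B", "C", "D", "E", "J"),
    to   = c("B", "C", "D", "E", "C", "F", "G", "H", "I", "K")))
  ann <- data.frame(
    gene_id  = c("A", "B", "C", "D", "E", "F", "J", "K"),
    location = c("plasma_membrane", "cytoplasm", "extracellular_space",
                 "plasma_membrane", "plasma_membrane", "nucleus", "other",
                 "plasma_membrane"),
    has_drug = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE))
  de <- data.frame(gene_id = c("A", "B", "C", "D", "E", "F", "J", "K"),
                   fc = c(4, 0.125, 8, 2.5, 1, 16, 0.25, 1.2))
  de$log2_fc <- log2(de$fc)

  net <- build_network(c("A", "B", "J"), edges, include_neighbors = TRUE)
  ## grown node set: focus + first neighbors, G/H/I/L stay out
  expect_setequal(igraph::V(net)$name,
                  c("A", "B", "C", "D", "E", "F", "J", "K"))
  deg <- connection_numbers(net)
  expect_equal(deg[c("A", "B", "C", "D", "E", "F", "J", "K")],
               c(A = 4, B = 3, C = 2, D = 1, E = 1, F = 1, J = 1, K = 1))

  ranked <- rank_candidates(filter_candidates(net, ann, de))
  ## hand enumeration: pass = {A, C, D, F, J};
  ## RI = {A: 2*4 = 8, C: 3*2 = 6, F: 4*1 = 4, J: 2*1 = 2, D: 1.3219*1}
  expect_equal(ranked$gene_id, c("A", "C", "F", "J", "D"))
  expect_equal(ranked$relevance_index,
               c(8, 6, 4, 2, log2(2.5)), tolerance = 1e-12)
  expect_equal(ranked$rank, 1:5)
})

test_that("the planted hub with the top fold change wins on simulations", {
  ## light version of the recovery experiment (the acceptance suite runs
  ## the full 20-seed design)
  hits <- sapply(1:5, function(s) {
    b <- simulate_all(sim_config(n_genes = 1000, seed = s))
    de <- call_de(floor_fpkm(b$study, 0.1), c("D2", "CTR"))
    ranked <- prioritize_genes(de, b$network$edges, b$annotation,
                               fraction = 0.10)
    d1 <- b$truth$de[[1]]
    vis <- b$truth$baseline[d1$gene_id] >= 1
    star <- d1$gene_id[vis][which.max(abs(d1$log2_fc[vis]))]
    identical(ranked$gene_id[1], star)
  })
  expect_gte(sum(hits), 4)
})
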