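## Ground-truthed simulator for an injury time-course expression study:
## log-normal baseline expression, planted per-stage fold changes, a planted
## detection limit expressed through CI lower bounds, a scale-free
## interaction network with planted hubs, per-gene isoform structure with
## switch events, and Ct tables consistent with the planted fold changes.
## One global seed; each sub-generator derives its own stream from it by a
## fixed offset so components can be regenerated independently.

derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) %% 2147483629 * 1103 + offset * 7919) %% 2147483629)
}

#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic-data generator. The
#' defaults emulate a three-stage injury design: a sham control with two
#' biological replicates and two post-injury stages (acute, subacute) with
#' three replicates each.
#'
#' @param n_genes number of genes.
#' @param stages ordered stage labels; the first stage is the control.
#' @param replicates integer vector of biological replicates per stage.
#' @param baseline_log2_mean,baseline_log2_sd log2-scale mean and sd of the
#'   log-normal baseline FPKM of the well-expressed gene component.
#' @param frac_low,low_log2_mean,low_log2_sd a second, weakly expressed
#'   component of the baseline mixture (fraction of expressed genes, and its
#'   log2 FPKM mean/sd), emulating the large population of genes hovering
#'   around the detection boundary in real tissue RNA-seq.
#' @param frac_silent fraction of genes with true expression 0 in all stages.
#' @param detection_limit planted FPKM detection limit; governs how the CI
#'   lower bound collapses to 0 as expression approaches it.
#' @param frac_up,frac_down fractions of expressed genes planted as up/down
#'   regulated in each post-injury stage (relative to control).
#' @param de_persistence fraction of a stage's DE genes carried over (same
#'   direction) into the next stage, emulating injury responses that span
#'   the acute and subacute phases.
#' @param lfc_mean,lfc_sd,lfc_min planted |log2 fold change| distribution:
#'   Normal(`lfc_mean`, `lfc_sd`) truncated below at `lfc_min`.
#' @param noise_sd replicate noise sd on the log2 scale (multiplicative
#'   log-normal noise on FPKM).
#' @param ci_a,ci_jitter_sd confidence-interval emulation: the log2
#'   half-width of a value v is `ci_a + (1 - ci_a) * sqrt(detection_limit /
#'   (v + 1e-8)) * J` with `J` log-normal(0, `ci_jitter_sd`); the lower
#'   bound hits 0 once the half-width reaches one log2 unit.
#' @param isoform list: `count_probs` (probabilities of 1..12 isoforms per
#'   gene), `switch_frac` (fraction of multi-isoform genes with a planted
#'   major-isoform switch), `prop_concentration` (Dirichlet concentration of
#'   replicate-level isoform proportions around the stage truth).
#' @param network list: `n_nodes` (defaults to `min(600, n_genes)`),
#'   `attach_m` (preferential-attachment edges per new node), `n_hubs`,
#'   `hub_min_degree`.
#' @param qpcr list: `housekeeping` gene label, `hk_ct` baseline cycle,
#'   `ct_sd` per-reaction Gaussian cycle noise, `n_tech` technical
#'   replicates.
#' @param seed global integer seed; every emitted table is a deterministic
#'   function of the configuration.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       stages = c("CTR", "D2", "D7"),
                       replicates = c(2, 3, 3),
                       baseline_log2_mean = 3,
                       baseline_log2_sd = 2,
                       frac_low = 0.25,
                       low_log2_mean = -3,
                       low_log2_sd = 1.5,
                       frac_silent = 0.15,
                       detection_limit = 0.1,
                       frac_up = 0.08,
                       frac_down = 0.08,
                       de_persistence = 0.5,
                       lfc_mean = 2, lfc_sd = 0.5, lfc_min = 1,
                       noise_sd = 0.25,
                       ci_a = 0.1, ci_jitter_sd = 0.5,
                       isoform = list(),
                       network = list(),
                       qpcr = list(),
                       seed = 1L) {
  iso_def <- list(count_probs = c(0.45, 0.25, 0.15, 0.09, 0.05,
                                  rep(0.01 / 7, 7)),
                  switch_frac = 0.05, prop_concentration = 200)
  net_def <- list(n_nodes = NULL, attach_m = 2, n_hubs = 3, hub_min_degree = 40)
  qp_def <- list(housekeeping = "Hprt", hk_ct = 20, ct_sd = 0.1, n_tech = 3)
  cfg <- list(n_genes = as.integer(n_genes), stages = as.character(stages),
              replicates = as.integer(replicates),
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd,
              frac_low = frac_low, low_log2_mean = low_log2_mean,
              low_log2_sd = low_log2_sd,
              frac_silent = frac_silent, detection_limit = detection_limit,
              frac_up = frac_up, frac_down = frac_down,
              de_persistence = de_persistence,
              lfc_mean = lfc_mean, lfc_sd = lfc_sd, lfc_min = lfc_min,
              noise_sd = noise_sd, ci_a = ci_a, ci_jitter_sd = ci_jitter_sd,
              isoform = utils::modifyList(iso_def, isoform),
              network = utils::modifyList(net_def, network),
              qpcr = utils::modifyList(qp_def, qpcr),
              seed = as.integer(seed))
  if (is.null(cfg$network$n_nodes))
    cfg$network$n_nodes <- min(600L, cfg$n_genes)
  for (f in c("frac_silent", "frac_low", "frac_up", "frac_down",
              "de_persistence"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("config error: `", f, "` must lie in [0, 1]")
  if (cfg$frac_up + cfg$frac_down > 1)
    stop("config error: frac_up + frac_down must not exceed 1")
  if (cfg$detection_limit <= 0) stop("config error: detection_limit must be > 0")
  if (length(cfg$replicates) != length(cfg$stages))
    stop("config error: one replicate count per stage required")
  if (any(cfg$replicates < 2))
    stop("config error: at least 2 replicates per stage required")
  if (length(cfg$isoform$count_probs) != 12 ||
      abs(sum(cfg$isoform$count_probs) - 1) > 1e-6)
    stop("config error: isoform count_probs must be 12 probabilities summing to 1")
  if (cfg$network$n_nodes > cfg$n_genes)
    stop("config error: network n_nodes must not exceed n_genes")
  structure(cfg, class = "sim_config")
}

rtrunc_norm_lower <- function(n, mean, sd, lower) {
  ## exact inverse-CDF sampling from Normal(mean, sd) truncated below;
  ## sd = 0 degenerates to a fixed effect size
  if (sd <= 0) return(rep(max(mean, lower), n))
  p0 <- stats::pnorm(lower, mean, sd)
  stats::qnorm(stats::runif(n, p0, 1), mean, sd)
}

#' Simulate a ground-truthed expression study
#'
#' Draws log-normal baseline FPKMs, plants per-stage fold changes, applies
#' multiplicative log-normal replicate noise, and emits 95% confidence
#' bounds whose lower bound collapses to zero as expression approaches the
#' planted detection limit.
#'
#' @param config a [sim_config()].
#' @return list with elements `study` (an [expression_study()] with CI
#'   matrices) and `truth` (gene-level ground truth: true stage means,
#'   per-contrast log2 fold changes and direction labels, silent gene set,
#'   detection limit).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 1L))
  n <- config$n_genes
  genes <- sprintf("G%05d", seq_len(n))
  stages <- config$stages
  silent <- sort(sample(n, round(config$frac_silent * n)))
  base <- 2^stats::rnorm(n, config$baseline_log2_mean, config$baseline_log2_sd)
  expressed <- setdiff(seq_len(n), silent)
  low <- sample_vec(expressed, round(config$frac_low * length(expressed)))
  base[low] <- 2^stats::rnorm(length(low), config$low_log2_mean,
                              config$low_log2_sd)
  base[silent] <- 0

  ## plant per-stage DE: carry a fraction of the previous stage's genes
  ## forward (same direction), fill the rest with fresh draws
  lfc <- matrix(0, n, length(stages), dimnames = list(genes, stages))
  n_up <- round(config$frac_up * length(expressed))
  n_dn <- round(config$frac_down * length(expressed))
  prev_up <- prev_dn <- integer(0)
  draw_mag <- function(k) if (k) rtrunc_norm_lower(k, config$lfc_mean,
                                                   config$lfc_sd, config$lfc_min) else numeric(0)
  for (s in stages[-1]) {
    keep_up <- sample_vec(prev_up, round(config$de_persistence * min(length(prev_up), n_up)))
    keep_dn <- sample_vec(prev_dn, round(config$de_persistence * min(length(prev_dn), n_dn)))
    pool <- setdiff(expressed, c(keep_up, keep_dn))
    new_up <- sample_vec(pool, max(0, n_up - length(keep_up)))
    pool <- setdiff(pool, new_up)
    new_dn <- sample_vec(pool, max(0, n_dn - length(keep_dn)))
    up <- c(keep_up, new_up); dn <- c(keep_dn, new_dn)
    lfc[up, s] <- draw_mag(length(up))
    lfc[dn, s] <- -draw_mag(length(dn))
    prev_up <- up; prev_dn <- dn
  }
  truth_means <- base * 2^lfc

  ## observed values: truth x log-normal replicate noise
  reps <- config$replicates
  sample_stage <- rep(stages, reps)
  sample_rep <- unlist(lapply(reps, seq_len))
  sample_ids <- paste0(sample_stage, "_r", sample_rep)
  vals <- truth_means[, sample_stage, drop = FALSE] *
    2^matrix(stats::rnorm(n * length(sample_ids), 0, config$noise_sd),
             n, length(sample_ids))
  dimnames(vals) <- list(genes, sample_ids)

  ## CI emulation: log2 half-width a + (1-a) sqrt(d/(v+eps)) J
  jit <- exp(matrix(stats::rnorm(length(vals), 0, config$ci_jitter_sd),
                    nrow(vals)))
  h <- pmin(config$ci_a + (1 - config$ci_a) *
              sqrt(config$detection_limit / (vals + 1e-8)) * jit, 50)
  ci_hi <- vals * 2^h
  ci_lo <- pmax(vals * (2 - 2^h), 0)
  dimnames(ci_lo) <- dimnames(ci_hi) <- dimnames(vals)

  samples <- data.frame(sample_id = sample_ids,
                        stage = factor(sample_stage, levels = stages),
                        replicate = sample_rep)
  study <- expression_study(vals, samples, ci_lo = ci_lo, ci_hi = ci_hi)

  contrasts <- lapply(stages[-1], function(s) {
    dir <- ifelse(lfc[, s] > 0, "up", ifelse(lfc[, s] < 0, "down", "flat"))
    data.frame(gene_id = genes, log2_fc = lfc[, s], direction = dir,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  names(contrasts) <- paste0(stages[-1], "_vs_", stages[1])
  truth <- list(gene_ids = genes, stage_means = truth_means,
                baseline = stats::setNames(base, genes),
                silent = genes[silent], de = contrasts,
                detection_limit = config$detection_limit,
                stages = stages, config = config)
  class(truth) <- "sim_truth"
  list(study = study, truth = truth)
}

## sample() without its scalar-x surprise
sample_vec <- function(x, k) {
  k <- min(k, length(x))
  if (k <= 0) return(x[0])
  x[sample.int(length(x), k)]
}

#' Simulate a scale-free interaction network with planted hubs
#'
#' Builds a connected preferential-attachment graph over the supplied genes,
#' then wires each planted hub with extra random edges until it reaches the
#' configured minimum degree.
#'
#' @param config a [sim_config()]; uses the `network` block.
#' @param gene_ids genes to use as nodes (length defines `n_nodes`; must not
#'   exceed `config$n_genes`).
#' @param hub_genes optional gene ids to plant as hubs; defaults to a random
#'   draw of `network$n_hubs` genes.
#' @return list with `edges` (normalized undirected edge data frame) and
#'   `hubs` (planted hub gene ids).
#' @export
simulate_network <- function(config, gene_ids, hub_genes = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 2L))
  n <- length(gene_ids)
  if (n < 2) stop("network needs at least 2 nodes")
  if (n > config$n_genes) stop("n_nodes must not exceed n_genes")
  net <- config$network
  if (is.null(hub_genes)) hub_genes <- sample_vec(gene_ids, net$n_hubs)
  if (!all(hub_genes %in% gene_ids)) stop("hub genes must be among the nodes")
  g <- igraph::sample_pa(n, power = 1, m = net$attach_m, directed = FALSE)
  ## random vertex relabeling so hubs of the attachment process are not
  ## systematically the first genes
  igraph::V(g)$name <- sample(gene_ids)
  for (hub in hub_genes) {
    need <- net$hub_min_degree - igraph::degree(g, hub)
    if (need > 0) {
      others <- setdiff(gene_ids, c(hub, igraph::V(g)$name[
        as.integer(igraph::neighbors(g, hub))]))
      add <- sample_vec(others, need)
      if (length(add))
        g <- igraph::add_edges(g, as.vector(rbind(hub, add)))
    }
  }
  g <- igraph::simplify(g)
  el <- igraph::as_edgelist(g)
  edges <- normalize_edges(data.frame(from = el[, 1], to = el[, 2],
                                      stringsAsFactors = FALSE))
  list(edges = edges, hubs = hub_genes)
}

#' Simulate isoform-level expression with planted switch events
#'
#' Assigns each gene 1-12 isoforms, gives every stage a true isoform
#' proportion vector (constant for non-switch genes; for planted switch
#' genes the leading isoform hands over to another across the time course),
#' and splits each observed gene-level replicate value among isoforms with
#' mild Dirichlet jitter around the stage truth, so isoform values sum
#' exactly to the gene value in every sample.
#'
#' @param config a [sim_config()]; uses the `isoform` block.
#' @param sim result of [simulate_study()] (study plus truth).
#' @return list with `study` (isoform-level [expression_study()]) and
#'   `truth` (isoform map, per-stage true proportions, planted switch table
#'   with the true major isoform per stage).
#' @export
simulate_isoforms <- function(config, sim) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 3L))
  study <- sim$study; truth <- sim$truth
  genes <- rownames(study$values)
  iso_cfg <- config$isoform
  counts <- sample(1:12, length(genes), replace = TRUE, prob = iso_cfg$count_probs)
  names(counts) <- genes
  ## switch events are planted among multi-isoform genes expressed well
  ## above the detection limit; a major-isoform change in a gene whose
  ## isoforms sit below the expression threshold is unobservable by design
  multi <- genes[counts >= 2 &
                   truth$baseline[genes] >= 10 * config$detection_limit]
  switch_genes <- sort(sample_vec(multi, round(iso_cfg$switch_frac * length(multi))))
  stages <- study$stages
  n_stage <- length(stages)

  iso_ids <- unlist(lapply(genes, function(g) paste0(g, ".", seq_len(counts[g]))))
  iso_gene <- rep(genes, counts)
  map <- data.frame(isoform_id = iso_ids, gene_id = iso_gene,
                    stringsAsFactors = FALSE)

  ## true per-stage proportions, rows = isoforms
  props <- matrix(0, length(iso_ids), n_stage,
                  dimnames = list(iso_ids, stages))
  offset <- 0L
  for (g in genes) {
    k <- counts[[g]]
    rows <- offset + seq_len(k)
    if (k == 1L) {
      props[rows, ] <- 1
    } else if (g %in% switch_genes) {
      ## leading isoform declines while isoform 2 rises (Morf4l2-like)
      pa <- seq(0.7, 0.2, length.out = n_stage)
      pb <- seq(0.2, 0.7, length.out = n_stage)
      if (k == 2L) {
        pa <- pa / (pa + pb)
        pb <- 1 - pa
      } else {
        w <- sort(stats::rgamma(k - 2, 1), decreasing = TRUE)
        props[rows[-(1:2)], ] <- outer(w / sum(w), 1 - pa - pb)
      }
      props[rows[1], ] <- pa
      props[rows[2], ] <- pb
    } else {
      w <- stats::rgamma(k, c(5, rep(1, k - 1)))
      props[rows, ] <- matrix(w / sum(w), k, n_stage)
    }
    offset <- offset + k
  }

  ## replicate-level proportions: Dirichlet around stage truth, then split
  ## the observed gene value so sums are exact
  vals <- matrix(0, length(iso_ids), ncol(study$values),
                 dimnames = list(iso_ids, colnames(study$values)))
  conc <- iso_cfg$prop_concentration
  for (j in seq_len(ncol(vals))) {
    st <- study$samples$stage[j]
    p <- props[, st]
    draw <- stats::rgamma(length(p), shape = conc * p)
    offset <- 0L
    for (g in genes) {
      k <- counts[[g]]
      rows <- offset + seq_len(k)
      d <- if (k == 1L) 1 else {
        dg <- draw[rows]
        if (sum(dg) <= 0) p[rows] else dg / sum(dg)
      }
      vals[rows, j] <- study$values[g, j] * d
      offset <- offset + k
    }
  }

  iso_study <- expression_study(vals, study$samples,
                                feature_kind = "isoform", isoform_map = map)
  true_major <- t(vapply(genes, function(g) {
    rows <- map$isoform_id[map$gene_id == g]
    apply(props[rows, , drop = FALSE], 2, function(p) rows[which.max(p)])
  }, character(n_stage)))
  colnames(true_major) <- stages
  iso_truth <- list(map = map, counts = counts, proportions = props,
                    switch_genes = switch_genes, major = true_major)
  list(study = iso_study, truth = iso_truth)
}

#' Simulate a qPCR Ct table consistent with the planted fold changes
#'
#' Emits technical-replicate threshold cycles for a gene subset plus the
#' housekeeping gene, with one cycle per two-fold of true expression change
#' and Gaussian cycle noise.
#'
#' @param truth `sim_truth` from [simulate_study()].
#' @param genes gene ids to assay (must be expressed in the truth).
#' @param config a [sim_config()]; uses the `qpcr` block.
#' @return long-format data frame (`gene_id`, `sample_id`, `stage`,
#'   `replicate`, `tech_rep`, `ct`) with attribute `housekeeping`; the
#'   housekeeping gene is included in every sample.
#' @export
simulate_qpcr <- function(truth, genes, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 4L))
  qp <- config$qpcr
  bad <- genes[truth$stage_means[genes, truth$stages[1]] <= 0]
  if (length(bad))
    stop("cannot assay silent gene(s): ", paste(bad, collapse = ", "))
  stages <- truth$stages
  reps <- truth$config$replicates
  dct0 <- stats::setNames(stats::runif(length(genes), 2, 8), genes)
  rows <- list()
  for (si in seq_along(stages)) {
    s <- stages[si]
    rel <- truth$stage_means[genes, s] / truth$stage_means[genes, stages[1]]
    for (r in seq_len(reps[si])) {
      sample_id <- paste0(s, "_q", r)
      for (tech in seq_len(qp$n_tech)) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = c(genes, qp$housekeeping),
          sample_id = sample_id, stage = s, replicate = r, tech_rep = tech,
          ct = c(qp$hk_ct + dct0[genes] - log2(rel) +
                   stats::rnorm(length(genes), 0, qp$ct_sd),
                 qp$hk_ct + stats::rnorm(1, 0, qp$ct_sd)),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "housekeeping") <- qp$housekeeping
  out
}

#' Simulate a gene annotation table
#'
#' Random cellular locations and drug flags; planted hubs are placed on the
#' plasma membrane or in extracellular space, emulating the framework's
#' focus on drug-accessible hub genes.
#'
#' @param truth `sim_truth` from [simulate_study()].
#' @param hubs gene ids planted as hubs.
#' @param config a [sim_config()].
#' @return annotation data frame (`gene_id`, `location`, `has_drug`).
#' @export
simulate_annotation <- function(truth, hubs, config) {
  set.seed(derive_seed(config$seed, 5L))
  genes <- truth$gene_ids
  loc <- sample(unname(.location_tokens), length(genes), replace = TRUE,
                prob = c(0.10, 0.20, 0.35, 0.25, 0.10))
  names(loc) <- genes
  loc[hubs] <- sample(c("plasma_membrane", "extracellular_space"),
                      length(hubs), replace = TRUE)
  data.frame(gene_id = genes, location = unname(loc),
             has_drug = stats::runif(length(genes)) < 0.15,
             stringsAsFactors = FALSE)
}

#' Simulate marker gene-set collections
#'
#' Two planted signature sets (the most strongly up-regulated genes of each
#' post-injury stage, emulating e.g. macrophage-subtype marker signatures)
#' plus random background sets.
#'
#' @param truth `sim_truth` from [simulate_study()].
#' @param config a [sim_config()].
#' @param set_size genes per set.
#' @param n_random number of random background sets.
#' @return named list of gene-id vectors (a GMT-compatible collection).
#' @export
simulate_gene_sets <- function(truth, config, set_size = 30, n_random = 8) {
  set.seed(derive_seed(config$seed, 6L))
  sets <- list()
  for (ct in names(truth$de)) {
    de <- truth$de[[ct]]
    top <- de$gene_id[order(-de$log2_fc)][seq_len(set_size)]
    sets[[paste0("sig_", ct, "_up")]] <- top
  }
  for (i in seq_len(n_random))
    sets[[sprintf("random_%02d", i)]] <- sort(sample_vec(truth$gene_ids, set_size))
  attr(sets, "description") <- stats::setNames(rep("synthetic", length(sets)),
                                               names(sets))
  sets
}

#' Simulate a complete ground-truthed input bundle
#'
#' Runs every sub-generator with streams derived from the single global
#' seed: the expression study with CI bounds, the isoform-level study, the
#' interaction network (nodes are the DE genes plus a random background
#' fill; the first planted hub is the DE gene with the largest planted
#' |log2 fold change|, so the framework's ideal candidate exists), the
#' annotation table, marker gene sets, and a qPCR Ct table for a panel of
#' strongly regulated genes.
#'
#' @param config a [sim_config()].
#' @return list with components `study`, `truth`, `isoforms`, `network`,
#'   `annotation`, `gene_sets`, `ct_table`, `qpcr_truth`.
#' @export
simulate_all <- function(config = sim_config()) {
  sim <- simulate_study(config)
  truth <- sim$truth
  iso <- simulate_isoforms(config, sim)

  ## network nodes: DE genes in any contrast + random expressed background
  lfc_abs <- do.call(pmax, lapply(truth$de, function(d) abs(d$log2_fc)))
  de_any <- truth$gene_ids[lfc_abs > 0]
  set.seed(derive_seed(config$seed, 7L))
  n_nodes <- max(config$network$n_nodes, length(de_any) + 2L)
  n_nodes <- min(n_nodes, config$n_genes)
  fill <- sample_vec(setdiff(setdiff(truth$gene_ids, de_any), truth$silent),
                     n_nodes - length(de_any))
  nodes <- c(de_any, fill)
  ## the ideal candidate: largest planted |log2FC| of the first contrast
  ## among well-expressed genes (a change at the detection boundary is not
  ## observable after flooring), wired as the first hub
  d1 <- truth$de[[1]]
  visible <- truth$baseline[d1$gene_id] >= 1
  star <- d1$gene_id[visible][which.max(abs(d1$log2_fc[visible]))]
  other_hubs <- sample_vec(setdiff(de_any, star), config$network$n_hubs - 1L)
  net <- simulate_network(config, nodes, hub_genes = c(star, other_hubs))

  annotation <- simulate_annotation(truth, net$hubs, config)
  gene_sets <- simulate_gene_sets(truth, config)

  first_contrast <- truth$de[[1]]
  panel <- first_contrast$gene_id[order(-abs(first_contrast$log2_fc))]
  panel <- utils::head(setdiff(panel, truth$silent), 10)
  ct_table <- simulate_qpcr(truth, panel, config)
  qpcr_truth <- do.call(rbind, lapply(names(truth$de), function(ct) {
    data.frame(gene_id = panel, contrast = ct,
               true_fold = 2^truth$de[[ct]]$log2_fc[match(panel, truth$de[[ct]]$gene_id)],
               stringsAsFactors = FALSE)
  }))

  list(study = sim$study, truth = truth, isoforms = iso, network = net,
       annotation = annotation, gene_sets = gene_sets,
       ct_table = ct_table, qpcr_truth = qpcr_truth)
}

#' Write a simulated input bundle to a fixture directory
#'
#' Emits every table of [simulate_all()] in the exact file dialects the
#' readers of this package consume: a genes-by-samples matrix plus sample
#' metadata, one fpkm_tracking file per sample, the isoform matrix and
#' isoform-to-gene map, the edge list, the annotation table, the gene-set
#' GMT, the Ct table, and the ground-truth fold-change table.
#'
#' @param bundle result of [simulate_all()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  study <- bundle$study
  write_expression_matrix(study, p("expression.tsv"), p("samples.tsv"))
  for (s in colnames(study$values))
    write_fpkm_tracking(study, p(paste0(s, ".fpkm_tracking")), sample = s)
  write_expression_matrix(bundle$isoforms$study, p("isoform_expression.tsv"))
  write_tsv(bundle$isoforms$truth$map, p("isoform_map.tsv"))
  write_edge_list(bundle$network$edges, p("edges.tsv"))
  write_annotation(bundle$annotation, p("annotation.tsv"))
  write_gmt(bundle$gene_sets, p("gene_sets.gmt"))
  write_tsv(bundle$ct_table, p("ct_table.tsv"))
  truth_de <- do.call(rbind, lapply(names(bundle$truth$de), function(ct) {
    d <- bundle$truth$de[[ct]]
    data.frame(gene_id = d$gene_id, contrast = ct, log2_fc = d$log2_fc,
               direction = d$direction, stringsAsFactors = FALSE)
  }))
  truth_de$silent <- truth_de$gene_id %in% bundle$truth$silent
  truth_de$hub <- truth_de$gene_id %in% bundle$network$hubs
  write_tsv(truth_de, p("truth.tsv"))
  invisible(dir)
}
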