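## Small in-code fixtures shared across test files.

## study with explicit per-stage replicate values; `mat` is genes x samples,
## columns grouped by stage
toy_study <- function(mat, stages, reps_per_stage, ci_lo = NULL, ci_hi = NULL,
                      feature_kind = "gene", isoform_map = NULL) {
  stage_vec <- rep(stages, reps_per_stage)
  ids <- paste0(stage_vec, "_r", unlist(lapply(reps_per_stage, seq_len)))
  colnames(mat) <- ids
  if (!is.null(ci_lo)) colnames(ci_lo) <- ids
  if (!is.null(ci_hi)) colnames(ci_hi) <- ids
  samples <- data.frame(sample_id = ids,
                        stage = factor(stage_vec, levels = stages),
                        replicate = unlist(lapply(reps_per_stage, seq_len)))
  expression_study(mat, samples, ci_lo = ci_lo, ci_hi = ci_hi,
                   feature_kind = feature_kind, isoform_map = isoform_map)
}

## study where every gene has the given per-stage means, replicated exactly
toy_study_means <- function(means, stages = colnames(means),
                            reps_per_stage = rep(2, length(stages))) {
  mat <- means[, rep(seq_along(stages), reps_per_stage), drop = FALSE]
  toy_study(mat, stages, reps_per_stage)
}

## random de_result-shaped table for brute-force comparisons
random_de_table <- function(n, prefix = "g", p_sig = 0.4) {
  lfc <- stats::rnorm(n, 0, 2)
  p <- stats::runif(n)
  fc <- 2^lfc
  sig <- (fc > 2 | fc < 0.5) & p < 0.05
  data.frame(gene_id = sprintf("%s%04d", prefix, seq_len(n)),
             contrast = "A_vs_B", fc = fc, log2_fc = lfc,
             direction = ifelse(!sig, "flat", ifelse(lfc > 0, "up", "down")),
             p_value = p, significant = sig, stringsAsFactors = FALSE)
}

## independent hand-walk of the weighted KS running sum (test-local oracle)
walk_es <- function(metric, hit, p = 1) {
  n <- length(metric)
  w <- abs(metric)^p
  run <- numeric(n)
  cur <- 0
  for (i in seq_len(n)) {
    cur <- if (hit[i]) cur + w[i] / sum(w[hit]) else cur - 1 / (n - sum(hit))
    run[i] <- cur
  }
  run[which.max(abs(run))]
}
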