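#' Expression study container
#'
#' An `expression_study` bundles a feature-by-sample matrix of non-negative
#' expression values (FPKM units) with sample metadata (stage and replicate
#' index) and, optionally, per-estimate 95% confidence bounds. Features are
#' either genes or isoforms; isoform-level studies carry an isoform-to-gene
#' map so gene-level summaries remain available.
#'
#' @param values numeric matrix, features in rows, samples in columns, with
#'   rownames (feature ids) and colnames (sample ids). All values must be
#'   non-negative and finite.
#' @param samples data frame with columns `sample_id`, `stage`, `replicate`.
#'   `stage` may be a factor whose level order defines the stage order;
#'   otherwise order of first appearance is used.
#' @param ci_lo,ci_hi optional matrices of the same shape as `values` holding
#'   the lower/upper 95% confidence bounds of each estimate. `ci_lo` must
#'   satisfy `0 <= ci_lo <= values <= ci_hi`.
#' @param feature_kind `"gene"` or `"isoform"`.
#' @param isoform_map for isoform-level studies, a data frame with columns
#'   `isoform_id` and `gene_id` covering every feature.
#'
#' @return an object of class `expression_study`: a list with elements
#'   `values`, `samples`, `ci_lo`, `ci_hi`, `feature_kind`, `isoform_map`,
#'   and `stages` (ordered stage labels).
#' @export
expression_study <- function(values, samples, ci_lo = NULL, ci_hi = NULL,
                             feature_kind = c("gene", "isoform"),
                             isoform_map = NULL) {
  feature_kind <- match.arg(feature_kind)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have feature ids as rownames and sample ids as colnames")
  samples <- as.data.frame(samples)
  required <- c("sample_id", "stage", "replicate")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols))
    stop("sample metadata lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (is.factor(samples$stage)) {
    stages <- levels(droplevels(samples$stage))
    samples$stage <- as.character(samples$stage)
  } else {
    samples$stage <- as.character(samples$stage)
    stages <- unique(samples$stage)
  }
  samples$sample_id <- as.character(samples$sample_id)
  ## align metadata rows to the column order of `values`
  idx <- match(colnames(values), samples$sample_id)
  if (anyNA(idx))
    stop("sample(s) in `values` missing from metadata: ",
         paste(setdiff(colnames(values), samples$sample_id), collapse = ", "))
  samples <- samples[idx, , drop = FALSE]
  rownames(samples) <- NULL
  study <- structure(
    list(values = values, samples = samples,
         ci_lo = if (!is.null(ci_lo)) as.matrix(ci_lo),
         ci_hi = if (!is.null(ci_hi)) as.matrix(ci_hi),
         feature_kind = feature_kind,
         isoform_map = isoform_map,
         stages = stages),
    class = "expression_study")
  validate_study(study)
}

#' Validate an expression study
#'
#' Checks the structural invariants of [expression_study()]: non-negative
#' finite values, unique sample ids, at least one replicate per stage,
#' consistent confidence bounds (`0 <= ci_lo <= values <= ci_hi`) and, for
#' isoform studies, a total isoform-to-gene map.
#'
#' @param study an `expression_study`.
#' @return `study`, invisibly usable, after passing all checks.
#' @export
validate_study <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  v <- study$values
  if (!is.numeric(v) || any(!is.finite(v)))
    stop("expression values must be finite numbers")
  if (any(v < 0)) stop("expression values must be non-negative")
  if (anyDuplicated(colnames(v))) stop("sample ids must be unique")
  if (anyDuplicated(rownames(v))) stop("feature ids must be unique")
  if (anyDuplicated(study$samples$sample_id)) stop("sample ids must be unique")
  if (!all(study$samples$stage %in% study$stages))
    stop("sample stage outside declared stage set")
  if (!all(table(factor(study$samples$stage, levels = study$stages)) >= 1))
    stop("every stage needs at least one replicate")
  for (nm in c("ci_lo", "ci_hi")) {
    ci <- study[[nm]]
    if (!is.null(ci) && !identical(dim(ci), dim(v)))
      stop("`", nm, "` must have the same shape as `values`")
  }
  if (!is.null(study$ci_lo)) {
    if (any(study$ci_lo < 0)) stop("ci_lo must be non-negative")
    if (any(study$ci_lo > v + 1e-9))
      stop("ci_lo must not exceed the estimate")
  }
  ## flooring raises values without touching bounds, so skip the upper-bound
  ## check on floored studies
  if (!is.null(study$ci_hi) && is.null(attr(study, "floor")) &&
      any(study$ci_hi < v - 1e-9))
    stop("ci_hi must not be below the estimate")
  if (identical(study$feature_kind, "isoform")) {
    map <- study$isoform_map
    if (is.null(map) || !all(c("isoform_id", "gene_id") %in% names(map)))
      stop("isoform study requires an isoform_map with isoform_id and gene_id")
    unmapped <- setdiff(rownames(v), map$isoform_id)
    if (length(unmapped))
      stop("unmapped isoform(s): ", paste(utils::head(unmapped, 5), collapse = ", "))
  }
  study
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("expression_study: %d %s feature(s) x %d sample(s)\n",
              nrow(x$values), x$feature_kind, ncol(x$values)))
  reps <- table(factor(x$samples$stage, levels = x$stages))
  cat("stages: ", paste(sprintf("%s (n=%d)", names(reps), reps), collapse = ", "), "\n")
  cat("confidence bounds: ", if (is.null(x$ci_lo)) "absent" else "present", "\n")
  invisible(x)
}

#' Per-stage mean expression
#'
#' Averages replicate columns within each stage.
#'
#' @param study an `expression_study`.
#' @return features x stages matrix of replicate-mean expression, stage
#'   columns in study stage order.
#' @export
stage_means <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  out <- vapply(study$stages, function(s) {
    cols <- study$samples$sample_id[study$samples$stage == s]
    rowMeans(study$values[, cols, drop = FALSE])
  }, numeric(nrow(study$values)))
  out <- matrix(out, nrow = nrow(study$values),
                dimnames = list(rownames(study$values), study$stages))
  out
}

#' Samples belonging to one stage
#' @param study an `expression_study`.
#' @param stage stage label.
#' @return character vector of sample ids.
#' @keywords internal
stage_samples <- function(study, stage) {
  if (!stage %in% study$stages)
    stop("stage '", stage, "' not present; stages are: ",
         paste(study$stages, collapse = ", "))
  study$samples$sample_id[study$samples$stage == stage]
}

#' Combine single-sample study fragments
#'
#' Binds studies over the identical feature set (e.g. fragments returned by
#' [read_fpkm_tracking()], one per sequencing library) into one multi-sample
#' study.
#'
#' @param ... `expression_study` objects sharing features and feature kind.
#' @param stages optional explicit stage order; defaults to order of first
#'   appearance across fragments.
#' @return a combined `expression_study`.
#' @export
combine_studies <- function(..., stages = NULL) {
  frags <- list(...)
  if (length(frags) == 1L && is.list(frags[[1]]) &&
      !inherits(frags[[1]], "expression_study"))
    frags <- frags[[1]]
  stopifnot(length(frags) >= 1)
  feats <- rownames(frags[[1]]$values)
  kind <- frags[[1]]$feature_kind
  for (f in frags) {
    stopifnot(inherits(f, "expression_study"))
    if (!identical(f$feature_kind, kind)) stop("feature kinds differ")
    if (!setequal(rownames(f$values), feats)) stop("feature sets differ")
  }
  align <- function(m, f) m[feats, , drop = FALSE]
  values <- do.call(cbind, lapply(frags, function(f) f$values[feats, , drop = FALSE]))
  has_ci <- !vapply(frags, function(f) is.null(f$ci_lo), logical(1))
  ci_lo <- ci_hi <- NULL
  if (all(has_ci)) {
    ci_lo <- do.call(cbind, lapply(frags, function(f) f$ci_lo[feats, , drop = FALSE]))
    ci_hi <- do.call(cbind, lapply(frags, function(f) f$ci_hi[feats, , drop = FALSE]))
  } else if (any(has_ci)) {
    warning("confidence bounds present only in some fragments; dropped")
  }
  samples <- do.call(rbind, lapply(frags, function(f) f$samples))
  if (!is.null(stages)) samples$stage <- factor(samples$stage, levels = stages)
  expression_study(values, samples, ci_lo = ci_lo, ci_hi = ci_hi,
                   feature_kind = kind, isoform_map = frags[[1]]$isoform_map)
}

#' Restrict a study to a feature subset
#' @param study an `expression_study`.
#' @param features character vector of feature ids to keep.
#' @return the restricted study.
#' @export
subset_features <- function(study, features) {
  stopifnot(inherits(study, "expression_study"))
  missing <- setdiff(features, rownames(study$values))
  if (length(missing))
    stop("feature(s) absent from study: ", paste(utils::head(missing, 5), collapse = ", "))
  study$values <- study$values[features, , drop = FALSE]
  if (!is.null(study$ci_lo)) study$ci_lo <- study$ci_lo[features, , drop = FALSE]
  if (!is.null(study$ci_hi)) study$ci_hi <- study$ci_hi[features, , drop = FALSE]
  if (!is.null(study$isoform_map) && identical(study$feature_kind, "isoform"))
    study$isoform_map <- study$isoform_map[study$isoform_map$isoform_id %in% features, , drop = FALSE]
  validate_study(study)
}
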