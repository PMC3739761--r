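## Detection thresholding from confidence-interval lower bounds: an FPKM
## estimate is "reliable" when its 95% CI lower bound is strictly above 0
## (the estimate is distinguishable from zero), "unreliable" otherwise.
## Calls are pooled across all samples and a single study-wide threshold is
## chosen from the reliability curve.

#' Label every estimate as reliable or unreliable
#'
#' An estimate is reliable iff its 95% confidence lower bound is strictly
#' greater than zero.
#'
#' @param study an [expression_study()] with confidence bounds.
#' @return data frame with columns `feature_id`, `sample_id`, `fpkm`,
#'   `reliable` (logical).
#' @export
label_reliability <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  if (is.null(study$ci_lo))
    stop("study carries no confidence bounds; read it from fpkm_tracking ",
         "files (or simulate one) to label reliability")
  data.frame(
    feature_id = rep(rownames(study$values), ncol(study$values)),
    sample_id = rep(colnames(study$values), each = nrow(study$values)),
    fpkm = as.vector(study$values),
    reliable = as.vector(study$ci_lo > 0),
    stringsAsFactors = FALSE)
}

#' Default logarithmic threshold grid
#' @param from,to grid range in FPKM.
#' @param length.out number of grid points.
#' @return strictly increasing numeric vector.
#' @export
default_grid <- function(from = 0.001, to = 10, length.out = 50) {
  10^seq(log10(from), log10(to), length.out = length.out)
}

#' Reliability / false-positive / false-negative curve over a threshold grid
#'
#' At each threshold t, calls with `fpkm >= t` are treated as detected:
#' `reliability(t)` is the reliable fraction among detected calls,
#' `fp_rate(t) = 1 - reliability(t)` the unreliable fraction among detected
#' calls, and `fn_rate(t)` the fraction of all reliable calls falling below
#' t (reliable signal lost to the threshold). Grid points with no detected
#' call are flagged undefined rather than set to 0.
#'
#' @param calls reliability table from [label_reliability()].
#' @param grid strictly increasing positive thresholds (FPKM).
#' @return data frame of class `detection_curve` with columns `threshold`,
#'   `n_detected`, `reliability`, `fp_rate`, `fn_rate`, `defined`.
#' @export
detection_curve <- function(calls, grid = default_grid()) {
  stopifnot(nrow(calls) > 0)
  if (any(grid <= 0) || is.unsorted(grid, strictly = TRUE))
    stop("grid must be strictly increasing and positive")
  fpkm <- calls$fpkm
  rel <- calls$reliable
  n_rel <- sum(rel)
  ## counts above threshold via one sort instead of a scan per grid point
  ord <- order(fpkm)
  fpkm_s <- fpkm[ord]
  rel_s <- rel[ord]
  cum_rel <- cumsum(rel_s)                      # reliable with fpkm <= x
  n <- length(fpkm_s)
  idx <- findInterval(grid, fpkm_s, left.open = TRUE)  # count fpkm < t
  n_below <- idx
  rel_below <- ifelse(idx == 0, 0, cum_rel[pmax(idx, 1)])
  n_det <- n - n_below
  rel_det <- n_rel - rel_below
  defined <- n_det > 0
  reliability <- ifelse(defined, rel_det / n_det, NA_real_)
  out <- data.frame(threshold = grid,
                    n_detected = n_det,
                    reliability = reliability,
                    fp_rate = 1 - reliability,
                    fn_rate = if (n_rel > 0) rel_below / n_rel else NA_real_,
                    defined = defined)
  class(out) <- c("detection_curve", "data.frame")
  out
}

#' Select the detection threshold from a reliability curve
#'
#' Returns the smallest grid threshold whose reliability reaches the target
#' (the probability that a detected transcript is reliably detected).
#'
#' @param curve a [detection_curve()].
#' @param target_reliability required reliability fraction.
#' @return list of class `threshold_selection` with `threshold`,
#'   `reliability` and `fn_rate` achieved at the selection.
#' @export
select_threshold <- function(curve, target_reliability = 0.99) {
  stopifnot(inherits(curve, "detection_curve"))
  ok <- which(curve$defined & curve$reliability >= target_reliability)
  if (!length(ok)) {
    best <- max(curve$reliability[curve$defined])
    stop(sprintf(paste0("target reliability %.4f unattainable on this grid; ",
                        "maximum achievable is %.4f"),
                 target_reliability, best))
  }
  i <- ok[1]
  structure(list(threshold = curve$threshold[i],
                 reliability = curve$reliability[i],
                 fn_rate = curve$fn_rate[i],
                 target = target_reliability),
            class = "threshold_selection")
}

#' @export
print.threshold_selection <- function(x, ...) {
  cat(sprintf("detection threshold %.4g FPKM (reliability %.4f, FN rate %.4f at target %.2f)\n",
              x$threshold, x$reliability, x$fn_rate, x$target))
  invisible(x)
}

#' Floor FPKM values before fold-change computation
#'
#' Replaces every value below the floor by the floor, the usual guard
#' against ratio inflation from near-zero denominators. Confidence bound
#' matrices are left untouched; the operation is idempotent and
#' order-preserving.
#'
#' @param study an [expression_study()].
#' @param floor FPKM floor (> 0), typically the selected detection
#'   threshold.
#' @return the study with floored values and attribute `floor` recorded.
#' @export
floor_fpkm <- function(study, floor = 0.1) {
  stopifnot(inherits(study, "expression_study"), floor > 0)
  study$values[study$values < floor] <- floor
  attr(study, "floor") <- floor
  study
}
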