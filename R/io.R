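## Readers and writers for the plain-text tables the pipeline touches.
## All tables are tab-separated UTF-8 with one header line; feature ids are
## case-sensitive strings. Readers validate eagerly and name the offending
## column/row in error messages.

.location_tokens <- c(E = "extracellular_space", P = "plasma_membrane",
                      C = "cytoplasm", N = "nucleus", O = "other")

read_tsv_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "")
}

#' Read a Cufflinks-style fpkm_tracking table
#'
#' Parses one `.fpkm_tracking`-dialect file (one sequencing library) into a
#' single-sample [expression_study()] fragment carrying the FPKM estimate and
#' its 95% confidence bounds. Mandatory columns are `tracking_id`, `FPKM`,
#' `FPKM_conf_lo` and `FPKM_conf_hi`; any other columns (including
#' `FPKM_status`) are ignored, since detection reliability is recomputed from
#' the confidence bounds downstream.
#'
#' @param path path to the tab-separated file.
#' @param sample_id sample identifier to assign to this library.
#' @param stage stage label (e.g. `"CTR"`, `"D2"`, `"D7"`).
#' @param replicate replicate index within the stage.
#' @return a one-sample `expression_study` with confidence bounds.
#' @export
read_fpkm_tracking <- function(path, sample_id, stage, replicate = 1L) {
  tab <- read_tsv_checked(path)
  needed <- c("tracking_id", "FPKM", "FPKM_conf_lo", "FPKM_conf_hi")
  miss <- setdiff(needed, names(tab))
  if (length(miss))
    stop("fpkm_tracking format error: missing column(s) ",
         paste(miss, collapse = ", "), " in ", path)
  for (col in c("FPKM", "FPKM_conf_lo", "FPKM_conf_hi")) {
    x <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(x) & !is.na(tab[[col]]))
    if (length(bad))
      stop("non-numeric ", col, " at data row(s) ",
           paste(utils::head(bad, 5), collapse = ", "))
    tab[[col]] <- x
  }
  bad_ci <- which(tab$FPKM_conf_lo > tab$FPKM + 1e-9)
  if (length(bad_ci))
    stop("validation error: FPKM_conf_lo exceeds FPKM at data row(s) ",
         paste(utils::head(bad_ci, 5), collapse = ", "))
  mk <- function(x) matrix(x, ncol = 1,
                           dimnames = list(tab$tracking_id, sample_id))
  expression_study(mk(tab$FPKM),
                   data.frame(sample_id = sample_id, stage = stage,
                              replicate = as.integer(replicate)),
                   ci_lo = mk(pmax(tab$FPKM_conf_lo, 0)),
                   ci_hi = mk(tab$FPKM_conf_hi))
}

#' Write one sample of a study in fpkm_tracking dialect
#'
#' @param study an `expression_study` with confidence bounds.
#' @param path output path.
#' @param sample sample id to write; defaults to the only sample.
#' @return `path`, invisibly.
#' @export
write_fpkm_tracking <- function(study, path, sample = NULL) {
  stopifnot(inherits(study, "expression_study"))
  if (is.null(study$ci_lo) || is.null(study$ci_hi))
    stop("study has no confidence bounds to write")
  if (is.null(sample)) {
    if (ncol(study$values) != 1L)
      stop("specify `sample` for a multi-sample study")
    sample <- colnames(study$values)
  }
  tab <- data.frame(tracking_id = rownames(study$values),
                    FPKM = study$values[, sample],
                    FPKM_conf_lo = study$ci_lo[, sample],
                    FPKM_conf_hi = study$ci_hi[, sample])
  write_tsv(tab, path)
}

#' Read a genes-by-samples expression matrix
#'
#' First column holds feature ids, the remaining columns one sample each.
#' Every sample column must be described in `metadata`.
#'
#' @param path path to the tab-separated matrix.
#' @param metadata data frame with columns `sample_id`, `stage`, `replicate`
#'   (or a path to such a table).
#' @param feature_kind `"gene"` or `"isoform"`.
#' @param isoform_map optional isoform-to-gene map (see [expression_study()]).
#' @return an `expression_study` without confidence bounds.
#' @export
read_expression_matrix <- function(path, metadata, feature_kind = "gene",
                                   isoform_map = NULL) {
  if (is.character(metadata) && length(metadata) == 1L)
    metadata <- read_tsv_checked(metadata)
  tab <- read_tsv_checked(path)
  ids <- as.character(tab[[1]])
  vals <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- ids
  unknown <- setdiff(colnames(vals), as.character(metadata$sample_id))
  if (length(unknown))
    stop("sample(s) in matrix header absent from metadata: ",
         paste(unknown, collapse = ", "))
  if (anyNA(vals)) stop("non-numeric expression value in ", path)
  if (any(vals < 0)) stop("negative expression value in ", path)
  if (is.factor(metadata$stage))
    metadata$stage <- factor(metadata$stage, levels = levels(metadata$stage))
  expression_study(vals, metadata[match(colnames(vals), metadata$sample_id), ],
                   feature_kind = feature_kind, isoform_map = isoform_map)
}

#' Write an expression matrix (plus metadata) for a study
#'
#' @param study an `expression_study`.
#' @param path output path for the feature-by-sample matrix.
#' @param metadata_path optional path for the sample-metadata table.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(study, path, metadata_path = NULL) {
  stopifnot(inherits(study, "expression_study"))
  tab <- data.frame(feature_id = rownames(study$values),
                    study$values, check.names = FALSE)
  if (!is.null(metadata_path)) write_tsv(study$samples, metadata_path)
  write_tsv(tab, path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, fields `name`, `description`, then member
#' gene ids. Duplicate members within a set are collapsed.
#'
#' @param path path to the GMT file.
#' @return a named list of character vectors with attribute `description`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nms <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(nms)) stop("duplicate gene-set name(s) in ", path)
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  empty <- which(!lengths(sets))
  if (length(empty))
    stop("empty gene set(s): ", paste(nms[empty], collapse = ", "))
  names(sets) <- nms
  attr(sets, "description") <- stats::setNames(
    vapply(fields, function(f) if (length(f) >= 2) f[[2]] else "", character(1)), nms)
  sets
}

#' Write a GMT gene-set collection
#' @param sets named list of character vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(desc) && nm %in% names(desc)) desc[[nm]] else ""
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an undirected interaction edge list
#'
#' Two-or-three-column TSV (`geneA`, `geneB`, optional interaction label) or
#' SIF (`geneA`, label, `geneB`). Edges are normalized to unordered pairs:
#' self-loops are dropped with a warning and duplicate pairs (in either
#' orientation) are collapsed.
#'
#' @param path path to the edge table.
#' @param sif logical; set `TRUE` for SIF column order.
#' @return data frame with columns `from`, `to` (lexicographically ordered
#'   within a pair) and `label`.
#' @export
read_edge_list <- function(path, sif = FALSE) {
  tab <- utils::read.delim(path, header = !sif, sep = "\t", quote = "",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(tab) < 2) stop("edge list needs at least two columns")
  if (sif && ncol(tab) >= 3) {
    edges <- data.frame(from = as.character(tab[[1]]),
                        to = as.character(tab[[3]]),
                        label = as.character(tab[[2]]))
  } else {
    edges <- data.frame(from = as.character(tab[[1]]),
                        to = as.character(tab[[2]]),
                        label = if (ncol(tab) >= 3) as.character(tab[[3]]) else "")
  }
  normalize_edges(edges)
}

#' Normalize an edge table to unordered, de-duplicated pairs
#' @param edges data frame with columns `from`, `to` and optionally `label`.
#' @return normalized edge data frame.
#' @export
normalize_edges <- function(edges) {
  stopifnot(all(c("from", "to") %in% names(edges)))
  if (is.null(edges$label)) edges$label <- ""
  loops <- edges$from == edges$to
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped")
    edges <- edges[!loops, , drop = FALSE]
  }
  a <- pmin(edges$from, edges$to)
  b <- pmax(edges$from, edges$to)
  keep <- !duplicated(paste(a, b, sep = "\r"))
  out <- data.frame(from = a[keep], to = b[keep],
                    label = edges$label[keep], stringsAsFactors = FALSE)
  out[order(out$from, out$to), , drop = FALSE][, , drop = FALSE]
}

#' Write an edge list
#' @param edges data frame with columns `from`, `to`, optionally `label`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path) write_tsv(edges, path)

#' Read a gene annotation table
#'
#' TSV with columns `gene_id`, `location`, `has_drug`. Locations use either
#' the one-letter tokens `E` (extracellular space), `P` (plasma membrane),
#' `C` (cytoplasm), `N` (nucleus), `O` (other) or the spelled-out forms; the
#' drug flag is `Y`/`N` (or logical).
#'
#' @param path path to the annotation table.
#' @return data frame with columns `gene_id`, `location` (spelled-out token)
#'   and `has_drug` (logical), one row per gene.
#' @export
read_annotation <- function(path) {
  tab <- read_tsv_checked(path)
  need <- c("gene_id", "location", "has_drug")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("annotation format error: missing column(s) ", paste(miss, collapse = ", "))
  loc <- as.character(tab$location)
  short <- loc %in% names(.location_tokens)
  loc[short] <- .location_tokens[loc[short]]
  bad <- !loc %in% .location_tokens
  if (any(bad))
    stop("unknown location token(s): ", paste(unique(loc[bad]), collapse = ", "),
         "; allowed: ", paste(names(.location_tokens), collapse = ", "),
         " or ", paste(.location_tokens, collapse = ", "))
  drug <- tab$has_drug
  if (!is.logical(drug)) drug <- toupper(as.character(drug)) %in% c("Y", "YES", "TRUE")
  if (anyDuplicated(tab$gene_id)) stop("duplicate gene_id in annotation")
  data.frame(gene_id = as.character(tab$gene_id), location = loc,
             has_drug = drug, stringsAsFactors = FALSE)
}

#' Write a gene annotation table
#' @param annotation data frame as returned by [read_annotation()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  out <- annotation
  out$has_drug <- ifelse(annotation$has_drug, "Y", "N")
  write_tsv(out, path)
}

#' Look up annotations for a gene set, with permissive defaults
#'
#' Genes absent from the table get location `"other"` and `has_drug = FALSE`
#' so that prioritization can still run on partially annotated networks.
#'
#' @param genes character vector of gene ids.
#' @param annotation annotation data frame (may be `NULL`).
#' @return data frame with one row per requested gene.
#' @export
annotation_for <- function(genes, annotation = NULL) {
  out <- data.frame(gene_id = genes, location = "other", has_drug = FALSE,
                    stringsAsFactors = FALSE)
  if (!is.null(annotation)) {
    idx <- match(genes, annotation$gene_id)
    hit <- !is.na(idx)
    out$location[hit] <- annotation$location[idx[hit]]
    out$has_drug[hit] <- annotation$has_drug[idx[hit]]
  }
  out
}

#' Write a tab-separated table
#'
#' Single header line, no quoting, no row names; the dialect every other
#' writer in the package uses.
#'
#' @param tab data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
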