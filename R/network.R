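## Network-based candidate prioritization: induce an interaction network
## over focus genes (optionally growing it by first neighbors), count each
## gene's interaction partners (connection number), filter by cellular
## location / drug availability, and rank by the Relevance Index
## RI = |log(fold change)| * connection number.

#' Build an interaction network over focus genes
#'
#' Induces the subgraph of the interaction edge list on the focus genes
#' (plus, when `include_neighbors = TRUE`, their first neighbors — the
#' "white nodes" a knowledge-base network grower would pull in). Nodes left
#' without any connection are removed.
#'
#' @param focus_genes character vector of seed genes (e.g. from
#'   [select_top_fraction()]).
#' @param edges normalized edge data frame (see [read_edge_list()] /
#'   [normalize_edges()]).
#' @param include_neighbors grow the node set by first neighbors of focus
#'   genes before inducing.
#' @return an [igraph][igraph::igraph-package] undirected graph whose
#'   vertices carry a logical `focus` attribute.
#' @export
build_network <- function(focus_genes, edges, include_neighbors = TRUE) {
  stopifnot(length(focus_genes) > 0)
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                     directed = FALSE)
  present <- intersect(focus_genes, igraph::V(g)$name)
  if (!length(present))
    stop("none of the focus genes appear in the edge list")
  nodes <- present
  if (include_neighbors) {
    nb <- unique(unlist(lapply(present, function(v)
      igraph::V(g)$name[as.integer(igraph::neighbors(g, v))])))
    nodes <- union(present, nb)
  }
  sub <- igraph::induced_subgraph(g, nodes)
  iso <- igraph::V(sub)$name[igraph::degree(sub) == 0]
  if (length(iso)) sub <- igraph::delete_vertices(sub, iso)
  igraph::V(sub)$focus <- igraph::V(sub)$name %in% focus_genes
  sub
}

#' Connection number (degree) of every network gene
#'
#' @param network graph from [build_network()].
#' @return named integer vector: number of distinct interaction partners
#'   per gene.
#' @export
connection_numbers <- function(network) {
  igraph::degree(igraph::simplify(network))
}

#' Filter network genes by location, fold change and drug availability
#'
#' A gene passes when it sits on the plasma membrane or in extracellular
#' space (drug-accessible compartments) and its fold change is beyond the
#' cutoff in either direction, or when drug information exists for it
#' regardless of location.
#'
#' @param network graph from [build_network()].
#' @param annotation annotation data frame (see [read_annotation()]); genes
#'   without a record default to location `"other"`, no drug.
#' @param de `de_result` table supplying fold changes; network genes absent
#'   from it are treated as unchanged (fc = 1).
#' @param fc_cutoff fold-change cutoff.
#' @return data frame with columns `gene_id`, `fc`, `log2_fc`,
#'   `connection_number`, `location`, `has_drug`, `passes_filter`.
#' @export
filter_candidates <- function(network, annotation, de, fc_cutoff = 2) {
  genes <- igraph::V(network)$name
  deg <- connection_numbers(network)
  ann <- annotation_for(genes, annotation)
  fc <- de$fc[match(genes, de$gene_id)]
  fc[is.na(fc)] <- 1
  accessible <- ann$location %in% c("plasma_membrane", "extracellular_space")
  changed <- fc > fc_cutoff | fc < 1 / fc_cutoff
  data.frame(gene_id = genes, fc = fc, log2_fc = log2(fc),
             connection_number = as.integer(deg[genes]),
             location = ann$location, has_drug = ann$has_drug,
             passes_filter = (accessible & changed) | ann$has_drug,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Relevance Index
#'
#' `RI = |log(fold change)| * connection number`: a candidate score that is
#' zero for unchanged (fc = 1) or unconnected genes and grows with both the
#' expression change and the gene's hubness. The log base (default 2) only
#' rescales RI by a positive constant, so rankings are base-invariant.
#'
#' @param fc positive fold change(s).
#' @param connection_number non-negative degree(s).
#' @param log_base logarithm base.
#' @return numeric RI value(s).
#' @export
relevance_index <- function(fc, connection_number, log_base = 2) {
  if (any(fc <= 0)) stop("fold change must be positive")
  if (any(connection_number < 0)) stop("connection number must be >= 0")
  abs(log(fc, base = log_base)) * connection_number
}

#' Rank filtered candidates by Relevance Index
#'
#' Orders candidates that pass the filter by decreasing RI; ties are broken
#' by higher connection number, then gene id, so rank 1 is the strongest
#' candidate and ranks are a permutation of 1..n within the filtered set.
#'
#' @param candidates data frame from [filter_candidates()].
#' @param log_base log base handed to [relevance_index()].
#' @return data frame of class `ranked_candidates`: the filtered rows with
#'   `relevance_index` and `rank` columns, ordered by rank.
#' @export
rank_candidates <- function(candidates, log_base = 2) {
  keep <- candidates[candidates$passes_filter, , drop = FALSE]
  keep$relevance_index <- relevance_index(keep$fc, keep$connection_number,
                                          log_base)
  ord <- order(-keep$relevance_index, -keep$connection_number, keep$gene_id)
  keep <- keep[ord, , drop = FALSE]
  keep$rank <- seq_len(nrow(keep))
  rownames(keep) <- NULL
  class(keep) <- c("ranked_candidates", "data.frame")
  keep
}

#' Full candidate-prioritization framework for one contrast
#'
#' Chains the framework: take the top fraction of up/down-regulated genes
#' as focus genes, build the interaction network (optionally separately per
#' direction, the sensible choice when one direction dominates), filter by
#' location/drug, compute RI and rank.
#'
#' @param de `de_result` table from [call_de()].
#' @param edges normalized interaction edge list.
#' @param annotation annotation data frame (or `NULL`).
#' @param fraction top fraction of each direction used as focus genes.
#' @param separate_directions build one network per direction instead of a
#'   single joint network.
#' @param include_neighbors grow networks by first neighbors.
#' @param fc_cutoff fold-change filter cutoff.
#' @param log_base RI log base.
#' @return if `separate_directions`, a named list of `ranked_candidates`
#'   tables (`up`, `down`); otherwise a single table.
#' @export
prioritize_genes <- function(de, edges, annotation = NULL, fraction = 0.10,
                             separate_directions = FALSE,
                             include_neighbors = TRUE,
                             fc_cutoff = 2, log_base = 2) {
  top <- select_top_fraction(de, fraction)
  run <- function(focus) {
    net <- build_network(focus, edges, include_neighbors = include_neighbors)
    rank_candidates(filter_candidates(net, annotation, de, fc_cutoff),
                    log_base = log_base)
  }
  if (separate_directions)
    list(up = run(top$up), down = run(top$down))
  else
    run(c(top$up, top$down))
}
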