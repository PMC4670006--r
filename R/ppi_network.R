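# Protein-protein interaction network features: simple undirected graph,
# restriction to the largest connected component, per-node degree,
# betweenness and average neighbor degree, and chromosome-group summaries.

#' Build a simple undirected graph from an edge list
#'
#' The node set is edge-defined: only proteins appearing in at least one
#' interaction enter the graph. Self-loops and duplicate edges are removed
#' (the edge-list reader already guarantees this for parsed files).
#'
#' @param edges Data.frame with columns `a`, `b` (see [read_edges()]).
#' @return An [igraph::igraph] undirected simple graph.
#' @export
build_graph <- function(edges) {
  stopifnot(is.data.frame(edges), all(c("a", "b") %in% names(edges)))
  if (nrow(edges) == 0L) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  g <- igraph::graph_from_data_frame(edges[, c("a", "b")], directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Restrict a graph to its largest connected component
#'
#' Ties between equally large components are broken by keeping the one
#' containing the lexicographically smallest node name.
#'
#' @param graph An igraph graph.
#' @return The induced subgraph on the largest component.
#' @export
largest_component <- function(graph) {
  if (igraph::vcount(graph) == 0L) stop("empty graph")
  comps <- igraph::components(graph)
  biggest <- which(comps$csize == max(comps$csize))
  if (length(biggest) > 1L) {
    reps <- vapply(biggest, function(ci) {
      min(igraph::V(graph)$name[comps$membership == ci])
    }, character(1))
    biggest <- biggest[order(reps)[1]]
  }
  igraph::induced_subgraph(graph,
                           which(comps$membership == biggest))
}

#' Per-node network features
#'
#' Degree (number of interaction partners), betweenness (for each node v,
#' the sum over unordered source-target pairs of the fraction of shortest
#' paths passing through v — reported unnormalized, on the pair-count
#' scale), and average neighbor degree (mean degree of direct neighbors).
#'
#' @param graph An igraph graph, typically the largest component.
#' @param normalized Divide betweenness by the pair count
#'   `(n-1)(n-2)/2`, turning it into a fraction.
#' @return Data.frame `node`, `degree`, `betweenness`,
#'   `avg_neighbor_degree`.
#' @export
node_features <- function(graph, normalized = FALSE) {
  if (igraph::vcount(graph) == 0L) stop("empty graph")
  deg <- igraph::degree(graph)
  btw <- igraph::betweenness(graph, directed = FALSE, normalized = FALSE)
  if (normalized) {
    n <- igraph::vcount(graph)
    if (n > 2L) btw <- btw / ((n - 1) * (n - 2) / 2)
  }
  knn <- igraph::knn(graph)$knn
  data.frame(node = igraph::V(graph)$name,
             degree = as.integer(unname(deg)),
             betweenness = unname(btw),
             avg_neighbor_degree = unname(knn),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Chromosome-group summaries of network features
#'
#' Joins node features with the genome map and reports, per chromosome,
#' mean, standard error (SD/sqrt(n)) and median of degree, betweenness and
#' average neighbor degree. Nodes absent from the map are grouped under
#' `"unmapped"`. Single-node groups get `se = 0` and `se_defined = FALSE`.
#'
#' @param features Data.frame from [node_features()].
#' @param genome_map Genome map data.frame, see [genome_map()].
#' @return Data.frame, one row per group.
#' @export
group_summary <- function(features, genome_map) {
  stopifnot(is.data.frame(features), nrow(features) > 0L)
  chrom <- genome_map$chromosome[match(features$node,
                                       genome_map$protein_id)]
  chrom[is.na(chrom)] <- "unmapped"
  groups <- c(unique(genome_map$chromosome), "unmapped")
  groups <- groups[groups %in% chrom]
  cols <- c("degree", "betweenness", "avg_neighbor_degree")
  do.call(rbind, lapply(groups, function(gl) {
    sub <- features[chrom == gl, , drop = FALSE]
    n <- nrow(sub)
    row <- data.frame(group = gl, n_nodes = n, stringsAsFactors = FALSE)
    for (cl in cols) {
      x <- sub[[cl]]
      row[[paste0("mean_", cl)]] <- mean(x)
      row[[paste0("se_", cl)]] <- if (n > 1L) stats::sd(x) / sqrt(n) else 0
      row[[paste0("median_", cl)]] <- stats::median(x)
    }
    row$se_defined <- n > 1L
    row
  }))
}
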