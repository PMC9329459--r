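#' Build a sequence similarity graph from alignment hits
#'
#' Nodes are sequences; an undirected edge links a query to a target
#' whenever some hit between them has an alignment of at least `min_aln`
#' residues with at least `min_prob` percent search probability (both
#' directions of an all-against-all table collapse to the same edge;
#' self-hits are dropped). A query with several qualifying alignments in
#' non-overlapping query regions represents distinct domains: its qualifying
#' hits are clustered by query-interval overlap (single linkage; two
#' intervals belong together when their overlap exceeds `overlap_frac` of
#' the shorter) and the query is duplicated into one suffixed node per
#' region (`id#1`, `id#2`, ...). Every query and target id appearing in the
#' input is retained as a node, so sequences whose hits all fail the
#' thresholds appear as isolated nodes.
#'
#' @param hits An alignment-hit tibble (see [alignment_hits()]).
#' @param min_aln Minimum alignment length (residues); default 20.
#' @param min_prob Minimum probability (percent); default 70.
#' @param overlap_frac Query-interval overlap tolerance for calling two
#'   alignments non-overlapping (fraction of the shorter interval).
#' @param node_class Optional named character vector mapping sequence ids to
#'   class labels (e.g. structural class or `"generated"`); duplicated
#'   nodes inherit their parent's class.
#' @return A `similarity_graph`: list with an igraph `graph` and a `nodes`
#'   tibble (`node`, `parent`, `class`).
#' @export
build_graph <- function(hits, min_aln = 20L, min_prob = 70,
                        overlap_frac = 0.1, node_class = NULL) {
  if (min_aln < 1L) abort_param("min_aln must be >= 1")
  if (min_prob < 0 || min_prob > 100) abort_param("min_prob must be in [0, 100]")
  validate_hits(hits)
  qual <- hits[hits$aln_length >= min_aln & hits$probability >= min_prob &
                 hits$query_id != hits$target_id, , drop = FALSE]
  # region assignment per query
  edge_from <- character(0)
  edge_to <- character(0)
  node_parent <- stats::setNames(character(0), character(0))
  add_node <- function(node, parent) {
    node_parent[[node]] <<- parent
  }
  for (q in unique(qual$query_id)) {
    h <- qual[qual$query_id == q, , drop = FALSE]
    regions <- cluster_intervals(h$qstart, h$qend, overlap_frac)
    n_regions <- max(regions)
    if (n_regions == 1L) {
      add_node(q, q)
      edge_from <- c(edge_from, rep(q, nrow(h)))
    } else {
      labels <- paste0(q, "#", regions)
      for (r in seq_len(n_regions)) add_node(paste0(q, "#", r), q)
      edge_from <- c(edge_from, labels)
    }
    edge_to <- c(edge_to, h$target_id)
  }
  # remaining ids become (possibly isolated) plain nodes; a target id is a
  # node even when the same sequence's query entry was split into regions
  for (id in setdiff(unique(c(hits$query_id, hits$target_id)), names(node_parent))) {
    if (id %in% edge_to ||
        !any(startsWith(names(node_parent), paste0(id, "#")))) {
      add_node(id, id)
    }
  }
  edges <- unique(tibble::tibble(
    from = pmin(edge_from, edge_to),
    to = pmax(edge_from, edge_to)))
  edges <- edges[edges$from != edges$to, , drop = FALSE]
  nodes <- tibble::tibble(node = names(node_parent),
                          parent = unname(node_parent))
  nodes <- nodes[order(nodes$node, method = "radix"), , drop = FALSE]
  nodes$class <- if (is.null(node_class)) NA_character_ else
    unname(node_class[nodes$parent])
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes$node)
  structure(list(graph = g, nodes = nodes), class = "similarity_graph")
}

# single-linkage clustering of intervals; same cluster when overlap exceeds
# overlap_frac of the shorter interval. returns cluster index per interval,
# numbered 1..k in order of leftmost start.
cluster_intervals <- function(starts, ends, overlap_frac) {
  n <- length(starts)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      ov <- min(ends[i], ends[j]) - max(starts[i], starts[j]) + 1L
      shorter <- min(ends[i] - starts[i], ends[j] - starts[j]) + 1L
      if (ov > overlap_frac * shorter) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1L))
  # order clusters by leftmost start for stable suffixes
  cluster_start <- vapply(unique(roots), function(r) min(starts[roots == r]),
                          numeric(1L))
  ord <- unique(roots)[order(cluster_start)]
  match(roots, ord)
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat(sprintf("<similarity_graph> %d nodes, %d edges\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph)))
  invisible(x)
}

#' Connected components of a similarity graph
#'
#' The "island-like" clusters of sequence space: maximal sets of sequences
#' connected through qualifying alignments. Returned largest first, ties
#' broken by the lexicographically smallest member.
#'
#' @param graph A `similarity_graph`.
#' @return A list of character vectors (sorted node names per component).
#' @export
graph_components <- function(graph) {
  comp <- igraph::components(graph$graph)
  sets <- split(names(comp$membership), comp$membership)
  sets <- lapply(sets, function(s) sort(s, method = "radix"))
  reps <- vapply(sets, `[`, character(1L), 1L)
  sizes <- lengths(sets)
  unname(sets[order(-sizes, reps, method = "radix")])
}

#' Compare networks with and without a bridging sequence set
#'
#' Side-by-side component statistics for a graph and the graph built without
#' a set of sequences (e.g. with and without generated sequences): if the
#' removed set bridges islands, the full graph has fewer components and a
#' larger major component.
#'
#' @param graph_with `similarity_graph` including the set.
#' @param graph_without `similarity_graph` excluding it; its nodes must be
#'   a subset of `graph_with`'s.
#' @return A tibble with one row per graph: `graph`, `n_nodes`, `n_edges`,
#'   `n_components`, `largest_component`.
#' @export
bridge_report <- function(graph_with, graph_without) {
  nw <- igraph::V(graph_with$graph)$name
  nwo <- igraph::V(graph_without$graph)$name
  if (!all(nwo %in% nw)) {
    abort_contract("graph_without contains nodes absent from graph_with")
  }
  stat <- function(g, label) {
    comps <- graph_components(g)
    tibble::tibble(graph = label,
                   n_nodes = igraph::vcount(g$graph),
                   n_edges = igraph::ecount(g$graph),
                   n_components = length(comps),
                   largest_component = if (length(comps)) lengths(comps)[1L] else 0L)
  }
  dplyr::bind_rows(stat(graph_with, "with"), stat(graph_without, "without"))
}

#' Write a similarity graph as plain-text files
#'
#' An edge-list file (`from<TAB>to`) and a node-attribute TSV
#' (`node`, `parent`, `class`).
#'
#' @param graph A `similarity_graph`.
#' @param edges_path,nodes_path Output paths.
#' @return `edges_path`, invisibly.
#' @export
write_graph_files <- function(graph, edges_path, nodes_path) {
  el <- igraph::as_edgelist(graph$graph)
  utils::write.table(data.frame(from = el[, 1L], to = el[, 2L]),
                     edges_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(graph$nodes, nodes_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(edges_path)
}
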