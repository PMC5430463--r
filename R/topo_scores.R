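#' Conserved subgraph of an alignment
#'
#' Given an alignment f of the smaller network G1 into the larger network G2,
#' the conserved edges are the edges (u, v) of G1 whose image (f(u), f(v)) is
#' an edge of G2. The induced target edge count is the number of G2 edges with
#' both endpoints in the image f(V1). These two counts drive EC, ICS and S3.
#'
#' @param net1 the smaller [ppi_network()] (G1).
#' @param net2 the larger [ppi_network()] (G2).
#' @param aln a [ppi_alignment()] from `net1` into `net2`.
#' @return an object of class `conserved_subgraph` with fields
#'   `aligned_source_nodes`, `conserved_edges` (two-column matrix of G1
#'   edges), `n_conserved`, and `induced_target_edges`.
#' @export
conserved_subgraph <- function(net1, net2, aln) {
  map <- alignment_map(aln)
  unknown <- setdiff(names(map), network_nodes(net1))
  if (length(unknown)) stop("alignment source node(s) not in G1: ",
                            paste(utils::head(unknown, 5L), collapse = ", "))
  unknown <- setdiff(unname(map), network_nodes(net2))
  if (length(unknown)) stop("alignment target node(s) not in G2: ",
                            paste(utils::head(unknown, 5L), collapse = ", "))
  e1 <- network_edges(net1)
  conserved <- matrix(character(), ncol = 2L)
  if (nrow(e1) && length(map)) {
    cand <- e1[e1[, 1L] %in% names(map) & e1[, 2L] %in% names(map), ,
               drop = FALSE]
    if (nrow(cand)) {
      vp <- as.vector(rbind(map[cand[, 1L]], map[cand[, 2L]]))
      ids <- igraph::get_edge_ids(net2$graph, vp)
      conserved <- cand[ids > 0L, , drop = FALSE]
    }
  }
  induced <- if (length(map)) {
    igraph::ecount(igraph::induced_subgraph(net2$graph, unname(map)))
  } else 0L
  structure(list(aligned_source_nodes = names(map),
                 conserved_edges = conserved,
                 n_conserved = nrow(conserved),
                 induced_target_edges = induced),
            class = "conserved_subgraph")
}

#' @export
print.conserved_subgraph <- function(x, ...) {
  cat(sprintf("<conserved_subgraph> %d aligned nodes, %d conserved edges, %d induced target edges\n",
              length(x$aligned_source_nodes), x$n_conserved,
              x$induced_target_edges))
  invisible(x)
}

undefined_score <- function(what, why) {
  warning(sprintf("%s is undefined (%s); returning NA", what, why))
  NA_real_
}

#' Node coverage (NC)
#'
#' The number of mapped nodes normalized by the node count of the smaller
#' network. Global aligners aim at NC = 1 but often fall short.
#'
#' @param net1 the smaller [ppi_network()].
#' @param aln a [ppi_alignment()].
#' @return fraction in `[0, 1]`.
#' @export
node_coverage <- function(net1, aln) {
  alignment_size(aln) / n_nodes(net1)
}

#' Edge correctness (EC)
#'
#' Conserved edges divided by the edge count of the smaller network: the
#' fraction of small-network interactions preserved by the alignment.
#'
#' @param cs a [conserved_subgraph()].
#' @param net1 the smaller [ppi_network()].
#' @return fraction in `[0, 1]`, or `NA` when G1 has no edges.
#' @export
edge_correctness <- function(cs, net1) {
  if (n_edges(net1) == 0L) return(undefined_score("EC", "smaller network has no edges"))
  cs$n_conserved / n_edges(net1)
}

#' Induced conserved sub-structure score (ICS)
#'
#' Conserved edges divided by the number of larger-network edges induced by
#' the image node set: the alignment seen from the larger network's side,
#' penalizing mapping a sparse region onto a dense one.
#'
#' @param cs a [conserved_subgraph()].
#' @return fraction in `[0, 1]`, or `NA` when the image induces no edges.
#' @export
induced_conserved_structure <- function(cs) {
  if (cs$induced_target_edges == 0L) {
    return(undefined_score("ICS", "no edges induced by the image"))
  }
  cs$n_conserved / cs$induced_target_edges
}

#' Symmetric sub-structure score (S3)
#'
#' Conserved edges divided by (smaller-network edges + induced larger-network
#' edges - conserved edges). S3 penalizes both missed small-network edges and
#' spurious density on the larger side, and satisfies
#' `S3 = 1 / (1/EC + 1/ICS - 1)` whenever EC and ICS are defined.
#'
#' @inheritParams edge_correctness
#' @return fraction in `[0, 1]`, or `NA` when the denominator is zero.
#' @export
symmetric_substructure <- function(cs, net1) {
  denom <- n_edges(net1) + cs$induced_target_edges - cs$n_conserved
  if (denom == 0L) return(undefined_score("S3", "zero denominator"))
  cs$n_conserved / denom
}

#' Largest conserved connected component (LCC)
#'
#' Size of the largest connected component of the conserved subgraph (aligned
#' source nodes joined by conserved edges), normalized by the smaller
#' network's node count so that it lies in `[0, 1]` and can be averaged and
#' correlated with the other scores. Isolated aligned nodes do not form
#' components: with no conserved edge the score is 0. The component is built
#' on the smaller network's side; its image in the larger network is
#' isomorphic by construction, so the choice of side does not matter.
#'
#' @inheritParams edge_correctness
#' @return fraction in `[0, 1]`. The raw node and edge counts of the largest
#'   component are available via [largest_conserved_component_size()].
#' @export
largest_conserved_component <- function(cs, net1) {
  largest_conserved_component_size(cs)[["nodes"]] / n_nodes(net1)
}

#' @rdname largest_conserved_component
#' @param cs a [conserved_subgraph()].
#' @export
largest_conserved_component_size <- function(cs) {
  if (cs$n_conserved == 0L) return(c(nodes = 0L, edges = 0L))
  g <- igraph::graph_from_data_frame(
    as.data.frame(cs$conserved_edges, stringsAsFactors = FALSE),
    directed = FALSE)
  comp <- igraph::components(g)
  best <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(g, which(comp$membership == best))
  c(nodes = igraph::vcount(sub), edges = igraph::ecount(sub))
}

#' All five topological scores of an alignment
#'
#' @param net1,net2 the smaller and larger [ppi_network()]s.
#' @param aln a [ppi_alignment()] from `net1` into `net2`.
#' @return named numeric vector with elements `nc`, `ec`, `ics`, `s3`, `lcc`
#'   (undefined scores are `NA`).
#' @export
topo_scores <- function(net1, net2, aln) {
  cs <- conserved_subgraph(net1, net2, aln)
  c(nc = node_coverage(net1, aln),
    ec = edge_correctness(cs, net1),
    ics = induced_conserved_structure(cs),
    s3 = symmetric_substructure(cs, net1),
    lcc = largest_conserved_component(cs, net1))
}
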