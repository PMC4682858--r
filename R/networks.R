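# Correlation-threshold co-expression networks and shortest-path PPI
# subnetworks.

#' Pairwise Pearson correlation of expression profiles
#'
#' Correlations are computed between rows (genes or promoters) of a profile
#' matrix, typically replicate-averaged log2 time courses within one
#' stimulus arm. Zero-variance rows have undefined correlations and are
#' excluded with a warning.
#'
#' @param profiles numeric matrix, one profile per row, at least 2 rows and
#'   3 columns.
#' @return symmetric correlation matrix over the retained rows.
#' @export
correlation_matrix <- function(profiles) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 2L) stop("at least 2 profiles are required")
  if (ncol(profiles) < 3L) stop("profiles need at least 3 points")
  sds <- apply(profiles, 1L, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance profile(s) excluded")
    profiles <- profiles[sds > 0, , drop = FALSE]
    if (nrow(profiles) < 2L) stop("fewer than 2 profiles with variance")
  }
  stats::cor(t(profiles))
}

#' Build a co-expression graph by thresholding correlations
#'
#' Two nodes are joined when the absolute correlation of their profiles
#' strictly exceeds `threshold`; the signed correlation is kept as the edge
#' weight.
#'
#' @param cmat symmetric correlation matrix with dimnames.
#' @param threshold absolute-correlation threshold, default 0.95
#'   (strict `>`).
#' @param node_attrs optional data frame with a `name` column plus node
#'   attributes (e.g. `is_tf`, `group`) copied onto matching vertices.
#' @return An undirected weighted [igraph::igraph] graph over all rows of
#'   `cmat`.
#' @export
build_coexpression_graph <- function(cmat, threshold = 0.95,
                                     node_attrs = NULL) {
  cmat <- as.matrix(cmat)
  if (nrow(cmat) != ncol(cmat) || max(abs(cmat - t(cmat))) > 1e-8)
    stop("'cmat' must be a symmetric correlation matrix")
  adj <- abs(cmat) > threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  if (igraph::ecount(g) > 0L) {
    el <- igraph::as_edgelist(g)
    igraph::E(g)$weight <- cmat[cbind(el[, 1L], el[, 2L])]
  }
  if (!is.null(node_attrs)) {
    stopifnot("name" %in% names(node_attrs))
    idx <- match(igraph::V(g)$name, node_attrs$name)
    for (col in setdiff(names(node_attrs), "name"))
      g <- igraph::set_vertex_attr(g, col, value = node_attrs[[col]][idx])
  }
  g
}

#' Shortest-path subnetwork connecting a seed set
#'
#' Extracts from an interaction graph the union, over all unordered seed
#' pairs, of every node and edge lying on any hop-count-shortest path
#' between the pair (all ties are kept, so the result is deterministic and
#' independent of seed order). Seeds absent from the graph are dropped with
#' a notice; disconnected seed pairs contribute nothing, but every seed
#' present in the graph appears in the result.
#'
#' @param ppi an undirected [igraph::igraph] graph with named vertices.
#' @param seeds character vector of seed node names (non-empty).
#' @return An [igraph::igraph] subgraph.
#' @export
shortest_path_subnetwork <- function(ppi, seeds) {
  seeds <- unique(as.character(seeds))
  if (length(seeds) == 0L) stop("empty seed set")
  present <- seeds %in% igraph::V(ppi)$name
  if (any(!present))
    message("seed(s) not in the interaction network dropped: ",
            paste(seeds[!present], collapse = ", "))
  seeds <- seeds[present]
  if (length(seeds) == 0L) stop("no seed is present in the network")
  eids <- integer(0)
  if (length(seeds) >= 2L) {
    for (i in seq_len(length(seeds) - 1L)) {
      asp <- igraph::all_shortest_paths(ppi, from = seeds[i],
                                        to = seeds[(i + 1L):length(seeds)],
                                        mode = "all", weights = NA)
      for (path in asp$vpaths) {
        if (length(path) >= 2L)
          eids <- c(eids, as.integer(igraph::E(ppi, path = path)))
      }
    }
  }
  g <- igraph::subgraph_from_edges(ppi, igraph::E(ppi)[unique(eids)],
                                   delete.vertices = TRUE)
  missing_seeds <- setdiff(seeds, igraph::V(g)$name)
  if (length(missing_seeds) > 0L)
    g <- igraph::add_vertices(g, length(missing_seeds),
                              name = missing_seeds)
  g
}
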