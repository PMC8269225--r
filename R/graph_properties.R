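#' Graph-level properties and module detection
#'
#' Edge lists throughout the package are two-column matrices or data.frames
#' of node identifiers (unordered, no self-loops). Graphs are undirected
#' and simple.
#'
#' @name graph_properties_module
NULL

as_edge_matrix <- function(edges) {
  if (is.data.frame(edges)) edges <- as.matrix(edges[, 1:2, drop = FALSE])
  if (is.null(edges) || nrow(edges) == 0L)
    return(matrix(character(0), 0L, 2L))
  if (ncol(edges) < 2L) stop_localweb("edge list needs two columns")
  e <- cbind(as.character(edges[, 1L]), as.character(edges[, 2L]))
  if (any(e[, 1L] == e[, 2L])) stop_localweb("self-loop(s) in edge list")
  # canonical order within an edge, then dedupe
  swap <- e[, 1L] > e[, 2L]
  e[swap, ] <- e[swap, 2:1]
  e[!duplicated(paste(e[, 1L], e[, 2L], sep = "\r")), , drop = FALSE]
}

edges_to_igraph <- function(e) {
  igraph::graph_from_edgelist(e, directed = FALSE)
}

#' Newman-Girvan modularity of a partition
#'
#' Q = sum over modules c of \[e_c / m - (d_c / 2m)^2\], with e_c the number
#' of edges inside module c, d_c the total degree of its nodes and m the
#' number of edges.
#'
#' @param edges edge list (2 columns of node ids).
#' @param assignment named vector mapping every endpoint node to a module id.
#' @return Q in \[-0.5, 1\].
#' @export
newman_modularity <- function(edges, assignment) {
  e <- as_edge_matrix(edges)
  m <- nrow(e)
  if (m == 0L) stop_localweb("modularity undefined on an empty graph")
  nodes <- unique(c(e))
  if (!all(nodes %in% names(assignment)))
    stop_localweb("assignment must cover all endpoint nodes")
  mod <- as.character(assignment[nodes]); names(mod) <- nodes
  ma <- mod[e[, 1L]]; mb <- mod[e[, 2L]]
  mods <- unique(mod)
  e_c <- vapply(mods, function(cc) sum(ma == cc & mb == cc), numeric(1))
  deg <- table(factor(c(e[, 1L], e[, 2L]), levels = nodes))
  d_c <- vapply(mods, function(cc) sum(deg[nodes[mod == cc]]), numeric(1))
  sum(e_c / m - (d_c / (2 * m))^2)
}

#' Random-walk (walktrap) module detection
#'
#' Agglomerative community detection from short random-walk distances
#' (Pons & Latapy), with the dendrogram cut at the merge level maximising
#' Newman-Girvan modularity. Disconnected graphs are handled per component.
#' The procedure is deterministic; `seed` is accepted for interface
#' symmetry with the stochastic stages but is not consumed.
#'
#' @param edges edge list.
#' @param steps random-walk length t (default 4).
#' @param seed unused; the algorithm is deterministic.
#' @return list of class `module_partition` with `assignment` (named module
#'   ids), `Q` (modularity of the returned partition, recomputed with
#'   [newman_modularity()]), and `merges` (the merge history).
#' @export
walktrap_communities <- function(edges, steps = 4L, seed = NULL) {
  e <- as_edge_matrix(edges)
  if (nrow(e) == 0L) stop_localweb("cannot partition an empty edge list")
  g <- edges_to_igraph(e)
  wt <- igraph::cluster_walktrap(g, steps = steps)
  assignment <- igraph::membership(wt)
  assignment <- stats::setNames(as.integer(assignment), names(assignment))
  out <- list(assignment = assignment,
              Q = newman_modularity(e, assignment),
              merges = wt$merges,
              steps = steps)
  class(out) <- "module_partition"
  out
}

#' @export
print.module_partition <- function(x, ...) {
  sizes <- sort(table(x$assignment), decreasing = TRUE)
  cat("Module partition:", length(sizes), "module(s), Q =",
      format(x$Q, digits = 4), "\n")
  cat("Module sizes:", paste(as.integer(sizes), collapse = ", "), "\n")
  invisible(x)
}

#' Community-level properties of a graph
#'
#' Reports, on the non-isolated node set defined by the edge list: the
#' number of nodes and edges, connected components, walktrap modularity,
#' the clustering coefficient as average transitivity (mean of local
#' clustering coefficients over nodes of degree >= 2; missing when no node
#' is eligible), and the average shortest-path length over connected node
#' pairs only. The edge proportion uses the full species pool `total_otus`
#' as denominator: |E| / C(S, 2).
#'
#' @param edges edge list.
#' @param total_otus number S of species in the pool (>= nodes with edges).
#' @param steps walktrap random-walk length for the modularity estimate.
#' @param modularity compute walktrap modularity (disable to speed up
#'   randomization loops that do not need it).
#' @return list of class `graph_properties`.
#' @export
graph_properties <- function(edges, total_otus, steps = 4L, modularity = TRUE) {
  e <- as_edge_matrix(edges)
  S <- total_otus
  if (!is_count(S)) stop_localweb("total_otus must be a non-negative integer")
  prop_den <- if (S >= 2) choose(S, 2) else NA_real_
  if (nrow(e) == 0L) {
    out <- list(n_nodes = 0L, n_edges = 0L, n_components = NA_integer_,
                modularity = NA_real_, clustering = NA_real_,
                avg_path_length = NA_real_,
                edge_proportion = if (is.na(prop_den)) NA_real_ else 0)
    class(out) <- "graph_properties"
    return(out)
  }
  g <- edges_to_igraph(e)
  n_nodes <- igraph::vcount(g)
  if (S < n_nodes)
    stop_localweb("total_otus (", S, ") smaller than the number of connected nodes (",
                  n_nodes, ")")
  local_cc <- igraph::transitivity(g, type = "local", isolates = "NaN")
  clustering <- if (all(is.nan(local_cc))) NA_real_ else mean(local_cc, na.rm = TRUE)
  Q <- if (modularity) walktrap_communities(e, steps = steps)$Q else NA_real_
  out <- list(
    n_nodes = n_nodes,
    n_edges = nrow(e),
    n_components = igraph::components(g)$no,
    modularity = Q,
    clustering = clustering,
    avg_path_length = igraph::mean_distance(g, directed = FALSE, unconnected = TRUE),
    edge_proportion = if (is.na(prop_den)) NA_real_ else nrow(e) / prop_den)
  class(out) <- "graph_properties"
  out
}

#' @export
print.graph_properties <- function(x, ...) {
  cat("Graph properties:\n")
  for (f in names(x))
    cat(sprintf("  %-16s %s\n", f, format(x[[f]], digits = 4)))
  invisible(x)
}
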