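# Undirected substrate-product graph and its topological metric panel.
#
# Compounds are nodes and reactions are edges: every substrate of a reaction
# is connected to every product of that reaction.  Edge direction is not
# represented (reaction directionality is generally ambiguous), duplicate
# substrate-product pairs arising from different reactions are collapsed,
# and a compound appearing on both sides of a reaction yields a self-loop.
# Isolated compounds are not part of the graph.  Common currency metabolites
# (water, ATP, NAD...) are deliberately retained.
#
# Conventions pinned by the metric identities (average connectivity =
# 2(E - L)/N and density = 2(E - L)/(N(N-1))): self-loops are excluded from
# node degrees and from the edge count entering density, and are reported
# separately as the self-loop count L.

#' Build the metabolic graph of a reconstruction
#'
#' @param recon a [reconstruction()].
#' @param tiers optional `gm_tiers` object (see [assign_tiers()]); when
#'   given, nodes carry a `tier` color attribute: `"yellow"` for core
#'   compounds, `"green"` for intermediate additions, `"blue"` for the rest.
#' @return an `igraph` object of class `gm_metabolic_graph` with vertex
#'   attributes `name` (compound local id), `label` (preferred name when
#'   available) and `tier`.
#' @export
build_metabolic_graph <- function(recon, tiers = NULL) {
  rx <- recon$reactions
  from <- character(); to <- character()
  for (i in seq_len(nrow(rx))) {
    s <- rx$substrates[[i]]$id
    p <- rx$products[[i]]$id
    pairs <- expand.grid(s = s, p = p, stringsAsFactors = FALSE)
    from <- c(from, pairs$s); to <- c(to, pairs$p)
  }
  # collapse duplicates as unordered pairs (self-loops kept, once each)
  if (length(from)) {
    key <- ifelse(from < to, paste(from, to, sep = "\r"),
                  paste(to, from, sep = "\r"))
    keep <- !duplicated(key)
    from <- from[keep]; to <- to[keep]
  }
  nodes <- sort(unique(c(from, to)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE)
  )
  cp <- recon$compounds
  lbl <- ifelse(is.na(cp$name_A), cp$name_B, cp$name_A)
  names(lbl) <- cp$local_id
  igraph::V(g)$label <- unname(lbl[igraph::V(g)$name])
  tier_col <- rep("blue", length(nodes))
  if (!is.null(tiers)) {
    tier_col[nodes %in% tiers$core$compounds$local_id] <- "yellow"
    tier_col[nodes %in% setdiff(tiers$intermediate$compounds$local_id,
                                tiers$core$compounds$local_id)] <- "green"
  } else if (recon$tier == "core") {
    tier_col <- rep("yellow", length(nodes))
  } else if (recon$tier == "intermediate") {
    tier_col <- rep("green", length(nodes))
  }
  igraph::V(g)$tier <- tier_col
  class(g) <- c("gm_metabolic_graph", class(g))
  g
}

.simple_graph <- function(g) {
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Betweenness centrality, normalized per connected component
#'
#' `C_b(n) = 2/((N-1)(N-2)) * sum over unordered pairs s != t (both != n) of
#' sigma_st(n)/sigma_st`, with `N` the node count of the component containing
#' `n`.  Nodes in components of one or two nodes get 0; self-loops are
#' ignored for path computations.  Values lie in `[0, 1]`.
#'
#' @param g a metabolic graph.
#' @return named numeric vector over nodes.
#' @export
graph_betweenness <- function(g) {
  gs <- .simple_graph(g)
  raw <- igraph::betweenness(gs, directed = FALSE, normalized = FALSE)
  comp <- igraph::components(gs)
  nsz <- comp$csize[comp$membership]
  denom <- (nsz - 1) * (nsz - 2) / 2
  out <- ifelse(denom > 0, raw / denom, 0)
  stats::setNames(as.numeric(out), igraph::V(gs)$name)
}

#' Closeness centrality, normalized per connected component
#'
#' `C_c(n) = (N-1) / sum over m != n in the same component of L(m, n)`, with
#' `L` the shortest-path length and `N` the component size.  Nodes in
#' singleton components get 0.
#'
#' @param g a metabolic graph.
#' @return named numeric vector over nodes.
#' @export
graph_closeness <- function(g) {
  gs <- .simple_graph(g)
  comp <- igraph::components(gs)
  out <- stats::setNames(numeric(igraph::vcount(gs)), igraph::V(gs)$name)
  for (ci in seq_len(comp$no)) {
    idx <- which(comp$membership == ci)
    if (length(idx) < 2) next
    d <- igraph::distances(gs, v = idx, to = idx)
    out[idx] <- (length(idx) - 1) / rowSums(d)
  }
  out
}

#' Local clustering coefficients
#'
#' Ratio of realized to possible edges among each node's neighbours
#' (self-loops excluded); nodes of degree below two are assigned 0.
#'
#' @param g a metabolic graph.
#' @return named numeric vector over nodes.
#' @export
graph_clustering <- function(g) {
  gs <- .simple_graph(g)
  cc <- igraph::transitivity(gs, type = "local", isolates = "zero")
  stats::setNames(ifelse(is.nan(cc), 0, cc), igraph::V(gs)$name)
}

#' Global topology report
#'
#' Computes the panel of global network properties: node count N, edge count
#' E (self-loops included), self-loop count L, density `2(E-L)/(N(N-1))`,
#' heterogeneity (coefficient of variation of the degree distribution),
#' mean clustering coefficient, connected components, diameter and average
#' path length over reachable pairs, centralisation
#' `N/(N-2) * (max_k/(N-1) - density)`, and average connectivity `2(E-L)/N`;
#' plus degree, shared-neighbour and shortest-path-length distributions.
#'
#' @param g a metabolic graph.
#' @return a list of class `gm_topology_report`.
#' @export
topology_report <- function(g) {
  gs <- .simple_graph(g)
  N <- igraph::vcount(g)
  E <- igraph::ecount(g)
  L <- sum(igraph::which_loop(g))
  k <- igraph::degree(gs)
  dens <- if (N > 1) 2 * (E - L) / (N * (N - 1)) else NA_real_
  het <- if (N > 0 && mean(k) > 0) {
    sqrt(mean((k - mean(k))^2)) / mean(k)
  } else {
    NA_real_
  }
  cc <- graph_clustering(g)
  comp <- igraph::components(gs)
  dia <- if (N > 0) igraph::diameter(gs, unconnected = TRUE) else NA_real_
  apl <- if (N > 1) igraph::mean_distance(gs, unconnected = TRUE) else NA_real_
  centr <- if (N >= 3) N / (N - 2) * (max(k) / (N - 1) - dens) else NA_real_
  # distributions
  deg_dist <- table(k)
  d <- igraph::distances(gs)
  finite_d <- d[upper.tri(d)]
  finite_d <- finite_d[is.finite(finite_d) & finite_d > 0]
  spl_dist <- table(finite_d)
  adj <- igraph::as_adjacency_matrix(gs, sparse = TRUE)
  shared <- as.matrix(adj %*% adj)
  diag(shared) <- 0
  sn <- shared[upper.tri(shared)]
  sn_dist <- table(sn[sn > 0])
  structure(list(
    n_nodes = N, n_edges = E, n_self_loops = L,
    density = dens, heterogeneity = het,
    clustering_coefficient = if (N > 0) mean(cc) else NA_real_,
    connected_components = comp$no,
    diameter = dia,
    centralisation = centr,
    average_path_length = apl,
    average_connectivity = if (N > 0) 2 * (E - L) / N else NA_real_,
    degree_distribution = deg_dist,
    shortest_path_distribution = spl_dist,
    shared_neighbour_distribution = sn_dist,
    notes = c(clustering = "degree<2 nodes contribute 0 to the mean",
              heterogeneity = "coefficient of variation, population variance",
              self_loops = "excluded from degree, density, connectivity")
  ), class = "gm_topology_report")
}

#' @export
print.gm_topology_report <- function(x, ...) {
  fmt <- function(v) ifelse(is.na(v), "NA", format(round(v, 3), nsmall = 0))
  rows <- c("Number of nodes" = x$n_nodes,
            "Number of edges" = x$n_edges,
            "Network density" = x$density,
            "Network heterogeneity" = x$heterogeneity,
            "Number of self-loops" = x$n_self_loops,
            "Clustering coefficient" = x$clustering_coefficient,
            "Connected components" = x$connected_components,
            "Network diameter" = x$diameter,
            "Network centralisation" = x$centralisation,
            "Average path length" = x$average_path_length,
            "Average connectivity" = x$average_connectivity)
  for (nm in names(rows)) cat(sprintf("%-24s %s\n", nm, fmt(rows[[nm]])))
  invisible(x)
}

#' Hub table: the most highly connected compounds
#'
#' @param g a metabolic graph.
#' @param top_k number of rows (>= 1).
#' @return data.frame with `node`, `label`, `degree`, sorted by degree
#'   descending with lexicographic id tie-break.
#' @export
hub_table <- function(g, top_k = 10) {
  stopifnot(top_k >= 1)
  gs <- .simple_graph(g)
  k <- igraph::degree(gs)
  nm <- igraph::V(gs)$name
  lb <- igraph::V(gs)$label %||% nm
  ord <- order(-k, nm)
  n <- min(top_k, length(k))
  data.frame(node = nm[ord][seq_len(n)],
             label = lb[ord][seq_len(n)],
             degree = as.integer(k[ord][seq_len(n)]),
             stringsAsFactors = FALSE)
}

#' Export a metabolic graph as GraphML or SIF
#'
#' GraphML preserves node attributes (tier color, labels) and self-loops and
#' round-trips through [read_graph_export()]; SIF is the minimal
#' Cytoscape-compatible edge list.
#'
#' @param g a metabolic graph.
#' @param path output file.
#' @param format `"graphml"` or `"sif"`.
#' @return `path`, invisibly.
#' @export
write_graph_export <- function(g, path, format = c("graphml", "sif")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(g)
    lines <- if (nrow(el)) paste(el[, 1], "rx", el[, 2]) else character()
    writeLines(lines, path)
  }
  invisible(path)
}

#' @rdname write_graph_export
#' @export
read_graph_export <- function(path, format = c("graphml", "sif")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::read_graph(path, format = "graphml")
  } else {
    lines <- readLines(path, warn = FALSE)
    if (!length(lines)) {
      return(igraph::make_empty_graph(0, directed = FALSE))
    }
    parts <- strsplit(lines, "[ \t]+")
    el <- do.call(rbind, lapply(parts, function(p) c(p[1], p[3])))
    igraph::graph_from_edgelist(el, directed = FALSE)
  }
}
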