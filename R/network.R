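# Co-occurrence network construction, statistics, and centrality.

#' Build a co-occurrence network from a correlation result
#'
#' One undirected edge per OTU pair with `rho > rho_min` AND `p < alpha`
#' (both strict). Only positive co-occurrence is kept by default; with
#' `signed = TRUE` pairs with `rho < -rho_min` are also connected
#' (mutual-exclusion edges). OTUs with no qualifying edge are excluded from
#' the node set. An empty network is a valid result.
#'
#' @param corr a [spearman_matrix()] result.
#' @param rho_min correlation threshold (default 0.75).
#' @param alpha significance threshold on the edge p-value (default 0.05).
#' @param signed also keep strong negative correlations.
#' @param p_adjust optional multiple-testing correction applied to the
#'   pairwise p-values before thresholding (a method name for
#'   [stats::p.adjust], e.g. `"BH"`); `"none"` (default) matches the
#'   uncorrected procedure.
#' @return an undirected \pkg{igraph} graph; edges carry `rho` and `p`,
#'   the graph carries `rho_min`, `alpha` and `n_samples` attributes.
#' @export
build_network <- function(corr, rho_min = 0.75, alpha = 0.05,
                          signed = FALSE, p_adjust = "none") {
  stopifnot(inherits(corr, "cooc_correlation"))
  rho <- corr$rho
  p <- corr$p
  ut <- upper.tri(rho)
  if (p_adjust != "none") {
    message("applying ", p_adjust, " correction to ", sum(ut), " edge p-values")
    p[ut] <- stats::p.adjust(p[ut], method = p_adjust)
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
  }
  keep <- ut & p < alpha &
    (rho > rho_min | (signed & rho < -rho_min))
  idx <- which(keep, arr.ind = TRUE)
  ids <- rownames(rho)
  if (nrow(idx) == 0L) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
  } else {
    edges <- data.frame(from = ids[idx[, 1L]], to = ids[idx[, 2L]],
                        rho = rho[idx], p = p[idx], stringsAsFactors = FALSE)
    nodes <- sort(unique(c(edges$from, edges$to)))
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = nodes)
  }
  g <- igraph::set_graph_attr(g, "rho_min", rho_min)
  g <- igraph::set_graph_attr(g, "alpha", alpha)
  igraph::set_graph_attr(g, "n_samples", corr$n_samples)
}

#' Connected components as cluster ids
#'
#' Cluster ids are assigned in decreasing component size; ties are broken by
#' the smallest member OTU id.
#'
#' @param net an undirected \pkg{igraph} graph.
#' @return named integer vector (cluster id per node); empty for an empty
#'   network.
#' @export
connected_clusters <- function(net) {
  if (igraph::vcount(net) == 0L) return(stats::setNames(integer(0), character(0)))
  comp <- igraph::components(net)
  names_ <- igraph::V(net)$name %||% as.character(seq_len(igraph::vcount(net)))
  mem <- comp$membership
  first <- vapply(seq_len(comp$no),
                  function(k) min(names_[mem == k]), character(1))
  ord <- order(-comp$csize, first)
  remap <- integer(comp$no)
  remap[ord] <- seq_len(comp$no)
  stats::setNames(remap[mem], names_)
}

#' Label network nodes by site type and maximum abundance
#'
#' Each node (OTU) is labeled with the flow status of the sample in which
#' its count is maximal, and carries that maximal count and its lineage
#' string. Ties are broken by earliest sample date, then by sample id, with
#' a warning.
#'
#' @param net co-occurrence network from [build_network()].
#' @param x the [otu_table] the network was built from (every node must be
#'   present).
#' @param meta sample metadata covering every sample of `x`.
#' @return `net` with vertex attributes `site_type_label`, `max_abundance`
#'   and `lineage`.
#' @export
label_nodes <- function(net, x, meta) {
  stopifnot(inherits(x, "otu_table"))
  meta <- validate_metadata(meta)
  meta <- match_metadata(x, meta)
  nodes <- igraph::V(net)$name
  missing <- setdiff(nodes, otu_ids(x))
  if (length(missing)) {
    stop("node(s) absent from the OTU table: ", paste(missing, collapse = ", "))
  }
  ord <- order(meta$date, meta$sample_id) # tie-break order
  tied <- character(0)
  lab <- character(length(nodes))
  mab <- integer(length(nodes))
  for (k in seq_along(nodes)) {
    v <- x$counts[nodes[k], ]
    best <- which(v == max(v))
    if (length(best) > 1L) {
      tied <- c(tied, nodes[k])
      best <- best[order(match(best, ord))][1L]
    }
    lab[k] <- meta$flow_status[best[1L]]
    mab[k] <- v[best[1L]]
  }
  if (length(tied)) {
    warning("max-abundance ties broken by earliest date then sample id for: ",
            paste(tied, collapse = ", "))
  }
  lin <- if (is.null(x$taxonomy)) rep(NA_character_, length(nodes)) else
    unname(x$taxonomy[nodes])
  net <- igraph::set_vertex_attr(net, "site_type_label", value = lab)
  net <- igraph::set_vertex_attr(net, "max_abundance", value = mab)
  igraph::set_vertex_attr(net, "lineage", value = lin)
}

#' Global graph statistics: clustering, path length, modularity
#'
#' `C` is the mean local clustering coefficient (nodes with degree < 2
#' contribute 0); `L` is the mean shortest-path length over reachable pairs
#' (disconnected pairs excluded; `NaN` with a warning for an edgeless
#' graph); `Q` is Newman modularity of the supplied partition, or of a
#' greedy agglomerative modularity-maximizing partition when none is given.
#'
#' @param net an undirected \pkg{igraph} graph with at least 1 node.
#' @param partition optional membership vector (named by node, or aligned
#'   with the vertex order).
#' @return object of class `graph_stats`: list with `clustering`,
#'   `path_length`, `modularity`, and the `partition` used.
#' @export
graph_statistics <- function(net, partition = NULL) {
  n <- igraph::vcount(net)
  if (n < 1L) stop("network has no nodes")
  m <- igraph::ecount(net)
  if (m == 0L) {
    warning("edgeless network: mean path length is undefined (NaN)")
    return(structure(list(clustering = 0, path_length = NaN,
                          modularity = NA_real_, partition = NULL),
                     class = "graph_stats"))
  }
  cc <- mean(igraph::transitivity(net, type = "localundirected",
                                  isolates = "zero"))
  pl <- igraph::mean_distance(net, directed = FALSE, unconnected = TRUE)
  if (is.null(partition)) {
    comm <- igraph::cluster_fast_greedy(net)
    membership <- igraph::membership(comm)
    q <- igraph::modularity(net, membership)
  } else {
    if (!is.null(names(partition)) && !is.null(igraph::V(net)$name)) {
      partition <- partition[igraph::V(net)$name]
    }
    membership <- as.integer(as.factor(partition))
    q <- igraph::modularity(net, membership)
  }
  structure(list(clustering = cc, path_length = pl, modularity = q,
                 partition = membership),
            class = "graph_stats")
}

#' @export
print.graph_stats <- function(x, ...) {
  cat(sprintf("graph statistics: C = %.4f, L = %.4f, Q = %.4f\n",
              x$clustering, x$path_length, x$modularity))
  invisible(x)
}

#' Node centrality table
#'
#' Degree is the incident edge count. Betweenness credits each node with the
#' fraction of shortest paths (geodesics) between unordered node pairs that
#' pass through it, endpoints excluded, with fractional credit across
#' multiple geodesics. Closeness is the inverse of the mean geodesic
#' distance from a node to the nodes reachable from it (note: mean, not sum);
#' nodes in singleton components get closeness 0.
#'
#' @param net an undirected \pkg{igraph} graph with >= 2 nodes.
#' @return data.frame with `otu_id`, `degree`, `betweenness`, `closeness`
#'   and, when present on the graph, `site_type_label` and `lineage`.
#' @export
centrality <- function(net) {
  n <- igraph::vcount(net)
  if (n < 2L) stop("need at least 2 nodes")
  ids <- igraph::V(net)$name %||% as.character(seq_len(n))
  deg <- igraph::degree(net)
  btw <- igraph::betweenness(net, directed = FALSE, weights = NA)
  dm <- igraph::distances(net, weights = NA)
  clo <- apply(dm, 1L, function(dv) {
    dv <- dv[is.finite(dv) & dv > 0]
    if (length(dv) == 0L) 0 else 1 / mean(dv)
  })
  out <- data.frame(otu_id = ids, degree = as.integer(deg),
                    betweenness = as.numeric(btw),
                    closeness = as.numeric(clo),
                    stringsAsFactors = FALSE, row.names = NULL)
  for (attr_ in c("site_type_label", "lineage")) {
    if (attr_ %in% igraph::vertex_attr_names(net)) {
      out[[attr_]] <- igraph::vertex_attr(net, attr_)
    }
  }
  out
}

#' Keystone candidates: top-ranked nodes per cluster
#'
#' Within each cluster, nodes are ranked by closeness (ties broken by higher
#' degree, then OTU id) and the top `top_k` reported with all three
#' centrality metrics.
#'
#' @param ct centrality table from [centrality()].
#' @param clusters cluster map from [connected_clusters()] over the same
#'   node set.
#' @param top_k how many nodes to report per cluster (>= 1).
#' @return data.frame sorted by cluster then rank.
#' @export
keystone_report <- function(ct, clusters, top_k = 10L) {
  if (top_k < 1L) stop("`top_k` must be >= 1")
  if (!setequal(ct$otu_id, names(clusters))) {
    stop("centrality table and cluster map cover different node sets")
  }
  ct$cluster <- unname(clusters[ct$otu_id])
  out <- lapply(sort(unique(ct$cluster)), function(cl) {
    sub <- ct[ct$cluster == cl, , drop = FALSE]
    sub <- sub[order(-sub$closeness, -sub$degree, sub$otu_id), , drop = FALSE]
    sub <- utils::head(sub, top_k)
    sub$rank <- seq_len(nrow(sub))
    sub
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Export a network as edge-list TSV or GraphML
#'
#' @param net co-occurrence network.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  el <- igraph::as_data_frame(net, what = "edges")
  colnames(el)[1:2] <- c("otu_a", "otu_b")
  write_tsv_file(el, path)
}

#' @rdname write_edge_list
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}
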