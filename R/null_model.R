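# Erdos-Renyi G(n, m) null-model validation of an observed network.

#' Erdos-Renyi null-model test of network structure
#'
#' Draws `n_random` G(n, m) graphs (uniform over simple graphs with the
#' observed node count n and edge count m; no self-loops or multi-edges),
#' computes the requested statistics for each (modularity via the same
#' greedy partitioner as [graph_statistics()]), and reports, per statistic,
#' the empirical p-value: the proportion of null values strictly greater
#' than the observed value (ties count as not greater; one-sided by
#' construction).
#'
#' @param net an undirected \pkg{igraph} graph with >= 2 nodes and >= 1 edge.
#' @param n_random number of null networks (default 1000).
#' @param seed integer seed; the draw is deterministic given it.
#' @param stats which statistics to compute (subset of `clustering`,
#'   `path_length`, `modularity`).
#' @return object of class `er_null_result`: list with `observed`
#'   ([graph_statistics()] of `net`), `null` (data.frame of null draws),
#'   `p` (named per-statistic), `n_random` and `seed`.
#' @export
er_null_test <- function(net, n_random = 1000L, seed = 1L,
                         stats = c("clustering", "path_length", "modularity")) {
  stats <- match.arg(stats, several.ok = TRUE)
  n <- igraph::vcount(net)
  m <- igraph::ecount(net)
  if (n < 2L || m < 1L) stop("need >= 2 nodes and >= 1 edge")
  observed <- graph_statistics(net)
  null <- with_seed(substream_seed(seed, "er_null"), {
    draws <- matrix(NA_real_, n_random, length(stats),
                    dimnames = list(NULL, stats))
    for (i in seq_len(n_random)) {
      g <- igraph::sample_gnm(n, m)
      if ("clustering" %in% stats) {
        draws[i, "clustering"] <-
          mean(igraph::transitivity(g, type = "localundirected",
                                    isolates = "zero"))
      }
      if ("path_length" %in% stats) {
        draws[i, "path_length"] <-
          igraph::mean_distance(g, directed = FALSE, unconnected = TRUE)
      }
      if ("modularity" %in% stats) {
        draws[i, "modularity"] <-
          igraph::modularity(g, igraph::membership(igraph::cluster_fast_greedy(g)))
      }
    }
    as.data.frame(draws)
  })
  obs_vec <- c(clustering = observed$clustering,
               path_length = observed$path_length,
               modularity = observed$modularity)[stats]
  p <- vapply(stats, function(s) mean(null[[s]] > obs_vec[[s]]), numeric(1))
  structure(list(observed = observed, null = null,
                 p = stats::setNames(p, stats),
                 n_random = n_random, seed = seed),
            class = "er_null_result")
}

#' @export
print.er_null_result <- function(x, ...) {
  cat(sprintf("Erdos-Renyi G(n, m) null model (%d draws)\n", x$n_random))
  for (s in names(x$p)) {
    obs <- switch(s, clustering = x$observed$clustering,
                  path_length = x$observed$path_length,
                  modularity = x$observed$modularity)
    cat(sprintf("  %-12s observed %.4f, null mean %.4f, p = %s\n",
                s, obs, mean(x$null[[s]]),
                format(x$p[[s]])))
  }
  invisible(x)
}

#' Serialize a null-model result to JSON
#'
#' Writes the observed statistics, empirical p-values, and a five-number
#' summary of each null distribution.
#'
#' @param x an `er_null_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_null_model <- function(x, path) {
  payload <- list(
    n_random = x$n_random,
    seed = x$seed,
    observed = list(clustering = x$observed$clustering,
                    path_length = x$observed$path_length,
                    modularity = x$observed$modularity),
    p = as.list(x$p),
    null_summary = lapply(x$null, function(v) {
      q <- stats::quantile(v, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
      list(min = q[1], q25 = q[2], median = q[3], q75 = q[4], max = q[5],
           mean = mean(v))
    })
  )
  write_json_file(payload, path)
}
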