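# Fixtures built in code and independent brute-force oracles.

# Small OTU table from a counts matrix.
tiny_table <- function(counts, taxonomy = NULL) {
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("OTU%02d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("S%02d", seq_len(ncol(counts)))
  }
  otu_table(counts, taxonomy = taxonomy)
}

random_table <- function(n_otus, n_samples, seed, lambda = 20) {
  set.seed(seed)
  m <- matrix(rpois(n_otus * n_samples, lambda), n_otus, n_samples)
  tiny_table(m)
}

metadata_for <- function(tab, flow_status = NULL, date = "2012-08-01",
                         site = "P1", habitat = "sediment") {
  n <- length(sample_ids(tab))
  data.frame(
    sample_id = sample_ids(tab),
    site = rep_len(site, n),
    habitat = rep_len(habitat, n),
    flow_status = if (is.null(flow_status)) rep("permanent", n) else
      rep_len(flow_status, n),
    date = rep_len(date, n),
    stringsAsFactors = FALSE
  )
}

# Bray-Curtis by direct elementwise evaluation of the formula.
bray_curtis_oracle <- function(counts) {
  n <- ncol(counts)
  d <- matrix(0, n, n, dimnames = list(colnames(counts), colnames(counts)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d[i, j] <- sum(abs(counts[, i] - counts[, j])) /
        sum(counts[, i] + counts[, j])
    }
  }
  d
}

# Spearman rho/p for one pair via explicit midrank Pearson arithmetic.
spearman_pair_oracle <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  rho <- if (den == 0) NA_real_ else num / den
  n <- length(x)
  p <- if (is.na(rho)) {
    NA_real_
  } else if (abs(rho) >= 1 - 1e-12) {
    0
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(abs(tt), df = n - 2, lower.tail = FALSE)
  }
  list(rho = rho, p = p)
}

# Edge set by a double loop applying the strict thresholds.
edge_set_oracle <- function(counts, rho_min = 0.75, alpha = 0.05) {
  ids <- rownames(counts)
  edges <- character(0)
  for (i in seq_len(nrow(counts) - 1L)) {
    for (j in (i + 1L):nrow(counts)) {
      o <- spearman_pair_oracle(counts[i, ], counts[j, ])
      if (!is.na(o$rho) && o$rho > rho_min && o$p < alpha) {
        edges <- c(edges, paste(sort(c(ids[i], ids[j])), collapse = "|"))
      }
    }
  }
  sort(edges)
}

edge_set_of <- function(net) {
  if (igraph::ecount(net) == 0L) return(character(0))
  el <- igraph::as_edgelist(net)
  sort(apply(el, 1L, function(e) paste(sort(e), collapse = "|")))
}

# Betweenness by exhaustive geodesic enumeration (small graphs only):
# for every unordered pair, enumerate all shortest paths and split credit.
betweenness_oracle <- function(net) {
  n <- igraph::vcount(net)
  ids <- igraph::V(net)$name
  btw <- setNames(numeric(n), ids)
  for (s in seq_len(n - 1L)) {
    for (t in (s + 1L):n) {
      paths <- suppressWarnings(
        igraph::all_shortest_paths(net, from = s, to = t)$vpaths
      )
      if (length(paths) == 0L) next
      for (p in paths) {
        inner <- setdiff(as.integer(p), c(s, t))
        if (length(inner)) {
          btw[inner] <- btw[inner] + 1 / length(paths)
        }
      }
    }
  }
  btw
}

# Venn partition by brute-force set algebra over presence sets.
venn_oracle <- function(counts, grouping) {
  groups <- sort(unique(grouping))
  present <- lapply(groups, function(g) {
    rownames(counts)[rowSums(counts[, grouping == g, drop = FALSE]) > 0]
  })
  names(present) <- groups
  out <- integer(0)
  for (k in seq_along(groups)) {
    for (combo in asplit(combn(groups, k), 2L)) {
      inside <- Reduce(intersect, present[combo])
      outside <- unique(unlist(present[setdiff(groups, combo)]))
      out[paste(combo, collapse = "&")] <- length(setdiff(inside, outside))
    }
  }
  out
}

# ANOSIM R by direct computation from the definition.
anosim_r_oracle <- function(d, labels) {
  n <- nrow(d)
  ranks <- rank(d[lower.tri(d)])
  idx <- which(lower.tri(d), arr.ind = TRUE)
  within <- labels[idx[, 1L]] == labels[idx[, 2L]]
  (mean(ranks[!within]) - mean(ranks[within])) / (n * (n - 1) / 4)
}
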