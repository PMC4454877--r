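graph_from_edges <- function(...) {
  igraph::make_graph(c(...), directed = FALSE)
}

test_that("Spearman matrix reproduces hand midrank computations", {
  counts <- rbind(
    mono_x = c(1, 2, 2, 4),
    mono_y = c(1, 3, 2, 4)
  )
  colnames(counts) <- paste0("s", 1:4)
  corr <- spearman_matrix(tiny_table(counts))
  # midranks x = (1, 2.5, 2.5, 4), y = (1, 3, 2, 4): rho = 4.5/sqrt(22.5)
  expect_equal(corr$rho["mono_x", "mono_y"], 4.5 / sqrt(22.5),
               tolerance = 1e-12)

  co <- rbind(a = c(1, 5, 20, 300), b = c(2, 8, 21, 1000))
  colnames(co) <- paste0("s", 1:4)
  cc <- spearman_matrix(tiny_table(co))
  expect_equal(cc$rho["a", "b"], 1)
  expect_equal(cc$p["a", "b"], 0)
})

test_that("Spearman matrix equals the per-pair brute-force oracle and cor.test", {
  for (s in 1:4) {
    tab <- random_table(8, 12, seed = 40 + s, lambda = 6)
    corr <- suppressWarnings(spearman_matrix(tab))
    counts <- otu_counts(tab)
    for (i in 1:7) {
      for (j in (i + 1):8) {
        o <- spearman_pair_oracle(counts[i, ], counts[j, ])
        if (is.na(o$rho)) o <- list(rho = 0, p = 1)
        expect_equal(corr$rho[i, j], o$rho, tolerance = 1e-12)
        expect_equal(corr$p[i, j], o$p, tolerance = 1e-12)
      }
    }
    # independent route: stats::cor.test's asymptotic Spearman p
    ct <- suppressWarnings(cor.test(counts[1, ], counts[2, ],
                                    method = "spearman", exact = FALSE))
    expect_equal(corr$rho[1, 2], unname(ct$estimate), tolerance = 1e-12)
    expect_equal(corr$p[1, 2], ct$p.value, tolerance = 1e-10)
  }
})

test_that("constant OTUs are recorded as rho 0, p 1 with a warning", {
  counts <- rbind(flat = rep(3, 5), vary = c(1, 4, 2, 8, 5),
                  vary2 = c(2, 1, 7, 3, 9))
  colnames(counts) <- paste0("s", 1:5)
  expect_warning(corr <- spearman_matrix(tiny_table(counts)), "flat")
  expect_equal(corr$rho["flat", "vary"], 0)
  expect_equal(corr$p["flat", "vary"], 1)
  expect_error(spearman_matrix(tiny_table(counts[1, , drop = FALSE])),
               "2 OTUs")
  expect_error(spearman_matrix(tiny_table(counts[, 1:3])), "4 samples")
})

test_that("network construction applies both strict thresholds", {
  counts <- rbind(
    OTU1 = c(1, 2, 3, 4, 5),
    OTU2 = c(2, 4, 6, 8, 10),
    OTU3 = c(5, 4, 3, 2, 1),
    OTU4 = c(3, 1, 4, 1, 5)
  )
  colnames(counts) <- paste0("s", 1:5)
  corr <- spearman_matrix(tiny_table(counts))
  net <- build_network(corr)
  expect_equal(igraph::vcount(net), 2L)
  expect_equal(edge_set_of(net), "OTU1|OTU2")
  # OTU3 is perfectly anti-correlated with OTU1: excluded by rho > 0.75,
  # but admitted in signed mode
  signed <- build_network(corr, signed = TRUE)
  expect_true("OTU1|OTU3" %in% edge_set_of(signed))

  # rho_min = 1 leaves nothing (strict inequality)
  empty <- build_network(corr, rho_min = 1)
  expect_equal(igraph::ecount(empty), 0L)
})

test_that("network edge sets match the brute-force double loop on random tables", {
  for (s in 1:6) {
    tab <- random_table(10, 8, seed = 70 + s, lambda = 4)
    corr <- suppressWarnings(spearman_matrix(tab))
    net <- build_network(corr, rho_min = 0.6, alpha = 0.05)
    expect_identical(edge_set_of(net),
                     edge_set_oracle(otu_counts(tab), 0.6, 0.05))
  }
})

test_that("connected clusters are numbered by size with id tie-breaks", {
  g <- graph_from_edges("a","b", "b","c", "x","y", "p","q", "q","r", "r","p", "p","s")
  cl <- connected_clusters(g)
  expect_equal(unname(cl[c("p", "q", "r", "s")]), rep(1L, 4)) # largest
  expect_equal(unname(cl[c("a", "b", "c")]), rep(2L, 3))      # tie: a < x? size 3 > 2
  expect_equal(unname(cl[c("x", "y")]), rep(3L, 3)[1:2])
  expect_length(connected_clusters(igraph::make_empty_graph(0, directed = FALSE)), 0L)

  # equal sizes: smaller member id first
  g2 <- graph_from_edges("m","n", "a","z")
  cl2 <- connected_clusters(g2)
  expect_equal(unname(cl2[c("a", "z")]), c(1L, 1L))
  expect_equal(unname(cl2[c("m", "n")]), c(2L, 2L))
})

test_that("node labeling picks the max-abundance sample's flow status", {
  counts <- rbind(OTU1 = c(10L, 3L, 0L, 2L), OTU2 = c(1L, 6L, 2L, 3L),
                  OTU3 = c(4L, 4L, 4L, 4L))
  colnames(counts) <- paste0("s", 1:4)
  tab <- tiny_table(counts)
  meta <- metadata_for(tab,
                       flow_status = c("permanent", "temporary_flowing",
                                       "temporary_dry", "temporary_dry"),
                       date = c("2012-08-01", "2012-04-01", "2012-11-01",
                                "2012-04-01"))
  g <- graph_from_edges("OTU1","OTU2", "OTU2","OTU3")
  expect_warning(lab <- label_nodes(g, tab, meta), "OTU3")
  v <- igraph::vertex_attr(lab)
  expect_equal(v$site_type_label[v$name == "OTU1"], "permanent")
  expect_equal(v$max_abundance[v$name == "OTU1"], 10L)
  expect_equal(v$site_type_label[v$name == "OTU2"], "temporary_flowing")
  # OTU3 ties everywhere: earliest date 2012-04-01, then sample id s2
  expect_equal(v$site_type_label[v$name == "OTU3"], "temporary_flowing")

  g2 <- graph_from_edges("OTU1","MISSING")
  expect_error(label_nodes(g2, tab, meta), "MISSING")
})

test_that("graph statistics match closed-form values on canonical graphs", {
  tri <- graph_from_edges("a","b", "b","c", "c","a")
  gs <- graph_statistics(tri, partition = c(a = 1, b = 1, c = 1))
  expect_equal(gs$clustering, 1)
  expect_equal(gs$path_length, 1)
  expect_equal(gs$modularity, 0)

  path <- graph_from_edges("a","b", "b","c")
  gp <- graph_statistics(path)
  expect_equal(gp$clustering, 0)
  expect_equal(gp$path_length, 4 / 3)

  twotri <- graph_from_edges("a","b", "b","c", "c","a", "x","y", "y","z", "z","x")
  part <- c(a = 1, b = 1, c = 1, x = 2, y = 2, z = 2)
  expect_equal(graph_statistics(twotri, partition = part)$modularity, 0.5)
  # the greedy partitioner finds the same communities here
  expect_equal(graph_statistics(twotri)$modularity, 0.5)

  edgeless <- igraph::make_empty_graph(3, directed = FALSE)
  expect_warning(ge <- graph_statistics(edgeless), "NaN")
  expect_equal(ge$clustering, 0)
  expect_true(is.nan(ge$path_length))
})

test_that("centrality reproduces hand geodesic enumeration", {
  star <- graph_from_edges("c","l1", "c","l2", "c","l3", "c","l4")
  ct <- centrality(star)
  cen <- ct[ct$otu_id == "c", ]
  expect_equal(cen$degree, 4L)
  expect_equal(cen$betweenness, 6)        # C(4,2) leaf pairs
  expect_equal(cen$closeness, 1)
  leaf <- ct[ct$otu_id == "l1", ]
  expect_equal(leaf$degree, 1L)
  expect_equal(leaf$betweenness, 0)
  expect_equal(leaf$closeness, 4 / 7)     # 1 / mean(1,2,2,2)

  path <- graph_from_edges("a","b", "b","c")
  pc <- centrality(path)
  expect_equal(pc$betweenness[pc$otu_id == "b"], 1)
  expect_equal(pc$closeness[pc$otu_id == "b"], 1)
  expect_equal(pc$closeness[pc$otu_id == "a"], 2 / 3)

  ring <- graph_from_edges("a","b", "b","c", "c","d", "d","a")
  rc <- centrality(ring)
  expect_equal(rc$betweenness, rep(0.5, 4)) # two geodesics, half credit

  # isolated node in a 2-component graph: closeness 0
  g <- igraph::add_vertices(path, 1, name = "iso")
  expect_equal(centrality(g)$closeness[4], 0)
})

test_that("betweenness matches exhaustive path enumeration on random graphs", {
  for (s in 1:5) {
    set.seed(s)
    g <- igraph::sample_gnm(10, 14)
    igraph::V(g)$name <- paste0("n", 1:10)
    got <- centrality(g)
    oracle <- betweenness_oracle(g)
    expect_equal(setNames(got$betweenness, got$otu_id), oracle,
                 tolerance = 1e-10)
  }
  # tree identity: total betweenness equals sum over pairs of (path length - 1)
  for (s in 1:5) {
    set.seed(100 + s)
    tree <- igraph::sample_tree(12)
    igraph::V(tree)$name <- paste0("t", 1:12)
    ct <- centrality(tree)
    dm <- igraph::distances(tree)
    expect_equal(sum(ct$betweenness),
                 sum(dm[upper.tri(dm)] - 1), tolerance = 1e-10)
  }
})

test_that("keystone report ranks by closeness with degree tie-breaks per cluster", {
  star <- graph_from_edges("c","l1", "c","l2", "c","l3", "c","l4")
  ct <- centrality(star)
  rep1 <- keystone_report(ct, connected_clusters(star), top_k = 1)
  expect_equal(rep1$otu_id, "c")

  two <- graph_from_edges("a","b", "b","c", "x","y", "y","z")
  ct2 <- centrality(two)
  rep2 <- keystone_report(ct2, connected_clusters(two), top_k = 2)
  expect_equal(nrow(rep2), 4L)
  expect_true(all(table(rep2$cluster) <= 2))
  expect_equal(rep2$otu_id[rep2$cluster == 1][1], "b")
  expect_error(keystone_report(ct2, connected_clusters(two), top_k = 0),
               "top_k")
})

test_that("a planted hub ranks first in its cluster", {
  edges <- c(rbind("hub", paste0("m", 1:6)))
  g <- igraph::make_graph(edges, directed = FALSE)
  g <- igraph::add_edges(g, c("m1", "m2", "m3", "m4"))
  ct <- centrality(g)
  rep_ <- keystone_report(ct, connected_clusters(g), top_k = 3)
  expect_equal(rep_$otu_id[1], "hub")
})

test_that("heatmap matrix applies transforms and guards degenerate rows", {
  counts <- rbind(o1 = c(0L, 9L, 99L), o2 = c(4L, 4L, 4L), o3 = c(1L, 2L, 3L))
  colnames(counts) <- paste0("s", 1:3)
  tab <- tiny_table(counts)
  raw <- heatmap_matrix(tab, otus = c("o3", "o1"), transform = "raw")
  expect_equal(unname(raw), unname(counts[c("o3", "o1"), ] + 0))
  lg <- heatmap_matrix(tab, otus = "o1", transform = "log10")
  expect_equal(unname(lg[1, ]), c(0, 1, 2))
  expect_warning(z <- heatmap_matrix(tab, otus = c("o1", "o2"),
                                     transform = "row_z"), "constant")
  expect_equal(unname(z["o2", ]), c(0, 0, 0))
  expect_error(heatmap_matrix(tab, otus = "nope"), "nope")

  meta <- metadata_for(tab, flow_status = c("permanent", "temporary_dry",
                                            "temporary_dry"))
  m <- heatmap_matrix(tab, otus = c("o1", "o3"), transform = "log10",
                      meta = meta)
  expect_equal(unname(attr(m, "sample_site_type")),
               c("permanent", "temporary_dry", "temporary_dry"))
  expect_equal(unname(attr(m, "otu_site_type")[["o1"]]), "temporary_dry")
})

test_that("network exports are readable text", {
  counts <- rbind(OTU1 = c(1, 2, 3, 4, 5), OTU2 = c(2, 4, 6, 8, 10),
                  OTU3 = c(1, 3, 2, 5, 4))
  colnames(counts) <- paste0("s", 1:5)
  net <- build_network(spearman_matrix(tiny_table(counts)))
  ep <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(net, ep)
  el <- read.delim(ep)
  expect_true(all(c("otu_a", "otu_b", "rho", "p") %in% colnames(el)))
  gp <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, gp)
  back <- igraph::read_graph(gp, format = "graphml")
  expect_equal(igraph::ecount(back), igraph::ecount(net))
})
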