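# Pipeline orchestration: preprocessing -> diversity -> network -> null
# model -> reports, with a manifest for reproducibility.

#' Pipeline configuration
#'
#' Defaults follow the source workflow: rarefaction depth 8960, 0.1%
#' low-abundance filter, edge threshold rho > 0.75 and p < 0.05, 1000
#' Erdos-Renyi null networks, 999 ANOSIM permutations.
#'
#' @param table path to the OTU table (classic TSV); `NULL` when `synthetic`
#'   is supplied.
#' @param metadata path to the sample metadata TSV; `NULL` with `synthetic`.
#' @param synthetic optional list describing a synthetic input: arguments
#'   for [synthetic_config()] plus optional `dates` and `dry_dates` (routed
#'   to [temporal_series()]).
#' @param out_dir output directory (created if needed).
#' @param depth rarefaction depth.
#' @param min_fraction low-abundance filter fraction.
#' @param rho_min,alpha network edge thresholds.
#' @param n_random Erdos-Renyi null draws.
#' @param n_perm ANOSIM permutations.
#' @param seed master seed; every stage derives a named substream from it.
#' @param order preprocessing order: `c("rarefy", "filter")` (default) or
#'   `c("filter", "rarefy")`.
#' @param anosim_by metadata columns defining ANOSIM groups; the derived
#'   column `flow_class` (permanent vs temporary) is available.
#' @param venn_by metadata column defining the shared-OTU groups.
#' @param top_k keystone candidates reported per cluster.
#' @return a validated `pipeline_config`.
#' @export
pipeline_config <- function(table = NULL, metadata = NULL, synthetic = NULL,
                            out_dir = "streamnet_out",
                            depth = 8960L, min_fraction = 0.001,
                            rho_min = 0.75, alpha = 0.05,
                            n_random = 1000L, n_perm = 999L, seed = 1L,
                            order = c("rarefy", "filter"),
                            anosim_by = c("flow_class", "habitat"),
                            venn_by = "site", top_k = 10L) {
  if (is.null(synthetic) && (is.null(table) || is.null(metadata))) {
    stop("supply `table` and `metadata` paths, or a `synthetic` description")
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1) {
    stop("`alpha` must be in (0, 1]")
  }
  if (!is.numeric(rho_min) || rho_min < -1 || rho_min > 1) {
    stop("`rho_min` must be in [-1, 1]")
  }
  if (min_fraction < 0 || min_fraction >= 1) stop("`min_fraction` must be in [0, 1)")
  if (depth < 1) stop("`depth` must be >= 1")
  if (n_random < 1 || n_perm < 1) stop("`n_random` and `n_perm` must be >= 1")
  if (!identical(sort(order), c("filter", "rarefy"))) {
    stop('`order` must be a permutation of c("rarefy", "filter")')
  }
  structure(list(table = table, metadata = metadata, synthetic = synthetic,
                 out_dir = out_dir, depth = as.integer(depth),
                 min_fraction = min_fraction, rho_min = rho_min,
                 alpha = alpha, n_random = as.integer(n_random),
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 order = order, anosim_by = anosim_by, venn_by = venn_by,
                 top_k = as.integer(top_k)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys are [pipeline_config()] arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$order)) raw$order <- as.character(raw$order)
  if (!is.null(raw$anosim_by)) raw$anosim_by <- as.character(raw$anosim_by)
  do.call(pipeline_config, raw)
}

#' Write a pipeline configuration to YAML
#' @param config a `pipeline_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

derive_flow_class <- function(meta) {
  meta$flow_class <- ifelse(meta$flow_status == "permanent",
                            "permanent", "temporary")
  meta
}

#' Run the full analysis pipeline
#'
#' Stages: load (or synthesize) inputs, preprocess (rarefy/filter in the
#' configured order), Bray-Curtis distances, PCoA, ANOSIM (global over the
#' configured grouping plus pairwise per factor), shared-OTU partition,
#' Chao1 richness, co-occurrence network with node labeling, Erdos-Renyi
#' null model, keystone report, heatmap matrix. Every output lands under
#' `config$out_dir` together with a run manifest; each stage draws its
#' randomness from a named substream of the master seed, so a rerun with
#' the same configuration reproduces every table and JSON byte for byte.
#'
#' Chao1 and the shared-OTU partition are computed on the rarefied
#' (unfiltered) table; the network on the fully preprocessed one.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with all stage results and output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package = "streamnet",
    version = as.character(utils::packageVersion("streamnet")),
    r_version = R.version.string,
    seed = config$seed,
    stages = character(0),
    parameters = unclass(config),
    timings = list()
  )
  results <- list()
  paths <- list()
  stage <- function(name, code) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(code, error = function(e) {
      manifest$stages <<- c(manifest$stages, paste0(name, ":failed"))
      write_json_file(manifest, file.path(config$out_dir, "manifest.json"))
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    manifest$stages <<- c(manifest$stages, name)
    manifest$timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  inputs <- stage("load", {
    if (!is.null(config$synthetic)) {
      syn <- config$synthetic
      dates <- syn$dates
      dry_dates <- syn$dry_dates
      syn$dates <- NULL
      syn$dry_dates <- NULL
      if (!is.null(syn$blocks)) {
        syn$blocks <- lapply(syn$blocks, as.list)
      }
      sc <- do.call(synthetic_config, syn)
      if (!is.null(dates)) temporal_series(sc, dates, dry_dates)
      else generate_community(sc)
    } else {
      list(table = read_otu_table(config$table),
           metadata = read_sample_metadata(config$metadata))
    }
  })
  tab <- inputs$table
  meta <- validate_metadata(inputs$metadata)

  pre <- tab
  for (step in config$order) {
    pre <- stage(step, {
      if (step == "rarefy") {
        rarefy(pre, config$depth,
               seed = substream_seed(config$seed, "rarefy"))
      } else {
        filter_low_abundance(pre, config$min_fraction)
      }
    })
    if (step == "rarefy") rarefied <- pre
  }
  if (!"rarefy" %in% config$order) rarefied <- tab
  meta <- meta[meta$sample_id %in% sample_ids(pre), , drop = FALSE]
  meta <- derive_flow_class(meta)
  paths$table <- file.path(config$out_dir, "preprocessed_table.tsv")
  write_otu_table(pre, paths$table)

  dm <- stage("bray_curtis", bray_curtis(pre))
  paths$distance <- file.path(config$out_dir, "distance_matrix.tsv")
  write_distance_matrix(dm, paths$distance)

  ord <- stage("pcoa", pcoa_ordination(dm, n_axes = 2L))
  paths$ordination <- file.path(config$out_dir, "ordination.tsv")
  write_tsv_file(data.frame(sample_id = rownames(ord$coordinates),
                            ord$coordinates, check.names = FALSE),
                 paths$ordination)

  anosim_res <- stage("anosim", {
    meta_m <- meta[match(rownames(dm), meta$sample_id), , drop = FALSE]
    global_labels <- do.call(paste, c(meta_m[config$anosim_by], sep = ":"))
    global <- anosim_test(dm, global_labels, n_perm = config$n_perm,
                          seed = substream_seed(config$seed, "anosim:global"))
    per_factor <- lapply(stats::setNames(config$anosim_by, config$anosim_by),
                         function(f) {
      if (length(unique(meta_m[[f]])) < 2L) return(NULL)
      a <- anosim_test(dm, meta_m[[f]], n_perm = config$n_perm,
                       seed = substream_seed(config$seed, paste0("anosim:", f)))
      list(R = a$R, p = a$p)
    })
    list(global = list(R = global$R, p = global$p,
                       n_perm = global$n_perm,
                       grouping = paste(config$anosim_by, collapse = ":")),
         per_factor = Filter(Negate(is.null), per_factor))
  })
  paths$anosim <- file.path(config$out_dir, "anosim.json")
  write_json_file(anosim_res, paths$anosim)

  venn <- stage("venn", {
    meta_r <- meta[match(sample_ids(rarefied), meta$sample_id), , drop = FALSE]
    meta_r <- derive_flow_class(meta_r)
    shared_otu_partition(rarefied,
                         stats::setNames(meta_r[[config$venn_by]],
                                         meta_r$sample_id))
  })
  paths$venn <- file.path(config$out_dir, "venn.json")
  write_json_file(as.list(stats::setNames(as.integer(venn), names(venn))),
                  paths$venn)

  chao <- stage("chao1", chao1_table(rarefied))
  paths$chao1 <- file.path(config$out_dir, "chao1.tsv")
  write_tsv_file(chao, paths$chao1)

  net <- stage("network", {
    corr <- spearman_matrix(pre)
    g <- build_network(corr, rho_min = config$rho_min, alpha = config$alpha)
    if (igraph::vcount(g) > 0L) g <- label_nodes(g, pre, meta) else g
  })
  paths$edges <- file.path(config$out_dir, "network_edges.tsv")
  write_edge_list(net, paths$edges)
  paths$graphml <- file.path(config$out_dir, "network.graphml")
  write_graphml(net, paths$graphml)

  if (igraph::vcount(net) >= 2L && igraph::ecount(net) >= 1L) {
    null_res <- stage("null_model",
                      er_null_test(net, n_random = config$n_random,
                                   seed = substream_seed(config$seed, "null")))
    paths$null_model <- file.path(config$out_dir, "null_model.json")
    write_null_model(null_res, paths$null_model)

    keystone <- stage("keystone", {
      ct <- centrality(net)
      keystone_report(ct, connected_clusters(net), top_k = config$top_k)
    })
    paths$keystone <- file.path(config$out_dir, "keystone.tsv")
    write_tsv_file(keystone, paths$keystone)

    hm <- stage("heatmap", {
      heatmap_matrix(pre, otus = unique(keystone$otu_id),
                     transform = "log10", meta = meta)
    })
    paths$heatmap <- file.path(config$out_dir, "heatmap.tsv")
    write_heatmap_tsv(hm, paths$heatmap)
    results$null_model <- null_res
    results$keystone <- keystone
    results$heatmap <- hm
  } else {
    warning("network too small for null model / keystone stages; skipped")
    null_res <- NULL
  }

  manifest$outputs <- lapply(paths, basename)
  manifest$completed <- TRUE
  write_json_file(manifest, file.path(config$out_dir, "manifest.json"))

  results <- c(list(table = pre, rarefied = rarefied, metadata = meta,
                    distance = dm, ordination = ord, anosim = anosim_res,
                    venn = venn, chao1 = chao, network = net,
                    manifest = manifest, paths = paths),
               results)
  invisible(results)
}

#' Write a ready-to-run synthetic demo dataset and configuration
#'
#' Emulates a three-site, three-date temporary-stream design: two permanent
#' sites and one temporary site sampled in sediment and water in April,
#' August (temporary site dry) and November, with one planted co-occurrence
#' block tied to permanent conditions and one to dry conditions.
#'
#' @param dir directory for the demo files (created if needed).
#' @param seed master seed.
#' @return invisibly, a list with the written `config_path`, `table_path`,
#'   `metadata_path`, the `pipeline_config`, and the ground `truth`.
#' @export
make_demo <- function(dir = "streamnet_demo", seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sc <- synthetic_config(
    sites = c(P1 = "permanent", P2 = "permanent", T1 = "temporary_flowing"),
    habitats = c("sediment", "water"),
    n_samples_per_group = 1L,
    n_background_otus = 30L,
    blocks = list(
      list(size = 8L, target_rho = 0.9, flow_status = "permanent"),
      list(size = 8L, target_rho = 0.9, flow_status = "temporary_dry")
    ),
    group_effect_sd = 1,
    seed = seed
  )
  dates <- c("2012-04-15", "2012-08-15", "2012-11-15")
  syn <- temporal_series(sc, dates, dry_dates = "2012-08-15")
  table_path <- file.path(dir, "demo_table.tsv")
  metadata_path <- file.path(dir, "demo_metadata.tsv")
  write_otu_table(syn$table, table_path)
  write_sample_metadata(syn$metadata, metadata_path)
  config <- pipeline_config(table = table_path, metadata = metadata_path,
                            out_dir = file.path(dir, "results"), seed = seed)
  config_path <- file.path(dir, "demo_config.yaml")
  write_pipeline_config(config, config_path)
  invisible(list(config_path = config_path, table_path = table_path,
                 metadata_path = metadata_path, config = config,
                 truth = syn$truth))
}
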