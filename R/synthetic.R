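# Synthetic community generator with planted ground truth.
#
# Abundances are built as lognormal baseline x per-group multiplier x
# flow-status multiplier, normalized to per-sample relative abundances and
# scaled to a lognormal sequencing depth. Counts are drawn with negative-
# binomial marginals through a Gaussian-copula quantile transform: block
# members share a per-sample latent factor with pairwise latent correlation
# r = 2*sin(pi*rho_s/6), which yields Spearman correlation rho_s in the
# continuous limit (ties from discreteness attenuate it slightly). Because
# the quantile transform is monotone, the planted rank correlation is
# invariant to the abundance scale.
#
# Group (site/habitat) and date multipliers are drawn per response unit: each
# background OTU is its own unit, while the members of a planted block share
# one unit. A co-occurring module responds coherently to environmental
# conditions -- independent per-member responses would dilute the planted
# rank correlation, which is the quantity the recovery tests control.

#' Configure the synthetic community generator
#'
#' @param sites named character vector: site id -> flow status
#'   (`permanent`, `temporary_flowing`, or `temporary_dry` when not
#'   date-resolved; temporary sites switch status by date in
#'   [temporal_series()]).
#' @param habitats habitats sampled at every site (`sediment`, `water`, `soil`).
#' @param n_samples_per_group replicate samples per site x habitat (x date).
#' @param n_background_otus number of OTUs outside any planted block.
#' @param blocks list of planted co-occurrence blocks, each a list with
#'   `size` (>= 2 OTUs), `target_rho` (target pairwise Spearman correlation,
#'   in (0, 0.99]), and `flow_status` (the status during which the block is
#'   amplified by `status_multiplier`).
#' @param group_effect_sd sd of per-OTU log-normal site/habitat multipliers;
#'   0 plants no group structure (ANOSIM null).
#' @param date_effect_sd sd of per-OTU log-normal date effects (temporal
#'   designs only).
#' @param status_multiplier fold-change applied to a block's OTUs in samples
#'   whose flow status matches the block's associated status.
#' @param baseline_meanlog,baseline_sdlog lognormal baseline abundances for
#'   background OTUs.
#' @param block_baseline_offset added to `baseline_meanlog` for block OTUs so
#'   planted OTUs sit in the abundant tail (ties and the 0.1% filter would
#'   otherwise erode the planted correlation).
#' @param depth_meanlog,depth_sdlog lognormal per-sample sequencing depth.
#' @param nb_size negative-binomial size (inverse overdispersion) of counts.
#' @param seed master seed; all randomness flows from it via named substreams.
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(sites = c(P1 = "permanent", P2 = "permanent",
                                       T1 = "temporary_flowing"),
                             habitats = "sediment",
                             n_samples_per_group = 5L,
                             n_background_otus = 24L,
                             blocks = list(),
                             group_effect_sd = 0.4,
                             date_effect_sd = 0.3,
                             status_multiplier = 5,
                             baseline_meanlog = 0,
                             baseline_sdlog = 1,
                             block_baseline_offset = 0.5,
                             depth_meanlog = log(2e4),
                             depth_sdlog = 0.25,
                             nb_size = 3,
                             seed = 1L) {
  if (is.null(names(sites)) || any(!nzchar(names(sites)))) {
    stop("`sites` must be a named vector: site id -> flow status")
  }
  bad <- setdiff(sites, c("permanent", "temporary_flowing", "temporary_dry"))
  if (length(bad)) stop("unknown flow status: ", paste(bad, collapse = ", "))
  bad <- setdiff(habitats, c("sediment", "water", "soil"))
  if (length(bad)) stop("unknown habitat: ", paste(bad, collapse = ", "))
  for (b in blocks) {
    if (!all(c("size", "target_rho", "flow_status") %in% names(b))) {
      stop("each block needs `size`, `target_rho` and `flow_status`")
    }
    if (b$size < 2) stop("block sizes must be >= 2")
    if (b$target_rho <= 0 || b$target_rho > 1) stop("target_rho must be in (0, 1]")
    if (!b$flow_status %in% c("permanent", "temporary_flowing", "temporary_dry")) {
      stop("unknown block flow_status: ", b$flow_status)
    }
  }
  stopifnot(n_samples_per_group >= 1, n_background_otus >= 0,
            group_effect_sd >= 0, date_effect_sd >= 0, status_multiplier > 0,
            baseline_sdlog > 0, depth_sdlog >= 0, nb_size > 0)
  structure(list(sites = sites, habitats = habitats,
                 n_samples_per_group = as.integer(n_samples_per_group),
                 n_background_otus = as.integer(n_background_otus),
                 blocks = blocks, group_effect_sd = group_effect_sd,
                 date_effect_sd = date_effect_sd,
                 status_multiplier = status_multiplier,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 block_baseline_offset = block_baseline_offset,
                 depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
                 nb_size = nb_size, seed = as.integer(seed)),
            class = "synthetic_config")
}

# A small pool of realistic lineage strings for synthetic taxonomy.
synthetic_lineage_pool <- function() {
  c("Proteobacteria|Gammaproteobacteria|Methylococcales|Crenotrichaceae|Crenothrix",
    "Proteobacteria|Betaproteobacteria|Burkholderiales|Comamonadaceae",
    "Proteobacteria|Betaproteobacteria|Nitrosomonadales|Nitrosomonadaceae|Unclassified",
    "Proteobacteria|Betaproteobacteria|Methylophilales|Methylophilaceae",
    "Proteobacteria|Alphaproteobacteria|Rhizobiales|Bradyrhizobiaceae",
    "Proteobacteria|Deltaproteobacteria|Syntrophobacterales|Syntrophaceae|Syntrophus",
    "Nitrospirae|Nitrospira|Nitrospirales|4-29|Unclassified",
    "Nitrospirae|Nitrospira|Nitrospirales|Nitrospiraceae|Nitrospira",
    "Bacteroidetes|Sphingobacteriia|Sphingobacteriales|Chitinophagaceae|Terrimonas",
    "Bacteroidetes|Sphingobacteriia|Sphingobacteriales|Saprospiraceae|Unclassified",
    "Spirochaetes|Spirochaetes|Spirochaetales|Spirochaetaceae|Spirochaeta",
    "Acidobacteria|Acidobacteriia|Acidobacteriales|Acidobacteriaceae")
}

#' Generate a synthetic community with known ground truth
#'
#' One sampling date; each site x habitat group contributes
#' `n_samples_per_group` samples with the site's configured flow status.
#'
#' @param config a [synthetic_config()].
#' @param date collection date recorded in the metadata.
#' @return a list with `table` ([otu_table]), `metadata` (data.frame), and
#'   `truth` (block membership per OTU, group multipliers, latent factors).
#'   Deterministic given `config$seed`.
#' @export
generate_community <- function(config, date = "2012-08-01") {
  stopifnot(inherits(config, "synthetic_config"))
  design <- expand.grid(site = names(config$sites), habitat = config$habitats,
                        rep = seq_len(config$n_samples_per_group),
                        stringsAsFactors = FALSE)
  design$date <- date
  design$flow_status <- unname(config$sites[design$site])
  generate_from_design(config, design)
}

#' Generate a synthetic temporal series
#'
#' One group of samples per site x habitat x date with a per-OTU date-level
#' random effect. Temporary sites are `temporary_dry` on `dry_dates` and
#' `temporary_flowing` otherwise; blocks associated with a flow status wax
#' (by `status_multiplier`) in samples where that status is active.
#'
#' @param config a [synthetic_config()].
#' @param dates character vector (>= 2) of ISO-8601 dates.
#' @param dry_dates subset of `dates` during which temporary sites are dry.
#' @return as [generate_community()].
#' @export
temporal_series <- function(config, dates, dry_dates = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (length(dates) < 2L) stop("`dates` must contain at least 2 dates")
  if (length(setdiff(dry_dates, dates))) stop("`dry_dates` must be a subset of `dates`")
  design <- expand.grid(site = names(config$sites), habitat = config$habitats,
                        rep = seq_len(config$n_samples_per_group),
                        date = dates, stringsAsFactors = FALSE)
  base_status <- unname(config$sites[design$site])
  temp <- base_status != "permanent"
  design$flow_status <- base_status
  design$flow_status[temp] <- ifelse(design$date[temp] %in% dry_dates,
                                     "temporary_dry", "temporary_flowing")
  generate_from_design(config, design, date_effects = TRUE)
}

generate_from_design <- function(config, design, date_effects = FALSE) {
  block_sizes <- vapply(config$blocks, function(b) as.integer(b$size), 1L)
  n_block <- sum(block_sizes)
  n_otus <- config$n_background_otus + n_block
  if (n_otus < 1L) stop("config yields no OTUs")
  for (b in config$blocks) {
    if (b$target_rho > 0.99) {
      stop(sprintf(paste0("target_rho %.3f is infeasible for discrete negative-",
                          "binomial counts; the attainable bound is 0.99"),
                   b$target_rho))
    }
  }
  n_samples <- nrow(design)
  otus <- sprintf("OTU_%04d", seq_len(n_otus))
  # block membership: background OTUs first, then blocks in order
  block_of <- rep(NA_integer_, n_otus)
  if (n_block > 0L) {
    block_of[config$n_background_otus + seq_len(n_block)] <-
      rep(seq_along(block_sizes), block_sizes)
  }
  design$sample_id <- sprintf("%s_%s_%s_%02d", design$site, design$habitat,
                              gsub("-", "", design$date), design$rep)
  group <- interaction(design$site, design$habitat, drop = TRUE)
  groups <- levels(group)
  seed <- config$seed

  baseline <- with_seed(substream_seed(seed, "baseline"), {
    b <- stats::rlnorm(n_otus, config$baseline_meanlog, config$baseline_sdlog)
    b[!is.na(block_of)] <- b[!is.na(block_of)] * exp(config$block_baseline_offset)
    b
  })
  # response units: one per background OTU, one per block (shared response)
  unit_of <- ifelse(is.na(block_of), seq_len(n_otus),
                    n_otus + block_of)
  unit_ids <- sort(unique(unit_of))
  unit_row <- match(unit_of, unit_ids)
  n_units <- length(unit_ids)
  mult_u <- with_seed(substream_seed(seed, "group_multipliers"), {
    if (config$group_effect_sd > 0) {
      matrix(stats::rlnorm(n_units * length(groups), 0, config$group_effect_sd),
             n_units, length(groups), dimnames = list(NULL, groups))
    } else {
      matrix(1, n_units, length(groups), dimnames = list(NULL, groups))
    }
  })
  mult <- mult_u[unit_row, , drop = FALSE]
  rownames(mult) <- otus
  log_mu <- log(baseline) + log(mult)[, as.integer(group), drop = FALSE]
  if (date_effects && config$date_effect_sd > 0) {
    udates <- unique(design$date)
    deff_u <- with_seed(substream_seed(seed, "date_effects"),
                        matrix(stats::rnorm(n_units * length(udates), 0,
                                            config$date_effect_sd),
                               n_units, length(udates),
                               dimnames = list(NULL, udates)))
    deff <- deff_u[unit_row, , drop = FALSE]
    log_mu <- log_mu + deff[, match(design$date, udates), drop = FALSE]
  }
  for (bi in seq_along(config$blocks)) {
    active <- design$flow_status == config$blocks[[bi]]$flow_status
    if (any(active)) {
      members <- which(block_of == bi)
      log_mu[members, active] <- log_mu[members, active] +
        log(config$status_multiplier)
    }
  }
  # relative abundances, scaled to a lognormal per-sample depth
  p <- exp(sweep(log_mu, 2L, apply(log_mu, 2L, max), "-"))
  p <- sweep(p, 2L, colSums(p), "/")
  depth <- with_seed(substream_seed(seed, "depths"),
                     stats::rlnorm(n_samples, config$depth_meanlog,
                                   config$depth_sdlog))
  mu <- sweep(p, 2L, depth, "*")

  # Gaussian copula: block members share a per-sample latent factor
  latent <- with_seed(substream_seed(seed, "latent"),
                      matrix(stats::rnorm(length(config$blocks) * n_samples),
                             nrow = length(config$blocks), ncol = n_samples))
  z <- with_seed(substream_seed(seed, "noise"),
                 matrix(stats::rnorm(n_otus * n_samples), n_otus, n_samples))
  for (bi in seq_along(config$blocks)) {
    r <- 2 * sin(pi * config$blocks[[bi]]$target_rho / 6)
    members <- which(block_of == bi)
    # Compositional-closure compensation: a block holding share s of the
    # community moves the per-sample total with its own latent factor, and
    # normalization (relative abundance, rarefaction) removes that shared
    # movement, attenuating the realized correlation by ~(1 - s)^2 on the
    # latent scale. Inflate the latent correlation so the realized pairwise
    # Spearman correlation lands near the target.
    share <- mean(colSums(p[members, , drop = FALSE]))
    a <- (1 - share)^2
    r_eff <- min(r / (a * (1 - r) + r), 0.999)
    z[members, ] <- sqrt(r_eff) * rep(latent[bi, ], each = length(members)) +
      sqrt(1 - r_eff) * z[members, ]
  }
  counts <- matrix(stats::qnbinom(stats::pnorm(z), size = config$nb_size,
                                  mu = mu),
                   n_otus, n_samples,
                   dimnames = list(otus, design$sample_id))
  taxonomy <- with_seed(substream_seed(seed, "taxonomy"),
                        stats::setNames(sample(synthetic_lineage_pool(),
                                               n_otus, replace = TRUE), otus))
  metadata <- data.frame(sample_id = design$sample_id, site = design$site,
                         habitat = design$habitat,
                         flow_status = design$flow_status,
                         date = design$date, stringsAsFactors = FALSE)
  truth <- list(
    block = stats::setNames(block_of, otus),
    block_flow_status = vapply(config$blocks, `[[`, "", "flow_status"),
    multipliers = mult,
    latent = latent,
    config = config
  )
  list(table = otu_table(counts, taxonomy = taxonomy),
       metadata = metadata, truth = truth)
}
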