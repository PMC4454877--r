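# Count-level preprocessing: low-abundance filtering and rarefaction.

#' Filter low-abundance OTUs
#'
#' Removes OTUs whose abundance falls strictly below `min_fraction` of the
#' total sequence count. By default the fraction is computed on the grand
#' total pooled across all samples ("less than 0.1% of total sequences");
#' with `per_sample = TRUE` an OTU is retained if it reaches `min_fraction`
#' of at least one sample's total.
#'
#' @param x an [otu_table].
#' @param min_fraction proportion in `[0, 1)`; default `0.001` (0.1%).
#' @param per_sample compute the threshold per sample instead of on the
#'   pooled total.
#' @return the filtered [otu_table]; the sample set is unchanged. The
#'   operation is idempotent at a fixed `min_fraction`.
#' @export
filter_low_abundance <- function(x, min_fraction = 0.001, per_sample = FALSE) {
  stopifnot(inherits(x, "otu_table"))
  if (!is.numeric(min_fraction) || min_fraction < 0 || min_fraction >= 1) {
    stop("`min_fraction` must be in [0, 1)")
  }
  counts <- x$counts
  if (nrow(counts) == 0L) stop("empty OTU table")
  if (per_sample) {
    frac <- sweep(counts, 2L, pmax(colSums(counts), 1L), "/")
    keep <- apply(frac, 1L, max) >= min_fraction
  } else {
    totals <- rowSums(counts)
    keep <- totals >= min_fraction * sum(as.numeric(counts))
  }
  if (!any(keep)) {
    stop("all OTUs fall below the abundance threshold; lower `min_fraction`")
  }
  otu_table(counts[keep, , drop = FALSE],
            taxonomy = x$taxonomy[names(x$taxonomy) %in% rownames(counts)[keep]])
}

#' Rarefy each sample to a common depth
#'
#' Subsamples each sample's sequences without replacement (a multivariate
#' hypergeometric draw) so that every retained sample sums to exactly
#' `depth`. Samples whose total is below `depth` are dropped with a warning.
#' The draw is deterministic given `seed`; each sample uses a named
#' substream keyed by its sample id, so results do not depend on column
#' order or on which other samples are present.
#'
#' @param x an [otu_table].
#' @param depth positive integer target depth (the source study used 8960).
#' @param seed integer master seed.
#' @return the rarefied [otu_table]. Output counts are elementwise `<=`
#'   input counts and column sums equal `depth` exactly.
#' @export
rarefy <- function(x, depth, seed = 1L) {
  stopifnot(inherits(x, "otu_table"))
  if (!is.numeric(depth) || length(depth) != 1L || depth < 1) {
    stop("`depth` must be a positive integer")
  }
  depth <- as.integer(depth)
  counts <- x$counts
  totals <- colSums(counts)
  drop <- totals < depth
  if (all(drop)) {
    stop("all samples have fewer than ", depth, " sequences")
  }
  if (any(drop)) {
    warning("dropping ", sum(drop), " sample(s) below depth ", depth, ": ",
            paste(colnames(counts)[drop], collapse = ", "))
  }
  keep <- which(!drop)
  out <- matrix(0L, nrow(counts), length(keep),
                dimnames = list(rownames(counts), colnames(counts)[keep]))
  for (k in seq_along(keep)) {
    j <- keep[k]
    if (totals[j] == depth) {
      out[, k] <- counts[, j]
      next
    }
    pool <- rep.int(seq_len(nrow(counts)), counts[, j])
    drawn <- with_seed(
      substream_seed(seed, paste0("rarefy:", colnames(counts)[j])),
      sample(pool, depth)
    )
    out[, k] <- tabulate(drawn, nbins = nrow(counts))
  }
  otu_table(out, taxonomy = x$taxonomy)
}
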