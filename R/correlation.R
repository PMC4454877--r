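# Pairwise Spearman rank correlation between OTUs across samples.

#' Spearman correlation matrix between OTUs
#'
#' `rho` is the Pearson correlation of midranks for each OTU pair; the
#' two-sided p-value uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` with `n - 2` degrees of freedom.
#' `rho = +/-1` yields `p = 0`. OTUs with constant counts across samples
#' have undefined correlations; these are recorded as `rho = 0`, `p = 1`
#' with a warning.
#'
#' @param x an [otu_table] (or counts matrix); at least 2 OTUs and 4 samples.
#' @return object of class `cooc_correlation`: list with symmetric `rho`
#'   (unit diagonal) and `p` matrices, `n_samples`, and `method`.
#' @export
spearman_matrix <- function(x) {
  counts <- if (inherits(x, "otu_table")) x$counts else x
  if (nrow(counts) < 2L) stop("need at least 2 OTUs")
  n <- ncol(counts)
  if (n < 4L) stop("need at least 4 samples for meaningful p-values")
  ranks <- t(apply(counts, 1L, rank))
  constant <- apply(counts, 1L, function(v) max(v) == min(v))
  rho <- suppressWarnings(stats::cor(t(ranks)))
  if (any(constant)) {
    warning("constant OTU vector(s), correlation undefined, recorded as 0: ",
            paste(rownames(counts)[constant], collapse = ", "))
    rho[constant, ] <- 0
    rho[, constant] <- 0
  }
  rho[is.na(rho)] <- 0
  diag(rho) <- 1
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, 0))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[abs(rho) >= 1 - 1e-12] <- 0
  if (any(constant)) {
    p[constant, ] <- 1
    p[, constant] <- 1
  }
  diag(p) <- 0
  dimnames(rho) <- dimnames(p) <- list(rownames(counts), rownames(counts))
  structure(list(rho = rho, p = p, n_samples = n,
                 method = "spearman midrank, two-sided t approximation"),
            class = "cooc_correlation")
}

#' @export
print.cooc_correlation <- function(x, ...) {
  cat(sprintf("Spearman correlation: %d OTUs over %d samples (%s)\n",
              nrow(x$rho), x$n_samples, x$method))
  invisible(x)
}
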