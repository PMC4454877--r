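# Principal coordinate analysis (metric MDS) of a distance matrix.

#' Principal coordinate analysis
#'
#' Eigendecomposition of the Gower-centered matrix `-1/2 J D^2 J` (J the
#' centering operator). Coordinates are eigenvectors scaled by `sqrt(lambda)`
#' for positive eigenvalues; `proportion_explained` is `lambda_i` over the
#' sum of positive eigenvalues. Negative eigenvalues (expected for
#' Bray-Curtis, a semi-metric) are reported but excluded from the variance
#' decomposition; no Lingoes/Cailliez correction is applied.
#'
#' @param d symmetric distance matrix with zero diagonal.
#' @param n_axes number of axes to return; truncated with a warning if it
#'   exceeds the number of positive eigenvalues.
#' @return an object of class `pcoa_result`: list with `coordinates`
#'   (samples x axes), `eigenvalues` (all, descending), and
#'   `proportion_explained` (per returned axis, on the positive-eigenvalue
#'   scale).
#' @export
pcoa_ordination <- function(d, n_axes = 2L) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2L || ncol(d) != n) stop("`d` must be a square matrix with >= 2 samples")
  if (max(abs(d - t(d))) > 1e-8) stop("`d` must be symmetric")
  a <- -0.5 * d^2
  rm_ <- rowMeans(a)
  b <- a - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + mean(a)
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  vals <- e$values
  tol <- 1e-9 * max(1, abs(vals))
  pos <- which(vals > tol)
  ids <- rownames(d) %||% paste0("sample", seq_len(n))
  if (length(pos) == 0L) {
    warning("no positive eigenvalues; returning all-zero coordinates")
    coords <- matrix(0, n, n_axes,
                     dimnames = list(ids, paste0("Axis", seq_len(n_axes))))
    return(structure(list(coordinates = coords, eigenvalues = vals,
                          proportion_explained = rep(0, n_axes),
                          trace = sum(diag(b))),
                     class = "pcoa_result"))
  }
  if (n_axes > length(pos)) {
    warning("only ", length(pos), " positive eigenvalue(s); truncating n_axes")
    n_axes <- length(pos)
  }
  take <- pos[seq_len(n_axes)]
  coords <- e$vectors[, take, drop = FALSE] *
    rep(sqrt(vals[take]), each = n)
  dimnames(coords) <- list(ids, paste0("Axis", seq_len(n_axes)))
  structure(list(coordinates = coords,
                 eigenvalues = vals,
                 proportion_explained = vals[take] / sum(vals[pos]),
                 trace = sum(diag(b))),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat("PCoA:", nrow(x$coordinates), "samples,", ncol(x$coordinates), "axes\n")
  cat("variance explained:",
      paste(sprintf("%.1f%%", 100 * x$proportion_explained), collapse = ", "),
      "\n")
  invisible(x)
}
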