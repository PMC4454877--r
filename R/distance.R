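# Bray-Curtis dissimilarity between samples.

#' Bray-Curtis distance matrix
#'
#' `d(x, y) = sum |x_i - y_i| / sum (x_i + y_i)` over OTUs: 0 for identical
#' samples, 1 for communities with disjoint support.
#'
#' @param x an [otu_table] (or a counts matrix with dimnames).
#' @return symmetric numeric matrix with zero diagonal, entries in `[0, 1]`,
#'   sample ids as dimnames.
#' @export
bray_curtis <- function(x) {
  counts <- if (inherits(x, "otu_table")) x$counts else x
  if (ncol(counts) < 2L) stop("need at least 2 samples")
  totals <- colSums(counts)
  if (any(totals == 0)) {
    stop("all-zero sample(s): ",
         paste(colnames(counts)[totals == 0], collapse = ", "))
  }
  num <- as.matrix(stats::dist(t(counts), method = "manhattan"))
  d <- num / outer(totals, totals, "+")
  diag(d) <- 0
  dimnames(d) <- list(colnames(counts), colnames(counts))
  d
}

#' Write / read a distance matrix as square TSV
#'
#' @param d symmetric distance matrix with sample ids as dimnames.
#' @param path file path.
#' @return `path` (write) or the matrix (read).
#' @export
write_distance_matrix <- function(d, path) {
  df <- data.frame(sample_id = rownames(d), d, check.names = FALSE)
  write_tsv_file(df, path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          comment.char = "", quote = "")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8))) {
    stop("distance matrix in ", path, " is not symmetric")
  }
  m
}
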