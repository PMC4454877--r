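# Abundance submatrix for heatmap plotting (selected OTUs x samples).

#' Abundance matrix for a heatmap of selected OTUs
#'
#' Extracts a submatrix in the requested OTU and sample order and applies a
#' transform: `raw` counts, `log10` (log10(x + 1)), or `row_z` (per-OTU
#' z-score; constant rows become all zeros with a warning). When metadata is
#' supplied, flow-status labels are attached to both axes (`sample_site_type`
#' and `otu_site_type` attributes) as used for color-coding.
#'
#' @param x an [otu_table].
#' @param otus ordered OTU ids (must exist in `x`).
#' @param samples ordered sample ids (default: all samples in table order).
#' @param transform `"raw"`, `"log10"`, or `"row_z"`.
#' @param meta optional sample metadata for the axis labels.
#' @return numeric matrix with `otus` as rows; attributes
#'   `sample_site_type`/`otu_site_type` when `meta` is given.
#' @export
heatmap_matrix <- function(x, otus, samples = NULL,
                           transform = c("raw", "log10", "row_z"),
                           meta = NULL) {
  stopifnot(inherits(x, "otu_table"))
  transform <- match.arg(transform)
  samples <- samples %||% sample_ids(x)
  bad <- setdiff(otus, otu_ids(x))
  if (length(bad)) stop("unknown OTU id(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(samples, sample_ids(x))
  if (length(bad)) stop("unknown sample id(s): ", paste(bad, collapse = ", "))
  m <- x$counts[otus, samples, drop = FALSE]
  m <- switch(transform,
    raw = m + 0, # numeric copy of the counts
    log10 = log10(m + 1),
    row_z = {
      z <- t(apply(m, 1L, function(v) {
        s <- stats::sd(v)
        if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
      }))
      if (any(apply(m, 1L, function(v) max(v) == min(v)))) {
        warning("constant row(s) z-scored to all zeros")
      }
      dimnames(z) <- dimnames(m)
      z
    })
  if (!is.null(meta)) {
    meta <- validate_metadata(meta)
    idx <- match(samples, meta$sample_id)
    if (anyNA(idx)) {
      stop("samples missing from metadata: ",
           paste(samples[is.na(idx)], collapse = ", "))
    }
    attr(m, "sample_site_type") <-
      stats::setNames(meta$flow_status[idx], samples)
    # per-OTU label: flow status of the sample with maximal count
    attr(m, "otu_site_type") <- stats::setNames(vapply(otus, function(o) {
      v <- x$counts[o, ]
      meta$flow_status[match(sample_ids(x)[which.max(v)], meta$sample_id)]
    }, ""), otus)
  }
  m
}

#' Write a heatmap matrix as TSV
#'
#' The matrix is written with an `otu_id` leading column; axis site-type
#' labels, when present, are written as commented header lines.
#'
#' @param m matrix from [heatmap_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_heatmap_tsv <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  sst <- attr(m, "sample_site_type")
  if (!is.null(sst)) {
    writeLines(paste0("# sample_site_type\t",
                      paste(sst, collapse = "\t")), con)
  }
  ost <- attr(m, "otu_site_type")
  header <- c("otu_id", colnames(m), if (!is.null(ost)) "otu_site_type")
  writeLines(paste(header, collapse = "\t"), con)
  for (i in seq_len(nrow(m))) {
    row <- c(rownames(m)[i], format(m[i, ], trim = TRUE),
             if (!is.null(ost)) ost[[rownames(m)[i]]])
    writeLines(paste(row, collapse = "\t"), con)
  }
  invisible(path)
}
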