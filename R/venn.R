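# Shared-OTU (Venn) partitioning across sample groups.

#' Partition OTUs by the exact set of groups they occur in
#'
#' An OTU is "present" in a group when its summed count over that group's
#' samples is greater than zero. Counts are reported per exclusive subset of
#' groups (the cells of a Venn diagram); subset counts sum to the number of
#' OTUs present in at least one group.
#'
#' @param x an [otu_table].
#' @param grouping named character vector mapping each sample id to a group
#'   (or an unnamed vector aligned with the table's samples).
#' @return named integer vector of class `venn_counts`; names are
#'   alphabetically sorted group subsets joined with `"&"`. All `2^k - 1`
#'   subsets are reported, including empty ones.
#' @export
shared_otu_partition <- function(x, grouping) {
  stopifnot(inherits(x, "otu_table"))
  if (!is.null(names(grouping))) {
    missing <- setdiff(sample_ids(x), names(grouping))
    if (length(missing)) {
      stop("samples missing from grouping: ", paste(missing, collapse = ", "))
    }
    grouping <- grouping[sample_ids(x)]
  } else if (length(grouping) != ncol(x$counts)) {
    stop("`grouping` must have one entry per sample")
  }
  grouping <- as.character(grouping)
  groups <- sort(unique(grouping))
  if (length(groups) < 2L) stop("need at least 2 groups")
  pooled <- vapply(groups,
                   function(g) rowSums(x$counts[, grouping == g, drop = FALSE]),
                   numeric(nrow(x$counts)))
  present <- pooled > 0
  keys <- apply(present, 1L, function(row) paste(groups[row], collapse = "&"))
  keys <- keys[nzchar(keys)]
  all_subsets <- unlist(lapply(seq_along(groups), function(k) {
    apply(utils::combn(groups, k), 2L, paste, collapse = "&")
  }))
  counts <- stats::setNames(integer(length(all_subsets)), all_subsets)
  tab <- table(keys)
  counts[names(tab)] <- as.integer(tab)
  structure(counts, class = c("venn_counts", "integer"), groups = groups)
}

#' @export
print.venn_counts <- function(x, ...) {
  cat("Shared-OTU partition over groups:",
      paste(attr(x, "groups"), collapse = ", "), "\n")
  print(stats::setNames(as.integer(x), names(x)))
  invisible(x)
}
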