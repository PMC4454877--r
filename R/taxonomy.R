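# Lineage strings: pipe- or semicolon-delimited ranked taxonomy.

#' Parse a delimited taxonomy lineage
#'
#' Lineages are ordered from highest to lowest rank, e.g.
#' `"Nitrospirae|Nitrospira|Nitrospirales|4-29|Unclassified"`.
#' `"Unclassified"` tokens are preserved as taxon strings. Parsing and then
#' re-serializing with [format()] reproduces the input up to whitespace.
#'
#' @param raw nonempty lineage string.
#' @param delimiter `"|"` or `";"`.
#' @return an object of class `lineage`: list with `taxa` (character vector,
#'   highest rank first), `delimiter`, and `raw`.
#' @export
#' @examples
#' parse_taxonomy("Proteobacteria|Gammaproteobacteria|Methylococcales")
parse_taxonomy <- function(raw, delimiter = c("|", ";")) {
  delimiter <- match.arg(delimiter)
  if (!is.character(raw) || length(raw) != 1L || !nzchar(trimws(raw))) {
    stop("`raw` must be a nonempty lineage string")
  }
  taxa <- trimws(strsplit(raw, delimiter, fixed = TRUE)[[1L]])
  structure(list(taxa = taxa, delimiter = delimiter, raw = raw),
            class = "lineage")
}

#' @export
format.lineage <- function(x, ...) paste(x$taxa, collapse = x$delimiter)

#' @export
print.lineage <- function(x, ...) {
  cat(sprintf("Lineage (%d ranks): %s\n", length(x$taxa), format(x)))
  invisible(x)
}

#' @export
as.character.lineage <- function(x, ...) format(x)

#' Number of ranks in a lineage
#' @param lin a `lineage`.
#' @return integer rank count.
#' @export
n_ranks <- function(lin) length(lin$taxa)
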