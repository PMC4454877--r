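# OTU table container and on-disk formats.

#' Construct an OTU count table
#'
#' An OTU table holds a nonnegative integer count matrix (rows = OTUs,
#' columns = samples) with unique OTU and sample identifiers and an optional
#' taxonomy map (raw lineage strings keyed by OTU id).
#'
#' @param counts numeric matrix of nonnegative integer counts with unique
#'   rownames (OTU ids) and colnames (sample ids).
#' @param taxonomy optional named character vector of raw lineage strings;
#'   names must be a subset of the OTU ids.
#' @return an object of class `otu_table`: a list with elements `counts`
#'   (integer matrix) and `taxonomy`.
#' @export
#' @examples
#' m <- matrix(c(5L, 0L, 2L, 7L), 2, dimnames = list(c("OTU1", "OTU2"), c("S1", "S2")))
#' otu_table(m)
otu_table <- function(counts, taxonomy = NULL) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("`counts` must be a numeric matrix")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` must have OTU ids as rownames and sample ids as colnames")
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate otu_id: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate sample_id: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  }
  if (anyNA(counts) || any(counts < 0)) stop("counts must be nonnegative and non-missing")
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop("counts must be integers; use round = TRUE when reading if needed")
  }
  storage.mode(counts) <- "integer"
  if (!is.null(taxonomy)) {
    if (is.null(names(taxonomy)) || !all(names(taxonomy) %in% rownames(counts))) {
      stop("taxonomy names must be a subset of the OTU ids")
    }
    taxonomy <- taxonomy[intersect(rownames(counts), names(taxonomy))]
  }
  structure(list(counts = counts, taxonomy = taxonomy), class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("OTU table: %d OTUs x %d samples (total count %s)%s\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(as.numeric(x$counts)), big.mark = ","),
              if (is.null(x$taxonomy)) "" else
                sprintf("; taxonomy for %d OTUs", length(x$taxonomy))))
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

#' OTU and sample identifiers
#' @param x an `otu_table`.
#' @return character vector of ids.
#' @export
otu_ids <- function(x) rownames(x$counts)

#' @rdname otu_ids
#' @export
sample_ids <- function(x) colnames(x$counts)

#' Extract the count matrix
#' @param x an `otu_table`.
#' @return integer matrix (OTUs x samples).
#' @export
otu_counts <- function(x) x$counts

#' Read an OTU table
#'
#' Supports the classic tab-separated OTU-table dialect (QIIME-1 style):
#' a header row of sample ids, optionally led by a `#OTU ID` cell, with an
#' optional trailing `taxonomy` column carrying pipe- or semicolon-delimited
#' lineage strings. BIOM-JSON files are read through the \pkg{biomformat}
#' package when available.
#'
#' @param path path to the file.
#' @param dialect `"classic_tsv"` (canonical) or `"biom_json"`.
#' @param round if `TRUE`, non-integer counts are rounded; otherwise they
#'   are an error.
#' @return an [otu_table].
#' @export
read_otu_table <- function(path, dialect = c("classic_tsv", "biom_json"),
                           round = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "biom_json") return(read_otu_table_biom(path, round = round))

  header <- readLines(path, n = 1L)
  if (!nzchar(header)) stop("malformed header at line 1 of ", path, ": empty")
  fields <- strsplit(header, "\t", fixed = TRUE)[[1]]
  if (length(fields) < 2L) {
    stop("malformed header at line 1 of ", path,
         ": expected tab-separated sample ids")
  }
  samples <- fields[-1L]
  has_tax <- tolower(samples[length(samples)]) == "taxonomy"
  if (has_tax) samples <- samples[-length(samples)]
  if (length(samples) == 0L) {
    stop("malformed header at line 1 of ", path, ": no sample columns")
  }
  if (anyDuplicated(samples)) {
    stop("duplicate sample_id in header: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  body <- utils::read.table(path, sep = "\t", skip = 1L, header = FALSE,
                            colClasses = "character", quote = "",
                            comment.char = "", stringsAsFactors = FALSE)
  if (ncol(body) != length(fields)) {
    stop("row width does not match header in ", path)
  }
  ids <- body[[1L]]
  tax <- NULL
  if (has_tax) {
    tax <- stats::setNames(body[[ncol(body)]], ids)
    tax <- tax[nzchar(trimws(tax))]
    if (length(tax) == 0L) tax <- NULL
    body <- body[, -ncol(body), drop = FALSE]
  }
  num <- suppressWarnings(
    vapply(body[-1L], as.numeric, numeric(nrow(body)))
  )
  num <- matrix(num, nrow = nrow(body),
                dimnames = list(ids, samples))
  if (anyNA(num)) stop("non-numeric count values in ", path)
  if (any(abs(num - round(num)) > 1e-8)) {
    if (round) num <- round(num) else
      stop("non-integer counts in ", path, "; pass round = TRUE to round them")
  } else {
    num <- round(num)
  }
  otu_table(num, taxonomy = tax)
}

read_otu_table_biom <- function(path, round = FALSE) {
  if (!requireNamespace("biomformat", quietly = TRUE)) {
    stop("reading BIOM-JSON requires the 'biomformat' package")
  }
  b <- biomformat::read_biom(path)
  m <- as(biomformat::biom_data(b), "matrix")
  if (any(abs(m - round(m)) > 1e-8) && !round) {
    stop("non-integer counts in ", path, "; pass round = TRUE to round them")
  }
  m <- round(m)
  tax <- tryCatch({
    om <- biomformat::observation_metadata(b)
    if (is.null(om)) NULL
    else if (is.data.frame(om)) {
      stats::setNames(apply(om, 1L, paste, collapse = ";"), rownames(om))
    } else {
      stats::setNames(vapply(om, paste, "", collapse = ";"), names(om))
    }
  }, error = function(e) NULL)
  otu_table(m, taxonomy = tax)
}

#' Write an OTU table in the classic TSV dialect
#'
#' @param x an [otu_table].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(x, path) {
  stopifnot(inherits(x, "otu_table"))
  df <- data.frame(check.names = FALSE, `#OTU ID` = otu_ids(x), x$counts)
  colnames(df) <- c("#OTU ID", sample_ids(x))
  if (!is.null(x$taxonomy)) {
    df$taxonomy <- unname(x$taxonomy[otu_ids(x)])
    df$taxonomy[is.na(df$taxonomy)] <- ""
  }
  write_tsv_file(df, path)
}

#' Read a sample metadata table
#'
#' A TSV with required columns `sample_id`, `site`, `habitat`
#' (sediment/water/soil), `flow_status` (permanent/temporary_flowing/
#' temporary_dry), and `date` (ISO-8601).
#'
#' @param path path to the TSV file.
#' @return a data.frame with one row per sample; `date` is a `Date`.
#' @export
read_sample_metadata <- function(path) {
  md <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  validate_metadata(md)
}

validate_metadata <- function(md) {
  required <- c("sample_id", "site", "habitat", "flow_status", "date")
  missing <- setdiff(required, colnames(md))
  if (length(missing)) {
    stop("metadata is missing required columns: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(md$sample_id)) {
    stop("duplicate sample_id in metadata: ",
         paste(unique(md$sample_id[duplicated(md$sample_id)]), collapse = ", "))
  }
  bad_h <- setdiff(unique(md$habitat), c("sediment", "water", "soil"))
  if (length(bad_h)) stop("unknown habitat value(s): ", paste(bad_h, collapse = ", "))
  bad_f <- setdiff(unique(md$flow_status),
                   c("permanent", "temporary_flowing", "temporary_dry"))
  if (length(bad_f)) stop("unknown flow_status value(s): ", paste(bad_f, collapse = ", "))
  md$date <- as.Date(md$date)
  if (anyNA(md$date)) stop("metadata dates must be ISO-8601 (YYYY-MM-DD)")
  md
}

#' Write a sample metadata table
#' @param md metadata data.frame (see [read_sample_metadata]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(md, path) {
  md$date <- as.character(md$date)
  write_tsv_file(md, path)
}

# Check that every analyzed sample has a metadata row, in table order.
match_metadata <- function(x, md) {
  missing <- setdiff(sample_ids(x), md$sample_id)
  if (length(missing)) {
    stop("samples missing from metadata: ", paste(missing, collapse = ", "))
  }
  md[match(sample_ids(x), md$sample_id), , drop = FALSE]
}
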