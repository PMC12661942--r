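## The ASV table container: a marker-specific read-count matrix
## (ASVs x station-fraction libraries) with one lineage string per ASV.

#' Construct an ASV table
#'
#' @param marker marker label (`"COI"`, `"V4"` or `"V9"`).
#' @param counts integer matrix, ASVs in rows, libraries in columns;
#'   column names `"<station>_<fraction>"`.
#' @param lineage character vector of rank-prefixed lineage strings, one
#'   per ASV (see [lineage_string()]).
#' @param station,fraction optional per-column labels; parsed from the
#'   column names if omitted (split at the first underscore).
#' @return object of class `asv_table`.
#' @export
asv_table <- function(marker, counts, lineage, station = NULL, fraction = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    abort_zp("read counts must be non-negative integers", "zp_bad_input")
  storage.mode(counts) <- "integer"
  stopifnot(length(lineage) == nrow(counts))
  if (is.null(station) || is.null(fraction)) {
    cn <- colnames(counts)
    stopifnot(!is.null(cn))
    station <- sub("_.*$", "", cn)
    fraction <- sub("^[^_]*_", "", cn)
  }
  structure(list(marker = marker, counts = counts,
                 lineage = as.character(lineage),
                 station = station, fraction = fraction),
            class = "asv_table")
}

#' @export
print.asv_table <- function(x, ...) {
  cat(sprintf("<asv_table> marker=%s: %d ASVs x %d libraries (%d stations), %s reads\n",
              x$marker, nrow(x$counts), ncol(x$counts),
              length(unique(x$station)),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' @export
dim.asv_table <- function(x) dim(x$counts)

subset_asvs <- function(table, keep) {
  table$counts <- table$counts[keep, , drop = FALSE]
  table$lineage <- table$lineage[keep]
  table
}

#' Write an ASV table as TSV
#'
#' Rows are ASVs (`asv_id`, `lineage`, then one column per
#' station-fraction library); a `#` header records the marker.
#'
#' @param table an `asv_table`.
#' @param path output path.
#' @param meta extra metadata for the header.
#' @return `path`, invisibly.
#' @export
write_asv_table <- function(table, path, meta = list()) {
  df <- data.frame(asv_id = rownames(table$counts), lineage = table$lineage,
                   stringsAsFactors = FALSE, check.names = FALSE)
  df <- cbind(df, as.data.frame(table$counts, check.names = FALSE))
  write_tsv_meta(df, path, c(list(marker = table$marker), meta))
}

#' Read an ASV table written by [write_asv_table()]
#'
#' @param path input path.
#' @param marker marker label; defaults to the header's `marker` field.
#' @return an `asv_table`.
#' @export
read_asv_table <- function(path, marker = NULL) {
  df <- read_tsv_meta(path)
  marker <- marker %||% attr(df, "meta")$marker
  counts <- as.matrix(df[, setdiff(names(df), c("asv_id", "lineage")),
                         drop = FALSE])
  rownames(counts) <- df$asv_id
  asv_table(marker, counts, df$lineage)
}
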