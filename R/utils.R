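## Internal helpers shared across modules: lineage strings, checked
## arithmetic, and TSV I/O with '#'-prefixed metadata headers.

RANKS <- c("phylum", "class", "order", "family", "genus", "species")

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_zp <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "zoopim_error")))
}

#' Format a lineage as a rank-prefixed string
#'
#' Lineages travel through tables as single strings of the form
#' `"p__Arthropoda;c__Copepoda;o__Calanoida;f__Calanidae;g__Calanus;s__Calanus hyperboreus"`.
#' Unresolved ranks are present but empty (`"g__;s__"`), so the string always
#' carries all six ranks phylum..species.
#'
#' @param x named character vector (names in `phylum...species`) or a list of
#'   such vectors.
#' @return character vector of lineage strings.
#' @seealso [parse_lineage()]
#' @export
lineage_string <- function(x) {
  if (is.list(x)) return(vapply(x, lineage_string, character(1)))
  vals <- x[RANKS]
  vals[is.na(vals)] <- ""
  paste(paste0(substr(RANKS, 1, 1), "__", vals), collapse = ";")
}

#' Parse rank-prefixed lineage strings
#'
#' @param s character vector of strings as produced by [lineage_string()].
#'   Bare names without rank prefixes are tolerated and mapped positionally
#'   onto phylum..species.
#' @return a character matrix with one row per input and columns
#'   `phylum...species`; unresolved ranks are `""`.
#' @export
parse_lineage <- function(s) {
  out <- matrix("", nrow = length(s), ncol = length(RANKS),
                dimnames = list(NULL, RANKS))
  parts <- strsplit(s, ";", fixed = TRUE)
  pref <- paste0(substr(RANKS, 1, 1), "__")
  for (i in seq_along(parts)) {
    p <- trimws(parts[[i]])
    has_pref <- grepl("^[pcofgs]__", p)
    if (all(has_pref)) {
      for (j in seq_along(RANKS)) {
        hit <- p[startsWith(p, pref[j])]
        if (length(hit)) out[i, j] <- sub(pref[j], "", hit[1], fixed = TRUE)
      }
    } else {
      k <- min(length(p), length(RANKS))
      out[i, seq_len(k)] <- p[seq_len(k)]
    }
  }
  out
}

## deepest resolved rank index (0 if nothing resolved)
deepest_rank <- function(lin_mat) {
  apply(lin_mat != "", 1L, function(z) if (any(z)) max(which(z)) else 0L)
}

## truncate lineage matrix rows at a rank (keep ranks 1..k, blank the rest)
truncate_lineage <- function(lin_mat, rank) {
  k <- match(rank, RANKS)
  if (is.na(k)) abort_zp(sprintf("unknown rank '%s'", rank), "zp_bad_rank")
  if (k < length(RANKS)) lin_mat[, (k + 1L):length(RANKS)] <- ""
  lin_mat
}

## percentage rounded to one decimal, as printed in accounting tables
pct1 <- function(x, total) round(100 * x / total, 1)

## derive a stream-specific 32-bit seed from a master seed
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 1000003L * as.integer(offset)) %% 2147483647L
}

#' Write a TSV with '#'-prefixed metadata header lines
#'
#' All pipeline outputs are tab-separated with a small header block recording
#' the tool version and, for stochastic steps, the seed.
#'
#' @param x data.frame to write.
#' @param path output path.
#' @param meta named list of metadata scalars written as `# key: value`.
#' @return `path`, invisibly.
#' @export
write_tsv_meta <- function(x, path, meta = list()) {
  meta <- c(list(tool = paste0("zoopim ", as.character(packageVersion("zoopim")))),
            meta)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta)) {
    writeLines(sprintf("# %s: %s", k, paste(meta[[k]], collapse = " ")), con)
  }
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_meta()]
#'
#' @param path input path.
#' @return data.frame; the parsed `# key: value` header is attached as the
#'   `"meta"` attribute.
#' @export
read_tsv_meta <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  if (length(hdr)) {
    kv <- sub("^#\\s*", "", lines[hdr])
    for (s in kv) {
      k <- sub(":.*$", "", s)
      meta[[trimws(k)]] <- trimws(sub("^[^:]*:", "", s))
    }
  }
  body <- if (length(hdr)) lines[-hdr] else lines
  df <- read.delim(text = paste(body, collapse = "\n"), sep = "\t",
                   stringsAsFactors = FALSE, check.names = FALSE)
  attr(df, "meta") <- meta
  df
}
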