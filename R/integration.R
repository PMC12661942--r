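## Cross-method taxon harmonization: one catalog of named categories with
## the set of methods that detected each, plus the overlap (Venn), per-rank
## richness and dominant-taxa summaries.

normalize_label <- function(x) {
  x <- gsub("\\s+", " ", trimws(x))
  ## canonical taxonomic capitalization: leading capital, rest lower, so
  ## pure case variants of one name collapse to a single label
  has <- nchar(x) > 0
  x[has] <- paste0(toupper(substr(x[has], 1, 1)),
                   tolower(substr(x[has], 2, nchar(x[has]))))
  x
}

#' Harmonize taxon lists across methods
#'
#' Builds one catalog of canonical taxon records from per-method lineage
#' lists. Labels are whitespace-normalized and case-insensitive synonyms
#' applied per rank name; identical lineage strings are merged and their
#' source methods unioned. A coarser record (e.g. family only) is never
#' merged into a species-level record of the same family -- they remain
#' distinct named categories, as presence/absence comparisons require.
#'
#' @param taxa_per_method named list: method -> character vector of
#'   lineage strings.
#' @param synonyms optional named character vector `c(from = "to")`
#'   applied to individual rank names; duplicate `from` entries with
#'   conflicting targets are an error.
#' @return data.frame of class `taxon_catalog`: `lineage`, `rank`
#'   (deepest resolved), `name` (deepest resolved name), `sources`
#'   (semicolon-joined method labels), one logical column per method.
#' @export
harmonize <- function(taxa_per_method, synonyms = NULL) {
  stopifnot(is.list(taxa_per_method), !is.null(names(taxa_per_method)))
  if (!is.null(synonyms)) {
    dup <- duplicated(names(synonyms))
    if (any(dup)) {
      conf <- tapply(synonyms, names(synonyms), function(z) length(unique(z)))
      if (any(conf > 1))
        abort_zp("conflicting synonym mapping", "zp_bad_synonyms")
      synonyms <- synonyms[!dup]
    }
  }
  methods <- names(taxa_per_method)
  recs <- list()
  for (m in methods) {
    lins <- taxa_per_method[[m]]
    if (length(lins) == 0) next
    mat <- parse_lineage(lins)
    mat[] <- normalize_label(mat)
    if (!is.null(synonyms)) {
      hit <- match(tolower(mat), tolower(names(synonyms)))
      mat[!is.na(hit)] <- unname(synonyms[hit[!is.na(hit)]])
    }
    canon <- lineage_string(lapply(seq_len(nrow(mat)),
                                   function(i) setNames(mat[i, ], RANKS)))
    recs[[m]] <- unique(canon)
  }
  all_lin <- sort(unique(unlist(recs)))
  pres <- vapply(methods, function(m) all_lin %in% (recs[[m]] %||% character(0)),
                 logical(length(all_lin)))
  if (is.null(dim(pres))) pres <- matrix(pres, nrow = length(all_lin),
                                         dimnames = list(NULL, methods))
  mat <- parse_lineage(all_lin)
  dr <- deepest_rank(mat)
  out <- data.frame(
    lineage = all_lin,
    rank = ifelse(dr > 0, RANKS[pmax(dr, 1)], "unknown"),
    name = vapply(seq_along(all_lin), function(i)
      if (dr[i] > 0) mat[i, dr[i]] else "unknown", character(1)),
    sources = apply(pres, 1, function(z) paste(methods[z], collapse = ";")),
    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(pres))
  class(out) <- c("taxon_catalog", "data.frame")
  attr(out, "methods") <- methods
  out
}

#' Venn counts over method subsets
#'
#' Counts catalog records in each of the `2^m - 1` non-empty method
#' subsets (exactly-this-subset counts, as drawn in a Venn diagram).
#'
#' @param catalog a [harmonize()] catalog.
#' @param exclude_unassigned drop records whose deepest resolved name is
#'   an unassigned placeholder (default `TRUE`).
#' @return data.frame `subset` (method labels joined by `+`), `count`;
#'   counts sum to the number of records.
#' @export
venn_counts <- function(catalog, exclude_unassigned = TRUE) {
  methods <- attr(catalog, "methods")
  df <- as.data.frame(catalog)
  if (exclude_unassigned)
    df <- df[!grepl("unassigned|unknown", df$name), , drop = FALSE]
  pres <- as.matrix(df[, methods, drop = FALSE])
  key <- apply(pres, 1, function(z) paste(methods[z], collapse = "+"))
  subsets <- vapply(seq_len(2^length(methods) - 1), function(b) {
    paste(methods[as.logical(bitwAnd(b, 2^(seq_along(methods) - 1)))],
          collapse = "+")
  }, character(1))
  cnt <- table(factor(key, levels = subsets))
  data.frame(subset = subsets, count = as.integer(cnt),
             stringsAsFactors = FALSE)
}

#' Per-rank richness by method
#'
#' Number of unique named categories each method resolves at each rank;
#' unassigned placeholders are not counted, and ranks a method never
#' resolves are `NA` (rendered as dashes in reports).
#'
#' @param taxa_per_method named list of lineage-string vectors (or a
#'   [harmonize()] catalog, whose per-method presence columns are used).
#' @return data.frame: `rank` plus one integer column per method.
#' @export
rank_richness <- function(taxa_per_method) {
  if (inherits(taxa_per_method, "taxon_catalog")) {
    methods <- attr(taxa_per_method, "methods")
    taxa_per_method <- lapply(methods, function(m)
      taxa_per_method$lineage[taxa_per_method[[m]]])
    names(taxa_per_method) <- methods
  }
  methods <- names(taxa_per_method)
  out <- data.frame(rank = RANKS, stringsAsFactors = FALSE)
  for (m in methods) {
    mat <- parse_lineage(taxa_per_method[[m]])
    out[[m]] <- vapply(seq_along(RANKS), function(k) {
      nm <- unique(mat[, k])
      nm <- nm[nm != "" & !grepl("unassigned|unknown", nm)]
      if (length(nm) == 0) NA_integer_ else length(nm)
    }, integer(1))
  }
  out
}

#' Dominant taxa per station
#'
#' Ranks taxa by relative share per station, keeps the top `k` (ties
#' broken lexicographically by taxon name) and pools the remainder as
#' `"other"`.
#'
#' @param matrix a [community_matrix()].
#' @param k number of taxa to keep per station (default 5).
#' @return data.frame: `station`, `rank`, `taxon`, `share_pct`; shares
#'   per station (including `"other"`) sum to 100.
#' @export
dominant_taxa <- function(matrix, k = 5L) {
  if (k < 1) abort_zp("k must be at least 1", "zp_bad_input")
  v <- matrix$values
  rows <- lapply(rownames(v), function(s) {
    x <- v[s, ]
    tot <- sum(x)
    share <- if (tot > 0) 100 * x / tot else x * 0
    ord <- order(-share, names(share))
    top <- ord[seq_len(min(k, length(ord)))]
    df <- data.frame(station = s, rank = seq_along(top),
                     taxon = names(share)[top],
                     share_pct = unname(share[top]),
                     stringsAsFactors = FALSE)
    rbind(df, data.frame(station = s, rank = length(top) + 1L,
                         taxon = "other",
                         share_pct = max(0, 100 - sum(df$share_pct)),
                         stringsAsFactors = FALSE))
  })
  do.call(rbind, rows)
}
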