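## Sequence-table processing: singleton removal, metazoan filtering with
## accounting, NSRA scaling-and-merge across size fractions, rank
## aggregation and ASV accumulation curves.

#' Metazoan phyla retained by the default filter
#'
#' The eleven metazoan phyla recorded in the emulated study system.
#'
#' @return character vector of phylum names.
#' @export
metazoan_phyla <- function() {
  c("Annelida", "Arthropoda", "Chaetognatha", "Chordata", "Cnidaria",
    "Ctenophora", "Echinodermata", "Mollusca", "Nemertea", "Rotifera",
    "Nematoda")
}

#' Remove singleton ASVs
#'
#' Drops ASVs whose total read count across all libraries is at or below
#' `threshold` (default 1: dataset-wide singletons).
#'
#' @param table an [asv_table()].
#' @param threshold total-read threshold; 0 keeps everything.
#' @return the filtered `asv_table`; attribute `"report"` carries the
#'   counts of dropped ASVs and reads.
#' @export
remove_singletons <- function(table, threshold = 1L) {
  tot <- rowSums(table$counts)
  drop <- tot <= threshold
  out <- subset_asvs(table, !drop)
  attr(out, "report") <- list(
    input_asvs = nrow(table$counts), input_reads = sum(table$counts),
    dropped_asvs = sum(drop), dropped_reads = sum(tot[drop]),
    kept_asvs = sum(!drop), kept_reads = sum(tot[!drop]),
    threshold = threshold)
  out
}

#' Filter an ASV table to metazoan phyla
#'
#' Keeps ASVs whose phylum is in `phyla` and reports the retained read and
#' ASV counts as percentages of the input (rounded to one decimal, the
#' accounting-table convention).
#'
#' @param table an [asv_table()].
#' @param phyla character set of phyla to keep; default [metazoan_phyla()].
#' @return filtered `asv_table` with a `"report"` attribute:
#'   kept/removed reads and ASVs plus `pct_reads` and `pct_asvs`.
#' @export
filter_metazoa <- function(table, phyla = metazoan_phyla()) {
  if (length(phyla) == 0) abort_zp("empty phylum set", "zp_bad_input")
  ph <- parse_lineage(table$lineage)[, "phylum"]
  keep <- ph %in% phyla
  tot <- rowSums(table$counts)
  out <- subset_asvs(table, keep)
  attr(out, "report") <- list(
    input_asvs = nrow(table$counts), input_reads = sum(table$counts),
    kept_asvs = sum(keep), kept_reads = sum(tot[keep]),
    removed_asvs = sum(!keep), removed_reads = sum(tot[!keep]),
    pct_reads = pct1(sum(tot[keep]), sum(table$counts)),
    pct_asvs = pct1(sum(keep), nrow(table$counts)))
  out
}

#' Marker-level accounting report
#'
#' Reconstructs the standard raw -> processed -> singleton-filtered ->
#' metazoan accounting for one marker, with percentages rounded to one
#' decimal: processed reads as a percentage of raw reads, and metazoan
#' reads/ASVs as percentages of the post-singleton table.
#'
#' @param table processed `asv_table` (post-bioinformatics, pre-filtering).
#' @param raw_reads raw read count before bioinformatic processing
#'   (optional; `NA` omits the processed percentage).
#' @param phyla metazoan phylum set.
#' @param singleton_threshold passed to [remove_singletons()].
#' @return list with the filtered table (`$table`) and a one-row
#'   data.frame `$accounting` mirroring the usual published layout.
#' @export
marker_accounting <- function(table, raw_reads = NA_real_,
                              phyla = metazoan_phyla(),
                              singleton_threshold = 1L) {
  processed_reads <- sum(table$counts)
  nos <- remove_singletons(table, singleton_threshold)
  rs <- attr(nos, "report")
  met <- filter_metazoa(nos, phyla)
  rm_ <- attr(met, "report")
  acc <- data.frame(
    marker = table$marker,
    raw_reads = raw_reads,
    processed_reads = processed_reads,
    processed_pct = if (is.na(raw_reads)) NA_real_ else
      pct1(processed_reads, raw_reads),
    total_asvs = rs$input_asvs,
    reads_after_singletons = rs$kept_reads,
    asvs_after_singletons = rs$kept_asvs,
    singleton_asvs = rs$dropped_asvs,
    metazoan_reads = rm_$kept_reads,
    metazoan_reads_pct = rm_$pct_reads,
    metazoan_asvs = rm_$kept_asvs,
    metazoan_asvs_pct = rm_$pct_asvs,
    stringsAsFactors = FALSE)
  list(table = met, accounting = acc)
}

#' NSRA scaling and merge for one station
#'
#' Within one station, each size fraction's library is scaled so its total
#' equals the station's minimum per-fraction depth (factor `D_min / D_f`;
#' within-fraction read proportions are unchanged), then the scaled
#' fractions are summed into one value per ASV. Fractions with zero total
#' reads are excluded with a warning (their scale factor is undefined).
#'
#' @param counts numeric matrix, ASVs x fractions, for a single station.
#' @return list: `nsra` (named vector per ASV), `report` (data.frame with
#'   per-fraction depth, `d_min`, scale factor).
#' @export
nsra_scale_merge <- function(counts) {
  counts <- as.matrix(counts)
  depth <- colSums(counts)
  zero <- depth == 0
  if (all(zero))
    abort_zp("no fraction with positive depth", "zp_bad_input")
  if (any(zero)) {
    warning(sprintf("[ZP_W01] dropping %d zero-depth fraction(s): %s",
                    sum(zero), paste(colnames(counts)[zero], collapse = ", ")))
    counts <- counts[, !zero, drop = FALSE]
    depth <- depth[!zero]
  }
  d_min <- min(depth)
  scale <- d_min / depth
  scaled <- sweep(counts, 2, scale, `*`)
  list(nsra = rowSums(scaled),
       report = data.frame(fraction = colnames(counts), depth = depth,
                           d_min = d_min, scale = scale,
                           row.names = NULL, stringsAsFactors = FALSE))
}

#' Normalized sequence read abundances for a whole ASV table
#'
#' Applies [nsra_scale_merge()] station by station and stacks the merged
#' rows into a station x ASV matrix of (real-valued) scaled reads.
#'
#' @param table an [asv_table()] (typically after singleton and metazoan
#'   filtering).
#' @return list of class `nsra_matrix`: `values` (stations x ASVs),
#'   `lineage` (per ASV), `marker`, `report` (per station x fraction
#'   scaling table).
#' @export
nsra <- function(table) {
  stns <- unique(table$station)
  vals <- matrix(0, nrow = length(stns), ncol = nrow(table$counts),
                 dimnames = list(stns, rownames(table$counts)))
  reports <- list()
  for (s in stns) {
    cols <- which(table$station == s)
    m <- table$counts[, cols, drop = FALSE]
    colnames(m) <- table$fraction[cols]
    res <- nsra_scale_merge(m)
    vals[s, ] <- res$nsra
    reports[[s]] <- cbind(station = s, res$report, stringsAsFactors = FALSE)
  }
  structure(list(values = vals, lineage = table$lineage,
                 marker = table$marker,
                 report = do.call(rbind, c(reports, make.row.names = FALSE))),
            class = "nsra_matrix")
}

#' @export
print.nsra_matrix <- function(x, ...) {
  cat(sprintf("<nsra_matrix> marker=%s: %d stations x %d ASVs\n",
              x$marker, nrow(x$values), ncol(x$values)))
  invisible(x)
}

## category label at a rank; unresolved lineages are pooled under their
## deepest resolved name, e.g. "Calanidae (unassigned species)"
rank_category <- function(lin_mat, rank) {
  k <- match(rank, RANKS)
  if (is.na(k)) abort_zp(sprintf("unknown rank '%s'", rank), "zp_bad_rank")
  nm <- lin_mat[, k]
  unres <- nm == ""
  if (any(unres)) {
    deep <- apply(lin_mat[unres, seq_len(k), drop = FALSE], 1L, function(z) {
      z <- z[z != ""]
      if (length(z)) z[length(z)] else "unknown"
    })
    nm[unres] <- sprintf("%s (unassigned %s)", deep, rank)
  }
  nm
}

#' Aggregate a community or NSRA matrix to a taxonomic rank
#'
#' Sums columns whose lineages share the named category at `rank`.
#' Lineages not resolved to that rank are pooled under their deepest
#' resolved name as `"<name> (unassigned <rank>)"` categories.
#'
#' @param x an `nsra_matrix`, [asv_table()] or [community_matrix()].
#' @param rank one of `phylum ... species`.
#' @param relative if `TRUE`, rows are rescaled to percentages summing to
#'   100 per station.
#' @return a [community_matrix()] (stations x categories).
#' @export
aggregate_rank <- function(x, rank, relative = FALSE) {
  if (inherits(x, "asv_table")) {
    vals <- t(x$counts); lineage <- x$lineage; currency <- "reads"
  } else if (inherits(x, "nsra_matrix")) {
    vals <- x$values; lineage <- x$lineage; currency <- "nsra"
  } else if (inherits(x, "community_matrix")) {
    vals <- x$values; lineage <- x$lineage; currency <- x$currency
  } else abort_zp("unsupported input to aggregate_rank", "zp_bad_input")
  cat_ <- rank_category(parse_lineage(lineage), rank)
  agg <- t(rowsum(t(vals), group = cat_, reorder = TRUE))
  lin_mat <- truncate_lineage(parse_lineage(lineage), rank)
  lin_by_cat <- tapply(lineage_string(
    lapply(seq_len(nrow(lin_mat)), function(i) setNames(lin_mat[i, ], RANKS))),
    cat_, function(z) z[1])
  lin_out <- as.character(lin_by_cat[colnames(agg)])
  if (relative) {
    rs <- rowSums(agg)
    agg <- sweep(agg, 1, ifelse(rs > 0, rs, 1), `/`) * 100
    currency <- paste0(currency, "_pct")
  }
  community_matrix(agg, lineage = lin_out, currency = currency)
}

#' ASV accumulation curve
#'
#' Expected number of distinct ASVs recovered when `d` reads are drawn
#' without replacement from the pooled table, for `d` on a grid with the
#' given step. Each replicate shuffles the pooled reads once and counts
#' distinct ASVs along prefixes of the shuffle (nested subsamples), so
#' every replicate curve -- and hence the reported mean -- is monotone
#' non-decreasing by construction.
#'
#' @param table an [asv_table()].
#' @param step grid step in reads (> 0).
#' @param n_rep subsamples per depth.
#' @param seed integer seed.
#' @return data.frame `reads`, `asvs` (mean distinct ASVs).
#' @export
asv_accumulation <- function(table, step, n_rep = 10L, seed = 1L) {
  if (step <= 0) abort_zp("step must be positive", "zp_bad_input")
  n <- rowSums(table$counts)
  n <- n[n > 0]
  total <- sum(n)
  depths <- unique(c(seq(step, total, by = step), total))
  set.seed(derive_seed(seed, 9L))
  reads <- rep.int(seq_along(n), n)
  acc <- matrix(0, nrow = n_rep, ncol = length(depths))
  for (r in seq_len(n_rep)) {
    perm <- sample(reads)
    first_pos <- match(seq_along(n), perm)  # first read of each ASV
    acc[r, ] <- vapply(depths, function(d) sum(first_pos <= d), numeric(1))
  }
  data.frame(reads = depths, asvs = colMeans(acc))
}
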