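## Image-based quantification: pixel/mm conversion, ellipsoid biovolume,
## dry-mass conversion with rank-fallback lookup, filtered volume, and the
## station x taxon community matrices in the three currencies.

#' Convert scanner pixels to millimetres
#'
#' @param length_px length in pixels.
#' @param dpi scanner resolution in dots per inch (default 2400, the
#'   standard flatbed-scanner setting).
#' @return length in mm: `length_px * 25.4 / dpi`.
#' @export
pixels_to_mm <- function(length_px, dpi = 2400) {
  if (any(dpi <= 0)) abort_zp("dpi must be positive", "zp_bad_input")
  length_px * 25.4 / dpi
}

#' Ellipsoid (prolate spheroid) biovolume
#'
#' `BV = (4/3) * pi * (major/2) * (minor/2)^2` in mm3, with the major axis
#' as the polar axis -- the standard body-shape model for copepod-like
#' plankton silhouettes.
#'
#' @param major,minor ellipse axes in mm; `major >= minor > 0` required.
#' @return biovolume in mm3.
#' @export
ellipsoid_biovolume <- function(major, minor) {
  if (any(minor <= 0)) abort_zp("axes must be positive", "zp_bad_input")
  if (any(minor > major))
    abort_zp("minor axis exceeds major axis (axes swapped?)", "zp_bad_input")
  (4 / 3) * pi * (major / 2) * (minor / 2)^2
}

#' Filtered water volume of a tow
#'
#' `V = net_area * speed_in_m_per_s * duration`, with knots converted at
#' 0.514444 m/s per knot.
#'
#' @param net_area effective net opening (m2).
#' @param speed_knots towing speed (knots).
#' @param duration_s tow duration (s).
#' @return volume in m3.
#' @export
filtered_volume <- function(net_area, speed_knots, duration_s) {
  if (any(net_area <= 0) || any(speed_knots <= 0) || any(duration_s <= 0))
    abort_zp("net area, speed and duration must all be positive", "zp_bad_input")
  net_area * speed_knots * 0.514444 * duration_s
}

#' Wet-to-dry conversion factor table
#'
#' Taxon-specific wet-to-dry mass conversion factors matched against any
#' rank of an object's lineage, deepest rank first. Ships with the two
#' literature values for Arctic zooplankton that the quantification relies
#' on: 0.16 for copepods and the halved 0.08 for *Calanus hyperboreus*
#' (whose oil sac makes the generic copepod factor a 2-fold
#' overestimate). Factors for other groups are user-supplied.
#'
#' @param extra optional data.frame with columns `taxon`, `factor` to
#'   append (rows here take precedence over the shipped defaults).
#' @param default global fallback factor used when no rank matches
#'   (`NA` = no fallback).
#' @param density assumed specific density in g/cm3 (default 1: neutrally
#'   buoyant, so 1 mm3 biovolume = 1 mg wet mass).
#' @return object of class `cf_table`.
#' @export
conversion_table <- function(extra = NULL, default = NA_real_, density = 1) {
  base <- data.frame(taxon = c("Calanus hyperboreus", "Copepoda"),
                     factor = c(0.08, 0.16), stringsAsFactors = FALSE)
  if (!is.null(extra)) {
    stopifnot(all(c("taxon", "factor") %in% names(extra)))
    base <- rbind(extra[, c("taxon", "factor")], base)
    base <- base[!duplicated(base$taxon), , drop = FALSE]
  }
  if (any(base$factor <= 0 | base$factor > 1))
    abort_zp("conversion factors must be in (0, 1]", "zp_bad_input")
  structure(list(table = base, default = default, density = density),
            class = "cf_table")
}

## most-resolved matching factor for one lineage row; NA if nothing matches
lookup_cf <- function(lin_row, cf) {
  nms <- rev(lin_row[lin_row != ""])
  for (nm in nms) {
    hit <- match(nm, cf$table$taxon)
    if (!is.na(hit)) return(cf$table$factor[hit])
  }
  cf$default
}

#' Individual dry mass from biovolume
#'
#' With the neutral-buoyancy assumption (density 1 g/cm3) biovolume in mm3
#' equals wet mass in mg, so dry mass is `BV * density * cf(lineage)` with
#' the conversion factor resolved by deepest-rank-first lookup in
#' `cf_table`.
#'
#' @param bv biovolume(s) in mm3.
#' @param lineage lineage string(s) (recycled against `bv`).
#' @param cf_table a [conversion_table()].
#' @param on_missing `"error"` (default) or `"na"` when no factor resolves
#'   even through the fallback chain.
#' @return dry mass in mg.
#' @export
object_dry_mass <- function(bv, lineage, cf_table = conversion_table(),
                            on_missing = c("error", "na")) {
  on_missing <- match.arg(on_missing)
  if (any(bv < 0)) abort_zp("biovolume must be non-negative", "zp_bad_input")
  lin <- parse_lineage(lineage)
  key <- lineage  # cache per distinct lineage string
  u <- !duplicated(key)
  fac_u <- vapply(which(u), function(i) lookup_cf(lin[i, ], cf_table),
                  numeric(1))
  fac <- fac_u[match(key, key[u])]
  if (any(is.na(fac))) {
    if (on_missing == "error")
      abort_zp("no conversion factor resolvable for some lineages",
               "zp_missing_cf")
  }
  bv * cf_table$density * fac
}

#' Construct a community matrix
#'
#' The common station x taxon container used by every stream: imaging
#' abundance/biovolume/biomass, read counts and NSRA.
#'
#' @param values numeric matrix, stations in rows, taxa in columns.
#' @param lineage lineage string per column (defaults to bare column
#'   names).
#' @param currency one of `"abundance"`, `"biovolume"`, `"biomass"`,
#'   `"reads"`, `"nsra"` (or a `_pct` variant).
#' @param units unit string for the header (derived from currency when
#'   omitted).
#' @return object of class `community_matrix`.
#' @export
community_matrix <- function(values, lineage = colnames(values),
                             currency = "abundance", units = NULL) {
  values <- as.matrix(values)
  units <- units %||% switch(currency,
    abundance = "ind/m3", biovolume = "mm3/m3", biomass = "mg DM/m3",
    reads = "reads", nsra = "scaled reads", currency)
  structure(list(values = values, lineage = as.character(lineage),
                 currency = currency, units = units),
            class = "community_matrix")
}

#' @export
print.community_matrix <- function(x, ...) {
  cat(sprintf("<community_matrix> %s (%s): %d stations x %d taxa\n",
              x$currency, x$units, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.community_matrix <- function(x) dim(x$values)

#' Build station x taxon matrices from image objects
#'
#' Each validated object contributes `value / split_factor` to its station
#' and taxon, where `value` is 1 (abundance), its ellipsoid biovolume
#' (biovolume) or its dry mass (biomass); station sums are divided by the
#' station's filtered volume. Objects not flagged as validated organisms
#' (artifacts, detritus, body parts) are excluded, with the
#' uploaded/discarded/retained accounting attached.
#'
#' @param objects data.frame with columns `station`, `lineage`, `major`,
#'   `minor`, `split`, `status` (extra columns tolerated).
#' @param meta station metadata: data.frame with `station` and
#'   `filtered_volume_m3` (or `net_area_m2`, `tow_speed_knots`,
#'   `tow_duration_s` to derive it).
#' @param currency `"abundance"`, `"biovolume"` or `"biomass"`.
#' @param cf_table a [conversion_table()] (biomass only).
#' @param species_lookup optional function mapping
#'   `(lineage, major) -> lineage`, applied before aggregation -- the hook
#'   for prosome-length-based species assignment within a genus.
#' @return a [community_matrix()]; attribute `"accounting"` holds
#'   `uploaded`, `discarded`, `retained` counts.
#' @export
station_matrix <- function(objects, meta,
                           currency = c("abundance", "biovolume", "biomass"),
                           cf_table = conversion_table(),
                           species_lookup = NULL) {
  currency <- match.arg(currency)
  stopifnot(all(c("station", "lineage", "split", "status") %in% names(objects)))
  if (!"filtered_volume_m3" %in% names(meta)) {
    meta$filtered_volume_m3 <- filtered_volume(meta$net_area_m2,
                                               meta$tow_speed_knots,
                                               meta$tow_duration_s)
  }
  uploaded <- nrow(objects)
  ok <- objects$status == "validated"
  discarded <- sum(!ok)
  objects <- objects[ok, , drop = FALSE]
  if (any(is.na(objects$split) | objects$split <= 0 | objects$split > 1))
    abort_zp("missing or invalid split factors", "zp_bad_input")
  if (!is.null(species_lookup))
    objects$lineage <- species_lookup(objects$lineage, objects$major)

  stns <- meta$station
  missing_v <- setdiff(unique(objects$station), stns)
  if (length(missing_v))
    abort_zp(paste("no filtered volume for station(s):",
                   paste(missing_v, collapse = ", ")), "zp_missing_volume")
  value <- switch(currency,
    abundance = rep(1, nrow(objects)),
    biovolume = ellipsoid_biovolume(objects$major, objects$minor),
    biomass = object_dry_mass(
      ellipsoid_biovolume(objects$major, objects$minor),
      objects$lineage, cf_table))
  w <- value / objects$split
  taxa <- sort(unique(objects$lineage))
  m <- matrix(0, nrow = length(stns), ncol = length(taxa),
              dimnames = list(stns, taxa))
  agg <- tapply(w, list(objects$station, objects$lineage), sum, default = 0)
  m[rownames(agg), colnames(agg)] <- agg
  m <- m / meta$filtered_volume_m3
  ## short display names, full lineage kept alongside
  lin <- taxa
  nm <- apply(parse_lineage(taxa), 1L, function(z) {
    z <- z[z != ""]
    if (length(z)) z[length(z)] else "unknown"
  })
  colnames(m) <- make.unique(nm)
  out <- community_matrix(m, lineage = lin, currency = currency)
  attr(out, "accounting") <- list(uploaded = uploaded, discarded = discarded,
                                  retained = uploaded - discarded)
  out
}

#' Per-station totals of a community matrix
#'
#' @param matrix a [community_matrix()].
#' @return named numeric vector of row sums, in the matrix's units.
#' @export
station_totals <- function(matrix) {
  rowSums(matrix$values)
}

#' Write a community matrix as TSV
#'
#' @param matrix a [community_matrix()].
#' @param path output path.
#' @param meta extra header metadata.
#' @return `path`, invisibly.
#' @export
write_community_matrix <- function(matrix, path, meta = list()) {
  df <- data.frame(station = rownames(matrix$values),
                   matrix$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_meta(df, path, c(list(currency = matrix$currency,
                                  units = matrix$units,
                                  lineage = paste(matrix$lineage,
                                                  collapse = " | ")),
                             meta))
}

#' Read a community matrix written by [write_community_matrix()]
#'
#' @param path input path.
#' @return a [community_matrix()].
#' @export
read_community_matrix <- function(path) {
  df <- read_tsv_meta(path)
  meta <- attr(df, "meta")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$station
  lin <- if (!is.null(meta$lineage))
    strsplit(meta$lineage, " | ", fixed = TRUE)[[1]] else colnames(m)
  community_matrix(m, lineage = lin,
                   currency = meta$currency %||% "abundance",
                   units = meta$units)
}

#' Read an imaging object table
#'
#' Reads tab-separated object exports in the flatbed-scanner dialect. The
#' canonical columns `object_id`, `station` (or `sample_id`), `fraction`,
#' `split`, `major` (or `object_major`), `minor` (or `object_minor`),
#' `lineage` (or `taxon`) and `status` are recognized; extra columns are
#' kept. If `dpi` is given the axes are taken as pixels and converted to
#' mm.
#'
#' @param path input path.
#' @param dpi optional scanner resolution; axes are pixels when set,
#'   millimetres otherwise.
#' @return data.frame of image objects.
#' @export
read_objects <- function(path, dpi = NULL) {
  df <- read_tsv_meta(path)
  ren <- c(sample_id = "station", object_major = "major",
           object_minor = "minor", taxon = "lineage",
           object_status = "status")
  for (from in names(ren)) {
    if (from %in% names(df) && !(ren[[from]] %in% names(df)))
      names(df)[names(df) == from] <- ren[[from]]
  }
  need <- c("station", "major", "minor", "lineage")
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort_zp(paste("object table lacks column(s):",
                   paste(miss, collapse = ", ")), "zp_bad_input")
  if (!is.null(dpi)) {
    df$major <- pixels_to_mm(df$major, dpi)
    df$minor <- pixels_to_mm(df$minor, dpi)
  }
  if (!"status" %in% names(df)) df$status <- "validated"
  df
}
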