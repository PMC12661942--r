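## End-to-end synthetic dataset generation: runs the observation chain and
## writes every file the pipeline readers consume, plus truth tables for
## parameter-recovery tests.

#' Generate a complete synthetic dataset on disk
#'
#' Runs the full forward simulation under the scenario seed and writes:
#' the imaging object table (with artifact/detritus rows mixed in so the
#' accounting filter is exercised), one ASV table per marker (columns =
#' station x size fraction libraries), the station environment table,
#' station metadata with filtered volumes, the conversion-factor table
#' implied by the pool, truth tables (expected and realized densities,
#' per-station dry mass per taxon, per-marker read-generating
#' proportions), and a YAML-style echo of the scenario with its seed.
#'
#' @param scenario a [scenario_config()].
#' @param pool a [make_taxon_pool()] pool.
#' @param out_dir output directory (created if missing).
#' @param markers markers to simulate.
#' @param artifact_frac fraction of uploaded images that are
#'   non-organism objects (artifacts/detritus; default 0.5, roughly the
#'   rate seen in real scanner uploads).
#' @return invisibly, a list with the in-memory pieces: `objects`,
#'   `asv` (per marker), `env`, `meta`, `truth`.
#' @export
generate_dataset <- function(scenario, pool, out_dir,
                             markers = c("COI", "V4", "V9"),
                             artifact_frac = 0.5) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir))
    abort_zp(paste("cannot create output directory", out_dir), "zp_io_error")
  seed <- scenario$seed

  env <- simulate_environment(scenario)
  dens <- simulate_community(pool, scenario, env)
  V <- filtered_volume(scenario$net_area_m2, scenario$tow_speed_knots,
                       scenario$tow_duration_s)
  catch <- simulate_tow(dens, V, seed)
  indiv <- simulate_individuals(catch, pool, seed)
  ss <- sieve_and_split(indiv, scenario, seed)

  ## truth: dry mass per station x taxon x fraction from the *whole* sieved
  ## catch (the sequencing half is not Motoda-split)
  above <- indiv[indiv$major >= scenario$sieve_cutoffs_mm[1], , drop = FALSE]
  labs <- fraction_labels(scenario)
  fr_idx <- findInterval(above$major, scenario$sieve_cutoffs_mm)
  above$fraction <- labs[fr_idx]
  bv <- ellipsoid_biovolume(above$major, above$minor)
  dm <- bv * pool$conversion_factor[match(above$taxon_id, pool$taxon_id)]
  stns <- scenario$stations$station
  biomass <- array(0, dim = c(length(stns), nrow(pool), length(labs)),
                   dimnames = list(stns, pool$taxon_id, labs))
  agg <- tapply(dm, list(above$station, above$taxon_id, above$fraction),
                sum, default = 0)
  biomass[dimnames(agg)[[1]], dimnames(agg)[[2]], dimnames(agg)[[3]]] <- agg

  asv <- list()
  for (mk in markers) {
    asv[[mk]] <- simulate_reads(biomass, pool, mk, scenario, seed)
  }

  ## imaging upload: retained organisms + artifact/detritus objects
  obj <- ss$objects
  n_art <- round(artifact_frac / (1 - artifact_frac) * nrow(obj))
  set.seed(derive_seed(seed, 10L))
  if (n_art > 0) {
    art <- data.frame(
      object_id = sprintf("art%07d", seq_len(n_art)),
      station = sample(stns, n_art, replace = TRUE),
      taxon_id = NA_character_,
      lineage = lineage_string(c(phylum = "")),
      major = exp(rnorm(n_art, 0.2, 0.6)),
      minor = NA_real_,
      status = sample(c("artifact", "detritus", "badfocus"), n_art,
                      replace = TRUE),
      fraction = NA_character_, split = 1,
      stringsAsFactors = FALSE)
    art$minor <- art$major / 1.5
    idx <- findInterval(art$major, scenario$sieve_cutoffs_mm)
    art <- art[idx > 0, , drop = FALSE]
    art$fraction <- labs[findInterval(art$major, scenario$sieve_cutoffs_mm)]
    obj <- rbind(obj, art)
  }
  obj <- obj[order(obj$station, obj$fraction, obj$object_id), , drop = FALSE]

  meta <- data.frame(
    station = stns,
    latitude = scenario$stations$latitude,
    longitude = scenario$stations$longitude %||% NA_real_,
    net_area_m2 = scenario$net_area_m2,
    tow_speed_knots = scenario$tow_speed_knots,
    tow_duration_s = scenario$tow_duration_s,
    filtered_volume_m3 = V,
    stringsAsFactors = FALSE)

  truth_density <- data.frame(
    station = rep(stns, times = ncol(dens)),
    taxon = rep(colnames(dens), each = nrow(dens)),
    expected_density = as.vector(attr(dens, "expected")),
    realized_density = as.vector(dens),
    stringsAsFactors = FALSE)
  dm_station <- apply(biomass, c(1, 2), sum)
  truth_biomass <- data.frame(
    station = rep(rownames(dm_station), times = ncol(dm_station)),
    taxon = rep(colnames(dm_station), each = nrow(dm_station)),
    dry_mass_mg = as.vector(dm_station),
    stringsAsFactors = FALSE)

  hdr <- list(seed = seed)
  write_tsv_meta(obj, file.path(out_dir, "objects.tsv"), hdr)
  for (mk in markers)
    write_asv_table(asv[[mk]], file.path(out_dir, paste0("asv_", mk, ".tsv")),
                    hdr)
  write_tsv_meta(env, file.path(out_dir, "env.tsv"), hdr)
  write_tsv_meta(meta, file.path(out_dir, "stations.tsv"), hdr)
  ## conversion factors keyed at the names the imaging stream reports:
  ## species-level entries plus group-level entries for taxa whose imaging
  ## resolution is coarser (factor averaged within the group)
  lin_all <- parse_lineage(pool$lineage)
  grp <- vapply(seq_len(nrow(pool)), function(i) {
    z <- truncate_lineage(lin_all[i, , drop = FALSE], pool$res_imaging[i])[1, ]
    z <- z[z != ""]
    z[length(z)]
  }, character(1))
  cf_df <- rbind(
    data.frame(taxon = pool$taxon_id, factor = pool$conversion_factor,
               stringsAsFactors = FALSE),
    data.frame(taxon = unique(grp),
               factor = vapply(unique(grp), function(g)
                 mean(pool$conversion_factor[grp == g]), numeric(1)),
               stringsAsFactors = FALSE))
  cf_df <- cf_df[!duplicated(cf_df$taxon), , drop = FALSE]
  write_tsv_meta(cf_df, file.path(out_dir, "conversion_factors.tsv"), hdr)
  write_tsv_meta(truth_density, file.path(out_dir, "truth_density.tsv"), hdr)
  write_tsv_meta(truth_biomass, file.path(out_dir, "truth_biomass.tsv"), hdr)
  for (mk in markers) {
    eff <- pool[[paste0("amp_", mk)]]
    props <- sweep(dm_station, 2, eff, `*`)
    rs <- rowSums(props)
    props <- sweep(props, 1, ifelse(rs > 0, rs, 1), `/`)
    write_tsv_meta(
      data.frame(station = rep(rownames(props), times = ncol(props)),
                 taxon = rep(colnames(props), each = nrow(props)),
                 read_prop = as.vector(props), stringsAsFactors = FALSE),
      file.path(out_dir, paste0("truth_read_props_", mk, ".tsv")), hdr)
  }
  write_scenario_echo(scenario, file.path(out_dir, "scenario.yml"))
  invisible(list(objects = obj, asv = asv, env = env, meta = meta,
                 truth = list(density = truth_density,
                              biomass = truth_biomass,
                              split_table = ss$split_table)))
}

## YAML-style echo of the scenario (write-only; configs are read as JSON)
write_scenario_echo <- function(scenario, path) {
  sc <- scenario
  lines <- c(
    "# scenario echo",
    paste0("seed: ", sc$seed),
    paste0("net_area_m2: ", sc$net_area_m2),
    paste0("tow_speed_knots: ", sc$tow_speed_knots),
    paste0("tow_duration_s: ", sc$tow_duration_s),
    paste0("sieve_cutoffs_mm: [", paste(sc$sieve_cutoffs_mm, collapse = ", "), "]"),
    paste0("motoda_min_fraction: ", sc$motoda_min_fraction),
    paste0("target_particles_per_aliquot: ", sc$target_particles_per_aliquot),
    paste0("seq_depth_range: [", paste(sc$seq_depth_range, collapse = ", "), "]"),
    paste0("ref_latitude: ", sc$ref_latitude),
    paste0("density_sdlog: ", sc$density_sdlog),
    paste0("background_read_frac: ", sc$background_read_frac),
    paste0("singletons_per_fraction: ", sc$singletons_per_fraction),
    "stations:",
    sprintf("  - {id: %s, latitude: %.5f}", sc$stations$station,
            sc$stations$latitude))
  writeLines(lines, path)
  invisible(path)
}
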