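## Forward simulation of the observation chain: true densities -> net tow
## -> individual body sizes -> sieve fractionation and Motoda splitting ->
## marker-specific sequence reads.

#' Simulate true community densities along the transect
#'
#' Expected density of taxon t at station s is
#' `mean_density0 * exp(latitude_slope * (lat - ref_latitude) +
#' temp_affinity * T_s)` with `T_s` the station's 0-100 m mean temperature;
#' the realized density is drawn lognormally around that expectation
#' (mean-corrected, spread `scenario$density_sdlog`).
#'
#' @param pool taxon pool from [make_taxon_pool()].
#' @param scenario a `zp_scenario`.
#' @param env station environment table; defaults to
#'   [simulate_environment()] under the scenario seed.
#' @return stations x taxa matrix of realized densities (ind/m3) with the
#'   expectation attached as attribute `"expected"`.
#' @export
simulate_community <- function(pool, scenario, env = simulate_environment(scenario)) {
  st <- scenario$stations
  stopifnot(all(st$station %in% env$station))
  env <- env[match(st$station, env$station), ]
  dlat <- st$latitude - scenario$ref_latitude
  expected <- outer(seq_len(nrow(st)), seq_len(nrow(pool)),
                    function(i, j) {
                      pool$mean_density0[j] *
                        exp(pool$latitude_slope[j] * dlat[i] +
                            pool$temp_affinity[j] * env$mean_temperature[i])
                    })
  dimnames(expected) <- list(st$station, pool$taxon_id)
  set.seed(derive_seed(scenario$seed, 2L))
  sdl <- scenario$density_sdlog
  noise <- matrix(rnorm(length(expected), -sdl^2 / 2, sdl), nrow = nrow(expected))
  realized <- expected * exp(noise)
  attr(realized, "expected") <- expected
  realized
}

#' Simulate a net tow
#'
#' Catch counts are Poisson with mean `density * filtered_volume`,
#' independently per taxon (an explicit modelling assumption: the net is
#' treated as a random sampler of a well-mixed layer).
#'
#' @param density taxon density vector or stations x taxa matrix (ind/m3).
#' @param filtered_volume filtered water volume in m3 (scalar, or one value
#'   per station row).
#' @param seed integer seed.
#' @return integer counts, same shape as `density`.
#' @export
simulate_tow <- function(density, filtered_volume, seed = 1L) {
  if (any(filtered_volume < 0))
    abort_zp("filtered_volume must be non-negative", "zp_bad_input")
  set.seed(derive_seed(seed, 3L))
  if (is.matrix(density)) {
    mu <- density * filtered_volume  # recycles per-station volumes by row
    out <- matrix(rpois(length(mu), mu), nrow = nrow(mu),
                  dimnames = dimnames(density))
  } else {
    out <- rpois(length(density), density * filtered_volume)
    names(out) <- names(density)
  }
  out
}

#' Simulate individual imaged organisms
#'
#' Draws one row per caught individual: major axis lognormal with the
#' taxon's `length_meanlog`/`length_sdlog`, minor axis = major /
#' `aspect_ratio`, and lineage truncated to the taxon's imaging resolution
#' (what a human validator could name from the image).
#'
#' @param catch named taxon count vector (single station) or stations x
#'   taxa matrix from [simulate_tow()].
#' @param pool taxon pool.
#' @param seed integer seed.
#' @return data.frame of image objects: `object_id`, `station`, `taxon_id`
#'   (truth), `lineage` (truncated), `major`, `minor` (mm), `status`.
#' @export
simulate_individuals <- function(catch, pool, seed = 1L) {
  if (!is.matrix(catch)) {
    catch <- matrix(catch, nrow = 1, dimnames = list("st1", names(catch)))
  }
  stopifnot(!is.null(colnames(catch)),
            all(colnames(catch) %in% pool$taxon_id))
  set.seed(derive_seed(seed, 4L))
  lin_full <- parse_lineage(pool$lineage)
  blocks <- vector("list", nrow(catch) * ncol(catch))
  b <- 0L
  for (i in seq_len(nrow(catch))) {
    for (j in seq_len(ncol(catch))) {
      n <- catch[i, j]
      if (n <= 0) next
      pj <- match(colnames(catch)[j], pool$taxon_id)
      major <- rlnorm(n, pool$length_meanlog[pj], pool$length_sdlog[pj])
      obs_lin <- lineage_string(
        setNames(truncate_lineage(lin_full[pj, , drop = FALSE],
                                  pool$res_imaging[pj])[1, ], RANKS))
      b <- b + 1L
      blocks[[b]] <- data.frame(
        station = rownames(catch)[i],
        taxon_id = pool$taxon_id[pj],
        lineage = obs_lin,
        major = major,
        minor = major / pool$aspect_ratio[pj],
        status = "validated",
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (b) do.call(rbind, blocks[seq_len(b)]) else
    data.frame(station = character(), taxon_id = character(),
               lineage = character(), major = numeric(), minor = numeric(),
               status = character(), stringsAsFactors = FALSE)
  out <- cbind(object_id = sprintf("obj%07d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

## split factor 2^-k with n * 2^-k <= target, clamped at the Motoda floor
motoda_factor <- function(n, target, min_fraction) {
  if (n <= target) return(1)
  k <- ceiling(log2(n / target))
  max(2^-k, min_fraction)
}

#' Sieve fractionation and Motoda splitting
#'
#' Assigns each object to a size fraction by its major axis against the
#' sieve cutoffs (half-open intervals, top fraction open-ended), then
#' emulates Motoda splitting per station and fraction: the aliquot is
#' halved until the expected retained count is at or below
#' `target_particles_per_aliquot` or the floor `motoda_min_fraction` is
#' reached, and each object is retained independently with probability
#' equal to the split factor (which keeps split-corrected counts unbiased).
#' Objects below the smallest cutoff are assigned to `below-mesh` and
#' excluded from the retained set.
#'
#' @param objects data.frame from [simulate_individuals()].
#' @param scenario a `zp_scenario`.
#' @param seed integer seed.
#' @return list with `objects` (retained, plus `fraction` and `split`
#'   columns), `below_mesh` (excluded objects) and `split_table`
#'   (station x fraction: `n_total`, `split`, `n_retained`).
#' @export
sieve_and_split <- function(objects, scenario, seed = 1L) {
  co <- scenario$sieve_cutoffs_mm
  labs <- fraction_labels(scenario)
  idx <- findInterval(objects$major, co)  # 0 = below mesh
  objects$fraction <- ifelse(idx == 0, "below-mesh", labs[pmax(idx, 1L)])
  below <- objects[idx == 0, , drop = FALSE]
  kept <- objects[idx > 0, , drop = FALSE]

  set.seed(derive_seed(seed, 5L))
  groups <- split(seq_len(nrow(kept)),
                  list(station = kept$station, fraction = kept$fraction),
                  drop = TRUE)
  split_rows <- list()
  kept$split <- NA_real_
  retain <- logical(nrow(kept))
  for (g in names(groups)) {
    ii <- groups[[g]]
    f <- motoda_factor(length(ii), scenario$target_particles_per_aliquot,
                       scenario$motoda_min_fraction)
    keep <- runif(length(ii)) < f
    kept$split[ii] <- f
    retain[ii] <- keep
    split_rows[[g]] <- data.frame(
      station = kept$station[ii[1]], fraction = kept$fraction[ii[1]],
      n_total = length(ii), split = f, n_retained = sum(keep),
      stringsAsFactors = FALSE)
  }
  split_table <- do.call(rbind, split_rows)
  rownames(split_table) <- NULL
  list(objects = kept[retain, , drop = FALSE],
       below_mesh = below,
       split_table = split_table)
}

#' Simulate marker-specific sequence reads
#'
#' Per station and size fraction, a sequencing depth is drawn uniformly
#' from `scenario$seq_depth_range` and reads are allocated multinomially
#' with probabilities proportional to taxon dry mass times the taxon's
#' amplification efficiency for the marker (reads track biomass, not
#' abundance, with primer bias on top). Each taxon's reads are spread over
#' a small, globally fixed number of ASVs; non-metazoan background ASVs
#' take an expected `background_read_frac` of each library; and
#' `singletons_per_fraction` brand-new 1-read ASVs are injected per
#' library as noise so the singleton filter has work to do. ASV lineages
#' are truncated to the taxon's resolution for the marker.
#'
#' @param biomass 3-d array `stations x taxa x fractions` of dry mass (mg),
#'   or a taxa x fractions matrix for a single station.
#' @param pool taxon pool.
#' @param marker one of `"COI"`, `"V4"`, `"V9"`.
#' @param scenario a `zp_scenario`.
#' @param seed integer seed.
#' @param asv_per_taxon_range integer range of ASV counts per taxon
#'   (default 1-6 for COI, 1-3 for the 18S markers).
#' @return an [asv_table()].
#' @export
simulate_reads <- function(biomass, pool, marker, scenario, seed = 1L,
                           asv_per_taxon_range = NULL) {
  stopifnot(marker %in% c("COI", "V4", "V9"))
  if (length(dim(biomass)) == 2L) {
    biomass <- array(biomass, dim = c(1L, dim(biomass)),
                     dimnames = c(list("st1"), dimnames(biomass)))
  }
  stns <- dimnames(biomass)[[1]]
  taxa <- dimnames(biomass)[[2]]
  fracs <- dimnames(biomass)[[3]]
  stopifnot(all(taxa %in% pool$taxon_id))
  if (any(scenario$seq_depth_range <= 0))
    abort_zp("sequencing depth must be positive", "zp_bad_input")
  asv_per_taxon_range <- asv_per_taxon_range %||%
    if (marker == "COI") c(1L, 6L) else c(1L, 3L)

  set.seed(derive_seed(seed, 6L + match(marker, c("COI", "V4", "V9"))))
  pj <- match(taxa, pool$taxon_id)
  eff <- pool[[paste0("amp_", marker)]][pj]
  res <- pool[[paste0("res_", marker)]][pj]
  lin_full <- parse_lineage(pool$lineage[pj])

  ## globally fixed ASV structure per taxon: ids, within-taxon weights
  n_asv <- sample(seq(asv_per_taxon_range[1], asv_per_taxon_range[2]),
                  length(taxa), replace = TRUE)
  asv_id <- list(); asv_w <- list(); asv_lin <- character(0)
  for (j in seq_along(taxa)) {
    ids <- sprintf("%s_t%02d_a%02d", marker, j, seq_len(n_asv[j]))
    w <- 0.5^(seq_len(n_asv[j]) - 1)  # dominant haplotype + minor variants
    asv_id[[j]] <- ids
    asv_w[[j]] <- w / sum(w)
    tl <- lineage_string(setNames(
      truncate_lineage(lin_full[j, , drop = FALSE], res[j])[1, ], RANKS))
    asv_lin <- c(asv_lin, rep(tl, n_asv[j]))
  }
  bg_phyla <- c("Bacillariophyta", "Dinoflagellata", "Haptophyta")
  bg_ids <- sprintf("%s_bg_%02d", marker, seq_along(bg_phyla))
  bg_lin <- vapply(bg_phyla, function(p) lin(p = p), character(1))

  all_ids <- c(unlist(asv_id), bg_ids)
  all_lin <- c(asv_lin, bg_lin)
  counts <- matrix(0L, nrow = length(all_ids), ncol = 0)
  rownames(counts) <- all_ids
  col_station <- character(0); col_fraction <- character(0)
  extra_singletons <- list()

  for (s in seq_along(stns)) for (f in seq_along(fracs)) {
    depth <- as.integer(round(runif(1, scenario$seq_depth_range[1],
                                    scenario$seq_depth_range[2])))
    w_tax <- biomass[s, , f] * eff
    ## expand to ASV-level weights, append background
    w_asv <- unlist(lapply(seq_along(taxa), function(j) w_tax[j] * asv_w[[j]]))
    tot <- sum(w_asv)
    bg <- scenario$background_read_frac
    w_bg <- if (tot > 0 && bg > 0) rep(bg / (1 - bg) * tot / length(bg_ids),
                                       length(bg_ids)) else rep(0, length(bg_ids))
    w <- c(w_asv, w_bg)
    n_single <- min(scenario$singletons_per_fraction, depth)
    col <- integer(length(all_ids))
    if (sum(w) > 0 && depth > n_single) {
      col <- as.integer(rmultinom(1, depth - n_single, w))
    }
    counts <- cbind(counts, col)
    col_station <- c(col_station, stns[s])
    col_fraction <- c(col_fraction, fracs[f])
    if (n_single > 0) {
      sj <- sample(seq_along(taxa), n_single, replace = TRUE)
      extra_singletons[[length(extra_singletons) + 1L]] <- data.frame(
        id = sprintf("%s_noise_%s_%s_%02d", marker, stns[s], fracs[f],
                     seq_len(n_single)),
        lin = asv_lin[cumsum(n_asv)[sj]],  # an existing taxon's (truncated) lineage
        col = ncol(counts), stringsAsFactors = FALSE)
    }
  }
  ## append injected singleton ASVs (brand-new ids, 1 read each)
  if (length(extra_singletons)) {
    es <- do.call(rbind, extra_singletons)
    add <- matrix(0L, nrow = nrow(es), ncol = ncol(counts),
                  dimnames = list(es$id, NULL))
    add[cbind(seq_len(nrow(es)), es$col)] <- 1L
    counts <- rbind(counts, add)
    all_lin <- c(all_lin, es$lin)
  }
  colnames(counts) <- paste(col_station, col_fraction, sep = "_")
  keep <- rowSums(counts) > 0
  asv_table(marker, counts[keep, , drop = FALSE], all_lin[keep],
            col_station, col_fraction)
}
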