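## Scenario configuration for the forward simulator.

#' Default station transect
#'
#' Twelve stations on a Barents Sea -> Nansen Basin -> Yermak Plateau
#' transect (80.8-83.7 degrees N), grouped into the regions BS, SNB, NB and
#' YP. Environmental covariates are generated from latitude by
#' [simulate_environment()].
#'
#' @return data.frame with columns `station`, `latitude`, `longitude`,
#'   `region`.
#' @export
default_stations <- function() {
  data.frame(
    station  = paste0("st", c(52, 64, 65, 67, 70, 71, 72, 73, 74, 76, 77, 78)),
    latitude = c(80.826, 81.414, 81.595, 81.954, 83.119, 83.334,
                 83.501, 83.714, 83.468, 82.490, 82.245, 82.050),
    longitude = c(31.954, 32.612, 33.207, 32.331, 32.924, 33.238,
                  32.981, 32.337, 28.085, 18.224, 17.782, 17.644),
    region = c("BS", "BS", "BS", "SNB", "NB", "NB", "NB", "NB", "NB",
               "YP", "YP", "YP"),
    stringsAsFactors = FALSE
  )
}

#' Build a simulation scenario
#'
#' Collects every knob of the observation chain: the station transect, the
#' net geometry used to derive filtered volume, the sieve cutoffs, the
#' Motoda-splitting floor and target aliquot size, and the per-fraction
#' sequencing-depth range.
#'
#' Defaults state the study design being emulated: a 1 m2 net towed at
#' 2.5 knots for ~10 min (filtered volume ~770 m3, inside the reported
#' 651-1443 m3 range), sieves at 0.5/1/2/4 mm, Motoda splitting down to at
#' most 1/256 aiming at ~1000 particles per scanned aliquot, and sequencing
#' depths of 30k-100k reads per size fraction.
#'
#' @param stations data.frame as [default_stations()]; must have `station`,
#'   `latitude` and optionally `longitude`, `region`.
#' @param net_area_m2 effective net opening (m2).
#' @param tow_speed_knots towing speed (knots).
#' @param tow_duration_s tow duration (s).
#' @param sieve_cutoffs_mm strictly increasing sieve cutoffs (mm); objects
#'   below the smallest cutoff are treated as below-mesh and excluded.
#' @param motoda_min_fraction smallest allowed Motoda aliquot, a power of
#'   1/2 (default 1/256).
#' @param target_particles_per_aliquot stop halving once the expected
#'   retained count is at or below this (default 1000).
#' @param seq_depth_range length-2 integer vector, per-fraction sequencing
#'   depth drawn uniformly from this range.
#' @param ref_latitude latitude at which `mean_density0` of a taxon applies.
#' @param density_sdlog lognormal spread of realized around expected density.
#' @param background_read_frac expected fraction of non-metazoan reads per
#'   library (emulates the <9 percent non-target signal in real libraries).
#' @param singletons_per_fraction count of injected 1-read noise ASVs per
#'   sequenced fraction.
#' @param seed integer; fixes all randomness downstream.
#' @return object of class `zp_scenario` (a list).
#' @export
scenario_config <- function(stations = default_stations(),
                            net_area_m2 = 1,
                            tow_speed_knots = 2.5,
                            tow_duration_s = 600,
                            sieve_cutoffs_mm = c(0.5, 1, 2, 4),
                            motoda_min_fraction = 1 / 256,
                            target_particles_per_aliquot = 1000,
                            seq_depth_range = c(30000L, 100000L),
                            ref_latitude = 80.8,
                            density_sdlog = 0.25,
                            background_read_frac = 0.05,
                            singletons_per_fraction = 5L,
                            seed = 1L) {
  stopifnot(is.data.frame(stations),
            all(c("station", "latitude") %in% names(stations)))
  if (any(diff(sieve_cutoffs_mm) <= 0))
    abort_zp("sieve cutoffs must be strictly increasing", "zp_bad_scenario")
  k <- -log2(motoda_min_fraction)
  if (abs(k - round(k)) > 1e-9 || motoda_min_fraction > 1)
    abort_zp("motoda_min_fraction must be 2^-k", "zp_bad_scenario")
  if (length(seq_depth_range) != 2L || any(seq_depth_range <= 0))
    abort_zp("seq_depth_range must be two positive numbers", "zp_bad_scenario")
  structure(list(
    stations = stations,
    net_area_m2 = net_area_m2,
    tow_speed_knots = tow_speed_knots,
    tow_duration_s = tow_duration_s,
    sieve_cutoffs_mm = sieve_cutoffs_mm,
    motoda_min_fraction = motoda_min_fraction,
    target_particles_per_aliquot = target_particles_per_aliquot,
    seq_depth_range = as.integer(seq_depth_range),
    ref_latitude = ref_latitude,
    density_sdlog = density_sdlog,
    background_read_frac = background_read_frac,
    singletons_per_fraction = as.integer(singletons_per_fraction),
    seed = as.integer(seed)
  ), class = "zp_scenario")
}

#' Size-fraction labels implied by the sieve cutoffs
#'
#' @param scenario a `zp_scenario`.
#' @return character vector, e.g. `"0.5-1" "1-2" "2-4" "4+"`.
#' @export
fraction_labels <- function(scenario) {
  co <- scenario$sieve_cutoffs_mm
  n <- length(co)
  c(paste0(co[-n], "-", co[-1]), paste0(co[n], "+"))
}

#' Generate station environmental covariates from latitude
#'
#' Emulates the hydrography of the emulated transect: temperature, salinity
#' and fluorescence (0-100 m means) decline northwards while sea-ice
#' thickness and the Polar Surface Water contribution increase. Small
#' station-level noise is added deterministically under the scenario seed.
#'
#' @param scenario a `zp_scenario`.
#' @return data.frame: `station`, `latitude`, `mean_temperature`,
#'   `mean_salinity`, `mean_fluorescence`, `mean_ice_thickness`, `pct_PSW`.
#' @export
simulate_environment <- function(scenario) {
  st <- scenario$stations
  dlat <- st$latitude - scenario$ref_latitude
  set.seed(derive_seed(scenario$seed, 11L))
  n <- nrow(st)
  data.frame(
    station = st$station,
    latitude = st$latitude,
    mean_temperature = round(2.0 - 1.1 * dlat + rnorm(n, 0, 0.15), 3),
    mean_salinity = round(34.6 - 0.25 * dlat + rnorm(n, 0, 0.05), 3),
    mean_fluorescence = round(pmax(0.05, 1.2 - 0.32 * dlat + rnorm(n, 0, 0.08)), 3),
    mean_ice_thickness = round(pmax(0, 0.15 + 0.45 * dlat + rnorm(n, 0, 0.08)), 3),
    pct_PSW = round(pmin(100, pmax(0, 10 + 26 * dlat + rnorm(n, 0, 4))), 2),
    stringsAsFactors = FALSE
  )
}
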