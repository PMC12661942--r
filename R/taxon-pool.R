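## Taxon pool for the forward simulator. Each row of the pool is one
## simulated taxon with its abundance gradient, body-size distribution,
## wet-to-dry conversion factor, per-marker amplification efficiency and
## per-method taxonomic resolution.

pool_columns <- c("taxon_id", "lineage", "mean_density0", "latitude_slope",
                  "temp_affinity", "length_meanlog", "length_sdlog",
                  "aspect_ratio", "conversion_factor",
                  "amp_COI", "amp_V4", "amp_V9",
                  "res_COI", "res_V4", "res_V9", "res_imaging")

lin <- function(p = "", c = "", o = "", f = "", g = "", s = "") {
  lineage_string(c(phylum = p, class = c, order = o, family = f,
                   genus = g, species = s))
}

## Curated core community: an Arctic Calanus-dominated assemblage. The
## first taxon is the large-bodied Calanus hyperboreus analogue with its
## reduced wet-to-dry conversion factor (0.08 vs the copepod default 0.16);
## the second is a hydrozoan invisible to the V4 marker. Densities are
## individuals per m3 at the reference (southernmost) latitude; slopes are
## log-density change per degree latitude northwards.
core_pool <- function() {
  cop <- function(f, g, s) lin("Arthropoda", "Copepoda", "Calanoida", f, g, s)
  rows <- list(
    list("Calanus hyperboreus", cop("Calanidae", "Calanus", "Calanus hyperboreus"),
         12, 0.05, -0.08, log(6.0), 0.25, 3.2, 0.08,
         0.9, 1.0, 1.0, "species", "family", "family", "species"),
    list("Aglantha digitale",
         lin("Cnidaria", "Hydrozoa", "Trachymedusae", "Rhopalonematidae",
             "Aglantha", "Aglantha digitale"),
         2, -0.40, 0.05, log(5.0), 0.30, 1.6, 0.04,
         1.2, 0.0, 0.6, "species", "family", "order", "species"),
    list("Calanus finmarchicus", cop("Calanidae", "Calanus", "Calanus finmarchicus"),
         25, -0.50, 0.12, log(2.6), 0.20, 3.0, 0.16,
         1.0, 1.0, 1.0, "species", "family", "family", "species"),
    list("Calanus glacialis", cop("Calanidae", "Calanus", "Calanus glacialis"),
         15, -0.30, 0.05, log(3.6), 0.20, 3.1, 0.16,
         1.0, 1.0, 1.0, "species", "family", "family", "species"),
    list("Pseudocalanus minutus",
         cop("Clausocalanidae", "Pseudocalanus", "Pseudocalanus minutus"),
         10, -0.45, 0.10, log(1.1), 0.20, 2.8, 0.16,
         1.1, 0.9, 0.9, "species", "family", "order", "genus"),
    list("Metridia longa", cop("Metridinidae", "Metridia", "Metridia longa"),
         6, -0.25, 0.00, log(2.2), 0.22, 3.0, 0.16,
         0.8, 1.0, 1.0, "species", "family", "order", "species"),
    list("Oithona similis",
         lin("Arthropoda", "Copepoda", "Cyclopoida", "Oithonidae",
             "Oithona", "Oithona similis"),
         8, -0.50, 0.10, log(0.75), 0.18, 2.5, 0.16,
         1.2, 0.8, 0.8, "species", "family", "order", "genus"),
    list("Oikopleura vanhoeffeni",
         lin("Chordata", "Appendicularia", "Copelata", "Oikopleuridae",
             "Oikopleura", "Oikopleura vanhoeffeni"),
         2, -0.35, 0.05, log(1.8), 0.30, 1.8, 0.05,
         0.0, 0.05, 0.0, "species", "family", "order", "genus"),
    list("Parasagitta elegans",
         lin("Chaetognatha", "Sagittoidea", "Aphragmophora", "Sagittidae",
             "Parasagitta", "Parasagitta elegans"),
         3, -0.35, 0.05, log(12), 0.25, 8.0, 0.10,
         0.9, 1.0, 1.0, "species", "family", "family", "species"),
    list("Eukrohnia hamata",
         lin("Chaetognatha", "Sagittoidea", "Phragmophora", "Eukrohniidae",
             "Eukrohnia", "Eukrohnia hamata"),
         2, -0.12, -0.05, log(10), 0.25, 9.0, 0.10,
         0.9, 1.0, 1.0, "species", "family", "family", "species"),
    list("Limacina helicina",
         lin("Mollusca", "Gastropoda", "Pteropoda", "Limacinidae",
             "Limacina", "Limacina helicina"),
         4, -0.45, 0.08, log(1.4), 0.28, 1.15, 0.28,
         1.0, 1.0, 1.0, "species", "family", "order", "species"),
    list("Themisto libellula",
         lin("Arthropoda", "Malacostraca", "Amphipoda", "Hyperiidae",
             "Themisto", "Themisto libellula"),
         1.5, -0.18, -0.02, log(8), 0.30, 3.5, 0.16,
         1.0, 1.0, 1.0, "species", "family", "family", "species"),
    list("Paraeuchaeta glacialis",
         cop("Euchaetidae", "Paraeuchaeta", "Paraeuchaeta glacialis"),
         2, -0.20, 0.00, log(4.5), 0.22, 3.3, 0.16,
         0.9, 1.0, 1.0, "species", "family", "order", "species"),
    list("Mertensia ovum",
         lin("Ctenophora", "Tentaculata", "Cydippida", "Mertensiidae",
             "Mertensia", "Mertensia ovum"),
         0.8, -0.15, -0.03, log(9), 0.35, 1.3, 0.03,
         0.8, 0.9, 0.9, "species", "order", "order", "phylum"),
    list("Microcalanus pygmaeus",
         cop("Clausocalanidae", "Microcalanus", "Microcalanus pygmaeus"),
         6, -0.40, 0.08, log(0.7), 0.15, 2.6, 0.16,
         1.0, 0.9, 0.9, "species", "family", "order", "genus"),
    list("Clione limacina",
         lin("Mollusca", "Gastropoda", "Pteropoda", "Clionidae",
             "Clione", "Clione limacina"),
         0.8, -0.25, 0.02, log(6), 0.30, 2.4, 0.06,
         1.0, 1.0, 1.0, "species", "family", "order", "species")
  )
  df <- as.data.frame(do.call(rbind, lapply(rows, function(r) {
    setNames(as.list(r), pool_columns)
  })), stringsAsFactors = FALSE)
  for (col in pool_columns) df[[col]] <- unlist(df[[col]], use.names = FALSE)
  num <- c("mean_density0", "latitude_slope", "temp_affinity", "length_meanlog",
           "length_sdlog", "aspect_ratio", "conversion_factor",
           "amp_COI", "amp_V4", "amp_V9")
  for (col in num) df[[col]] <- as.numeric(df[[col]])
  df
}

#' Build a taxon pool for the forward simulator
#'
#' Returns `n_taxa` taxon specifications. Up to 16 taxa come from a curated
#' Arctic assemblage whose first members guarantee the structural features
#' the downstream tests rely on: a large-bodied taxon with a distinct
#' (halved) conversion factor, and a taxon with zero amplification
#' efficiency for one marker. Additional taxa beyond the curated set are
#' drawn at random, deterministically under `seed`.
#'
#' Random extras form a rare tail: reference densities log-uniform on
#' 0.01-1 ind/m3 with steep northward declines, so some taxa drop below
#' detection at northern stations in every stream -- the presence/absence
#' structure real assemblages show.
#'
#' @param n_taxa number of taxa, at least 2 (default 30: the curated head
#'   plus a rare tail).
#' @param seed integer seed; the pool is bit-identical under the same seed.
#' @return data.frame with one row per taxon; columns include `lineage`
#'   (rank-prefixed string), `mean_density0` (ind/m3 at the reference
#'   latitude), `latitude_slope` (per degree), `temp_affinity`,
#'   `length_meanlog`/`length_sdlog` (lognormal major axis, mm),
#'   `aspect_ratio`, `conversion_factor` (wet to dry, in (0,1]),
#'   `amp_COI`/`amp_V4`/`amp_V9` (relative amplification weights, 0 =
#'   marker-blind) and `res_*` (deepest reported rank per method).
#' @export
make_taxon_pool <- function(n_taxa = 30L, seed = 1L) {
  if (!is.numeric(n_taxa) || n_taxa < 2)
    abort_zp("n_taxa must be at least 2", "zp_bad_scenario")
  n_taxa <- as.integer(n_taxa)
  base <- core_pool()
  if (n_taxa <= nrow(base)) return(base[seq_len(n_taxa), , drop = FALSE])
  n_extra <- n_taxa - nrow(base)
  set.seed(derive_seed(seed, 1L))
  phyla <- c("Arthropoda", "Mollusca", "Annelida", "Cnidaria", "Chordata")
  cls <- c(Arthropoda = "Copepoda", Mollusca = "Gastropoda",
           Annelida = "Polychaeta", Cnidaria = "Hydrozoa",
           Chordata = "Appendicularia")
  extra <- lapply(seq_len(n_extra), function(i) {
    p <- sample(phyla, 1)
    g <- sprintf("Genus%02d", i)
    s <- sprintf("%s sp%02d", g, i)
    data.frame(
      taxon_id = s,
      lineage = lin(p, cls[[p]], paste0(cls[[p]], "iformes"),
                    paste0(g, "idae"), g, s),
      mean_density0 = round(exp(runif(1, log(0.01), log(1))), 4),
      latitude_slope = round(runif(1, -0.9, -0.2), 3),
      temp_affinity = round(runif(1, -0.05, 0.12), 3),
      length_meanlog = round(log(runif(1, 0.8, 5)), 3),
      length_sdlog = round(runif(1, 0.15, 0.35), 3),
      aspect_ratio = round(runif(1, 1.2, 4), 2),
      conversion_factor = round(runif(1, 0.05, 0.3), 3),
      amp_COI = round(runif(1, 0.3, 1.5), 3),
      amp_V4 = round(runif(1, 0.3, 1.5), 3),
      amp_V9 = round(runif(1, 0.3, 1.5), 3),
      res_COI = "species", res_V4 = "family",
      res_V9 = sample(c("order", "family"), 1),
      res_imaging = sample(c("species", "genus", "family"), 1),
      stringsAsFactors = FALSE
    )
  })
  rbind(base, do.call(rbind, extra))
}
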