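test_that("taxon pool is deterministic and carries the required structure", {
  expect_error(make_taxon_pool(1), class = "zp_bad_scenario")

  p1 <- make_taxon_pool(2, seed = 1)
  p2 <- make_taxon_pool(2, seed = 1)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 2)

  pool <- make_taxon_pool(20, seed = 7)
  expect_identical(pool, make_taxon_pool(20, seed = 7))
  # marker-blind taxon and the large-bodied distinct-conversion-factor taxon
  expect_true(any(pool$amp_V4 == 0))
  big <- which.max(pool$length_meanlog * 0 + exp(pool$length_meanlog))
  expect_true(any(pool$conversion_factor == 0.08))
  # every lineage resolves a phylum
  expect_true(all(parse_lineage(pool$lineage)[, "phylum"] != ""))
  # invariants
  expect_true(all(pool$mean_density0 >= 0))
  expect_true(all(pool$aspect_ratio >= 1))
  expect_true(all(pool$conversion_factor > 0 & pool$conversion_factor <= 1))
})

test_that("community expectation follows the stated gradient model", {
  pool <- make_taxon_pool(6, seed = 1)
  stations <- data.frame(station = paste0("s", 1:5),
                         latitude = seq(80, 84, by = 1),
                         longitude = 30, region = "X")
  sc <- scenario_config(stations = stations, seed = 3)
  env <- simulate_environment(sc)

  flat <- pool
  flat$latitude_slope <- 0
  flat$temp_affinity <- 0
  d <- simulate_community(flat, sc, env)
  exp_d <- attr(d, "expected")
  for (j in seq_len(ncol(exp_d)))
    expect_equal(unname(exp_d[, j]), rep(flat$mean_density0[j], 5))

  down <- pool
  down$latitude_slope <- runif(nrow(pool), -0.5, -0.1)
  down$temp_affinity <- 0
  d2 <- simulate_community(down, sc, env)
  totals <- rowSums(attr(d2, "expected"))
  expect_true(all(diff(totals[order(stations$latitude)]) < 0))

  expect_identical(simulate_community(pool, sc, env),
                   simulate_community(pool, sc, env))
})

test_that("tow catch is Poisson in density and volume", {
  expect_error(simulate_tow(c(a = 1), -5), class = "zp_bad_input")
  expect_identical(unname(simulate_tow(c(a = 0, b = 0), 100, seed = 4)),
                   c(0L, 0L))
  # Monte-Carlo mean against the Poisson expectation, 3 s.e.
  n_rep <- 10000
  counts <- simulate_tow(setNames(rep(1, n_rep), paste0("t", 1:n_rep)),
                         100, seed = 11)
  se <- sd(counts) / sqrt(n_rep)
  expect_lt(abs(mean(counts) - 100), 3 * se)
  # doubling the volume doubles the mean
  counts2 <- simulate_tow(setNames(rep(1, n_rep), paste0("t", 1:n_rep)),
                          200, seed = 12)
  se2 <- sqrt(sd(counts)^2 + sd(counts2)^2) / sqrt(n_rep)
  expect_lt(abs(mean(counts2) - 2 * mean(counts)), 3 * se2)
})

test_that("individual sizes follow the taxon body-size model", {
  pool <- make_taxon_pool(3, seed = 1)
  pool$aspect_ratio <- 1
  obj <- simulate_individuals(c(`Calanus hyperboreus` = 50), pool, seed = 2)
  expect_equal(obj$major, obj$minor)

  pool2 <- make_taxon_pool(3, seed = 1)
  pool2$length_sdlog <- 0
  obj2 <- simulate_individuals(c(`Aglantha digitale` = 20), pool2, seed = 2)
  expect_equal(obj2$major,
               rep(exp(pool2$length_meanlog[pool2$taxon_id == "Aglantha digitale"]), 20))

  pool3 <- make_taxon_pool(3, seed = 1)
  pool3$length_meanlog <- 0
  pool3$length_sdlog <- 0.3
  obj3 <- simulate_individuals(c(`Calanus finmarchicus` = 10000), pool3, seed = 5)
  expect_lt(abs(median(obj3$major) - 1), 0.01)  # lognormal median = exp(meanlog)

  # imaging-resolution truncation
  pool4 <- make_taxon_pool(5, seed = 1)
  obj4 <- simulate_individuals(c(`Pseudocalanus minutus` = 5), pool4, seed = 1)
  lin <- parse_lineage(obj4$lineage)
  expect_true(all(lin[, "species"] == ""))   # genus-level imaging resolution
  expect_true(all(lin[, "genus"] == "Pseudocalanus"))
})

test_that("sieving assigns half-open fractions and Motoda splitting clamps", {
  sc <- scenario_config(seed = 1)
  mk_obj <- function(major, station = "s1") {
    data.frame(object_id = paste0("o", seq_along(major)), station = station,
               taxon_id = "x", lineage = "p__A", major = major,
               minor = major / 2, status = "validated",
               stringsAsFactors = FALSE)
  }
  # boundary values: cutoffs are half-open [lo, hi)
  res <- sieve_and_split(mk_obj(c(0.4, 0.5, 1, 2, 4, 7)), sc, seed = 1)
  expect_equal(nrow(res$below_mesh), 1)
  expect_equal(res$objects$fraction[res$objects$major == 0.5], "0.5-1")
  expect_equal(res$objects$fraction[res$objects$major == 1], "1-2")
  expect_equal(res$objects$fraction[res$objects$major == 4], "4+")

  # 100 objects, target 1000 -> no splitting
  res100 <- sieve_and_split(mk_obj(runif(100, 1, 2)), sc, seed = 1)
  expect_true(all(res100$split_table$split == 1))
  expect_equal(nrow(res100$objects), 100)

  # 1e6 objects in one fraction -> 1/1024 needed, clamped to the 1/256 floor
  resM <- sieve_and_split(mk_obj(rep(1.5, 1e6)), sc, seed = 1)
  expect_equal(resM$split_table$split, 1 / 256)

  # binomial retention mean: 2000 objects, split 1/2, 3 s.e. over 1e3 reps
  ret <- vapply(seq_len(1000), function(i) {
    nrow(sieve_and_split(mk_obj(runif(2000, 1, 2)), sc, seed = i)$objects)
  }, numeric(1))
  expect_lt(abs(mean(ret) - 1000), 3 * sd(ret) / sqrt(length(ret)))
})

test_that("reads are biomass-proportional with amplification bias", {
  pool <- make_taxon_pool(4, seed = 1)
  sc <- scenario_config(seq_depth_range = c(10000L, 10000L),
                        background_read_frac = 0,
                        singletons_per_fraction = 0L, seed = 1)
  bm <- matrix(c(5, 1, 2, 0.5), nrow = 4,
               dimnames = list(pool$taxon_id, "1-2"))
  tab <- simulate_reads(bm, pool, "V4", sc, seed = 1)
  # marker-blind taxon (Aglantha, amp_V4 = 0) yields no reads
  agl <- grepl("_t02_", rownames(tab$counts))
  expect_true(all(tab$counts[agl, ] == 0))
  # conservation at fixed depth
  expect_equal(unname(colSums(tab$counts)), 10000)
  # determinism
  tab2 <- simulate_reads(bm, pool, "V4", sc, seed = 1)
  expect_identical(tab$counts, tab2$counts)
  # depth must be positive
  sc_bad <- sc; sc_bad$seq_depth_range <- c(0L, 0L)
  expect_error(simulate_reads(bm, pool, "V4", sc_bad, seed = 1),
               class = "zp_bad_input")
})

test_that("expected read ratio matches the biomass ratio (Monte Carlo)", {
  pool <- make_taxon_pool(2, seed = 1)
  pool$amp_COI <- 1
  sc <- scenario_config(seq_depth_range = c(100000L, 100000L),
                        background_read_frac = 0,
                        singletons_per_fraction = 0L, seed = 1)
  bm <- matrix(c(3, 1), nrow = 2, dimnames = list(pool$taxon_id, "1-2"))
  ratios <- vapply(seq_len(1000), function(i) {
    tab <- simulate_reads(bm, pool, "COI", sc, seed = i,
                          asv_per_taxon_range = c(1L, 1L))
    r1 <- sum(tab$counts[grepl("_t01_", rownames(tab$counts)), ])
    r2 <- sum(tab$counts[grepl("_t02_", rownames(tab$counts)), ])
    r1 / r2
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 3), 3 * sd(ratios) / sqrt(length(ratios)))
})

test_that("ASV lineages never exceed the marker's resolution", {
  pool <- make_taxon_pool(10, seed = 2)
  sc <- small_scenario(seed = 2)
  bm <- matrix(runif(10 * 2, 0.5, 3), nrow = 10,
               dimnames = list(pool$taxon_id, c("1-2", "2-4")))
  for (mk in c("COI", "V4", "V9")) {
    tab <- simulate_reads(bm, pool, mk, sc, seed = 2)
    depth_rank <- setNames(match(pool[[paste0("res_", mk)]],
                                 c("phylum", "class", "order", "family",
                                   "genus", "species")), pool$taxon_id)
    lin <- parse_lineage(tab$lineage)
    own <- grepl("_t[0-9]+_", rownames(tab$counts))
    tx_idx <- as.integer(sub(".*_t([0-9]+)_.*", "\\1", rownames(tab$counts)[own]))
    deepest <- apply(lin[own, , drop = FALSE] != "", 1, function(z)
      if (any(z)) max(which(z)) else 0L)
    expect_true(all(deepest <= depth_rank[pool$taxon_id[tx_idx]]))
  }
})

test_that("generate_dataset writes a complete, re-readable, reproducible set", {
  pool <- make_taxon_pool(8, seed = 5)
  sc <- small_scenario(seed = 5)
  d1 <- file.path(tempdir(), "zp_gen1")
  d2 <- file.path(tempdir(), "zp_gen2")
  unlink(c(d1, d2), recursive = TRUE)
  res <- generate_dataset(sc, pool, d1)
  generate_dataset(sc, pool, d2)

  files <- c("objects.tsv", "asv_COI.tsv", "asv_V4.tsv", "asv_V9.tsv",
             "env.tsv", "stations.tsv", "conversion_factors.tsv",
             "truth_density.tsv", "truth_biomass.tsv", "scenario.yml")
  expect_true(all(file.exists(file.path(d1, files))))
  # byte-identical rerun under the same seed
  for (f in files)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  # re-readable by the package readers
  obj <- read_objects(file.path(d1, "objects.tsv"))
  expect_true(all(c("station", "major", "minor", "lineage", "split") %in%
                    names(obj)))
  tab <- read_asv_table(file.path(d1, "asv_COI.tsv"))
  expect_identical(tab$counts, res$asv$COI$counts)
  # 12 stations x 4 fractions of libraries per marker
  expect_equal(ncol(tab$counts), 12 * 4)
  # truth biomass positive wherever organisms were caught
  tb <- read_tsv_meta(file.path(d1, "truth_biomass.tsv"))
  caught <- table(res$objects$taxon_id[res$objects$status == "validated"],
                  res$objects$station[res$objects$status == "validated"])
  for (tx in rownames(caught)) for (st in colnames(caught)) {
    if (caught[tx, st] > 0)
      expect_gt(tb$dry_mass_mg[tb$taxon == tx & tb$station == st], 0)
  }
  unlink(c(d1, d2), recursive = TRUE)
})
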