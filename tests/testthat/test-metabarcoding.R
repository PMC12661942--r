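mk_table <- function(counts, lineage, marker = "COI") {
  asv_table(marker, counts, lineage)
}

lin_met <- "p__Arthropoda;c__Copepoda;o__Calanoida;f__Calanidae;g__Calanus;s__Calanus glacialis"
lin_non <- "p__Bacillariophyta;c__;o__;f__;g__;s__"

test_that("singleton removal drops dataset-wide singletons only", {
  counts <- rbind(a = c(1L, 0L), b = c(5L, 3L), c = c(0L, 6L))
  colnames(counts) <- c("s1_1-2", "s1_2-4")
  tab <- mk_table(counts, rep(lin_met, 3))
  out <- remove_singletons(tab)
  rep_ <- attr(out, "report")
  expect_equal(rownames(out$counts), c("b", "c"))  # only "a" totals <= 1
  expect_equal(rep_$dropped_asvs, 1)
  expect_equal(rep_$dropped_reads, 1)
  # threshold 0 is the identity
  out0 <- remove_singletons(tab, threshold = 0)
  expect_identical(out0$counts, tab$counts)
  # note: ASV "b" totals 8 spread as (5, 3): per-sample ones never count
  out_b <- remove_singletons(mk_table(matrix(c(1, 1), 1,
                                             dimnames = list("x", c("s1_a", "s1_b"))),
                                      lin_met))
  expect_equal(nrow(out_b$counts), 1)  # total 2 > 1, kept
})

test_that("injected synthetic singletons are exactly what the filter removes", {
  pool <- make_taxon_pool(6, seed = 3)
  sc <- scenario_config(seq_depth_range = c(5000L, 5000L),
                        singletons_per_fraction = 4L, seed = 3)
  bm <- matrix(runif(12, 1, 5), nrow = 6,
               dimnames = list(pool$taxon_id, c("1-2", "2-4")))
  tab <- simulate_reads(bm, pool, "COI", sc, seed = 3)
  noise <- grepl("_noise_", rownames(tab$counts))
  expect_equal(sum(noise), 8)  # 4 per fraction x 2 fractions
  out <- remove_singletons(tab)
  expect_false(any(grepl("_noise_", rownames(out$counts))))
})

test_that("metazoan filter keeps the configured phyla and reports percentages", {
  counts <- matrix(c(90, 10, 60, 40), nrow = 2, byrow = TRUE,
                   dimnames = list(c("m", "n"), c("s1_1-2", "s1_2-4")))
  tab <- mk_table(counts, c(lin_met, lin_non))
  out <- filter_metazoa(tab)
  rep_ <- attr(out, "report")
  expect_equal(rownames(out$counts), "m")
  expect_equal(rep_$pct_reads, 50)     # 100 of 200 reads
  expect_equal(rep_$pct_asvs, 50)
  # all-metazoan input is the identity
  all_met <- mk_table(counts, c(lin_met, lin_met))
  expect_identical(filter_metazoa(all_met)$counts, all_met$counts)
  expect_error(filter_metazoa(tab, phyla = character(0)),
               class = "zp_bad_input")
})

test_that("NSRA scales each fraction to the station minimum and merges", {
  # worked example: depths (1000, 4000), ASV A = (100, 2000) -> 100 + 500
  counts <- matrix(c(100, 900, 2000, 2000), nrow = 2,
                   dimnames = list(c("A", "B"), c("0.5-1", "1-2")))
  res <- nsra_scale_merge(counts)
  expect_equal(unname(res$nsra["A"]), 600)
  expect_equal(res$report$d_min, c(1000, 1000))
  expect_equal(res$report$scale, c(1, 0.25))

  # single fraction: identity
  one <- matrix(c(10, 30), ncol = 1, dimnames = list(c("A", "B"), "1-2"))
  expect_equal(unname(nsra_scale_merge(one)$nsra), c(10, 30))

  # equal depths: plain sum
  eq <- matrix(c(10, 90, 40, 60), nrow = 2,
               dimnames = list(c("A", "B"), c("f1", "f2")))
  expect_equal(unname(nsra_scale_merge(eq)$nsra), c(50, 150))

  # zero-depth fraction dropped with warning
  z <- matrix(c(10, 90, 0, 0), nrow = 2,
              dimnames = list(c("A", "B"), c("f1", "f2")))
  expect_warning(rz <- nsra_scale_merge(z), "ZP_W01")
  expect_equal(unname(rz$nsra), c(10, 90))
  expect_error(suppressWarnings(
    nsra_scale_merge(matrix(0, 2, 2,
                            dimnames = list(c("A", "B"), c("f1", "f2"))))),
    class = "zp_bad_input")
})

test_that("NSRA conservation and proportion preservation hold on random tables", {
  set.seed(7)
  for (rep_i in 1:20) {
    n_asv <- sample(3:12, 1)
    n_fr <- sample(2:4, 1)
    counts <- matrix(rpois(n_asv * n_fr, lambda = 50), n_asv, n_fr,
                     dimnames = list(paste0("a", seq_len(n_asv)),
                                     paste0("f", seq_len(n_fr))))
    counts[, 1] <- counts[, 1] + 1  # ensure positive depth
    res <- nsra_scale_merge(counts)
    d_min <- min(colSums(counts))
    scaled <- sweep(counts, 2, res$report$scale, `*`)
    # each included fraction's scaled total equals D_min
    expect_equal(unname(colSums(scaled)), rep(d_min, n_fr),
                 tolerance = 1e-9)
    # within-fraction proportions unchanged
    for (f in seq_len(n_fr)) {
      nz <- counts[, f] > 0
      if (sum(nz) >= 2) {
        i <- which(nz)[1]; j <- which(nz)[2]
        expect_equal(scaled[i, f] / scaled[j, f], counts[i, f] / counts[j, f],
                     tolerance = 1e-12)
      }
    }
    # merged station total = n_fractions x D_min
    expect_equal(sum(res$nsra), n_fr * d_min, tolerance = 1e-9)
  }
})

test_that("whole-table NSRA stacks stations and reports scaling", {
  counts <- matrix(c(100, 900,   2000, 2000,   50, 50,   10, 90), nrow = 2,
                   dimnames = list(c("A", "B"),
                                   c("s1_0.5-1", "s1_1-2", "s2_0.5-1", "s2_1-2")))
  nm <- nsra(mk_table(counts, c(lin_met, lin_met)))
  expect_equal(unname(nm$values["s1", "A"]), 600)
  expect_equal(unname(nm$values["s2", "A"]), 60)  # 50 + 10 (equal depths 100)
  expect_equal(nrow(nm$report), 4)
})

test_that("rank aggregation pools ASVs and normalizes percentages", {
  counts <- matrix(c(10, 5, 20), ncol = 1,
                   dimnames = list(c("a1", "a2", "a3"), "s1_1-2"))
  lin_fam <- "p__Arthropoda;c__Copepoda;o__Calanoida;f__Metridinidae;g__;s__"
  tab <- mk_table(counts, c(lin_met, lin_met, lin_fam))
  sp <- aggregate_rank(tab, "species")
  # two ASVs of the same species pool into one row of 15
  expect_equal(unname(sp$values[1, "Calanus glacialis"]), 15)
  # family-only lineage pools into an unassigned-species category
  expect_true("Metridinidae (unassigned species)" %in% colnames(sp$values))
  rel <- aggregate_rank(tab, "species", relative = TRUE)
  expect_equal(unname(rowSums(rel$values)), 100, tolerance = 1e-9)
  expect_error(aggregate_rank(tab, "superfamily"), class = "zp_bad_rank")
  # species-rank aggregation of a species-resolved table = ASV pooling only
  fam <- aggregate_rank(tab, "family")
  expect_equal(sum(fam$values), sum(counts))
})

test_that("accumulation curves rise to the ASV total and are monotone", {
  set.seed(1)
  counts <- matrix(rpois(10, 40) + 1, ncol = 1,
                   dimnames = list(paste0("a", 1:10), "s1_1-2"))
  tab <- mk_table(counts, rep(lin_met, 10))
  cur <- asv_accumulation(tab, step = 1, n_rep = 5, seed = 2)
  expect_equal(cur$asvs[1], 1)                    # one read -> one ASV
  expect_equal(cur$asvs[nrow(cur)], 10)           # full depth -> all ASVs
  expect_true(all(diff(cur$asvs) >= 0))           # monotone
  expect_error(asv_accumulation(tab, step = 0), class = "zp_bad_input")
  # deep sampling of a uniform 10-ASV table plateaus at 10
  u <- matrix(rep(100L, 10), ncol = 1,
              dimnames = list(paste0("u", 1:10), "s1_1-2"))
  cu <- asv_accumulation(mk_table(u, rep(lin_met, 10)), step = 250,
                         n_rep = 3, seed = 3)
  expect_equal(cu$asvs[nrow(cu)], 10)
})

test_that("ASV tables round-trip through TSV", {
  pool <- make_taxon_pool(5, seed = 9)
  sc <- small_scenario(seed = 9)
  bm <- matrix(runif(10, 1, 4), nrow = 5,
               dimnames = list(pool$taxon_id, c("1-2", "2-4")))
  tab <- simulate_reads(bm, pool, "V9", sc, seed = 9)
  path <- file.path(tempdir(), "asv_rt.tsv")
  write_asv_table(tab, path)
  back <- read_asv_table(path)
  expect_identical(back$counts, tab$counts)
  expect_identical(back$lineage, tab$lineage)
  expect_identical(back$marker, "V9")
  expect_identical(back$station, tab$station)
  unlink(path)
})
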