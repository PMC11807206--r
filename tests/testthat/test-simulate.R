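lib8 <- design_library(8, 4, 4, n_pools = 4, seed = 11)

test_that("zero sequencing depth yields all-zero counts", {
  cfg <- simulation_config(sequencing_depth = 0, seed = 1)
  arms <- simulate_screen_counts(lib8, effect_profile(lib8), cfg)
  expect_true(all(arms$reference$counts == 0L))
  expect_true(all(arms$treated$counts == 0L))
})

test_that("counts follow the negative-binomial moment law", {
  # single-construct library, baseline share 1: each sample is one NB draw
  # with mu = depth; variance mu + phi * mu^2
  lib1 <- design_library(1, 1, 1, n_pools = 1, seed = 1)
  cfg <- simulation_config(n_replicates = 5000, sequencing_depth = 1e4,
                           dispersion = 0.1, seed = 8)
  arms <- simulate_screen_counts(lib1, effect_profile(lib1), cfg)
  draws <- c(arms$reference$counts[1, ], arms$treated$counts[1, ])
  expect_length(draws, 10000)
  expect_lt(abs(mean(draws) - 1e4) / 1e4, 0.01)
  v_expected <- 1e4 + 0.1 * 1e4^2
  expect_lt(abs(stats::var(draws) - v_expected) / v_expected, 0.05)
})

test_that("arms are exchangeable under the null", {
  # no effects, phi = 0: treated and reference replicates are draws from
  # identical distributions
  lib <- design_library(40, 4, 4, n_pools = 4, seed = 2)
  pvals <- vapply(1:3, function(s) {
    cfg <- simulation_config(n_replicates = 3, sequencing_depth = 2e5,
                             dispersion = 0, seed = s)
    arms <- simulate_screen_counts(lib, effect_profile(lib), cfg)
    suppressWarnings(stats::ks.test(as.numeric(arms$reference$counts),
                                    as.numeric(arms$treated$counts))$p.value)
  }, numeric(1))
  expect_true(all(pvals > 0.01))
})

test_that("dispersion zero reduces to Poisson (index of dispersion -> 1)", {
  lib <- design_library(30, 4, 4, n_pools = 4, seed = 3)
  idx_for <- function(n_rep) {
    cfg <- simulation_config(n_replicates = n_rep, sequencing_depth = 1e5,
                             dispersion = 0, seed = 4)
    arms <- simulate_screen_counts(lib, effect_profile(lib), cfg)
    p1 <- lib$constructs$pool == 1
    s1 <- arms$reference$samples$pool == 1
    mat <- arms$reference$counts[p1, s1, drop = FALSE]
    stats::median(apply(mat, 1, stats::var) / rowMeans(mat))
  }
  expect_lt(abs(idx_for(50) - 1), abs(idx_for(5) - 1) + 0.15)
  expect_lt(abs(idx_for(50) - 1), 0.25)
})

test_that("simulation is bit-reproducible under (config, seed)", {
  cfg <- simulation_config(sequencing_depth = 1e4, seed = 21)
  a <- simulate_screen_counts(lib8, effect_profile(lib8), cfg)
  b <- simulate_screen_counts(lib8, effect_profile(lib8), cfg)
  expect_identical(a$reference$counts, b$reference$counts)
  expect_identical(a$treated$counts, b$treated$counts)
  cfg2 <- simulation_config(sequencing_depth = 1e4, seed = 22)
  c <- simulate_screen_counts(lib8, effect_profile(lib8), cfg2)
  expect_false(identical(a$reference$counts, c$reference$counts))
})

test_that("planted effects scale treated-arm abundance by ~2^effect", {
  lib <- design_library(60, 4, 4, n_pools = 4, seed = 5)
  g <- lib$constructs$gene_id[1]
  eff <- effect_profile(lib, gene_effects = stats::setNames(2, g))
  cfg <- simulation_config(sequencing_depth = 5e5, dispersion = 0.05,
                           seed = 6)
  arms <- simulate_screen_counts(lib, eff, cfg)
  ids <- lib$constructs$shrna_id[lib$constructs$gene_id == g]
  ratios <- vapply(ids, function(id) {
    p <- lib$constructs$pool[lib$constructs$shrna_id == id]
    rsel <- arms$reference$samples$pool == p
    tsel <- arms$treated$samples$pool == p
    mean(cpm(arms$treated[, tsel])[id, ]) /
      mean(cpm(arms$reference[, rsel])[id, ])
  }, numeric(1))
  expect_true(all(ratios > 2.5 & ratios < 6.5))
})

test_that("effect profiles map gene effects onto members correctly", {
  eff <- effect_profile(lib8)
  expect_true(all(eff == 0))
  expect_named(eff, lib8$constructs$shrna_id)

  g <- unique(lib8$constructs$gene_id)[2]
  members <- lib8$constructs$shrna_id[lib8$constructs$gene_id == g]
  eff <- effect_profile(lib8, gene_effects = stats::setNames(1.5, g))
  expect_true(all(eff[members] == 1.5))
  expect_true(all(eff[setdiff(names(eff), members)] == 0))

  eff2 <- effect_profile(lib8, gene_effects = stats::setNames(1.5, g),
                         n_affected = 2)
  expect_equal(sum(eff2 != 0), 2)
  expect_true(all(eff2[members[1:2]] == 1.5))

  eff3 <- effect_profile(lib8, gene_effects = stats::setNames(1.5, g),
                         shrna_effects = stats::setNames(-1, members[1]))
  expect_equal(unname(eff3[members[1]]), -1)

  expect_error(effect_profile(lib8, gene_effects = c(NOPE = 1)),
               "unknown gene")
  expect_error(effect_profile(lib8, shrna_effects = c(NOPE = 1)),
               "unknown shRNA")
})

test_that("FASTQ emission obeys the spike-in arithmetic", {
  con1 <- lib8$constructs[lib8$constructs$pool == 1, ]

  # all-zero counts, no spike-in: empty FASTQ
  cfg0 <- simulation_config(spike_in_fraction = 0, seed = 1)
  zero <- stats::setNames(integer(nrow(con1)), con1$shrna_id)
  path <- withr::local_tempfile(fileext = ".fastq.gz")
  emit_fastq(zero, lib8, path, cfg0)
  expect_length(Biostrings::readDNAStringSet(path, format = "fastq"), 0)

  # 90 assigned reads at spike fraction 0.10: 100 reads total, 10
  # unassignable
  counts <- zero
  counts[1:3] <- c(30L, 30L, 30L)
  cfg <- simulation_config(spike_in_fraction = 0.10, seed = 2)
  emit_fastq(counts, lib8, path, cfg)
  reads <- Biostrings::readDNAStringSet(path, format = "fastq")
  expect_length(reads, 100)
  col <- quantify(path, lib8, pool_index = 1, max_mismatches = 0)
  expect_equal(col$samples$unassigned, 10)
  expect_equal(sum(col$counts), 90)
})

test_that("emitted reads meet the read-length contract", {
  con1 <- lib8$constructs[lib8$constructs$pool == 1, ]
  counts <- stats::setNames(rep(5L, nrow(con1)), con1$shrna_id)
  path <- withr::local_tempfile(fileext = ".fastq.gz")
  emit_fastq(counts, lib8, path, simulation_config(seed = 3))
  reads <- Biostrings::readDNAStringSet(path, format = "fastq")
  expect_true(all(Biostrings::width(reads) >= 75))

  expect_error(
    emit_fastq(counts, lib8, path,
               simulation_config(read_length = 20, seed = 3)),
    "read_length")
})

test_that("substitution errors are applied at the configured rate", {
  lib1 <- design_library(1, 1, 1, n_pools = 1, seed = 1)
  counts <- stats::setNames(2000L, lib1$constructs$shrna_id)
  path <- withr::local_tempfile(fileext = ".fastq")
  cfg <- simulation_config(spike_in_fraction = 0, error_rate = 0.01,
                           seed = 4)
  emit_fastq(counts, lib1, path, cfg)
  reads <- as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
  ref <- construct_reference(lib1$constructs$barcode, 75)
  nmis <- vapply(reads, function(r)
    sum(strsplit(r, "")[[1]] != strsplit(ref, "")[[1]]), numeric(1))
  rate <- sum(nmis) / (2000 * 75)
  expect_gt(rate, 0.005)
  expect_lt(rate, 0.015)
})
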