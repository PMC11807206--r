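# a small hand-built library and result table builder
hit_lib <- function() {
  con <- data.frame(
    shrna_id = paste0("sh", 1:10),
    gene_id = rep(c("GA", "GB", "GC", "GD", "GE"), each = 2),
    pool = rep(c(1L, 3L), 5),
    barcode = replicate(10, paste0(sample(c("A", "C", "G", "T"), 22,
                                          replace = TRUE), collapse = "")),
    stringsAsFactors = FALSE)
  structure(list(constructs = con, n_pools = 3L, barcode_length = 22L,
                 seed = 1L, per_gene_min = 2L, per_gene_max = 2L,
                 equal_pools = FALSE),
            class = "library_design")
}

res_row <- function(shrna_id, pool, log2fc, fdr) {
  data.frame(shrna_id = shrna_id, pool = pool, log2fc = log2fc, fdr = fdr,
             stringsAsFactors = FALSE)
}

test_that("the conjunction rule is applied exactly", {
  lib <- hit_lib()
  res <- rbind(
    # GA: two enriched shRNAs in pools 1 and 3, one above LogFC 1 -> hit
    res_row("sh1", 1, 1.5, 0.01), res_row("sh2", 3, 0.6, 0.03),
    # GB: two enriched but both in pool 2 -> distinct-pools failure
    res_row("sh3", 2, 1.2, 0.01), res_row("sh4", 2, 1.1, 0.02),
    # GC: enriched in distinct pools but max LogFC < 1 -> lfc failure
    res_row("sh5", 1, 0.8, 0.01), res_row("sh6", 3, 0.9, 0.02),
    # GD: qualifies on enrichment but has a depleted shRNA -> excluded
    res_row("sh7", 1, 1.2, 0.01), res_row("sh8", 3, 1.1, 0.02),
    res_row("sh7b", 2, -0.4, 0.01),
    # GE: only one enriched -> min_enriched failure
    res_row("sh9", 1, 2.0, 0.001), res_row("sh10", 3, 0.1, 0.9))
  # add the extra depleted construct for GD to the library
  lib$constructs <- rbind(lib$constructs,
                          data.frame(shrna_id = "sh7b", gene_id = "GD",
                                     pool = 2L, barcode = strrep("A", 22)))
  calls <- call_hits(res, lib)
  rownames(calls) <- calls$gene_id
  expect_true(calls["GA", "is_hit"])
  expect_equal(calls["GA", "n_enriched"], 2L)
  expect_equal(calls["GA", "enriched_pools"], "1,3")
  expect_false(calls["GB", "is_hit"])
  expect_match(calls["GB", "failure_reasons"], "distinct_pools")
  expect_false(calls["GC", "is_hit"])
  expect_match(calls["GC", "failure_reasons"], "lfc_threshold")
  expect_false(calls["GD", "is_hit"])
  expect_match(calls["GD", "failure_reasons"], "depleted_shrna")
  expect_equal(calls["GD", "n_depleted"], 1L)
  expect_false(calls["GE", "is_hit"])
  expect_match(calls["GE", "failure_reasons"], "min_enriched")
})

test_that("a two-shRNA metal-transporter-style profile is called as a hit", {
  # a gene with exactly two enriched shRNAs in different pools, one of them
  # enriched more than two-fold, and nothing depleted
  lib <- hit_lib()
  res <- rbind(res_row("sh1", 1, 1.8, 0.004), res_row("sh2", 3, 0.7, 0.04))
  calls <- call_hits(res, lib)
  dmt <- calls[calls$gene_id == "GA", ]
  expect_true(dmt$is_hit)
  expect_equal(dmt$n_enriched, 2L)
})

test_that("every violated rule is reported, not only the first", {
  lib <- hit_lib()
  res <- rbind(res_row("sh1", 1, 0.5, 0.01),
               res_row("sh2", 3, -0.5, 0.01))
  calls <- call_hits(res, lib)
  r <- calls$failure_reasons[calls$gene_id == "GA"]
  expect_match(r, "min_enriched")
  expect_match(r, "distinct_pools")
  expect_match(r, "lfc_threshold")
  expect_match(r, "depleted_shrna")
})

test_that("genes with too few constructs are flagged insufficient", {
  lib <- hit_lib()
  lib$constructs <- lib$constructs[-2, ]  # GA now has one construct
  lib$per_gene_min <- 1L
  res <- res_row("sh1", 1, 2.0, 0.001)
  calls <- call_hits(res, lib)
  expect_match(calls$failure_reasons[calls$gene_id == "GA"],
               "insufficient_constructs")
  expect_false(calls$is_hit[calls$gene_id == "GA"])
})

test_that("results referencing unknown shRNAs are rejected", {
  expect_error(call_hits(res_row("ghost", 1, 1, 0.01), hit_lib()),
               "unknown shRNA")
})

test_that("call_hits agrees with the enumeration oracle on random tables", {
  set.seed(61)
  for (rep in 1:15) {
    n_genes <- sample(5:20, 1)
    per_gene <- sample(2:4, 1)
    con <- data.frame(
      shrna_id = paste0("sh", seq_len(n_genes * per_gene)),
      gene_id = rep(paste0("G", seq_len(n_genes)), each = per_gene),
      pool = sample(1:5, n_genes * per_gene, replace = TRUE),
      barcode = "X", stringsAsFactors = FALSE)
    lib <- structure(list(constructs = con, n_pools = 5L,
                          barcode_length = 1L, seed = 1L,
                          per_gene_min = per_gene, per_gene_max = per_gene,
                          equal_pools = FALSE), class = "library_design")
    res <- data.frame(shrna_id = con$shrna_id, pool = con$pool,
                      log2fc = round(rnorm(nrow(con), 0, 1.2), 2),
                      fdr = round(runif(nrow(con))^2, 3) + 1e-4,
                      stringsAsFactors = FALSE)
    crit <- hit_criteria(fdr_threshold = 0.1,
                         lfc_threshold = sample(c(0.5, 1), 1),
                         min_enriched = sample(2:3, 1))
    calls <- call_hits(res, lib, crit)
    expected <- oracle_hits(res, lib, crit)
    expect_identical(stats::setNames(calls$is_hit, calls$gene_id),
                     expected)
  }
})

test_that("relaxing any threshold never removes a hit", {
  set.seed(67)
  con <- data.frame(
    shrna_id = paste0("sh", 1:60),
    gene_id = rep(paste0("G", 1:20), each = 3),
    pool = rep(1:3, 20), barcode = "X", stringsAsFactors = FALSE)
  lib <- structure(list(constructs = con, n_pools = 3L, barcode_length = 1L,
                        seed = 1L, per_gene_min = 3L, per_gene_max = 3L,
                        equal_pools = FALSE), class = "library_design")
  res <- data.frame(shrna_id = con$shrna_id, pool = con$pool,
                    log2fc = rnorm(60, 0.5, 1), fdr = runif(60)^2 + 1e-4,
                    stringsAsFactors = FALSE)
  base <- hit_criteria(0.05, 1, 2)
  hits0 <- call_hits(res, lib, base)$is_hit
  relaxed <- list(hit_criteria(0.05, 0.5, 2),
                  hit_criteria(0.05, 1, 1),
                  hit_criteria(0.05, 1, 2, require_distinct_pools = FALSE),
                  hit_criteria(0.05, 1, 2, exclude_if_any_depleted = FALSE))
  for (crit in relaxed) {
    hits1 <- call_hits(res, lib, crit)$is_hit
    expect_true(all(hits1[hits0]))
  }

  # a higher FDR threshold is a pure relaxation only with the depletion
  # veto disabled: it otherwise also admits new depleted shRNAs, which can
  # disqualify a former hit
  base_nd <- hit_criteria(0.05, 1, 2, exclude_if_any_depleted = FALSE)
  hits_nd <- call_hits(res, lib, base_nd)$is_hit
  relax_fdr <- call_hits(res, lib,
                         hit_criteria(0.2, 1, 2,
                                      exclude_if_any_depleted = FALSE))$is_hit
  expect_true(all(relax_fdr[hits_nd]))
})

test_that("counter-screen subtraction is the set difference", {
  expect_equal(subtract_counter_screen(c("A", "B", "C"), "B"), c("A", "C"))
  expect_equal(subtract_counter_screen(c("A", "B"), c("A", "B")),
               character(0))
  expect_equal(subtract_counter_screen(c("C", "A", "B"), character(0)),
               c("A", "B", "C"))  # deterministic sorted order
})
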