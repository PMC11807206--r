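# shared fixtures and independent oracles, built in code at test time

# a hand-specified toy library with known barcodes (pairwise Hamming >= 3)
toy_library <- function() {
  con <- data.frame(
    shrna_id = c("sh1", "sh2", "sh3"),
    gene_id = c("G1", "G1", "G2"),
    pool = c(1L, 1L, 1L),
    barcode = c("AAAAAAAAAA", "CCCCCCCCCC", "GGGGGGGGGG"),
    stringsAsFactors = FALSE)
  structure(list(constructs = con, n_pools = 1L, barcode_length = 10L,
                 seed = NA_integer_, per_gene_min = 1L, per_gene_max = 2L,
                 equal_pools = FALSE),
            class = "library_design")
}

# minimal FASTQ writer independent of emit_fastq (for quantify fixtures)
write_fastq_fixture <- function(reads, path) {
  lines <- unlist(lapply(seq_along(reads), function(i)
    c(paste0("@r", i), reads[i], "+", strrep("I", nchar(reads[i])))))
  writeLines(lines, path)
  path
}

# build a screen_counts from a plain matrix
make_counts <- function(mat, conditions, pool = 1L) {
  if (is.null(rownames(mat))) rownames(mat) <- paste0("sh", seq_len(nrow(mat)))
  colnames(mat) <- paste0("s", seq_len(ncol(mat)))
  screen_counts(mat, data.frame(
    sample_id = colnames(mat), pool = pool, condition = conditions,
    replicate = as.integer(stats::ave(seq_along(conditions), conditions,
                                      FUN = seq_along)),
    unassigned = 0L, total_reads = colSums(mat),
    stringsAsFactors = FALSE))
}

# brute-force BH step-up: fdr_i = min_{j: p_(j) >= p_(i)} (m * p_(j) / rank_j)
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  sorted <- p[o]
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(m * sorted[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# exact hypergeometric upper tail by enumerating all size-n hit lists
oracle_hyper <- function(k, K, n, N) {
  universe <- seq_len(N)
  term <- seq_len(K)
  combos <- utils::combn(N, n)
  mean(apply(combos, 2, function(s) sum(s %in% term) >= k))
}

# brute-force re-statement of the gene hit rule
oracle_hits <- function(results, library, criteria) {
  con <- library$constructs
  vapply(unique(con$gene_id), function(g) {
    ids <- con$shrna_id[con$gene_id == g]
    r <- results[results$shrna_id %in% ids, , drop = FALSE]
    enr <- r[r$fdr < criteria$fdr_threshold & r$log2fc > 0, , drop = FALSE]
    dep <- r[r$fdr < criteria$fdr_threshold & r$log2fc < 0, , drop = FALSE]
    ok <- nrow(enr) >= criteria$min_enriched
    if (criteria$require_distinct_pools)
      ok <- ok && length(unique(enr$pool)) >= criteria$min_enriched
    ok <- ok && nrow(enr) > 0 && max(enr$log2fc) >= criteria$lfc_threshold
    if (criteria$exclude_if_any_depleted) ok <- ok && nrow(dep) == 0
    ok
  }, logical(1))
}

# independent construction of the conditional NB split probability:
# product of two dnbinom masses, normalized over all splits of t
oracle_exact_nb <- function(s1, s2, n1, n2, phi) {
  t <- s1 + s2
  if (t == 0) return(1)
  mu <- t / (n1 + n2)
  k <- 0:t
  if (phi == 0) {
    f <- stats::dpois(k, n1 * mu) * stats::dpois(t - k, n2 * mu)
  } else {
    f <- stats::dnbinom(k, size = n1 / phi, mu = n1 * mu) *
      stats::dnbinom(t - k, size = n2 / phi, mu = n2 * mu)
  }
  f <- f / sum(f)
  min(1, sum(f[f <= f[s1 + 1] * (1 + 1e-10)]))
}
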