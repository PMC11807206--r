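#' Design a pooled shRNA library
#'
#' Constructs a synthetic pooled shRNA library emulating the layout of
#' commercial genome-wide pooled libraries: each gene is targeted by
#' `per_gene_min`..`per_gene_max` hairpins, each hairpin carries a unique
#' nucleotide barcode, and a gene's hairpins are distributed across distinct
#' pools. With `equal_pools = TRUE` every pool receives exactly the same
#' number of constructs.
#'
#' Per-gene construct counts are drawn uniformly from the allowed range and
#' then repaired by +/-1 adjustments on randomly chosen genes until they sum
#' to `total_constructs` (when given). Pools are assigned greedily: each
#' gene's constructs go to its k least-filled pools among those it does not
#' already occupy, which keeps pool sizes within 1 of each other at every
#' step and yields exactly equal pools whenever the total is divisible by
#' `n_pools`.
#'
#' Barcodes are uniform random sequences with pairwise Hamming distance >= 3
#' (enforced by rejection), so that single-mismatch read assignment is
#' unambiguous by construction.
#'
#' @param n_genes number of target genes.
#' @param per_gene_min,per_gene_max allowed range of constructs per gene;
#'   `per_gene_max` must not exceed `n_pools` since a gene's constructs
#'   occupy distinct pools.
#' @param n_pools number of library pools.
#' @param equal_pools require all pools to hold the same number of constructs.
#' @param total_constructs optional exact library size; must lie in
#'   `[n_genes * per_gene_min, n_genes * per_gene_max]` and, with
#'   `equal_pools`, be divisible by `n_pools`.
#' @param barcode_length barcode length in nucleotides (default 22).
#' @param seed integer seed; the design is bit-reproducible given the same
#'   arguments and seed.
#'
#' @return An object of class `library_design`: a list with `constructs`
#'   (data.frame with columns `shrna_id`, `gene_id`, `pool`, `barcode`),
#'   `n_pools`, `barcode_length` and `seed`.
#'
#' @examples
#' lib <- design_library(n_genes = 12, per_gene_min = 4, per_gene_max = 7,
#'                       n_pools = 10, seed = 1)
#' table(lib$constructs$pool)
#' @export
design_library <- function(n_genes, per_gene_min = 4L, per_gene_max = 7L,
                           n_pools = 10L, equal_pools = FALSE,
                           total_constructs = NULL, barcode_length = 22L,
                           seed = 1L) {
  n_genes <- as.integer(n_genes)
  per_gene_min <- as.integer(per_gene_min)
  per_gene_max <- as.integer(per_gene_max)
  n_pools <- as.integer(n_pools)
  barcode_length <- as.integer(barcode_length)

  if (n_genes < 1L)
    stop("constraint violation: n_genes must be >= 1", call. = FALSE)
  if (per_gene_min < 1L)
    stop("constraint violation: per_gene_min must be >= 1", call. = FALSE)
  if (per_gene_max < per_gene_min)
    stop("constraint violation: per_gene_max < per_gene_min", call. = FALSE)
  if (per_gene_max > n_pools)
    stop("constraint violation: per_gene_max (", per_gene_max,
         ") exceeds n_pools (", n_pools,
         "); a gene's constructs must occupy distinct pools", call. = FALSE)
  if (!is.null(total_constructs)) {
    total_constructs <- as.integer(total_constructs)
    lo <- n_genes * per_gene_min
    hi <- n_genes * per_gene_max
    if (total_constructs < lo || total_constructs > hi)
      stop("constraint violation: total_constructs (", total_constructs,
           ") outside feasible range [", lo, ", ", hi, "]", call. = FALSE)
    if (equal_pools && total_constructs %% n_pools != 0L)
      stop("constraint violation: total_constructs (", total_constructs,
           ") not divisible by n_pools (", n_pools, ")", call. = FALSE)
  } else if (equal_pools) {
    # choose the feasible multiple of n_pools closest to the expected total
    target <- n_genes * (per_gene_min + per_gene_max) / 2
    cand <- round(target / n_pools) * n_pools
    cand <- min(max(cand, ceiling(n_genes * per_gene_min / n_pools) * n_pools),
                floor(n_genes * per_gene_max / n_pools) * n_pools)
    if (cand < n_genes * per_gene_min || cand > n_genes * per_gene_max)
      stop("constraint violation: no multiple of n_pools lies in the feasible",
           " total range; supply total_constructs", call. = FALSE)
    total_constructs <- as.integer(cand)
  }

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)

  counts <- if (per_gene_min == per_gene_max) rep(per_gene_min, n_genes)
            else sample(per_gene_min:per_gene_max, n_genes, replace = TRUE)
  if (!is.null(total_constructs)) {
    # repair: +/-1 on randomly chosen genes still inside the allowed range
    delta <- total_constructs - sum(counts)
    while (delta != 0L) {
      if (delta > 0L) {
        room <- which(counts < per_gene_max)
        pick <- room[sample.int(length(room), min(delta, length(room)))]
        counts[pick] <- counts[pick] + 1L
        delta <- delta - length(pick)
      } else {
        room <- which(counts > per_gene_min)
        pick <- room[sample.int(length(room), min(-delta, length(room)))]
        counts[pick] <- counts[pick] - 1L
        delta <- delta + length(pick)
      }
    }
  }
  total <- sum(counts)

  gene_ids <- sprintf("GENE%05d", seq_len(n_genes))

  # pool assignment: each gene takes its k least-filled pools (ties broken by
  # pool index); keeps the max-min pool load spread <= 1 throughout
  load <- integer(n_pools)
  pool_of <- integer(total)
  gene_of <- integer(total)
  idx <- 1L
  ord <- sample.int(n_genes)  # random processing order
  for (g in ord) {
    k <- counts[g]
    pick <- order(load, seq_len(n_pools))[seq_len(k)]
    load[pick] <- load[pick] + 1L
    pool_of[idx:(idx + k - 1L)] <- sort(pick)
    gene_of[idx:(idx + k - 1L)] <- g
    idx <- idx + k
  }

  barcodes <- .random_barcodes(total, barcode_length)

  ord2 <- order(gene_of, pool_of)
  constructs <- data.frame(
    shrna_id = sprintf("SH%06d", seq_len(total)),
    gene_id = gene_ids[gene_of[ord2]],
    pool = pool_of[ord2],
    barcode = barcodes,
    stringsAsFactors = FALSE
  )

  structure(
    list(constructs = constructs, n_pools = n_pools,
         barcode_length = barcode_length, seed = as.integer(seed),
         per_gene_min = per_gene_min, per_gene_max = per_gene_max,
         equal_pools = isTRUE(equal_pools)),
    class = "library_design"
  )
}

#' @export
print.library_design <- function(x, ...) {
  cat("Pooled shRNA library design\n")
  cat("  constructs:", nrow(x$constructs), " genes:",
      length(unique(x$constructs$gene_id)), " pools:", x$n_pools, "\n")
  cat("  barcode length:", x$barcode_length, " seed:", x$seed, "\n")
  print(table(pool = x$constructs$pool))
  invisible(x)
}

# generate n unique random barcodes with pairwise Hamming distance >= 3.
# rejection uses a pigeonhole partition into 3 segments: any pair at distance
# <= 2 must agree exactly on at least one segment, so candidates are screened
# against per-segment hash buckets instead of all previous barcodes.
.random_barcodes <- function(n, len) {
  if (len < 3L)
    stop("barcode_length must be >= 3 to enforce pairwise distance >= 3",
         call. = FALSE)
  cuts <- .segment_cuts(len)
  out <- character(n)
  seg_env <- lapply(1:3, function(i) new.env(hash = TRUE, size = 2L * n))
  made <- 0L
  while (made < n) {
    batch <- min(n - made, 20000L)
    mat <- matrix(sample(c("A", "C", "G", "T"), batch * len, replace = TRUE),
                  nrow = batch)
    cand <- apply(mat, 1L, paste0, collapse = "")
    for (bc in cand) {
      if (made == n) break
      segs <- substring(bc, cuts$from, cuts$to)
      clash <- FALSE
      for (i in 1:3) {
        bucket <- seg_env[[i]][[segs[i]]]
        if (!is.null(bucket) &&
            any(.hamming(bc, bucket) < 3L)) { clash <- TRUE; break }
      }
      if (clash) next
      made <- made + 1L
      out[made] <- bc
      for (i in 1:3)
        seg_env[[i]][[segs[i]]] <- c(seg_env[[i]][[segs[i]]], bc)
    }
  }
  out
}

.segment_cuts <- function(len) {
  b <- floor(len / 3)
  from <- c(1L, b + 1L, 2L * b + 1L)
  to <- c(b, 2L * b, len)
  list(from = from, to = to)
}

# vectorized Hamming distance between one string and a vector of equal-length
# strings
.hamming <- function(x, ys) {
  xs <- strsplit(x, "", fixed = TRUE)[[1]]
  vapply(strsplit(ys, "", fixed = TRUE),
         function(y) sum(xs != y), integer(1))
}

#' Validate a library design
#'
#' Independent re-check of every design invariant: barcode uniqueness and
#' minimum pairwise Hamming distance, pool indices in range, non-empty gene
#' ids, per-gene construct counts within the declared range, no gene with two
#' constructs in the same pool, and (when the design requested it) equal pool
#' sizes.
#'
#' @param design a `library_design`.
#' @param min_distance minimum pairwise barcode Hamming distance to require
#'   (default 3).
#' @return `TRUE` invisibly; otherwise stops with the violated invariant.
#' @export
validate_library <- function(design, min_distance = 3L) {
  stopifnot(inherits(design, "library_design"))
  con <- design$constructs
  if (nrow(con) == 0L) stop("empty design", call. = FALSE)
  if (anyDuplicated(con$barcode))
    stop("invariant violated: duplicate barcodes", call. = FALSE)
  if (any(nchar(con$barcode) != design$barcode_length))
    stop("invariant violated: barcode length mismatch", call. = FALSE)
  if (any(con$pool < 1L | con$pool > design$n_pools))
    stop("invariant violated: pool index out of range", call. = FALSE)
  if (any(!nzchar(con$gene_id)))
    stop("invariant violated: empty gene_id", call. = FALSE)
  per_gene <- table(con$gene_id)
  if (any(per_gene < design$per_gene_min) || any(per_gene > design$per_gene_max))
    stop("invariant violated: per-gene construct count outside [",
         design$per_gene_min, ", ", design$per_gene_max, "]", call. = FALSE)
  if (anyDuplicated(con[, c("gene_id", "pool")]))
    stop("invariant violated: gene with two constructs in one pool",
         call. = FALSE)
  if (isTRUE(design$equal_pools)) {
    sizes <- tabulate(con$pool, nbins = design$n_pools)
    if (length(unique(sizes)) != 1L)
      stop("invariant violated: unequal pool sizes", call. = FALSE)
  }
  if (barcode_min_distance(con$barcode) < min_distance)
    stop("invariant violated: barcode pairwise Hamming distance < ",
         min_distance, call. = FALSE)
  invisible(TRUE)
}

#' Minimum pairwise Hamming distance of a barcode set
#'
#' Exact, but avoids the quadratic scan: barcodes are bucketed by each of
#' three segments; any pair at distance <= 2 must collide in some bucket, so
#' only bucket-mates are compared (distances >= 3 are reported as `3`, which
#' is sufficient for the single-mismatch assignment guarantee).
#'
#' @param barcodes character vector of equal-length barcodes.
#' @return the minimum pairwise distance, truncated at 3.
#' @export
barcode_min_distance <- function(barcodes) {
  n <- length(barcodes)
  if (n < 2L) return(3L)
  if (anyDuplicated(barcodes)) return(0L)
  len <- nchar(barcodes[1])
  cuts <- .segment_cuts(len)
  best <- 3L
  for (i in 1:3) {
    segs <- substring(barcodes, cuts$from[i], cuts$to[i])
    for (bucket in split(barcodes, segs)) {
      m <- length(bucket)
      if (m < 2L) next
      for (a in seq_len(m - 1L)) {
        d <- .hamming(bucket[a], bucket[(a + 1L):m])
        best <- min(best, d, 3L)
        if (best == 0L) return(0L)
      }
    }
  }
  as.integer(best)
}

#' Screen-design budget calculator
#'
#' Computes the cells to seed for a pooled transduction and the genomic DNA
#' mass consumed by PCR amplification. Cells are seeded so that each shRNA is
#' represented by at least `coverage` transduced cells at the given
#' multiplicity of infection: `cells_to_seed = ceiling(n_shrnas * coverage /
#' moi)`. The per-specimen gDNA budget is `n_pcr_replicates *
#' gdna_per_replicate_ng / 1000` micrograms.
#'
#' @param n_shrnas number of shRNAs in the pool.
#' @param coverage desired copies per shRNA in the transduced population
#'   (default 1000).
#' @param moi lentiviral multiplicity of infection (default 0.3, so that most
#'   cells carry a single integration).
#' @param gdna_per_replicate_ng gDNA mass per PCR technical replicate in ng
#'   (default 825).
#' @param n_pcr_replicates number of PCR technical replicates per specimen
#'   (default 8).
#' @return a `design_budget` list: `n_shrnas`, `coverage`, `moi`,
#'   `cells_to_seed`, `gdna_per_replicate_ng`, `n_pcr_replicates`,
#'   `gdna_total_ug`.
#' @examples
#' coverage_calculator(9570, coverage = 1000, moi = 0.3)
#' @export
coverage_calculator <- function(n_shrnas, coverage = 1000, moi = 0.3,
                                gdna_per_replicate_ng = 825,
                                n_pcr_replicates = 8) {
  if (moi <= 0) stop("moi must be > 0", call. = FALSE)
  if (n_shrnas < 0 || coverage < 0 || gdna_per_replicate_ng < 0 ||
      n_pcr_replicates < 0)
    stop("inputs must be non-negative", call. = FALSE)
  structure(list(
    n_shrnas = n_shrnas,
    coverage = coverage,
    moi = moi,
    cells_to_seed = ceiling(n_shrnas * coverage / moi),
    gdna_per_replicate_ng = gdna_per_replicate_ng,
    n_pcr_replicates = n_pcr_replicates,
    gdna_total_ug = n_pcr_replicates * gdna_per_replicate_ng / 1000
  ), class = "design_budget")
}

#' @export
print.design_budget <- function(x, ...) {
  cat("Screen design budget\n")
  cat(sprintf("  %d shRNAs at %gx coverage, MOI %g -> seed %s cells\n",
              x$n_shrnas, x$coverage, x$moi,
              format(x$cells_to_seed, big.mark = ",")))
  cat(sprintf("  %d PCR replicates x %g ng gDNA -> %g ug per specimen\n",
              x$n_pcr_replicates, x$gdna_per_replicate_ng, x$gdna_total_ug))
  invisible(x)
}

#' Write / read a library manifest
#'
#' The manifest is a tab-separated table with header
#' `shrna_id gene_id pool barcode`.
#'
#' @param design a `library_design`.
#' @param path output TSV path.
#' @return `path` invisibly.
#' @export
write_library_manifest <- function(design, path) {
  stopifnot(inherits(design, "library_design"))
  utils::write.table(design$constructs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_library_manifest
#' @param n_pools,barcode_length optional overrides when reading; inferred
#'   from the table otherwise.
#' @export
read_library_manifest <- function(path, n_pools = NULL, barcode_length = NULL) {
  con <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = c("character", "character",
                                          "integer", "character"))
  needed <- c("shrna_id", "gene_id", "pool", "barcode")
  if (!all(needed %in% names(con)))
    stop("manifest must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  per_gene <- table(con$gene_id)
  structure(
    list(constructs = con[, needed],
         n_pools = if (is.null(n_pools)) max(con$pool) else as.integer(n_pools),
         barcode_length = if (is.null(barcode_length)) nchar(con$barcode[1])
                          else as.integer(barcode_length),
         seed = NA_integer_,
         per_gene_min = min(per_gene), per_gene_max = max(per_gene),
         equal_pools = FALSE),
    class = "library_design"
  )
}

#' Export per-pool construct references as FASTA
#'
#' One FASTA file per pool, each record holding a construct's full reference
#' sequence (constant flanks with the barcode embedded, as sequenced).
#'
#' @param design a `library_design`.
#' @param dir output directory (created if needed).
#' @param read_length pad references to this length (default 75).
#' @return character vector of written file paths, invisibly.
#' @export
write_pool_fasta <- function(design, dir, read_length = 75L) {
  stopifnot(inherits(design, "library_design"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(design$n_pools)
  for (p in seq_len(design$n_pools)) {
    con <- design$constructs[design$constructs$pool == p, ]
    seqs <- construct_reference(con$barcode, read_length)
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- con$shrna_id
    paths[p] <- file.path(dir, sprintf("pool%02d.fasta", p))
    Biostrings::writeXStringSet(x, paths[p])
  }
  invisible(paths)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
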