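#' Screen count matrix
#'
#' Container for integer shRNA x sample counts with per-sample metadata.
#' Rows are shRNA ids in a fixed order; columns are samples. Per-sample
#' metadata records the pool, condition (`reference` or `treated`), replicate
#' index, the number of sequenced reads that could not be assigned to any
#' library barcode, and the total read count. The read-conservation
#' invariant `colSums(counts) + unassigned == total_reads` is checked at
#' construction.
#'
#' @param counts integer matrix, rownames = shRNA ids, colnames = sample ids.
#' @param samples data.frame with one row per column of `counts` and columns
#'   `sample_id`, `pool`, `condition`, `replicate`, `unassigned`,
#'   `total_reads`.
#' @return an object of class `screen_counts`.
#' @export
screen_counts <- function(counts, samples) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (is.null(rownames(counts))) stop("counts must have shRNA rownames")
  if (any(counts < 0L, na.rm = TRUE)) stop("counts must be non-negative")
  needed <- c("sample_id", "pool", "condition", "replicate",
              "unassigned", "total_reads")
  if (!all(needed %in% names(samples)))
    stop("samples must have columns: ", paste(needed, collapse = ", "))
  samples <- samples[, needed]
  for (f in c("pool", "replicate", "unassigned", "total_reads"))
    samples[[f]] <- as.integer(samples[[f]])
  if (nrow(samples) != ncol(counts))
    stop("samples must have one row per counts column")
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_ids: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
               collapse = ", "))
  colnames(counts) <- samples$sample_id
  bad <- which(colSums(counts) + samples$unassigned != samples$total_reads)
  if (length(bad))
    stop("read conservation violated (assigned + unassigned != total) in: ",
         paste(samples$sample_id[bad], collapse = ", "))
  if (!all(samples$condition %in% c("reference", "treated")))
    stop("condition must be 'reference' or 'treated'")
  rownames(samples) <- NULL
  structure(list(counts = counts, samples = samples), class = "screen_counts")
}

#' @export
print.screen_counts <- function(x, ...) {
  cat("screen_counts:", nrow(x$counts), "shRNAs x", ncol(x$counts),
      "samples\n")
  print(x$samples)
  invisible(x)
}

#' @export
dim.screen_counts <- function(x) dim(x$counts)

#' Subset a screen_counts by row/column
#' @param x a `screen_counts`.
#' @param i,j row (shRNA) and column (sample) indices.
#' @param ... ignored.
#' @export
`[.screen_counts` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  screen_counts(x$counts[i, j, drop = FALSE], x$samples[j, , drop = FALSE])
}

#' Quantify barcode abundance in a FASTQ file
#'
#' Counts reads per library shRNA by mismatch-tolerant matching of the
#' barcode window (the `barcode_length` bases starting after
#' `barcode_offset`) against the barcodes of one library pool. A read is
#' assigned if and only if exactly one pool barcode lies within
#' `max_mismatches` Hamming distance of its window; unmatched and ambiguous
#' reads are tallied as unassigned. With `scan_offsets = TRUE` every offset
#' compatible with the read length is tried and the read must hit a single
#' distinct barcode across all offsets (for reads whose barcode position is
#' unknown).
#'
#' Single-mismatch assignment (`max_mismatches = 1`) is only permitted when
#' the pool's barcodes have pairwise Hamming distance >= 3, which makes
#' 1-neighbourhoods disjoint and assignment unambiguous.
#'
#' @param fastq_path path to a FASTQ file (optionally gzipped).
#' @param library a `library_design`.
#' @param pool_index which pool the sample was sequenced from.
#' @param max_mismatches 0 or 1.
#' @param barcode_offset 0-based offset of the barcode within the read
#'   (default `default_barcode_offset()`).
#' @param scan_offsets try all offsets instead of the fixed one.
#' @param sample_id,condition,replicate sample metadata recorded in the
#'   returned column.
#' @return a one-column `screen_counts` whose rows are all constructs of the
#'   pool, in library order.
#' @export
quantify <- function(fastq_path, library, pool_index,
                     max_mismatches = 0L,
                     barcode_offset = default_barcode_offset(),
                     scan_offsets = FALSE,
                     sample_id = basename(fastq_path),
                     condition = "reference", replicate = 1L) {
  stopifnot(inherits(library, "library_design"))
  if (!max_mismatches %in% c(0L, 1L))
    stop("max_mismatches must be 0 or 1", call. = FALSE)
  con <- library$constructs[library$constructs$pool == pool_index, ,
                            drop = FALSE]
  if (nrow(con) == 0L) stop("no constructs in pool ", pool_index)
  L <- library$barcode_length
  if (max_mismatches == 1L && barcode_min_distance(con$barcode) < 3L)
    stop("max_mismatches = 1 requires pairwise barcode Hamming distance >= 3",
         call. = FALSE)

  reads <- .read_fastq(fastq_path)
  total <- length(reads)
  widths <- nchar(reads)

  assign_idx <- rep(NA_integer_, total)
  if (total > 0L) {
    if (scan_offsets) {
      offsets <- 0L:max(0L, max(widths) - L)
      hit_read <- integer(0)
      hit_bc <- integer(0)
      for (off in offsets) {
        ok <- widths >= off + L
        win <- substr(reads[ok], off + 1L, off + L)
        m <- match(win, con$barcode)
        hit_read <- c(hit_read, which(ok)[!is.na(m)])
        hit_bc <- c(hit_bc, m[!is.na(m)])
      }
      if (length(hit_read)) {
        u <- !duplicated(cbind(hit_read, hit_bc))
        nhits <- tabulate(hit_read[u], nbins = total)
        first <- hit_bc[u][match(seq_len(total), hit_read[u])]
        assign_idx[nhits == 1L] <- first[nhits == 1L]
      }
    } else {
      short <- widths < barcode_offset + L
      if (any(short))
        warning(sum(short), " read(s) shorter than barcode_offset + ",
                "barcode_length; counted as unassigned")
      ok <- !short
      win <- substr(reads[ok], barcode_offset + 1L, barcode_offset + L)
      if (max_mismatches == 0L) {
        assign_idx[ok] <- match(win, con$barcode)
      } else {
        lut <- .mismatch_lut(con$barcode)
        m <- lut$idx[match(win, lut$variant)]
        assign_idx[ok] <- m
      }
    }
  }
  counts <- tabulate(assign_idx, nbins = nrow(con))
  mat <- matrix(as.integer(counts), ncol = 1,
                dimnames = list(con$shrna_id, sample_id))
  screen_counts(mat, data.frame(
    sample_id = sample_id, pool = as.integer(pool_index),
    condition = condition, replicate = as.integer(replicate),
    unassigned = total - sum(counts), total_reads = total,
    stringsAsFactors = FALSE))
}

# all Hamming-distance-<=1 variants of each barcode; ambiguous variants
# (reachable from two barcodes) are dropped so they map to unassigned
.mismatch_lut <- function(barcodes) {
  L <- nchar(barcodes[1])
  vars <- list(barcodes)
  idx <- list(seq_along(barcodes))
  bases <- c("A", "C", "G", "T")
  for (pos in seq_len(L)) {
    orig <- substr(barcodes, pos, pos)
    for (b in bases) {
      keep <- orig != b
      if (!any(keep)) next
      v <- barcodes[keep]
      substr(v, pos, pos) <- b
      vars[[length(vars) + 1L]] <- v
      idx[[length(idx) + 1L]] <- which(keep)
    }
  }
  variant <- unlist(vars, use.names = FALSE)
  index <- unlist(idx, use.names = FALSE)
  o <- order(variant, index)
  variant <- variant[o]; index <- index[o]
  first <- !duplicated(variant)
  grp <- cumsum(first)
  # a variant reachable from >1 distinct barcode is ambiguous -> dropped
  n <- length(variant)
  clash <- c(FALSE, variant[-1] == variant[-n] & index[-1] != index[-n])
  bad <- unique(grp[clash])
  keep <- first & !(grp %in% bad)
  list(variant = variant[keep], idx = index[keep])
}

.read_fastq <- function(path) {
  nl <- length(readLines(path, warn = FALSE))
  if (nl %% 4L != 0L)
    stop("malformed FASTQ '", path, "': truncated record ", nl %/% 4L + 1L,
         call. = FALSE)
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq", use.names = FALSE),
    error = function(e) {
      stop("malformed FASTQ '", path, "': ", conditionMessage(e),
           call. = FALSE)
    })
  as.character(x)
}

#' Merge per-sample count columns into one matrix
#'
#' All columns must come from the same pool and share the same row (shRNA)
#' set; metadata is preserved and samples are put into a canonical order
#' (condition, then replicate, then sample id), so the result is invariant
#' to the input order.
#'
#' @param columns list of `screen_counts` objects (typically one column each).
#' @return a `screen_counts` with all samples.
#' @export
merge_columns <- function(columns) {
  if (!length(columns)) stop("no columns to merge")
  stopifnot(all(vapply(columns, inherits, logical(1), "screen_counts")))
  rn <- rownames(columns[[1]]$counts)
  for (x in columns) {
    if (!identical(sort(rownames(x$counts)), sort(rn)))
      stop("mismatched row sets between columns")
  }
  pools <- unlist(lapply(columns, function(x) x$samples$pool))
  if (length(unique(pools)) != 1L)
    stop("columns come from different pools: ",
         paste(sort(unique(pools)), collapse = ", "))
  mat <- do.call(cbind, lapply(columns, function(x) x$counts[rn, , drop = FALSE]))
  samples <- do.call(rbind, lapply(columns, function(x) x$samples))
  ord <- order(match(samples$condition, c("reference", "treated")),
               samples$replicate, samples$sample_id)
  screen_counts(mat[, ord, drop = FALSE], samples[ord, , drop = FALSE])
}

#' Write / read a count matrix as TSV
#'
#' Sample metadata is stored as `#`-prefixed header lines (`#pool`,
#' `#condition`, `#replicate`, `#unassigned`, `#total_reads`), followed by a
#' standard TSV with an `shrna_id` column and one column per sample.
#'
#' @param x a `screen_counts`.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_counts_tsv <- function(x, path) {
  stopifnot(inherits(x, "screen_counts"))
  s <- x$samples
  hdr <- c(
    paste0("#pool\t", paste(s$pool, collapse = "\t")),
    paste0("#condition\t", paste(s$condition, collapse = "\t")),
    paste0("#replicate\t", paste(s$replicate, collapse = "\t")),
    paste0("#unassigned\t", paste(s$unassigned, collapse = "\t")),
    paste0("#total_reads\t", paste(s$total_reads, collapse = "\t"))
  )
  body <- data.frame(shrna_id = rownames(x$counts), x$counts,
                     check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(body, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  body <- utils::read.table(text = lines[!startsWith(lines, "#")],
                            header = TRUE, sep = "\t", check.names = FALSE)
  mat <- as.matrix(body[, -1, drop = FALSE])
  rownames(mat) <- body$shrna_id
  getmeta <- function(key) {
    ln <- meta[startsWith(meta, paste0("#", key, "\t"))]
    strsplit(sub(paste0("^#", key, "\t"), "", ln), "\t")[[1]]
  }
  screen_counts(mat, data.frame(
    sample_id = colnames(mat),
    pool = as.integer(getmeta("pool")),
    condition = getmeta("condition"),
    replicate = as.integer(getmeta("replicate")),
    unassigned = as.integer(getmeta("unassigned")),
    total_reads = as.integer(getmeta("total_reads")),
    stringsAsFactors = FALSE))
}
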