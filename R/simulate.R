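#' Default barcode offset within a read
#'
#' Simulated reads place the hairpin barcode immediately after a constant
#' 10-nt 5' flank; quantification defaults to the same offset.
#' @return integer offset (number of bases before the barcode).
#' @export
default_barcode_offset <- function() nchar(.FLANK5)

.FLANK5 <- "TCGACTTAGG"
.FILLER <- "TGCA"  # repeated to pad references to the read length

#' Full construct reference sequence as sequenced
#'
#' Constant 5' flank, then the barcode, then constant filler padded to
#' `read_length`.
#' @param barcode character vector of barcodes.
#' @param read_length total reference/read length (>= offset + barcode
#'   length).
#' @param barcode_length barcode length used for validation when `barcode`
#'   is empty.
#' @return character vector of reference sequences.
#' @export
construct_reference <- function(barcode, read_length = 75L,
                                barcode_length = NULL) {
  off <- nchar(.FLANK5)
  L <- if (length(barcode)) nchar(barcode[1]) else barcode_length
  if (is.null(L)) stop("barcode_length needed for empty barcode set")
  if (read_length < off + L)
    stop("read_length (", read_length, ") < barcode_offset + barcode_length (",
         off + L, ")", call. = FALSE)
  pad <- read_length - off - L
  if (!length(barcode)) return(character(0))
  filler <- substr(strrep(.FILLER, ceiling(pad / nchar(.FILLER)) + 1L), 1, pad)
  paste0(.FLANK5, barcode, filler)
}

#' Simulation configuration
#'
#' Parameters of the generative model for a pooled screen: per-pool samples
#' of `n_replicates` reference and `n_replicates` treated specimens,
#' negative-binomial sequencing counts at the given expected depth and
#' dispersion, a log-normal baseline abundance skew, and FASTQ emission with
#' an unassignable spike-in fraction (emulating a phiX spike-in) and
#' optional substitution errors.
#'
#' @param n_replicates replicates per arm (default 3, one screen's gDNA
#'   specimens per pool).
#' @param sequencing_depth expected assigned reads per sample (default 5e6).
#' @param dispersion negative-binomial dispersion phi >= 0; counts have
#'   variance `mu + phi * mu^2` (default 0.1; 0 gives Poisson counts).
#' @param abundance_sdlog sd(log) of the log-normal baseline abundance of
#'   constructs within a pool (default 0.5).
#' @param spike_in_fraction fraction of emitted reads that are unassignable
#'   random sequences (default 0.10).
#' @param read_length simulated read length in nt (default 75).
#' @param error_rate per-base substitution error probability (default 0).
#' @param seed integer seed.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_replicates = 3L, sequencing_depth = 5e6,
                              dispersion = 0.1, abundance_sdlog = 0.5,
                              spike_in_fraction = 0.10, read_length = 75L,
                              error_rate = 0, seed = 1L) {
  if (sequencing_depth < 0) stop("sequencing_depth must be >= 0")
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (spike_in_fraction < 0 || spike_in_fraction >= 1)
    stop("spike_in_fraction must be in [0, 1)")
  if (error_rate < 0 || error_rate >= 1)
    stop("error_rate must be in [0, 1)")
  structure(list(n_replicates = as.integer(n_replicates),
                 sequencing_depth = sequencing_depth,
                 dispersion = dispersion,
                 abundance_sdlog = abundance_sdlog,
                 spike_in_fraction = spike_in_fraction,
                 read_length = as.integer(read_length),
                 error_rate = error_rate,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Map planted gene-level effects onto member shRNAs
#'
#' Builds a per-shRNA true selection effect vector (log2 scale; 0 neutral,
#' positive enriched under treatment, negative depleted). Gene-level effects
#' are applied to all member shRNAs, or to the first `n_affected` members in
#' library order; per-shRNA overrides take precedence.
#'
#' @param design a `library_design`.
#' @param gene_effects named numeric vector (names = gene ids) of log2
#'   effects.
#' @param shrna_effects named numeric vector (names = shRNA ids) of per-shRNA
#'   overrides.
#' @param n_affected optional number of member shRNAs per listed gene that
#'   receive the gene effect (default: all members).
#' @return named numeric vector with one effect per library shRNA.
#' @export
effect_profile <- function(design, gene_effects = NULL, shrna_effects = NULL,
                           n_affected = NULL) {
  stopifnot(inherits(design, "library_design"))
  con <- design$constructs
  eff <- stats::setNames(numeric(nrow(con)), con$shrna_id)
  if (!is.null(gene_effects)) {
    unknown <- setdiff(names(gene_effects), con$gene_id)
    if (length(unknown))
      stop("unknown gene(s) in gene_effects: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    for (g in names(gene_effects)) {
      members <- con$shrna_id[con$gene_id == g]
      if (!is.null(n_affected)) members <- utils::head(members, n_affected)
      eff[members] <- gene_effects[[g]]
    }
  }
  if (!is.null(shrna_effects)) {
    unknown <- setdiff(names(shrna_effects), con$shrna_id)
    if (length(unknown))
      stop("unknown shRNA(s) in shrna_effects: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    eff[names(shrna_effects)] <- shrna_effects
  }
  eff
}

#' Simulate screen sequencing counts
#'
#' Per pool, per replicate, counts are negative-binomial draws with mean
#' proportional to a log-normal baseline abundance (and multiplied by
#' `2^effect` in the treated arm, then renormalized), scaled to the sample's
#' expected depth; variance is `mu + phi * mu^2`. With `dispersion = 0`
#' counts are Poisson. Baseline abundances are drawn once per pool and
#' shared by both arms.
#'
#' @param design a `library_design`.
#' @param effects per-shRNA effect vector from [effect_profile()] (log2
#'   scale); must cover every construct.
#' @param config a `simulation_config`.
#' @return list with `reference` and `treated`, each a `screen_counts`
#'   holding `n_pools * n_replicates` samples; a sample's rows outside its
#'   own pool are structurally zero.
#' @export
simulate_screen_counts <- function(design, effects,
                                   config = simulation_config()) {
  stopifnot(inherits(design, "library_design"),
            inherits(config, "simulation_config"))
  con <- design$constructs
  if (nrow(con) == 0L) stop("empty design", call. = FALSE)
  if (!all(con$shrna_id %in% names(effects)))
    stop("effects must cover every construct", call. = FALSE)
  effects <- effects[con$shrna_id]

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed)

  n_rep <- config$n_replicates
  phi <- config$dispersion
  draw <- function(mu) {
    if (phi == 0) stats::rpois(length(mu), mu)
    else stats::rnbinom(length(mu), mu = mu, size = 1 / phi)
  }

  arms <- list(reference = NULL, treated = NULL)
  mats <- list(reference = list(), treated = list())
  meta <- list(reference = list(), treated = list())
  for (p in seq_len(design$n_pools)) {
    rows <- which(con$pool == p)
    base <- stats::rlnorm(length(rows), meanlog = 0,
                          sdlog = config$abundance_sdlog)
    prop_ref <- base / sum(base)
    w <- base * 2^effects[rows]
    prop_trt <- w / sum(w)
    for (arm in c("reference", "treated")) {
      prop <- if (arm == "reference") prop_ref else prop_trt
      for (r in seq_len(n_rep)) {
        y <- integer(nrow(con))
        y[rows] <- draw(config$sequencing_depth * prop)
        mats[[arm]][[length(mats[[arm]]) + 1L]] <- y
        meta[[arm]][[length(meta[[arm]]) + 1L]] <- data.frame(
          sample_id = sprintf("pool%02d_%s_rep%d", p, arm, r),
          pool = p, condition = arm, replicate = r,
          stringsAsFactors = FALSE)
      }
    }
  }
  for (arm in c("reference", "treated")) {
    mat <- do.call(cbind, mats[[arm]])
    rownames(mat) <- con$shrna_id
    s <- do.call(rbind, meta[[arm]])
    s$unassigned <- 0L
    s$total_reads <- colSums(mat)
    colnames(mat) <- s$sample_id
    arms[[arm]] <- screen_counts(mat, s)
  }
  arms
}

#' Emit a FASTQ file for one sample
#'
#' Writes one read per counted molecule: the construct reference (constant
#' flank, barcode at [default_barcode_offset()], filler to `read_length`),
#' with substitution errors at `error_rate`. In addition,
#' `ceiling(f / (1 - f) * n_assigned)` unassignable random-sequence reads are
#' appended (spike-in emulation, `f = spike_in_fraction`), so that the
#' spike-in makes up approximately `f` of all reads. Read order is shuffled.
#' Output is 4-line FASTQ with Phred+33 qualities, gzipped when `path` ends
#' in `.gz`.
#'
#' @param counts named integer vector (shRNA id -> molecule count) for the
#'   constructs of one pool, or a one-column `screen_counts`.
#' @param design a `library_design`.
#' @param path output FASTQ path (`.gz` for gzip).
#' @param config a `simulation_config`.
#' @param seed optional seed override (default `config$seed`).
#' @return `path` invisibly.
#' @export
emit_fastq <- function(counts, design, path, config = simulation_config(),
                       seed = config$seed) {
  stopifnot(inherits(design, "library_design"))
  if (inherits(counts, "screen_counts")) {
    if (ncol(counts$counts) != 1L)
      stop("counts must be a single sample column")
    counts <- stats::setNames(counts$counts[, 1], rownames(counts$counts))
  }
  con <- design$constructs
  counts <- counts[counts > 0]
  if (length(counts) && !all(names(counts) %in% con$shrna_id))
    stop("counts name shRNAs absent from the library", call. = FALSE)
  pools <- unique(con$pool[match(names(counts), con$shrna_id)])
  if (length(pools) > 1L)
    stop("sample column spans several pools: ",
         paste(sort(pools), collapse = ", "), call. = FALSE)

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)

  rl <- config$read_length
  refs <- construct_reference(con$barcode[match(names(counts), con$shrna_id)],
                              rl, barcode_length = design$barcode_length)
  reads <- if (length(refs)) rep(refs, counts) else character(0)
  n_assigned <- length(reads)

  if (config$error_rate > 0 && n_assigned > 0) {
    nerr <- stats::rbinom(n_assigned, rl, config$error_rate)
    for (i in which(nerr > 0L)) {
      pos <- sample.int(rl, nerr[i])
      for (p in pos) {
        cur <- substr(reads[i], p, p)
        substr(reads[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
      }
    }
  }

  f <- config$spike_in_fraction
  n_spike <- if (f > 0) ceiling(f / (1 - f) * n_assigned) else 0L
  if (n_spike > 0) {
    spikes <- vapply(seq_len(n_spike), function(i)
      paste0(sample(c("A", "C", "G", "T"), rl, replace = TRUE),
             collapse = ""), character(1))
    reads <- c(reads, spikes)
  }
  if (length(reads)) reads <- reads[sample.int(length(reads))]

  x <- Biostrings::DNAStringSet(reads)
  names(x) <- sprintf("read%07d", seq_along(reads))
  qual <- Biostrings::BStringSet(strrep("I", nchar(reads)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}
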