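#' Read a pipeline configuration file
#'
#' YAML configuration mirroring the pipeline stages. Top-level keys:
#' `seed`, `outdir`, `library` (either `manifest: <tsv>` or a `design`
#' block with [design_library()] arguments), `counts` (either a `simulate`
#' block with [simulation_config()] fields plus `effects` /
#' `counter_effects` gene maps, or a `samples` sheet whose rows have
#' `sample_id`, `pool`, `condition`, `replicate`, `file`), `quantify`
#' ([quantify()] options), `hit_criteria` ([hit_criteria()] fields),
#' `subtract` (optional `counter_hits` path, one gene per line) and
#' `enrichment` (optional `gmt` path and `fdr_threshold`).
#'
#' @param path YAML file.
#' @return the configuration as a named list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  cfg$config_path <- path
  cfg
}

#' Run the pooled-screen pipeline end-to-end
#'
#' Orchestrates library design (or manifest loading), count acquisition
#' (simulation or FASTQ quantification via a sample sheet), per-pool
#' differential representation, gene-level hit calling, optional
#' counter-screen subtraction and optional gene-set over-representation.
#' Writes `library_manifest.tsv`, per-arm count TSVs, `differential.tsv`,
#' `gene_hits.tsv`, `hits_final.txt`, optional counter-screen tables,
#' optional `enrichment.tsv`, and a `run_manifest.json` recording package
#' version, seed and a config digest. Re-running with an identical config
#' and seed reproduces byte-identical result tables.
#'
#' @param config a configuration list or path to a YAML file
#'   (see [read_pipeline_config()]).
#' @param outdir,seed optional overrides of the config values.
#' @return invisibly, a run report list: output paths, the hit data.frame,
#'   final hit list, and per-stage row counts.
#' @export
run_pipeline <- function(config, outdir = NULL, seed = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (is.null(outdir)) outdir <- config$outdir
  if (is.null(outdir)) stop("no output directory configured", call. = FALSE)
  if (is.null(seed)) seed <- config$seed
  if (is.null(seed)) seed <- 1L
  seed <- as.integer(seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "': ", conditionMessage(e),
           call. = FALSE))
  }
  paths <- list()

  ## --- library ---------------------------------------------------------
  design <- stage("library", {
    lib_cfg <- config$library
    if (is.null(lib_cfg)) stop("missing 'library' block")
    if (!is.null(lib_cfg$manifest)) {
      read_library_manifest(lib_cfg$manifest)
    } else if (!is.null(lib_cfg$design)) {
      d <- lib_cfg$design
      design_library(
        n_genes = d$n_genes,
        per_gene_min = d$per_gene_min %||% 4L,
        per_gene_max = d$per_gene_max %||% 7L,
        n_pools = d$n_pools %||% 10L,
        equal_pools = d$equal_pools %||% FALSE,
        total_constructs = d$total_constructs,
        barcode_length = d$barcode_length %||% 22L,
        seed = seed)
    } else stop("library block needs 'manifest' or 'design'")
  })
  paths$library_manifest <- file.path(outdir, "library_manifest.tsv")
  write_library_manifest(design, paths$library_manifest)

  ## --- counts ----------------------------------------------------------
  counts_cfg <- config$counts
  if (is.null(counts_cfg)) stop("missing 'counts' block", call. = FALSE)
  counter_pools <- NULL

  if (!is.null(counts_cfg$simulate)) {
    sim <- counts_cfg$simulate
    mk_config <- function(s) simulation_config(
      n_replicates = sim$n_replicates %||% 3L,
      sequencing_depth = sim$sequencing_depth %||% 5e6,
      dispersion = sim$dispersion %||% 0.1,
      abundance_sdlog = sim$abundance_sdlog %||% 0.5,
      spike_in_fraction = sim$spike_in_fraction %||% 0.10,
      read_length = sim$read_length %||% 75L,
      error_rate = sim$error_rate %||% 0,
      seed = s)
    arms <- stage("simulate", {
      eff <- effect_profile(design,
                            gene_effects = unlist(sim$effects),
                            n_affected = sim$n_affected)
      simulate_screen_counts(design, eff, mk_config(seed + 1L))
    })
    pools_list <- .per_pool(arms$reference, arms$treated, design)
    if (!is.null(sim$counter_effects)) {
      counter_arms <- stage("simulate_counter", {
        eff <- effect_profile(design,
                              gene_effects = unlist(sim$counter_effects),
                              n_affected = sim$n_affected)
        simulate_screen_counts(design, eff, mk_config(seed + 2L))
      })
      counter_pools <- .per_pool(counter_arms$reference,
                                 counter_arms$treated, design)
    }
  } else if (!is.null(counts_cfg$samples)) {
    sheet <- stage("sample_sheet", {
      s <- do.call(rbind, lapply(counts_cfg$samples, as.data.frame))
      needed <- c("sample_id", "pool", "condition", "replicate", "file")
      if (!all(needed %in% names(s)))
        stop("sample sheet rows need: ", paste(needed, collapse = ", "))
      if (!all(s$condition %in% c("reference", "treated")))
        stop("sample sheet conditions must be 'reference' or 'treated'")
      for (p in unique(s$pool)) {
        have <- unique(s$condition[s$pool == p])
        miss <- setdiff(c("reference", "treated"), have)
        if (length(miss))
          stop("pool ", p, " is missing the ", paste(miss, collapse = " and "),
               " arm")
      }
      s
    })
    q <- config$quantify
    pools_list <- stage("quantify", {
      cols <- lapply(seq_len(nrow(sheet)), function(i) {
        r <- sheet[i, ]
        quantify(r$file, design, pool_index = r$pool,
                 max_mismatches = q$max_mismatches %||% 0L,
                 barcode_offset = q$barcode_offset %||%
                   default_barcode_offset(),
                 scan_offsets = q$scan_offsets %||% FALSE,
                 sample_id = r$sample_id, condition = r$condition,
                 replicate = r$replicate)
      })
      lapply(split(cols, sheet$pool), merge_columns)
    })
  } else stop("counts block needs 'simulate' or 'samples'", call. = FALSE)

  paths$counts <- vapply(names(pools_list), function(p) {
    f <- file.path(outdir, sprintf("counts_pool%02d.tsv", as.integer(p)))
    write_counts_tsv(pools_list[[p]], f)
    f
  }, character(1))

  ## --- differential ----------------------------------------------------
  diff_res <- stage("differential", {
    do.call(rbind, lapply(pools_list, test_shrna, design = design))
  })
  rownames(diff_res) <- NULL
  paths$differential <- file.path(outdir, "differential.tsv")
  .write_tsv(diff_res, paths$differential)

  ## --- hit calling -----------------------------------------------------
  hc_cfg <- config$hit_criteria
  criteria <- hit_criteria(
    fdr_threshold = hc_cfg$fdr_threshold %||% 0.05,
    lfc_threshold = hc_cfg$lfc_threshold %||% 1,
    min_enriched = hc_cfg$min_enriched %||% 2L,
    require_distinct_pools = hc_cfg$require_distinct_pools %||% TRUE,
    exclude_if_any_depleted = hc_cfg$exclude_if_any_depleted %||% TRUE)
  hits_df <- stage("hit_calling", call_hits(diff_res, design, criteria))
  paths$gene_hits <- file.path(outdir, "gene_hits.tsv")
  .write_tsv(hits_df, paths$gene_hits)
  hits_main <- hits_df$gene_id[hits_df$is_hit]

  ## --- counter screen --------------------------------------------------
  hits_counter <- character(0)
  if (!is.null(counter_pools)) {
    counter_diff <- stage("differential_counter", {
      do.call(rbind, lapply(counter_pools, test_shrna, design = design))
    })
    rownames(counter_diff) <- NULL
    paths$counter_differential <- file.path(outdir,
                                            "counter_differential.tsv")
    .write_tsv(counter_diff, paths$counter_differential)
    counter_hits_df <- stage("hit_calling_counter",
                             call_hits(counter_diff, design, criteria))
    paths$counter_gene_hits <- file.path(outdir, "counter_gene_hits.tsv")
    .write_tsv(counter_hits_df, paths$counter_gene_hits)
    hits_counter <- counter_hits_df$gene_id[counter_hits_df$is_hit]
  } else if (!is.null(config$subtract$counter_hits)) {
    hits_counter <- stage("subtract",
                          readLines(config$subtract$counter_hits,
                                    warn = FALSE))
  }
  hits_final <- subtract_counter_screen(hits_main, hits_counter)
  paths$hits_final <- file.path(outdir, "hits_final.txt")
  writeLines(hits_final, paths$hits_final)

  ## --- enrichment ------------------------------------------------------
  enr_res <- NULL
  if (!is.null(config$enrichment$gmt)) {
    enr_res <- stage("enrichment", {
      sets <- read_gmt(config$enrichment$gmt)
      enrich(hits_final, sets,
             universe = unique(design$constructs$gene_id),
             fdr_threshold = config$enrichment$fdr_threshold %||% 0.1,
             ease = config$enrichment$ease %||% FALSE)
    })
    paths$enrichment <- file.path(outdir, "enrichment.tsv")
    .write_tsv(enr_res, paths$enrichment)
  }

  ## --- run manifest ----------------------------------------------------
  manifest <- list(
    package = "poolscreen",
    version = as.character(utils::packageVersion("poolscreen")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    config_md5 = if (!is.null(config$config_path))
      unname(tools::md5sum(config$config_path)) else NA,
    n_constructs = nrow(design$constructs),
    n_pools = design$n_pools,
    n_hits_main = length(hits_main),
    n_hits_counter = length(hits_counter),
    n_hits_final = length(hits_final),
    outputs = paths)
  paths$run_manifest <- file.path(outdir, "run_manifest.json")
  jsonlite::write_json(manifest, paths$run_manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(paths = paths, design = design, differential = diff_res,
                 gene_hits = hits_df, hits_main = hits_main,
                 hits_counter = hits_counter, hits_final = hits_final,
                 enrichment = enr_res))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# split reference/treated whole-library matrices into per-pool
# screen_counts (rows restricted to the pool's constructs)
.per_pool <- function(reference, treated, design) {
  pools <- sort(unique(design$constructs$pool))
  out <- lapply(pools, function(p) {
    ids <- design$constructs$shrna_id[design$constructs$pool == p]
    rsel <- which(reference$samples$pool == p)
    tsel <- which(treated$samples$pool == p)
    mat <- cbind(reference$counts[ids, rsel, drop = FALSE],
                 treated$counts[ids, tsel, drop = FALSE])
    samp <- rbind(reference$samples[rsel, ], treated$samples[tsel, ])
    samp$total_reads <- colSums(mat) + samp$unassigned
    screen_counts(mat, samp)
  })
  names(out) <- pools
  out
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
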