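#' Gene-level hit-calling criteria
#'
#' The screen's selection rule for a hit gene is the conjunction of:
#' at least `min_enriched` member shRNAs enriched (FDR below
#' `fdr_threshold` with positive log2 fold change); the enriched shRNAs
#' coming from at least `min_enriched` distinct pools (when
#' `require_distinct_pools`); at least one enriched shRNA with log2 fold
#' change at or above `lfc_threshold`; and no member shRNA significantly
#' depleted (FDR below threshold with negative fold change, any magnitude)
#' when `exclude_if_any_depleted`.
#'
#' @param fdr_threshold shRNA-level FDR cutoff (default 0.05).
#' @param lfc_threshold log2 fold-change cutoff for the strongest enriched
#'   shRNA (default 1, i.e. more than two-fold).
#' @param min_enriched minimum number of enriched shRNAs (default 2).
#' @param require_distinct_pools require the enriched shRNAs to come from
#'   distinct pools (default TRUE).
#' @param exclude_if_any_depleted disqualify genes with any significantly
#'   depleted shRNA (default TRUE).
#' @return a `hit_criteria` list.
#' @export
hit_criteria <- function(fdr_threshold = 0.05, lfc_threshold = 1,
                         min_enriched = 2L, require_distinct_pools = TRUE,
                         exclude_if_any_depleted = TRUE) {
  if (fdr_threshold <= 0 || lfc_threshold <= 0)
    stop("thresholds must be positive")
  if (min_enriched < 1L) stop("min_enriched must be >= 1")
  structure(list(fdr_threshold = fdr_threshold,
                 lfc_threshold = lfc_threshold,
                 min_enriched = as.integer(min_enriched),
                 require_distinct_pools = isTRUE(require_distinct_pools),
                 exclude_if_any_depleted = isTRUE(exclude_if_any_depleted)),
            class = "hit_criteria")
}

#' Call gene-level hits from per-shRNA differential results
#'
#' Aggregates per-shRNA statistics to one call per library gene by the
#' conjunction rule in [hit_criteria()]. Every violated rule is recorded in
#' `failure_reasons` (semicolon-separated), not only the first. Genes with
#' fewer than `min_enriched` constructs in the library can never qualify and
#' are reported with reason `insufficient_constructs`.
#'
#' @param results data.frame of per-shRNA results (needs `shrna_id`,
#'   `pool`, `log2fc`, `fdr`), e.g. from [screen_differential()]. shRNAs of
#'   the library absent from `results` are treated as untested (neutral).
#' @param library a `library_design`; every result's `shrna_id` must exist
#'   in it.
#' @param criteria a `hit_criteria`.
#' @return data.frame with one row per library gene: `gene_id`,
#'   `n_constructs`, `n_enriched`, `enriched_pools` (comma-separated),
#'   `max_log2fc_enriched`, `n_depleted`, `is_hit`, `failure_reasons`.
#' @export
call_hits <- function(results, library, criteria = hit_criteria()) {
  stopifnot(inherits(library, "library_design"),
            inherits(criteria, "hit_criteria"))
  con <- library$constructs
  unknown <- setdiff(results$shrna_id, con$shrna_id)
  if (length(unknown))
    stop("results reference unknown shRNA(s): ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)

  enr <- results$fdr < criteria$fdr_threshold & results$log2fc > 0
  dep <- results$fdr < criteria$fdr_threshold & results$log2fc < 0
  gene_of <- con$gene_id[match(results$shrna_id, con$shrna_id)]

  genes <- unique(con$gene_id)
  n_constructs <- as.integer(table(con$gene_id)[genes])

  out <- data.frame(gene_id = genes, n_constructs = n_constructs,
                    n_enriched = 0L, enriched_pools = "",
                    max_log2fc_enriched = NA_real_, n_depleted = 0L,
                    is_hit = FALSE, failure_reasons = "",
                    stringsAsFactors = FALSE)
  rownames(out) <- genes

  enr_split <- split(which(enr), gene_of[enr])
  dep_split <- split(which(dep), gene_of[dep])

  for (g in genes) {
    e <- enr_split[[g]]
    d <- dep_split[[g]]
    n_e <- length(e)
    pools_e <- sort(unique(results$pool[e]))
    max_lfc <- if (n_e) max(results$log2fc[e]) else NA_real_
    n_d <- length(d)

    reasons <- character(0)
    if (out[g, "n_constructs"] < criteria$min_enriched)
      reasons <- c(reasons, "insufficient_constructs")
    if (n_e < criteria$min_enriched)
      reasons <- c(reasons, "min_enriched")
    if (criteria$require_distinct_pools &&
        length(pools_e) < criteria$min_enriched)
      reasons <- c(reasons, "distinct_pools")
    if (is.na(max_lfc) || max_lfc < criteria$lfc_threshold)
      reasons <- c(reasons, "lfc_threshold")
    if (criteria$exclude_if_any_depleted && n_d > 0L)
      reasons <- c(reasons, "depleted_shrna")

    out[g, "n_enriched"] <- n_e
    out[g, "enriched_pools"] <- paste(pools_e, collapse = ",")
    out[g, "max_log2fc_enriched"] <- max_lfc
    out[g, "n_depleted"] <- n_d
    out[g, "is_hit"] <- length(reasons) == 0L
    out[g, "failure_reasons"] <- paste(reasons, collapse = ";")
  }
  rownames(out) <- NULL
  out
}

#' Subtract counter-screen hits from the main hit list
#'
#' Genes that are also hits under a generic selective pressure (e.g. a
#' proapoptotic drug) are removed, leaving hits specific to the main
#' treatment. Output is sorted for deterministic serialization.
#'
#' @param hits_main character vector of main-screen hit genes.
#' @param hits_counter character vector of counter-screen hit genes.
#' @return sorted character vector `hits_main` minus `hits_counter`.
#' @export
subtract_counter_screen <- function(hits_main, hits_counter) {
  sort(setdiff(hits_main, hits_counter))
}
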