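#' Read gene sets from a GMT file
#'
#' Standard GMT format: one set per line, tab-separated
#' `term_id <TAB> term_name <TAB> gene1 <TAB> gene2 ...`.
#'
#' @param path path to a GMT file.
#' @return named list of gene sets; each element is a list with `term_id`,
#'   `term_name` and `members` (character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("malformed GMT line (need id, name, >=1 member): ",
           substr(ln, 1, 40), call. = FALSE)
    list(term_id = f[1], term_name = f[2], members = unique(f[-(1:2)]))
  })
  names(sets) <- vapply(sets, `[[`, character(1), "term_id")
  sets
}

#' Hypergeometric over-representation analysis
#'
#' Tests each gene set for over-representation in a hit list against a gene
#' universe. Set members are intersected with the universe before testing;
#' the p-value is the exact upper hypergeometric tail `P(X >= k)` of drawing
#' `k` set members in a hit list of size `n` from a universe of `N` genes of
#' which `K` belong to the set. BH adjustment is applied across all supplied
#' terms. With `ease = TRUE` the more conservative EASE-style variant
#' (`P(X >= k)` computed with one overlapping gene removed, i.e. on `k - 1`)
#' is used.
#'
#' @param hits character vector of hit genes; must be contained in
#'   `universe`.
#' @param gene_sets list of gene sets from [read_gmt()] (or any list of
#'   `list(term_id, term_name, members)`).
#' @param universe character vector of all genes considered by the screen
#'   (typically every gene in the library design).
#' @param fdr_threshold significance cutoff on the adjusted p-value
#'   (default 0.1).
#' @param ease use the EASE-adjusted score (default FALSE).
#' @return data.frame sorted by p-value then term id, with columns
#'   `term_id`, `term_name`, `k` (overlap), `K` (set size in universe),
#'   `n` (hit-list size), `N` (universe size), `p_value`, `fdr`,
#'   `significant`.
#' @export
enrich <- function(hits, gene_sets, universe, fdr_threshold = 0.1,
                   ease = FALSE) {
  hits <- unique(hits)
  universe <- unique(universe)
  stray <- setdiff(hits, universe)
  if (length(stray))
    stop("hit genes not in universe: ", paste(stray, collapse = ", "),
         call. = FALSE)
  n <- length(hits)
  N <- length(universe)
  rows <- lapply(gene_sets, function(gs) {
    members <- intersect(gs$members, universe)
    K <- length(members)
    k <- length(intersect(hits, members))
    kk <- if (ease) max(k - 1L, 0L) else k
    p <- stats::phyper(kk - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = gs$term_id, term_name = gs$term_name,
               k = k, K = K, n = n, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$fdr <- bh_adjust(out$p_value)
  out$significant <- out$fdr < fdr_threshold
  out[order(out$p_value, out$term_id), , drop = FALSE]
}
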