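#' Counts-per-million normalization
#'
#' Scales each sample (column) to a common library size of one million:
#' `cpm_ij = count_ij / colsum_j * 1e6`.
#'
#' @param counts a `screen_counts` or an integer matrix.
#' @return numeric matrix of the same shape; every column sums to 1e6.
#' @export
cpm <- function(counts) {
  mat <- if (inherits(counts, "screen_counts")) counts$counts else
    as.matrix(counts)
  cs <- colSums(mat)
  zero <- which(cs == 0)
  if (length(zero))
    stop("zero-sum sample column(s): ",
         paste(colnames(mat)[zero], collapse = ", "), call. = FALSE)
  sweep(mat, 2, cs, "/") * 1e6
}

#' Moderated method-of-moments dispersion estimate
#'
#' Per-shRNA negative-binomial dispersion from size-normalized counts
#' (scaled to the geometric-mean library size), pooled across the two arms
#' by within-arm degrees of freedom: `phi_i = (v_i - m_i) / m_i^2`. Raw
#' estimates are shrunk toward the common (all-shRNA mean) dispersion with a
#' prior weight of `prior_df` degrees of freedom,
#' `phi_shrunk = (prior_df * phi_common + df_i * max(phi_i, 0)) /
#' (prior_df + df_i)`, and floored at 1e-8. With a single replicate per arm
#' the per-shRNA estimate is unavailable and the common dispersion (computed
#' across arms, which conservatively absorbs treatment effects) is used for
#' every shRNA, with a warning.
#'
#' @param counts a `screen_counts` for one pool (both arms).
#' @param arm_labels character vector per sample (`reference`/`treated`);
#'   default from metadata.
#' @param prior_df shrinkage weight in pseudo-degrees of freedom
#'   (default 10).
#' @return list with `dispersion` (named per-shRNA vector), `common`
#'   (scalar) and `raw` (unshrunk per-shRNA estimates).
#' @export
estimate_dispersion <- function(counts, arm_labels = NULL, prior_df = 10) {
  stopifnot(inherits(counts, "screen_counts"))
  mat <- counts$counts
  if (is.null(arm_labels)) arm_labels <- counts$samples$condition
  arms <- split(seq_len(ncol(mat)), arm_labels)
  libsize <- colSums(mat)
  gm <- exp(mean(log(libsize[libsize > 0])))
  adj <- sweep(mat, 2, gm / libsize, "*")

  floor_val <- 1e-8
  n_per_arm <- lengths(arms)
  if (all(n_per_arm < 2L)) {
    warning("single replicate per arm: falling back to common dispersion ",
            "estimated across arms")
    m <- rowMeans(adj)
    v <- apply(adj, 1, stats::var)
    raw <- ifelse(m > 0, (v - m) / m^2, NA_real_)
    common <- max(mean(raw, na.rm = TRUE), floor_val)
    disp <- rep(common, nrow(mat))
    names(disp) <- rownames(mat)
    return(list(dispersion = disp, common = common, raw = raw))
  }

  ss <- numeric(nrow(mat))   # weighted sum of (v - m)/m^2 per shRNA
  df <- 0
  raw <- numeric(nrow(mat))
  for (a in arms) {
    if (length(a) < 2L) next
    m <- rowMeans(adj[, a, drop = FALSE])
    v <- apply(adj[, a, drop = FALSE], 1, stats::var)
    w <- length(a) - 1L
    contrib <- ifelse(m > 0, (v - m) / m^2, 0)
    ss <- ss + w * contrib
    df <- df + w
  }
  raw <- ss / df
  common <- max(mean(raw[is.finite(raw)]), floor_val)
  shrunk <- (prior_df * common + df * pmax(raw, 0)) / (prior_df + df)
  disp <- pmax(shrunk, floor_val)
  names(disp) <- rownames(mat)
  list(dispersion = disp, common = common, raw = raw)
}

#' Exact conditional negative-binomial test for one shRNA
#'
#' Conditions on the total of size-adjusted counts over both arms. Under the
#' null of equal proportional representation, the reference-arm total `S1`
#' given `S1 + S2 = t` follows the conditional law of two independent
#' negative binomials with sizes `n1/phi` and `n2/phi` and a common mean per
#' replicate; the two-sided p-value is the probability mass of all splits
#' whose conditional probability does not exceed that of the observed split.
#' For `phi` below 1e-6 the Poisson limit (binomial conditional) is used.
#'
#' @param s1,s2 rounded size-adjusted arm totals.
#' @param n1,n2 replicates per arm.
#' @param phi dispersion.
#' @return two-sided p-value in (0, 1].
#' @export
exact_nb_test <- function(s1, s2, n1, n2, phi) {
  t <- s1 + s2
  if (t == 0L) return(1)
  k <- 0:t
  if (phi < 1e-6) {
    lf <- stats::dbinom(k, t, n1 / (n1 + n2), log = TRUE)
  } else {
    r1 <- n1 / phi
    r2 <- n2 / phi
    lf <- lchoose(k + r1 - 1, k) + lchoose(t - k + r2 - 1, t - k)
  }
  lf <- lf - max(lf)
  f <- exp(lf)
  f <- f / sum(f)
  min(1, sum(f[f <= f[s1 + 1L] * (1 + 1e-10)]))
}

#' Test shRNAs for differential representation between arms
#'
#' For each shRNA of one pool: the log2 fold change of mean CPM (treated vs
#' reference, pseudocount-stabilized), and a two-sided p-value from the
#' exact conditional negative-binomial test on arm totals of counts scaled
#' to the geometric-mean library size, using the moderated per-shRNA
#' dispersion. P-values are Benjamini-Hochberg adjusted within the pool.
#' shRNAs with zero counts in every sample get `p = 1`, `log2fc = 0` and the
#' flag `all_zero`.
#'
#' @param counts a `screen_counts` holding both arms of one pool.
#' @param arm_labels optional condition labels per sample (default from
#'   metadata).
#' @param pseudocount CPM pseudocount for the fold change (default 0.5).
#' @param dispersion optional per-shRNA dispersion vector; estimated via
#'   [estimate_dispersion()] when missing.
#' @param design optional `library_design` used to annotate gene ids.
#' @return data.frame with columns `shrna_id`, `gene_id`, `pool`,
#'   `mean_cpm_ref`, `mean_cpm_trt`, `log2fc`, `dispersion`, `p_value`,
#'   `fdr`, `flag`.
#' @export
test_shrna <- function(counts, arm_labels = NULL, pseudocount = 0.5,
                       dispersion = NULL, design = NULL) {
  stopifnot(inherits(counts, "screen_counts"))
  mat <- counts$counts
  if (is.null(arm_labels)) arm_labels <- counts$samples$condition
  if (!all(arm_labels %in% c("reference", "treated")))
    stop("arm_labels must be 'reference' or 'treated'")
  ref <- which(arm_labels == "reference")
  trt <- which(arm_labels == "treated")
  if (!length(ref) || !length(trt))
    stop("both arms need at least one replicate")
  pool <- unique(counts$samples$pool)
  if (length(pool) != 1L)
    stop("test_shrna expects samples from a single pool")

  if (is.null(dispersion))
    dispersion <- estimate_dispersion(counts)$dispersion
  dispersion <- dispersion[rownames(mat)]

  cpm_mat <- cpm(counts)
  mean_ref <- rowMeans(cpm_mat[, ref, drop = FALSE])
  mean_trt <- rowMeans(cpm_mat[, trt, drop = FALSE])
  log2fc <- log2((mean_trt + pseudocount) / (mean_ref + pseudocount))

  libsize <- colSums(mat)
  gm <- exp(mean(log(libsize[libsize > 0])))
  adj <- sweep(mat, 2, gm / pmax(libsize, 1), "*")
  s1 <- round(rowSums(adj[, ref, drop = FALSE]))
  s2 <- round(rowSums(adj[, trt, drop = FALSE]))

  n1 <- length(ref); n2 <- length(trt)
  pvals <- vapply(seq_len(nrow(mat)), function(i)
    exact_nb_test(s1[i], s2[i], n1, n2, dispersion[i]), numeric(1))

  all_zero <- s1 + s2 == 0
  pvals[all_zero] <- 1
  log2fc[all_zero] <- 0

  gene <- if (!is.null(design))
    design$constructs$gene_id[match(rownames(mat),
                                    design$constructs$shrna_id)]
  else NA_character_

  data.frame(
    shrna_id = rownames(mat),
    gene_id = gene,
    pool = pool,
    mean_cpm_ref = mean_ref,
    mean_cpm_trt = mean_trt,
    log2fc = log2fc,
    dispersion = unname(dispersion),
    p_value = pvals,
    fdr = bh_adjust(pvals),
    flag = ifelse(all_zero, "all_zero", ""),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment, capped at 1 and
#' order-consistent with the input.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return adjusted values, same order as `p`; empty in, empty out.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(is.na(p)) || any(p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Differential representation across all pools
#'
#' Runs [test_shrna()] within each pool of a screen (reference and treated
#' count matrices from the same library) and concatenates the per-pool
#' results; BH adjustment is within-pool, mirroring the per-pool
#' experimental units of the screen design.
#'
#' @param reference,treated `screen_counts` objects covering the same
#'   constructs, with samples from one or more pools.
#' @param design a `library_design` for gene annotation.
#' @param pseudocount CPM pseudocount (default 0.5).
#' @return data.frame of per-shRNA results, all pools.
#' @export
screen_differential <- function(reference, treated, design,
                                pseudocount = 0.5) {
  stopifnot(inherits(reference, "screen_counts"),
            inherits(treated, "screen_counts"))
  pools <- sort(unique(c(reference$samples$pool, treated$samples$pool)))
  out <- vector("list", length(pools))
  for (i in seq_along(pools)) {
    p <- pools[i]
    rsel <- which(reference$samples$pool == p)
    tsel <- which(treated$samples$pool == p)
    rows <- which(design$constructs$pool == p)
    ids <- design$constructs$shrna_id[rows]
    mat <- cbind(reference$counts[ids, rsel, drop = FALSE],
                 treated$counts[ids, tsel, drop = FALSE])
    samp <- rbind(reference$samples[rsel, ], treated$samples[tsel, ])
    samp$total_reads <- colSums(mat) + samp$unassigned
    x <- screen_counts(mat, samp)
    out[[i]] <- test_shrna(x, pseudocount = pseudocount, design = design)
  }
  do.call(rbind, out)
}
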