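#' Pair an RNA and a protein dataset
#'
#' Bundles two matched tables — either two expression tables (gene
#' level) or two PAL tables (pathway level) — with an explicit sample
#' pairing. Pairing is supplied as a two-column table (RNA sample id,
#' protein sample id) rather than inferred from id string matching,
#' because id conventions differ across repositories; with `pairing =
#' NULL` samples present in both tables are paired by identity.
#'
#' @param rna,protein Two `expression_tbl`s or two `pal_tbl`s.
#' @param pairing Data frame whose first two columns are RNA and protein
#'   sample ids, or `NULL` for identity pairing on shared ids.
#' @return A `paired_omics` object (list: rna, protein, pairing tibble
#'   with `pair_id`, level = `"gene"` or `"pal"`).
#' @export
pair_omics <- function(rna, protein, pairing = NULL) {
  level <- if (inherits(rna, "pal_tbl") && inherits(protein, "pal_tbl")) {
    "pal"
  } else if (!inherits(rna, "pal_tbl") && !inherits(protein, "pal_tbl")) {
    "gene"
  } else {
    stop("rna and protein must be at the same level (both gene or both PAL)",
         call. = FALSE)
  }
  fcol <- if (level == "pal") "pathway_id" else "gene"
  rna_ids <- setdiff(names(rna), fcol)
  prot_ids <- setdiff(names(protein), fcol)
  if (is.null(pairing)) {
    shared <- intersect(rna_ids, prot_ids)
    if (length(shared) == 0) stop("no shared sample ids; supply `pairing`",
                                  call. = FALSE)
    pairing <- tibble::tibble(rna_sample = shared, protein_sample = shared)
  } else {
    pairing <- tibble::as_tibble(pairing)[, 1:2]
    names(pairing) <- c("rna_sample", "protein_sample")
    missing_r <- setdiff(pairing$rna_sample, rna_ids)
    missing_p <- setdiff(pairing$protein_sample, prot_ids)
    if (length(missing_r) + length(missing_p) > 0) {
      stop("pairing references absent sample(s): ",
           paste(c(missing_r, missing_p), collapse = ", "), call. = FALSE)
    }
  }
  pairing$pair_id <- pairing$rna_sample
  structure(list(rna = rna, protein = protein, pairing = pairing,
                 level = level, feature_col = fcol),
            class = "paired_omics")
}

#' @export
print.paired_omics <- function(x, ...) {
  cat(sprintf("<paired_omics> level=%s, %d sample pairs\n",
              x$level, nrow(x$pairing)))
  invisible(x)
}

paired_matrices <- function(paired) {
  fcol <- paired$feature_col
  to_mat <- function(tbl) {
    m <- as.matrix(tbl[, setdiff(names(tbl), fcol), drop = FALSE])
    rownames(m) <- tbl[[fcol]]
    m
  }
  mr <- to_mat(paired$rna)
  mp <- to_mat(paired$protein)
  feats <- intersect(rownames(mr), rownames(mp))
  if (length(feats) == 0) stop("no shared features between platforms",
                               call. = FALSE)
  list(rna = mr[feats, paired$pairing$rna_sample, drop = FALSE],
       protein = mp[feats, paired$pairing$protein_sample, drop = FALSE],
       pair_id = paired$pairing$pair_id)
}

#' Pearson and Spearman correlation of paired vectors
#'
#' `pearson_cor()` is the product-moment correlation; `spearman_cor()`
#' is the Pearson correlation of average-rank transformed values (ties
#' receive average ranks). Pairs with a missing value in either vector
#' are dropped. With fewer than 3 complete pairs, or zero variance in
#' either (ranked) vector, the correlation is undefined and `NA` is
#' returned.
#'
#' @param x,y Numeric vectors of equal length.
#' @return A single correlation in \[-1, 1\], or `NA`.
#' @export
pearson_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' @rdname pearson_cor
#' @export
spearman_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) return(NA_real_)
  pearson_cor(rank(x[ok]), rank(y[ok]))
}

cor_fun <- function(method = c("spearman", "pearson")) {
  switch(match.arg(method), spearman = spearman_cor, pearson = pearson_cor)
}

new_correlation_set <- function(tbl, axis, level, method, pooled = NULL) {
  attr(tbl, "axis") <- axis
  attr(tbl, "level") <- level
  attr(tbl, "method") <- method
  attr(tbl, "pooled") <- pooled
  class(tbl) <- unique(c("correlation_set", class(tbl)))
  tbl
}

#' @export
print.correlation_set <- function(x, ...) {
  cat(sprintf("<correlation_set> axis=%s level=%s method=%s (%d ids)\n",
              attr(x, "axis"), attr(x, "level"), attr(x, "method"), nrow(x)))
  pl <- attr(x, "pooled")
  if (!is.null(pl)) {
    cat(sprintf("  pooled 'average biosample' correlation: %.4f (n=%d)\n",
                pl$correlation, pl$n))
  }
  NextMethod()
}

#' Pooled "average biosample" correlation of a per-sample set
#'
#' @param x A per-sample `correlation_set`.
#' @return A list with elements `correlation` and `n` — the correlation
#'   over all (feature, sample-pair) points concatenated, the quantity
#'   plotted when every dot is one gene-sample pair.
#' @export
pooled_correlation <- function(x) attr(x, "pooled")

#' Per-sample RNA-protein correlation
#'
#' For each sample pair, correlates the RNA profile against the protein
#' profile across the shared features (genes or pathways). Also computes
#' the pooled "average biosample" correlation over all (feature, pair)
#' points concatenated, retrievable with [pooled_correlation()]. Pairs
#' with fewer than `min_n` complete shared features are dropped with a
#' message.
#'
#' @param paired A `paired_omics` object from [pair_omics()].
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param min_n Minimum complete feature pairs per sample (default 3).
#' @return A `correlation_set` tibble with columns `id` (pair id),
#'   `correlation`, `n`.
#' @export
per_sample_correlation <- function(paired, method = c("spearman", "pearson"),
                                   min_n = 3) {
  method <- match.arg(method)
  f <- cor_fun(method)
  m <- paired_matrices(paired)
  vals <- purrr::map2(
    seq_len(ncol(m$rna)), m$pair_id,
    function(j, id) {
      x <- m$rna[, j]; y <- m$protein[, j]
      ok <- is.finite(x) & is.finite(y)
      tibble::tibble(id = id, correlation = if (sum(ok) >= min_n) f(x, y)
                                            else NA_real_,
                     n = sum(ok))
    }) |> dplyr::bind_rows()
  dropped <- sum(is.na(vals$correlation))
  if (dropped > 0) {
    message(dropped, " sample pair(s) without a defined correlation dropped")
  }
  pooled_ok <- is.finite(m$rna) & is.finite(m$protein)
  pooled <- list(correlation = f(m$rna[pooled_ok], m$protein[pooled_ok]),
                 n = sum(pooled_ok))
  new_correlation_set(dplyr::filter(vals, !is.na(.data$correlation)),
                      axis = "per_sample", level = paired$level,
                      method = method, pooled = pooled)
}

#' Per-feature RNA-protein correlation
#'
#' For each shared feature (gene or pathway), correlates its RNA values
#' against its protein values across the sample pairs. Features constant
#' on either platform, or with fewer than `min_n` complete pairs, have
#' no defined correlation and are dropped with a message.
#'
#' @inheritParams per_sample_correlation
#' @param min_n Minimum complete sample pairs per feature (default 3).
#' @return A `correlation_set` tibble with columns `id` (feature id),
#'   `correlation`, `n`.
#' @export
per_feature_correlation <- function(paired, method = c("spearman", "pearson"),
                                    min_n = 3) {
  method <- match.arg(method)
  f <- cor_fun(method)
  m <- paired_matrices(paired)
  if (ncol(m$rna) < 3) stop("need at least 3 sample pairs", call. = FALSE)
  ok <- is.finite(m$rna) & is.finite(m$protein)
  n <- rowSums(ok)
  corr <- vapply(seq_len(nrow(m$rna)),
                 function(i) f(m$rna[i, ], m$protein[i, ]), numeric(1))
  vals <- tibble::tibble(id = rownames(m$rna), correlation = corr, n = n)
  dropped <- sum(is.na(vals$correlation))
  if (dropped > 0) {
    message(dropped, " feature(s) without a defined correlation dropped")
  }
  new_correlation_set(dplyr::filter(vals, !is.na(.data$correlation)),
                      axis = "per_feature", level = paired$level,
                      method = method, pooled = NULL)
}

#' Wilcoxon signed-rank test with exact small-sample p-values
#'
#' Paired test on `a - b`. Zero differences are dropped; tied absolute
#' differences receive average ranks. For `n <= exact_limit` (default
#' 25) the p-value is exact, from the full null distribution of the
#' positive-rank sum over all 2^n sign assignments (computed by
#' convolution over the — possibly tied — rank multiset); above that a
#' normal approximation with continuity and tie correction is used. The
#' null distribution is symmetric, so the exact two-sided p-value equals
#' the probability of a deviation from the mean rank sum at least as
#' large as observed.
#'
#' @param a,b Paired numeric vectors of equal length.
#' @param alternative `"two.sided"` (default), `"greater"` (a > b) or
#'   `"less"`.
#' @param exact_limit Largest n for which the exact distribution is
#'   enumerated.
#' @return A one-row tibble: `statistic` (positive-rank sum W), `p_value`,
#'   `n_used`, `n_zero`, `method` (`"exact"`/`"normal"`), `degenerate`
#'   (`TRUE` when all differences are zero, in which case `p_value = 1`).
#' @export
wilcoxon_signed_rank <- function(a, b,
                                 alternative = c("two.sided", "greater",
                                                 "less"),
                                 exact_limit = 25) {
  alternative <- match.arg(alternative)
  stopifnot(length(a) == length(b))
  ok <- is.finite(a) & is.finite(b)
  d <- a[ok] - b[ok]
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(tibble::tibble(statistic = 0, p_value = 1, n_used = 0L,
                          n_zero = n_zero, method = "degenerate",
                          degenerate = TRUE))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  if (n <= exact_limit) {
    # exact null distribution of W by convolution over doubled ranks
    r2 <- as.integer(round(2 * r))
    f <- 1
    for (rk in r2) f <- (c(f, rep(0, rk)) + c(rep(0, rk), f)) / 2
    support <- seq_along(f) - 1  # doubled-scale sums 0..n(n+1)
    w2 <- 2 * w
    mu2 <- 2 * mu
    p <- switch(alternative,
      two.sided = sum(f[abs(support - mu2) >= abs(w2 - mu2) - 1e-9]),
      greater   = sum(f[support >= w2 - 1e-9]),
      less      = sum(f[support <= w2 + 1e-9]))
    method <- "exact"
  } else {
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    cc <- function(shift) (w - mu - shift) / sqrt(sigma2)
    p <- switch(alternative,
      two.sided = 2 * stats::pnorm(-abs((w - mu - sign(w - mu) * 0.5) /
                                          sqrt(sigma2))),
      greater   = stats::pnorm(cc(0.5), lower.tail = FALSE),
      less      = stats::pnorm(cc(-0.5)))
    method <- "normal"
  }
  tibble::tibble(statistic = w, p_value = min(p, 1), n_used = n,
                 n_zero = n_zero, method = method, degenerate = FALSE)
}

#' Compare gene-level and pathway-level concordance
#'
#' Tests whether correlations at the pathway (PAL) level exceed those at
#' the gene level. With `pairing = "per_sample"` the two sets are paired
#' by sample-pair id and compared by the Wilcoxon signed-rank test
#' ([wilcoxon_signed_rank()] on PAL minus gene); per-feature sets have
#' different populations (genes vs pathways), so `pairing = "unpaired"`
#' falls back to the Wilcoxon rank-sum test. Undefined correlations were
#' already excluded from the sets; means are over the compared values.
#'
#' No multiple-testing correction is applied across datasets; p-values
#' are reported raw.
#'
#' @param gene_set,pal_set `correlation_set`s at the gene and PAL level.
#' @param pairing `"per_sample"` (paired by id) or `"unpaired"`.
#' @param alternative Test laterality; default `"two.sided"`.
#' @return A `level_comparison` object; see [tidy.level_comparison()]
#'   and [glance.level_comparison()].
#' @export
compare_levels <- function(gene_set, pal_set,
                           pairing = c("per_sample", "unpaired"),
                           alternative = "two.sided") {
  pairing <- match.arg(pairing)
  if (pairing == "per_sample") {
    ids <- intersect(gene_set$id, pal_set$id)
    if (length(ids) == 0) stop("no shared ids between the two sets",
                               call. = FALSE)
    g <- gene_set$correlation[match(ids, gene_set$id)]
    p <- pal_set$correlation[match(ids, pal_set$id)]
    test <- wilcoxon_signed_rank(p, g, alternative = alternative)
    stat <- test$statistic; pval <- test$p_value
  } else {
    g <- gene_set$correlation
    p <- pal_set$correlation
    if (length(g) == 0 || length(p) == 0) stop("empty correlation set",
                                               call. = FALSE)
    ht <- suppressWarnings(
      stats::wilcox.test(p, g, alternative = alternative))
    stat <- unname(ht$statistic); pval <- ht$p.value
    ids <- NULL
  }
  mean_gene <- mean(g)
  mean_pal <- mean(p)
  structure(list(
    gene_corrs = g, pal_corrs = p, ids = ids,
    statistic = stat, p_value = pval,
    mean_gene = mean_gene, mean_pal = mean_pal,
    fold_change = if (mean_gene != 0) mean_pal / mean_gene else NA_real_,
    pairing = pairing, alternative = alternative,
    method = attr(gene_set, "method"),
    n_gene = length(g), n_pal = length(p)),
    class = "level_comparison")
}

#' @export
print.level_comparison <- function(x, ...) {
  cat("<level_comparison>\n")
  cat(sprintf("  mean gene-level correlation: %.4f (n=%d)\n",
              x$mean_gene, x$n_gene))
  cat(sprintf("  mean PAL-level correlation:  %.4f (n=%d)\n",
              x$mean_pal, x$n_pal))
  cat(sprintf("  fold change (PAL/gene): %.3f\n", x$fold_change))
  cat(sprintf("  Wilcoxon (%s, %s): statistic=%.1f, p=%.3g\n",
              x$pairing, x$alternative, x$statistic, x$p_value))
  invisible(x)
}

#' Rank pathways by cross-sample RNA-protein correlation
#'
#' Builds the "top-k most / least correlated pathways" tables: pathways
#' are sorted by Spearman correlation (primary key, descending), ties
#' broken by pathway id, with Pearson reported alongside when supplied.
#'
#' @param spearman A per-feature `correlation_set` over pathways
#'   (Spearman).
#' @param pearson Optional matching Pearson `correlation_set`.
#' @param k Table depth (default 10). With fewer than `2k` pathways the
#'   tables shrink to `floor(n/2)` with a warning.
#' @return A tibble with columns `table` (`"top"`/`"bottom"`), `rank`,
#'   `pathway_id`, `spearman`, and `pearson` if supplied; the two tables
#'   are disjoint.
#' @export
rank_pathways <- function(spearman, pearson = NULL, k = 10) {
  tbl <- tibble::tibble(pathway_id = spearman$id,
                        spearman = spearman$correlation)
  if (!is.null(pearson)) {
    tbl$pearson <- pearson$correlation[match(tbl$pathway_id, pearson$id)]
  }
  n <- nrow(tbl)
  if (n < 2 * k) {
    k <- floor(n / 2)
    warning("fewer than 2k pathways; tables shrunk to k = ", k)
  }
  ord <- order(-tbl$spearman, tbl$pathway_id)
  top <- tbl[ord[seq_len(k)], ]
  bottom <- tbl[rev(ord)[seq_len(k)], ]
  dplyr::bind_rows(
    dplyr::mutate(top, table = "top", rank = dplyr::row_number()),
    dplyr::mutate(bottom, table = "bottom", rank = dplyr::row_number())) |>
    dplyr::relocate("table", "rank")
}

#' Sign concordance of pathway members across platforms
#'
#' For each member gene shared between an RNA and a protein CNR profile,
#' checks whether the direction of regulation agrees: the sign of
#' ln(CNR) on one platform equals its sign on the other, with CNR = 1
#' (no change) counted as zero sign that matches only zero.
#'
#' @param rna_cnr,prot_cnr CNR profiles from [compute_cnr()].
#' @param pathway A tibble with columns `gene` and `arr` (one pathway's
#'   membership).
#' @return A tibble with columns `gene`, `arr`, `sign_rna`,
#'   `sign_protein`, `agree`; the fraction of agreeing members is in
#'   attribute `fraction`.
#' @export
sign_concordance <- function(rna_cnr, prot_cnr, pathway) {
  shared <- pathway$gene[pathway$gene %in% rna_cnr$gene &
                         pathway$gene %in% prot_cnr$gene]
  if (length(shared) == 0) stop("no shared measured member", call. = FALSE)
  lsign <- function(cnr, genes) {
    l <- log(cnr$cnr[match(genes, cnr$gene)])
    s <- sign(l)
    s[abs(l) < 1e-12] <- 0
    s
  }
  out <- tibble::tibble(
    gene = shared,
    arr = pathway$arr[match(shared, pathway$gene)],
    sign_rna = lsign(rna_cnr, shared),
    sign_protein = lsign(prot_cnr, shared))
  out$agree <- out$sign_rna == out$sign_protein
  attr(out, "fraction") <- mean(out$agree)
  out
}
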