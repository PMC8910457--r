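#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a level comparison
#'
#' One row per compared correlation value, in long format.
#'
#' @param x A `level_comparison` from [compare_levels()].
#' @param ... Unused.
#' @return A tibble with columns `id` (when paired), `level`
#'   (`"gene"`/`"pal"`) and `correlation`.
#' @export
tidy.level_comparison <- function(x, ...) {
  if (!is.null(x$ids)) {
    dplyr::bind_rows(
      tibble::tibble(id = x$ids, level = "gene", correlation = x$gene_corrs),
      tibble::tibble(id = x$ids, level = "pal", correlation = x$pal_corrs))
  } else {
    dplyr::bind_rows(
      tibble::tibble(level = "gene", correlation = x$gene_corrs),
      tibble::tibble(level = "pal", correlation = x$pal_corrs))
  }
}

#' Glance at a level comparison
#'
#' @param x A `level_comparison` from [compare_levels()].
#' @param ... Unused.
#' @return A one-row tibble: mean correlations at both levels, fold
#'   change, Wilcoxon statistic and p-value, pairing and method tags.
#' @export
glance.level_comparison <- function(x, ...) {
  tibble::tibble(
    mean_gene = x$mean_gene,
    mean_pal = x$mean_pal,
    fold_change = x$fold_change,
    statistic = x$statistic,
    p_value = x$p_value,
    n_gene = x$n_gene,
    n_pal = x$n_pal,
    pairing = x$pairing,
    alternative = x$alternative,
    method = x$method %||% NA_character_)
}

#' Tidy a correlation set
#'
#' @param x A `correlation_set`.
#' @param ... Unused.
#' @return The underlying tibble plus `axis`, `level` and `method`
#'   columns.
#' @export
tidy.correlation_set <- function(x, ...) {
  dplyr::mutate(tibble::as_tibble(x),
                axis = attr(x, "axis"),
                level = attr(x, "level"),
                method = attr(x, "method"))
}

#' Glance at a correlation set
#'
#' @param x A `correlation_set`.
#' @param ... Unused.
#' @return A one-row tibble with the mean, sd, range and count of the
#'   correlations plus the pooled "average biosample" correlation when
#'   available.
#' @export
glance.correlation_set <- function(x, ...) {
  pl <- pooled_correlation(x)
  tibble::tibble(
    mean = mean(x$correlation),
    sd = stats::sd(x$correlation),
    min = min(x$correlation),
    max = max(x$correlation),
    n = nrow(x),
    pooled = if (!is.null(pl)) pl$correlation else NA_real_,
    axis = attr(x, "axis"),
    level = attr(x, "level"),
    method = attr(x, "method"))
}

#' Glance at a concordance report
#'
#' @param x A `concordance_report` from [run_concordance_pipeline()].
#' @param ... Unused.
#' @return The one-row glance of the main gene-vs-PAL comparison with
#'   the scored pathway count and sample-pair count appended.
#' @export
glance.concordance_report <- function(x, ...) {
  dplyr::mutate(glance(x$comparison),
                n_pathways_scored = x$manifest$n_pathways_scored,
                n_pairs = x$manifest$n_pairs)
}
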