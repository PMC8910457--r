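#' Expression tables
#'
#' An expression table is a tibble whose first column `gene` holds gene
#' symbols and whose remaining columns hold one sample each, with two
#' attributes:
#' \describe{
#'   \item{platform}{`"rna"` or `"protein"`}
#'   \item{state}{`"raw"`, `"pseudocounted"` or `"normalized"`; state
#'     only ever advances in that order}
#' }
#' RNA tables start life `raw` (integer counts) and pass through
#' [apply_pseudocount()] and [size_factor_normalize()]. Relative protein
#' abundances carry no sequencing-depth artefact, so they are loaded
#' directly as `normalized` by default. Protein values missing for a
#' sample (genes not quantified in that run) are stored as `NA` and
#' excluded gene-wise downstream rather than imputed.
#'
#' @name expression-tables
NULL

EXPR_STATES <- c("raw", "pseudocounted", "normalized")

new_expression_table <- function(tbl, platform, state) {
  platform <- match.arg(platform, c("rna", "protein"))
  state <- match.arg(state, EXPR_STATES)
  tbl <- tibble::as_tibble(tbl)
  stopifnot(names(tbl)[1] == "gene")
  attr(tbl, "platform") <- platform
  attr(tbl, "state") <- state
  class(tbl) <- unique(c("expression_tbl", class(tbl)))
  tbl
}

#' @export
print.expression_tbl <- function(x, ...) {
  cat(sprintf("<expression_tbl> %d genes x %d samples [platform=%s, state=%s]\n",
              nrow(x), ncol(x) - 1L, expr_platform(x), expr_state(x)))
  NextMethod()
}

#' @rdname expression-tables
#' @param x An expression table.
#' @export
expr_state <- function(x) attr(x, "state")

#' @rdname expression-tables
#' @export
expr_platform <- function(x) attr(x, "platform")

#' @rdname expression-tables
#' @export
sample_ids <- function(x) setdiff(names(x), "gene")

#' Convert an expression table to a genes-by-samples matrix
#'
#' @param x An expression table.
#' @return A numeric matrix with gene rownames and sample colnames.
#' @export
expr_values <- function(x) {
  m <- as.matrix(x[, setdiff(names(x), "gene"), drop = FALSE])
  rownames(m) <- x$gene
  m
}

#' Build an expression table from a matrix
#'
#' @param m Genes-by-samples numeric matrix with rownames and colnames.
#' @param platform `"rna"` or `"protein"`.
#' @param state Normalization state tag.
#' @return An expression table tibble.
#' @export
as_expression_table <- function(m, platform, state = "raw") {
  stopifnot(!is.null(rownames(m)), !is.null(colnames(m)))
  tbl <- tibble::as_tibble(m, .name_repair = "minimal")
  tbl <- dplyr::bind_cols(tibble::tibble(gene = rownames(m)), tbl)
  new_expression_table(tbl, platform, state)
}

#' Read a delimited gene-by-sample expression table
#'
#' Expects a header row of sample ids, a first column of gene symbols and
#' a numeric body. The delimiter is sniffed from the first line (tab or
#' comma); gzip input is accepted. Empty protein cells are read as `NA`
#' when `allow_missing = TRUE`; otherwise any non-numeric cell is an
#' error naming its position.
#'
#' @param file Path to a TSV/CSV file (optionally gzipped).
#' @param platform `"rna"` or `"protein"`.
#' @param state State tag of the stored values; RNA counts are `"raw"`,
#'   relative protein abundances default to `"normalized"`.
#' @param allow_missing Permit `NA` cells (default for protein input).
#' @return An expression table tibble; see [expression-tables].
#' @export
read_expression_table <- function(file,
                                  platform = c("rna", "protein"),
                                  state = if (platform[1] == "rna") "raw"
                                          else "normalized",
                                  allow_missing = platform[1] == "protein") {
  platform <- match.arg(platform)
  first <- readr::read_lines(file, n_max = 1, progress = FALSE)
  delim <- if (grepl("\t", first)) "\t" else ","
  tbl <- readr::read_delim(file, delim = delim, show_col_types = FALSE,
                           progress = FALSE,
                           col_types = readr::cols(
                             .default = readr::col_character()))
  names(tbl)[1] <- "gene"
  if (anyDuplicated(tbl$gene)) {
    stop("duplicate gene row(s): ",
         paste(unique(tbl$gene[duplicated(tbl$gene)])[1:3], collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(names(tbl))) {
    stop("duplicate sample id(s) in header", call. = FALSE)
  }
  body <- tbl[-1]
  num <- suppressWarnings(
    purrr::map(body, ~ as.numeric(.x)))
  for (j in seq_along(num)) {
    bad <- which(is.na(num[[j]]) & !(allow_missing &
                   (is.na(body[[j]]) | body[[j]] %in% c("NA", ""))))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                   body[[j]][bad[1]], tbl$gene[bad[1]], names(body)[j]),
           call. = FALSE)
    }
  }
  vals <- tibble::as_tibble(num)
  neg <- purrr::map_lgl(vals, ~ any(.x < 0, na.rm = TRUE))
  if (any(neg)) stop("negative abundance in sample ", names(vals)[neg][1],
                     call. = FALSE)
  new_expression_table(dplyr::bind_cols(tbl["gene"], vals), platform, state)
}

#' Write an expression table as TSV
#'
#' @param x An expression table.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_expression_table <- function(x, file) {
  readr::write_tsv(tibble::as_tibble(x), file, progress = FALSE)
  invisible(file)
}

#' Harmonize gene identifiers via a mapping table
#'
#' Renames genes according to a two-column old-to-new mapping (e.g.
#' Ensembl ids to HGNC symbols). Unmapped genes are dropped and their
#' count reported via a message; several old ids mapping to one new
#' symbol have their rows summed (counts of merged transcripts add).
#'
#' @param x An expression table.
#' @param mapping A data frame whose first two columns are old and new
#'   symbol, or a path to a 2-column TSV.
#' @return An expression table on the new symbol space, same state.
#' @export
map_gene_symbols <- function(x, mapping) {
  if (is.character(mapping) && length(mapping) == 1) {
    mapping <- readr::read_tsv(mapping, show_col_types = FALSE,
                               progress = FALSE)
  }
  mapping <- tibble::as_tibble(mapping)[, 1:2]
  names(mapping) <- c("old", "new")
  m <- expr_values(x)
  idx <- match(rownames(m), mapping$old)
  dropped <- sum(is.na(idx))
  if (dropped > 0) {
    message(dropped, " gene(s) without a mapping were dropped")
  }
  keep <- !is.na(idx)
  m <- m[keep, , drop = FALSE]
  new_sym <- mapping$new[idx[keep]]
  summed <- rowsum(m, group = new_sym, reorder = FALSE)
  as_expression_table(summed, expr_platform(x), expr_state(x))
}

#' Add a pseudocount to raw counts
#'
#' Adds `value` (default 1) to every cell so zero counts survive the log
#' transforms downstream. Only valid on a `raw` table; the state advances
#' to `pseudocounted`.
#'
#' @param x A raw expression table.
#' @param value Pseudocount, >= 0.
#' @return The incremented table, state `pseudocounted`.
#' @export
apply_pseudocount <- function(x, value = 1) {
  if (expr_state(x) != "raw") {
    stop("pseudocount requires state 'raw' (got '", expr_state(x), "')",
         call. = FALSE)
  }
  stopifnot(value >= 0)
  out <- dplyr::mutate(tibble::as_tibble(x),
                       dplyr::across(-"gene", ~ .x + value))
  new_expression_table(out, expr_platform(x), "pseudocounted")
}

#' Median-of-ratios size-factor normalization
#'
#' Computes per-sample size factors as the median, over genes positive
#' in every sample, of the ratio of the sample's abundance to that
#' gene's geometric mean across samples — the standard median-of-ratios
#' depth estimator — rescaled to unit geometric mean so the factors are
#' a pure relative-depth profile. Each column is then divided by its
#' factor; with that convention renormalizing an already-normalized
#' matrix returns factors of exactly 1.
#'
#' @param x A `pseudocounted` expression table with positive values.
#' @return The normalized table (state `normalized`) with the factors in
#'   attribute `size_factors` (named numeric).
#' @export
size_factor_normalize <- function(x) {
  if (expr_state(x) != "pseudocounted") {
    stop("size-factor normalization requires state 'pseudocounted' (got '",
         expr_state(x), "')", call. = FALSE)
  }
  m <- expr_values(x)
  ref_ok <- apply(m > 0, 1, all)
  if (!any(ref_ok)) {
    stop("no gene is positive in all samples; cannot form reference",
         call. = FALSE)
  }
  logm <- log(m[ref_ok, , drop = FALSE])
  loggeo <- rowMeans(logm)
  factors <- apply(exp(logm - loggeo), 2, stats::median)
  factors <- factors / exp(mean(log(factors)))
  norm <- sweep(m, 2, factors, "/")
  out <- as_expression_table(norm, expr_platform(x), "normalized")
  attr(out, "size_factors") <- factors
  out
}

#' @rdname size_factor_normalize
#' @param x A normalized expression table.
#' @export
size_factors <- function(x) attr(x, "size_factors")

#' Drop samples below a uniquely-mapped-read threshold
#'
#' Quality gate for RNA-seq libraries: samples whose uniquely mapped
#' read count falls below the threshold (default 2.5 million) are
#' removed. The comparison is inclusive: exactly-at-threshold samples
#' pass. Retained values are untouched.
#'
#' @param x An expression table.
#' @param qc A data frame whose first two columns are sample id and
#'   uniquely mapped read count, or a path to a 2-column TSV.
#' @param threshold Minimum read count to keep a sample.
#' @param missing What to do with samples absent from `qc`: `"error"`
#'   (default) or `"drop"`.
#' @return The filtered table; removed sample ids are in attribute
#'   `qc_removed`.
#' @export
qc_filter_samples <- function(x, qc, threshold = 2.5e6,
                              missing = c("error", "drop")) {
  missing <- match.arg(missing)
  if (is.character(qc) && length(qc) == 1) {
    qc <- readr::read_tsv(qc, show_col_types = FALSE, progress = FALSE)
  }
  qc <- tibble::as_tibble(qc)[, 1:2]
  names(qc) <- c("sample", "reads")
  stopifnot(all(qc$reads >= 0))
  ids <- sample_ids(x)
  reads <- qc$reads[match(ids, qc$sample)]
  if (anyNA(reads)) {
    absent <- ids[is.na(reads)]
    if (missing == "error") {
      stop("sample(s) missing from QC table: ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
    reads[is.na(reads)] <- -Inf
  }
  keep <- reads >= threshold
  if (!any(keep)) stop("QC filter removed every sample", call. = FALSE)
  removed <- ids[!keep]
  if (length(removed) > 0) {
    message("QC filter removed ", length(removed), " sample(s): ",
            paste(removed, collapse = ", "))
  }
  out <- new_expression_table(
    dplyr::select(tibble::as_tibble(x), "gene", dplyr::all_of(ids[keep])),
    expr_platform(x), expr_state(x))
  attr(out, "qc_removed") <- removed
  out
}

#' Hierarchical QC clustering of samples
#'
#' Agglomerates samples under Ward linkage (the squared-increment
#' "ward.D2" variant) on Euclidean distances between expression columns,
#' the standard visual check that libraries group by tissue rather than
#' by technical batch.
#'
#' @param x A normalized expression table with >= 2 samples.
#' @param log Cluster on log-transformed values instead of the
#'   normalized scale (default FALSE).
#' @return An [stats::hclust] tree over the samples.
#' @export
qc_cluster <- function(x, log = FALSE) {
  if (expr_state(x) != "normalized") {
    stop("qc_cluster requires a normalized table", call. = FALSE)
  }
  m <- expr_values(x)
  if (ncol(m) < 2) stop("need at least 2 samples to cluster", call. = FALSE)
  if (log) m <- base::log(m + 1e-9)
  stats::hclust(stats::dist(t(m), method = "euclidean"), method = "ward.D2")
}
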