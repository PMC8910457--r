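#' Role-annotated pathway collections
#'
#' A pathway collection is stored as a long tibble with one row per
#' (pathway, member gene) pair and columns:
#' \describe{
#'   \item{pathway_id}{unique pathway identifier}
#'   \item{pathway_name}{display name}
#'   \item{source}{originating database label (free text)}
#'   \item{gene}{member gene symbol (opaque, case-sensitive)}
#'   \item{arr}{activator/repressor role weight, one of
#'     -1, -0.5, 0, 0.5, 1: +1 activator, -1 repressor, +/-0.5 weak
#'     activator/repressor, 0 for genes with both activities}
#' }
#' The attribute \code{min_size_applied} records the last size filter
#' applied with [filter_by_size()], if any.
#'
#' @name pathway-collections
NULL

ARR_VALUES <- c(-1, -0.5, 0, 0.5, 1)

new_pathway_collection <- function(tbl, min_size_applied = NULL) {
  tbl <- tibble::as_tibble(tbl)
  attr(tbl, "min_size_applied") <- min_size_applied
  class(tbl) <- c("pathway_collection", class(tbl))
  tbl
}

#' @export
print.pathway_collection <- function(x, ...) {
  n_pw <- dplyr::n_distinct(x$pathway_id)
  cat(sprintf("<pathway_collection> %d pathways, %d membership records\n",
              n_pw, nrow(x)))
  ms <- attr(x, "min_size_applied")
  if (!is.null(ms)) cat(sprintf("  min_size_applied: %d\n", ms))
  NextMethod()
}

validate_pathway_collection <- function(tbl) {
  stopifnot(all(c("pathway_id", "pathway_name", "gene", "arr") %in% names(tbl)))
  if (any(!tbl$arr %in% ARR_VALUES)) {
    bad <- unique(tbl$arr[!tbl$arr %in% ARR_VALUES])
    stop("invalid arr value(s): ", paste(bad, collapse = ", "),
         "; allowed: -1, -0.5, 0, 0.5, 1", call. = FALSE)
  }
  if (any(!nzchar(tbl$gene)) || anyNA(tbl$gene)) {
    stop("empty gene symbol in pathway collection", call. = FALSE)
  }
  dup <- tbl |>
    dplyr::count(.data$pathway_id, .data$gene) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("duplicate gene(s) within a pathway: ",
         paste(utils::head(paste0(dup$pathway_id, "/", dup$gene), 5),
               collapse = ", "), call. = FALSE)
  }
  invisible(tbl)
}

#' Parse a role-annotated gene-set collection
#'
#' Reads the tab-delimited role-annotated gene-set format: one pathway per
#' line as \code{id<TAB>name<TAB>gene:arr<TAB>gene:arr...}, where
#' \code{arr} is one of -1, -0.5, 0, 0.5, 1. This extends the plain
#' gene-set (GMT-like) convention with a \code{:arr} role suffix per gene
#' so a single streamable file carries the whole collection.
#'
#' Duplicate genes within one line are collapsed to a single membership
#' when their roles agree; conflicting roles are an error, as is a
#' duplicated pathway id or a role outside the allowed set.
#'
#' @param file Path to a file (gzip accepted), or a character vector of
#'   lines via \code{text}.
#' @param text Optional character vector of lines, used instead of `file`.
#' @param source Fallback source label stored for every pathway.
#' @return A pathway collection tibble; see [pathway-collections].
#' @examples
#' pc <- parse_pathway_collection(
#'   text = c("P1\tToy\tA:1\tB:-1", "P2\tToy2\tC:0.5"))
#' pc
#' @export
parse_pathway_collection <- function(file = NULL, text = NULL,
                                     source = "user") {
  if (is.null(text)) {
    stopifnot(!is.null(file))
    text <- readr::read_lines(file, progress = FALSE)
  }
  text <- text[nzchar(trimws(text))]
  if (length(text) == 0) {
    return(new_pathway_collection(tibble::tibble(
      pathway_id = character(), pathway_name = character(),
      source = character(), gene = character(), arr = double())))
  }
  rows <- purrr::imap(text, function(line, i) {
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      stop(sprintf("line %d: expected id, name and at least one gene:arr token", i),
           call. = FALSE)
    }
    tokens <- parts[-(1:2)]
    m <- stringr::str_match(tokens, "^(.+):(-?[0-9.]+)$")
    if (anyNA(m[, 1])) {
      stop(sprintf("line %d (%s): malformed gene:arr token '%s'",
                   i, parts[1], tokens[which(is.na(m[, 1]))[1]]), call. = FALSE)
    }
    arr <- as.numeric(m[, 3])
    if (any(is.na(arr)) || any(!arr %in% ARR_VALUES)) {
      bad <- tokens[which(is.na(arr) | !arr %in% ARR_VALUES)[1]]
      stop(sprintf("line %d (%s): arr value in '%s' not in {-1,-0.5,0,0.5,1}",
                   i, parts[1], bad), call. = FALSE)
    }
    tb <- tibble::tibble(pathway_id = parts[1], pathway_name = parts[2],
                         source = source, gene = m[, 2], arr = arr)
    # duplicate genes: collapse when roles agree, error on conflict
    if (anyDuplicated(tb$gene)) {
      conf <- tb |>
        dplyr::summarise(n_roles = dplyr::n_distinct(.data$arr),
                         .by = "gene") |>
        dplyr::filter(.data$n_roles > 1)
      if (nrow(conf) > 0) {
        stop(sprintf("line %d (%s): gene '%s' listed with conflicting roles",
                     i, parts[1], conf$gene[1]), call. = FALSE)
      }
      tb <- dplyr::distinct(tb, .data$gene, .keep_all = TRUE)
    }
    tb
  })
  out <- dplyr::bind_rows(rows)
  first_tok <- vapply(strsplit(text, "\t", fixed = TRUE), `[`, "", 1)
  if (anyDuplicated(first_tok)) {
    stop("duplicate pathway id(s): ",
         paste(unique(first_tok[duplicated(first_tok)]), collapse = ", "),
         call. = FALSE)
  }
  validate_pathway_collection(out)
  new_pathway_collection(out)
}

#' Write a pathway collection to the role-annotated gene-set format
#'
#' Inverse of [parse_pathway_collection()]; genes are emitted in stored
#' (input) order.
#'
#' @param collection A pathway collection tibble.
#' @param file Output path; when `NULL` the lines are returned invisibly
#'   without writing.
#' @return The formatted lines, invisibly.
#' @export
write_pathway_collection <- function(collection, file = NULL) {
  # canonical short form: 1, -1, 0.5, -0.5, 0
  fmt_arr <- function(a) as.character(a)
  lines <- collection |>
    dplyr::summarise(
      line = paste(c(.data$pathway_id[1], .data$pathway_name[1],
                     paste0(.data$gene, ":", fmt_arr(.data$arr))),
                   collapse = "\t"),
      .by = "pathway_id") |>
    dplyr::pull("line")
  if (!is.null(file)) readr::write_lines(lines, file)
  invisible(lines)
}

#' Pathway sizes
#'
#' @param collection A pathway collection tibble.
#' @return A tibble with `pathway_id` and member count `size`.
#' @export
pathway_sizes <- function(collection) {
  dplyr::count(tibble::as_tibble(collection), .data$pathway_id, name = "size")
}

#' Filter a collection by minimum pathway size
#'
#' Retains pathways with at least `min_size` member genes (inclusive).
#' Pathway scoring conventionally restricts to gene sets with >= 10
#' members; size strata such as 10/20/40 are built by repeated calls.
#'
#' @param collection A pathway collection tibble.
#' @param min_size Minimum member count, >= 1.
#' @return The filtered collection; the threshold is recorded in the
#'   `min_size_applied` attribute.
#' @export
filter_by_size <- function(collection, min_size) {
  stopifnot(is.numeric(min_size), length(min_size) == 1, min_size >= 1)
  keep <- pathway_sizes(collection) |>
    dplyr::filter(.data$size >= min_size) |>
    dplyr::pull("pathway_id")
  out <- dplyr::filter(tibble::as_tibble(collection),
                       .data$pathway_id %in% keep)
  new_pathway_collection(out, min_size_applied = as.integer(min_size))
}

#' Restrict a collection to a gene subset
#'
#' Intersects every pathway's membership with `genes` (e.g. a
#' drug-target gene list) and drops pathways emptied by the
#' intersection: a pathway score over zero genes is undefined. A pathway
#' is retained for subset analysis as soon as it contains at least one
#' listed gene.
#'
#' @param collection A pathway collection tibble.
#' @param genes Non-empty character vector of gene symbols to keep.
#' @return The restricted collection (the `min_size_applied` marker is
#'   cleared, since sizes may have shrunk below it).
#' @export
restrict_to_genes <- function(collection, genes) {
  stopifnot(length(genes) > 0)
  out <- dplyr::filter(tibble::as_tibble(collection), .data$gene %in% genes)
  new_pathway_collection(out)
}
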