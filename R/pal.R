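#' Pathway activation level (PAL) scoring
#'
#' For a pathway p and a sample, the activation level is the
#' role-weighted, significance-gated sum of log case-to-normal ratios
#' over the pathway's member genes:
#'
#' \deqn{PAL_p = \sum_n ARR_{n,p} \cdot BTIF_n \cdot \ln CNR_n}
#'
#' where \eqn{CNR_n} (case-to-normal ratio) is the gene's abundance in
#' the sample divided by the geometric mean of its abundance across the
#' reference (control) samples, \eqn{BTIF_n} (beyond tolerance interval
#' flag) is 1 only when the deviation from the reference distribution is
#' significant, and \eqn{ARR_{n,p}} is the activator/repressor role
#' weight in \{-1, -0.5, 0, 0.5, 1\}. Positive PAL means pathway
#' up-regulation, negative PAL down-regulation, and the magnitude scales
#' with the extent of differential regulation. The sum is unweighted by
#' pathway size, so PALs are comparable across pathways only within
#' that convention.
#'
#' When no dedicated control group exists, the reference defaults to all
#' samples of the dataset under analysis, so each profile is normalized
#' against the cohort's per-gene geometric mean.
#'
#' @name pal-scoring
NULL

#' Build a per-gene reference profile
#'
#' Computes, per gene, the geometric mean abundance over the reference
#' samples and the standard deviation of natural-log abundances, the two
#' ingredients of CNR and of the BTIF significance gate.
#'
#' Missing values (genes unquantified in a sample, common for protein
#' data) are excluded sample-wise: the gene's geometric mean and log-sd
#' are taken over the reference samples where it was measured. A gene
#' with a true zero abundance anywhere in the reference, or measured in
#' fewer than `min_measured` reference samples, has no usable geometric
#' mean and is excluded with a message.
#'
#' @param x A normalized expression table.
#' @param reference_samples Optional character vector naming the control
#'   samples; default: all samples in `x`.
#' @param min_measured Minimum measured reference samples per gene.
#' @return A tibble with columns `gene`, `geomean`, `log_mean`
#'   (= log(geomean)), `log_sd` and `n_obs` (measured reference
#'   samples), plus attribute `n_ref`.
#' @export
build_reference <- function(x, reference_samples = NULL, min_measured = 2) {
  if (expr_state(x) != "normalized") {
    stop("reference must be built from a normalized table", call. = FALSE)
  }
  m <- expr_values(x)
  if (is.null(reference_samples)) reference_samples <- colnames(m)
  stopifnot(all(reference_samples %in% colnames(m)))
  m <- m[, reference_samples, drop = FALSE]
  has_zero <- apply(m, 1, function(v) any(is.finite(v) & v <= 0))
  n_obs <- rowSums(is.finite(m) & m > 0)
  ok <- !has_zero & n_obs >= min(min_measured, length(reference_samples))
  if (any(!ok)) {
    message(sum(!ok),
            " gene(s) with zero or insufficient reference abundance excluded")
  }
  if (!any(ok)) stop("no gene has a usable reference", call. = FALSE)
  logm <- log(m[ok, , drop = FALSE])
  log_mean <- unname(rowMeans(logm, na.rm = TRUE))
  log_sd <- if (ncol(logm) > 1) {
    unname(apply(logm, 1, stats::sd, na.rm = TRUE))
  } else {
    rep(0, nrow(logm))
  }
  log_sd[is.na(log_sd)] <- 0
  out <- tibble::tibble(gene = rownames(logm),
                        geomean = exp(log_mean),
                        log_mean = log_mean,
                        log_sd = log_sd,
                        n_obs = unname(n_obs[ok]))
  attr(out, "n_ref") <- length(reference_samples)
  out
}

#' Case-to-normal ratios for one sample
#'
#' Divides a sample's abundances by the reference geometric means over
#' the gene intersection. A CNR of 1 means the gene sits exactly at the
#' reference level.
#'
#' @param x An expression table (normalized) containing the sample, or a
#'   named numeric vector of abundances.
#' @param reference A reference profile from [build_reference()].
#' @param sample Sample id (required when `x` is a table).
#' @return A tibble with columns `gene`, `cnr` and `btif` (initialized
#'   to `NA`; fill with [compute_btif()]), plus attribute `sample`.
#' @export
compute_cnr <- function(x, reference, sample = NULL) {
  if (inherits(x, "expression_tbl") || is.data.frame(x)) {
    stopifnot(!is.null(sample), sample %in% sample_ids(x))
    v <- stats::setNames(x[[sample]], x$gene)
  } else {
    v <- x
    if (is.null(sample)) sample <- "sample"
  }
  v <- v[is.finite(v) & v > 0]
  shared <- intersect(names(v), reference$gene)
  if (length(shared) == 0) {
    stop("sample and reference share no measured genes", call. = FALSE)
  }
  ref <- reference[match(shared, reference$gene), ]
  out <- tibble::tibble(gene = shared,
                        cnr = unname(v[shared]) / ref$geomean,
                        btif = NA_real_)
  attr(out, "sample") <- sample
  out
}

#' Beyond-tolerance-interval flags
#'
#' Gates each gene's PAL contribution on the significance of its
#' deviation from the reference distribution. The sample's natural-log
#' abundance is compared with the reference log distribution by a
#' two-sided z score, \eqn{z = |\ln v - \bar{\ell}| / s_\ell}; the flag
#' is 1 iff the normal two-sided p-value is <= `alpha`. A single case
#' sample against a control group admits no paired test, and the z test
#' on logs matches the ln-ratio scale of the PAL sum.
#'
#' Degenerate cases: a gene whose reference log-sd is 0 is flagged iff
#' its CNR differs from 1; with fewer than 2 reference samples no
#' distribution exists, so every flag is set to 1 with a warning.
#'
#' @param cnr A CNR profile from [compute_cnr()].
#' @param reference The reference profile used to build it.
#' @param alpha Significance level (default 0.05); `alpha = 1` turns
#'   every flag on.
#' @return The CNR profile with the `btif` column filled (0/1).
#' @export
compute_btif <- function(cnr, reference, alpha = 0.05) {
  stopifnot(alpha > 0, alpha <= 1)
  n_ref <- attr(reference, "n_ref")
  ref <- reference[match(cnr$gene, reference$gene), ]
  if (is.null(n_ref) || n_ref < 2) {
    warning("fewer than 2 reference samples: all BTIF flags set to 1")
    cnr$btif <- 1
    return(cnr)
  }
  lv <- log(cnr$cnr) + ref$log_mean  # sample log abundance
  z <- abs(lv - ref$log_mean) / ref$log_sd
  p <- 2 * stats::pnorm(-z)
  btif <- as.numeric(p <= alpha)
  degen <- ref$log_sd == 0
  btif[degen] <- as.numeric(abs(log(cnr$cnr[degen])) > 1e-12)
  cnr$btif <- btif
  cnr
}

#' PAL of one pathway for one sample
#'
#' The unweighted sum over measured member genes of
#' \eqn{ARR \cdot BTIF \cdot \ln CNR}. Members absent from the CNR
#' profile (unmeasured on this platform) contribute zero; their number
#' feeds the coverage diagnostic of [pal_matrix()]. With no member
#' measured at all the score is undefined (`NA`).
#'
#' @param cnr A CNR profile with `btif` filled (see [compute_btif()]; use
#'   `btif = 1` rows for the deterministic ungated mode).
#' @param pathway A tibble with columns `gene` and `arr` (one pathway's
#'   membership, e.g. one `pathway_id` slice of a collection).
#' @return A single signed numeric value in natural-log units.
#' @export
compute_pal <- function(cnr, pathway) {
  idx <- match(pathway$gene, cnr$gene)
  measured <- !is.na(idx)
  if (!any(measured)) return(NA_real_)
  i <- idx[measured]
  sum(pathway$arr[measured] * cnr$btif[i] * log(cnr$cnr[i]))
}

#' PAL matrix over a collection and a dataset
#'
#' Scores every pathway of a (size-filtered) collection in every sample
#' of an expression table against a reference profile. With
#' `btif_mode = "test"` flags come from the z gate at `alpha`; with
#' `"off"` every flag is 1, giving the deterministic ungated score
#' \eqn{\sum ARR \ln CNR}.
#'
#' Genes missing from a sample's CNR profile contribute zero to the
#' affected pathway; pathways with no measured member in any sample are
#' dropped. Per-pathway measurement coverage is reported so users can
#' filter poorly covered pathways.
#'
#' @param x A normalized expression table.
#' @param collection A pathway collection tibble.
#' @param reference A reference profile; default builds one from all
#'   samples of `x`.
#' @param btif_mode `"test"` (significance-gated) or `"off"`.
#' @param alpha Significance level for the gate.
#' @return A tibble with column `pathway_id` then one column per sample
#'   (class `pal_tbl`), with attributes `coverage` (tibble: pathway_id,
#'   n_members, n_measured), `btif_mode`, `alpha`.
#' @export
pal_matrix <- function(x, collection, reference = NULL,
                       btif_mode = c("test", "off"), alpha = 0.05) {
  btif_mode <- match.arg(btif_mode)
  if (is.null(reference)) reference <- build_reference(x)
  m <- expr_values(x)
  genes <- intersect(rownames(m), reference$gene)
  ref <- reference[match(genes, reference$gene), ]
  lm_ref <- ref$log_mean
  sd_ref <- ref$log_sd
  v <- m[genes, , drop = FALSE]
  # log CNR per gene x sample; non-positive/missing values are unmeasured
  lcnr <- log(v) - lm_ref
  lcnr[!is.finite(lcnr)] <- NA
  if (btif_mode == "test") {
    n_ref <- attr(reference, "n_ref")
    if (is.null(n_ref) || n_ref < 2) {
      warning("fewer than 2 reference samples: all BTIF flags set to 1")
      gate <- 1
    } else {
      z <- abs(lcnr) / sd_ref
      p <- 2 * stats::pnorm(-z)
      gate <- (p <= alpha) * 1
      degen <- sd_ref == 0
      if (any(degen)) {
        gate[degen, ] <- (abs(lcnr[degen, , drop = FALSE]) > 1e-12) * 1
      }
    }
    contrib <- lcnr * gate
  } else {
    contrib <- lcnr
  }
  measured <- !is.na(contrib)
  contrib[!measured] <- 0
  # role-weighted membership: pathways x genes (sparse in spirit; the
  # dense product is fast at the sizes this package targets)
  members <- dplyr::filter(tibble::as_tibble(collection), .data$gene %in% genes)
  if (nrow(members) == 0) stop("no pathway member is measured", call. = FALSE)
  pw_ids <- unique(collection$pathway_id)
  W <- matrix(0, nrow = length(pw_ids), ncol = length(genes),
              dimnames = list(pw_ids, genes))
  W[cbind(match(members$pathway_id, pw_ids), match(members$gene, genes))] <-
    members$arr
  pal <- W %*% contrib
  # coverage: members measured in >= 1 sample
  msd <- rownames(measured)[rowSums(measured) > 0]
  cov <- tibble::as_tibble(collection) |>
    dplyr::summarise(n_members = dplyr::n(),
                     n_measured = sum(.data$gene %in% msd),
                     .by = "pathway_id")
  keep <- cov$pathway_id[cov$n_measured > 0]
  if (length(keep) < length(pw_ids)) {
    message(length(pw_ids) - length(keep),
            " pathway(s) with no measured member dropped")
  }
  pal <- pal[keep, , drop = FALSE]
  out <- dplyr::bind_cols(tibble::tibble(pathway_id = rownames(pal)),
                          tibble::as_tibble(pal, .name_repair = "minimal"))
  attr(out, "coverage") <- dplyr::filter(cov, .data$pathway_id %in% keep)
  attr(out, "btif_mode") <- btif_mode
  attr(out, "alpha") <- if (btif_mode == "test") alpha else NA_real_
  class(out) <- unique(c("pal_tbl", class(out)))
  out
}

#' @export
print.pal_tbl <- function(x, ...) {
  cat(sprintf("<pal_tbl> %d pathways x %d samples [btif_mode=%s]\n",
              nrow(x), ncol(x) - 1L, attr(x, "btif_mode")))
  NextMethod()
}

#' Convert a PAL table to a pathways-by-samples matrix
#'
#' @param x A `pal_tbl` from [pal_matrix()].
#' @return A numeric matrix with pathway rownames.
#' @export
pal_values <- function(x) {
  m <- as.matrix(x[, setdiff(names(x), "pathway_id"), drop = FALSE])
  rownames(m) <- x$pathway_id
  m
}

#' Write a PAL table with its provenance sidecar
#'
#' Emits the pathways-by-samples scores as TSV plus a JSON sidecar
#' (`<file>.json`) recording the gating mode, alpha and per-pathway
#' member coverage.
#'
#' @param x A `pal_tbl`.
#' @param file Output TSV path.
#' @return `file`, invisibly.
#' @export
write_pal_matrix <- function(x, file) {
  readr::write_tsv(tibble::as_tibble(x), file, progress = FALSE)
  meta <- list(btif_mode = attr(x, "btif_mode"),
               alpha = attr(x, "alpha"),
               coverage = attr(x, "coverage"))
  jsonlite::write_json(meta, paste0(file, ".json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(file)
}
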