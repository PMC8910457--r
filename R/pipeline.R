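#' Log case-to-normal ratio table
#'
#' Expresses a normalized table on the ln(CNR) scale: each gene's log
#' abundance minus the log of its reference geometric mean. This is the
#' gene-level quantity entering the PAL sum, and the scale on which the
#' pipeline compares gene-level RNA-protein concordance, so the
#' gene-vs-pathway comparison isolates the effect of aggregation rather
#' than of scale. Values unmeasured (zero or missing) in a sample are
#' `NA`; genes absent from the reference are dropped.
#'
#' @param x A normalized expression table.
#' @param reference A reference profile from [build_reference()];
#'   default builds one from all samples of `x`.
#' @return A tibble `gene` + one column per sample of ln(CNR) values.
#' @export
log_cnr_table <- function(x, reference = NULL) {
  if (is.null(reference)) reference <- build_reference(x)
  m <- expr_values(x)
  genes <- intersect(rownames(m), reference$gene)
  lm_ref <- reference$log_mean[match(genes, reference$gene)]
  lcnr <- log(m[genes, , drop = FALSE]) - lm_ref
  lcnr[!is.finite(lcnr)] <- NA
  dplyr::bind_cols(tibble::tibble(gene = genes),
                   tibble::as_tibble(lcnr, .name_repair = "minimal"))
}

#' Validate pipeline inputs
#'
#' Diagnostic pre-flight for [run_concordance_pipeline()]: checks the
#' RNA-protein gene-space overlap, pairing completeness and pathway
#' collection coverage. Returns diagnostics only; nothing is modified
#' and nothing stops, but any `"fatal"` row predicts a pipeline error.
#'
#' @param rna,protein Expression tables.
#' @param pathways A pathway collection tibble.
#' @param pairing Optional pairing table (RNA id, protein id).
#' @param min_overlap Warn when fewer shared genes than this (default
#'   200).
#' @return A tibble with columns `severity` (`"info"`, `"warning"`,
#'   `"fatal"`), `check`, `message`.
#' @export
validate_inputs <- function(rna, protein, pathways, pairing = NULL,
                            min_overlap = 200) {
  diags <- list()
  add <- function(severity, check, message) {
    diags[[length(diags) + 1]] <<- tibble::tibble(
      severity = severity, check = check, message = message)
  }
  shared_genes <- intersect(rna$gene, protein$gene)
  if (length(shared_genes) == 0) {
    add("fatal", "gene_overlap", "RNA and protein gene spaces are disjoint")
  } else if (length(shared_genes) < min_overlap) {
    add("warning", "gene_overlap",
        sprintf("only %d shared genes (< %d)", length(shared_genes),
                min_overlap))
  } else {
    add("info", "gene_overlap",
        sprintf("%d shared genes", length(shared_genes)))
  }
  if (!is.null(pairing)) {
    pairing <- tibble::as_tibble(pairing)[, 1:2]
    bad_r <- setdiff(pairing[[1]], sample_ids(rna))
    bad_p <- setdiff(pairing[[2]], sample_ids(protein))
    if (length(bad_r) > 0) {
      add("fatal", "pairing",
          paste("pairing references absent RNA sample(s):",
                paste(bad_r, collapse = ", ")))
    }
    if (length(bad_p) > 0) {
      add("fatal", "pairing",
          paste("pairing references absent protein sample(s):",
                paste(bad_p, collapse = ", ")))
    }
    if (length(bad_r) + length(bad_p) == 0) {
      add("info", "pairing", sprintf("%d sample pairs", nrow(pairing)))
    }
  } else {
    n_shared <- length(intersect(sample_ids(rna), sample_ids(protein)))
    if (n_shared == 0) {
      add("fatal", "pairing",
          "no shared sample ids and no pairing table supplied")
    } else {
      add("info", "pairing",
          sprintf("identity pairing on %d shared sample ids", n_shared))
    }
  }
  pw_genes <- unique(pathways$gene)
  cov <- mean(pw_genes %in% shared_genes)
  add(if (cov == 0) "fatal" else if (cov < 0.5) "warning" else "info",
      "pathway_coverage",
      sprintf("%.1f%% of pathway genes measured on both platforms",
              100 * cov))
  dplyr::bind_rows(diags)
}

#' Run the full gene- and pathway-level concordance analysis
#'
#' End-to-end orchestration: RNA preprocessing (QC read-count gate,
#' pseudocount, median-of-ratios normalization), per-platform reference
#' profiles (all samples of each dataset as the control group), ln(CNR)
#' profiles, PAL matrices, then per-sample and per-feature RNA-protein
#' correlations at the gene and PAL levels, their paired Wilcoxon
#' comparison, pathway rankings, optional pathway-size strata and an
#' optional restricted gene list (e.g. drug targets).
#'
#' @param rna RNA expression table (raw counts) or path.
#' @param protein Protein abundance table (state `normalized`) or path.
#' @param pathways Pathway collection tibble or path to a
#'   role-annotated gene-set file.
#' @param pairing Optional sample pairing table (RNA id, protein id) or
#'   path; default identity on shared ids.
#' @param qc Optional QC table (sample, uniquely mapped reads) or path;
#'   when supplied, RNA samples below `qc_threshold` are dropped.
#' @param qc_threshold Read-count gate (default 2.5e6).
#' @param gene_mapping Optional old-to-new symbol mapping applied to
#'   both platforms.
#' @param restricted_genes Optional gene list (character vector or
#'   one-column file) for the subset analysis.
#' @param min_size Pathway size filter (default 10).
#' @param strata Optional vector of additional minimum sizes, e.g.
#'   `c(10, 20, 40)`; must be ascending.
#' @param method Correlation method for the level comparison (default
#'   `"spearman"`; Pearson always computed alongside for rankings).
#' @param btif_mode `"test"` (significance-gated PAL, default) or
#'   `"off"`.
#' @param alpha BTIF significance level.
#' @param k Depth of the most/least-correlated pathway tables.
#' @param with_per_feature Also compute per-feature correlation sets
#'   and pathway rankings (default TRUE); disable for seeded
#'   simulation studies that only need the per-sample comparison.
#' @return A `concordance_report` list: `comparison` (per-sample
#'   level comparison), `per_feature` (gene and PAL correlation sets),
#'   `rankings`, `strata`, `restricted`, `pal` (per-platform
#'   `pal_tbl`s), `diagnostics`, `manifest`.
#' @export
run_concordance_pipeline <- function(rna, protein, pathways,
                                     pairing = NULL,
                                     qc = NULL, qc_threshold = 2.5e6,
                                     gene_mapping = NULL,
                                     restricted_genes = NULL,
                                     min_size = 10,
                                     strata = NULL,
                                     method = c("spearman", "pearson"),
                                     btif_mode = c("test", "off"),
                                     alpha = 0.05,
                                     k = 10,
                                     with_per_feature = TRUE) {
  method <- match.arg(method)
  btif_mode <- match.arg(btif_mode)
  if (is.character(rna)) rna <- read_expression_table(rna, "rna")
  if (is.character(protein)) {
    protein <- read_expression_table(protein, "protein")
  }
  if (is.character(pathways)) pathways <- parse_pathway_collection(pathways)
  if (is.character(pairing)) {
    pairing <- readr::read_tsv(pairing, show_col_types = FALSE,
                               progress = FALSE)
  }
  if (is.character(restricted_genes) && length(restricted_genes) == 1 &&
      file.exists(restricted_genes)) {
    restricted_genes <- readr::read_lines(restricted_genes, progress = FALSE)
  }
  if (!is.null(gene_mapping)) {
    rna <- map_gene_symbols(rna, gene_mapping)
    protein <- map_gene_symbols(protein, gene_mapping)
  }
  diagnostics <- validate_inputs(rna, protein, pathways, pairing)
  if (any(diagnostics$severity == "fatal")) {
    stop("input validation failed: ",
         paste(diagnostics$message[diagnostics$severity == "fatal"],
               collapse = "; "), call. = FALSE)
  }

  # --- stage: RNA preprocessing -------------------------------------
  if (!is.null(qc)) rna <- qc_filter_samples(rna, qc, qc_threshold)
  if (expr_state(rna) == "raw") rna <- apply_pseudocount(rna)
  if (expr_state(rna) == "pseudocounted") rna <- size_factor_normalize(rna)
  if (expr_state(protein) != "normalized") {
    stop("protein table must be state 'normalized'", call. = FALSE)
  }

  # --- stage: references and gene-level profiles --------------------
  ref_rna <- build_reference(rna)
  ref_prot <- build_reference(protein)
  lcnr_rna <- log_cnr_table(rna, ref_rna)
  lcnr_prot <- log_cnr_table(protein, ref_prot)

  # --- stage: PAL per platform --------------------------------------
  collection <- filter_by_size(pathways, min_size)
  if (dplyr::n_distinct(collection$pathway_id) == 0) {
    stop("no pathway survives the size filter", call. = FALSE)
  }
  pal_rna <- pal_matrix(rna, collection, ref_rna,
                        btif_mode = btif_mode, alpha = alpha)
  pal_prot <- pal_matrix(protein, collection, ref_prot,
                         btif_mode = btif_mode, alpha = alpha)

  # --- stage: concordance -------------------------------------------
  paired_gene <- pair_omics(lcnr_rna, lcnr_prot, pairing)
  paired_pal <- pair_omics(pal_rna, pal_prot, pairing)
  ps_gene <- per_sample_correlation(paired_gene, method)
  ps_pal <- per_sample_correlation(paired_pal, method)
  comparison <- compare_levels(ps_gene, ps_pal, pairing = "per_sample")
  pf_gene <- pf_pal_sp <- pf_pal_pe <- rankings <- NULL
  if (with_per_feature) {
    pf_gene <- per_feature_correlation(paired_gene, method)
    pf_pal_sp <- per_feature_correlation(paired_pal, "spearman")
    pf_pal_pe <- per_feature_correlation(paired_pal, "pearson")
    rankings <- rank_pathways(pf_pal_sp, pf_pal_pe,
                              k = min(k, floor(nrow(pf_pal_sp) / 2)))
  }

  # --- stage: size strata -------------------------------------------
  strata_out <- NULL
  if (!is.null(strata)) {
    stopifnot(!is.unsorted(strata))
    strata_out <- purrr::map(stats::setNames(strata, strata), function(ms) {
      coll_s <- filter_by_size(pathways, ms)
      if (dplyr::n_distinct(coll_s$pathway_id) == 0) return(NULL)
      pr <- pal_matrix(rna, coll_s, ref_rna, btif_mode = btif_mode,
                       alpha = alpha)
      pp <- pal_matrix(protein, coll_s, ref_prot, btif_mode = btif_mode,
                       alpha = alpha)
      cmp <- compare_levels(
        ps_gene, per_sample_correlation(pair_omics(pr, pp, pairing), method),
        pairing = "per_sample")
      list(min_size = ms,
           n_pathways = dplyr::n_distinct(coll_s$pathway_id),
           comparison = cmp)
    })
  }

  # --- stage: restricted gene list ----------------------------------
  restricted_out <- NULL
  if (!is.null(restricted_genes)) {
    coll_r <- restrict_to_genes(collection, restricted_genes)
    sub_gene <- function(tbl) tbl[tbl$gene %in% restricted_genes, ]
    pg <- pair_omics(sub_gene(lcnr_rna), sub_gene(lcnr_prot), pairing)
    pr <- pal_matrix(rna, coll_r, ref_rna, btif_mode = btif_mode,
                     alpha = alpha)
    pp <- pal_matrix(protein, coll_r, ref_prot, btif_mode = btif_mode,
                     alpha = alpha)
    restricted_out <- compare_levels(
      per_sample_correlation(pg, method),
      per_sample_correlation(pair_omics(pr, pp, pairing), method),
      pairing = "per_sample")
  }

  manifest <- list(
    package = "palconcord",
    version = as.character(utils::packageVersion("palconcord")),
    method = method, btif_mode = btif_mode,
    alpha = if (btif_mode == "test") alpha else NA,
    min_size = min_size, strata = strata, k = k,
    qc_threshold = if (!is.null(qc)) qc_threshold else NA,
    n_pairs = nrow(paired_gene$pairing),
    n_pathways_scored = nrow(pal_rna))

  structure(list(comparison = comparison,
                 per_sample = list(gene = ps_gene, pal = ps_pal),
                 per_feature = list(gene = pf_gene, pal = pf_pal_sp,
                                    pal_pearson = pf_pal_pe),
                 rankings = rankings,
                 strata = strata_out,
                 restricted = restricted_out,
                 pal = list(rna = pal_rna, protein = pal_prot),
                 diagnostics = diagnostics,
                 manifest = manifest),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("<concordance_report>\n")
  print(x$comparison)
  if (!is.null(x$strata)) {
    cat("  strata:",
        paste(vapply(x$strata, function(s)
          sprintf(">=%d: %d pathways", s$min_size, s$n_pathways),
          character(1)), collapse = "; "), "\n")
  }
  invisible(x)
}

#' Write a concordance report to disk
#'
#' Emits `report.json` (manifest plus the glance of every comparison),
#' `rankings.tsv` (the most/least-correlated pathway tables),
#' `per_sample_correlations.tsv`, `per_feature_correlations.tsv` and
#' the two PAL matrices with sidecars.
#'
#' @param report A `concordance_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_concordance_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  js <- list(
    manifest = report$manifest,
    comparison = as.list(glance(report$comparison)),
    strata = purrr::map(report$strata, function(s) {
      if (is.null(s)) return(NULL)
      c(list(min_size = s$min_size, n_pathways = s$n_pathways),
        as.list(glance(s$comparison)))
    }),
    restricted = if (!is.null(report$restricted))
      as.list(glance(report$restricted)) else NULL,
    pooled_gene = pooled_correlation(report$per_sample$gene),
    pooled_pal = pooled_correlation(report$per_sample$pal))
  jsonlite::write_json(js, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(report$rankings)) {
    readr::write_tsv(report$rankings, file.path(dir, "rankings.tsv"),
                     progress = FALSE)
  }
  ps <- dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(report$per_sample$gene), level = "gene"),
    dplyr::mutate(tibble::as_tibble(report$per_sample$pal), level = "pal"))
  readr::write_tsv(ps, file.path(dir, "per_sample_correlations.tsv"),
                   progress = FALSE)
  if (!is.null(report$per_feature$gene)) {
    pf <- dplyr::bind_rows(
      dplyr::mutate(tibble::as_tibble(report$per_feature$gene),
                    level = "gene"),
      dplyr::mutate(tibble::as_tibble(report$per_feature$pal),
                    level = "pal"))
    readr::write_tsv(pf, file.path(dir, "per_feature_correlations.tsv"),
                     progress = FALSE)
  }
  write_pal_matrix(report$pal$rna, file.path(dir, "pal_rna.tsv"))
  write_pal_matrix(report$pal$protein, file.path(dir, "pal_protein.tsv"))
  invisible(dir)
}
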