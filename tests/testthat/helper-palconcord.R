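# Small in-code fixtures shared across test files.

# genes-by-samples matrix of positive abundances
rand_matrix <- function(n_genes, n_samples, seed = 1, lognormal_sd = 1) {
  set.seed(seed)
  m <- matrix(exp(rnorm(n_genes * n_samples, mean = 3, sd = lognormal_sd)),
              n_genes, n_samples,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("S%02d", seq_len(n_samples))))
  m
}

toy_expression <- function(m, platform = "rna", state = "normalized") {
  as_expression_table(m, platform, state)
}

# random CNR profile over `genes`, flags drawn 0/1
rand_cnr <- function(genes, seed = 1, btif = NULL) {
  set.seed(seed)
  tibble::tibble(
    gene = genes,
    cnr = exp(rnorm(length(genes), sd = 0.8)),
    btif = if (is.null(btif)) sample(0:1, length(genes), replace = TRUE)
           else rep(btif, length.out = length(genes)))
}

# random role-annotated pathway membership over `genes`
rand_pathway <- function(genes, seed = 1) {
  set.seed(seed)
  tibble::tibble(gene = genes,
                 arr = sample(c(-1, -0.5, 0, 0.5, 1), length(genes),
                              replace = TRUE))
}

# reference profile built by hand (the documented contract fields)
manual_reference <- function(genes, log_mean, log_sd, n_ref = 10) {
  out <- tibble::tibble(gene = genes,
                        geomean = exp(log_mean),
                        log_mean = log_mean,
                        log_sd = log_sd,
                        n_obs = n_ref)
  attr(out, "n_ref") <- n_ref
  out
}

# average ranks from first principles (independent of base::rank)
oracle_rank <- function(v) {
  vapply(v, function(x) sum(v < x) + (1 + sum(v == x)) / 2, numeric(1))
}

# product-moment correlation from the covariance / sd formula
oracle_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  sxy / (sqrt(sum((x - mean(x))^2) / (n - 1)) *
           sqrt(sum((y - mean(y))^2) / (n - 1)))
}
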