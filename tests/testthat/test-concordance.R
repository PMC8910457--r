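test_that("correlations match first-principles recomputation, including ties", {
  expect_equal(spearman_cor(1:3, c(10, 20, 30)), 1)
  expect_equal(spearman_cor(1:3, 3:1), -1)
  expect_equal(pearson_cor(1:10, 2 * (1:10) + 1), 1)
  expect_equal(pearson_cor(c(-1, 0, 1), c(1, -2, 1)), 0)

  # tie case against manually averaged ranks
  x <- c(1, 2, 2, 4); y <- c(4, 2, 3, 1)
  expect_equal(spearman_cor(x, y),
               oracle_pearson(oracle_rank(x), oracle_rank(y)),
               tolerance = 1e-12)

  set.seed(12)
  x50 <- rnorm(50); y50 <- 0.4 * x50 + rnorm(50)
  expect_equal(pearson_cor(x50, y50), oracle_pearson(x50, y50),
               tolerance = 1e-12)

  # undefined on zero variance and tiny n
  expect_true(is.na(pearson_cor(rep(1, 5), 1:5)))
  expect_true(is.na(spearman_cor(rep(2, 4), 1:4)))
  expect_true(is.na(pearson_cor(1:2, 2:1)))
})

test_that("Spearman is invariant under strictly monotone transforms", {
  set.seed(13)
  for (i in 1:10) {
    x <- rnorm(40); y <- rnorm(40)
    rho <- spearman_cor(x, y)
    expect_equal(spearman_cor(exp(x), y), rho, tolerance = 1e-12)
    expect_equal(spearman_cor(x, y^3), rho, tolerance = 1e-12)
    expect_equal(spearman_cor(-x, y), -rho, tolerance = 1e-12)
  }
})

test_that("signed-rank test: degenerate, all-positive and exact-regime cases", {
  a <- c(1, 2, 3, 4)
  expect_equal(wilcoxon_signed_rank(a, a)$p_value, 1)
  expect_true(wilcoxon_signed_rank(a, a)$degenerate)

  # five all-positive differences: two-sided p = 2 / 2^5
  res <- wilcoxon_signed_rank(c(2, 3, 4, 5, 6), c(1, 2, 3, 4, 5))
  expect_equal(res$p_value, 2 / 32, tolerance = 1e-12)
  expect_equal(res$statistic, 15)
  expect_equal(res$method, "exact")

  # matches stats::wilcox.test exactly in the tie-free exact regime
  set.seed(14)
  for (i in 1:10) {
    a <- rnorm(12); b <- rnorm(12)
    expect_equal(wilcoxon_signed_rank(a, b)$p_value,
                 wilcox.test(a, b, paired = TRUE, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("signed-rank exact p equals full sign-pattern enumeration with ties", {
  set.seed(15)
  for (n in c(4, 6, 8, 10)) {
    for (rep in 1:5) {
      d <- sample(c(-3, -2, -1, 1, 2, 3, 4), n, replace = TRUE)
      a <- d; b <- numeric(n)
      r <- rank(abs(d))
      w_obs <- sum(r[d > 0])
      signs <- as.matrix(expand.grid(rep(list(0:1), n)))
      W <- signs %*% r
      mu <- sum(r) / 2
      p_enum <- mean(abs(W - mu) >= abs(w_obs - mu) - 1e-9)
      expect_equal(wilcoxon_signed_rank(a, b)$p_value, p_enum,
                   tolerance = 1e-12)
    }
  }
})

test_that("exact and normal-approximation regimes agree at the boundary", {
  set.seed(16)
  a <- rnorm(25, mean = 0.45); b <- rnorm(25)
  p_exact <- wilcoxon_signed_rank(a, b, exact_limit = 25)
  p_norm <- wilcoxon_signed_rank(a, b, exact_limit = 10)
  expect_equal(p_exact$method, "exact")
  expect_equal(p_norm$method, "normal")
  expect_lt(abs(p_norm$p_value - p_exact$p_value) / p_exact$p_value, 0.10)
})

test_that("per-sample correlation is 1 on identical inputs and supports pooling", {
  m <- rand_matrix(50, 6, seed = 17)
  x <- toy_expression(m)
  y <- toy_expression(m, platform = "protein")
  paired <- pair_omics(x, y)
  cs <- per_sample_correlation(paired, "spearman")
  expect_equal(cs$correlation, rep(1, 6), tolerance = 1e-12)
  expect_equal(pooled_correlation(cs)$correlation, 1, tolerance = 1e-12)
  expect_equal(pooled_correlation(cs)$n, 300)

  # PAL-level identity behaves the same
  coll <- parse_pathway_collection(text = c(
    paste(c("P1", "x", paste0(rownames(m)[1:15], ":1")), collapse = "\t"),
    paste(c("P2", "x", paste0(rownames(m)[16:30], ":-1")), collapse = "\t"),
    paste(c("P3", "x", paste0(rownames(m)[31:45], ":1")), collapse = "\t")))
  palx <- pal_matrix(x, coll, btif_mode = "off")
  paly <- pal_matrix(y, coll, btif_mode = "off")
  cs_pal <- per_sample_correlation(pair_omics(palx, paly), "pearson")
  expect_equal(cs_pal$correlation, rep(1, 6), tolerance = 1e-12)
})

test_that("per-sample correlation matches a hand-computed toy case", {
  mr <- matrix(c(1, 2, 3, 4,
                 4, 1, 3, 2), 4, 2,
               dimnames = list(c("A", "B", "C", "D"), c("S1", "S2")))
  mp <- matrix(c(2, 1, 4, 3,
                 1, 2, 3, 4), 4, 2,
               dimnames = list(c("A", "B", "C", "D"), c("S1", "S2")))
  paired <- pair_omics(toy_expression(mr), toy_expression(mp, "protein"))
  cs <- per_sample_correlation(paired, "spearman")
  expect_equal(cs$correlation[cs$id == "S1"],
               oracle_pearson(oracle_rank(mr[, 1]), oracle_rank(mp[, 1])))
  expect_equal(cs$correlation[cs$id == "S2"],
               oracle_pearson(oracle_rank(mr[, 2]), oracle_rank(mp[, 2])))
})

test_that("rank-scrambled profiles decorrelate on average", {
  set.seed(18)
  m <- rand_matrix(400, 8, seed = 18)
  scr <- apply(m, 2, sample)
  rownames(scr) <- rownames(m)
  cs <- per_sample_correlation(
    pair_omics(toy_expression(m), toy_expression(scr, "protein")),
    "spearman")
  expect_lt(abs(mean(cs$correlation)), 0.05)
})

test_that("per-feature correlation works across samples and drops constants", {
  m <- rand_matrix(10, 8, seed = 19)
  m2 <- m; m2[3, ] <- 5  # constant on one platform
  paired <- pair_omics(toy_expression(m), toy_expression(m2, "protein"))
  expect_message(cs <- per_feature_correlation(paired, "pearson"),
                 "1 feature")
  expect_false("g003" %in% cs$id)
  expect_equal(cs$correlation[cs$id == "g001"], 1, tolerance = 1e-12)
  expect_equal(unique(cs$n), 8)
})

test_that("level comparison: identity, uniform shift and scale-freeness", {
  cs <- function(ids, vals, method = "spearman") {
    out <- tibble::tibble(id = ids, correlation = vals, n = 50)
    attr(out, "method") <- method
    class(out) <- c("correlation_set", class(out))
    out
  }
  ids <- paste0("S", 1:20)
  set.seed(20)
  g <- runif(20, 0.1, 0.5)

  same <- compare_levels(cs(ids, g), cs(ids, g))
  expect_equal(same$fold_change, 1)
  expect_equal(same$p_value, 1)

  up <- compare_levels(cs(ids, g), cs(ids, g + 0.1))
  expect_equal(up$p_value, 2 / 2^20, tolerance = 1e-12)
  expect_gt(up$fold_change, 1)

  # scale-freeness: multiplying every correlation by c leaves the fold
  # change of means unchanged
  sc <- compare_levels(cs(ids, 0.5 * g), cs(ids, 0.5 * (g + 0.1)))
  expect_equal(sc$fold_change, up$fold_change, tolerance = 1e-12)
  expect_equal(sc$mean_gene, 0.5 * up$mean_gene, tolerance = 1e-12)

  # unpaired fallback uses the rank-sum test
  unp <- compare_levels(cs(paste0("G", 1:20), g),
                        cs(paste0("P", 1:8), g[1:8] + 0.3),
                        pairing = "unpaired")
  expect_lt(unp$p_value, 0.05)
  expect_error(compare_levels(cs("A", 0.1), cs("B", 0.2)), "no shared ids")
})

test_that("pathway ranking tables slice a deterministic full sort", {
  cs <- function(ids, vals) {
    out <- tibble::tibble(id = ids, correlation = vals, n = 50)
    class(out) <- c("correlation_set", class(out))
    out
  }
  r9 <- cs(paste0("P", 1:9), seq(0.1, 0.9, by = 0.1))
  rk <- rank_pathways(r9, k = 2)
  expect_equal(rk$spearman[rk$table == "top"], c(0.9, 0.8))
  expect_equal(rk$spearman[rk$table == "bottom"], c(0.1, 0.2))

  # all equal: tie-break by id, tables disjoint
  req <- cs(paste0("P", 1:10), rep(0.5, 10))
  rk2 <- rank_pathways(req, k = 3)
  expect_equal(rk2$pathway_id[rk2$table == "top"], c("P1", "P10", "P2"))
  expect_length(intersect(rk2$pathway_id[rk2$table == "top"],
                          rk2$pathway_id[rk2$table == "bottom"]), 0)

  # random values equal full-sort slicing; shrink warns
  set.seed(21)
  vals <- runif(30)
  r30 <- cs(sprintf("P%02d", 1:30), vals)
  rk3 <- rank_pathways(r30, k = 10)
  ord <- order(-vals, sprintf("P%02d", 1:30))
  expect_equal(rk3$pathway_id[rk3$table == "top"],
               sprintf("P%02d", 1:30)[ord[1:10]])
  expect_equal(rk3$pathway_id[rk3$table == "bottom"],
               sprintf("P%02d", 1:30)[rev(ord)[1:10]])
  expect_warning(rank_pathways(cs(paste0("P", 1:5), runif(5)), k = 10),
                 "shrunk")
})

test_that("sign concordance counts directional agreement of members", {
  genes <- paste0("g", 1:10)
  pw <- rand_pathway(genes, seed = 22)
  cnr <- rand_cnr(genes, seed = 22, btif = 1)

  same <- sign_concordance(cnr, cnr, pw)
  expect_equal(attr(same, "fraction"), 1)

  recip <- dplyr::mutate(cnr, cnr = 1 / cnr)
  opp <- sign_concordance(cnr, recip, pw)
  expect_equal(attr(opp, "fraction"), 0)

  # random pair equals a direct per-gene count
  other <- rand_cnr(genes, seed = 23, btif = 1)
  sc <- sign_concordance(cnr, other, pw)
  want <- mean(sign(log(cnr$cnr)) == sign(log(other$cnr)))
  expect_equal(attr(sc, "fraction"), want)

  # CNR exactly 1 has zero sign and only matches zero
  c1 <- tibble::tibble(gene = c("a", "b"), cnr = c(1, 2), btif = 1)
  c2 <- tibble::tibble(gene = c("a", "b"), cnr = c(2, 2), btif = 1)
  sc2 <- sign_concordance(c1, c2, tibble::tibble(gene = c("a", "b"),
                                                 arr = c(1, 1)))
  expect_equal(sc2$agree, c(FALSE, TRUE))
})
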