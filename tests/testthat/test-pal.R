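test_that("reference profile computes geometric means and log dispersions", {
  x <- toy_expression(matrix(c(2, 8), 1, 2,
                             dimnames = list("A", c("S1", "S2"))))
  ref <- build_reference(x)
  expect_equal(ref$geomean, 4)
  expect_equal(attr(ref, "n_ref"), 2)

  # identical samples: zero dispersion everywhere
  m <- rand_matrix(20, 1, seed = 1)
  xx <- toy_expression(cbind(S1 = m[, 1], S2 = m[, 1], S3 = m[, 1]))
  expect_true(all(build_reference(xx)$log_sd == 0))

  # 20 lognormal draws: geomean equals exp(mean of logs)
  set.seed(8)
  v <- exp(rnorm(20, 1, 0.7))
  mm <- matrix(v, 1, 20, dimnames = list("A", paste0("S", 1:20)))
  ref20 <- build_reference(toy_expression(mm))
  expect_equal(ref20$geomean, exp(mean(log(v))), tolerance = 1e-12)
  expect_equal(ref20$log_sd, sd(log(v)), tolerance = 1e-12)

  # a zero abundance disqualifies the gene
  mz <- rand_matrix(5, 3, seed = 2); mz[2, 1] <- 0
  refz <- expect_message(build_reference(toy_expression(mz)), "excluded")
  expect_false(rownames(mz)[2] %in% refz$gene)

  # protein-style missingness: geomean over the measured samples only
  mp <- rand_matrix(4, 6, seed = 3); mp[1, 1:2] <- NA
  refp <- build_reference(toy_expression(mp, platform = "protein"))
  expect_equal(refp$geomean[refp$gene == "g001"],
               exp(mean(log(mp[1, 3:6]))), tolerance = 1e-12)
  expect_equal(refp$n_obs[refp$gene == "g001"], 4)
})

test_that("CNR is the sample-to-reference-geomean ratio over shared genes", {
  ref <- manual_reference(c("A", "B"), log_mean = log(c(4, 2)),
                          log_sd = c(0.5, 0.5))
  cnr <- compute_cnr(c(A = 4, B = 8), ref)
  expect_equal(cnr$cnr[cnr$gene == "A"], 1)
  expect_equal(cnr$cnr[cnr$gene == "B"], 4)

  expect_error(compute_cnr(c(Z = 1), ref), "share no measured genes")

  # a sample that is the sole reference sample has CNR = 1 everywhere
  m <- rand_matrix(25, 1, seed = 4)
  x <- toy_expression(m)
  ref1 <- build_reference(x)
  cnr1 <- compute_cnr(x, ref1, sample = "S01")
  expect_equal(cnr1$cnr, rep(1, 25), tolerance = 1e-12)
})

test_that("BTIF gates on the two-sided normal tail of the log deviation", {
  ref <- manual_reference("A", log_mean = 1, log_sd = 0.5)
  # at the reference geomean: z = 0, p = 1, flag off
  cnr <- compute_btif(compute_cnr(c(A = exp(1)), ref), ref)
  expect_equal(cnr$btif, 0)

  # three reference sds away: p = 2*pnorm(-3) ~ 0.0027 < 0.05, flag on
  cnr3 <- compute_btif(compute_cnr(c(A = exp(1 + 3 * 0.5)), ref), ref)
  expect_equal(cnr3$btif, 1)
  # just inside vs just outside the alpha = 2*pnorm(-3) boundary
  a3 <- 2 * pnorm(-3)
  expect_equal(compute_btif(compute_cnr(c(A = exp(1 + 3 * 0.5)), ref), ref,
                            alpha = a3 * 1.0001)$btif, 1)
  expect_equal(compute_btif(compute_cnr(c(A = exp(1 + 3.001 * 0.5)), ref),
                            ref, alpha = a3 * 0.999)$btif, 1)
  expect_equal(compute_btif(compute_cnr(c(A = exp(1 + 2.999 * 0.5)), ref),
                            ref, alpha = a3 * 0.999)$btif, 0)

  # degenerate reference: sd = 0 flags any departure from CNR = 1
  ref0 <- manual_reference(c("A", "B"), log_mean = c(0, 0), log_sd = c(0, 0))
  cnr0 <- compute_btif(compute_cnr(c(A = 2, B = 1), ref0), ref0)
  expect_equal(cnr0$btif[cnr0$gene == "A"], 1)
  expect_equal(cnr0$btif[cnr0$gene == "B"], 0)

  # no reference distribution at all: every flag on, with a warning
  ref1 <- manual_reference("A", log_mean = 0, log_sd = 0, n_ref = 1)
  expect_warning(out <- compute_btif(compute_cnr(c(A = 3), ref1), ref1),
                 "fewer than 2")
  expect_equal(out$btif, 1)
})

test_that("PAL is the role-weighted gated sum of log ratios", {
  p1 <- tibble::tibble(gene = "A", arr = 1)
  cnr <- tibble::tibble(gene = "A", cnr = exp(1), btif = 1)
  expect_equal(compute_pal(cnr, p1), 1)

  p2 <- tibble::tibble(gene = c("A", "B"), arr = c(1, -1))
  cnr2 <- tibble::tibble(gene = c("A", "B"), cnr = c(exp(2), exp(1)),
                         btif = c(1, 1))
  expect_equal(compute_pal(cnr2, p2), 2 - 1)

  # no change anywhere: PAL = 0 regardless of roles and flags
  genes <- paste0("g", 1:12)
  cnr_flat <- tibble::tibble(gene = genes, cnr = 1,
                             btif = rep(c(0, 1), 6))
  expect_equal(compute_pal(cnr_flat, rand_pathway(genes, seed = 1)), 0)

  # unmeasured members contribute zero; none measured -> NA
  expect_equal(compute_pal(cnr2, tibble::tibble(gene = c("A", "Z"),
                                                arr = c(1, 1))), 2)
  expect_true(is.na(compute_pal(cnr2, tibble::tibble(gene = "Z", arr = 1))))
})

test_that("PAL equals an independent term-by-term summation on random input", {
  for (seed in 1:20) {
    genes <- paste0("g", 1:30)
    cnr <- rand_cnr(genes, seed = seed)
    pw <- rand_pathway(genes, seed = seed + 100)
    want <- 0
    for (i in seq_len(30)) {
      j <- which(cnr$gene == pw$gene[i])
      want <- want + pw$arr[i] * cnr$btif[j] * log(cnr$cnr[j])
    }
    expect_equal(compute_pal(cnr, pw), want, tolerance = 1e-12)
  }
})

test_that("PAL invariants: sign flip, additivity, monotonicity", {
  genes <- paste0("g", 1:24)
  cnr <- rand_cnr(genes, seed = 5)
  pw <- rand_pathway(genes, seed = 6)

  flipped <- dplyr::mutate(pw, arr = -arr)
  expect_identical(compute_pal(cnr, flipped), -compute_pal(cnr, pw))

  # additivity over any partition of the members
  set.seed(7)
  part <- split(seq_len(24), sample(1:3, 24, replace = TRUE))
  expect_equal(sum(vapply(part, function(idx)
    compute_pal(cnr, pw[idx, ]), numeric(1))),
    compute_pal(cnr, pw), tolerance = 1e-12)

  # raising the CNR of a gated activator strictly raises PAL
  act <- which(pw$arr == 1 & cnr$btif[match(pw$gene, cnr$gene)] == 1)[1]
  cnr_up <- cnr
  j <- match(pw$gene[act], cnr$gene)
  cnr_up$cnr[j] <- cnr_up$cnr[j] * 2
  expect_gt(compute_pal(cnr_up, pw), compute_pal(cnr, pw))
})

test_that("PAL matrix composes per-sample scoring and matches gating modes", {
  m <- rand_matrix(30, 4, seed = 10)
  x <- toy_expression(m)
  coll <- parse_pathway_collection(text = paste(
    c("P1", "toy", paste0(rownames(m)[1:12], ":",
                          rep(c("1", "-1", "0.5"), 4))), collapse = "\t"))
  ref <- build_reference(x)
  pal <- pal_matrix(x, coll, ref, btif_mode = "off")
  expect_equal(dim(pal_values(pal)), c(1, 4))
  for (s in sample_ids(x)) {
    cnr <- compute_cnr(x, ref, sample = s)
    cnr$btif <- 1
    expect_equal(pal_values(pal)["P1", s],
                 compute_pal(cnr, coll), tolerance = 1e-12)
  }
  # gated scoring composes with compute_btif the same way
  pal_t <- pal_matrix(x, coll, ref, btif_mode = "test", alpha = 0.3)
  for (s in sample_ids(x)) {
    cnr <- compute_btif(compute_cnr(x, ref, sample = s), ref, alpha = 0.3)
    expect_equal(pal_values(pal_t)["P1", s],
                 compute_pal(cnr, coll), tolerance = 1e-12)
  }
  # alpha = 1 forces every flag on, reproducing the ungated matrix
  pal_a1 <- pal_matrix(x, coll, ref, btif_mode = "test", alpha = 1)
  expect_equal(pal_values(pal_a1), pal_values(pal), tolerance = 1e-12)

  # coverage diagnostic counts measured members
  cov <- attr(pal, "coverage")
  expect_equal(cov$n_members, 12)
  expect_equal(cov$n_measured, 12)
})

test_that("PAL is invariant to global rescaling and reference-shifts as expected", {
  m <- rand_matrix(40, 6, seed = 11)
  coll <- parse_pathway_collection(text = paste(
    c("P1", "toy", paste0(rownames(m)[1:15], ":1")), collapse = "\t"))
  pal_fun <- function(mm) {
    x <- toy_expression(mm)
    pal_values(pal_matrix(x, coll, build_reference(x), btif_mode = "off"))
  }
  # multiplying the whole dataset by a constant changes nothing
  expect_equal(pal_fun(m * 7.3), pal_fun(m), tolerance = 1e-10)

  # doubling one sample and rebuilding the reference leaves the PAL
  # differences between the untouched samples unchanged
  m2 <- m; m2[, 1] <- 2 * m2[, 1]
  p_before <- pal_fun(m); p_after <- pal_fun(m2)
  expect_equal(p_after[, 3] - p_after[, 2], p_before[, 3] - p_before[, 2],
               tolerance = 1e-10)
})
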