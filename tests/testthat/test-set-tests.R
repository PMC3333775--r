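make_score_table <- function(genes, s, universe = "intersection") {
  tab <- tibble::tibble(gene = genes, s_INT = s,
                        n_platforms = 1L, converged = TRUE, flagged = FALSE)
  attr(tab, "universe") <- universe
  class(tab) <- c("gene_score_table", class(tab))
  tab
}

test_that("competitive test reproduces the exact enumeration example", {
  tab <- make_score_table(letters[1:5], c(5, 6, 7, 1, 2))
  coll <- gene_set_collection(list(S = c("a", "b", "c")),
                              universe = letters[1:5])
  res <- competitive_test(tab, coll, "s_INT")
  expect_equal(res$statistic, 6)      # all 3 x 2 pairwise wins
  expect_equal(res$p_value, 1 / 10)   # 1 of C(5,2) assignments as extreme
})

test_that("competitive test equals brute-force enumeration on small instances", {
  set.seed(14)
  for (n1 in c(2, 3, 5)) {
    for (n2 in c(2, 4, 5)) {
      s <- sample(seq_len(50), n1 + n2)  # distinct -> tie-free
      genes <- sprintf("g%02d", seq_along(s))
      tab <- make_score_table(genes, s)
      coll <- gene_set_collection(list(S = genes[seq_len(n1)]),
                                  universe = genes)
      res <- competitive_test(tab, coll)
      expect_equal(res$p_value, enumerate_mw_p(s[seq_len(n1)], s[-seq_len(n1)]),
                   tolerance = 1e-12)
    }
  }
})

test_that("competitive normal approximation matches wilcox.test", {
  set.seed(15)
  s <- rnorm(80)
  genes <- sprintf("g%02d", seq_along(s))
  tab <- make_score_table(genes, s)
  coll <- gene_set_collection(list(S = genes[1:25]), universe = genes)
  res <- competitive_test(tab, coll)
  ref <- wilcox.test(s[1:25], s[-(1:25)], alternative = "greater",
                     exact = FALSE, correct = FALSE)
  expect_equal(res$statistic, unname(ref$statistic))
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("identical in- and out-set distributions give a central p-value", {
  vals <- rep(c(1, 2, 3, 4), 10)
  genes <- sprintf("g%02d", seq_along(vals))
  tab <- make_score_table(genes, vals)
  # first and second half hold the same multiset of values
  coll <- gene_set_collection(list(S = genes[1:20]), universe = genes)
  res <- competitive_test(tab, coll)
  expect_equal(res$statistic, 20 * 20 / 2)
  expect_gt(res$p_value, 0.4)
  expect_lt(res$p_value, 0.6)
})

test_that("competitive test is invariant to monotone score transforms", {
  set.seed(16)
  s <- rchisq(60, df = 2)
  genes <- sprintf("g%02d", seq_along(s))
  coll <- gene_set_collection(list(S = genes[1:12]), universe = genes)
  p1 <- competitive_test(make_score_table(genes, s), coll)$p_value
  p2 <- competitive_test(make_score_table(genes, log(s)), coll)$p_value
  p3 <- competitive_test(make_score_table(genes, s^3), coll)$p_value
  expect_equal(p1, p2, tolerance = 1e-12)
  expect_equal(p1, p3, tolerance = 1e-12)
})

test_that("competitive test refuses union-universe scores and empty sets", {
  tab <- make_score_table(letters[1:5], 1:5, universe = "union")
  coll <- gene_set_collection(list(S = c("a", "b")), universe = letters[1:5])
  expect_error(competitive_test(tab, coll), class = "gsetint_error_universe")

  tab2 <- make_score_table(letters[1:5], 1:5)
  coll2 <- gene_set_collection(list(S = c("a", "b"), XX = c("zz", "zy")),
                               universe = letters[1:5])
  expect_warning(res <- competitive_test(tab2, coll2), "skipped")
  expect_identical(attr(res, "skipped"), "XX")
  expect_equal(nrow(res), 1)
})

test_that("permutation null is reproducible and preserves class structure", {
  st <- toy_study(n_genes = 30, n_samples = 20, D = 2, seed = 17)
  n1 <- build_permutation_null(st, "intersection", B = 2, seed = 5)
  n2 <- build_permutation_null(st, "intersection", B = 2, seed = 5)
  expect_identical(n1$integrative, n2$integrative)
  expect_identical(n1$single, n2$single)

  # null scores from a null study match the observed score distribution
  st_null <- toy_study(n_genes = 400, n_samples = 60, D = 1, seed = 18)
  obs <- score_genes(st_null)
  nul <- build_permutation_null(st_null, "intersection", B = 10, seed = 6)
  expect_equal(mean(nul$single$P1), mean(obs$s_P1), tolerance = 0.25)
})

test_that("self-contained statistic matches its closed-form examples", {
  genes <- c("a", "b", "c")
  tab <- make_score_table(genes, c(10, 11, 12), universe = "union")
  # null always below observed: W_b = 6 for every permutation
  nullmat <- matrix(1, 3, 4, dimnames = list(genes, NULL))
  null <- structure(list(B = 4L, genes = genes, platform_ids = "P1",
                         universe = "union",
                         single = list(P1 = nullmat), integrative = nullmat),
                    class = "permutation_null")
  coll <- gene_set_collection(list(S = genes), universe = genes)
  res <- selfcontained_test(tab, null, coll)
  expect_equal(res$statistic, 6)
  expect_equal(res$p_value, pnorm((6 - 3) / sqrt(3.5), lower.tail = FALSE),
               tolerance = 1e-12)

  # n = 2 with differences {+a, -a}: tied midranks give the null mean
  genes2 <- c("a", "b")
  tab2 <- make_score_table(genes2, c(5, 1), universe = "union")
  nm2 <- matrix(c(4, 2), 2, 3, dimnames = list(genes2, NULL))
  null2 <- structure(list(B = 3L, genes = genes2, platform_ids = "P1",
                          universe = "union",
                          single = list(P1 = nm2), integrative = nm2),
                     class = "permutation_null")
  coll2 <- gene_set_collection(list(S = genes2), universe = genes2)
  res2 <- selfcontained_test(tab2, null2, coll2)
  expect_equal(res2$statistic, 2 * 3 / 4)
  expect_equal(res2$p_value, 0.5)
})

test_that("all-zero differences fall back to the signed-rank null mean", {
  genes <- c("a", "b", "c", "d")
  tab <- make_score_table(genes, c(2, 2, 2, 2), universe = "union")
  nm <- matrix(2, 4, 2, dimnames = list(genes, NULL))
  null <- structure(list(B = 2L, genes = genes, platform_ids = "P1",
                         universe = "union",
                         single = list(P1 = nm), integrative = nm),
                    class = "permutation_null")
  coll <- gene_set_collection(list(S = genes), universe = genes)
  res <- selfcontained_test(tab, null, coll)
  expect_equal(res$statistic, 4 * 5 / 4)
  expect_equal(res$p_value, 0.5)
})

test_that("self-contained test skips sets below two scored genes", {
  genes <- c("a", "b")
  tab <- make_score_table(genes, c(1, 2), universe = "union")
  nm <- matrix(0, 2, 2, dimnames = list(genes, NULL))
  null <- structure(list(B = 2L, genes = genes, platform_ids = "P1",
                         universe = "union",
                         single = list(P1 = nm), integrative = nm),
                    class = "permutation_null")
  coll <- gene_set_collection(list(S1 = c("a", "zz"), S2 = genes),
                              universe = c(genes, "zz"))
  expect_warning(res <- selfcontained_test(tab, null, coll), "skipped")
  expect_identical(attr(res, "skipped"), "S1")
})

test_that("statistics stay within their theoretical bounds", {
  set.seed(19)
  s <- rchisq(40, 1)
  genes <- sprintf("g%02d", seq_along(s))
  coll <- gene_set_collection(
    list(A = genes[1:10], B = genes[11:14], C = genes[20:39]),
    universe = genes)
  res <- competitive_test(make_score_table(genes, s), coll)
  expect_true(all(res$statistic >= 0))
  expect_true(all(res$statistic <= res$n_genes * (40 - res$n_genes)))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
})
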