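test_that("truth labeling follows the 50% overlap rule", {
  coll <- gene_set_collection(
    list(A = sprintf("g%02d", 1:10), B = sprintf("g%02d", 11:20),
         C = c(sprintf("g%02d", 1:5), sprintf("h%02d", 1:5)),
         D = c(sprintf("g%02d", 1:4), sprintf("h%02d", 1:6))))
  truth <- truth_labels(coll, "A")
  expect_true(truth[["A"]])
  expect_false(truth[["B"]])
  expect_true(truth[["C"]])   # shares 5/10 -> boundary inclusive
  expect_false(truth[["D"]])  # shares 4/10

  # disjoint collection: exactly the spiked sets are true
  coll2 <- gene_set_collection(
    list(A = sprintf("g%02d", 1:10), B = sprintf("g%02d", 11:20),
         E = sprintf("g%02d", 21:30)))
  expect_identical(unname(truth_labels(coll2, c("A", "E"))),
                   c(TRUE, FALSE, TRUE))
})

test_that("top-k counting clamps, breaks ties deterministically", {
  res <- tibble::tibble(set_id = sprintf("S%02d", 1:20),
                        p_value = c(rep(0.001, 10), rep(0.5, 10)))
  truth <- setNames(rep(c(TRUE, FALSE), each = 10), res$set_id)
  expect_equal(topk_true_positives(res, truth, k = 10), 10)
  expect_warning(n <- topk_true_positives(res, truth, k = 25), "clamped")
  expect_equal(n, 10)

  # tie at the boundary: lexicographic set order decides, reproducibly
  res2 <- tibble::tibble(set_id = c("Sb", "Sa", "Sc"),
                         p_value = c(0.1, 0.1, 0.1))
  truth2 <- c(Sa = TRUE, Sb = FALSE, Sc = TRUE)
  expect_equal(topk_true_positives(res2, truth2, k = 2), 1)
})

test_that("under a global null the top-k hit rate matches the hypergeometric mean", {
  set.seed(81)
  ids <- sprintf("S%03d", 1:200)
  truth <- setNames(c(rep(TRUE, 10), rep(FALSE, 190)), ids)
  hits <- replicate(400, {
    res <- tibble::tibble(set_id = ids, p_value = runif(200))
    topk_true_positives(res, truth, 10)
  })
  expect_equal(mean(hits), 10 * 10 / 200, tolerance = 0.3)
})

test_that("trapezoid AUC equals the rank-statistic AUC exactly", {
  set.seed(82)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    ids <- sprintf("S%03d", seq_len(n))
    p <- round(runif(n), sample(c(1, 2, 6), 1))  # provoke ties
    truth <- setNames(sample(c(TRUE, FALSE), n, replace = TRUE), ids)
    if (!any(truth) || all(truth)) next
    res <- tibble::tibble(set_id = ids, p_value = p)
    out <- roc_auc(res, truth)
    expect_equal(out$auc, gsetint:::rank_auc(res, truth), tolerance = 1e-12)
    expect_true(all(out$curve$sensitivity >= 0 &
                      out$curve$sensitivity <= 1))
  }
})

test_that("AUC hits its endpoints for perfect and degenerate inputs", {
  ids <- sprintf("S%02d", 1:10)
  truth <- setNames(rep(c(TRUE, FALSE), each = 5), ids)
  res <- tibble::tibble(set_id = ids, p_value = c(1:5 / 100, 6:10 / 10))
  expect_equal(roc_auc(res, truth)$auc, 1)
  res_flip <- tibble::tibble(set_id = ids, p_value = rev(res$p_value))
  expect_equal(roc_auc(res_flip, truth)$auc, 0)
  expect_error(roc_auc(res, setNames(rep(TRUE, 10), ids)),
               class = "gsetint_error_input")
})

test_that("exclusive fractions follow their set-algebra definitions", {
  tp <- list(E1 = c("A", "B"), E2 = c("B", "C"), C1 = character())
  expect_equal(exclusive_fraction(tp, "E1"), 0.5)
  expect_true(is.na(exclusive_fraction(tp, "C1")))
  expect_equal(exclusive_fraction(list(E1 = "A", E2 = "B"), "E1"), 1)
  expect_equal(exclusive_fraction(list(E1 = "A", E2 = c("A", "B")), "E1"), 0)

  expect_equal(exclusive_fraction_integration(
    list(E1 = "C", E2 = character()), c("A", "B", "C")), 2 / 3)
  expect_equal(exclusive_fraction_integration(
    list(E1 = c("A", "B")), c("A", "B")), 0)
  expect_equal(exclusive_fraction_integration(
    list(E1 = character(), E2 = character()), c("A")), 1)
  # invariance to what the non-TP sets are called
  expect_equal(exclusive_fraction(tp, "E2"), 0.5)
})

test_that("scenario evaluation summarizes per-method performance", {
  cfg <- backbone_config(n_genes = 400L, n_samples = 40L, n_class1 = 20L)
  sim <- run_scenario(cfg, spike_config(n_spiked = 3, beta = 0.9, gamma = 1),
                      n_sets = 12L, size_range = c(10L, 30L),
                      n_reps = 3L, seed = 83)
  ev <- evaluate_scenario(sim, k = 5)
  expect_setequal(ev$summary$method,
                  c("E1", "E2", "C1", "C2", "INT", "AvgP", "MinP"))
  expect_true(all(ev$summary$mean_auc >= 0 & ev$summary$mean_auc <= 1))
  expect_true(all(ev$summary$mean_topk_tp <= 5))
  expect_true(all(ev$ef$mean_ef >= 0 & ev$ef$mean_ef <= 1, na.rm = TRUE))
  # strong signal: integrative AUC should be near-perfect here
  expect_gt(ev$summary$mean_auc[ev$summary$method == "INT"], 0.9)
  # averaged ROC is on the fixed grid, monotone in specificity
  roc_int <- ev$roc[ev$roc$method == "INT", ]
  expect_equal(nrow(roc_int), 101)
  expect_true(all(diff(roc_int$mean_sensitivity) <= 1e-9))
})
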