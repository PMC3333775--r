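test_that("backbone generation is seed-reproducible with the right shape", {
  cfg <- backbone_config(n_genes = 100L, n_samples = 20L, n_class1 = 10L)
  s1 <- generate_backbone(cfg, seed = 77)
  s2 <- generate_backbone(cfg, seed = 77)
  expect_identical(s1$matrices$E1$values, s2$matrices$E1$values)
  expect_identical(s1$phenotype$labels, s2$phenotype$labels)
  expect_equal(sum(s1$phenotype$labels), 10)
  expect_equal(dim(s1$matrices$C2$values), c(100, 20))
})

test_that("independent backbone platforms are uncorrelated", {
  cfg <- backbone_config(n_genes = 300L, n_samples = 99L)
  st <- generate_backbone(cfg, seed = 31)
  g <- sample(300, 40)
  r_cross <- sapply(g, function(i)
    cor(st$matrices$E1$values[i, ], st$matrices$E2$values[i, ]))
  expect_lt(abs(mean(r_cross)), 0.1)
  r_adj <- sapply(g[g < 300], function(i)
    cor(st$matrices$C1$values[i, ], st$matrices$C1$values[i + 1, ]))
  expect_lt(abs(mean(r_adj)), 0.1)
})

test_that("pair correlation and CN autocorrelation are realized", {
  cfg <- backbone_config(n_genes = 400L, n_samples = 99L,
                         rho_pair = 0.6, cn_corlen = 50)
  st <- generate_backbone(cfg, seed = 32)
  g <- seq_len(200)
  r_pair <- sapply(g, function(i)
    cor(st$matrices$E1$values[i, ], st$matrices$E2$values[i, ]))
  expect_equal(mean(r_pair), 0.6, tolerance = 0.1)

  cn <- st$matrices$C1$values
  r_near <- mean(sapply(g, function(i) cor(cn[i, ], cn[i + 1, ])))
  r_far <- mean(sapply(g, function(i) cor(cn[i, ], cn[i + 190, ])))
  expect_gt(r_near, r_far + 0.3)
})

test_that("label permutation keeps matrices and class counts", {
  st <- toy_study(n_samples = 21, seed = 33,
                  labels = rep(c(0L, 1L), c(10, 11)))
  perm <- permute_labels_backbone(st, seed = 4)
  expect_identical(perm$matrices$P1$values, st$matrices$P1$values)
  expect_equal(sum(perm$phenotype$labels), 11)
})

test_that("synthetic collections are disjoint with in-range sizes", {
  universe <- sprintf("g%04d", 1:2000)
  coll <- synthetic_collection(universe, n_sets = 30, seed = 9)
  sizes <- lengths(coll$sets)
  expect_true(all(sizes >= 10 & sizes <= 100))
  expect_equal(anyDuplicated(unlist(coll$sets)), 0)
  expect_error(synthetic_collection(sprintf("g%02d", 1:50), n_sets = 30),
               class = "gsetint_error_input")
})

test_that("set gene assignment is uniform over the universe", {
  universe <- sprintf("g%03d", 1:60)
  counts <- integer(60)
  set.seed(10)
  for (i in 1:300) {
    coll <- synthetic_collection(universe, n_sets = 2,
                                 size_sampler = function(n) rep(15L, n))
    counts <- counts + universe %in% unlist(coll$sets)
  }
  expect_gt(chisq.test(counts)$p.value, 0.001)
})

test_that("band collections partition the ordered universe contiguously", {
  universe <- sprintf("g%03d", 1:105)
  coll <- band_collection(universe, band_size = 20)
  expect_equal(length(coll$sets), 6)
  expect_identical(unlist(coll$sets, use.names = FALSE), universe)
  expect_identical(coll$sets[[1]], universe[1:20])
  expect_equal(length(coll$sets[[6]]), 5)
})

test_that("delta calibration inverts the t-test power function", {
  # beta = 0.5 at alpha 0.05: delta is essentially z_{0.975} * se
  d <- calibrate_delta(1, 49, 50, beta = 0.5)
  expect_equal(d, qnorm(0.975) * sqrt(1 / 49 + 1 / 50), tolerance = 0.01)

  # equal group sizes: agreement with the power.t.test oracle
  ref <- power.t.test(n = 50, power = 0.8, sig.level = 0.05)$delta
  expect_equal(calibrate_delta(1, 50, 50, beta = 0.8), ref, tolerance = 1e-4)

  # limits and monotonicity
  expect_lt(calibrate_delta(1, 49, 50, beta = 0.0501), 0.01)
  betas <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  ds <- sapply(betas, function(b) calibrate_delta(1, 49, 50, beta = b))
  expect_true(all(diff(ds) > 0))
  expect_equal(calibrate_delta(2.5, 49, 50, beta = 0.5), 2.5 * ds[3],
               tolerance = 1e-9)
  expect_error(calibrate_delta(1, 49, 50, beta = 0.04),
               class = "gsetint_error_input")
})

test_that("spike-in alters exactly the class-1 entries of altered genes", {
  st <- generate_backbone(backbone_config(n_genes = 200L, n_samples = 30L,
                                          n_class1 = 15L), seed = 55)
  coll <- synthetic_collection(backbone_gene_ids_for_test(200L), n_sets = 8,
                               size_sampler = function(n) rep(20L, n),
                               seed = 56)
  # gamma = 0: nothing changes
  set.seed(57)
  sp0 <- spike_in(st, coll, spike_config(n_spiked = 4, beta = 0.5, gamma = 0))
  expect_identical(sp0$study$matrices$E1$values, st$matrices$E1$values)
  expect_equal(nrow(sp0$truth$altered), 0)
  expect_length(sp0$truth$spiked_sets, 4)

  # gamma = 1: every spiked gene altered on every platform by exactly delta
  set.seed(58)
  sp1 <- spike_in(st, coll, spike_config(n_spiked = 4, beta = 0.5, gamma = 1))
  diff <- sp1$study$matrices$E1$values - st$matrices$E1$values
  class1 <- st$phenotype$labels == 1
  spiked_genes <- unlist(coll$sets[sp1$truth$spiked_sets])
  expect_true(all(abs(diff[!rownames(diff) %in% spiked_genes, ]) == 0))
  expect_true(all(diff[spiked_genes, !class1] == 0))
  d1 <- sp1$truth$altered$delta[sp1$truth$altered$platform == "E1"][1]
  expect_gt(d1, 0)
  one_set <- coll$sets[[sp1$truth$spiked_sets[1]]]
  expect_true(all(abs(diff[one_set, class1] -
                        unique(sp1$truth$altered$delta[
                          sp1$truth$altered$set_id == sp1$truth$spiked_sets[1] &
                          sp1$truth$altered$platform == "E1"])) < 1e-12))
})

test_that("binomial gene selection is independent across platforms", {
  st <- generate_backbone(backbone_config(n_genes = 100L, n_samples = 20L,
                                          n_class1 = 10L), seed = 60)
  coll <- gene_set_collection(list(S = sprintf("g%05d", 1:50)),
                              universe = sprintf("g%05d", 1:100))
  set.seed(61)
  counts <- matrix(0, 200, 2)
  for (i in 1:200) {
    sp <- spike_in(st, coll, spike_config(n_spiked = 1, beta = 0.5,
                                          gamma = 0.1))
    a <- sp$truth$altered
    counts[i, 1] <- sum(a$platform == "E1")
    counts[i, 2] <- sum(a$platform == "E2")
  }
  expect_equal(mean(counts[, 1]), 5, tolerance = 0.15)
  expect_lt(abs(cor(counts[, 1], counts[, 2])), 0.2)
})

test_that("scenario runs are reproducible end to end", {
  cfg <- backbone_config(n_genes = 300L, n_samples = 30L, n_class1 = 15L)
  a <- run_scenario(cfg, spike_config(n_spiked = 3, beta = 0.8, gamma = 0.5),
                    n_sets = 10L, size_range = c(10L, 25L),
                    n_reps = 2L, seed = 70)
  b <- run_scenario(cfg, spike_config(n_spiked = 3, beta = 0.8, gamma = 0.5),
                    n_sets = 10L, size_range = c(10L, 25L),
                    n_reps = 2L, seed = 70)
  expect_identical(a$results, b$results)
  expect_identical(a$spiked, b$spiked)
  expect_equal(a$failed, 0L)
  expect_setequal(unique(a$results$method),
                  c("E1", "E2", "C1", "C2", "INT", "AvgP", "MinP"))
  # every repetition covers the identical collection
  expect_equal(dplyr::n_distinct(a$results$set_id), 10)
})
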