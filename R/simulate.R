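# Spike-in simulation suite: synthetic multi-platform null backbones,
# gene set collection generators, power-calibrated mean shifts, and the
# scenario runner that benchmarks every analysis method.

#' Backbone configuration
#'
#' Describes the synthetic null study: D gene-by-sample platforms on the
#' same samples with random binary labels and no gene-phenotype
#' association. Expression-like platforms draw independent standard
#' normals per gene; copy-number-like platforms optionally carry AR(1)
#' spatial autocorrelation along the gene order (unit marginal variance).
#' Consecutive platforms of the same kind (E1/E2, C1/C2) are correlated
#' gene-wise at `rho_pair`.
#'
#' @param n_genes Genes per platform (every platform measures all genes).
#' @param n_samples Total samples (>= 4); default 99 with a 49/50 class
#'   split.
#' @param n_class1 Samples in class 1.
#' @param platforms Platform labels.
#' @param kinds `"expression"` or `"cn"` per platform.
#' @param rho_pair Same-gene correlation within consecutive same-kind
#'   platform pairs, in \[0, 1).
#' @param cn_corlen Autocorrelation length (in genes) for CN-like
#'   platforms; 0 disables it. The AR(1) coefficient is `exp(-1/corlen)`.
#' @param seed Optional default seed used by [generate_backbone()].
#' @return A `backbone_config` list.
#' @export
backbone_config <- function(n_genes = 10000L, n_samples = 99L,
                            n_class1 = 49L,
                            platforms = c("E1", "E2", "C1", "C2"),
                            kinds = c("expression", "expression", "cn", "cn"),
                            rho_pair = 0, cn_corlen = 0, seed = NULL) {
  if (n_samples < 4L) stop_input("`n_samples` must be >= 4.")
  if (n_class1 < 1L || n_class1 >= n_samples) {
    stop_input("`n_class1` must leave both classes non-empty.")
  }
  if (rho_pair < 0 || rho_pair >= 1) stop_input("`rho_pair` must be in [0, 1).")
  if (length(kinds) != length(platforms)) {
    stop_input("`kinds` must match `platforms`.")
  }
  kinds <- match.arg(kinds, c("expression", "cn"), several.ok = TRUE)
  structure(list(n_genes = as.integer(n_genes),
                 n_samples = as.integer(n_samples),
                 n_class1 = as.integer(n_class1),
                 platforms = platforms, kinds = kinds,
                 rho_pair = rho_pair, cn_corlen = cn_corlen, seed = seed),
            class = "backbone_config")
}

backbone_gene_ids <- function(config) sprintf("g%05d", seq_len(config$n_genes))

ar1_colwise <- function(Z, corlen) {
  if (corlen <= 0) return(Z)
  a <- exp(-1 / corlen)
  s <- sqrt(1 - a^2)
  X <- Z
  for (g in 2:nrow(Z)) X[g, ] <- a * X[g - 1L, ] + s * Z[g, ]
  X
}

#' Generate a synthetic null backbone study
#'
#' @param config A [backbone_config()].
#' @param seed Integer seed (overrides `config$seed`); `NULL` continues
#'   the current RNG stream.
#' @return A [build_study()] result whose labels are random, so no gene
#'   is associated with the phenotype.
#' @export
generate_backbone <- function(config = backbone_config(), seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  G <- config$n_genes
  N <- config$n_samples
  genes <- backbone_gene_ids(config)
  samples <- sprintf("s%03d", seq_len(N))

  draw_platform <- function(kind) {
    Z <- matrix(rnorm(G * N), G, N)
    if (kind == "cn") Z <- ar1_colwise(Z, config$cn_corlen)
    Z
  }

  D <- length(config$platforms)
  mats <- vector("list", D)
  # pair consecutive platforms of the same kind at rho_pair
  prev_of_kind <- list(expression = NA_integer_, cn = NA_integer_)
  for (d in seq_len(D)) {
    kind <- config$kinds[d]
    fresh <- draw_platform(kind)
    prev <- prev_of_kind[[kind]]
    if (!is.na(prev) && config$rho_pair > 0) {
      fresh <- config$rho_pair * mats[[prev]] +
        sqrt(1 - config$rho_pair^2) * fresh
      prev_of_kind[[kind]] <- NA_integer_
    } else {
      prev_of_kind[[kind]] <- d
    }
    mats[[d]] <- fresh
  }
  mats <- lapply(seq_len(D), function(d) {
    dimnames(mats[[d]]) <- list(genes, samples)
    genomic_matrix(mats[[d]], config$platforms[d])
  })

  labels <- sample(rep(c(0L, 1L), c(N - config$n_class1, config$n_class1)))
  build_study(mats, phenotype_binary(samples, labels))
}

#' Permute the phenotype labels of a study
#'
#' Reconstructs the empirical-null backbone from a real study: the
#' matrices are untouched (so gene-gene and cross-platform correlations
#' are preserved) and the binary labels are shuffled, preserving class
#' counts.
#'
#' @param study A [build_study()] result with a binary phenotype.
#' @param seed Optional integer seed.
#' @return The study with shuffled labels.
#' @export
permute_labels_backbone <- function(study, seed = NULL) {
  check_binary_study(study)
  if (!is.null(seed)) set.seed(seed)
  ph <- study$phenotype
  study$phenotype <- phenotype_binary(ph$sample_ids, sample(ph$labels))
  study
}

#' Synthetic disjoint gene set collection
#'
#' Random, non-overlapping gene sets mimicking a canonical-pathway size
#' distribution: sizes are drawn log-uniformly on `size_range` by default
#' and genes are assigned uniformly at random without replacement, so
#' genes in a set are no more correlated than genes across sets.
#'
#' @param universe Character vector of genes to draw from.
#' @param n_sets Number of sets.
#' @param size_range Inclusive size bounds for the default log-uniform
#'   size sampler.
#' @param size_sampler Optional function(n) returning n integer sizes.
#' @param seed Optional integer seed.
#' @return A [gene_set_collection()] whose sets are pairwise disjoint.
#' @export
synthetic_collection <- function(universe, n_sets = 200L,
                                 size_range = c(10L, 100L),
                                 size_sampler = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sizes <- if (is.null(size_sampler)) {
    as.integer(round(exp(stats::runif(n_sets, log(size_range[1]),
                                      log(size_range[2])))))
  } else {
    as.integer(size_sampler(n_sets))
  }
  if (sum(sizes) > length(universe)) {
    stop_input(sprintf(
      "total set size %d exceeds the %d-gene universe.",
      sum(sizes), length(universe)))
  }
  shuffled <- sample(universe)
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  sets <- lapply(seq_len(n_sets), function(k) shuffled[starts[k]:ends[k]])
  names(sets) <- sprintf("set%03d", seq_len(n_sets))
  gene_set_collection(sets, universe = universe)
}

#' Positional (chromosome-band-like) gene set collection
#'
#' Partitions an ordered gene universe into contiguous non-overlapping
#' blocks, emulating chromosome-band sets. The order of `universe` is the
#' genome order, so with CN autocorrelation switched on in the backbone,
#' genes within a block are spatially correlated.
#'
#' @param universe Genes in genome order (not re-sorted).
#' @param band_size Genes per band (the last band may be shorter).
#' @return A [gene_set_collection()] partitioning the universe.
#' @export
band_collection <- function(universe, band_size = 50L) {
  if (band_size < 1L) stop_input("`band_size` must be >= 1.")
  idx <- ceiling(seq_along(universe) / band_size)
  sets <- split(universe, idx)
  names(sets) <- sprintf("band%03d", seq_along(sets))
  coll <- gene_set_collection(sets, universe = universe)
  coll$universe <- universe  # preserve genome order
  coll
}

#' Power-calibrated spike-in shift
#'
#' Solves for the mean shift Delta such that a two-sample t-test at
#' two-sided level `alpha`, on normal data with standard deviation
#' `avg_sd` and group sizes `n1`, `n2`, has power `beta` against the
#' shift. The noncentral-t power function is inverted by monotone
#' root-finding on the noncentrality parameter.
#'
#' @param avg_sd Average gene standard deviation of the spiked set
#'   (vectorized).
#' @param n1,n2 Group sample sizes (>= 2).
#' @param beta Target power in (alpha, 1).
#' @param alpha Two-sided test level.
#' @return Delta >= 0, proportional to `avg_sd` and strictly increasing
#'   in `beta`.
#' @examples
#' calibrate_delta(1, 49, 50, beta = 0.5)  # about 0.39
#' @export
calibrate_delta <- function(avg_sd, n1, n2, beta, alpha = 0.05) {
  if (n1 < 2L || n2 < 2L) stop_input("group sizes must be >= 2.")
  if (beta <= alpha || beta >= 1) {
    stop_input("`beta` must lie in (alpha, 1): power below the test size is unattainable with a nonnegative shift.")
  }
  df <- n1 + n2 - 2
  tq <- qt(1 - alpha / 2, df)
  pwr <- function(ncp) pt(tq, df, ncp, lower.tail = FALSE) + pt(-tq, df, ncp)
  ncp <- uniroot(function(x) pwr(x) - beta, c(0, 50),
                 tol = 1e-10, extendInt = "upX")$root
  se <- sqrt(1 / n1 + 1 / n2)
  avg_sd * se * ncp
}

#' Spike-in configuration
#'
#' @param n_spiked Number of gene sets to spike (default 10).
#' @param beta Signal strength: the target two-sample t-test power used
#'   to calibrate the shift, in (alpha, 1).
#' @param gamma Expected altered fraction: each gene of a spiked set is
#'   altered with probability gamma, independently per data type.
#' @param alpha Level of the calibration t-test (two-sided).
#' @return A `spike_config` list.
#' @export
spike_config <- function(n_spiked = 10L, beta = 0.5, gamma = 0.1,
                         alpha = 0.05) {
  if (gamma < 0 || gamma > 1) stop_input("`gamma` must be in [0, 1].")
  if (beta <= alpha || beta >= 1) stop_input("`beta` must be in (alpha, 1).")
  structure(list(n_spiked = as.integer(n_spiked), beta = beta,
                 gamma = gamma, alpha = alpha),
            class = "spike_config")
}

#' Spike phenotype association into a null study
#'
#' Picks `n_spiked` sets at random. For each spiked set and each data
#' type independently, every set gene is altered with probability
#' `gamma`, and the set's shift Delta_k -- calibrated per platform from
#' the average standard deviation of the set's genes there (see
#' [calibrate_delta()]) -- is added to the class-1 samples of the altered
#' genes. Only class-1 entries of altered genes change; everything else
#' is bit-identical. A spiked set whose binomial draws alter no genes
#' anywhere stays labeled true, which conservatively deflates measured
#' power.
#'
#' @param study A null [build_study()] result (random binary labels).
#' @param collection A [gene_set_collection()] over the study's genes.
#' @param config A [spike_config()].
#' @return A list with `study` (modified) and `truth`, a `spike_truth`
#'   object holding the spiked set ids, the per-platform altered gene
#'   lists with their shifts, and the union of spiked-set genes.
#' @export
spike_in <- function(study, collection, config = spike_config()) {
  check_binary_study(study)
  if (config$n_spiked > length(collection$set_ids)) {
    stop_input("more spiked sets requested than the collection holds.")
  }
  spiked <- sample(collection$set_ids, config$n_spiked)
  class1 <- study$phenotype$labels == 1L
  n1 <- sum(class1)
  n2 <- sum(!class1)

  altered <- list()
  for (d in study$platform_ids) {
    vals <- study$matrices[[d]]$values
    hits <- character()
    shifts <- numeric()
    for (k in spiked) {
      set_genes <- collection$sets[[k]]
      g_meas <- set_genes[set_genes %in% rownames(study$availability)]
      g_meas <- g_meas[study$availability[g_meas, d]]
      if (!length(g_meas)) next
      rows <- vals[g_meas, , drop = FALSE]
      sds <- sqrt(rowSums((rows - rowMeans(rows))^2) / (ncol(rows) - 1L))
      delta <- calibrate_delta(mean(sds), n1, n2, config$beta, config$alpha)
      hit <- g_meas[stats::runif(length(g_meas)) < config$gamma]
      if (length(hit)) {
        hits <- c(hits, hit)
        shifts <- c(shifts, rep(delta, length(hit)))
        altered[[length(altered) + 1L]] <-
          tibble(set_id = k, platform = d, gene = hit, delta = delta)
      }
    }
    if (length(hits)) {
      # one batched update per platform; a gene hit through several
      # overlapping spiked sets accumulates every shift
      per_gene <- rowsum(shifts, hits)
      idx <- match(rownames(per_gene), rownames(vals))
      vals[idx, class1] <- vals[idx, class1] + as.numeric(per_gene)
      study$matrices[[d]]$values <- vals
    }
  }
  truth <- structure(
    list(spiked_sets = spiked,
         altered = dplyr::bind_rows(altered),
         union_genes = sort(unique(unlist(collection$sets[spiked])))),
    class = "spike_truth")
  list(study = study, truth = truth)
}

#' Run a full spike-in simulation scenario
#'
#' For each repetition: draw a fresh null backbone (or freshly permute
#' the labels of a supplied real study), spike in association, score
#' every gene on the intersection universe, run the competitive test per
#' single platform and for the integrative score, and combine the
#' per-platform P-values meta-analytically. The gene set collection is
#' fixed across repetitions. Everything is reproducible from the master
#' seed; per-repetition sub-seeds are recorded.
#'
#' @param backbone A [backbone_config()]; ignored when `study` is given.
#' @param spike A [spike_config()].
#' @param collection A [gene_set_collection()], or `NULL` to generate a
#'   [synthetic_collection()] over the backbone genes.
#' @param n_sets,size_range Passed to [synthetic_collection()] when
#'   `collection` is `NULL`.
#' @param n_reps Number of repetitions.
#' @param methods Methods to report: platform labels, `"INT"`, `"AvgP"`,
#'   `"MinP"`.
#' @param study Optional real [build_study()] result used (with label
#'   permutation) instead of the synthetic backbone.
#' @param seed Master integer seed.
#' @param spec A [model_spec()].
#' @return An object of class `simulation_result`: `results` (tibble
#'   `rep`, `set_id`, `method`, `n_genes`, `statistic`, `p_value`),
#'   `spiked` (tibble `rep`, `set_id` of the spiked sets), the
#'   collection, configs, `rep_seeds` and the count of failed
#'   repetitions.
#' @export
run_scenario <- function(backbone = backbone_config(),
                         spike = spike_config(),
                         collection = NULL,
                         n_sets = 200L, size_range = c(10L, 100L),
                         n_reps = 100L,
                         methods = c(backbone$platforms, "INT", "AvgP", "MinP"),
                         study = NULL,
                         seed = 1L,
                         spec = model_spec()) {
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)
  coll_seed <- sample.int(.Machine$integer.max - 1L, 1L)

  platform_ids <- if (is.null(study)) backbone$platforms else study$platform_ids
  if (is.null(collection)) {
    universe <- if (is.null(study)) backbone_gene_ids(backbone) else
      gene_universe(study, "intersection")
    collection <- synthetic_collection(universe, n_sets = n_sets,
                                       size_range = size_range,
                                       seed = coll_seed)
  }
  single_methods <- intersect(methods, platform_ids)
  need_singles <- length(single_methods) > 0 ||
    any(c("AvgP", "MinP") %in% methods)

  results <- vector("list", n_reps)
  spiked <- vector("list", n_reps)
  failed <- 0L
  for (r in seq_len(n_reps)) {
    res_r <- tryCatch({
      set.seed(rep_seeds[r])
      st <- if (is.null(study)) generate_backbone(backbone, seed = NULL)
            else permute_labels_backbone(study)
      sp <- spike_in(st, collection, spike)
      scores <- score_genes(sp$study, "intersection", spec)

      per_platform <- if (need_singles) {
        dplyr::bind_rows(lapply(platform_ids, function(p) {
          competitive_test(scores, collection, paste0("s_", p))
        }))
      } else NULL
      parts <- list()
      if (!is.null(per_platform)) {
        parts$single <- dplyr::filter(per_platform,
                                      .data$method %in% single_methods)
      }
      if ("INT" %in% methods) {
        parts$int <- competitive_test(scores, collection, "s_INT")
      }
      meta_wanted <- intersect(c("AvgP", "MinP"), methods)
      if (length(meta_wanted)) {
        parts$meta <- meta_combine(per_platform, methods = meta_wanted)
      }
      list(results = dplyr::bind_rows(parts),
           spiked = sp$truth$spiked_sets)
    }, error = function(e) e)
    if (inherits(res_r, "error")) {
      failed <- failed + 1L
      warn(sprintf("repetition %d failed (%s); excluded.", r,
                   conditionMessage(res_r)))
    } else {
      results[[r]] <- dplyr::mutate(res_r$results, rep = r, .before = 1L)
      spiked[[r]] <- tibble(rep = r, set_id = res_r$spiked)
    }
  }

  structure(
    list(results = dplyr::bind_rows(results),
         spiked = dplyr::bind_rows(spiked),
         collection = collection,
         backbone = backbone, spike = spike,
         methods = methods, n_reps = as.integer(n_reps),
         seed = as.integer(seed), rep_seeds = rep_seeds,
         failed = failed),
    class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(
    "<simulation_result> %d repetition(s), %d method(s), %d sets (beta=%g, gamma=%g)\n",
    x$n_reps - x$failed, length(x$methods), length(x$collection$set_ids),
    x$spike$beta, x$spike$gamma))
  if (x$failed > 0) cat(sprintf("  %d failed repetition(s) excluded\n", x$failed))
  invisible(x)
}
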