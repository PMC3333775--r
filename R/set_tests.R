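# Stage II: gene set tests on a gene score table.
#
# Competitive test: one-sided Mann-Whitney comparing in-set scores to the
# remainder of the scored genes. Self-contained test: one-sample signed
# rank comparing observed in-set scores to the same genes' scores under
# phenotype-label permutation, averaged over permutations.

method_tag <- function(score_col) sub("^s_", "", score_col)

#' Competitive gene set test (Mann-Whitney)
#'
#' For each set, tests one-sidedly whether gene scores inside the set tend
#' to be larger than scores of the remaining genes in the table. Exact
#' P-values are computed by enumeration when the smaller group has at most
#' 8 genes and there are no ties; otherwise the normal approximation with
#' tie correction is used (no continuity correction by default).
#'
#' Scores must come from the intersection universe: genes measured on
#' fewer platforms carry systematically smaller deviance scores, which
#' would bias any between-gene comparison.
#'
#' @param scores A [score_genes()] table.
#' @param collection A [gene_set_collection()].
#' @param score Score column to test (`"s_INT"` or a per-platform column
#'   such as `"s_E1"`).
#' @param continuity Apply a 0.5 continuity correction in the normal
#'   approximation (off by default).
#' @return A tibble with columns `set_id`, `method`, `n_genes`,
#'   `statistic` (the Mann-Whitney U of the in-set group) and `p_value`.
#'   Sets with no scored genes or no scored non-members are skipped and
#'   listed in the `"skipped"` attribute.
#' @export
competitive_test <- function(scores, collection, score = "s_INT",
                             continuity = FALSE) {
  if (identical(attr(scores, "universe"), "union")) {
    abort(paste("competitive tests require scores computed on the",
                "intersection universe; rerun score_genes() with",
                'universe = "intersection".'),
          class = "gsetint_error_universe")
  }
  if (!score %in% names(scores)) {
    stop_input(sprintf("no score column '%s'.", score))
  }
  s <- scores[[score]]
  genes <- scores$gene
  ok <- !is.na(s)
  s <- s[ok]
  genes <- genes[ok]
  n_tot <- length(s)
  r <- rank(s)
  tie_sizes <- tabulate(match(s, unique(s)))
  tie_term <- sum(tie_sizes^3 - tie_sizes)
  has_ties <- tie_term > 0

  # one hash build for all set-membership lookups
  all_pos <- match(unlist(collection$sets, use.names = FALSE), genes)
  pos_by_set <- split(all_pos, rep(seq_along(collection$sets),
                                   lengths(collection$sets)))

  n_sets <- length(collection$set_ids)
  U <- stat_n <- pval <- rep(NA_real_, n_sets)
  for (k in seq_len(n_sets)) {
    pos <- all_pos_k <- pos_by_set[[k]]
    pos <- pos[!is.na(pos)]
    n1 <- length(pos)
    n2 <- n_tot - n1
    if (n1 < 1L || n2 < 1L) next
    Uk <- sum(r[pos]) - n1 * (n1 + 1) / 2
    if (min(n1, n2) <= 8L && !has_ties) {
      p <- 1 - pwilcox(Uk - 1, n1, n2)
    } else {
      mu <- n1 * n2 / 2
      sig2 <- n1 * n2 / 12 * ((n_tot + 1) - tie_term / (n_tot * (n_tot - 1)))
      cc <- if (continuity) 0.5 else 0
      p <- pnorm((Uk - cc - mu) / sqrt(sig2), lower.tail = FALSE)
    }
    U[k] <- Uk
    stat_n[k] <- n1
    pval[k] <- min(max(p, 0), 1)
  }
  ok_sets <- !is.na(pval)
  skipped <- collection$set_ids[!ok_sets]
  out <- tibble(set_id = collection$set_ids[ok_sets],
                method = method_tag(score),
                n_genes = as.integer(stat_n[ok_sets]),
                statistic = U[ok_sets], p_value = pval[ok_sets])
  if (length(skipped)) {
    warn(sprintf("%d set(s) had no scored genes or non-members; skipped.",
                 length(skipped)))
  }
  attr(out, "skipped") <- skipped
  out
}

# Transposed (samples x genes) predictor blocks for the C++ scorer.
prepare_score_inputs <- function(study, universe) {
  genes <- gene_universe(study, universe)
  av <- study$availability[genes, , drop = FALSE]
  platforms <- lapply(study$matrices, function(m) {
    idx <- match(genes, m$gene_ids)
    vals <- t(m$values)[, ifelse(is.na(idx), 1L, idx), drop = FALSE]
    vals[, is.na(idx)] <- NA_real_
    colnames(vals) <- genes
    vals
  })
  list(genes = genes, av = av, platforms = platforms)
}

#' Permutation null score tables
#'
#' Rescoring of every gene under B independent shuffles of the phenotype
#' labels (class counts preserved). The null is computed once per
#' analysis and shared across all sets; because every permutation scores
#' the same genes on the same platforms, a gene's null scores reflect its
#' own platform count, which is what lets self-contained tests run on the
#' union universe.
#'
#' @param study A [build_study()] result with a binary phenotype.
#' @param universe Universe mode, as in [score_genes()].
#' @param B Number of permutations (default 500).
#' @param seed Integer seed; the null is bit-reproducible given the seed.
#' @param spec A [model_spec()] (logistic family).
#' @return An object of class `permutation_null`.
#' @export
build_permutation_null <- function(study,
                                   universe = c("intersection", "union"),
                                   B = 500L, seed = 1L,
                                   spec = model_spec()) {
  universe <- match.arg(universe)
  check_binary_study(study)
  if (B < 1L) stop_input("`B` must be >= 1.")
  inp <- prepare_score_inputs(study, universe)
  G <- length(inp$genes)
  D <- length(study$platform_ids)
  y <- as.numeric(study$phenotype$labels)

  single <- lapply(study$platform_ids, function(p) {
    matrix(NA_real_, G, B, dimnames = list(inp$genes, NULL))
  })
  names(single) <- study$platform_ids
  integ <- matrix(NA_real_, G, B, dimnames = list(inp$genes, NULL))

  set.seed(seed)
  for (b in seq_len(B)) {
    yb <- sample(y)
    res <- cpp_score_genes(inp$platforms, inp$av * 1L, yb,
                           spec$max_iterations, spec$tolerance,
                           spec$separation_tol)
    sm <- res$single
    sm[!inp$av] <- NA_real_
    for (d in seq_len(D)) single[[d]][, b] <- sm[, d]
    integ[, b] <- res$integrative
  }
  structure(
    list(B = as.integer(B), seed = as.integer(seed), genes = inp$genes,
         platform_ids = study$platform_ids, universe = universe,
         single = single, integrative = integ,
         n_platforms = as.integer(rowSums(inp$av))),
    class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf("<permutation_null> %d genes x %d permutations (%s universe)\n",
              length(x$genes), x$B, x$universe))
  invisible(x)
}

null_matrix_for <- function(null, score) {
  if (score == "s_INT") return(null$integrative)
  p <- method_tag(score)
  if (!p %in% names(null$single)) {
    stop_input(sprintf("no null scores for column '%s'.", score))
  }
  null$single[[p]]
}

signed_rank_W <- function(d) {
  r <- rank(abs(d))
  sum(r[d > 0]) + 0.5 * sum(r[d == 0])
}

#' Self-contained gene set test (permutation-averaged signed rank)
#'
#' For each permutation b, the paired differences between a set's
#' observed gene scores and the b-th permutation-null scores of the same
#' genes are reduced to the one-sample Wilcoxon signed-rank statistic W_b
#' (sum of ranks of the positive differences; zero differences contribute
#' half their midrank). The W_b are averaged over permutations and the
#' one-sided P-value is read from the normal approximation to the
#' signed-rank null, with mean n(n+1)/4 and variance n(n+1)(2n+1)/24.
#'
#' @param scores Observed [score_genes()] table (union universe allowed).
#' @param null A [build_permutation_null()] built on the same study and
#'   universe.
#' @param collection A [gene_set_collection()].
#' @param score Score column to test.
#' @return A tibble like [competitive_test()]'s, with `statistic` the
#'   permutation-averaged W. Sets with fewer than 2 scored genes are
#'   skipped.
#' @export
selfcontained_test <- function(scores, null, collection, score = "s_INT") {
  if (!score %in% names(scores)) {
    stop_input(sprintf("no score column '%s'.", score))
  }
  nm <- null_matrix_for(null, score)
  obs <- setNames(scores[[score]], scores$gene)

  rows <- lapply(collection$set_ids, function(id) {
    g <- intersect(collection$sets[[id]], scores$gene)
    g <- g[!is.na(obs[g]) & g %in% rownames(nm)]
    n <- length(g)
    if (n < 2L) return(NULL)
    dmat <- obs[g] - nm[g, , drop = FALSE]
    W <- apply(dmat, 2L, signed_rank_W)
    Wbar <- mean(W)
    mu <- n * (n + 1) / 4
    sig <- sqrt(n * (n + 1) * (2 * n + 1) / 24)
    p <- pnorm((Wbar - mu) / sig, lower.tail = FALSE)
    tibble(set_id = id, method = method_tag(score), n_genes = n,
           statistic = Wbar, p_value = p)
  })
  skipped <- collection$set_ids[vapply(rows, is.null, logical(1))]
  out <- dplyr::bind_rows(rows)
  if (length(skipped)) {
    warn(sprintf("%d set(s) had fewer than 2 scored genes; skipped.",
                 length(skipped)))
  }
  attr(out, "skipped") <- skipped
  out
}
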