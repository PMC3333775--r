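# Stage I: gene-to-phenotype association scores.
#
# For a binary phenotype the score of a gene is the deviance difference
# between the intercept-only logistic regression and the logistic
# regression with the gene's genomic measurements as predictors -- one
# predictor for a single-data-type score, one predictor per available
# platform for the integrative score. For survival phenotypes the
# analogous likelihood-ratio statistic from a Cox model is used.

#' Model specification for gene-level fits
#'
#' @param family `"logistic"` for binary phenotypes or `"cox"` for
#'   survival phenotypes.
#' @param max_iterations Maximum IRLS / Newton iterations (>= 10).
#' @param tolerance Relative deviance convergence tolerance (> 0).
#' @param separation_tol Fitted probabilities within this distance of 0/1
#'   for every sample flag the fit as separated; the reported score is
#'   then capped at the null deviance.
#' @return A `model_spec` list.
#' @export
model_spec <- function(family = c("logistic", "cox"),
                       max_iterations = 100L,
                       tolerance = 1e-8,
                       separation_tol = 1e-8) {
  family <- match.arg(family)
  if (tolerance <= 0) stop_input("`tolerance` must be > 0.")
  if (max_iterations < 10L) stop_input("`max_iterations` must be >= 10.")
  structure(list(family = family,
                 max_iterations = as.integer(max_iterations),
                 tolerance = tolerance,
                 separation_tol = separation_tol),
            class = "model_spec")
}

#' Logistic regression fit with deviances
#'
#' Maximum-likelihood logistic regression (IRLS with step-halving) of a
#' binary response on one or more predictor columns, returning the null
#' and residual deviances that gene scores are built from. Predictors are
#' centered and scaled internally (deviances are invariant to affine
#' predictor transforms); constant columns are dropped and contribute
#' nothing.
#'
#' @param y Binary 0/1 response with both classes present.
#' @param X Numeric predictor matrix or vector (samples in rows).
#' @param spec A [model_spec()] (logistic family).
#' @return An object of class `deviance_fit` with elements
#'   `coefficients` (on the standardized scale, intercept first),
#'   `null_deviance`, `residual_deviance`, `converged` and
#'   `separation_detected`.
#' @examples
#' y <- rep(0:1, each = 25)
#' X <- matrix(rnorm(100), 50, 2)
#' fit <- fit_glm_deviance(y, X)
#' fit$null_deviance - fit$residual_deviance
#' @export
fit_glm_deviance <- function(y, X, spec = model_spec()) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop_input("`y` must be 0/1.")
  if (length(unique(y)) < 2L) stop_degenerate("`y` must contain both classes.")
  X <- as.matrix(X)
  if (!is.numeric(X) || anyNA(X) || any(is.infinite(X))) {
    stop_input("`X` must be finite numeric.")
  }
  if (nrow(X) != length(y)) stop_input("`X` rows must match `y`.")
  if (length(y) <= ncol(X) + 1L) {
    stop_input("need more samples than predictors.")
  }
  fit <- cpp_logit_deviance(X, y, spec$max_iterations, spec$tolerance,
                            spec$separation_tol)
  structure(
    list(coefficients = drop(fit$coefficients),
         kept_columns = as.integer(fit$kept_columns),
         null_deviance = fit$null_deviance,
         residual_deviance = fit$residual_deviance,
         converged = fit$converged,
         separation_detected = fit$separation),
    class = "deviance_fit")
}

#' @export
print.deviance_fit <- function(x, ...) {
  cat(sprintf(
    "<deviance_fit> null dev %.4f, residual dev %.4f (score %.4f)%s%s\n",
    x$null_deviance, x$residual_deviance,
    x$null_deviance - x$residual_deviance,
    if (!x$converged) " [not converged]" else "",
    if (x$separation_detected) " [separated]" else ""))
  invisible(x)
}

deviance_score <- function(fit) {
  s <- fit$null_deviance - fit$residual_deviance
  if (fit$separation_detected) s <- fit$null_deviance
  max(s, 0)
}

#' Single-data-type gene score
#'
#' Deviance difference of the logistic regressions with and without the
#' gene's measurement on one platform as the single predictor.
#'
#' @param study A [build_study()] result with a binary phenotype.
#' @param platform Platform identifier.
#' @param gene Gene identifier.
#' @param spec A [model_spec()].
#' @return Non-negative score, or `NA` if the gene is unmeasured on the
#'   platform.
#' @export
single_type_score <- function(study, platform, gene, spec = model_spec()) {
  check_binary_study(study)
  if (!platform %in% study$platform_ids) {
    stop_input(sprintf("unknown platform '%s'.", platform))
  }
  if (!gene %in% rownames(study$availability) ||
      !study$availability[gene, platform]) {
    return(NA_real_)
  }
  x <- study$matrices[[platform]]$values[gene, ]
  deviance_score(fit_glm_deviance(study$phenotype$labels, x, spec))
}

#' Integrative gene score
#'
#' Deviance difference between the intercept-only logistic model and the
#' multivariate logistic model whose predictors are the gene's
#' measurements on every platform that measures it (fewer than the full
#' platform count is allowed).
#'
#' @inheritParams single_type_score
#' @return Non-negative score.
#' @export
integrative_score <- function(study, gene, spec = model_spec()) {
  check_binary_study(study)
  av <- study$availability
  if (!gene %in% rownames(av) || !any(av[gene, ])) {
    stop_input(sprintf("gene '%s' is unmeasured on every platform.", gene))
  }
  pids <- study$platform_ids[av[gene, ]]
  X <- vapply(pids, function(p) study$matrices[[p]]$values[gene, ],
              numeric(length(study$phenotype$sample_ids)))
  deviance_score(fit_glm_deviance(study$phenotype$labels, X, spec))
}

check_binary_study <- function(study) {
  if (!inherits(study, "multi_omic_study")) {
    stop_input("`study` must be a multi_omic_study.")
  }
  if (study$phenotype$kind != "binary") {
    stop_input("a binary phenotype is required here (see dichotomize_survival).")
  }
  invisible(study)
}

#' Cox-model gene score
#'
#' Likelihood-ratio statistic 2 * (log partial likelihood of the model
#' with the gene's measurements minus the null model), the survival
#' counterpart of the logistic deviance-difference score. Ties are
#' handled by the Breslow approximation.
#'
#' @param time Positive survival times.
#' @param event Event indicator 0/1 (>= 2 events required).
#' @param X Predictor matrix or vector (samples in rows).
#' @return Non-negative score.
#' @export
cox_score <- function(time, event, X) {
  event <- as.integer(event)
  if (sum(event) < 2L) stop_degenerate("need at least 2 events.")
  if (any(time <= 0)) stop_input("survival times must be positive.")
  X <- as.matrix(X)
  keep <- apply(X, 2L, function(col) sd(col) > 0)
  if (!any(keep)) return(0)
  X <- scale(X[, keep, drop = FALSE])
  fit <- survival::coxph(survival::Surv(time, event) ~ X, ties = "breslow")
  max(2 * (fit$loglik[2] - fit$loglik[1]), 0)
}

#' Score every gene of a study
#'
#' Computes, for each gene of the chosen universe, the per-platform
#' deviance scores and the integrative score across all platforms
#' measuring the gene. Fits that hit complete separation are capped at
#' the null deviance and flagged rather than dropped, so the table always
#' covers the full universe.
#'
#' @param study A [build_study()] result (binary phenotype for the
#'   logistic family; survival for the Cox family).
#' @param universe `"intersection"` (genes on all platforms; required for
#'   competitive set tests) or `"union"` (genes on at least one).
#' @param spec A [model_spec()].
#' @return A tibble of class `gene_score_table` with columns `gene`, one
#'   `s_<platform>` column per platform (`NA` where unmeasured), `s_INT`,
#'   `n_platforms`, `converged` (all fits for the gene converged) and
#'   `flagged` (any separation cap). The universe mode and null deviance
#'   are attached as attributes.
#' @export
score_genes <- function(study, universe = c("intersection", "union"),
                        spec = model_spec()) {
  universe <- match.arg(universe)
  genes <- gene_universe(study, universe)
  if (!length(genes)) stop_input("empty gene universe.")
  av <- study$availability[genes, , drop = FALSE]
  D <- length(study$platform_ids)

  if (spec$family == "logistic") {
    check_binary_study(study)
    y <- as.numeric(study$phenotype$labels)
    platforms <- prepare_score_inputs(study, universe)$platforms
    res <- cpp_score_genes(platforms, av * 1L, y,
                           spec$max_iterations, spec$tolerance,
                           spec$separation_tol)
    single <- res$single
    single[!av] <- NA_real_
    colnames(single) <- study$platform_ids
    conv <- rowSums(!res$single_converged & av) == 0 &
      as.logical(res$integrative_converged)
    flag <- rowSums(res$single_separation & av) > 0 |
      as.logical(res$integrative_separation)
    out <- tibble(gene = genes)
    for (d in seq_len(D)) {
      out[[paste0("s_", study$platform_ids[d])]] <- single[, d]
    }
    out$s_INT <- as.numeric(res$integrative)
    out$n_platforms <- as.integer(rowSums(av))
    out$converged <- conv
    out$flagged <- flag
    attr(out, "null_deviance") <- res$null_deviance
  } else {
    ph <- study$phenotype
    if (ph$kind != "survival") {
      stop_input("the Cox family requires a survival phenotype.")
    }
    score_one <- function(gene, pids) {
      X <- vapply(pids, function(p) study$matrices[[p]]$values[gene, ],
                  numeric(length(ph$sample_ids)))
      cox_score(ph$time, ph$event, X)
    }
    single <- matrix(NA_real_, length(genes), D,
                     dimnames = list(genes, study$platform_ids))
    integ <- numeric(length(genes))
    for (i in seq_along(genes)) {
      pids <- study$platform_ids[av[i, ]]
      for (p in pids) single[i, p] <- score_one(genes[i], p)
      integ[i] <- score_one(genes[i], pids)
    }
    out <- tibble(gene = genes)
    for (d in seq_len(D)) {
      out[[paste0("s_", study$platform_ids[d])]] <- single[, d]
    }
    out$s_INT <- integ
    out$n_platforms <- as.integer(rowSums(av))
    out$converged <- TRUE
    out$flagged <- FALSE
  }

  attr(out, "universe") <- universe
  attr(out, "platform_ids") <- study$platform_ids
  attr(out, "family") <- spec$family
  class(out) <- c("gene_score_table", class(out))
  out
}
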