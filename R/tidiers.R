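# broom-style accessors.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a logistic deviance fit
#'
#' @param x A [fit_glm_deviance()] result.
#' @param ... Unused.
#' @return One row per coefficient (standardized predictor scale).
#' @export
tidy.deviance_fit <- function(x, ...) {
  tibble(term = c("(Intercept)", paste0("x", x$kept_columns)),
         estimate = as.numeric(x$coefficients))
}

#' @rdname tidy.deviance_fit
#' @export
glance.deviance_fit <- function(x, ...) {
  tibble(null_deviance = x$null_deviance,
         residual_deviance = x$residual_deviance,
         score = x$null_deviance - x$residual_deviance,
         converged = x$converged,
         separation_detected = x$separation_detected)
}

#' Tidy / summarize a simulation result
#'
#' `tidy()` returns the long per-repetition set-result table; `glance()`
#' one row of scenario-level facts.
#'
#' @param x A [run_scenario()] result.
#' @param ... Unused.
#' @export
tidy.simulation_result <- function(x, ...) x$results

#' @rdname tidy.simulation_result
#' @export
glance.simulation_result <- function(x, ...) {
  tibble(n_reps = x$n_reps, failed = x$failed,
         n_sets = length(x$collection$set_ids),
         n_methods = length(x$methods),
         beta = x$spike$beta, gamma = x$spike$gamma,
         seed = x$seed)
}

#' @rdname tidy.simulation_result
#' @export
tidy.evaluation_report <- function(x, ...) x$per_rep

#' @rdname tidy.simulation_result
#' @export
glance.evaluation_report <- function(x, ...) {
  tidyr::pivot_wider(x$summary[, c("method", "mean_auc")],
                     names_from = "method", values_from = "mean_auc",
                     names_prefix = "auc_")
}
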