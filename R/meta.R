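# Meta-analytic combination of per-platform set-level P-values.

#' Geometric-mean P-value combination (AvgP)
#'
#' `exp(mean(log(p)))` over the available platforms. Missing values are
#' excluded (with a diagnostic attribute); zero P-values are clamped to
#' the smallest positive double and flagged.
#'
#' @param pvalues Numeric vector of per-platform P-values in (0, 1].
#' @return Combined P-value (always within the range of the inputs).
#' @examples
#' avgp(c(0.01, 0.04, 0.16))  # 0.04
#' @export
avgp <- function(pvalues) {
  p <- pvalues[!is.na(pvalues)]
  if (!length(p)) return(NA_real_)
  if (any(p < 0 | p > 1)) stop_input("P-values must lie in [0, 1].")
  clamped <- p == 0
  if (any(clamped)) {
    warn("zero P-value(s) clamped to the smallest positive double.")
    p[clamped] <- .Machine$double.xmin
  }
  out <- exp(mean(log(p)))
  attr(out, "n_missing") <- sum(is.na(pvalues))
  attr(out, "clamped") <- any(clamped)
  out
}

#' Minimum P-value combination (MinP)
#'
#' The minimum over available platforms, reported uncorrected (its use is
#' as a ranking score favouring strong evidence from a single data type).
#' Set `bonferroni = TRUE` for a D * min(p) variant capped at 1 when
#' calibrated P-values are wanted; rankings are unaffected.
#'
#' @inheritParams avgp
#' @param bonferroni Multiply by the number of available platforms.
#' @return Combined P-value.
#' @export
minp <- function(pvalues, bonferroni = FALSE) {
  p <- pvalues[!is.na(pvalues)]
  if (!length(p)) return(NA_real_)
  if (any(p < 0 | p > 1)) stop_input("P-values must lie in [0, 1].")
  out <- min(p)
  if (bonferroni) out <- min(out * length(p), 1)
  attr(out, "n_missing") <- sum(is.na(pvalues))
  out
}

#' Combine per-platform set results meta-analytically
#'
#' Takes the long set-result table produced by running
#' [competitive_test()] (or [selfcontained_test()]) once per platform and
#' appends AvgP and/or MinP rows combining each set's per-platform
#' P-values.
#'
#' @param results Tibble with columns `set_id`, `method`, `p_value` where
#'   `method` holds platform tags.
#' @param methods Which combinations to compute.
#' @param bonferroni Passed to [minp()].
#' @return Tibble in the same shape with `method` set to `"AvgP"` /
#'   `"MinP"`; `n_platforms` counts the P-values combined.
#' @export
meta_combine <- function(results, methods = c("AvgP", "MinP"),
                         bonferroni = FALSE) {
  methods <- match.arg(methods, several.ok = TRUE)
  stopifnot(all(c("set_id", "method", "p_value") %in% names(results)))
  wide <- results |>
    dplyr::group_by(.data$set_id) |>
    dplyr::summarise(
      ps = list(.data$p_value),
      n_platforms = sum(!is.na(.data$p_value)),
      .groups = "drop")
  out <- list()
  if ("AvgP" %in% methods) {
    out$AvgP <- wide |>
      dplyr::mutate(method = "AvgP",
                    p_value = vapply(.data$ps, function(p)
                      as.numeric(avgp(p)), numeric(1)))
  }
  if ("MinP" %in% methods) {
    out$MinP <- wide |>
      dplyr::mutate(method = "MinP",
                    p_value = vapply(.data$ps, function(p)
                      as.numeric(minp(p, bonferroni)), numeric(1)))
  }
  dplyr::bind_rows(out) |>
    dplyr::select("set_id", "method", "n_platforms", "p_value")
}
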