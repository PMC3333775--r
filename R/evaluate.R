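# Benchmark evaluation: truth labeling, top-k discovery counts, ROC/AUC,
# and exclusive-discovery fractions.

#' Label sets true or false for a spike-in repetition
#'
#' A set is a true positive if at least `overlap_threshold` of its genes
#' lie in the union of the spiked sets' genes. For disjoint collections
#' this reduces to "the spiked sets are true"; for overlapping
#' collections it also credits sets dragged along by shared genes.
#'
#' @param collection A [gene_set_collection()].
#' @param spiked_sets Character vector of spiked set ids (or a
#'   `spike_truth` object).
#' @param overlap_threshold Inclusive overlap fraction (default 0.5).
#' @return Named logical vector over the collection's sets.
#' @export
truth_labels <- function(collection, spiked_sets, overlap_threshold = 0.5) {
  if (inherits(spiked_sets, "spike_truth")) {
    spiked_sets <- spiked_sets$spiked_sets
  }
  union_genes <- unique(unlist(collection$sets[spiked_sets]))
  vapply(collection$sets, function(g) {
    mean(g %in% union_genes) >= overlap_threshold
  }, logical(1))
}

#' True positives among the top-k sets
#'
#' Ranks sets by ascending P-value (ties broken by set id, so the count
#' is deterministic) and counts true sets among the k best.
#'
#' @param results Tibble with `set_id` and `p_value` for one method and
#'   one repetition.
#' @param truth Named logical vector from [truth_labels()].
#' @param k List size (clamped with a warning if fewer sets exist).
#' @return Integer count <= k.
#' @export
topk_true_positives <- function(results, truth, k = 10L) {
  top <- topk_sets(results, k)
  sum(truth[top], na.rm = TRUE)
}

topk_sets <- function(results, k = 10L) {
  if (k > nrow(results)) {
    warn(sprintf("k = %d exceeds the %d available sets; clamped.",
                 k, nrow(results)))
    k <- nrow(results)
  }
  ord <- order(results$p_value, results$set_id)
  results$set_id[ord][seq_len(k)]
}

#' ROC curve and AUC for one set-result table
#'
#' Sweeps the P-value threshold over the table, treating smaller
#' P-values as stronger calls. Tied P-values are grouped, so the curve
#' runs diagonally through ties and the trapezoid AUC equals the
#' tie-corrected rank (Mann-Whitney) AUC exactly.
#'
#' @inheritParams topk_true_positives
#' @return A list with `curve` (tibble `specificity`, `sensitivity`) and
#'   `auc`.
#' @export
roc_auc <- function(results, truth) {
  lab <- truth[results$set_id]
  if (anyNA(lab)) stop_input("truth labels missing for some sets.")
  n_true <- sum(lab)
  n_false <- sum(!lab)
  if (n_true == 0L || n_false == 0L) {
    stop_input("need at least one true and one false set.")
  }
  p <- results$p_value
  ord <- order(p)
  p <- p[ord]
  lab <- lab[ord]
  grp <- cumsum(!duplicated(p))
  tp <- cumsum(lab)
  fp <- cumsum(!lab)
  last <- !duplicated(grp, fromLast = TRUE)
  sens <- c(0, tp[last] / n_true)
  fpr <- c(0, fp[last] / n_false)
  auc <- sum(diff(fpr) * (head(sens, -1) + sens[-1]) / 2)
  list(curve = tibble(specificity = 1 - fpr, sensitivity = sens),
       auc = auc)
}

# Mann-Whitney form of the AUC (rank identity; used as a cross-check).
rank_auc <- function(results, truth) {
  lab <- truth[results$set_id]
  r <- rank(-results$p_value)  # smaller p = stronger call = higher rank
  n1 <- sum(lab)
  n0 <- sum(!lab)
  (sum(r[lab]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Exclusive-discovery fraction of a single data type
#'
#' The fraction of a data type's true discoveries that no other single
#' data type also discovers: `EF(i) = 1 - |U_{j != i} TP(j) n TP(i)| /
#' |TP(i)|`.
#'
#' @param tp_sets Named list of character vectors: the true-positive set
#'   ids discovered per single data type.
#' @param target Name of the data type to evaluate.
#' @return Value in \[0, 1\], or `NA` if the target discovered nothing
#'   (undefined; excluded from averages).
#' @export
exclusive_fraction <- function(tp_sets, target) {
  tpi <- tp_sets[[target]]
  if (!length(tpi)) return(NA_real_)
  others <- unique(unlist(tp_sets[setdiff(names(tp_sets), target)]))
  1 - length(intersect(others, tpi)) / length(tpi)
}

#' Exclusive-discovery fraction of an integration method
#'
#' As [exclusive_fraction()], but the union runs over all single data
#' types: `EF*(l) = 1 - |U_{j in S} TP(j) n TP(l)| / |TP(l)|`.
#'
#' @param tp_single Named list of per-single-data-type true-positive ids.
#' @param tp_method True-positive ids of the integration method.
#' @return Value in \[0, 1\], or `NA` when the method discovered nothing.
#' @export
exclusive_fraction_integration <- function(tp_single, tp_method) {
  if (!length(tp_method)) return(NA_real_)
  others <- unique(unlist(tp_single))
  1 - length(intersect(others, tp_method)) / length(tp_method)
}

average_roc <- function(curves, grid = seq(0, 1, length.out = 101L)) {
  # vertical averaging on a fixed specificity grid
  sens <- vapply(curves, function(cv) {
    stats::approx(x = cv$specificity, y = cv$sensitivity, xout = grid,
                  ties = max, yleft = 1, yright = 0)$y
  }, numeric(length(grid)))
  tibble(specificity = grid,
         mean_sensitivity = rowMeans(sens),
         sd_sensitivity = apply(sens, 1L, sd))
}

#' Evaluate a simulation scenario
#'
#' Computes, per repetition and method, the AUC of spiked versus
#' non-spiked sets and the number of true positives among the top-k,
#' then summarizes across repetitions. Exclusive-discovery fractions use
#' the top-k lists: EF per single data type, EF* for each integration
#' method against all single data types. Repetitions where a method's
#' true-positive list is empty are skipped for EF/EF* and counted.
#'
#' @param sim A [run_scenario()] result.
#' @param k Discovery list size (default 10).
#' @param overlap_threshold Passed to [truth_labels()].
#' @return An object of class `evaluation_report` with `summary`
#'   (per-method mean/sd AUC and top-k true positives), `ef`
#'   (exclusive-discovery fractions with skip counts), `roc`
#'   (vertically averaged curves on a 101-point specificity grid) and
#'   `per_rep` (the underlying per-repetition measures).
#' @export
evaluate_scenario <- function(sim, k = 10L, overlap_threshold = 0.5) {
  reps <- unique(sim$results$rep)
  methods <- unique(sim$results$method)
  platform_methods <- intersect(methods, sim$backbone$platforms)
  integration_methods <- intersect(methods, c("INT", "AvgP", "MinP"))

  per_rep <- list()
  curves <- stats::setNames(vector("list", length(methods)), methods)
  ef_rows <- list()
  for (r in reps) {
    truth <- truth_labels(sim$collection,
                          sim$spiked$set_id[sim$spiked$rep == r],
                          overlap_threshold)
    res_r <- sim$results[sim$results$rep == r, ]
    tops <- list()
    for (m in methods) {
      res_m <- res_r[res_r$method == m, ]
      roc <- roc_auc(res_m, truth)
      top <- topk_sets(res_m, k)
      tops[[m]] <- top[truth[top]]
      curves[[m]] <- c(curves[[m]], list(roc$curve))
      per_rep[[length(per_rep) + 1L]] <-
        tibble(rep = r, method = m, auc = roc$auc,
               topk_tp = length(tops[[m]]))
    }
    tp_single <- tops[platform_methods]
    for (m in platform_methods) {
      ef_rows[[length(ef_rows) + 1L]] <-
        tibble(rep = r, method = m, kind = "EF",
               value = exclusive_fraction(tp_single, m))
    }
    for (m in integration_methods) {
      ef_rows[[length(ef_rows) + 1L]] <-
        tibble(rep = r, method = m, kind = "EF*",
               value = exclusive_fraction_integration(tp_single, tops[[m]]))
    }
  }
  per_rep <- dplyr::bind_rows(per_rep)
  ef_rep <- dplyr::bind_rows(ef_rows)

  summary <- per_rep |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(mean_auc = mean(.data$auc), sd_auc = sd(.data$auc),
                     mean_topk_tp = mean(.data$topk_tp),
                     sd_topk_tp = sd(.data$topk_tp), .groups = "drop")
  ef <- ef_rep |>
    dplyr::group_by(.data$method, .data$kind) |>
    dplyr::summarise(mean_ef = mean(.data$value, na.rm = TRUE),
                     sd_ef = sd(.data$value, na.rm = TRUE),
                     n_undefined = sum(is.na(.data$value)),
                     .groups = "drop")
  roc <- dplyr::bind_rows(lapply(methods, function(m) {
    dplyr::mutate(average_roc(curves[[m]]), method = m, .before = 1L)
  }))

  structure(list(summary = summary, ef = ef, roc = roc, per_rep = per_rep,
                 ef_per_rep = ef_rep, k = k,
                 overlap_threshold = overlap_threshold),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  print(x$summary)
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Emits a JSON summary plus TSV tables (summary, EF, averaged ROC
#' curves) under `dir`.
#'
#' @param report An [evaluate_scenario()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_evaluation_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(summary = report$summary, ef = report$ef, k = report$k,
         overlap_threshold = report$overlap_threshold),
    file.path(dir, "report.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA)
  write_result_table(report$summary, file.path(dir, "summary.tsv"))
  write_result_table(report$ef, file.path(dir, "exclusive_fractions.tsv"))
  write_result_table(report$roc, file.path(dir, "roc_curves.tsv"))
  invisible(dir)
}
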