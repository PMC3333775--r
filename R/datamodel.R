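# Core data containers: per-platform genomic matrices, phenotypes, and the
# aligned multi-platform study object all downstream analyses consume.

#' Create a genomic data matrix for one data type
#'
#' A `genomic_matrix` holds gene-level summaries of a single genomic data
#' type (an expression platform, a copy-number platform, ...) as a numeric
#' genes-by-samples matrix with a short platform label such as `"E1"` or
#' `"C1"`.
#'
#' @param values Numeric matrix, genes in rows and samples in columns, with
#'   row names (gene identifiers) and column names (sample identifiers).
#'   Values must be finite or `NA` (a gene with any `NA` is treated as
#'   unmeasured on this platform).
#' @param platform_id Short character label for the data type.
#' @return An object of class `genomic_matrix`.
#' @examples
#' m <- matrix(rnorm(6), 2, 3,
#'             dimnames = list(c("TP53", "EGFR"), c("s1", "s2", "s3")))
#' gm <- genomic_matrix(m, "E1")
#' @export
genomic_matrix <- function(values, platform_id) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_input("`values` must be a numeric matrix (genes x samples).")
  }
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop_input("`values` must carry gene row names and sample column names.")
  }
  if (anyDuplicated(gene_ids)) stop_input("duplicate gene identifiers.")
  if (anyDuplicated(sample_ids)) stop_input("duplicate sample identifiers.")
  if (any(is.infinite(values))) {
    stop_input("`values` must be finite or NA.")
  }
  structure(
    list(platform_id = as.character(platform_id)[1],
         gene_ids = gene_ids,
         sample_ids = sample_ids,
         values = values),
    class = "genomic_matrix")
}

#' @export
print.genomic_matrix <- function(x, ...) {
  cat(sprintf("<genomic_matrix> platform %s: %d genes x %d samples\n",
              x$platform_id, length(x$gene_ids), length(x$sample_ids)))
  invisible(x)
}

#' Phenotype vectors
#'
#' `phenotype_binary()` stores a two-class phenotype coded 0/1;
#' `phenotype_survival()` stores right-censored survival data (time in
#' days, event indicator 0/1).
#'
#' @param sample_ids Character vector of sample identifiers.
#' @param labels Integer/numeric 0/1 class labels (binary case). Both
#'   classes must be present.
#' @return An object of class `phenotype`.
#' @export
phenotype_binary <- function(sample_ids, labels) {
  sample_ids <- as.character(sample_ids)
  labels <- as.integer(labels)
  if (anyDuplicated(sample_ids)) stop_input("duplicate sample identifiers.")
  if (length(labels) != length(sample_ids)) {
    stop_input("`labels` and `sample_ids` lengths differ.")
  }
  if (anyNA(labels) || !all(labels %in% c(0L, 1L))) {
    stop_input("binary labels must be 0/1 with no missing values.")
  }
  if (length(unique(labels)) < 2L) {
    stop_degenerate("binary phenotype must contain both classes.")
  }
  structure(list(sample_ids = sample_ids, kind = "binary", labels = labels),
            class = "phenotype")
}

#' @rdname phenotype_binary
#' @param time Positive survival/follow-up times (days).
#' @param event Event indicator, 1 = event observed, 0 = censored.
#' @export
phenotype_survival <- function(sample_ids, time, event) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop_input("duplicate sample identifiers.")
  time <- as.numeric(time)
  event <- as.integer(event)
  if (length(time) != length(sample_ids) || length(event) != length(sample_ids)) {
    stop_input("`time`, `event` and `sample_ids` lengths differ.")
  }
  if (anyNA(time) || any(time <= 0)) {
    stop_input("survival times must be strictly positive.")
  }
  if (anyNA(event) || !all(event %in% c(0L, 1L))) {
    stop_input("`event` must be 0/1.")
  }
  structure(list(sample_ids = sample_ids, kind = "survival",
                 time = time, event = event),
            class = "phenotype")
}

#' @export
print.phenotype <- function(x, ...) {
  if (x$kind == "binary") {
    cat(sprintf("<phenotype> binary: %d samples (%d/%d per class)\n",
                length(x$sample_ids), sum(x$labels == 0), sum(x$labels == 1)))
  } else {
    cat(sprintf("<phenotype> survival: %d samples, %d events\n",
                length(x$sample_ids), sum(x$event)))
  }
  invisible(x)
}

subset_phenotype <- function(ph, samples) {
  idx <- match(samples, ph$sample_ids)
  if (ph$kind == "binary") {
    phenotype_binary(samples, ph$labels[idx])
  } else {
    phenotype_survival(samples, ph$time[idx], ph$event[idx])
  }
}

#' Align matrices and phenotype into a multi-platform study
#'
#' Restricts every platform matrix and the phenotype to their common
#' samples (in the phenotype's order) and records, for every gene measured
#' anywhere, which platforms measure it. A gene with any missing value on
#' a platform counts as unmeasured there.
#'
#' @param matrices List of [genomic_matrix()] objects, one per data type.
#' @param phenotype A [phenotype_binary()] or [phenotype_survival()] object.
#' @return An object of class `multi_omic_study` with elements `matrices`
#'   (sample-aligned), `phenotype`, `platform_ids` and `availability`
#'   (genes x platforms logical matrix over the union gene universe,
#'   lexicographically ordered).
#' @examples
#' m <- matrix(rnorm(40), 4, 10,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
#' ph <- phenotype_binary(paste0("s", 1:10), rep(0:1, each = 5))
#' study <- build_study(list(genomic_matrix(m, "E1")), ph)
#' @export
build_study <- function(matrices, phenotype) {
  if (!length(matrices)) stop_input("at least one matrix is required.")
  if (!all(vapply(matrices, inherits, logical(1), "genomic_matrix"))) {
    stop_input("`matrices` must be a list of genomic_matrix objects.")
  }
  pids <- unname(vapply(matrices, function(m) m$platform_id, character(1)))
  if (anyDuplicated(pids)) stop_input("duplicate platform identifiers.")
  names(matrices) <- pids

  common <- phenotype$sample_ids
  for (m in matrices) common <- intersect(common, m$sample_ids)
  if (length(common) < 2L) {
    stop_alignment("fewer than 2 samples shared by all matrices and the phenotype.")
  }
  # keep the phenotype's ordering on the common samples
  common <- phenotype$sample_ids[phenotype$sample_ids %in% common]

  ph <- tryCatch(subset_phenotype(phenotype, common),
                 gsetint_error_degenerate_phenotype = function(e) {
                   stop_degenerate(
                     "only one phenotype class remains after sample alignment.")
                 })

  aligned <- lapply(matrices, function(m) {
    genomic_matrix(m$values[, common, drop = FALSE], m$platform_id)
  })

  universe <- sort(unique(unlist(lapply(aligned, function(m) m$gene_ids))))
  availability <- vapply(aligned, function(m) {
    ok <- logical(length(universe))
    idx <- match(universe, m$gene_ids)
    measured <- !is.na(idx)
    # any NA value makes the gene unmeasured on this platform
    complete <- rowSums(is.na(m$values)) == 0L
    ok[measured] <- complete[idx[measured]]
    ok
  }, logical(length(universe)))
  availability <- matrix(availability, nrow = length(universe),
                         dimnames = list(universe, pids))

  structure(
    list(matrices = aligned, phenotype = ph, platform_ids = pids,
         availability = availability),
    class = "multi_omic_study")
}

#' @export
print.multi_omic_study <- function(x, ...) {
  cat(sprintf("<multi_omic_study> %d platforms (%s), %d samples\n",
              length(x$platform_ids), paste(x$platform_ids, collapse = ", "),
              length(x$phenotype$sample_ids)))
  cat(sprintf("  gene universe: %d (union), %d (intersection)\n",
              nrow(x$availability), sum(rowSums(x$availability) ==
                                          ncol(x$availability))))
  invisible(x)
}

#' Gene universe of a study
#'
#' The `intersection` universe contains genes measured on every platform;
#' the `union` universe genes measured on at least one. Competitive gene
#' set tests require the intersection (genes measured on fewer platforms
#' get deflated scores, biasing between-gene comparisons); self-contained
#' tests may use the union.
#'
#' @param study A [build_study()] result.
#' @param mode `"intersection"` or `"union"`.
#' @return Character vector of gene identifiers, lexicographically ordered.
#' @export
gene_universe <- function(study, mode = c("intersection", "union")) {
  mode <- match.arg(mode)
  av <- study$availability
  keep <- if (mode == "intersection") {
    rowSums(av) == ncol(av)
  } else {
    rowSums(av) >= 1L
  }
  rownames(av)[keep]
}

#' Dichotomize survival into extreme phenotype groups
#'
#' Implements the extreme discordant phenotype design: samples with
#' survival time strictly below the lower quantile are labeled 1
#' (short-term survivors), those strictly above the upper quantile 0
#' (long-term survivors), and samples in between -- including ties at
#' either threshold -- are excluded. Quantiles use the default empirical
#' definition with linear interpolation (`stats::quantile` type 7).
#'
#' @param phenotype A [phenotype_survival()] object, or a numeric vector
#'   of survival times.
#' @param lower_q,upper_q Quantile fractions in (0, 1), lower <= upper.
#'   Defaults give quartile-based groups; use `1/3` and `2/3` for tertiles.
#' @param sample_ids Sample identifiers when `phenotype` is a bare numeric
#'   vector.
#' @return A list with `phenotype` (a binary [phenotype_binary()] over the
#'   retained samples) and `excluded` (character vector of dropped sample
#'   identifiers).
#' @export
dichotomize_survival <- function(phenotype, lower_q = 0.25, upper_q = 0.75,
                                 sample_ids = NULL) {
  if (inherits(phenotype, "phenotype")) {
    if (phenotype$kind != "survival") {
      stop_input("`phenotype` must be a survival phenotype.")
    }
    times <- phenotype$time
    ids <- phenotype$sample_ids
  } else {
    times <- as.numeric(phenotype)
    ids <- if (is.null(sample_ids)) {
      if (!is.null(names(phenotype))) names(phenotype) else
        sprintf("sample%03d", seq_along(times))
    } else {
      as.character(sample_ids)
    }
  }
  if (!(lower_q > 0 && lower_q <= upper_q && upper_q < 1)) {
    stop_input("need 0 < lower_q <= upper_q < 1.")
  }
  if (length(times) < 4L) stop_input("need at least 4 samples.")

  lo <- quantile(times, lower_q, names = FALSE, type = 7)
  hi <- quantile(times, upper_q, names = FALSE, type = 7)
  short <- times < lo
  long <- times > hi
  keep <- short | long
  if (!any(short) || !any(long)) {
    stop_degenerate(
      "dichotomization leaves no samples in one or both extreme groups.")
  }
  list(
    phenotype = phenotype_binary(ids[keep], as.integer(short[keep])),
    excluded = ids[!keep])
}
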