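# Tabular readers and writers: genomic matrices, phenotype tables and
# result tables travel as TSV/CSV with a gene/sample identifier column.

delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read / write a genomic matrix
#'
#' Matrices are stored as delimited text with gene identifiers in the
#' first column and one column per sample; the delimiter follows the file
#' extension (`.csv` comma, anything else tab).
#'
#' @param path File path.
#' @param platform_id Platform label to attach on read.
#' @return `read_genomic_matrix()` returns a [genomic_matrix()].
#' @export
read_genomic_matrix <- function(path, platform_id) {
  df <- readr::read_delim(path, delim = delim_for(path),
                          show_col_types = FALSE, progress = FALSE,
                          comment = "#")
  if (ncol(df) < 2L) stop_input("matrix file needs a gene column and samples.")
  genes <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  dimnames(m) <- list(genes, colnames(df)[-1])
  genomic_matrix(m, platform_id)
}

#' @rdname read_genomic_matrix
#' @param x A [genomic_matrix()] to write.
#' @export
write_genomic_matrix <- function(x, path) {
  df <- tibble::as_tibble(x$values, rownames = "gene")
  readr::write_delim(df, path, delim = delim_for(path))
  invisible(path)
}

#' Read a phenotype table
#'
#' Two-column tables (`sample`, `label`) are read as binary phenotypes;
#' three-column tables (`sample`, `time`, `event`) as survival phenotypes.
#'
#' @param path File path (TSV or CSV by extension).
#' @return A [phenotype_binary()] or [phenotype_survival()] object.
#' @export
read_phenotype <- function(path) {
  df <- readr::read_delim(path, delim = delim_for(path),
                          show_col_types = FALSE, progress = FALSE,
                          comment = "#")
  if (ncol(df) == 2L) {
    phenotype_binary(df[[1]], df[[2]])
  } else if (ncol(df) == 3L) {
    phenotype_survival(df[[1]], df[[2]], df[[3]])
  } else {
    stop_input("phenotype table must have 2 (binary) or 3 (survival) columns.")
  }
}

#' @rdname read_phenotype
#' @param phenotype Phenotype object to write.
#' @export
write_phenotype <- function(phenotype, path) {
  df <- if (phenotype$kind == "binary") {
    tibble(sample = phenotype$sample_ids, label = phenotype$labels)
  } else {
    tibble(sample = phenotype$sample_ids, time = phenotype$time,
           event = phenotype$event)
  }
  readr::write_delim(df, path, delim = delim_for(path))
  invisible(path)
}

version_header <- function() {
  sprintf("# gsetint %s", as.character(utils::packageVersion("gsetint")))
}

#' Write / read tabular results
#'
#' Gene score tables and set result tables round-trip as TSV with a
#' leading comment line carrying the package version.
#'
#' @param x A tibble (gene score table or set result table).
#' @param path Output path.
#' @export
write_result_table <- function(x, path) {
  writeLines(version_header(), path)
  readr::write_tsv(as_tibble(x), path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_result_table
#' @export
read_result_table <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}
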