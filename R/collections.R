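# Gene set collections (GMT-backed membership structure).

#' Create a gene set collection
#'
#' @param sets Named list of character vectors (genes per set). Sets must
#'   be non-empty; duplicate genes within a set are removed with a warning.
#' @param universe Optional explicit gene universe; genes appearing in any
#'   set are always included.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe = NULL) {
  if (!length(sets)) stop_input("collection must contain at least one set.")
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop_input("every set needs a name.")
  }
  if (anyDuplicated(names(sets))) stop_input("duplicate set identifiers.")
  sets <- lapply(sets, as.character)
  if (any(lengths(sets) == 0L)) stop_input("sets must be non-empty.")
  ndup <- sum(vapply(sets, anyDuplicated, integer(1)) > 0L)
  if (ndup > 0L) {
    warn(sprintf("%d set(s) contained duplicate genes; deduplicated.", ndup))
    sets <- lapply(sets, unique)
  }
  universe <- sort(unique(c(unlist(sets, use.names = FALSE),
                            as.character(universe))))
  structure(list(sets = sets, set_ids = names(sets), universe = universe),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets over %d genes (sizes %d-%d)\n",
              length(x$sets), length(x$universe),
              min(lengths(x$sets)), max(lengths(x$sets))))
  invisible(x)
}

#' Set membership indicators
#'
#' Returns the membership indicator m_gs for the requested set over a gene
#' vector: 1 if the gene belongs to the set, 0 otherwise.
#'
#' @param collection A [gene_set_collection()].
#' @param set_id Set identifier.
#' @param genes Genes to query (default: the collection universe).
#' @return Named integer vector of 0/1 indicators.
#' @export
set_membership <- function(collection, set_id, genes = NULL) {
  if (!set_id %in% collection$set_ids) {
    stop_input(sprintf("unknown set '%s'.", set_id))
  }
  if (is.null(genes)) genes <- collection$universe
  setNames(as.integer(genes %in% collection$sets[[set_id]]), genes)
}

#' Read / write GMT gene set files
#'
#' GMT is the tab-separated gene set exchange format (set name,
#' description, then one gene per field). Duplicate genes within a set are
#' removed with a warning; malformed lines (fewer than three fields) raise
#' an error naming the line.
#'
#' @param path File path.
#' @return `read_gmt()` returns a [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop_input("empty GMT file.")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) {
    stop_input(sprintf("malformed GMT line %d: fewer than 3 fields.", bad[1]))
  }
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[[`, character(1), 1L)
  descr <- vapply(fields, `[[`, character(1), 2L)
  coll <- gene_set_collection(sets)
  coll$descriptions <- setNames(descr, names(sets))
  coll
}

#' @rdname read_gmt
#' @param collection A [gene_set_collection()] to write.
#' @export
write_gmt <- function(collection, path) {
  descr <- collection$descriptions
  if (is.null(descr)) descr <- setNames(rep("na", length(collection$sets)),
                                        collection$set_ids)
  lines <- vapply(collection$set_ids, function(id) {
    paste(c(id, descr[[id]], collection$sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
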