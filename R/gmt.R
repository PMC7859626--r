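# Gene-set collections and the GMT carrier format (one set per line:
# name <tab> description <tab> member genes...).

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (pathway -> member genes).
#'   Membership is many-to-many: a gene may belong to several pathways.
#' @param descriptions optional character vector of per-set descriptions.
#' @param source label for provenance (free text).
#' @return object of class `gene_sets`.
#' @export
gene_sets <- function(sets, descriptions = NULL, source = "user") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (anyDuplicated(names(sets))) stop("pathway names must be unique")
  if (any(lengths(sets) == 0)) stop("member lists must be non-empty")
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  structure(sets, descriptions = stats::setNames(descriptions, names(sets)),
            source = source, class = "gene_sets")
}

#' @export
print.gene_sets <- function(x, ...) {
  cat(sprintf("gene_sets: %d sets, %d distinct genes (source: %s)\n",
              length(x), length(unique(unlist(x))), attr(x, "source")))
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' Duplicate member genes within a line are deduplicated. A line with fewer
#' than three tab-separated fields is malformed and raises an error naming
#' the line number. An empty file yields an empty collection with a warning.
#'
#' @param path GMT file.
#' @param source provenance label (defaults to the file name).
#' @return a [gene_sets()] collection.
#' @export
read_gmt <- function(path, source = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    warning("empty GMT file: ", path)
    return(structure(list(), descriptions = character(0), source = source,
                     class = "gene_sets"))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad) > 0) {
    stop(sprintf("malformed GMT line %d in %s: expected name, description, members",
                 bad[1], path))
  }
  nm <- vapply(parts, `[[`, "", 1L)
  desc <- vapply(parts, `[[`, "", 2L)
  members <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(members) <- nm
  gene_sets(members, descriptions = desc, source = source)
}

#' Write gene sets to a GMT file
#'
#' @param sets a [gene_sets()] collection.
#' @param path output file.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(inherits(sets, "gene_sets"))
  desc <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(nm) {
    d <- desc[[nm]]
    if (is.null(d) || is.na(d) || !nzchar(d)) d <- "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Count distinct genes across (selected) gene sets
#'
#' Genes appearing in several of the selected sets are counted once.
#'
#' @param sets a [gene_sets()] collection.
#' @param pathways names of the sets to include (default: all).
#' @return integer count of distinct member genes.
#' @export
n_distinct_genes <- function(sets, pathways = NULL) {
  stopifnot(inherits(sets, "gene_sets"))
  if (is.null(pathways)) pathways <- names(sets)
  length(unique(unlist(sets[pathways], use.names = FALSE)))
}
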