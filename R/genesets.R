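#' Gene-set collections
#'
#' A collection is stored as a lightweight S3 object: a named list of
#' character vectors (`sets`), a parallel named character vector of
#' descriptions, and a source label. Gene identifiers are opaque,
#' case-sensitive strings; no alias resolution is attempted.
#'
#' @param sets named list of character vectors (unique member ids per set).
#' @param descriptions optional named character vector, one per set.
#' @param source label recording where the collection came from.
#' @return object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL, source = "unknown") {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("every gene set needs a non-empty name")
  }
  if (anyDuplicated(names(sets))) {
    stop("duplicate gene-set names: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  }
  sets <- lapply(sets, function(m) unique(as.character(m)))
  if (any(lengths(sets) == 0)) stop("gene sets must have at least one member")
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  }
  structure(list(sets = sets,
                 descriptions = descriptions[names(sets)],
                 source = source),
            class = "gene_set_collection")
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' @export
print.gene_set_collection <- function(x, ...) {
  sz <- lengths(x$sets)
  cat(sprintf("gene_set_collection: %d sets (sizes %s..%s), source: %s\n",
              length(sz), if (length(sz)) min(sz) else "-",
              if (length(sz)) max(sz) else "-", x$source))
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' Standard GMT dialect: one set per line,
#' `name<TAB>description<TAB>member<TAB>member...`. Duplicate member tokens
#' within a line are deduplicated with a warning; duplicate set names are an
#' error. Malformed lines (< 3 fields) are reported with their line number.
#'
#' @param path path to a GMT file.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad)) {
    stop(sprintf("malformed GMT line %d: fewer than 3 tab-separated fields",
                 bad[1]))
  }
  nm <- vapply(fields, `[[`, "", 1L)
  desc <- vapply(fields, `[[`, "", 2L)
  members <- lapply(fields, function(f) f[-(1:2)])
  dup_in_line <- vapply(members, anyDuplicated, 0L) > 0L
  if (any(dup_in_line)) {
    warning(sprintf("%d GMT line(s) contained duplicate member tokens; deduplicated",
                    sum(dup_in_line)))
  }
  gene_set_collection(stats::setNames(members, nm),
                      stats::setNames(desc, nm),
                      source = path)
}

#' Write a collection to GMT
#'
#' @param collection a [gene_set_collection()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$descriptions[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Filter a collection by set size
#'
#' Retains sets whose raw membership count lies strictly between the bounds
#' (default: more than 10 and fewer than 500 member genes), the size window
#' conventionally used to keep gene-set enrichment away from very small and
#' very large sets. Sizes are counted on raw GMT membership, before any
#' intersection with an expression universe. Order is preserved; the counts
#' before/after are attached as the `"filter_report"` attribute.
#'
#' @param collection a [gene_set_collection()].
#' @param min_exclusive,max_exclusive strict size bounds.
#' @return filtered [gene_set_collection()].
#' @export
filter_by_size <- function(collection, min_exclusive = 10,
                           max_exclusive = 500) {
  stopifnot(inherits(collection, "gene_set_collection"))
  sz <- lengths(collection$sets)
  keep <- sz > min_exclusive & sz < max_exclusive
  out <- gene_set_collection(collection$sets[keep],
                             collection$descriptions[keep],
                             source = collection$source)
  attr(out, "filter_report") <- c(before = length(sz), after = sum(keep))
  out
}
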