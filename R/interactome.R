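#' Load a ligand/receptor pair table
#'
#' TSV with columns `ligand`, `receptor`, `source`. Duplicate
#' ligand-receptor pairs are collapsed (first source kept); self-pairings
#' are kept with a warning.
#'
#' @param path TSV file path.
#' @return data.frame of directed pairs.
#' @export
load_pairs <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("ligand", "receptor", "source")
  if (!all(need %in% names(d))) {
    stop("pair table needs columns: ", paste(need, collapse = ", "))
  }
  key <- paste(d$ligand, d$receptor, sep = "->")
  d <- d[!duplicated(key), need, drop = FALSE]
  if (any(d$ligand == d$receptor)) {
    warning("self-pairing ligand == receptor present; kept")
  }
  rownames(d) <- NULL
  d
}

#' Bundled curated interleukin/interferon pair table
#'
#' Path to the ligand/receptor snapshot shipped with the package, compiled
#' by hand from well-established HGNC family assignments (interleukins,
#' interleukin receptors, interferons and their receptors) and standard
#' reviews of cytokine-receptor pairing. It is a static curated snapshot,
#' not a live database export.
#'
#' @return file path usable with [load_pairs()].
#' @export
interleukin_pairs_path <- function() {
  system.file("extdata", "interleukin_pairs.tsv", package = "enrichscape",
              mustWork = TRUE)
}

#' Overlay gene-level significance classes on an interactome
#'
#' Annotates every gene of the pair table, per comparison, with its
#' shrunken fold change, adjusted p-value and volcano class (see
#' [classify_volcano()] -- the single source of truth for the class). Each
#' pair is then flagged per comparison: `receptor-only activation` when the
#' receptor is `up` and the ligand is not (the paracrine pattern),
#' `autocrine-candidate` when both are `up`, `ligand-only activation`,
#' `no-data` when both genes are absent from the comparison, else `other`.
#'
#' @param pairs data.frame from [load_pairs()] or [simulate_interactome()].
#' @param stats_list named list of [classify_volcano()]-annotated
#'   [gene_stats()] tables, one per comparison.
#' @return object of class `interactome_graph`: `pairs`, `genes`
#'   (per-gene per-comparison annotations), `pair_flags`.
#' @export
overlay_interactome <- function(pairs, stats_list) {
  if (is.null(names(stats_list)) || any(!nzchar(names(stats_list)))) {
    stop("stats_list must be a named list (one entry per comparison)")
  }
  genes <- sort(unique(c(pairs$ligand, pairs$receptor)))
  gene_rows <- list()
  flag_rows <- list()
  for (cmp in names(stats_list)) {
    st <- stats_list[[cmp]]
    if (!"class" %in% names(st)) {
      stop("stats for ", cmp, " lack a class column; run classify_volcano()")
    }
    idx <- match(genes, st$gene)
    cls <- ifelse(is.na(idx), "no-data", st$class[idx])
    gene_rows[[cmp]] <- data.frame(
      gene = genes, comparison = cmp,
      slfc = st$slfc[idx], padj = st$padj[idx], class = cls,
      stringsAsFactors = FALSE)
    lig_cls <- cls[match(pairs$ligand, genes)]
    rec_cls <- cls[match(pairs$receptor, genes)]
    flag <- rep("other", nrow(pairs))
    flag[rec_cls == "up" & lig_cls != "up"] <- "receptor-only activation"
    flag[lig_cls == "up" & rec_cls != "up"] <- "ligand-only activation"
    flag[rec_cls == "up" & lig_cls == "up"] <- "autocrine-candidate"
    flag[rec_cls == "no-data" & lig_cls == "no-data"] <- "no-data"
    flag_rows[[cmp]] <- data.frame(
      ligand = pairs$ligand, receptor = pairs$receptor, comparison = cmp,
      flag = flag, stringsAsFactors = FALSE)
  }
  structure(list(pairs = pairs,
                 genes = do.call(rbind, c(unname(gene_rows),
                                          list(make.row.names = FALSE))),
                 pair_flags = do.call(rbind, c(unname(flag_rows),
                                               list(make.row.names = FALSE)))),
            class = "interactome_graph")
}

#' @export
print.interactome_graph <- function(x, ...) {
  cat(sprintf("interactome_graph: %d pairs, %d genes, comparisons: %s\n",
              nrow(x$pairs), length(unique(x$genes$gene)),
              paste(unique(x$genes$comparison), collapse = ", ")))
  invisible(x)
}

#' Export an overlaid interactome
#'
#' Writes `<prefix>.graphml` (one node per gene, one directed edge per
#' pair, per-comparison node attributes slfc/padj/class and edge flag
#' attributes) plus `<prefix>_genes.tsv` and `<prefix>_pairs.tsv`.
#'
#' @param graph an [overlay_interactome()] result.
#' @param prefix output path prefix.
#' @return named character vector of written paths, invisibly.
#' @export
export_interactome <- function(graph, prefix) {
  stopifnot(inherits(graph, "interactome_graph"))
  genes <- sort(unique(c(graph$pairs$ligand, graph$pairs$receptor)))
  nd <- data.frame(name = genes, stringsAsFactors = FALSE)
  for (cmp in unique(graph$genes$comparison)) {
    sub <- graph$genes[graph$genes$comparison == cmp, , drop = FALSE]
    idx <- match(genes, sub$gene)
    nd[[paste0("slfc_", cmp)]] <- ifelse(is.na(sub$slfc[idx]), 0,
                                         sub$slfc[idx])
    nd[[paste0("padj_", cmp)]] <- ifelse(is.na(sub$padj[idx]), -1,
                                         sub$padj[idx])
    nd[[paste0("class_", cmp)]] <- sub$class[idx]
  }
  ed <- graph$pairs[, c("ligand", "receptor"), drop = FALSE]
  names(ed) <- c("from", "to")
  ed$source <- graph$pairs$source
  for (cmp in unique(graph$pair_flags$comparison)) {
    sub <- graph$pair_flags[graph$pair_flags$comparison == cmp, ,
                            drop = FALSE]
    key_all <- paste(ed$from, ed$to)
    key_sub <- paste(sub$ligand, sub$receptor)
    ed[[paste0("flag_", cmp)]] <- sub$flag[match(key_all, key_sub)]
  }
  g <- igraph::graph_from_data_frame(ed, directed = TRUE, vertices = nd)
  paths <- c(graphml = paste0(prefix, ".graphml"),
             genes = paste0(prefix, "_genes.tsv"),
             pairs = paste0(prefix, "_pairs.tsv"))
  igraph::write_graph(g, paths["graphml"], format = "graphml")
  utils::write.table(graph$genes, paths["genes"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(graph$pair_flags, paths["pairs"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
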