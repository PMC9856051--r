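#' Select gene-set nodes for the landscape network
#'
#' A set becomes a node when its adjusted p-value is below `padj_thr`
#' (default 0.001, strict) and at least a fraction `le_frac_thr` (default
#' 0.3334, i.e. 33.34%) of its members in the ranked universe lie in its
#' leading edge. Enriched and depleted sets are both retained; direction is
#' an annotation, not a filter.
#'
#' @param table an `enrichment_table` from [run_enrichment()].
#' @param padj_thr adjusted-p threshold (strict `<`).
#' @param le_frac_thr minimum leading-edge fraction (inclusive `>=`).
#' @return subset of `table` (same class and attributes).
#' @export
select_nodes <- function(table, padj_thr = 0.001, le_frac_thr = 0.3334) {
  keep <- !is.na(table$padj) & table$padj < padj_thr &
    table$le_fraction >= le_frac_thr
  out <- table[keep, , drop = FALSE]
  for (a in c("comparison", "nperm", "seed", "weight_p")) {
    attr(out, a) <- attr(table, a)
  }
  class(out) <- class(table)
  out
}

#' Build overlap edges between landscape nodes
#'
#' For each unordered node pair the leading-edge share
#' `|LE_A inter LE_B| / min(|M_A|, |M_B|)` (with M the member genes present
#' in the ranked universe) acts as the gate: an edge exists when it reaches
#' `le_gate` (default 5%). The edge weight is the member overlap
#' coefficient `|M_A inter M_B| / min(|M_A|, |M_B|)` (or the Jaccard
#' `/|M_A union M_B|` when `weight_denom = "union"`).
#'
#' @param nodes a [select_nodes()] result.
#' @param collection the [gene_set_collection()] the enrichment was run on.
#' @param universe character vector of ranked gene ids.
#' @param le_gate minimum leading-edge share (inclusive `>=`).
#' @param weight_denom `"min"` (overlap coefficient, default) or `"union"`.
#' @return data.frame with columns `from`, `to`, `weight`, `le_share`.
#' @export
build_edges <- function(nodes, collection, universe, le_gate = 0.05,
                        weight_denom = c("min", "union")) {
  weight_denom <- match.arg(weight_denom)
  sets <- nodes$set
  members <- lapply(collection$sets[sets], function(m) {
    intersect(unique(m), universe)
  })
  le <- nodes$leading_edge
  n <- length(sets)
  from <- to <- character(0)
  weight <- le_share <- numeric(0)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        mn <- min(length(members[[i]]), length(members[[j]]))
        ls <- length(intersect(le[[i]], le[[j]])) / mn
        if (ls >= le_gate) {
          ov <- length(intersect(members[[i]], members[[j]]))
          den <- if (weight_denom == "min") mn else {
            length(union(members[[i]], members[[j]]))
          }
          w <- ov / den
          if (w > 0) {
            from <- c(from, sets[i]); to <- c(to, sets[j])
            weight <- c(weight, w); le_share <- c(le_share, ls)
          }
        }
      }
    }
  }
  data.frame(from = from, to = to, weight = weight, le_share = le_share,
             stringsAsFactors = FALSE)
}

#' Build the landscape network from an anchor comparison
#'
#' Applies the node criteria ([select_nodes()]) and edge criteria
#' ([build_edges()]) to the anchor comparison's enrichment table. The
#' resulting scaffold is fixed: further comparisons are only projected onto
#' it ([project_comparison()]), never change it.
#'
#' @param anchor_table `enrichment_table` of the anchor comparison.
#' @param collection the [gene_set_collection()] used for enrichment.
#' @param universe ranked gene ids of the anchor comparison.
#' @param padj_thr,le_frac_thr node thresholds (see [select_nodes()]).
#' @param le_gate,weight_denom edge parameters (see [build_edges()]).
#' @return object of class `landscape_network`: `nodes` (data.frame),
#'   `edges` (data.frame), `annotations` (per-comparison list), `anchor`
#'   (comparison label), `params`.
#' @export
build_landscape <- function(anchor_table, collection, universe,
                            padj_thr = 0.001, le_frac_thr = 0.3334,
                            le_gate = 0.05, weight_denom = "min") {
  nodes <- select_nodes(anchor_table, padj_thr, le_frac_thr)
  edges <- build_edges(nodes, collection, universe, le_gate, weight_denom)
  net <- structure(
    list(nodes = nodes, edges = edges,
         annotations = list(), anchor = attr(anchor_table, "comparison"),
         params = list(padj_thr = padj_thr, le_frac_thr = le_frac_thr,
                       le_gate = le_gate, weight_denom = weight_denom)),
    class = "landscape_network")
  project_comparison(net, anchor_table)
}

#' @export
print.landscape_network <- function(x, ...) {
  cat(sprintf("landscape_network: %d nodes, %d edges (anchor %s; projections: %s)\n",
              nrow(x$nodes), nrow(x$edges), x$anchor,
              paste(names(x$annotations), collapse = ", ")))
  invisible(x)
}

#' Markov clustering (MCL) of a weighted undirected graph
#'
#' Simulates stochastic flow on the weighted adjacency matrix: self-loops
#' are added (weight = the node's maximum incident edge weight, or 1 for
#' isolates), columns are normalized to a stochastic matrix, then expansion
#' (matrix power) and inflation (entrywise power followed by column
#' renormalization) alternate, with entries below `prune` removed, until
#' the matrix change falls below 1e-8 or `max_iter` is reached. Clusters
#' are read off the attractor structure: rows retaining positive diagonal
#' mass are attractors, nodes join the attractors they flow to, and
#' overlapping assignments resolve to the lowest cluster index.
#'
#' @param edges data.frame with `from`, `to`, `weight` (e.g. from
#'   [build_edges()]).
#' @param nodes optional character vector of all node names (to include
#'   isolated nodes); defaults to the nodes appearing in `edges`.
#' @param inflation inflation exponent r (default 2.0, the canonical MCL
#'   default; 2.5 matches the common Cytoscape clustering default).
#' @param expansion matrix-power exponent (default 2).
#' @param prune entries below this are set to zero each iteration.
#' @param max_iter iteration cap.
#' @return object of class `cluster_assignment`: list with `assignment`
#'   (named integer vector, cluster ids numbered by first member),
#'   `n_clusters`, `iterations`, `converged`, `inflation`.
#' @export
mcl_cluster <- function(edges, nodes = NULL, inflation = 2.0, expansion = 2,
                        prune = 1e-5, max_iter = 200) {
  if (is.null(nodes)) nodes <- unique(c(edges$from, edges$to))
  nodes <- as.character(nodes)
  n <- length(nodes)
  if (n == 0) stop("node set is empty")
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(edges)) {
    i <- match(edges$from, nodes)
    j <- match(edges$to, nodes)
    for (k in seq_along(i)) {
      A[i[k], j[k]] <- A[i[k], j[k]] + edges$weight[k]
      A[j[k], i[k]] <- A[j[k], i[k]] + edges$weight[k]
    }
  }
  mx <- apply(A, 1, max)
  diag(A) <- ifelse(mx > 0, mx, 1)

  normalize <- function(M) {
    cs <- colSums(M)
    zero <- cs == 0
    if (any(zero)) {           # resurrect fully pruned columns as self-flow
      M[cbind(which(zero), which(zero))] <- 1
      cs[zero] <- 1
    }
    sweep(M, 2, cs, "/")
  }
  M <- normalize(A)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    E <- M
    for (e in seq_len(expansion - 1)) E <- E %*% M
    E <- E^inflation
    E[E < prune] <- 0
    E <- normalize(E)
    delta <- max(abs(E - M))
    M <- E
    if (delta < 1e-8) {
      converged <- TRUE
      break
    }
  }
  if (!converged) warning("MCL did not converge within max_iter")

  attractors <- which(diag(M) > 0)
  # attractor systems: connect attractors sharing flow in either direction
  g <- igraph::make_empty_graph(n = length(attractors), directed = FALSE)
  if (length(attractors) > 1) {
    sub <- M[attractors, attractors, drop = FALSE]
    link <- which((sub > 0 | t(sub) > 0) &
                  upper.tri(sub), arr.ind = TRUE)
    if (nrow(link)) g <- igraph::add_edges(g, t(link))
  }
  comp <- igraph::components(g)$membership
  assignment <- integer(n)
  for (v in seq_len(n)) {
    owners <- attractors[M[attractors, v] > 0]
    if (length(owners) == 0) {
      assignment[v] <- 0L        # no attractor mass: resolved below
    } else {
      assignment[v] <- min(comp[match(owners, attractors)])
    }
  }
  # orphan nodes (fully drained and pruned): own singleton clusters
  if (any(assignment == 0)) {
    nxt <- max(comp, 0) + seq_len(sum(assignment == 0))
    assignment[assignment == 0] <- nxt
  }
  # renumber clusters 1..K in order of first member node
  first <- tapply(seq_len(n), assignment, min)
  relabel <- stats::setNames(rank(first), names(first))
  assignment <- as.integer(relabel[as.character(assignment)])
  names(assignment) <- nodes
  structure(list(assignment = assignment,
                 n_clusters = length(unique(assignment)),
                 iterations = iter, converged = converged,
                 inflation = inflation),
            class = "cluster_assignment")
}

#' Project another comparison onto the fixed scaffold
#'
#' Annotates every node with the other comparison's adjusted p-value,
#' direction and significance tier (smallest passed threshold among
#' `tiers`, else `"ns"`). Sets absent from the other table are marked
#' `"not-tested"`. Topology is never altered.
#'
#' @param network a [build_landscape()] result.
#' @param other_table `enrichment_table` of the comparison to project.
#' @param tiers descending significance thresholds.
#' @return the network with an added entry in `annotations`.
#' @export
project_comparison <- function(network, other_table,
                               tiers = c(0.001, 0.01, 0.05)) {
  stopifnot(inherits(network, "landscape_network"))
  cmp <- attr(other_table, "comparison")
  if (is.null(cmp)) cmp <- "unnamed"
  idx <- match(network$nodes$set, other_table$set)
  padj <- other_table$padj[idx]
  direction <- other_table$direction[idx]
  tier <- rep("not-tested", length(idx))
  tested <- !is.na(idx)
  tier[tested] <- "ns"
  for (t in sort(tiers, decreasing = TRUE)) {
    tier[tested & !is.na(padj) & padj < t] <- sprintf("p<%g", t)
  }
  network$annotations[[cmp]] <- data.frame(
    set = network$nodes$set, padj = padj, direction = direction,
    tier = tier, stringsAsFactors = FALSE)
  network
}

#' Signed log10 adjusted p-values per cluster and comparison
#'
#' The themed directional summary: for every node and projected comparison,
#' `value = sign * -log10(padj)` with positive sign for enrichment and
#' negative for depletion; adjusted p-values are floored at 1e-16 before
#' the log, capping the magnitude at 16. Returned tidy (one row per
#' node x comparison), ready for violin-style theme plots.
#'
#' @param network a projected [build_landscape()] result.
#' @param clusters a [mcl_cluster()] result on the same nodes.
#' @param cap magnitude cap (default 16).
#' @return data.frame: cluster, comparison, set, value.
#' @export
theme_signed_pvalues <- function(network, clusters, cap = 16) {
  rows <- list()
  for (cmp in names(network$annotations)) {
    ann <- network$annotations[[cmp]]
    tested <- ann$tier != "not-tested" & !is.na(ann$padj)
    if (!any(tested)) next
    sgn <- ifelse(ann$direction[tested] == "enriched", 1, -1)
    val <- sgn * pmin(-log10(pmax(ann$padj[tested], 10^(-cap))), cap)
    rows[[cmp]] <- data.frame(
      cluster = unname(clusters$assignment[ann$set[tested]]),
      comparison = cmp, set = ann$set[tested], value = val,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(cluster = integer(0), comparison = character(0),
                      set = character(0), value = numeric(0)))
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(out$cluster, out$comparison, out$set), , drop = FALSE]
}

#' Suggest cluster labels from member set names
#'
#' Returns the most frequent informative tokens (lower-cased, split on
#' non-alphanumerics, stop-words removed) across the member set names,
#' descending by frequency with lexicographic tie-break. Curation of the
#' biological theme stays with the analyst; this only orders the evidence.
#'
#' @param set_names character vector of member gene-set names.
#' @param top_n number of tokens to return.
#' @return character vector of tokens (may be shorter than `top_n`).
#' @export
suggest_labels <- function(set_names, top_n = 5) {
  if (!length(set_names)) stop("cluster is empty")
  toks <- unlist(lapply(set_names, .tokenize_name))
  toks <- toks[!(toks %in% .label_stopwords)]
  if (!length(toks)) return(character(0))
  tab <- table(toks)
  ord <- order(-as.integer(tab), names(tab), method = "radix")
  utils::head(names(tab)[ord], top_n)
}

# igraph twin of a landscape network with flattened per-comparison attributes
.landscape_igraph <- function(network, clusters = NULL) {
  nd <- data.frame(name = network$nodes$set,
                   ES = network$nodes$ES,
                   direction = network$nodes$direction,
                   padj_anchor = network$nodes$padj,
                   le_fraction = network$nodes$le_fraction,
                   stringsAsFactors = FALSE)
  for (cmp in names(network$annotations)) {
    ann <- network$annotations[[cmp]]
    nd[[paste0("padj_", cmp)]] <- ifelse(is.na(ann$padj), -1, ann$padj)
    nd[[paste0("direction_", cmp)]] <- ifelse(is.na(ann$direction),
                                              "not-tested", ann$direction)
    nd[[paste0("tier_", cmp)]] <- ann$tier
  }
  if (!is.null(clusters)) {
    nd$cluster <- unname(clusters$assignment[nd$name])
  }
  igraph::graph_from_data_frame(
    network$edges[, c("from", "to", "weight", "le_share"), drop = FALSE],
    directed = FALSE, vertices = nd)
}

#' Export the landscape network
#'
#' Writes `<prefix>.graphml` plus `<prefix>_nodes.tsv` and
#' `<prefix>_edges.tsv` twins. Node attributes carry per-comparison
#' adjusted p-values, directions and tiers (missing p-values encoded as
#' -1 in GraphML, empty in TSV), the anchor leading-edge fraction and the
#' cluster id; edges carry weight and leading-edge share. TSV headers
#' record the thresholds used.
#'
#' @param network a projected [build_landscape()] result.
#' @param clusters optional [mcl_cluster()] result.
#' @param prefix output path prefix.
#' @return named character vector of written paths, invisibly.
#' @export
export_network <- function(network, clusters = NULL, prefix) {
  g <- .landscape_igraph(network, clusters)
  paths <- c(graphml = paste0(prefix, ".graphml"),
             nodes = paste0(prefix, "_nodes.tsv"),
             edges = paste0(prefix, "_edges.tsv"))
  igraph::write_graph(g, paths["graphml"], format = "graphml")

  meta <- sprintf("# anchor=%s padj_thr=%g le_frac_thr=%g le_gate=%g weight_denom=%s",
                  network$anchor, network$params$padj_thr,
                  network$params$le_frac_thr, network$params$le_gate,
                  network$params$weight_denom)
  nd <- igraph::as_data_frame(g, what = "vertices")
  con <- file(paths["nodes"], "w")
  writeLines(meta, con)
  utils::write.table(nd, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  ed <- igraph::as_data_frame(g, what = "edges")
  con <- file(paths["edges"], "w")
  writeLines(meta, con)
  utils::write.table(format(ed, digits = 15), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  close(con)
  invisible(paths)
}
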