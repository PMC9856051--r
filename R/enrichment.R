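# all-zero ranking metric: substitute the uniform-weight limit (|score|^p
# weights all equal), keeping the deterministic ranking order
.degenerate_uniform <- function(ranked) {
  if (nrow(ranked) && all(ranked$score == 0)) {
    warning("ranking metric is identically zero: using uniform hit weights")
    ranked$score <- rep(1, nrow(ranked))
  }
  ranked
}

#' Weighted running-sum enrichment score with leading edge
#'
#' Classic weighted Kolmogorov-Smirnov statistic on a ranked gene list:
#' walking the ranking from top to bottom, a member gene ("hit") adds
#' `|score|^p / sum_set(|score|^p)` and a non-member subtracts
#' `1 / (N - n_set)`. The enrichment score (ES) is the running-sum value of
#' maximal absolute deviation, signed; ties in the deviation (within 1e-9,
#' so that exact rational ties resolve identically across float paths)
#' break to the earliest walk position. For ES > 0 the leading edge is the member genes
#' at or before the peak; for ES < 0 the member genes at or after the
#' trough.
#'
#' @param ranked a `ranked_list` (see [rank_genes()]): data.frame with
#'   `gene` and `score`, ordered.
#' @param members character vector of member gene ids.
#' @param weight_p hit-weight exponent (default 1, the conventional value).
#' When the entire ranking metric is zero (a fully collapsed shrunken
#' ranking, e.g. from a pure-null study), the weighted statistic is taken
#' at its limit of uniform hit weights: the unweighted Kolmogorov-Smirnov
#' form on the (still deterministically ordered) ranking. A set whose
#' members alone have all-zero scores within a non-degenerate ranking is
#' skipped with a warning.
#'
#' @return list with `es`, `peak` (walk position of the extremum),
#'   `leading_edge` (gene ids, rank order), `size_in_universe`.
#' @export
enrichment_score <- function(ranked, members, weight_p = 1) {
  ranked <- .degenerate_uniform(ranked)
  pos <- sort(match(unique(members), ranked$gene))
  pos <- pos[!is.na(pos)]
  n <- length(pos)
  N <- nrow(ranked)
  if (n == 0) stop("gene set is disjoint from the ranked universe")
  if (n >= N) stop("gene set covers the whole universe: no misses possible")
  r <- .es_stat_cpp(ranked$score, as.integer(pos), weight_p)
  if (!r$defined) {
    warning("all member scores are zero: ES undefined")
    return(list(es = NA_real_, peak = NA_integer_,
                leading_edge = character(0), size_in_universe = n))
  }
  le_pos <- if (r$es >= 0) pos[pos <= r$peak] else pos[pos > r$peak]
  list(es = r$es, peak = r$peak,
       leading_edge = ranked$gene[le_pos], size_in_universe = n)
}

#' Permutation null distribution of the enrichment score
#'
#' Samples `nperm` uniformly drawn member subsets of the given size from the
#' ranked universe (the gene-sampling null) and returns their enrichment
#' scores. Reproducible via `seed`.
#'
#' @param ranked a `ranked_list`.
#' @param set_size subset size (must leave at least one miss).
#' @param nperm number of permutations (>= 100).
#' @param seed optional integer seed (set only when non-NULL, so callers
#'   managing the RNG state themselves can pass NULL).
#' @param weight_p hit-weight exponent.
#' @return numeric vector of `nperm` null ES values.
#' @export
permutation_null <- function(ranked, set_size, nperm, seed = NULL,
                             weight_p = 1) {
  if (nperm < 100) stop("nperm must be >= 100")
  N <- nrow(ranked)
  if (set_size >= N) stop("set_size must be smaller than the universe")
  if (set_size < 1) stop("set_size must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  ranked <- .degenerate_uniform(ranked)
  .es_null_cpp(ranked$score, as.integer(set_size), as.integer(nperm),
               weight_p)
}

#' Normalized enrichment score and permutation p-value
#'
#' Sign-partitioned normalization (the standard GSEA convention): the NES is
#' the observed ES divided by the mean absolute null ES of matching sign,
#' and the p-value is the +1-smoothed fraction of matching-sign null values
#' at least as extreme: `(1 + #{|null| >= |ES|}) / (1 + #null_same_sign)`.
#' With no matching-sign null values the p-value is 1 and the NES undefined
#' (flagged as NA).
#'
#' @param es_obs observed ES.
#' @param null numeric vector of null ES values (NAs dropped).
#' @return list with `nes` and `pval`.
#' @export
nes_and_pvalue <- function(es_obs, null) {
  null <- null[!is.na(null)]
  if (!length(null)) stop("empty null distribution")
  same <- if (es_obs >= 0) null[null > 0] else null[null < 0]
  if (!length(same)) {
    return(list(nes = NA_real_, pval = 1))
  }
  k <- sum(abs(same) >= abs(es_obs))
  list(nes = es_obs / mean(abs(same)), pval = (1 + k) / (1 + length(same)))
}

#' Preranked gene-set enrichment over a collection
#'
#' For every set with at least `min_size` members in the ranked universe,
#' computes the enrichment score and leading edge, a gene-sampling
#' permutation p-value and NES (one shared null per distinct set size), and
#' Benjamini-Hochberg adjusted p-values across all tested sets. Sets whose
#' member scores are all zero are skipped with a warning. Deterministic
#' given `seed`.
#'
#' @param ranked a `ranked_list`.
#' @param collection a [gene_set_collection()] (size-filter it first with
#'   [filter_by_size()] for the conventional >10 / <500 window).
#' @param nperm permutations per distinct set size (default 10000).
#' @param seed integer seed for the permutation null.
#' @param weight_p hit-weight exponent.
#' @param min_size minimum members in the universe (default 2).
#' @return data.frame of class `enrichment_table`: set, size_in_universe,
#'   ES, NES, pval, padj, le_fraction, direction, leading_edge (list
#'   column). Attributes: comparison, nperm, seed, weight_p.
#' @export
run_enrichment <- function(ranked, collection, nperm = 10000, seed = 1L,
                           weight_p = 1, min_size = 2) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (!length(collection$sets)) stop("empty collection")
  set.seed(seed)
  ranked <- .degenerate_uniform(ranked)
  N <- nrow(ranked)

  pos_list <- lapply(collection$sets, function(m) {
    p <- match(unique(m), ranked$gene)
    sort(p[!is.na(p)])
  })
  sizes <- lengths(pos_list)
  testable <- sizes >= min_size & sizes < N
  pos_list <- pos_list[testable]
  sizes <- sizes[testable]
  if (!length(pos_list)) stop("no set has enough members in the universe")

  # one shared null per distinct size, generated in sorted-size order
  null_by_size <- list()
  for (s in sort(unique(sizes))) {
    null_by_size[[as.character(s)]] <-
      .es_null_cpp(ranked$score, as.integer(s), as.integer(nperm), weight_p)
  }

  n_sets <- length(pos_list)
  es <- nes <- pv <- lef <- rep(NA_real_, n_sets)
  peak <- rep(NA_integer_, n_sets)
  le <- vector("list", n_sets)
  skipped <- 0L
  for (i in seq_len(n_sets)) {
    r <- .es_stat_cpp(ranked$score, as.integer(pos_list[[i]]), weight_p)
    if (!r$defined) {
      skipped <- skipped + 1L
      le[[i]] <- character(0)
      next
    }
    es[i] <- r$es
    peak[i] <- r$peak
    p <- pos_list[[i]]
    le_pos <- if (r$es >= 0) p[p <= r$peak] else p[p > r$peak]
    le[[i]] <- ranked$gene[le_pos]
    lef[i] <- length(le_pos) / length(p)
    np <- nes_and_pvalue(r$es, null_by_size[[as.character(sizes[i])]])
    nes[i] <- np$nes
    pv[i] <- np$pval
  }
  if (skipped > 0) {
    warning(skipped, " set(s) skipped: all member scores zero")
  }

  out <- data.frame(set = names(pos_list), size_in_universe = sizes,
                    ES = es, NES = nes, pval = pv, padj = bh_adjust(pv),
                    le_fraction = lef,
                    direction = ifelse(es >= 0, "enriched", "depleted"),
                    stringsAsFactors = FALSE)
  out$leading_edge <- le
  rownames(out) <- NULL
  ok <- !is.na(out$ES)
  out <- out[ok, , drop = FALSE]
  attr(out, "comparison") <- attr(ranked, "comparison")
  attr(out, "nperm") <- nperm
  attr(out, "seed") <- seed
  attr(out, "weight_p") <- weight_p
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Write an enrichment table to TSV
#'
#' Header comment lines record the comparison, nperm, seed and weight
#' exponent; leading-edge genes are pipe-separated.
#'
#' @param table an `enrichment_table` from [run_enrichment()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_tsv <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# comparison=%s nperm=%d seed=%d weight_p=%g",
                     attr(table, "comparison"), attr(table, "nperm"),
                     attr(table, "seed"), attr(table, "weight_p")), con)
  flat <- table
  flat$leading_edge <- vapply(table$leading_edge, paste, "", collapse = "|")
  utils::write.table(flat, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
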