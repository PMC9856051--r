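#' Pipeline configuration
#'
#' Collects every path and tunable of an end-to-end landscape run. The
#' anchor comparison defines the network scaffold; the remaining
#' comparisons are projected onto it.
#'
#' @param counts,design,gmt,pairs input file paths (see [read_counts()],
#'   [read_design()], [read_gmt()], [load_pairs()]).
#' @param outdir output directory.
#' @param anchor anchor comparison, `"<group1>_vs_<group2>"`.
#' @param comparisons additional comparisons to project (character vector
#'   of the same form).
#' @param pseudocount,de_method,fc_mode differential-expression settings
#'   (see [gene_stats()], [classify_volcano()]).
#' @param min_set_size,max_set_size strict size window for
#'   [filter_by_size()] (defaults: keep sets with >10 and <500 members).
#' @param nperm permutations per distinct set size. The default 50000 keeps
#'   the smoothed p-value floor (about `2/nperm` after sign-partitioning of
#'   the null) low enough that a Benjamini-Hochberg-adjusted value can
#'   still clear the 0.001 node gate in a collection of a few hundred sets.
#' @param weight_p GSEA hit-weight exponent.
#' @param node_padj,node_le_frac node criteria (see [select_nodes()]).
#' @param le_gate,weight_denom edge criteria (see [build_edges()]).
#' @param inflation MCL inflation.
#' @param gene_padj,gene_fc gene-level significance criteria
#'   (see [classify_volcano()]).
#' @param seed master seed; stage seeds are derived as `seed + stage index`.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(counts, design, gmt, pairs, outdir,
                            anchor = "A_vs_C",
                            comparisons = c("B_vs_C", "A_vs_B"),
                            pseudocount = 0.5, de_method = "welch",
                            fc_mode = "linear",
                            min_set_size = 10, max_set_size = 500,
                            nperm = 50000, weight_p = 1,
                            node_padj = 0.001, node_le_frac = 0.3334,
                            le_gate = 0.05, weight_denom = "min",
                            inflation = 2.0,
                            gene_padj = 0.05, gene_fc = 2,
                            seed = 1L) {
  cfg <- list(counts = counts, design = design, gmt = gmt, pairs = pairs,
              outdir = outdir, anchor = anchor,
              comparisons = as.character(comparisons),
              pseudocount = pseudocount, de_method = de_method,
              fc_mode = fc_mode, min_set_size = min_set_size,
              max_set_size = max_set_size, nperm = nperm,
              weight_p = weight_p, node_padj = node_padj,
              node_le_frac = node_le_frac, le_gate = le_gate,
              weight_denom = weight_denom, inflation = inflation,
              gene_padj = gene_padj, gene_fc = gene_fc,
              seed = as.integer(seed))
  if (!(cfg$node_padj > 0 && cfg$node_padj < 1) ||
      !(cfg$gene_padj > 0 && cfg$gene_padj < 1)) {
    stop("significance thresholds must lie in (0, 1)")
  }
  structure(cfg, class = "pipeline_config")
}

.parse_comparison <- function(cmp, groups) {
  parts <- strsplit(cmp, "_vs_", fixed = TRUE)[[1]]
  if (length(parts) != 2 || !all(parts %in% groups)) {
    stop("comparison '", cmp, "' does not name two design groups")
  }
  parts
}

#' Run the full landscape pipeline
#'
#' Executes every stage in order: differential expression, shrinkage,
#' ranking and volcano classification per comparison; size-filtered
#' preranked enrichment per comparison; scaffold construction from the
#' anchor comparison; MCL clustering; projection of the other comparisons;
#' themed directional summaries and label suggestions; ligand/receptor
#' overlay; and a JSON run manifest with every parameter and the md5
#' checksum of every input and output. Deterministic for a given config.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the in-memory stage objects (`stats`,
#'   `ranked`, `enrichment`, `network`, `clusters`, `themes`,
#'   `interactome`) and `manifest_path`.
#' @export
run_landscape_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (f in c("counts", "design", "gmt", "pairs")) {
    if (is.null(config[[f]]) || !file.exists(config[[f]])) {
      stop("missing input file for '", f, "': ", config[[f]])
    }
  }
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)

  counts <- read_counts(config$counts)
  design <- read_design(config$design)
  collection <- filter_by_size(read_gmt(config$gmt),
                               config$min_set_size, config$max_set_size)
  pairs <- load_pairs(config$pairs)

  all_cmps <- c(config$anchor, config$comparisons)
  stats_list <- list()
  ranked_list <- list()
  enrich_list <- list()
  out_paths <- character(0)
  for (k in seq_along(all_cmps)) {
    cmp <- all_cmps[k]
    contrast <- .parse_comparison(cmp, design$group)
    st <- gene_stats(counts, design, contrast,
                     pseudocount = config$pseudocount,
                     method = config$de_method)
    st <- shrink_lfc(st)
    st <- classify_volcano(st, padj_thr = config$gene_padj,
                           fc_thr = config$gene_fc,
                           fc_mode = config$fc_mode)
    rk <- rank_genes(st, comparison = cmp)
    en <- run_enrichment(rk, collection, nperm = config$nperm,
                         seed = config$seed + k,
                         weight_p = config$weight_p)
    stats_list[[cmp]] <- st
    ranked_list[[cmp]] <- rk
    enrich_list[[cmp]] <- en

    p_stats <- file.path(config$outdir, paste0("gene_stats_", cmp, ".tsv"))
    utils::write.table(st, p_stats, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    p_rnk <- file.path(config$outdir, paste0("ranked_", cmp, ".rnk"))
    write_rnk(rk, p_rnk)
    p_enr <- file.path(config$outdir, paste0("enrichment_", cmp, ".tsv"))
    write_enrichment_tsv(en, p_enr)
    out_paths <- c(out_paths, p_stats, p_rnk, p_enr)
  }

  network <- build_landscape(enrich_list[[config$anchor]], collection,
                             universe = ranked_list[[config$anchor]]$gene,
                             padj_thr = config$node_padj,
                             le_frac_thr = config$node_le_frac,
                             le_gate = config$le_gate,
                             weight_denom = config$weight_denom)
  for (cmp in config$comparisons) {
    network <- project_comparison(network, enrich_list[[cmp]])
  }
  clusters <- if (nrow(network$nodes) > 0) {
    mcl_cluster(network$edges, nodes = network$nodes$set,
                inflation = config$inflation)
  } else {
    NULL
  }

  net_paths <- export_network(network, clusters,
                              file.path(config$outdir, "landscape"))
  out_paths <- c(out_paths, net_paths)

  themes <- NULL
  if (!is.null(clusters)) {
    themes <- theme_signed_pvalues(network, clusters)
    p_themes <- file.path(config$outdir, "theme_summary.tsv")
    utils::write.table(themes, p_themes, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    labels <- do.call(rbind, lapply(split(names(clusters$assignment),
                                          clusters$assignment),
                                    function(nm) data.frame(
                                      cluster = clusters$assignment[nm[1]],
                                      label_tokens = paste(
                                        suggest_labels(nm), collapse = "|"),
                                      n_nodes = length(nm))))
    p_labels <- file.path(config$outdir, "cluster_labels.tsv")
    utils::write.table(labels, p_labels, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out_paths <- c(out_paths, p_themes, p_labels)
  }

  inter <- overlay_interactome(pairs, stats_list)
  inter_paths <- export_interactome(inter,
                                    file.path(config$outdir, "interactome"))
  out_paths <- c(out_paths, inter_paths)

  manifest <- list(
    package_version = as.character(utils::packageVersion("enrichscape")),
    parameters = unclass(config),
    inputs = as.list(.checksum_files(unlist(config[c("counts", "design",
                                                     "gmt", "pairs")]))),
    outputs = as.list(.checksum_files(unname(out_paths))))
  manifest_path <- file.path(config$outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(stats = stats_list, ranked = ranked_list,
                 enrichment = enrich_list, network = network,
                 clusters = clusters, themes = themes, interactome = inter,
                 manifest_path = manifest_path))
}

#' Default planted signals of the packaged demo study
#'
#' Ten planted sets of 50 genes, responder fraction 0.5 and effect size
#' 1 log2 unit: five specific to disease group A versus control (three
#' enriched, two depleted) and five shared by both disease groups versus
#' control (three enriched, two depleted). This mirrors the shared-versus-
#' specific dichotomy the projection stage is designed to expose.
#'
#' @return list of [planted_signal()] objects.
#' @export
fixture_signals <- function() {
  mk <- function(id, cmps, dir) {
    planted_signal(id, cmps, dir, member_effect_lfc = 1.0,
                   responder_fraction = 0.5, size = 50L)
  }
  c(lapply(1:3, function(i) mk(sprintf("specificA_enr_%d", i), "A_vs_C",
                               "enriched")),
    lapply(1:2, function(i) mk(sprintf("specificA_dep_%d", i), "A_vs_C",
                               "depleted")),
    lapply(1:3, function(i) mk(sprintf("shared_enr_%d", i),
                               c("A_vs_C", "B_vs_C"), "enriched")),
    lapply(1:2, function(i) mk(sprintf("shared_dep_%d", i),
                               c("A_vs_C", "B_vs_C"), "depleted")))
}

#' Write the packaged demo study to disk
#'
#' Generates the documented default synthetic three-group study (two
#' disease groups and one control, with the [fixture_signals()] planted
#' ground truth) and writes it with [write_study()]. Regenerating with the
#' same seed is byte-identical.
#'
#' @param outdir output directory.
#' @param seed integer seed (default 1).
#' @return named character vector of written paths, invisibly.
#' @export
make_fixture_study <- function(outdir, seed = 1L) {
  cfg <- simulation_config(planted_sets = fixture_signals(), seed = seed)
  study <- simulate_study(cfg)
  write_study(study, outdir)
}
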