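#' Configuration for a synthetic three-group RNA-seq study
#'
#' Describes a negative-binomial count simulation emulating a bulk RNA-seq
#' study with two disease groups and one control group. Gene base means are
#' log-normal; the gene-level dispersion follows the common decreasing trend
#' `phi(mu) = phi0 + a / mu`, so that `Var = mu + phi * mu^2`. Sample library
#' sizes are drawn log-uniformly within a relative range; planted signals
#' shift the means of responder member genes by `2^member_effect_lfc` in the
#' affected groups.
#'
#' @param n_genes number of genes in the simulated universe.
#' @param groups ordered group labels; the last label is the control.
#' @param n_per_group samples per group (>= 2).
#' @param mean_log_mu,sd_log_mu natural-log mean and sd of gene base means.
#' @param phi0 dispersion intercept (> 0).
#' @param dispersion_slope dispersion slope `a` (>= 0) in `phi = phi0 + a/mu`.
#' @param n_sets total number of gene sets in the simulated collection
#'   (planted sets count towards this total).
#' @param set_size_range inclusive size range for non-planted sets.
#' @param planted_sets list of [planted_signal()] objects (ground truth).
#' @param library_size_range relative library-size factor range (log-uniform).
#' @param batch_lfc optional scalar log2 batch offset; when non-NULL, samples
#'   are assigned round-robin to two batches and a random half of genes gets
#'   the offset in batch 2 (a known covariate for adjustment, not a hidden
#'   surrogate).
#' @param seed integer seed; identical configs are bit-reproducible.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 5000,
                              groups = c("A", "B", "C"),
                              n_per_group = 8,
                              mean_log_mu = 4,
                              sd_log_mu = 1.5,
                              phi0 = 0.05,
                              dispersion_slope = 1,
                              n_sets = 200,
                              set_size_range = c(20, 60),
                              planted_sets = list(),
                              library_size_range = c(0.7, 1.4),
                              batch_lfc = NULL,
                              seed = 1L) {
  n_genes <- .assert_scalar_count(n_genes, "n_genes", min = 2)
  n_per_group <- .assert_scalar_count(n_per_group, "n_per_group", min = 2)
  n_sets <- .assert_scalar_count(n_sets, "n_sets", min = 0)
  if (length(groups) < 2 || anyDuplicated(groups)) {
    stop("groups must be >= 2 distinct labels")
  }
  if (phi0 <= 0) stop("phi0 must be > 0")
  if (dispersion_slope < 0) stop("dispersion_slope must be >= 0")
  if (sd_log_mu < 0) stop("sd_log_mu must be >= 0")
  if (length(set_size_range) != 2 || set_size_range[1] < 2 ||
      set_size_range[2] < set_size_range[1] || set_size_range[2] > n_genes) {
    stop("set_size_range must be [min, max] within [2, n_genes]")
  }
  if (length(library_size_range) != 2 || any(library_size_range <= 0) ||
      library_size_range[2] < library_size_range[1]) {
    stop("library_size_range must be positive [min, max]")
  }
  for (p in planted_sets) {
    if (!inherits(p, "planted_signal")) {
      stop("planted_sets must be a list of planted_signal objects")
    }
  }
  structure(list(n_genes = n_genes, groups = as.character(groups),
                 n_per_group = n_per_group, mean_log_mu = mean_log_mu,
                 sd_log_mu = sd_log_mu, phi0 = phi0,
                 dispersion_slope = dispersion_slope, n_sets = n_sets,
                 set_size_range = as.integer(set_size_range),
                 planted_sets = planted_sets,
                 library_size_range = library_size_range,
                 batch_lfc = batch_lfc, seed = as.integer(seed)),
            class = "simulation_config")
}

#' A planted gene-set signal (simulation ground truth)
#'
#' @param set_id name of the planted set.
#' @param affected_comparisons character vector of comparisons, each
#'   `"<group1>_vs_<group2>"`; the shift is applied to the first-named group
#'   of each affected comparison (so `"A_vs_C"` + `direction = "enriched"`
#'   means the responders go up in group A).
#' @param direction `"enriched"` (responders shifted up) or `"depleted"`.
#' @param member_effect_lfc magnitude of the log2 mean shift (> 0).
#' @param responder_fraction fraction of member genes that actually shift,
#'   in (0, 1]; exactly `round(responder_fraction * size)` genes respond.
#' @param size number of member genes in the planted set.
#' @return object of class `planted_signal`.
#' @export
planted_signal <- function(set_id, affected_comparisons,
                           direction = c("enriched", "depleted"),
                           member_effect_lfc = 1.0,
                           responder_fraction = 0.5,
                           size = 50L) {
  direction <- match.arg(direction)
  if (responder_fraction <= 0 || responder_fraction > 1) {
    stop("responder_fraction must be in (0, 1]")
  }
  if (member_effect_lfc <= 0) stop("member_effect_lfc must be > 0")
  size <- .assert_scalar_count(size, "size", min = 2)
  structure(list(set_id = as.character(set_id),
                 affected_comparisons = as.character(affected_comparisons),
                 direction = direction,
                 member_effect_lfc = member_effect_lfc,
                 responder_fraction = responder_fraction,
                 size = size),
            class = "planted_signal")
}

# per-signal group shifts on the log2 scale; returns named numeric vector
.signal_shifts <- function(signal, groups) {
  sgn <- if (signal$direction == "enriched") 1 else -1
  shift <- stats::setNames(numeric(length(groups)), groups)
  for (cmp in signal$affected_comparisons) {
    parts <- strsplit(cmp, "_vs_", fixed = TRUE)[[1]]
    if (length(parts) != 2 || !all(parts %in% groups)) {
      stop("affected comparison '", cmp, "' does not name two known groups")
    }
    shift[parts[1]] <- sgn * signal$member_effect_lfc
  }
  shift
}

#' Simulate a complete synthetic study
#'
#' Draws the count matrix, the gene-set collection (planted sets plus null
#' sets), the recorded ground truth, and a small synthetic ligand/receptor
#' pair table, all from one seed. Planted sets receive disjoint member genes
#' so each ground-truth signal is unambiguous; null sets are drawn uniformly
#' from the whole gene universe.
#'
#' @param config a [simulation_config()].
#' @return object of class `synthetic_study`: list with `counts` (integer
#'   matrix, genes x samples), `design` (data.frame sample/group\[/batch\]),
#'   `collection` (a [gene_set_collection()]), `truth` (data.frame of planted
#'   signals with responder genes), and `interactome` (pair data.frame).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  ng <- config$n_genes
  genes <- sprintf("gene%05d", seq_len(ng))
  groups <- config$groups
  ns <- config$n_per_group * length(groups)
  samples <- sprintf("s%02d_%s", seq_len(ns),
                     rep(groups, each = config$n_per_group))
  design <- data.frame(sample = samples,
                       group = rep(groups, each = config$n_per_group),
                       stringsAsFactors = FALSE)

  mu <- exp(stats::rnorm(ng, config$mean_log_mu, config$sd_log_mu))
  phi <- config$phi0 + config$dispersion_slope / mu
  lib <- exp(stats::runif(ns, log(config$library_size_range[1]),
                          log(config$library_size_range[2])))

  # planted membership: disjoint across planted sets
  planted <- config$planted_sets
  need <- sum(vapply(planted, function(p) p$size, 0L))
  if (need > ng) stop("planted sets require more genes than the universe holds")
  pool <- sample(genes, need)
  offset <- 0L
  truth_rows <- list()
  shift <- matrix(0, nrow = ng, ncol = length(groups),
                  dimnames = list(genes, groups))
  planted_members <- list()
  for (p in planted) {
    members <- pool[offset + seq_len(p$size)]
    offset <- offset + p$size
    n_resp <- max(1L, round(p$responder_fraction * p$size))
    responders <- sample(members, n_resp)
    shift[responders, ] <- shift[responders, , drop = FALSE] +
      matrix(.signal_shifts(p, groups), nrow = n_resp,
             ncol = length(groups), byrow = TRUE)
    planted_members[[p$set_id]] <- members
    truth_rows[[p$set_id]] <- data.frame(
      set_id = p$set_id,
      affected_comparisons = paste(p$affected_comparisons, collapse = ";"),
      direction = p$direction,
      member_effect_lfc = p$member_effect_lfc,
      responder_fraction = p$responder_fraction,
      size = p$size,
      responders = paste(sort(responders), collapse = ";"),
      stringsAsFactors = FALSE)
  }

  # optional known batch covariate: round-robin batches, half the genes offset
  batch_shift <- NULL
  if (!is.null(config$batch_lfc)) {
    design$batch <- paste0("b", rep_len(1:2, ns))
    affected_genes <- sample(ng, floor(ng / 2))
    batch_shift <- numeric(ng)
    batch_shift[affected_genes] <- config$batch_lfc
  }

  counts <- matrix(0L, nrow = ng, ncol = ns, dimnames = list(genes, samples))
  group_of <- design$group
  for (j in seq_len(ns)) {
    lfc_j <- shift[, group_of[j]]
    if (!is.null(batch_shift) && design$batch[j] == "b2") {
      lfc_j <- lfc_j + batch_shift
    }
    mu_j <- mu * lib[j] * 2^lfc_j
    counts[, j] <- stats::rnbinom(ng, mu = mu_j, size = 1 / phi)
  }
  storage.mode(counts) <- "integer"

  # collection: planted sets first, then uniform null sets
  n_null <- config$n_sets - length(planted)
  if (n_null < 0) stop("n_sets is smaller than the number of planted sets")
  sets <- planted_members
  if (n_null > 0) {
    null_sizes <- sample(seq(config$set_size_range[1],
                             config$set_size_range[2]), n_null,
                         replace = TRUE)
    null_sets <- lapply(null_sizes, function(s) sample(genes, s))
    names(null_sets) <- sprintf("null_set_%03d", seq_len(n_null))
    sets <- c(sets, null_sets)
  }
  collection <- if (length(sets)) {
    gene_set_collection(sets, source = sprintf("simulated(seed=%d)",
                                               config$seed))
  } else {
    structure(list(sets = list(), descriptions = character(0),
                   source = "simulated(empty)"),
              class = "gene_set_collection")
  }

  interactome <- simulate_interactome(genes, n_pairs = 30)

  structure(list(counts = counts, design = design, collection = collection,
                 truth = if (length(truth_rows)) {
                   do.call(rbind, unname(truth_rows))
                 } else {
                   data.frame()
                 },
                 config = config, interactome = interactome),
            class = "synthetic_study")
}

#' Simulate only the gene-set collection of a study
#'
#' Convenience accessor running the full generator and returning the
#' collection component (so counts and collection stay mutually consistent).
#'
#' @param config a [simulation_config()].
#' @return a [gene_set_collection()].
#' @export
simulate_collection <- function(config) {
  simulate_study(config)$collection
}

#' Simulate a synthetic ligand/receptor pair table
#'
#' Draws unique directed ligand-to-receptor pairs from a gene universe
#' (no self-pairs, duplicates collapsed).
#'
#' @param genes character vector of available gene ids.
#' @param n_pairs number of pairs requested (>= 1).
#' @return data.frame with columns `ligand`, `receptor`, `source`.
#' @export
simulate_interactome <- function(genes, n_pairs) {
  n_pairs <- .assert_scalar_count(n_pairs, "n_pairs", min = 1)
  seen <- character(0)
  lig <- character(0)
  rec <- character(0)
  while (length(lig) < n_pairs) {
    l <- sample(genes, 1)
    r <- sample(genes, 1)
    key <- paste(l, r, sep = "->")
    if (l != r && !(key %in% seen)) {
      seen <- c(seen, key)
      lig <- c(lig, l)
      rec <- c(rec, r)
    }
  }
  data.frame(ligand = lig, receptor = rec, source = "simulated",
             stringsAsFactors = FALSE)
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("synthetic_study: %d genes x %d samples, %d sets (%d planted), seed %d\n",
              nrow(x$counts), ncol(x$counts), length(x$collection),
              nrow(x$truth), x$config$seed))
  invisible(x)
}

#' Write a synthetic study to plain-text files
#'
#' Writes `counts.tsv` (first column `gene`, header = sample ids),
#' `design.tsv`, `sets.gmt`, `truth.tsv` and `pairs.tsv` into a directory.
#'
#' @param study a [simulate_study()] result.
#' @param dir output directory (created if missing).
#' @return named character vector of the written paths, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             design = file.path(dir, "design.tsv"),
             gmt = file.path(dir, "sets.gmt"),
             truth = file.path(dir, "truth.tsv"),
             pairs = file.path(dir, "pairs.tsv"))
  write_counts(study$counts, paths["counts"])
  utils::write.table(study$design, paths["design"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gmt(study$collection, paths["gmt"])
  utils::write.table(study$truth, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(study$interactome, paths["pairs"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
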