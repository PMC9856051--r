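#' Read / write a gene-by-sample count matrix
#'
#' TSV with the gene id in the first column (header `gene`) and one column
#' per sample. Counts must be non-negative integers; duplicate gene ids are
#' rejected.
#'
#' @param path TSV file path.
#' @return integer matrix with gene rownames and sample colnames.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(df[[1]])) stop("duplicate gene ids in count matrix")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (any(m < 0) || any(m != round(m))) {
    stop("counts must be non-negative integers")
  }
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_counts
#' @param counts integer matrix, genes x samples.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample design table
#'
#' TSV with columns `sample`, `group` and optionally `batch`.
#'
#' @param path TSV file path.
#' @return data.frame.
#' @export
read_design <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(d))) {
    stop("design table needs 'sample' and 'group' columns")
  }
  d
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed against a pseudo-reference
#' sample: the gene-wise geometric mean over genes with all-positive counts;
#' each sample's factor is the median of its count/reference ratios. When no
#' gene is positive in every sample the function falls back to total-count
#' (CPM-style) factors scaled to geometric mean 1, with a warning.
#'
#' @param counts integer matrix, genes x samples.
#' @return positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  if (any(colSums(counts) == 0)) stop("every sample needs >= 1 nonzero count")
  all_pos <- rowSums(counts == 0) == 0
  if (!any(all_pos)) {
    warning("no gene with all-positive counts; falling back to total-count factors")
    ls <- colSums(counts)
    return(ls / exp(mean(log(ls))))
  }
  sub <- counts[all_pos, , drop = FALSE]
  ref <- exp(rowMeans(log(sub)))
  apply(sub, 2, function(col) stats::median(col / ref))
}

#' Counts per million
#'
#' @param counts integer matrix, genes x samples.
#' @return numeric matrix: `count / library_size * 1e6` per sample.
#' @export
cpm <- function(counts) {
  ls <- colSums(counts)
  if (any(ls == 0)) stop("zero library size")
  sweep(counts, 2, ls, "/") * 1e6
}

# vectorized Welch test on a numeric matrix, columns split by idx_a/idx_b
.welch_rows <- function(x, idx_a, idx_b) {
  na <- length(idx_a); nb <- length(idx_b)
  ma <- rowMeans(x[, idx_a, drop = FALSE])
  mb <- rowMeans(x[, idx_b, drop = FALSE])
  va <- apply(x[, idx_a, drop = FALSE], 1, stats::var)
  vb <- apply(x[, idx_b, drop = FALSE], 1, stats::var)
  se2 <- va / na + vb / nb
  se <- sqrt(se2)
  t <- ifelse(se > 0, (ma - mb) / se, ifelse(ma == mb, 0, Inf))
  df <- ifelse(se2 > 0,
               se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1)),
               na + nb - 2)
  p <- ifelse(is.finite(t), 2 * stats::pt(-abs(t), df), 0)
  p[se == 0 & ma == mb] <- 1
  list(stat = t, se = se, p = p)
}

# NB Wald (optional mode): per-group log-link mean by Newton iteration with
# gene-wise moment dispersion; Wald se from the Fisher information.
.nb_wald_rows <- function(norm, idx_a, idx_b) {
  phi_hat <- function(sub) {
    m <- rowMeans(sub)
    v <- apply(sub, 1, stats::var)
    pmax(1e-8, (v - m) / pmax(m, 1e-8)^2)
  }
  phi <- pmax(phi_hat(norm[, idx_a, drop = FALSE]),
              phi_hat(norm[, idx_b, drop = FALSE]))
  fit_group <- function(sub, phi) {
    y_bar <- rowMeans(sub)
    mu <- pmax(y_bar, 1e-8)
    n <- ncol(sub)
    for (it in 1:25) {
      w <- mu / (1 + phi * mu)            # NB unit Fisher weight, log link
      score <- n * (y_bar - mu) / (1 + phi * mu)
      info <- n * w
      step <- score / pmax(info, 1e-12)
      step <- pmin(pmax(step, -5), 5)
      mu <- mu * exp(step)
    }
    list(eta = log(mu), var_eta = 1 / pmax(n * mu / (1 + phi * mu), 1e-12))
  }
  fa <- fit_group(norm[, idx_a, drop = FALSE], phi)
  fb <- fit_group(norm[, idx_b, drop = FALSE], phi)
  se <- sqrt(fa$var_eta + fb$var_eta) / log(2)
  z <- (fa$eta - fb$eta) / log(2) / se
  list(stat = z, se = se, p = 2 * stats::pnorm(-abs(z)))
}

#' Per-gene differential-expression statistics for one contrast
#'
#' Normalizes by [size_factors()], drops genes with zero counts across all
#' samples of both contrast groups, and computes per gene: the base mean,
#' the log2 fold change `log2((mean_A + c) / (mean_B + c))` of group-mean
#' normalized counts with pseudocount `c`, a standard error and p-value from
#' a Welch test on `log2(normalized + c)` (default) or from a
#' negative-binomial Wald fit (`method = "nbwald"`), and Benjamini-Hochberg
#' adjusted p-values over all retained genes.
#'
#' @param counts integer matrix, genes x samples.
#' @param design data.frame with `sample`, `group` and optionally `batch`.
#' @param contrast character of length 2: `c(numerator_group, denominator_group)`.
#' @param pseudocount pseudocount `c` on the normalized scale (default 0.5).
#' @param method `"welch"` (default) or `"nbwald"`.
#' @param adjust_batch when TRUE and the design has a `batch` column, the
#'   log2 normalized values are centered per batch (known-covariate offset
#'   removal) before testing.
#' @return data.frame of class `gene_stats`: gene, baseMean, lfc, se, stat,
#'   wald_p, padj, plus the contrast as attribute `"contrast"`.
#' @export
gene_stats <- function(counts, design, contrast, pseudocount = 0.5,
                       method = c("welch", "nbwald"), adjust_batch = FALSE) {
  method <- match.arg(method)
  if (length(contrast) != 2 || !all(contrast %in% design$group)) {
    stop("contrast must name two groups present in the design")
  }
  design <- design[match(colnames(counts), design$sample), , drop = FALSE]
  if (anyNA(design$sample)) stop("design does not cover all count columns")
  idx_a <- which(design$group == contrast[1])
  idx_b <- which(design$group == contrast[2])
  if (length(idx_a) < 2 || length(idx_b) < 2) {
    stop("each contrast group needs >= 2 samples")
  }

  sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")

  used <- c(idx_a, idx_b)
  keep <- rowSums(counts[, used, drop = FALSE]) > 0
  norm <- norm[keep, , drop = FALSE]

  c0 <- pseudocount
  logn <- log2(norm + c0)
  if (adjust_batch && "batch" %in% names(design)) {
    for (b in unique(design$batch)) {
      cols <- which(design$batch == b)
      logn[, cols] <- logn[, cols, drop = FALSE] -
        rowMeans(logn[, cols, drop = FALSE]) + rowMeans(logn)
    }
  }

  ma <- rowMeans(norm[, idx_a, drop = FALSE])
  mb <- rowMeans(norm[, idx_b, drop = FALSE])
  lfc <- log2((ma + c0) / (mb + c0))

  tst <- if (method == "welch") {
    .welch_rows(logn, idx_a, idx_b)
  } else {
    .nb_wald_rows(norm, idx_a, idx_b)
  }

  out <- data.frame(
    gene = rownames(norm),
    baseMean = rowMeans(norm[, used, drop = FALSE]),
    lfc = lfc,
    se = tst$se,
    stat = tst$stat,
    wald_p = tst$p,
    padj = bh_adjust(tst$p),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "contrast") <- contrast
  attr(out, "pseudocount") <- c0
  class(out) <- c("gene_stats", "data.frame")
  out
}

#' Ridge shrinkage of log2 fold changes
#'
#' Shrinks each gene's fold change towards zero with a normal-prior ridge
#' factor `tau2 / (tau2 + se^2)`, where the prior variance `tau2` is
#' moment-matched as `max(0, var(lfc) - mean(se^2))` across genes. Genes
#' with `se = 0` keep their raw fold change (the no-noise limit); when
#' `tau2 = 0` (pure-noise fold changes) everything shrinks to zero. With
#' fewer than 10 genes the prior variance is not estimable and shrinkage is
#' skipped with a warning.
#'
#' @param stats a [gene_stats()] data.frame.
#' @return the input with an added `slfc` column.
#' @export
shrink_lfc <- function(stats) {
  if (!all(c("lfc", "se") %in% names(stats))) stop("need lfc and se columns")
  if (nrow(stats) < 10) {
    warning("fewer than 10 genes: prior variance undefined, shrinkage skipped")
    stats$slfc <- stats$lfc
    return(stats)
  }
  tau2 <- max(0, stats::var(stats$lfc) - mean(stats$se^2))
  stats$slfc <- ifelse(stats$se == 0, stats$lfc,
                       stats$lfc * tau2 / (tau2 + stats$se^2))
  attr(stats, "tau2") <- tau2
  stats
}

#' Rank genes by shrunken fold change
#'
#' Strict total order: descending shrunken log2 fold change, ties broken by
#' the test statistic (descending), then by gene id (lexicographic), so the
#' ranking is deterministic.
#'
#' @param stats a [gene_stats()] data.frame with `slfc` (see [shrink_lfc()]).
#' @param comparison label for the contrast, e.g. `"A_vs_C"`.
#' @return data.frame of class `ranked_list` with columns `gene`, `score`.
#' @export
rank_genes <- function(stats, comparison = NULL) {
  if (!"slfc" %in% names(stats)) stop("run shrink_lfc() first")
  o <- order(-stats$slfc, -stats$stat, stats$gene, method = "radix")
  out <- data.frame(gene = stats$gene[o], score = stats$slfc[o],
                    stringsAsFactors = FALSE)
  if (is.null(comparison)) {
    ctr <- attr(stats, "contrast")
    comparison <- if (!is.null(ctr)) paste(ctr, collapse = "_vs_") else "unnamed"
  }
  attr(out, "comparison") <- comparison
  class(out) <- c("ranked_list", "data.frame")
  out
}

#' Classify genes for a volcano plot
#'
#' A gene is `up` when its adjusted p-value passes `padj_thr` and its
#' shrunken fold change passes the fold criterion upwards, `down` for the
#' mirrored criterion, `significant-only` when only the p criterion passes,
#' and `ns` otherwise. The fold criterion of 2 is read as a linear 2-fold
#' change by default (`|slfc| >= 1` in log2 units); `fc_mode = "log2"`
#' selects the literal reading `slfc > 2` / `slfc < -2` in log2 units.
#'
#' @param stats a [gene_stats()] data.frame with `slfc` and `padj`.
#' @param padj_thr adjusted-p threshold (default 0.05, strict `<`).
#' @param fc_thr fold-change threshold (default 2).
#' @param fc_mode `"linear"` (default) or `"log2"`.
#' @return the input with an added `class` column.
#' @export
classify_volcano <- function(stats, padj_thr = 0.05, fc_thr = 2,
                             fc_mode = c("linear", "log2")) {
  fc_mode <- match.arg(fc_mode)
  if (!all(c("slfc", "padj") %in% names(stats))) {
    stop("need slfc and padj columns")
  }
  sig <- !is.na(stats$padj) & stats$padj < padj_thr
  if (fc_mode == "linear") {
    up_fc <- stats$slfc >= log2(fc_thr)
    dn_fc <- stats$slfc <= -log2(fc_thr)
  } else {
    up_fc <- stats$slfc > fc_thr
    dn_fc <- stats$slfc < -fc_thr
  }
  cls <- rep("ns", nrow(stats))
  cls[sig] <- "significant-only"
  cls[sig & up_fc] <- "up"
  cls[sig & dn_fc] <- "down"
  stats$class <- cls
  stats
}

#' Read / write a two-column RNK ranking file
#'
#' `gene<TAB>score`, no header; lines starting with `#` carry metadata and
#' are skipped on read.
#'
#' @param ranked a [rank_genes()] result.
#' @param path file path.
#' @return `write_rnk`: `path` invisibly; `read_rnk`: a `ranked_list`.
#' @export
write_rnk <- function(ranked, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# comparison=%s", attr(ranked, "comparison")), con)
  utils::write.table(ranked[, c("gene", "score")], con, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_rnk
#' @export
read_rnk <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  out <- data.frame(gene = vapply(parts, `[[`, "", 1L),
                    score = as.numeric(vapply(parts, `[[`, "", 2L)),
                    stringsAsFactors = FALSE)
  cmp <- sub("^# comparison=", "", meta[startsWith(meta, "# comparison=")])
  attr(out, "comparison") <- if (length(cmp)) cmp[1] else "unnamed"
  class(out) <- c("ranked_list", "data.frame")
  out
}
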