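#' Benjamini-Hochberg step-up adjustment
#'
#' Closed-form step-up false discovery rate adjustment: p-values are
#' multiplied by `n / rank` and a cumulative minimum is taken from the
#' largest p downwards, capped at 1. Equivalent to
#' `stats::p.adjust(p, method = "BH")`; implemented explicitly because the
#' adjustment is part of this pipeline's contract (gene-set nodes are gated
#' at adjusted p < 0.001 and genes at adjusted p < 0.05).
#'
#' @param pvals numeric vector of p-values in \[0, 1\]; NAs are propagated.
#' @return numeric vector of adjusted p-values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(pvals) {
  if (!is.numeric(pvals)) stop("pvals must be numeric")
  ok <- !is.na(pvals)
  p <- pvals[ok]
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  n <- length(p)
  out <- rep(NA_real_, length(pvals))
  if (n > 0) {
    o <- order(p, decreasing = TRUE)
    ro <- order(o)
    adj <- pmin(1, cummin(n / (n:1) * p[o]))[ro]
    out[ok] <- adj
  }
  out
}

# deterministic tokenization of gene-set names for label suggestions
.tokenize_name <- function(x) {
  toks <- unlist(strsplit(tolower(x), "[^a-z0-9]+"))
  toks[nzchar(toks)]
}

.label_stopwords <- c(
  "of", "the", "and", "to", "in", "by", "via", "a", "an", "on", "for",
  "with", "from", "into", "gobp", "gomf", "gocc", "go", "reactome",
  "kegg", "hallmark", "pathway", "process", "regulation", "positive",
  "negative", "set", "gs"
)

# md5 manifest helper (tools::md5sum over files that exist)
.checksum_files <- function(paths) {
  paths <- paths[file.exists(paths)]
  sums <- tools::md5sum(paths)
  stats::setNames(as.character(sums), basename(paths))
}

.assert_scalar_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min ||
      x != as.integer(x)) {
    stop(sprintf("%s must be a single integer >= %d", name, min))
  }
  as.integer(x)
}
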