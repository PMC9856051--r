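# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's vectorized / compiled code paths.

make_ranked <- function(scores, genes = sprintf("g%d", seq_along(scores)),
                        comparison = "test") {
  out <- data.frame(gene = genes, score = scores, stringsAsFactors = FALSE)
  attr(out, "comparison") <- comparison
  class(out) <- c("ranked_list", "data.frame")
  out
}

# plain O(N) running-sum walk; returns NULL when all member weights are zero
oracle_es <- function(scores, hit_pos, weight_p = 1) {
  N <- length(scores)
  n <- length(hit_pos)
  hit <- rep(FALSE, N)
  hit[hit_pos] <- TRUE
  w <- abs(scores)^weight_p
  W <- sum(w[hit_pos])
  if (W == 0) return(NULL)
  run <- 0
  best <- 0
  best_step <- NA_integer_
  for (k in seq_len(N)) {
    run <- run + if (hit[k]) w[k] / W else -1 / (N - n)
    # earliest extremum wins; the 1e-9 tolerance makes exact rational ties
    # reached through different float paths resolve identically
    if (is.na(best_step) || abs(run) > abs(best) + 1e-9) {
      best <- run
      best_step <- k
    }
  }
  le <- if (best >= 0) hit_pos[hit_pos <= best_step] else
    hit_pos[hit_pos > best_step]
  list(es = best, peak = best_step, le_pos = sort(le))
}

# exhaustive gene-sampling null: ES of every size-s subset of 1..N
oracle_null_enum <- function(scores, s) {
  subsets <- utils::combn(length(scores), s)
  apply(subsets, 2, function(h) oracle_es(scores, h)$es)
}

oracle_enum_pvalue <- function(scores, hit_pos, s) {
  obs <- oracle_es(scores, hit_pos)$es
  null <- oracle_null_enum(scores, s)
  same <- if (obs >= 0) null[null > 0] else null[null < 0]
  sum(abs(same) >= abs(obs)) / length(same)
}

# explicit median-of-ratios computation, one ratio at a time
oracle_size_factors <- function(counts) {
  all_pos <- apply(counts, 1, function(r) all(r > 0))
  sub <- counts[all_pos, , drop = FALSE]
  ref <- apply(sub, 1, function(r) prod(r)^(1 / length(r)))
  out <- numeric(ncol(sub))
  for (j in seq_len(ncol(sub))) {
    ratios <- numeric(nrow(sub))
    for (i in seq_len(nrow(sub))) ratios[i] <- sub[i, j] / ref[i]
    out[j] <- stats::median(ratios)
  }
  out
}

# textbook dense MCL with fixed iteration count and union-find extraction;
# mirrors the same self-loop convention but shares no code with the package
reference_mcl <- function(adj, inflation = 2, expansion = 2, prune = 1e-5,
                          iters = 300) {
  n <- nrow(adj)
  mx <- apply(adj, 1, max)
  for (i in seq_len(n)) adj[i, i] <- if (mx[i] > 0) mx[i] else 1
  M <- adj
  for (j in seq_len(n)) M[, j] <- M[, j] / sum(M[, j])
  for (it in seq_len(iters)) {
    E <- diag(n)
    for (e in seq_len(expansion)) E <- E %*% M
    E <- E^inflation
    E[E < prune] <- 0
    for (j in seq_len(n)) {
      if (sum(E[, j]) == 0) E[j, j] <- 1
      E[, j] <- E[, j] / sum(E[, j])
    }
    if (max(abs(E - M)) < 1e-10) {
      M <- E
      break
    }
    M <- E
  }
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  attractors <- which(diag(M) > 0)
  for (a in attractors) {
    for (v in which(M[a, ] > 0)) {
      ra <- find(a)
      rv <- find(v)
      if (ra != rv) parent[rv] <- ra
    }
  }
  vapply(seq_len(n), find, 0L)
}

# label-invariant partition comparison
same_partition <- function(a, b) {
  identical(outer(a, a, "=="), outer(b, b, "=="))
}

adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_idx <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == exp_idx) return(1)
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}

# a minimal enrichment_table for tests that exercise network stages directly
fake_enrichment_table <- function(set, padj, es, le_fraction,
                                  leading_edge = NULL,
                                  comparison = "X_vs_Y") {
  out <- data.frame(set = set, size_in_universe = rep(10L, length(set)),
                    ES = es, NES = es * 2, pval = padj, padj = padj,
                    le_fraction = le_fraction,
                    direction = ifelse(es >= 0, "enriched", "depleted"),
                    stringsAsFactors = FALSE)
  out$leading_edge <- if (is.null(leading_edge)) {
    replicate(length(set), character(0), simplify = FALSE)
  } else {
    leading_edge
  }
  attr(out, "comparison") <- comparison
  attr(out, "nperm") <- 100L
  attr(out, "seed") <- 1L
  attr(out, "weight_p") <- 1
  class(out) <- c("enrichment_table", "data.frame")
  out
}
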