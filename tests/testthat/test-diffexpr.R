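test_that("size factors match forced cases and the brute-force oracle", {
  m <- matrix(c(10L, 20L, 30L, 20L, 40L, 60L), ncol = 2,
              dimnames = list(paste0("g", 1:3), c("a", "b")))
  expect_equal(size_factors(m), c(a = 1 / sqrt(2), b = sqrt(2)))

  same <- cbind(a = c(5L, 8L, 2L), b = c(5L, 8L, 2L), c = c(5L, 8L, 2L))
  expect_equal(unname(size_factors(same)), rep(1, 3))

  set.seed(42)
  for (k in 1:20) {
    m <- matrix(rpois(8 * 4, 30) + 1L, ncol = 4)
    expect_equal(unname(size_factors(m)), oracle_size_factors(m),
                 tolerance = 1e-12)
  }

  # no gene positive everywhere: CPM-style fallback with a warning
  m0 <- rbind(c(5L, 0L), c(0L, 7L))
  expect_warning(sf <- size_factors(m0), "total-count")
  expect_true(all(sf > 0))
  expect_error(size_factors(cbind(c(0L, 0L), c(1L, 2L))), "nonzero")
})

test_that("cpm normalizes to counts per million", {
  m <- matrix(c(500L, 999500L, 250L, 999750L), ncol = 2)
  out <- cpm(m)
  expect_equal(out[1, 1], 500)
  expect_equal(unname(colSums(out)), c(1e6, 1e6))
  m2 <- rbind(m, c(0L, 0L))
  expect_equal(unname(cpm(m2)[3, ]), c(0, 0))
})

test_that("gene_stats computes fold changes and calibrated tests", {
  # identical library sizes -> unit size factors; group means 8 and 2
  counts <- rbind(
    gA = c(8L, 8L, 8L, 2L, 2L, 2L),
    gB = c(2L, 2L, 2L, 8L, 8L, 8L),
    gC = c(5L, 5L, 5L, 5L, 5L, 5L))
  colnames(counts) <- paste0("s", 1:6)
  design <- data.frame(sample = paste0("s", 1:6),
                       group = rep(c("A", "C"), each = 3))
  st <- gene_stats(counts, design, c("A", "C"), pseudocount = 0)
  expect_equal(st$lfc[st$gene == "gA"], 2)
  expect_equal(st$lfc[st$gene == "gB"], -2)
  expect_equal(st$lfc[st$gene == "gC"], 0)
  expect_equal(st$wald_p[st$gene == "gC"], 1)
  expect_true(all(st$padj >= st$wald_p))

  # swapping the contrast negates lfc exactly
  st2 <- gene_stats(counts, design, c("C", "A"), pseudocount = 0)
  expect_equal(st2$lfc, -st$lfc)

  expect_error(gene_stats(counts, design, c("A", "Z")), "contrast")
  d1 <- design
  d1$group[2:3] <- "B"
  expect_error(gene_stats(counts, d1, c("A", "C")), ">= 2 samples")
})

test_that("NB Wald mode agrees with Welch on direction and calibration", {
  study <- simulate_study(simulation_config(
    n_genes = 800, n_sets = 1, seed = 17,
    planted_sets = list(planted_signal("p", "A_vs_C", "enriched",
                                       member_effect_lfc = 2,
                                       responder_fraction = 1, size = 40))))
  w <- gene_stats(study$counts, study$design, c("A", "C"))
  nb <- gene_stats(study$counts, study$design, c("A", "C"),
                   method = "nbwald")
  expect_equal(w$lfc, nb$lfc)  # lfc definition is shared across modes
  resp <- strsplit(study$truth$responders[1], ";")[[1]]
  # detectably expressed responders must all come out significant
  detectable <- nb$gene %in% resp & nb$baseMean > 5
  expect_true(all(nb$padj[detectable] < 0.05))
  expect_gt(mean(nb$padj[nb$gene %in% resp] < 0.05), 0.9)
  expect_gt(cor(w$stat, nb$stat), 0.9)
})

test_that("ridge shrinkage obeys its limits and never amplifies", {
  st <- data.frame(gene = sprintf("g%d", 1:50),
                   lfc = rnorm(50, sd = 3),
                   se = rep(0, 50), stat = rnorm(50))
  expect_equal(shrink_lfc(st)$slfc, st$lfc)  # se = 0: no shrinkage

  set.seed(1)
  noise <- data.frame(gene = sprintf("g%d", 1:200),
                      lfc = rnorm(200, sd = 0.05),
                      se = rep(2, 200), stat = rnorm(200))
  expect_equal(shrink_lfc(noise)$slfc, rep(0, 200))  # pure noise: tau2 = 0

  mixed <- data.frame(gene = sprintf("g%d", 1:300),
                      lfc = rnorm(300, sd = 2), se = runif(300, 0.1, 2),
                      stat = rnorm(300))
  out <- shrink_lfc(mixed)
  expect_true(all(abs(out$slfc) <= abs(out$lfc) + 1e-12))
  expect_true(all(sign(out$slfc) %in% c(0, sign(out$lfc))))

  tiny <- mixed[1:5, ]
  expect_warning(out5 <- shrink_lfc(tiny), "fewer than 10")
  expect_equal(out5$slfc, tiny$lfc)
})

test_that("shrinkage reduces mean squared error against planted truth", {
  study <- simulate_study(simulation_config(
    n_genes = 1500, n_sets = 1, seed = 23,
    planted_sets = list(planted_signal("p", "A_vs_C", "enriched",
                                       member_effect_lfc = 1,
                                       responder_fraction = 1, size = 100))))
  st <- shrink_lfc(gene_stats(study$counts, study$design, c("A", "C")))
  resp <- strsplit(study$truth$responders[1], ";")[[1]]
  true_lfc <- ifelse(st$gene %in% resp, 1, 0)
  mse_raw <- mean((st$lfc - true_lfc)^2)
  mse_shrunk <- mean((st$slfc - true_lfc)^2)
  expect_lt(mse_shrunk, mse_raw)
})

test_that("ranking is a deterministic total order with documented tie-breaks", {
  st <- data.frame(gene = c("g1", "g2", "g3"), lfc = c(2, 0, -1),
                   se = 1, stat = c(1, 0, -1), slfc = c(2, 0, -1))
  rk <- rank_genes(st, "toy")
  expect_equal(rk$gene, c("g1", "g2", "g3"))
  expect_equal(attr(rk, "comparison"), "toy")

  ties <- data.frame(gene = c("b", "a", "c"), lfc = 1, se = 1,
                     stat = c(5, 5, 7), slfc = c(1, 1, 1))
  rk2 <- rank_genes(ties)
  expect_equal(rk2$gene, c("c", "a", "b"))  # stat desc, then gene id

  # contrast reversal reverses the ranking (strict scores)
  study <- simulate_study(simulation_config(n_genes = 300, n_sets = 0,
                                            seed = 29))
  fwd <- shrink_lfc(gene_stats(study$counts, study$design, c("A", "C")))
  rev <- shrink_lfc(gene_stats(study$counts, study$design, c("C", "A")))
  expect_equal(rev$lfc, -fwd$lfc)
  expect_equal(rev$slfc, -fwd$slfc, tolerance = 1e-10)
  strict <- abs(fwd$slfc) > 1e-9 & !duplicated(fwd$slfc) &
    !duplicated(fwd$slfc, fromLast = TRUE)
  rk_f <- rank_genes(fwd)$gene
  rk_r <- rank_genes(rev)$gene
  expect_equal(rk_f[rk_f %in% fwd$gene[strict]],
               rev(rk_r[rk_r %in% fwd$gene[strict]]))
})

test_that("volcano classes follow the padj and fold-change gates", {
  st <- data.frame(gene = paste0("g", 1:6),
                   slfc = c(3, 5, 0.2, -3, -0.5, 1.5),
                   padj = c(0.01, 0.2, 0.01, 0.001, 0.03, 0.04))
  out <- classify_volcano(st)
  expect_equal(out$class,
               c("up", "ns", "significant-only", "down",
                 "significant-only", "up"))
  # literal log2 reading: |slfc| must exceed 2 log2 units
  out2 <- classify_volcano(st, fc_mode = "log2")
  expect_equal(out2$class,
               c("up", "ns", "significant-only", "down",
                 "significant-only", "significant-only"))
})

test_that("RNK files round-trip with their comparison label", {
  rk <- make_ranked(c(2.5, 1, -0.5), comparison = "A_vs_C")
  f <- withr::local_tempfile(fileext = ".rnk")
  write_rnk(rk, f)
  back <- read_rnk(f)
  expect_equal(back$gene, rk$gene)
  expect_equal(back$score, rk$score)
  expect_equal(attr(back, "comparison"), "A_vs_C")
})
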