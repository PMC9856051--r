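test_that("node selection applies both gates strictly", {
  tab <- fake_enrichment_table(
    set = c("keep", "fail_p", "fail_le"),
    padj = c(0.0005, 0.002, 0.0001),
    es = c(0.8, 0.7, -0.6),
    le_fraction = c(0.50, 0.90, 0.20))
  nodes <- select_nodes(tab)
  expect_equal(nodes$set, "keep")

  # perturbing padj across 0.001 or le_fraction across the gate flips
  # membership and nothing else
  tab2 <- tab
  tab2$padj <- c(0.0005, 0.0009, 0.0001)
  tab2$le_fraction <- c(0.50, 0.90, 0.3334)
  expect_equal(select_nodes(tab2)$set, c("keep", "fail_p", "fail_le"))
})

test_that("edge gate uses leading-edge share, weight uses member overlap", {
  universe <- sprintf("u%03d", 1:200)
  m_a <- universe[1:40]
  m_b <- universe[c(21:40, 61:100)]     # |A|=40 |B|=60 overlap 20
  coll <- gene_set_collection(list(A = m_a, B = m_b))
  nodes <- fake_enrichment_table(
    set = c("A", "B"), padj = c(1e-4, 1e-4), es = c(0.9, 0.9),
    le_fraction = c(0.5, 0.5),
    leading_edge = list(universe[c(21:24, 1:6)], universe[c(21:24, 61:70)]))
  edges <- build_edges(nodes, coll, universe)
  expect_equal(nrow(edges), 1)
  expect_equal(edges$le_share, 4 / 40)   # 4 shared LE genes / min(40, 60)
  expect_equal(edges$weight, 20 / 40)    # 20 shared members / min(40, 60)

  jac <- build_edges(nodes, coll, universe, weight_denom = "union")
  expect_equal(jac$weight, 20 / 80)

  # identical member sets give weight 1
  coll2 <- gene_set_collection(list(A = m_a, B = m_a))
  nodes2 <- nodes
  nodes2$leading_edge <- list(m_a[1:10], m_a[1:10])
  expect_equal(build_edges(nodes2, coll2, universe)$weight, 1)

  # disjoint leading edges: no edge despite full member overlap
  nodes3 <- nodes2
  nodes3$leading_edge <- list(m_a[1:5], m_a[11:15])
  expect_equal(nrow(build_edges(nodes3, coll2, universe)), 0)

  # gate is a sharp threshold: 2/40 = 0.05 passes, 1/40 does not
  nodes4 <- nodes
  nodes4$leading_edge <- list(universe[21:22], universe[21:22])
  expect_equal(nrow(build_edges(nodes4, coll, universe)), 1)
  nodes4$leading_edge <- list(universe[21], universe[21])
  expect_equal(nrow(build_edges(nodes4, coll, universe)), 0)
})

test_that("MCL solves the canonical graphs exactly", {
  tri2 <- data.frame(
    from = c("a1", "a2", "a3", "b1", "b2", "b3"),
    to = c("a2", "a3", "a1", "b2", "b3", "b1"),
    weight = 1)
  cl <- mcl_cluster(tri2)
  expect_equal(cl$n_clusters, 2)
  expect_true(cl$converged)
  a <- cl$assignment
  expect_equal(unname(a[c("a1", "a2", "a3")]), rep(a[["a1"]], 3))
  expect_equal(unname(a[c("b1", "b2", "b3")]), rep(a[["b1"]], 3))

  single <- mcl_cluster(data.frame(from = character(0), to = character(0),
                                   weight = numeric(0)), nodes = "lonely")
  expect_equal(single$n_clusters, 1)

  # two 4-cliques joined by a weak bridge split into the two cliques
  cliq <- function(v) t(utils::combn(v, 2))
  e <- rbind(cliq(paste0("x", 1:4)), cliq(paste0("y", 1:4)))
  barbell <- data.frame(from = c(e[, 1], "x1"), to = c(e[, 2], "y1"),
                        weight = c(rep(1, nrow(e)), 0.01))
  cl2 <- mcl_cluster(barbell, inflation = 2.0)
  expect_equal(cl2$n_clusters, 2)
  expect_equal(length(unique(cl2$assignment[paste0("x", 1:4)])), 1)
  expect_equal(length(unique(cl2$assignment[paste0("y", 1:4)])), 1)

  # matches an independently coded dense MCL on the same graph
  nodes <- sort(unique(c(barbell$from, barbell$to)))
  adj <- matrix(0, 8, 8, dimnames = list(nodes, nodes))
  for (k in seq_len(nrow(barbell))) {
    adj[barbell$from[k], barbell$to[k]] <- barbell$weight[k]
    adj[barbell$to[k], barbell$from[k]] <- barbell$weight[k]
  }
  ref <- reference_mcl(adj)
  expect_true(same_partition(unname(cl2$assignment[nodes]), ref))
})

test_that("MCL always yields a partition confined to graph components", {
  set.seed(7)
  for (k in 1:40) {
    n <- sample(5:14, 1)
    nodes <- sprintf("n%02d", seq_len(n))
    pairs <- t(utils::combn(n, 2))
    take <- runif(nrow(pairs)) < 0.25
    edges <- data.frame(from = nodes[pairs[take, 1]],
                        to = nodes[pairs[take, 2]],
                        weight = runif(sum(take), 0.1, 1))
    cl <- mcl_cluster(edges, nodes = nodes)
    # partition: every node exactly once
    expect_setequal(names(cl$assignment), nodes)
    expect_true(all(cl$assignment >= 1))
    # no cluster spans graph components
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = nodes)
    comp <- igraph::components(g)$membership[names(cl$assignment)]
    expect_true(all(tapply(comp, cl$assignment,
                           function(x) length(unique(x))) == 1))
  }
})

test_that("raising inflation never merges the barbell family", {
  cliq <- function(v) t(utils::combn(v, 2))
  e <- rbind(cliq(paste0("x", 1:5)), cliq(paste0("y", 1:5)))
  counts <- vapply(c(1.5, 2.0, 2.5, 3.0), function(r) {
    barbell <- data.frame(from = c(e[, 1], "x1"), to = c(e[, 2], "y1"),
                          weight = c(rep(1, nrow(e)), 0.05))
    mcl_cluster(barbell, inflation = r)$n_clusters
  }, 0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("MCL recovers planted set families from overlap edges", {
  # two families of sets drawing members from disjoint gene pools:
  # within-family overlap creates edges, across families none
  ari <- vapply(1:20, function(s) {
    set.seed(s)
    pool1 <- sprintf("a%03d", 1:60)
    pool2 <- sprintf("b%03d", 1:60)
    sets <- c(lapply(1:6, function(i) sample(pool1, 30)),
              lapply(1:6, function(i) sample(pool2, 30)))
    names(sets) <- sprintf("set%02d", 1:12)
    coll <- gene_set_collection(sets)
    nodes <- fake_enrichment_table(
      set = names(sets), padj = rep(1e-4, 12), es = rep(0.8, 12),
      le_fraction = rep(0.5, 12),
      leading_edge = lapply(sets, function(m) m[1:15]))
    edges <- build_edges(nodes, coll, c(pool1, pool2))
    cl <- mcl_cluster(edges, nodes = names(sets))
    adjusted_rand_index(unname(cl$assignment), rep(1:2, each = 6))
  }, 0)
  expect_true(all(ari >= 0.9))
})

test_that("projection annotates nodes without touching topology", {
  universe <- sprintf("u%03d", 1:100)
  coll <- gene_set_collection(list(A = universe[1:20], B = universe[10:30]))
  anchor <- fake_enrichment_table(
    set = c("A", "B"), padj = c(1e-4, 5e-4), es = c(0.8, -0.7),
    le_fraction = c(0.6, 0.5),
    leading_edge = list(universe[10:15], universe[10:15]),
    comparison = "A_vs_C")
  net <- build_landscape(anchor, coll, universe)
  expect_equal(nrow(net$nodes), 2)
  expect_equal(nrow(net$edges), 1)

  # anchor projected onto itself equals the anchor stats
  ann <- net$annotations[["A_vs_C"]]
  expect_equal(ann$padj, anchor$padj)
  expect_equal(ann$direction, anchor$direction)
  expect_equal(ann$tier, c("p<0.001", "p<0.001"))

  other <- fake_enrichment_table(
    set = c("A", "Z"), padj = c(0.2, 0.01), es = c(0.5, 0.5),
    le_fraction = c(0.5, 0.5), comparison = "A_vs_B")
  before <- net[c("nodes", "edges")]
  net2 <- project_comparison(net, other)
  expect_identical(net2[c("nodes", "edges")], before)
  ann2 <- net2$annotations[["A_vs_B"]]
  expect_equal(ann2$tier, c("ns", "not-tested"))  # padj 0.2; B absent

  empty <- fake_enrichment_table(set = character(0), padj = numeric(0),
                                 es = numeric(0),
                                 le_fraction = numeric(0),
                                 comparison = "empty")
  net3 <- project_comparison(net, empty)
  expect_true(all(net3$annotations[["empty"]]$tier == "not-tested"))
  expect_identical(net3[c("nodes", "edges")], before)
})

test_that("theme summaries are signed log10 adjusted p-values with a cap", {
  universe <- sprintf("u%03d", 1:100)
  coll <- gene_set_collection(list(A = universe[1:20], B = universe[10:30]))
  anchor <- fake_enrichment_table(
    set = c("A", "B"), padj = c(0.001, 0.01), es = c(0.8, -0.7),
    le_fraction = c(0.6, 0.5),
    leading_edge = list(universe[10:15], universe[10:15]),
    comparison = "A_vs_C")
  # padj exactly at a tier boundary stays outside the tier (strict <) but
  # the signed value is exact
  net <- build_landscape(anchor, coll, universe, padj_thr = 0.05)
  ext <- fake_enrichment_table(
    set = c("A", "B"), padj = c(1, 1e-20), es = c(0.5, 0.5),
    le_fraction = c(0.5, 0.5), comparison = "X_vs_Y")
  net <- project_comparison(net, ext)
  cl <- mcl_cluster(net$edges, nodes = net$nodes$set)
  th <- theme_signed_pvalues(net, cl)
  expect_equal(th$value[th$comparison == "A_vs_C" & th$set == "A"], 3)
  expect_equal(th$value[th$comparison == "A_vs_C" & th$set == "B"], -2)
  expect_equal(th$value[th$comparison == "X_vs_Y" & th$set == "A"], 0)
  expect_equal(th$value[th$comparison == "X_vs_Y" & th$set == "B"], 16)
})

test_that("label suggestions rank informative tokens deterministically", {
  nm <- c("GOBP_INTERLEUKIN_7_SIGNALING", "REACTOME_INTERLEUKIN_7_RESPONSE",
          "INTERLEUKIN_12_PRODUCTION")
  toks <- suggest_labels(nm)
  expect_equal(toks[1], "interleukin")
  expect_equal(toks[2], "7")  # frequency 2, before the frequency-1 tokens
  expect_equal(suggest_labels("ALPHA_BETA")[1], "alpha")  # lexicographic tie
  expect_error(suggest_labels(character(0)), "empty")
})

test_that("network export round-trips through GraphML and TSV", {
  universe <- sprintf("u%03d", 1:100)
  coll <- gene_set_collection(list(A = universe[1:20], B = universe[10:30],
                                   C = universe[15:35]))
  anchor <- fake_enrichment_table(
    set = c("A", "B", "C"), padj = c(1e-4, 5e-4, 2e-4),
    es = c(0.8, -0.7, 0.6), le_fraction = c(0.6, 0.5, 0.55),
    leading_edge = list(universe[10:18], universe[10:18], universe[15:20]),
    comparison = "A_vs_C")
  net <- build_landscape(anchor, coll, universe)
  cl <- mcl_cluster(net$edges, nodes = net$nodes$set)
  prefix <- file.path(withr::local_tempdir(), "net")
  paths <- export_network(net, cl, prefix)
  g <- igraph::read_graph(paths[["graphml"]], format = "graphml")
  expect_setequal(igraph::V(g)$name, net$nodes$set)
  expect_equal(igraph::ecount(g), nrow(net$edges))
  expect_equal(sort(igraph::E(g)$weight), sort(net$edges$weight),
               tolerance = 1e-6)
  nd <- utils::read.delim(paths[["nodes"]], comment.char = "#")
  expect_setequal(nd$name, net$nodes$set)
  expect_setequal(nd$cluster, cl$assignment[nd$name])

  # empty scaffold still exports valid files
  none <- select_nodes(anchor, padj_thr = 1e-9)
  net0 <- build_landscape(fake_enrichment_table(
    set = character(0), padj = numeric(0), es = numeric(0),
    le_fraction = numeric(0), comparison = "A_vs_C"), coll, universe)
  p0 <- export_network(net0, NULL, file.path(withr::local_tempdir(), "e"))
  g0 <- igraph::read_graph(p0[["graphml"]], format = "graphml")
  expect_equal(igraph::vcount(g0), 0)
})
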