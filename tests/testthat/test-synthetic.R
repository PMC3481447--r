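test_that("scale-free generator is deterministic, connected and heavy-tailed", {
  g1 <- sample_ppi_network(200, 3, seed = 5)
  g2 <- sample_ppi_network(200, 3, seed = 5)
  expect_identical(igraph::as_edgelist(g1), igraph::as_edgelist(g2))
  expect_true(igraph::is_connected(g1))
  deg <- igraph::degree(g1)
  expect_gt(max(deg), 4 * median(deg))

  tree <- sample_ppi_network(10, 1, seed = 1)
  expect_equal(igraph::ecount(tree), 9)
  expect_error(sample_ppi_network(3, 3), "n_nodes")
})

test_that("planted connectors and DE genes are disjoint, sized and hub-like", {
  net <- sample_ppi_network(500, 3, seed = 1)
  pl <- plant_connectors(net, n_de = 60, n_connectors = 10, seed = 2)
  expect_identical(length(pl$de_genes), 60L)
  expect_identical(length(pl$connectors), 10L)
  expect_length(intersect(pl$de_genes, pl$connectors), 0)
  expect_true(all(c(pl$de_genes, pl$connectors) %in% igraph::V(net)$name))
  # connectors are pairwise non-adjacent high-degree nodes
  sub <- igraph::induced_subgraph(net, pl$connectors)
  expect_equal(igraph::ecount(sub), 0)
  expect_gt(min(igraph::degree(net, pl$connectors)),
            median(igraph::degree(net)))
  expect_error(plant_connectors(net, n_de = 490, n_connectors = 20), "exceeds")
})

test_that("star graph planting picks the center as the connector", {
  g <- star4()
  pl <- plant_connectors(g, n_de = 3, n_connectors = 1, seed = 1)
  expect_identical(pl$connectors, "hub")
  expect_setequal(pl$de_genes, c("a", "b", "d"))
})

test_that("a connector whose removal separates DE genes always becomes an STM", {
  net <- sample_ppi_network(300, 1, seed = 3)   # a tree: many cut vertices
  pl <- plant_connectors(net, n_de = 20, n_connectors = 4, seed = 4)
  s <- discover_stms(net, pl$de_genes, max_iterations = 5, patience = 5,
                     seed = 5)
  for (v in pl$connectors) {
    rest <- igraph::delete_vertices(net, v)
    comp <- igraph::components(rest)$membership[match(pl$de_genes,
                                                      igraph::V(rest)$name)]
    if (length(unique(comp)) > 1) {
      expect_true(v %in% s$genes,
                  label = sprintf("cut vertex %s present in STMs", v))
    }
  }
})

test_that("expression simulation is reproducible and calibrated", {
  genes <- sprintf("g%03d", 1:150)
  de <- genes[1:40]
  e1 <- simulate_expression(genes, de, n_samples = 100, seed = 6)
  e2 <- simulate_expression(genes, de, n_samples = 100, seed = 6)
  expect_identical(e1$expr, e2$expr)
  expect_identical(sum(e1$labels), 50L)

  # null: no effect, rejection near the nominal alpha
  e0 <- simulate_expression(genes, character(0), n_samples = 200, seed = 7)
  p0 <- de_ttest(e0$expr, e0$labels)
  expect_lt(mean(p0 < 0.05), 0.12)
  # 2 SD shift on 200 samples: essentially every DE gene detected
  e2sd <- simulate_expression(genes, de, n_samples = 200,
                              effect_size = 2, seed = 8)
  pde <- de_ttest(e2sd$expr, e2sd$labels)[de]
  expect_gt(mean(pde < 0.001), 0.95)
  # class means differ by effect*sd on DE genes, not on the rest
  shift <- rowMeans(e2sd$expr[, e2sd$labels == 1]) -
    rowMeans(e2sd$expr[, e2sd$labels == 0])
  expect_equal(unname(mean(shift[de])), 2, tolerance = 0.15)
  expect_equal(unname(mean(shift[setdiff(genes, de)])), 0, tolerance = 0.1)
})

test_that("scenario assembly is a pure function of its seed", {
  s1 <- synthetic_scenario(n_nodes = 150, n_de = 20, n_connectors = 4,
                           n_samples = 30, seed = 10)
  s2 <- synthetic_scenario(n_nodes = 150, n_de = 20, n_connectors = 4,
                           n_samples = 30, seed = 10)
  expect_identical(s1$de_genes, s2$de_genes)
  expect_identical(s1$expr, s2$expr)
  expect_identical(igraph::as_edgelist(s1$network),
                   igraph::as_edgelist(s2$network))
  expect_length(intersect(s1$de_genes, s1$connectors), 0)

  tdir <- withr::local_tempdir()
  paths <- write_scenario(s1, tdir)
  expect_true(all(file.exists(paths)))
  g <- read_edge_list(paths[["network"]])
  expect_identical(igraph::vcount(g), igraph::vcount(s1$network))
  expect_identical(read_gene_list(paths[["de"]]), s1$de_genes)
  expect_identical(read_labels(paths[["labels"]]), s1$labels)
  expect_equal(read_expression(paths[["expr"]]), s1$expr, tolerance = 1e-10)
})

test_that("mini end-to-end: STMs enrich for planted connectors", {
  sc <- synthetic_scenario(n_nodes = 400, n_de = 40, n_connectors = 8,
                           n_samples = 40, seed = 20)
  s <- discover_stms(sc$network, sc$de_genes, max_iterations = 30,
                     patience = 30, seed = 21)
  cov <- known_marker_coverage(s, sc$connectors, igraph::vcount(sc$network))
  expect_gt(cov$coverage, 0.5)
  expect_lt(cov$overlap$p_value, 0.05)
})
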