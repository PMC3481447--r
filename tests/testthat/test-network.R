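test_that("edge-list loading collapses duplicates and drops self-loops", {
  tf <- withr::local_tempfile(lines = c("# comment", "A B", "B A", "B C", "A A"))
  g <- read_edge_list(tf)
  expect_setequal(igraph::V(g)$name, c("A", "B", "C"))
  expect_equal(igraph::ecount(g), 2)
  expect_identical(igraph::graph_attr(g, "self_loops"), 1L)
  expect_identical(igraph::graph_attr(g, "duplicate_edges"), 1L)
  expect_equal(igraph::E(g)$weight, c(1, 1))
})

test_that("weighted, SIF and malformed inputs are handled", {
  tf <- withr::local_tempfile(lines = c("A\tB\t0.5", "B\tC\t2"))
  g <- read_edge_list(tf)
  expect_equal(sort(igraph::E(g)$weight), c(0.5, 2))

  sif <- withr::local_tempfile(lines = c("A interaction B", "B pp C"))
  gs <- read_edge_list(sif, sif = TRUE)
  expect_setequal(igraph::V(gs)$name, c("A", "B", "C"))
  expect_equal(igraph::ecount(gs), 2)

  bad <- withr::local_tempfile(lines = c("A B", "LONELY"))
  expect_error(read_edge_list(bad), "malformed.*line 2")
  empty <- withr::local_tempfile(lines = "# nothing")
  expect_error(read_edge_list(empty), "empty")
  negw <- withr::local_tempfile(lines = "A\tB\t-1")
  expect_error(read_edge_list(negw), "positive")
})

test_that("edge lists round-trip through write and load", {
  g <- sample_ppi_network(400, 2, seed = 11)
  tf <- withr::local_tempfile()
  write_edge_list(g, tf)
  g2 <- read_edge_list(tf)
  key <- function(gr) {
    el <- igraph::as_edgelist(gr, names = TRUE)
    sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
  }
  expect_identical(key(g2), key(g))
  # idempotence under re-serialization
  tf2 <- withr::local_tempfile()
  write_edge_list(g2, tf2)
  expect_identical(key(read_edge_list(tf2)), key(g))
})

test_that("largest component extraction is correct and tie-stable", {
  # tie in size: component holding the lexicographically smallest name wins
  g <- named_graph(cbind(c("A", "C"), c("B", "D")))
  lcc <- largest_component(g)
  expect_setequal(igraph::V(lcc)$name, c("A", "B"))

  g2 <- named_graph(cbind(c("a", "b"), c("b", "c")))
  g2 <- igraph::add_vertices(g2, 1, name = "d")
  lcc2 <- largest_component(g2)
  expect_setequal(igraph::V(lcc2)$name, c("a", "b", "c"))
  expect_equal(igraph::ecount(lcc2), 2)
  expect_error(largest_component(igraph::make_empty_graph()), "empty")
})

test_that("largest component dominates all components (union-find oracle)", {
  set.seed(401)
  for (rep in 1:12) {
    n <- sample(20:200, 1)
    g <- igraph::sample_gnp(n, 1.2 / n)
    igraph::V(g)$name <- sprintf("v%03d", seq_len(n))
    sizes <- table(uf_components(g))
    lcc <- largest_component(g)
    expect_equal(as.numeric(igraph::vcount(lcc)), as.numeric(max(sizes)))
    expect_true(igraph::is_connected(lcc))
  }
})

test_that("two-component synthetic graph yields the 900-node component", {
  a <- sample_ppi_network(900, 2, seed = 5)
  b <- sample_ppi_network(100, 2, seed = 6)
  igraph::V(b)$name <- paste0("x", igraph::V(b)$name)
  g <- igraph::disjoint_union(a, b)
  lcc <- largest_component(g)
  expect_equal(igraph::vcount(lcc), 900)
  expect_true(igraph::is_connected(lcc))
})

test_that("terminal restriction partitions the query set", {
  g <- named_graph(cbind(c("A", "B"), c("B", "C")))
  expect_warning(ts <- restrict_terminals(g, c("A", "C", "X")), "dropped")
  expect_setequal(ts$terminals, c("A", "C"))
  expect_identical(ts$dropped, "X")
  expect_error(restrict_terminals(g, c("X", "Y")), "no terminal maps")
  expect_error(restrict_terminals(g, character(0)), "empty")

  net <- sample_ppi_network(500, 3, seed = 2)
  planted <- plant_connectors(net, n_de = 60, n_connectors = 8, seed = 3)
  query <- c(planted$de_genes, sprintf("absent%02d", 1:10))
  expect_warning(ts2 <- restrict_terminals(net, query))
  expect_identical(length(ts2$terminals), 60L)
  expect_identical(length(ts2$dropped), 10L)
  expect_identical(length(ts2$terminals) + length(ts2$dropped),
                   length(unique(query)))
})
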