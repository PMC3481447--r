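test_that("weight perturbation stays in band, is seed-reproducible and pure", {
  g <- sample_ppi_network(120, 2, seed = 4)
  set.seed(1)
  gp <- perturb_weights(g)
  w <- igraph::E(gp)$weight
  expect_true(all(w >= 0.99 & w < 1.0))
  expect_equal(igraph::E(g)$weight, rep(1, igraph::ecount(g)))  # input untouched
  set.seed(1)
  expect_identical(igraph::E(perturb_weights(g))$weight, w)
  set.seed(2)
  expect_true(any(igraph::E(perturb_weights(g))$weight != w))
  expect_error(perturb_weights(g, low = 1, high = 0.5), "low < high")
})

test_that("near-degenerate perturbation band reduces to hop-count paths", {
  g <- ring4()
  # one long cheap detour vs a short path: with an epsilon band the
  # 2-edge connections always beat any longer alternative
  gp <- perturb_weights(g, low = 1 - 1e-9, high = 1)
  st <- steiner_tree(gp, c("a", "c"))
  expect_equal(igraph::ecount(st$tree), 2)
})

test_that("a forced unique solution saturates immediately and stops on patience", {
  s <- discover_stms(star4(), c("a", "b", "d"), max_iterations = 100,
                     patience = 7, seed = 3)
  expect_identical(s$genes, "hub")
  expect_identical(s$n_iterations, 8L)          # 1 discovery + 7 patience
  expect_identical(s$per_iteration_new, c(1L, rep(0L, 7)))
  expect_identical(unname(s$frequency["hub"]), 8L)
})

test_that("the ensemble captures both alternative connectors on a cycle", {
  s <- discover_stms(ring4(), c("a", "c"), max_iterations = 50,
                     patience = 25, seed = 1)
  expect_setequal(s$genes, c("b", "d"))
})

test_that("discovery is reproducible and its trace is consistent", {
  net <- sample_ppi_network(300, 3, seed = 7)
  pl <- plant_connectors(net, n_de = 40, n_connectors = 6, seed = 8)
  s1 <- discover_stms(net, pl$de_genes, max_iterations = 40, patience = 40,
                      seed = 11, keep_trees = TRUE)
  s2 <- discover_stms(net, pl$de_genes, max_iterations = 40, patience = 40,
                      seed = 11)
  expect_identical(s1$genes, s2$genes)
  expect_identical(s1$per_iteration_new, s2$per_iteration_new)
  # sum of per-iteration new genes equals the set size; cumulative counts
  # are non-decreasing by construction
  expect_identical(sum(s1$per_iteration_new), length(s1$genes))
  expect_true(all(diff(cumsum(s1$per_iteration_new)) >= 0))
  # different seed explores differently
  s3 <- discover_stms(net, pl$de_genes, max_iterations = 40, patience = 40,
                      seed = 12)
  expect_false(identical(s1$per_iteration_new, s3$per_iteration_new))
})

test_that("early stopping does not change what was discovered up to the stop", {
  net <- sample_ppi_network(200, 2, seed = 13)
  R <- sample_terminals <- igraph::V(net)$name[seq(1, 200, by = 20)]
  long <- discover_stms(net, R, max_iterations = 60, patience = 60, seed = 5)
  short <- discover_stms(net, R, max_iterations = 60, patience = 5, seed = 5)
  k <- short$n_iterations
  expect_identical(short$per_iteration_new, long$per_iteration_new[1:k])
  expect_identical(short$genes, long$genes[seq_len(length(short$genes))])
})

test_that("every STM is an internal vertex of at least one ensemble tree", {
  net <- sample_ppi_network(150, 2, seed = 21)
  R <- igraph::V(net)$name[seq(5, 150, by = 15)]
  s <- discover_stms(net, R, max_iterations = 20, patience = 20, seed = 9)
  # replay the ensemble through the public single-tree interface
  seen <- character(0)
  for (i in seq_len(s$n_iterations)) {
    set.seed(stmarker:::substream_seed(9, i))
    gp <- perturb_weights(net)
    seen <- union(seen, internal_vertices(steiner_tree(gp, R)))
  }
  expect_setequal(s$genes, seen)
  expect_true(all(s$frequency >= 1))
})

test_that("stability report delegates to the overlap statistics", {
  a <- structure(list(genes = c("x", "y", "z")), class = "stm_set")
  b <- structure(list(genes = c("y", "z", "w", "u")), class = "stm_set")
  ov <- stability_report(a, b, N = 100)
  expect_identical(c(ov$m, ov$n, ov$o), c(3L, 4L, 2L))
  expect_equal(ov$percent, 100 * 2 / 5)
  expect_error(stability_report(a, b, N = 4), "background")
})
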