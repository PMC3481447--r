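# fixtures built in code: toy graphs, random graphs, independent oracles

named_graph <- function(edges, weights = NULL) {
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::E(g)$weight <- if (is.null(weights)) rep(1, nrow(edges)) else weights
  g
}

# path a - b - c - d, unit weights
path4 <- function() {
  named_graph(cbind(c("a", "b", "c"), c("b", "c", "d")))
}

# star with center "hub" and leaves a, b, d
star4 <- function() {
  named_graph(cbind(rep("hub", 3), c("a", "b", "d")))
}

# 4-cycle a - b - c - d - a
ring4 <- function() {
  named_graph(cbind(c("a", "b", "c", "d"), c("b", "c", "d", "a")))
}

# triangle with corners at pairwise weight 2 and a cheap unit-weight hub
triangle_hub <- function() {
  named_graph(cbind(c("A", "B", "C", "H", "H", "H"),
                    c("B", "C", "A", "A", "B", "C")),
              weights = c(2, 2, 2, 1, 1, 1))
}

# random connected G(n, p) graph with unit weights and named vertices
random_connected_graph <- function(n, p = 0.35) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g) && igraph::ecount(g) > 0) break
  }
  igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
  igraph::E(g)$weight <- 1
  g
}

# independent connected-components labelling by plain union-find
uf_components <- function(net) {
  n <- igraph::vcount(net)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  el <- matrix(as.integer(igraph::as_edgelist(net, names = FALSE)), ncol = 2)
  for (k in seq_len(nrow(el))) {
    a <- find(el[k, 1L]); b <- find(el[k, 2L])
    if (a != b) parent[b] <- a
  }
  roots <- vapply(seq_len(n), function(i) as.integer(find(i)), integer(1))
  stats::setNames(match(roots, unique(roots)), igraph::V(net)$name)
}

# check every structural invariant a Steiner tree must satisfy
expect_valid_steiner_tree <- function(st, net, R) {
  tr <- st$tree
  vn <- igraph::V(tr)$name
  expect_true(igraph::is_connected(tr))
  expect_equal(igraph::ecount(tr), igraph::vcount(tr) - 1)
  expect_true(all(R %in% vn))
  deg <- igraph::degree(tr)
  leaves <- vn[deg <= 1L]
  expect_true(all(leaves %in% R))
  # tree edges are network edges with matching weights
  key <- function(el) paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  nel <- igraph::as_edgelist(net, names = TRUE)
  tel <- igraph::as_edgelist(tr, names = TRUE)
  expect_true(all(key(tel) %in% key(nel)))
  netw <- stats::setNames(igraph::E(net)$weight, key(nel))
  if (nrow(tel) > 0) {
    expect_equal(sum(netw[key(tel)]), st$total_weight, tolerance = 1e-12)
    expect_equal(st$total_weight, sum(igraph::E(tr)$weight),
                 tolerance = 1e-12)
  }
  invisible(st)
}

# exact hypergeometric upper tail by direct rational enumeration,
# independent of the package's log-space route
enum_upper_tail <- function(N, m, n, o) {
  i <- o:min(m, n)
  terms <- choose(m, i) * choose(N - m, n - i) / choose(N, n)
  sum(terms)
}
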