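#' Generate a synthetic scale-free interaction network
#'
#' Preferential-attachment (Barabási–Albert) graph as a stand-in for a PPI
#' network: connected, undirected, unit edge weights, heavy-tailed degree
#' distribution with a few hubs — the topological feature the marker
#' discovery relies on. Vertex names are zero-padded (\code{g0001}, ...).
#'
#' @param n_nodes number of genes.
#' @param edges_per_node edges added per new node (attachment parameter;
#'   1 gives a tree). Requires \code{n_nodes >= edges_per_node + 1}.
#' @param seed integer seed; the generator is a pure function of it.
#' @return an undirected \pkg{igraph} graph with unit weights.
#' @export
sample_ppi_network <- function(n_nodes, edges_per_node = 3L, seed = 1L) {
  if (n_nodes < edges_per_node + 1L) {
    stop("need n_nodes >= edges_per_node + 1")
  }
  set.seed(seed)
  g <- igraph::sample_pa(n_nodes, m = edges_per_node, directed = FALSE)
  igraph::V(g)$name <- sprintf(paste0("g%0", nchar(n_nodes), "d"),
                               seq_len(n_nodes))
  igraph::E(g)$weight <- 1
  g
}

#' Plant connector ("disease") genes and a DE seed set
#'
#' Chooses \code{n_connectors} high-degree, pairwise non-adjacent hub nodes
#' as hidden connectors, then draws the \code{n_de} differentially
#' expressed seed genes from the connectors' immediate neighborhoods
#' (topping up from the remaining nodes only if the neighborhoods are too
#' small). By construction the connectors sit on many shortest paths
#' between DE genes — the topology the marker discovery is meant to
#' exploit — while never being DE themselves.
#'
#' @param net an undirected \pkg{igraph} graph with named vertices.
#' @param n_de number of DE seed genes.
#' @param n_connectors number of planted connectors.
#' @param seed integer seed.
#' @return list with character vectors \code{de_genes} and
#'   \code{connectors} (disjoint).
#' @export
plant_connectors <- function(net, n_de = 100L, n_connectors = 20L, seed = 1L) {
  if (n_de + n_connectors > igraph::vcount(net)) {
    stop("n_de + n_connectors exceeds the number of nodes")
  }
  set.seed(seed)
  vn <- igraph::V(net)$name
  deg <- igraph::degree(net)
  ord <- vn[order(-deg, vn)]
  connectors <- character(0)
  for (v in ord) {
    if (length(connectors) == n_connectors) break
    nb <- igraph::neighbors(net, v)$name
    if (!any(nb %in% connectors)) connectors <- c(connectors, v)
  }
  if (length(connectors) < n_connectors) {
    stop("only ", length(connectors),
         " pairwise non-adjacent hubs available; reduce n_connectors")
  }
  pool <- setdiff(unique(unlist(
    lapply(connectors, function(v) igraph::neighbors(net, v)$name))),
    connectors)
  if (length(pool) >= n_de) {
    de <- sample(pool, n_de)
  } else {
    rest <- setdiff(vn, c(connectors, pool))
    de <- c(pool, sample(rest, n_de - length(pool)))
  }
  list(de_genes = de, connectors = connectors)
}

#' Simulate a two-class expression matrix
#'
#' Independent Gaussian expression for every gene; the DE genes get a mean
#' shift of \code{effect_size * noise_sd} in class 1 (the event class),
#' all other genes have identical class means. Classes are split evenly.
#'
#' @param genes character vector of gene identifiers (matrix rows).
#' @param de_genes subset of \code{genes} receiving the class-1 shift.
#' @param n_samples total samples (>= 20; split evenly between classes).
#' @param effect_size mean shift in units of \code{noise_sd}.
#' @param noise_sd within-class standard deviation.
#' @param seed integer seed.
#' @return list with \code{expr} (genes x samples matrix) and
#'   \code{labels} (named 0/1 vector).
#' @export
simulate_expression <- function(genes, de_genes, n_samples = 200L,
                                effect_size = 2, noise_sd = 1, seed = 1L) {
  if (n_samples < 20L) stop("need at least 20 samples")
  stopifnot(all(de_genes %in% genes))
  set.seed(seed)
  n1 <- n_samples %/% 2L
  labels <- c(rep(0L, n_samples - n1), rep(1L, n1))
  samples <- sprintf("s%03d", seq_len(n_samples))
  names(labels) <- samples
  expr <- matrix(stats::rnorm(length(genes) * n_samples, sd = noise_sd),
                 nrow = length(genes), dimnames = list(genes, samples))
  expr[de_genes, labels == 1L] <- expr[de_genes, labels == 1L] +
    effect_size * noise_sd
  list(expr = expr, labels = labels)
}

#' Per-gene two-sample t-test p-values
#'
#' Welch t-test of each gene's expression between the two classes; a small
#' calibration utility for synthetic data, not a DE-selection method.
#'
#' @param expr genes x samples matrix.
#' @param labels 0/1 vector aligned with columns.
#' @return named vector of p-values.
#' @export
de_ttest <- function(expr, labels) {
  labels <- as.integer(labels)
  apply(expr, 1L, function(x) stats::t.test(x[labels == 1L],
                                            x[labels == 0L])$p.value)
}

#' Build a complete synthetic benchmark scenario
#'
#' Convenience wrapper chaining \code{\link{sample_ppi_network}},
#' \code{\link{plant_connectors}} and \code{\link{simulate_expression}}
#' with sub-seeds derived from one master seed. The defaults define the
#' package's reference benchmark: a 2000-gene scale-free network, 100 DE
#' seeds drawn around 20 planted hub connectors, and a 200-sample
#' expression matrix with a 2-SD class shift on the DE genes.
#'
#' @inheritParams sample_ppi_network
#' @inheritParams plant_connectors
#' @inheritParams simulate_expression
#' @param seed master seed.
#' @return object of class \code{stm_scenario}: list with \code{network},
#'   \code{de_genes}, \code{connectors}, \code{expr}, \code{labels},
#'   \code{params}.
#' @export
synthetic_scenario <- function(n_nodes = 2000L, edges_per_node = 3L,
                               n_de = 100L, n_connectors = 20L,
                               n_samples = 200L, effect_size = 2,
                               noise_sd = 1, seed = 1L) {
  net <- sample_ppi_network(n_nodes, edges_per_node,
                            seed = substream_seed(seed, 1L))
  planted <- plant_connectors(net, n_de, n_connectors,
                              seed = substream_seed(seed, 2L))
  ex <- simulate_expression(igraph::V(net)$name, planted$de_genes,
                            n_samples, effect_size, noise_sd,
                            seed = substream_seed(seed, 3L))
  structure(list(network = net, de_genes = planted$de_genes,
                 connectors = planted$connectors,
                 expr = ex$expr, labels = ex$labels,
                 params = list(n_nodes = n_nodes,
                               edges_per_node = edges_per_node,
                               n_de = n_de, n_connectors = n_connectors,
                               n_samples = n_samples,
                               effect_size = effect_size,
                               noise_sd = noise_sd, seed = seed)),
            class = "stm_scenario")
}

#' @export
print.stm_scenario <- function(x, ...) {
  p <- x$params
  cat("Synthetic scenario:", p$n_nodes, "genes,",
      igraph::ecount(x$network), "interactions;",
      p$n_de, "DE seeds around", p$n_connectors, "planted connectors;",
      p$n_samples, "samples (effect", p$effect_size, "SD)\n")
  invisible(x)
}

#' Write a scenario's files to a directory
#'
#' Writes \code{edges.tsv}, \code{de.txt}, \code{connectors.txt},
#' \code{expr.tsv} and \code{labels.tsv} in the formats the loaders of this
#' package read.
#'
#' @param scenario an \code{stm_scenario}.
#' @param dir output directory (created if needed).
#' @return named character vector of the file paths, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(network = file.path(dir, "edges.tsv"),
             de = file.path(dir, "de.txt"),
             connectors = file.path(dir, "connectors.txt"),
             expr = file.path(dir, "expr.tsv"),
             labels = file.path(dir, "labels.tsv"))
  write_edge_list(scenario$network, paths[["network"]])
  writeLines(scenario$de_genes, paths[["de"]])
  writeLines(scenario$connectors, paths[["connectors"]])
  write_expression(scenario$expr, paths[["expr"]])
  write_labels(scenario$labels, paths[["labels"]])
  invisible(paths)
}
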