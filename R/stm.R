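#' Randomly perturb edge weights to break ties
#'
#' Returns a copy of the network with every edge weight drawn independently
#' and uniformly from \code{[low, high)}. With the default narrow band just
#' below 1, shortest paths remain (near-)hop-count paths, but among paths of
#' equal hop count one is chosen at random — the randomization that drives
#' the ensemble of alternative Steiner trees.
#'
#' Uses the current RNG state; seed management belongs to the caller (see
#' \code{\link{discover_stms}} for per-iteration substreams).
#'
#' @param net an undirected \pkg{igraph} graph.
#' @param low,high bounds of the uniform weight band; \code{0 < low < high}.
#' @return the perturbed graph; the input is not modified.
#' @export
perturb_weights <- function(net, low = 0.99, high = 1.0) {
  if (!(low > 0 && low < high)) stop("need 0 < low < high")
  igraph::E(net)$weight <- stats::runif(igraph::ecount(net), min = low, max = high)
  net
}

substream_seed <- function(seed, i) {
  as.integer((as.double(seed) %% 2147483647 + 10007 * as.double(i)) %% 2147483647)
}

#' Discover Steiner-tree-based markers (STMs)
#'
#' Runs the randomized Steiner tree ensemble: at each iteration every edge
#' of the network receives a fresh random weight in
#' \code{[weight_low, weight_high)}, a Steiner tree over the terminal (seed)
#' genes is built with \code{\link{steiner_tree}}, and the tree's internal
#' vertices (\code{\link{internal_vertices}}) are added to the running
#' union. The union — Steiner vertices plus internal terminals, accumulated
#' across trees — is the STM set. Iteration stops when \code{patience}
#' consecutive iterations contribute no new gene, or after
#' \code{max_iterations}.
#'
#' Each iteration reseeds the RNG deterministically from
#' \code{(seed, iteration)}, so a run is reproducible and unaffected by
#' where early stopping triggers.
#'
#' @param net an undirected \pkg{igraph} graph (use
#'   \code{\link{largest_component}} first). Any existing edge weights are
#'   replaced by the random perturbation.
#' @param terminals character vector or \code{terminal_set} of seed genes;
#'   all must lie in one component of \code{net}.
#' @param max_iterations maximum number of randomized trees (default 500).
#' @param patience stop after this many consecutive iterations that add no
#'   new marker (default 50); must not exceed \code{max_iterations}.
#' @param weight_low,weight_high the perturbation band (default
#'   \code{[0.99, 1)}).
#' @param seed integer master seed.
#' @param keep_trees also return a per-iteration summary (vertex and edge
#'   counts, weight) of every tree.
#' @param verbose print a progress line per iteration.
#' @return an object of class \code{stm_set}: list with \code{genes} (the
#'   markers, in order of first appearance), \code{n_iterations},
#'   \code{per_iteration_new} (new markers added at each iteration),
#'   \code{frequency} (named count: in how many trees each marker was
#'   internal), \code{terminals}, \code{config}, and optionally
#'   \code{trees}.
#' @examples
#' g <- igraph::make_ring(4)
#' igraph::V(g)$name <- c("a", "b", "c", "d")
#' stm <- discover_stms(g, c("a", "c"), max_iterations = 30,
#'                      patience = 10, seed = 1)
#' sort(stm$genes)   # both alternative connectors "b" and "d"
#' @export
discover_stms <- function(net, terminals,
                          max_iterations = 500L, patience = 50L,
                          weight_low = 0.99, weight_high = 1.0,
                          seed = 1L, keep_trees = FALSE, verbose = FALSE) {
  stopifnot(max_iterations >= 1L, patience >= 1L)
  if (patience > max_iterations) stop("patience must be <= max_iterations")
  if (!(weight_low > 0 && weight_low < weight_high)) {
    stop("need 0 < weight_low < weight_high")
  }
  R <- as_terminals(terminals)
  missing <- setdiff(R, igraph::V(net)$name)
  if (length(missing) > 0L) {
    stop("terminal(s) not in network: ", paste(missing, collapse = ", "))
  }
  check_one_component(net, R)

  # the graph topology is fixed across iterations: map names to the
  # compiled core's id space once, and redraw only the weight vector
  nm <- igraph::V(net)$name
  ordnm <- sort(nm)
  id <- match(nm, ordnm) - 1L
  el <- igraph::as_edgelist(net, names = FALSE)
  ei <- id[el[, 1L]]
  ej <- id[el[, 2L]]
  tid <- id[match(R, nm)]
  m <- igraph::ecount(net)

  genes <- character(0)
  freq <- integer(0)
  per_new <- integer(max_iterations)
  trees <- if (keep_trees) vector("list", max_iterations) else NULL
  streak <- 0L
  n_done <- 0L
  for (i in seq_len(max_iterations)) {
    set.seed(substream_seed(seed, i))
    w <- stats::runif(m, min = weight_low, max = weight_high)
    if (length(R) > 1L) {
      res <- .steiner_sph_cpp(length(nm), ei, ej, w, tid)
      deg <- tabulate(c(res$edge_i, res$edge_j) + 1L, nbins = length(nm))
      iv <- ordnm[deg > 1L]
    } else {
      res <- list(vertices = tid, edge_i = integer(0), edge_j = integer(0),
                  total_weight = 0)
      iv <- character(0)
    }
    newg <- setdiff(iv, genes)
    genes <- c(genes, newg)
    freq <- c(freq, stats::setNames(integer(length(newg)), newg))
    freq[iv] <- freq[iv] + 1L
    per_new[i] <- length(newg)
    if (keep_trees) {
      trees[[i]] <- list(n_vertices = length(res$vertices),
                         n_edges = length(res$edge_i),
                         total_weight = res$total_weight,
                         n_internal = length(iv))
    }
    n_done <- i
    if (verbose) {
      message(sprintf("iter %d: tree %d vertices, %d new STMs (total %d)",
                      i, length(res$vertices), length(newg), length(genes)))
    }
    streak <- if (length(newg) == 0L) streak + 1L else 0L
    if (streak >= patience) break
  }

  structure(list(
    genes = genes,
    n_iterations = n_done,
    per_iteration_new = per_new[seq_len(n_done)],
    frequency = freq,
    terminals = R,
    config = list(max_iterations = max_iterations, patience = patience,
                  weight_low = weight_low, weight_high = weight_high,
                  seed = seed),
    trees = if (keep_trees) trees[seq_len(n_done)] else NULL
  ), class = "stm_set")
}

#' @export
print.stm_set <- function(x, ...) {
  cat("STM set:", length(x$genes), "markers from", x$n_iterations,
      "randomized Steiner trees\n")
  cat("  terminals:", length(x$terminals),
      "| markers that are terminals:", sum(x$genes %in% x$terminals),
      "| Steiner-only:", sum(!(x$genes %in% x$terminals)), "\n")
  invisible(x)
}

#' @export
summary.stm_set <- function(object, ...) {
  cum <- cumsum(object$per_iteration_new)
  last_new <- max(which(object$per_iteration_new > 0))
  cat("STM discovery over", object$n_iterations, "iterations\n")
  cat("  markers:", length(object$genes),
      "(", sum(!(object$genes %in% object$terminals)), "Steiner,",
      sum(object$genes %in% object$terminals), "internal terminals )\n")
  cat("  last iteration adding a new marker:", last_new, "\n")
  cat("  median per-tree occurrence:", stats::median(object$frequency), "\n")
  invisible(object)
}

#' Plot the STM convergence trace
#'
#' Cumulative number of unique markers against the iteration index; the
#' curve saturating is the stopping diagnostic for the ensemble.
#'
#' @param x an \code{stm_set}.
#' @param ... passed to \code{plot}.
#' @export
plot.stm_set <- function(x, ...) {
  cum <- cumsum(x$per_iteration_new)
  plot(seq_along(cum), cum, type = "s",
       xlab = "iteration", ylab = "cumulative unique STMs", ...)
  invisible(x)
}

#' Cross-set stability of two STM sets
#'
#' Overlap statistics (percent overlap and hypergeometric p-value) between
#' two marker sets discovered from different datasets or networks, against a
#' common background of \code{N} network genes.
#'
#' @param stms_a,stms_b \code{stm_set} objects or character gene vectors.
#' @param N background size (genes in the network's largest component).
#' @return an \code{\link[=overlap_stats]{overlap_result}}.
#' @export
stability_report <- function(stms_a, stms_b, N) {
  a <- if (inherits(stms_a, "stm_set")) stms_a$genes else stms_a
  b <- if (inherits(stms_b, "stm_set")) stms_b$genes else stms_b
  if (N < length(union(a, b))) stop("background N smaller than the union of the sets")
  overlap_sets(a, b, N)
}
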