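as_terminals <- function(x) {
  if (inherits(x, "terminal_set")) x$terminals else unique(as.character(x))
}

# all terminals must sit in one connected component; error names offenders
check_one_component <- function(net, R) {
  comp <- igraph::components(net)
  tcomp <- comp$membership[match(R, igraph::V(net)$name)]
  if (length(unique(tcomp)) > 1L) {
    split_terms <- split(R, tcomp)
    stop("terminals fall in ", length(split_terms),
         " different components; e.g. {",
         paste(vapply(split_terms, `[[`, character(1), 1L),
               collapse = "} vs {"),
         "} are disconnected")
  }
  invisible(TRUE)
}

#' Steiner tree by the shortest-path heuristic
#'
#' Connects a set of terminal genes into a single tree in a weighted
#' network using the classical polynomial-time 2-approximation shortest-path
#' heuristic. Starting from a forest containing only the terminals, the two
#' closest vertices (weighted shortest-path distance) lying in different
#' components of the forest are connected and all vertices on the connecting
#' path join the forest; once the forest is connected, a minimum spanning
#' tree of the subgraph induced by the collected vertices is built, and
#' non-terminal leaves are pruned iteratively.
#'
#' Ties in distance and in the spanning tree are broken lexicographically by
#' vertex name; in ensemble use, \code{\link{perturb_weights}} breaks them
#' randomly instead.
#'
#' @param net an undirected, connected-enough \pkg{igraph} graph with named
#'   vertices and (optionally) an edge \code{weight} attribute.
#' @param terminals a character vector of terminal gene identifiers, or a
#'   \code{terminal_set} from \code{\link{restrict_terminals}}. All terminals
#'   must lie in one connected component of \code{net}.
#' @return an object of class \code{steiner_tree}: a list with the tree as
#'   an \pkg{igraph} graph (\code{$tree}), the terminal identifiers
#'   (\code{$terminals}), the Steiner (non-terminal) vertices
#'   (\code{$steiner_vertices}) and the tree's total edge weight
#'   (\code{$total_weight}).
#' @examples
#' g <- igraph::make_star(4, mode = "undirected", center = 1)
#' igraph::V(g)$name <- c("hub", "a", "b", "d")
#' st <- steiner_tree(g, c("a", "b", "d"))
#' st$steiner_vertices     # "hub"
#' internal_vertices(st)   # also "hub"
#' @export
steiner_tree <- function(net, terminals) {
  R <- as_terminals(terminals)
  missing <- setdiff(R, igraph::V(net)$name)
  if (length(missing) > 0L) {
    stop("terminal(s) not in network: ", paste(missing, collapse = ", "))
  }
  w <- edge_weights(net)
  igraph::E(net)$weight <- w
  check_one_component(net, R)
  if (length(R) == 1L) {
    tree <- igraph::induced_subgraph(net, R)
    tree <- igraph::delete_edges(tree, igraph::E(tree))
    return(new_steiner_tree(tree, R))
  }

  # hand the graph to the compiled core with vertices renumbered in
  # lexicographic name order, so its smallest-id tie-breaks are
  # lexicographic name tie-breaks
  nm <- igraph::V(net)$name
  ordnm <- sort(nm)
  id <- match(nm, ordnm) - 1L
  el <- igraph::as_edgelist(net, names = FALSE)
  res <- .steiner_sph_cpp(length(nm), id[el[, 1L]], id[el[, 2L]], w,
                          id[match(R, nm)])

  tree <- igraph::graph_from_edgelist(
    cbind(ordnm[res$edge_i + 1L], ordnm[res$edge_j + 1L]), directed = FALSE)
  wkey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  wmap <- stats::setNames(w, wkey(nm[el[, 1L]], nm[el[, 2L]]))
  tel <- igraph::as_edgelist(tree, names = TRUE)
  igraph::E(tree)$weight <- unname(wmap[wkey(tel[, 1L], tel[, 2L])])
  new_steiner_tree(tree, R)
}

# iteratively remove degree-1 vertices that are not terminals
prune_nonterminal_leaves <- function(tree, R) {
  repeat {
    deg <- igraph::degree(tree)
    drop <- igraph::V(tree)$name[deg <= 1L & !(igraph::V(tree)$name %in% R)]
    if (length(drop) == 0L) break
    tree <- igraph::delete_vertices(tree, drop)
  }
  tree
}

new_steiner_tree <- function(tree, R) {
  vn <- igraph::V(tree)$name
  structure(list(
    tree = tree,
    terminals = intersect(R, vn),
    steiner_vertices = setdiff(vn, R),
    total_weight = sum(edge_weights(tree))
  ), class = "steiner_tree")
}

#' @export
print.steiner_tree <- function(x, ...) {
  cat("Steiner tree:", igraph::vcount(x$tree), "vertices,",
      igraph::ecount(x$tree), "edges\n")
  cat("  terminals:      ", length(x$terminals), "\n")
  cat("  Steiner vertices:", length(x$steiner_vertices), "\n")
  cat("  total weight:    ", format(x$total_weight), "\n")
  invisible(x)
}

#' Internal (marker) vertices of a Steiner tree
#'
#' Returns the vertices that actively connect the terminals: all Steiner
#' vertices together with the terminals that are internal to the tree
#' (tree degree greater than one). Because non-terminal leaves are pruned,
#' this is exactly the set of vertices with tree degree > 1. These are the
#' candidate markers contributed by one tree.
#'
#' @param tree a \code{steiner_tree} object.
#' @return character vector of gene identifiers.
#' @export
internal_vertices <- function(tree) {
  stopifnot(inherits(tree, "steiner_tree"))
  deg <- igraph::degree(tree$tree)
  igraph::V(tree$tree)$name[deg > 1L]
}

#' Exact minimum Steiner tree by exhaustive search
#'
#' Enumerates all subsets of non-terminal vertices; for each subset whose
#' union with the terminals induces a connected subgraph, computes that
#' subgraph's minimum-spanning-tree weight, and returns a minimum-weight
#' tree over the best subset (non-terminal leaves pruned). Exponential in
#' the number of non-terminals; intended as a ground-truth reference on
#' small instances only.
#'
#' @inheritParams steiner_tree
#' @param max_nodes refuse graphs larger than this (default 16).
#' @return a \code{steiner_tree} object attaining the optimal weight.
#' @export
steiner_exact <- function(net, terminals, max_nodes = 16L) {
  R <- as_terminals(terminals)
  nv <- igraph::vcount(net)
  if (nv > max_nodes) {
    stop("graph has ", nv, " > max_nodes = ", max_nodes,
         " vertices; exhaustive search refused")
  }
  vn <- igraph::V(net)$name
  missing <- setdiff(R, vn)
  if (length(missing) > 0L) {
    stop("terminal(s) not in network: ", paste(missing, collapse = ", "))
  }
  w <- edge_weights(net)
  igraph::E(net)$weight <- w
  A <- as.matrix(igraph::as_adjacency_matrix(net, attr = "weight", sparse = FALSE))
  A[A == 0] <- Inf
  diag(A) <- Inf
  ridx <- match(R, vn)
  nonterm <- setdiff(seq_len(nv), ridx)
  if (length(R) == 1L) {
    tree <- igraph::induced_subgraph(net, R)
    tree <- igraph::delete_edges(tree, igraph::E(tree))
    return(new_steiner_tree(tree, R))
  }

  best_w <- Inf
  best_set <- NULL
  for (mask in 0:(2^length(nonterm) - 1L)) {
    extra <- nonterm[bitwAnd(mask, bitwShiftL(1L, seq_along(nonterm) - 1L)) != 0L]
    sel <- c(ridx, extra)
    mw <- mst_weight_dense(A, sel)
    if (!is.na(mw) && mw < best_w) {
      best_w <- mw
      best_set <- sel
    }
  }
  if (is.null(best_set)) stop("terminals cannot be connected")
  sub <- igraph::induced_subgraph(net, vn[best_set])
  tree <- igraph::mst(sub, weights = igraph::E(sub)$weight)
  tree <- prune_nonterminal_leaves(tree, R)
  new_steiner_tree(tree, R)
}

# Prim's algorithm on a dense weight matrix restricted to `sel`;
# NA if the induced subgraph is disconnected
mst_weight_dense <- function(A, sel) {
  n <- length(sel)
  if (n == 1L) return(0)
  B <- A[sel, sel, drop = FALSE]
  intree <- logical(n)
  intree[1L] <- TRUE
  mind <- B[1L, ]
  total <- 0
  for (i in seq_len(n - 1L)) {
    mind[intree] <- Inf
    j <- which.min(mind)
    if (!is.finite(mind[j])) return(NA_real_)
    total <- total + mind[j]
    intree[j] <- TRUE
    mind <- pmin(mind, B[j, ])
  }
  total
}
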