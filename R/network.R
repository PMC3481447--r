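#' Read a PPI network from an edge-list file
#'
#' Parses a plain-text edge list (one interaction per line, tab- or
#' space-separated) into an undirected \pkg{igraph} graph. Gene identifiers
#' are opaque strings; no identifier mapping is attempted. Self-loops are
#' discarded and duplicate edges (including reversed duplicates) collapsed;
#' the counts of both are recorded as graph attributes \code{self_loops} and
#' \code{duplicate_edges}. A third numeric column, when present, is read as
#' the edge weight; otherwise all weights are 1.
#'
#' @param path path to the edge-list file, or a connection. Lines starting
#'   with \code{#} are comments.
#' @param sif if \code{TRUE}, treat the file as simple-interaction format
#'   (\code{A type B}): the middle token is ignored and the third token is
#'   the second endpoint.
#' @return an undirected \pkg{igraph} graph with vertex \code{name} and edge
#'   \code{weight} attributes.
#' @examples
#' tf <- tempfile()
#' writeLines(c("A\tB", "B\tA", "B\tC", "A\tA"), tf)
#' g <- read_edge_list(tf)
#' igraph::ecount(g)            # 2: reversed duplicate and self-loop dropped
#' igraph::graph_attr(g, "self_loops")
#' @export
read_edge_list <- function(path, sif = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  data_lines <- lines[keep]
  if (length(data_lines) == 0L) {
    stop("empty edge list: no data lines in ", if (is.character(path)) path else "input")
  }
  toks <- strsplit(data_lines, "[ \t]+")
  ntok <- lengths(toks)
  bad <- which(ntok < 2L | (sif & ntok < 3L))
  if (length(bad) > 0L) {
    stop("malformed edge line ", which(keep)[bad[1L]], ": '",
         data_lines[bad[1L]], "'")
  }
  from <- vapply(toks, `[[`, character(1), 1L)
  if (sif) {
    to <- vapply(toks, `[[`, character(1), 3L)
    w <- rep(1, length(toks))
  } else {
    to <- vapply(toks, `[[`, character(1), 2L)
    w <- vapply(toks, function(x) {
      if (length(x) >= 3L) suppressWarnings(as.numeric(x[3L])) else 1
    }, numeric(1))
    if (anyNA(w)) stop("non-numeric weight on line ",
                       which(keep)[which(is.na(w))[1L]])
    if (any(w <= 0)) stop("edge weights must be strictly positive")
  }
  self <- from == to
  n_self <- sum(self)
  from <- from[!self]; to <- to[!self]; w <- w[!self]
  if (length(from) == 0L) stop("edge list contains only self-loops")
  # canonical unordered-pair key for deduplication
  key <- ifelse(from < to, paste(from, to, sep = "\r"), paste(to, from, sep = "\r"))
  dup <- duplicated(key)
  n_dup <- sum(dup)
  g <- igraph::graph_from_edgelist(cbind(from[!dup], to[!dup]), directed = FALSE)
  igraph::E(g)$weight <- w[!dup]
  igraph::graph_attr(g, "self_loops") <- n_self
  igraph::graph_attr(g, "duplicate_edges") <- n_dup
  g
}

#' Write a network as a tab-separated edge list
#'
#' @param net an undirected \pkg{igraph} graph with named vertices.
#' @param path output file path.
#' @param weights write the third (weight) column? Default writes it only
#'   when some weight differs from 1.
#' @return \code{path}, invisibly.
#' @export
write_edge_list <- function(net, path,
                            weights = !all(edge_weights(net) == 1)) {
  el <- igraph::as_edgelist(net, names = TRUE)
  lines <- if (weights) {
    paste(el[, 1L], el[, 2L], format(edge_weights(net), digits = 17), sep = "\t")
  } else {
    paste(el[, 1L], el[, 2L], sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

# weight vector with the unit-weight default
edge_weights <- function(net) {
  w <- igraph::E(net)$weight
  if (is.null(w)) rep(1, igraph::ecount(net)) else w
}

#' Extract the largest connected component
#'
#' Returns the node-induced subgraph on the largest connected component of
#' the network, the standard preprocessing step before any Steiner
#' computation. A tie in component size is broken deterministically in
#' favour of the component containing the lexicographically smallest vertex
#' name.
#'
#' @param net an undirected \pkg{igraph} graph with named vertices.
#' @return a connected \pkg{igraph} graph.
#' @export
largest_component <- function(net) {
  if (igraph::vcount(net) == 0L) stop("network is empty")
  comp <- igraph::components(net)
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1L) {
    # tie: pick the component holding the smallest vertex name
    firsts <- vapply(best, function(k) {
      min(igraph::V(net)$name[comp$membership == k])
    }, character(1))
    best <- best[order(firsts)][1L]
  }
  igraph::induced_subgraph(net, which(comp$membership == best))
}

#' Map a gene list onto a network as terminal vertices
#'
#' Intersects a requested gene set with the network's vertices. Genes absent
#' from the network (typically a platform mismatch between the expression
#' data and the interaction database) are reported, not silently dropped.
#'
#' @param net an undirected \pkg{igraph} graph with named vertices.
#' @param genes character vector of gene identifiers.
#' @return an object of class \code{terminal_set}: a list with elements
#'   \code{terminals} (genes found in the network) and \code{dropped}
#'   (genes absent from it).
#' @export
restrict_terminals <- function(net, genes) {
  if (length(genes) == 0L) stop("gene list is empty")
  genes <- unique(as.character(genes))
  present <- genes %in% igraph::V(net)$name
  terminals <- genes[present]
  dropped <- genes[!present]
  if (length(terminals) == 0L) stop("no terminal maps to network")
  if (length(dropped) > 0L) {
    warning(length(dropped), " gene(s) not found in the network and dropped")
  }
  structure(list(terminals = terminals, dropped = dropped),
            class = "terminal_set")
}

#' @export
print.terminal_set <- function(x, ...) {
  cat("Terminal set:", length(x$terminals), "genes mapped,",
      length(x$dropped), "dropped\n")
  invisible(x)
}

#' Read a one-identifier-per-line gene list
#'
#' @param path path to a plain-text file, one gene identifier per line;
#'   \code{#} comments and blank lines are skipped.
#' @return character vector of unique identifiers.
#' @export
read_gene_list <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  unique(lines)
}
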