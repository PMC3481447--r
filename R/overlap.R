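#' Percent overlap between two gene sets
#'
#' The Jaccard index of the two sets, expressed as a percentage:
#' \code{100 * o / (m + n - o)} for set sizes \code{m}, \code{n} and
#' intersection size \code{o}.
#'
#' @param m,n sizes of the two sets (non-negative integers).
#' @param o size of their intersection; \code{0 <= o <= min(m, n)} and the
#'   union \code{m + n - o} must be at least 1.
#' @return percent overlap in \code{[0, 100]}.
#' @examples
#' percent_overlap(1047, 1100, 410)   # 23.6
#' @export
percent_overlap <- function(m, n, o) {
  check_overlap_counts(Inf, m, n, o)
  if (m + n - o < 1) stop("union m + n - o must be >= 1")
  100 * o / (m + n - o)
}

check_overlap_counts <- function(N, m, n, o) {
  if (any(c(N, m, n, o) < 0) || o > min(m, n) || m > N || n > N) {
    stop("invalid counts: need 0 <= o <= min(m, n) and m, n <= N ",
         "(got N=", N, ", m=", m, ", n=", n, ", o=", o, ")")
  }
  invisible(TRUE)
}

# log(sum(exp(x))) without overflow/underflow
log_sum_exp <- function(x) {
  x <- x[is.finite(x) | x == Inf]
  if (length(x) == 0L) return(-Inf)
  mx <- max(x)
  mx + log(sum(exp(x - mx)))
}

#' Hypergeometric upper-tail p-value of a gene-set overlap
#'
#' One-sided Fisher's exact test of whether two gene sets of sizes \code{m}
#' and \code{n}, drawn from a background of \code{N} genes (the largest
#' connected component of the interaction network), share at least \code{o}
#' genes: \code{P(X >= o)} for \code{X ~ Hypergeometric(N, m, n)}. The tail
#' is summed in log space (log-gamma binomial coefficients, log-sum-exp), so
#' p-values far below the double underflow threshold keep full precision on
#' the log10 scale. Terms with impossible counts contribute zero.
#'
#' @param N background size: number of genes in the network component.
#' @param m,n sizes of the two gene sets.
#' @param o observed intersection size.
#' @return a list with \code{p_value} (clamped to the smallest positive
#'   double when it underflows) and \code{log10_p}, the authoritative
#'   quantity for extreme p-values.
#' @examples
#' overlap_pvalue(10794, 1047, 1100, 410)$log10_p   # about -158.2
#' @export
overlap_pvalue <- function(N, m, n, o) {
  check_overlap_counts(N, m, n, o)
  if (o == 0L) return(list(p_value = 1, log10_p = 0))
  i <- o:min(m, n)
  logterms <- lchoose(m, i) + lchoose(N - m, n - i) - lchoose(N, n)
  lp <- log_sum_exp(logterms)
  lp <- min(lp, 0)  # guard numerical overshoot above 1
  list(p_value = max(exp(lp), .Machine$double.xmin),
       log10_p = lp / log(10))
}

#' Full overlap report for two gene sets
#'
#' Combines \code{\link{percent_overlap}} and \code{\link{overlap_pvalue}}
#' into one result, either from raw counts or from the sets themselves.
#'
#' @inheritParams overlap_pvalue
#' @return an object of class \code{overlap_result}: list with \code{N},
#'   \code{m}, \code{n}, \code{o}, \code{percent}, \code{p_value},
#'   \code{log10_p}.
#' @seealso \code{\link{overlap_sets}} to start from gene vectors.
#' @export
overlap_stats <- function(N, m, n, o) {
  pv <- overlap_pvalue(N, m, n, o)
  structure(list(N = N, m = m, n = n, o = o,
                 percent = percent_overlap(m, n, o),
                 p_value = pv$p_value, log10_p = pv$log10_p),
            class = "overlap_result")
}

#' @rdname overlap_stats
#' @param set_a,set_b character vectors of gene identifiers.
#' @export
overlap_sets <- function(set_a, set_b, N) {
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  overlap_stats(N, length(set_a), length(set_b),
                length(intersect(set_a, set_b)))
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("Overlap: o = %d of m = %d vs n = %d (background N = %s)\n",
              x$o, x$m, x$n, format(x$N)))
  cat(sprintf("  percent overlap: %.3g%%\n", x$percent))
  cat(sprintf("  p-value: %.3g (log10 = %.2f)\n", x$p_value, x$log10_p))
  invisible(x)
}
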