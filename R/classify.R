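#' Read an expression matrix
#'
#' Tab-separated text: first column gene identifier, header row of sample
#' identifiers, one gene per row.
#'
#' @param path file path.
#' @return numeric matrix, genes in rows (rownames), samples in columns.
#' @export
read_expression <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1L,
                          check.names = FALSE, stringsAsFactors = FALSE)
  as.matrix(df)
}

#' @rdname read_expression
#' @param expr genes x samples matrix with dimnames.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample binary outcome labels
#'
#' Two-column tab-separated text (sample identifier, 0/1 label), no header.
#'
#' @param path file path.
#' @return integer vector of 0/1 labels named by sample identifier.
#' @export
read_labels <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  stats::setNames(as.integer(df[[2L]]), as.character(df[[1L]]))
}

#' @rdname read_labels
#' @param labels named 0/1 vector.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(data.frame(names(labels), unname(labels)), path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# stratified fold ids: within each class, samples are shuffled and dealt
# round-robin into n_folds folds, so every fold sees both classes
stratified_folds <- function(labels, n_folds) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  fold
}

# class-1 score from a fitted classifier on new rows
predict_score <- function(fit, classifier, newx) {
  if (classifier == "logistic") {
    unname(stats::predict(fit, newdata = as.data.frame(newx), type = "response"))
  } else {
    pr <- stats::predict(fit, newx, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    # e1071 decision values are oriented "first level vs second"; the
    # column name records the orientation
    s <- drop(dv)
    if (grepl("^0/", colnames(dv)[1L])) -s else s
  }
}

#' Evaluate a feature gene set by repeated cross-validated classification
#'
#' Restricts the expression matrix to the given feature genes and estimates
#' how well they separate the two outcome classes: \code{n_repetitions}
#' repetitions of stratified \code{n_folds}-fold cross-validation, with a
#' logistic-regression or linear-kernel SVM classifier at default settings
#' (no tuning, no internal feature selection). Per repetition, the
#' out-of-fold predicted scores are pooled and one AUC is computed; the
#' result carries the full vector of per-repetition AUCs so that two
#' feature sets evaluated with the same seed can be compared run by run
#' (\code{\link{paired_run_comparison}}).
#'
#' @param expr genes x samples numeric matrix with gene rownames.
#' @param labels 0/1 outcome per sample (1 = event, e.g. metastasis within
#'   five years), in column order of \code{expr} or named by sample.
#' @param features character vector of feature gene identifiers; genes
#'   absent from \code{expr} are recorded in \code{features_missing}.
#' @param classifier \code{"logistic"} (default) or \code{"svm"}
#'   (linear kernel, default cost).
#' @param n_repetitions number of CV repetitions (default 100).
#' @param n_folds folds per repetition (default 10).
#' @param seed integer seed; fold assignments for repetition r are drawn
#'   from a substream of \code{(seed, r)}, so different feature sets
#'   evaluated with the same seed share fold splits.
#' @return an object of class \code{stm_cv}: list with \code{auc_runs},
#'   \code{mean_auc}, \code{n_repetitions}, \code{n_folds},
#'   \code{classifier}, \code{features_used}, \code{features_missing}.
#' @export
evaluate_features <- function(expr, labels, features,
                              classifier = c("logistic", "svm"),
                              n_repetitions = 100L, n_folds = 10L,
                              seed = 1L) {
  classifier <- match.arg(classifier)
  if (!is.null(names(labels)) && !is.null(colnames(expr))) {
    labels <- labels[colnames(expr)]
  }
  labels <- as.integer(labels)
  stopifnot(length(labels) == ncol(expr), all(labels %in% c(0L, 1L)))
  if (min(table(labels)) < n_folds) {
    stop("each class needs at least n_folds = ", n_folds, " samples")
  }
  features <- unique(as.character(features))
  used <- intersect(features, rownames(expr))
  if (length(used) == 0L) stop("no feature gene maps to the expression matrix")
  X <- t(expr[used, , drop = FALSE])
  colnames(X) <- make.names(colnames(X))  # safe model.frame names

  auc_runs <- numeric(n_repetitions)
  for (r in seq_len(n_repetitions)) {
    set.seed(substream_seed(seed, r))
    fold <- stratified_folds(labels, n_folds)
    score <- numeric(length(labels))
    for (k in seq_len(n_folds)) {
      test <- fold == k
      fit <- if (classifier == "logistic") {
        df <- data.frame(.y = labels[!test], X[!test, , drop = FALSE])
        suppressWarnings(stats::glm(.y ~ ., family = stats::binomial(), data = df))
      } else {
        e1071::svm(X[!test, , drop = FALSE],
                   factor(labels[!test], levels = c(0L, 1L)),
                   kernel = "linear", scale = FALSE)
      }
      score[test] <- suppressWarnings(
        predict_score(fit, classifier, X[test, , drop = FALSE]))
    }
    auc_runs[r] <- as.numeric(pROC::roc(labels, score, levels = c(0L, 1L),
                                        direction = "<", quiet = TRUE)$auc)
  }
  structure(list(auc_runs = auc_runs, mean_auc = mean(auc_runs),
                 n_repetitions = n_repetitions, n_folds = n_folds,
                 classifier = classifier, features_used = used,
                 features_missing = setdiff(features, used)),
            class = "stm_cv")
}

#' @export
print.stm_cv <- function(x, ...) {
  cat(sprintf("%s classifier, %d x %d-fold CV on %d features\n",
              x$classifier, x$n_repetitions, x$n_folds,
              length(x$features_used)))
  cat(sprintf("  mean AUC: %.3f (sd %.3f over runs)\n",
              x$mean_auc, stats::sd(x$auc_runs)))
  if (length(x$features_missing) > 0L) {
    cat("  features not in matrix:", length(x$features_missing), "\n")
  }
  invisible(x)
}

#' Paired per-run comparison of two cross-validation results
#'
#' Compares two \code{\link{evaluate_features}} results run for run:
#' counts the runs where the first beats the second (ties are not wins) and
#' tests the mean per-run AUC difference with a paired t-test. Meaningful
#' only when both were evaluated with the same seed, i.e. on identical fold
#' splits.
#'
#' @param a,b \code{stm_cv} objects or numeric AUC vectors of equal length.
#' @return list with \code{wins_a}, \code{wins_b}, \code{ties},
#'   \code{mean_diff}, \code{p_value}.
#' @export
paired_run_comparison <- function(a, b) {
  va <- if (inherits(a, "stm_cv")) a$auc_runs else as.numeric(a)
  vb <- if (inherits(b, "stm_cv")) b$auc_runs else as.numeric(b)
  if (length(va) != length(vb)) stop("run vectors have different lengths")
  d <- va - vb
  n <- length(d)
  if (stats::sd(d) < 1e-12) {
    # degenerate zero-variance difference: identical runs give p = 1,
    # a constant nonzero shift is (numerically) infinitely significant
    p <- if (abs(mean(d)) < 1e-12) 1 else .Machine$double.xmin
  } else {
    p <- stats::t.test(va, vb, paired = TRUE)$p.value
  }
  list(wins_a = sum(d > 0), wins_b = sum(d < 0), ties = sum(d == 0),
       mean_diff = mean(d), p_value = p)
}

#' Coverage of a known-marker list by a discovered marker set
#'
#' Fraction of an externally curated marker list recovered by the
#' discovered set, with the hypergeometric significance of the overlap
#' against the network background.
#'
#' @param stms discovered marker set (\code{stm_set} or character vector).
#' @param known character vector of known marker genes (non-empty).
#' @param N background size (genes in the network's largest component).
#' @return object of class \code{coverage_result}: list with
#'   \code{coverage} (fraction in \code{[0, 1]}), \code{n_known},
#'   \code{n_covered}, \code{covered} (the gene identifiers), and
#'   \code{overlap} (an \code{overlap_result}).
#' @export
known_marker_coverage <- function(stms, known, N) {
  s <- unique(if (inherits(stms, "stm_set")) stms$genes else as.character(stms))
  known <- unique(as.character(known))
  if (length(known) == 0L) stop("known-marker list is empty")
  hit <- intersect(s, known)
  structure(list(coverage = length(hit) / length(known),
                 n_known = length(known), n_covered = length(hit),
                 covered = hit,
                 overlap = overlap_stats(N, length(s), length(known),
                                         length(hit))),
            class = "coverage_result")
}

#' @export
print.coverage_result <- function(x, ...) {
  cat(sprintf("Known-marker coverage: %d of %d (%.2f%%), overlap p = %.3g\n",
              x$n_covered, x$n_known, 100 * x$coverage, x$overlap$p_value))
  invisible(x)
}
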