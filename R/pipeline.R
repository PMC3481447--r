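#' Read a flat key = value configuration file
#'
#' One \code{key = value} pair per line; \code{#} comments and blank lines
#' ignored. Values are kept as strings; the pipeline coerces what it needs.
#'
#' @param path config file path.
#' @return named list of strings.
#' @export
read_config <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- lengths(kv) != 3L
  if (any(bad)) stop("malformed config line: '", lines[bad][1L], "'")
  stats::setNames(as.list(trimws(vapply(kv, `[[`, character(1), 3L))),
                  trimws(vapply(kv, `[[`, character(1), 2L)))
}

cfg_get <- function(config, key, default = NULL, as = identity) {
  if (!is.null(config[[key]])) as(config[[key]]) else default
}

#' Run the full marker-discovery pipeline
#'
#' Chains the stages: load the network, extract its largest connected
#' component, map the DE gene list(s) onto it, discover STMs by the
#' randomized Steiner tree ensemble, and — when the corresponding inputs
#' are configured — compute cross-set overlap statistics, known-marker
#' coverage and cross-validated classification performance. All outputs are
#' written under \code{out_dir}; every JSON output embeds the resolved
#' configuration.
#'
#' Recognised config keys (paths unless noted): \code{network},
#' \code{de_genes} (required), \code{de_genes_b} (second seed list, enables
#' the stability report), \code{expression} + \code{labels} (enable
#' classification), \code{known_markers} (enables coverage),
#' \code{out_dir}, \code{seed}, \code{iterations}, \code{patience},
#' \code{weight_low}, \code{weight_high}, \code{classifier}
#' (\code{logistic}/\code{svm}), \code{reps}, \code{folds}, \code{sif}
#' (\code{true} to read the network as SIF).
#'
#' @param config named list (e.g. from \code{\link{read_config}}) or a
#'   config file path. Entries override nothing: missing optional stages
#'   are skipped.
#' @return named character vector of written files (the run manifest last),
#'   invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_config(config)
  }
  for (key in c("network", "de_genes")) {
    if (is.null(config[[key]])) stop("config is missing required key '", key, "'")
  }
  for (key in intersect(names(config),
                        c("network", "de_genes", "de_genes_b",
                          "expression", "labels", "known_markers"))) {
    if (!file.exists(config[[key]])) {
      stop("config path for '", key, "' does not exist: ", config[[key]])
    }
  }
  out_dir <- cfg_get(config, "out_dir", ".")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- cfg_get(config, "seed", 1L, as = as.integer)
  iters <- cfg_get(config, "iterations", 500L, as = as.integer)
  patience <- cfg_get(config, "patience", 50L, as = as.integer)
  wlo <- cfg_get(config, "weight_low", 0.99, as = as.numeric)
  whi <- cfg_get(config, "weight_high", 1.0, as = as.numeric)
  sif <- isTRUE(cfg_get(config, "sif", FALSE,
                        as = function(x) tolower(x) %in% c("true", "1", "yes")))
  resolved <- config
  resolved[c("seed", "iterations", "patience")] <- list(seed, iters, patience)
  written <- character(0)
  emit <- function(name, obj) {
    p <- file.path(out_dir, name)
    jsonlite::write_json(c(obj, list(config = resolved)), p,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written[[name]] <<- p
    p
  }

  net <- largest_component(read_edge_list(config$network, sif = sif))
  N <- igraph::vcount(net)
  ts <- suppressWarnings(restrict_terminals(net, read_gene_list(config$de_genes)))
  stm <- discover_stms(net, ts, max_iterations = iters, patience = patience,
                       weight_low = wlo, weight_high = whi, seed = seed)
  writeLines(stm$genes, file.path(out_dir, "stm.txt"))
  written[["stm.txt"]] <- file.path(out_dir, "stm.txt")
  emit("stm.json", list(genes = stm$genes, n_iterations = stm$n_iterations,
                        trace = stm$per_iteration_new,
                        n_dropped_terminals = length(ts$dropped)))

  if (!is.null(config$de_genes_b)) {
    tsb <- suppressWarnings(
      restrict_terminals(net, read_gene_list(config$de_genes_b)))
    stmb <- discover_stms(net, tsb, max_iterations = iters,
                          patience = patience, weight_low = wlo,
                          weight_high = whi, seed = seed + 1L)
    ov <- stability_report(stm, stmb, N)
    emit("overlap.json", unclass(ov))
  }

  if (!is.null(config$known_markers)) {
    cov <- known_marker_coverage(stm, read_gene_list(config$known_markers), N)
    emit("coverage.json", list(coverage = cov$coverage,
                               n_known = cov$n_known,
                               n_covered = cov$n_covered,
                               p_value = cov$overlap$p_value,
                               log10_p = cov$overlap$log10_p))
  }

  if (!is.null(config$expression) && !is.null(config$labels)) {
    expr <- read_expression(config$expression)
    labels <- read_labels(config$labels)
    cv <- evaluate_features(expr, labels, stm$genes,
                            classifier = cfg_get(config, "classifier", "logistic"),
                            n_repetitions = cfg_get(config, "reps", 100L,
                                                    as = as.integer),
                            n_folds = cfg_get(config, "folds", 10L,
                                              as = as.integer),
                            seed = seed)
    emit("classification.json",
         list(mean_auc = cv$mean_auc, auc_runs = cv$auc_runs,
              classifier = cv$classifier,
              n_features_used = length(cv$features_used),
              n_features_missing = length(cv$features_missing)))
  }

  emit("manifest.json",
       list(package = "stmarker",
            version = as.character(utils::packageVersion("stmarker")),
            background_N = N, n_terminals = length(ts$terminals),
            n_stms = length(stm$genes), outputs = names(written)))
  invisible(written)
}
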