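#' Undirected co-variation network baseline
#'
#' Places an undirected edge between every pair of nodes whose Pearson
#' correlation test rejects at level `alpha`. This is the package's simple
#' co-expression-style baseline: like weighted co-expression approaches it
#' can only estimate an undirected network, and it stands in for them in
#' the benchmark.
#'
#' @param dataset an `"omics_dataset"` or numeric matrix (samples x nodes).
#' @param alpha per-pair significance level (default 0.05).
#' @return an object of class `"cor_network"`: list with `nodes` and an
#'   undirected `edges` data frame (`parent`, `child`, `r`, `p_value`;
#'   the parent/child labels carry no direction).
#' @examples
#' x <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("A", "B", "C")))
#' x[, 2] <- x[, 1] + rnorm(100, sd = 0.1)
#' correlation_baseline(x)$edges
#' @export
correlation_baseline <- function(dataset, alpha = 0.05) {
  dat <- if (inherits(dataset, "omics_dataset")) dataset$data else as.matrix(dataset)
  n <- nrow(dat); p <- ncol(dat)
  if (n < 3L) stop2("correlation test needs at least 3 samples")
  nodes <- colnames(dat) %||% paste0("V", seq_len(p))
  sds <- apply(dat, 2, stats::sd)
  if (any(sds == 0))
    warning("constant column(s) ", paste(nodes[sds == 0], collapse = ", "),
            " receive no edges")
  r <- suppressWarnings(stats::cor(dat))
  ## two-sided t test for Pearson correlation
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  pv <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  pv[r^2 >= 1] <- 0
  pv[is.na(r)] <- 1          # constant columns: never significant
  idx <- which(upper.tri(pv) & pv < alpha, arr.ind = TRUE)
  edges <- data.frame(parent = nodes[idx[, 1L]], child = nodes[idx[, 2L]],
                      r = r[idx], p_value = pv[idx],
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, alpha = alpha),
            class = "cor_network")
}

#' @export
print.cor_network <- function(x, ...) {
  cat(sprintf("Undirected correlation network: %d nodes, %d edges (alpha %g)\n",
              length(x$nodes), nrow(x$edges), x$alpha))
  invisible(x)
}

#' Power/FDR benchmark of network-recovery methods on random DAGs
#'
#' For every row of the configuration grid and every method, repeatedly
#' draws a random DAG and dataset, runs the estimator, and scores it
#' against the truth with [evaluate_network()]. Directed and undirected
#' comparisons are reported for the directed estimators; the correlation
#' baseline is undirected only.
#'
#' @param configs a single [sim_config()] or list of them (the grid).
#' @param methods character subset of `"correlation_baseline"`, `"sem"`,
#'   `"semip"`.
#' @param seed master seed; each replicate derives its own sub-seed.
#' @param alpha significance level for the baseline and SEM edge retention.
#' @param settings optional list of settings forwarded to
#'   [learn_semip_network()] / [fit_sem_network()].
#' @param verbose print one line per cell.
#' @return data frame of class `"semip_benchmark"` with columns `method`,
#'   `nodes`, `samples`, `mode`, `power`, `fdr`, `fdr_ref`, `replicates`
#'   (power and both FDR summaries averaged over replicates; `fdr` is the
#'   conventional false-discovery proportion).
#' @seealso [write_benchmark_tsv()]
#' @export
run_benchmark <- function(configs, methods = c("correlation_baseline", "sem", "semip"),
                          seed = 1L, alpha = 0.05, settings = list(),
                          verbose = FALSE) {
  if (inherits(configs, "sim_config")) configs <- list(configs)
  stopifnot(length(configs) >= 1L)
  methods <- match.arg(methods, c("correlation_baseline", "sem", "semip"),
                       several.ok = TRUE)
  rows <- list()
  cell <- 0L
  for (cfg in configs) {
    stopifnot(inherits(cfg, "sim_config"))
    if (cfg$n_replicates < 1L) stop2("replicate count must be positive")
    for (method in methods) {
      cell <- cell + 1L
      res_dir <- list(); res_und <- list()
      for (r in seq_len(cfg$n_replicates)) {
        s <- derive_seed(seed + cfg$seed, cell * 100003L + r)
        model <- random_dag(cfg, seed = s)
        dat <- simulate_dataset(model, cfg$n_samples)
        est <- switch(method,
          correlation_baseline = correlation_baseline(dat, alpha = alpha),
          sem = do.call(fit_sem_network,
                        c(list(dat, alpha = alpha), settings)),
          semip = do.call(learn_semip_network, c(list(dat), settings)))
        res_und[[r]] <- evaluate_network(model, est, mode = "undirected")
        if (method != "correlation_baseline")
          res_dir[[r]] <- evaluate_network(model, est, mode = "directed")
      }
      summarize <- function(lst, mode) {
        m <- do.call(rbind, lst)
        data.frame(method = method, nodes = cfg$n_nodes,
                   samples = cfg$n_samples, mode = mode,
                   power = mean(m$power, na.rm = TRUE),
                   fdr = mean(m$fdr_conventional, na.rm = TRUE),
                   fdr_ref = mean(m$fdr_ref, na.rm = TRUE),
                   replicates = cfg$n_replicates,
                   stringsAsFactors = FALSE)
      }
      rows[[length(rows) + 1L]] <- summarize(res_und, "undirected")
      if (method != "correlation_baseline")
        rows[[length(rows) + 1L]] <- summarize(res_dir, "directed")
      if (verbose) {
        last <- rows[[length(rows)]]
        message(sprintf("%s nodes=%d n=%d: power %.1f%% fdr %.1f%%",
                        method, cfg$n_nodes, cfg$n_samples,
                        100 * last$power, 100 * last$fdr))
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "seed") <- seed
  class(out) <- c("semip_benchmark", class(out))
  out
}

#' Write a benchmark table to TSV
#'
#' Seeds are recorded in `#`-prefixed header lines before the column header.
#'
#' @param bench result of [run_benchmark()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_benchmark_tsv <- function(bench, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# semip benchmark, seed %s",
                     attr(bench, "seed") %||% "unset"), con)
  out <- as.data.frame(bench)
  out$power <- round(100 * out$power, 2)
  out$fdr <- round(100 * out$fdr, 2)
  out$fdr_ref <- round(100 * out$fdr_ref, 2)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
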