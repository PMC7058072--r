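#' Draw a random layered causal DAG with linear-model coefficients
#'
#' Genotype nodes are exogenous roots (in-degree zero); the remaining
#' endogenous nodes receive a random topological order. Each admissible
#' ordered pair (genotype -> endogenous, or earlier -> later endogenous)
#' is included independently with probability `target_edges / n_admissible`,
#' so the expected edge count equals `config$target_edges`. Coefficient
#' magnitudes are i.i.d. U(coeff_low, coeff_high), optionally signed.
#'
#' @param config a [sim_config()].
#' @param seed optional integer seed; when `NULL` the current RNG state is
#'   used.
#' @return an object of class `"true_model"`: list with elements `nodes`
#'   (labels), `layer` (named `"genotype"`/`"endogenous"` vector), `adj`
#'   (0/1 adjacency, `adj[i, j] = 1` for i -> j), `coef` (matching
#'   coefficient matrix), `order` (a topological order) and `noise_sd`.
#' @examples
#' m <- random_dag(sim_config(n_nodes = 6, n_genotype = 2, target_edges = 5),
#'                 seed = 1)
#' sum(m$adj)
#' @export
random_dag <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  G <- config$n_genotype
  E <- config$n_nodes - G
  nodes <- c(paste0("X", seq_len(G)), paste0("Y", seq_len(E)))
  layer <- c(rep("genotype", G), rep("endogenous", E))
  names(layer) <- nodes
  p <- config$n_nodes

  n_adm <- G * E + E * (E - 1L) / 2
  prob <- config$target_edges / n_adm
  if (prob > 1) prob <- 1   # guarded already by sim_config

  ## random topological order over the endogenous block
  endo_order <- G + sample.int(E)
  adj <- matrix(0L, p, p, dimnames = list(nodes, nodes))
  ## genotype -> endogenous pairs
  for (g in seq_len(G)) {
    pick <- stats::runif(E) < prob
    adj[g, G + which(pick)] <- 1L
  }
  ## endogenous pairs respecting the order
  if (E > 1L) {
    for (a in seq_len(E - 1L)) {
      for (b in seq(a + 1L, E)) {
        if (stats::runif(1) < prob) adj[endo_order[a], endo_order[b]] <- 1L
      }
    }
  }

  ne <- sum(adj)
  coef <- matrix(0, p, p, dimnames = list(nodes, nodes))
  if (ne > 0) {
    mag <- stats::runif(ne, config$coeff_low, config$coeff_high)
    if (config$random_sign) mag <- mag * sample(c(-1, 1), ne, replace = TRUE)
    coef[adj == 1L] <- mag
  }

  structure(list(
    nodes = nodes, layer = layer, adj = adj, coef = coef,
    order = c(seq_len(G), endo_order), noise_sd = config$noise_sd,
    config = config
  ), class = "true_model")
}

#' @export
print.true_model <- function(x, ...) {
  cat(sprintf("Causal model: %d nodes (%d genotype), %d directed edges\n",
              length(x$nodes), sum(x$layer == "genotype"), sum(x$adj)))
  invisible(x)
}

#' Simulate a sample-aligned dataset from a linear structural model
#'
#' Genotype nodes are drawn as standardized exogenous variables; each
#' endogenous node is then computed in topological order as
#' \deqn{y_i = \sum_{j \in pa(i)} \gamma_{ji} y_j +
#'       \sum_{k \in pa(i)} \beta_{ki} x_k + e_i,\qquad e_i \sim N(0, \sigma^2).}
#'
#' @param model a `"true_model"` from [random_dag()] (or built by hand with
#'   the same fields).
#' @param n_samples number of rows to draw.
#' @param seed optional integer seed.
#' @return an object of class `"omics_dataset"`: list with `data`
#'   (n_samples x n_nodes numeric matrix, columns in node order) and
#'   `layer` (named layer vector).
#' @examples
#' m <- random_dag(sim_config(n_nodes = 5, n_genotype = 2, target_edges = 4),
#'                 seed = 2)
#' d <- simulate_dataset(m, 100, seed = 3)
#' dim(d$data)
#' @export
simulate_dataset <- function(model, n_samples, seed = NULL) {
  stopifnot(inherits(model, "true_model"))
  n_samples <- as.integer(n_samples)
  if (n_samples < 1L) stop2("n_samples must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  p <- length(model$nodes)
  dat <- matrix(0, n_samples, p, dimnames = list(NULL, model$nodes))
  cfg <- model$config
  gmode <- if (!is.null(cfg)) cfg$genotype_mode else "gaussian"
  for (v in model$order) {
    if (model$layer[v] == "genotype") {
      if (gmode == "hwe") {
        maf <- cfg$maf
        g <- stats::rbinom(n_samples, 2L, maf)
        s <- stats::sd(g)
        dat[, v] <- if (is.na(s) || s == 0) g - mean(g) else (g - mean(g)) / s
      } else {
        dat[, v] <- stats::rnorm(n_samples)
      }
    } else {
      pa <- which(model$adj[, v] != 0)
      mu <- if (length(pa)) dat[, pa, drop = FALSE] %*% model$coef[pa, v] else 0
      dat[, v] <- mu + stats::rnorm(n_samples, sd = model$noise_sd)
    }
  }
  new_omics_dataset(dat, model$layer)
}

#' Construct an omics dataset container
#'
#' @param data numeric matrix, samples in rows, named node columns.
#' @param layer character vector of layer labels, one per column.
#' @return an `"omics_dataset"` object.
#' @export
new_omics_dataset <- function(data, layer) {
  data <- as.matrix(data)
  if (is.null(colnames(data))) colnames(data) <- paste0("V", seq_len(ncol(data)))
  layer <- as.character(layer)
  names(layer) <- colnames(data)
  structure(list(data = data, layer = layer), class = "omics_dataset")
}

#' @export
print.omics_dataset <- function(x, ...) {
  cat(sprintf("Omics dataset: %d samples x %d nodes (%s)\n",
              nrow(x$data), ncol(x$data),
              paste(sprintf("%s: %d", names(table(x$layer)), table(x$layer)),
                    collapse = ", ")))
  invisible(x)
}
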