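#' Simulation configuration for random causal networks
#'
#' Bundles the parameters of the benchmark generative model: a random DAG
#' over `n_nodes` nodes of which `n_genotype` are exogenous genotype nodes
#' (in-degree zero), with an expected `target_edges` directed edges, path
#' coefficients drawn uniformly from `[coeff_low, coeff_high]` in magnitude
#' and Gaussian node noise.
#'
#' The defaults reproduce the benchmark design used throughout the package:
#' 20 nodes (15 endogenous expression/phenotype nodes, 5 genotype nodes),
#' a mean of 30 directed edges, coefficients U(1, 2) and N(0, 1) noise.
#'
#' @param n_nodes total number of nodes.
#' @param n_genotype number of exogenous genotype nodes (must be < `n_nodes`).
#' @param target_edges expected number of directed edges in a draw.
#' @param n_samples number of samples per simulated dataset.
#' @param coeff_low,coeff_high bounds of the uniform coefficient magnitude.
#' @param noise_sd standard deviation of the additive Gaussian node noise.
#' @param random_sign if `TRUE` (default) each coefficient magnitude is
#'   multiplied by an independent random sign, avoiding a degenerate
#'   all-positive correlation structure; set `FALSE` for strictly positive
#'   U(coeff_low, coeff_high) coefficients.
#' @param genotype_mode `"gaussian"` draws genotype node values as i.i.d.
#'   standard normal exogenous scores (the role FPC scores of real variants
#'   play); `"hwe"` simulates 0/1/2 genotypes at minor allele frequency
#'   `maf` under Hardy-Weinberg equilibrium and standardizes them.
#' @param maf minor allele frequency for `genotype_mode = "hwe"`.
#' @param n_replicates number of replicate (DAG, dataset) draws in benchmarks.
#' @param seed integer seed controlling all randomness downstream.
#' @return an object of class `"sim_config"`.
#' @examples
#' cfg <- sim_config(n_nodes = 20, n_genotype = 5, target_edges = 30)
#' @export
sim_config <- function(n_nodes = 20L, n_genotype = 5L, target_edges = 30,
                       n_samples = 1000L, coeff_low = 1, coeff_high = 2,
                       noise_sd = 1, random_sign = TRUE,
                       genotype_mode = c("gaussian", "hwe"), maf = 0.2,
                       n_replicates = 100L, seed = 1L) {
  genotype_mode <- match.arg(genotype_mode)
  n_nodes <- as.integer(n_nodes)
  n_genotype <- as.integer(n_genotype)
  if (n_nodes < 2L) stop2("n_nodes must be at least 2")
  if (n_genotype < 1L || n_genotype >= n_nodes)
    stop2("n_genotype must be positive and smaller than n_nodes")
  if (target_edges <= 0) stop2("target_edges must be positive")
  if (n_samples < 1L) stop2("n_samples must be positive")
  if (coeff_low >= coeff_high) stop2("coeff_low must be < coeff_high")
  if (noise_sd <= 0) stop2("noise_sd must be positive")
  if (n_replicates < 1L) stop2("n_replicates must be positive")
  n_endo <- n_nodes - n_genotype
  max_edges <- n_genotype * n_endo + n_endo * (n_endo - 1L) / 2
  if (target_edges > max_edges)
    stop2("target_edges (", target_edges, ") exceeds the maximum of ",
          max_edges, " admissible edges under the layer constraint")
  structure(list(
    n_nodes = n_nodes, n_genotype = n_genotype,
    target_edges = target_edges, n_samples = as.integer(n_samples),
    coeff_low = coeff_low, coeff_high = coeff_high, noise_sd = noise_sd,
    random_sign = isTRUE(random_sign), genotype_mode = genotype_mode,
    maf = maf, n_replicates = as.integer(n_replicates),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  nodes: %d (%d genotype + %d endogenous)\n",
              x$n_nodes, x$n_genotype, x$n_nodes - x$n_genotype))
  cat(sprintf("  mean edges: %g  samples: %d  replicates: %d\n",
              x$target_edges, x$n_samples, x$n_replicates))
  cat(sprintf("  coefficients: U(%g, %g)%s, noise sd %g, genotype mode %s\n",
              x$coeff_low, x$coeff_high,
              if (x$random_sign) " with random sign" else "",
              x$noise_sd, x$genotype_mode))
  invisible(x)
}
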