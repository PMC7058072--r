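## The SEMIP estimator: sparse-SEM screening of candidate parents per
## node, penalized projection scores over the screened parent sets, and
## exact DAG selection by the integer program of solve_ilp(). The
## multilevel variant runs one joint program over methylation,
## expression, phenotype and disease nodes with layer-respecting
## candidate sets and exogenous genotype parents.

## Admissible parent layers per child layer (causality flows downstream
## of genotype; disease nodes are sinks).
.layer_rules <- list(
  endogenous = c("endogenous", "genotype"),
  methylation = c("methylation", "genotype"),
  expression = c("expression", "methylation", "genotype"),
  phenotype = c("phenotype", "expression", "methylation", "genotype"),
  disease = c("phenotype", "expression", "methylation", "genotype")
)

## Screen candidate parents for one node. Two complementary signals are
## combined: (i) the union of sparse penalized-2SLS supports over the
## penalty path -- informative about instrumented effects but limited to
## the rank of the instrument space; (ii) neighborhood-selection lasso
## supports (plain penalized regression of the child on all candidates)
## over its own penalty path -- high-recall recovery of the Markov
## blanket, in which every true parent appears. Candidates are ranked by
## their combined selection frequency along both paths (ties: larger
## penalized coefficient, then name) and capped at max_candidates.
screen_candidates <- function(y, W, X, max_candidates = 8L, n_lambda = 20L) {
  cn <- colnames(W)
  freq <- numeric(ncol(W)); coefmax <- numeric(ncol(W))
  tally <- function(fits) {
    for (f in fits) {
      freq[f$support] <<- freq[f$support] + 1
      coefmax <<- pmax(coefmax, abs(f$coef_pen))
    }
  }
  tally(fit_sparse_sem_node(y, W, X, select = "all",
                            n_lambda = n_lambda)$fits)
  tally(neighborhood_lasso_path(y, W, n_lambda = n_lambda))
  hit <- which(freq > 0)
  hit <- hit[order(-freq[hit], -coefmax[hit], cn[hit])]
  cn[utils::head(hit, max_candidates)]
}

## Plain lasso path of y on the standardized columns of W, solved with
## the same ADMM core (P = W'W, q = W'y on centered, scaled data).
## Returns per-lambda fits shaped like fit_sparse_sem_node's path fits.
neighborhood_lasso_path <- function(y, W, n_lambda = 20L,
                                    lambda_min_ratio = 1e-3) {
  Wc <- scale(as.matrix(W))
  Wc[is.na(Wc)] <- 0
  yc <- as.numeric(scale(y)); yc[is.na(yc)] <- 0
  P <- crossprod(Wc)
  q <- as.numeric(crossprod(Wc, yc))
  lambda_max <- max(abs(2 * q)); if (lambda_max <= 0) lambda_max <- 1
  grid <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                  length.out = n_lambda))
  fits <- vector("list", length(grid))
  init <- NULL
  for (k in seq_along(grid)) {
    f <- admm_lasso_quad(P, q, grid[k], init = init)
    init <- f$coef
    fits[[k]] <- list(support = which(f$coef != 0), coef_pen = f$coef)
  }
  fits
}

## Shared core of the SEMIP and multilevel learners.
semip_core <- function(dataset, max_parents = 3L, penalty_c = 1,
                       max_candidates = 8L, n_lambda = 20L,
                       score = c("rss", "bic", "tsls"), edge_alpha = 0.05,
                       time_limit_s = 15, verbose = FALSE) {
  score <- match.arg(score)
  stopifnot(inherits(dataset, "omics_dataset"))
  dat <- dataset$data
  layer <- dataset$layer
  exo <- names(layer)[layer == "genotype"]
  scored <- names(layer)[layer != "genotype"]
  if (!length(scored)) stop2("dataset has no endogenous layer")
  if (!length(exo)) stop2("2SLS screening needs at least one genotype node")
  X <- dat[, exo, drop = FALSE]
  screens <- list()
  for (node in scored) {
    adm_layers <- .layer_rules[[layer[node]]]
    if (is.null(adm_layers))
      stop2("no layer rule for layer '", layer[node], "'")
    cand_all <- setdiff(names(layer)[layer %in% adm_layers], node)
    screens[[node]] <- if (length(cand_all)) {
      screen_candidates(dat[, node], dat[, cand_all, drop = FALSE], X,
                        max_candidates = max_candidates, n_lambda = n_lambda)
    } else character(0)
  }
  ## symmetry completion: if v screened u, u is also a candidate parent
  ## of v (when admissible) -- an adjacency missed from one side is
  ## usually visible from the other
  scores <- list()
  for (node in scored) {
    adm_layers <- .layer_rules[[layer[node]]]
    back <- names(screens)[vapply(screens, function(s) node %in% s,
                                  logical(1))]
    back <- back[layer[back] %in% adm_layers]
    cand <- union(screens[[node]], back)
    scores[[node]] <- enumerate_parent_sets(node, cand, dat,
                                            max_parents = max_parents,
                                            penalty_c = penalty_c,
                                            score = score, instruments = X)
  }
  net <- solve_ilp(scores, layer = layer, time_limit_s = time_limit_s,
                   verbose = verbose)
  if (!is.null(edge_alpha) && is.finite(edge_alpha) && nrow(net$edges)) {
    ## retain an edge only when its path coefficient is significantly
    ## nonzero in the unpenalized 2SLS refit of the chosen parent set.
    ## The test is applied only to identifiable parents (first-stage
    ## F >= 10 on the instruments, the usual weak-instrument rule);
    ## edges from weakly instrumented parents are kept as selected.
    n <- nrow(dat); K <- ncol(X)
    fstage <- vapply(colnames(dat), function(v) {
      if (v %in% exo) return(Inf)
      r2 <- summary(stats::lm(dat[, v] ~ X))$r.squared
      (r2 / K) / ((1 - r2) / (n - K - 1))
    }, numeric(1))
    keep <- rep(TRUE, nrow(net$edges))
    coefs <- pvals <- rep(NA_real_, nrow(net$edges))
    for (node in names(net$parent_sets)) {
      pa <- net$parent_sets[[node]]
      if (!length(pa)) next
      obj <- two_stage_objective(dat[, node], dat[, pa, drop = FALSE], X)
      rf <- refit_support(obj, seq_along(pa))
      idx <- match(paste(pa, node), paste(net$edges$parent, net$edges$child))
      coefs[idx] <- rf$coef
      pvals[idx] <- rf$p_values
      keep[idx] <- rf$p_values < edge_alpha | fstage[pa] < 10
    }
    net$edges$coefficient <- coefs
    net$edges$p_value <- pvals
    net$edges <- net$edges[keep, , drop = FALSE]
    rownames(net$edges) <- NULL
    net$edge_alpha <- edge_alpha
  }
  net
}

#' Learn a causal DAG by sparse SEM screening and integer programming
#'
#' The SEMIP estimator: for every endogenous node, candidate parents are
#' pre-screened as the union of sparse penalized-2SLS supports over the
#' penalty path (other endogenous nodes plus all genotype nodes as
#' candidates, genotype nodes as instruments); all parent subsets up to
#' `max_parents` of the screened candidates are scored by the penalized
#' projection score; and the score-optimal DAG is selected exactly by
#' [solve_ilp()]. Genotype nodes enter only as candidate parents and keep
#' in-degree zero.
#'
#' @param dataset an `"omics_dataset"` with a `"genotype"` layer and at
#'   least one endogenous layer.
#' @param max_parents maximum parent-set size (default 3).
#' @param penalty_c complexity-penalty multiplier of [node_score()].
#' @param max_candidates cap on screened candidate parents per node.
#' @param n_lambda penalty-grid size of the screening fits.
#' @param score parent-set score: `"rss"` (default) is the penalized
#'   projection score of [node_score()]; `"tsls"` scores a parent set by
#'   the two-stage least-squares quadratic form at its minimizer
#'   ([node_score_tsls()]).
#' @param edge_alpha after the optimal DAG is selected, each chosen
#'   parent set is refit by unpenalized 2SLS and an edge is retained only
#'   when its path coefficient differs significantly from zero at this
#'   level (default 0.05; `NULL` to keep all selected edges).
#' @param time_limit_s solver wall-clock limit in seconds (default 15).
#'   When the search finishes earlier the result carries a proof of
#'   optimality; at the limit the best incumbent is returned with
#'   `optimal = FALSE`.
#' @param verbose print solver progress.
#' @return a `"layered_network"` (acyclic; see [solve_ilp()]).
#' @examples
#' m <- random_dag(sim_config(n_nodes = 6, n_genotype = 2, target_edges = 5),
#'                 seed = 4)
#' d <- simulate_dataset(m, 300, seed = 5)
#' net <- learn_semip_network(d)
#' evaluate_network(m, net, mode = "directed")
#' @export
learn_semip_network <- function(dataset, max_parents = 3L, penalty_c = 1,
                                max_candidates = 8L, n_lambda = 20L,
                                score = c("rss", "bic", "tsls"), edge_alpha = 0.05,
                                time_limit_s = 15, verbose = FALSE) {
  semip_core(dataset, max_parents = max_parents, penalty_c = penalty_c,
             max_candidates = max_candidates, n_lambda = n_lambda,
             score = score, edge_alpha = edge_alpha,
             time_limit_s = time_limit_s, verbose = verbose)
}

#' Learn a joint multilevel causal network across omics layers
#'
#' Builds one joint scored program over methylation, expression,
#' phenotype and disease nodes with layer-respecting candidate parent
#' sets -- methylation nodes may have methylation or genotype parents;
#' expression nodes may additionally have methylation parents; phenotype
#' and disease nodes may have parents from any upstream non-disease
#' layer -- and solves it as a single integer program, so acyclity holds
#' jointly across layers. Genotype variables are exogenous instruments
#' and candidate parents only.
#'
#' By default the nodes are scored by the penalized projection
#' (residual-sum-of-squares) score of [node_score()]; `score = "tsls"`
#' switches to the instrumented score as in [learn_semip_network()].
#'
#' @param genotype samples x variants/genes numeric matrix (exogenous).
#' @param methylation,expression,phenotype,disease optional sample-aligned
#'   numeric matrices of the remaining layers (at least one required).
#' @param score parent-set score, `"rss"` (default) or `"tsls"`.
#' @param ... further settings forwarded to the learner (see
#'   [learn_semip_network()]).
#' @return a `"layered_network"` over all supplied layers.
#' @export
learn_multilevel_network <- function(genotype, methylation = NULL,
                                     expression = NULL, phenotype = NULL,
                                     disease = NULL,
                                     score = c("rss", "bic", "tsls"), ...) {
  score <- match.arg(score)
  mats <- list(genotype = genotype, methylation = methylation,
               expression = expression, phenotype = phenotype,
               disease = disease)
  mats <- Filter(Negate(is.null), mats)
  if (length(mats) < 2L)
    stop2("need the genotype layer plus at least one downstream layer")
  n <- nrow(as.matrix(mats[[1L]]))
  for (nm in names(mats)) {
    mats[[nm]] <- as.matrix(mats[[nm]])
    if (nrow(mats[[nm]]) != n)
      stop2("matrix '", nm, "' is not sample-aligned (", nrow(mats[[nm]]),
            " rows, expected ", n, ")")
    if (is.null(colnames(mats[[nm]])))
      colnames(mats[[nm]]) <- paste0(substr(nm, 1, 1), seq_len(ncol(mats[[nm]])))
  }
  dat <- do.call(cbind, unname(mats))
  if (anyDuplicated(colnames(dat)))
    stop2("column names must be unique across layers")
  layer <- rep(names(mats), vapply(mats, ncol, integer(1)))
  dataset <- new_omics_dataset(dat, layer)
  semip_core(dataset, score = score, ...)
}
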