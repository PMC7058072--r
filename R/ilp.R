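## Score-and-search causal DAG learning. Each node carries a list of
## candidate parent sets with decomposable scores; selecting exactly one
## set per node (convexity constraint) subject to the cluster constraints
## (every node subset contains a node whose parents lie outside it --
## acyclicity) is a 0-1 integer program. It is solved exactly by branch
## and bound with lazily generated cycle constraints: the relaxation
## drops acyclicity, each node independently takes its cheapest allowed
## parent set; a directed cycle in the relaxed solution yields the
## violated constraint on which we branch.

#' Penalized projection score of a child given a parent set
#'
#' Residual sum of squares of the child after projection onto the parent
#' design (an intercept column is always included), plus the complexity
#' penalty `penalty_c * n_parents * log(n)`. The empty parent set scores
#' the centered total sum of squares. Smaller is better.
#'
#' @param y child data vector.
#' @param D parent design matrix (columns = parents), or `NULL` for the
#'   empty set.
#' @param penalty_c penalty multiplier (default 1, a BIC-type penalty).
#' @param ridge relative ridge applied if the design is singular
#'   (flagged with a warning).
#' @param form `"rss"` (default) returns the residual sum of squares plus
#'   penalty; `"bic"` returns the scale-invariant Gaussian form
#'   `n log(RSS/n)` plus the same penalty, which weighs fit gains
#'   relative to the child's residual variance and is comparable across
#'   children of very different scales.
#' @return numeric scalar.
#' @examples
#' y <- rnorm(30); D <- cbind(rnorm(30))
#' node_score(y, D) - node_score(y, NULL)  # gain from one parent
#' @export
node_score <- function(y, D = NULL, penalty_c = 1, ridge = 1e-8,
                       form = c("rss", "bic")) {
  form <- match.arg(form)
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(D) || NCOL(D) == 0L) {
    rss <- sum((y - mean(y))^2)
    return(if (form == "bic") n * log(max(rss, 1e-12) / n) else rss)
  }
  D <- as.matrix(D)
  if (nrow(D) != n) stop2("y and design have different sample counts")
  if (ncol(D) >= n) stop2("parent design must have fewer columns than samples")
  X <- cbind(1, D)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    warning("singular parent design; ridge-regularized projection used")
    G <- crossprod(X) + diag(ridge * sum(diag(crossprod(X))) / ncol(X),
                             ncol(X))
    beta <- solve(G, crossprod(X, y))
    rss <- sum((y - X %*% beta)^2)
  } else {
    rss <- sum(qr.resid(qrx, y)^2)
  }
  fit <- if (form == "bic") n * log(max(rss, 1e-12) / n) else rss
  fit + penalty_c * ncol(D) * log(n)
}

#' Penalized two-stage least squares score of a child given a parent set
#'
#' The instrumental-variable analogue of [node_score()]: the 2SLS
#' quadratic-form objective `f(D)` of [two_stage_objective()] evaluated at
#' its unpenalized minimizer over the parent-set coefficients, plus the
#' complexity penalty `penalty_c * n_parents * log(n)`. Because the fit
#' criterion projects through the exogenous instruments, this score can
#' distinguish edge orientations that a plain residual-sum-of-squares
#' score cannot.
#'
#' @param y child data vector.
#' @param D parent design matrix (columns = parents), or `NULL` for the
#'   empty set.
#' @param X instrument matrix (exogenous variables).
#' @param penalty_c penalty multiplier (default 1).
#' @return numeric scalar (smaller is better).
#' @export
node_score_tsls <- function(y, D = NULL, X, penalty_c = 1) {
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(D) || NCOL(D) == 0L) {
    ## empty set: f(0) = y'X (X'X)^{-1} X'y on centered data
    Xc <- scale(as.matrix(X), center = TRUE, scale = FALSE)
    yc <- y - mean(y)
    A <- crossprod(Xc)
    r <- crossprod(Xc, yc)
    return(as.numeric(t(r) %*% chol2inv(chol(A)) %*% r))
  }
  D <- as.matrix(D)
  obj <- two_stage_objective(y, W = D, X = X)
  f_min <- obj$eval(obj$minimizer)
  f_min + penalty_c * ncol(D) * log(n)
}

#' Enumerate and score candidate parent sets for one child
#'
#' Scores every subset of the candidate parents up to `max_parents`
#' members with [node_score()]. The empty set is always included. With
#' `prune = TRUE`, any set scoring no better than one of its proper
#' subsets is dropped (dominance pruning); this never removes the optimum
#' of the downstream DAG program because any selection using a dominated
#' set can be replaced by its dominating subset without creating cycles.
#'
#' @param child child column name.
#' @param candidates character vector of candidate parent names (must not
#'   contain the child).
#' @param data samples x variables numeric matrix containing child and
#'   candidates.
#' @param max_parents maximum parent-set size (default 3).
#' @param penalty_c passed to the score function.
#' @param prune apply dominance pruning (default TRUE).
#' @param score `"rss"` for the projection score [node_score()]; `"bic"`
#'   for its scale-invariant Gaussian form; `"tsls"` for the instrumented
#'   score [node_score_tsls()] (requires `instruments`).
#' @param instruments matrix of exogenous instrument columns for
#'   `score = "tsls"`.
#' @return list of entries `list(parents = <character>, score = <numeric>)`,
#'   ordered by score (ties: smaller set, then lexicographic parents).
#' @export
enumerate_parent_sets <- function(child, candidates, data, max_parents = 3L,
                                  penalty_c = 1, prune = TRUE,
                                  score = c("rss", "bic", "tsls"),
                                  instruments = NULL) {
  score <- match.arg(score)
  if (max_parents < 0L) stop2("max_parents must be >= 0")
  if (child %in% candidates) stop2("candidate list contains the child")
  if (score == "tsls" && is.null(instruments))
    stop2("score = 'tsls' needs an instruments matrix")
  data <- as.matrix(data)
  y <- data[, child]
  candidates <- as.character(candidates)
  sets <- list(character(0))
  for (k in seq_len(min(max_parents, length(candidates)))) {
    cmb <- utils::combn(candidates, k, simplify = FALSE)
    sets <- c(sets, cmb)
  }
  scores <- vapply(sets, function(s) {
    D <- if (length(s)) data[, s, drop = FALSE] else NULL
    if (score == "tsls") node_score_tsls(y, D, instruments,
                                         penalty_c = penalty_c)
    else node_score(y, D, penalty_c = penalty_c,
                    form = if (score == "bic") "bic" else "rss")
  }, numeric(1))
  entries <- Map(function(s, sc) list(parents = s, score = sc), sets, scores)
  if (prune && length(entries) > 1L) {
    keys <- vapply(entries, function(e) paste(sort(e$parents), collapse = ","),
                   character(1))
    best_sub <- function(e) {
      ## best score among proper subsets present in the enumeration
      if (!length(e$parents)) return(Inf)
      subs <- unlist(lapply(0:(length(e$parents) - 1L), function(k)
        utils::combn(e$parents, k, simplify = FALSE)), recursive = FALSE)
      min(vapply(subs, function(s) {
        i <- match(paste(sort(s), collapse = ","), keys)
        if (is.na(i)) Inf else entries[[i]]$score
      }, numeric(1)))
    }
    keep <- vapply(entries, function(e) e$score < best_sub(e), logical(1))
    keep[1L] <- TRUE   # empty set always kept
    entries <- entries[keep]
  }
  entries[order_parent_sets(entries)]
}

## deterministic candidate ordering: score, then set size, then
## lexicographic sorted-parent encoding
order_parent_sets <- function(entries) {
  sc <- vapply(entries, `[[`, numeric(1), "score")
  sz <- vapply(entries, function(e) length(e$parents), integer(1))
  key <- vapply(entries, function(e) paste(sort(e$parents), collapse = ","),
                character(1))
  order(sc, sz, key)
}

## ---- internal solver state -------------------------------------------

## Build the internal instance from a named list of candidate lists:
## scores[[child]] = list(list(parents = chr, score = num), ...).
build_instance <- function(scores) {
  scored <- names(scores)
  if (is.null(scored) || any(!nzchar(scored)))
    stop2("scores must be a named list (one entry per scored node)")
  for (v in scored) {
    if (!length(scores[[v]])) stop2("node ", v, " has no candidate parent set")
    if (!any(vapply(scores[[v]], function(e) length(e$parents) == 0L,
                    logical(1))))
      stop2("node ", v, " must include the empty parent set")
  }
  m <- length(scored)
  inst <- list(scored = scored, m = m)
  inst$score <- vector("list", m)
  inst$pa_scored <- vector("list", m)  # parents among scored nodes (indices)
  inst$pa_all <- vector("list", m)     # full parent label sets
  for (v in seq_len(m)) {
    ent <- scores[[scored[v]]]
    ent <- ent[order_parent_sets(ent)]
    inst$score[[v]] <- vapply(ent, `[[`, numeric(1), "score")
    inst$pa_all[[v]] <- lapply(ent, `[[`, "parents")
    inst$pa_scored[[v]] <- lapply(ent, function(e)
      match(intersect(e$parents, scored), scored))
    if (any(vapply(inst$pa_all[[v]], function(s) scored[v] %in% s,
                   logical(1))))
      stop2("node ", scored[v], " appears in one of its own parent sets")
  }
  ## membership masks: has_par[[v]][k, u] is TRUE when candidate k of
  ## node v contains scored node u -- used for fast edge forcing
  inst$has_par <- lapply(seq_len(m), function(v) {
    mk <- matrix(FALSE, length(inst$score[[v]]), m)
    for (k in seq_along(inst$pa_scored[[v]]))
      mk[k, inst$pa_scored[[v]][[k]]] <- TRUE
    mk
  })
  inst
}

## Relaxed solution under an allowed-mask list: each node takes its first
## allowed (= cheapest) candidate. Returns NULL if some node has none.
relax_choose <- function(inst, allowed) {
  chosen <- integer(inst$m)
  for (v in seq_len(inst$m)) {
    i <- which(allowed[[v]])[1L]
    if (is.na(i)) return(NULL)
    chosen[v] <- i
  }
  chosen
}

relax_bound <- function(inst, chosen) {
  sum(vapply(seq_len(inst$m), function(v) inst$score[[v]][chosen[v]],
             numeric(1)))
}

chosen_cycle <- function(inst, chosen) {
  parents <- lapply(seq_len(inst$m), function(v)
    inst$pa_scored[[v]][[chosen[v]]])
  find_cycle(parents, inst$m)
}

## Greedy incumbent: repeatedly repair the cheapest-choice solution by
## forbidding, for some cycle edge u -> w, all of w's candidates that
## contain u -- picking the repair with the smallest score increase.
greedy_incumbent <- function(inst) {
  allowed <- lapply(inst$score, function(s) rep(TRUE, length(s)))
  repeat {
    chosen <- relax_choose(inst, allowed)
    if (is.null(chosen)) return(NULL)
    cyc <- chosen_cycle(inst, chosen)
    if (is.null(cyc)) return(list(chosen = chosen,
                                  score = relax_bound(inst, chosen)))
    k <- length(cyc)
    best_v <- NA_integer_; best_mask <- NULL; best_inc <- Inf
    for (i in seq_len(k)) {
      u <- cyc[i]; w <- cyc[if (i == k) 1L else i + 1L]
      mask <- allowed[[w]] & !vapply(inst$pa_scored[[w]],
                                     function(s) u %in% s, logical(1))
      j <- which(mask)[1L]
      if (is.na(j)) next
      inc <- inst$score[[w]][j] - inst$score[[w]][chosen[w]]
      if (inc < best_inc) { best_inc <- inc; best_v <- w; best_mask <- mask }
    }
    if (is.na(best_v)) return(NULL)
    allowed[[best_v]] <- best_mask
  }
}

#' Exact DAG selection from parent-set scores by branch and bound
#'
#' Minimizes the decomposable total score subject to the convexity
#' constraint (exactly one parent set per node) and the cluster
#' constraints (acyclicity). Constraints are generated lazily: the
#' relaxation lets every node take its cheapest admissible parent set; a
#' directed cycle in the relaxed solution is the violated cluster, and
#' the search branches over which cycle edge to forbid (a partition:
#' branch i keeps cycle edges 1..i-1 and forbids edge i). Node bounds
#' from the relaxation prune the search; the result carries a proof of
#' optimality unless the time limit is hit, in which case the best
#' incumbent is returned with `optimal = FALSE`.
#'
#' Layer rules are enforced upstream through the candidate parent sets;
#' exogenous (e.g. genotype) variables may appear in parent sets without
#' being scored nodes and can never participate in a cycle.
#'
#' @param scores named list: `scores[[child]]` is a list of candidate
#'   entries `list(parents = <character>, score = <numeric>)`, each
#'   including the empty set (e.g. from [enumerate_parent_sets()]).
#' @param layer optional named layer vector for the output network.
#' @param time_limit_s wall-clock limit in seconds (default `Inf`).
#' @param verbose print search progress.
#' @return object of class `"layered_network"`: list with `nodes`,
#'   `layer`, `edges` (data frame `parent`, `child`, `parent_layer`,
#'   `child_layer`), `parent_sets` (chosen set per scored node),
#'   `total_score`, `optimal`, and solver statistics in `stats`.
#' @seealso [exhaustive_dag_search()] for the small-instance oracle.
#' @export
solve_ilp <- function(scores, layer = NULL, time_limit_s = Inf,
                      verbose = FALSE) {
  inst <- build_instance(scores)
  t0 <- proc.time()[["elapsed"]]
  inc <- greedy_incumbent(inst)
  if (is.null(inc)) stop2("no acyclic selection exists for these candidates")
  ## candidate parent sets as 0-based indices for the compiled search
  pa0 <- lapply(inst$pa_scored, function(lst)
    lapply(lst, function(p) as.integer(p - 1L)))
  res <- .solve_ilp_engine(inst$score, pa0, inst$m, time_limit_s,
                           as.integer(inc$chosen - 1L), inc$score)
  best_chosen <- res$chosen + 1L
  best_score <- res$total
  if (verbose)
    message(sprintf("optimum %.6g (%d branches, %d cuts, %.2f s)",
                    best_score, as.integer(res$branches),
                    as.integer(res$cycle_cuts), res$seconds))
  build_network(inst, best_chosen, best_score, layer,
                optimal = isTRUE(res$optimal),
                stats = list(branches = res$branches,
                             cycle_cuts = res$cycle_cuts,
                             seconds = proc.time()[["elapsed"]] - t0))
}

## Assemble a layered_network from a chosen-candidate vector.
build_network <- function(inst, chosen, total, layer, optimal, stats) {
  parent_sets <- stats::setNames(
    lapply(seq_len(inst$m), function(v) inst$pa_all[[v]][[chosen[v]]]),
    inst$scored)
  edges <- do.call(rbind, lapply(inst$scored, function(v) {
    pa <- parent_sets[[v]]
    if (!length(pa)) return(NULL)
    data.frame(parent = pa, child = v, stringsAsFactors = FALSE)
  }))
  if (is.null(edges))
    edges <- data.frame(parent = character(0), child = character(0))
  nodes <- unique(c(inst$scored, edges$parent))
  if (is.null(layer)) {
    layer <- stats::setNames(
      ifelse(nodes %in% inst$scored, "endogenous", "genotype"), nodes)
  } else {
    layer <- layer[nodes]
  }
  edges$parent_layer <- unname(layer[edges$parent])
  edges$child_layer <- unname(layer[edges$child])
  rownames(edges) <- NULL
  structure(list(nodes = nodes, layer = layer, edges = edges,
                 parent_sets = parent_sets, total_score = total,
                 optimal = optimal, stats = stats),
            class = "layered_network")
}

#' @export
print.layered_network <- function(x, ...) {
  cat(sprintf("Layered causal network: %d nodes, %d edges, score %.4g%s\n",
              length(x$nodes), nrow(x$edges), x$total_score,
              if (isTRUE(x$optimal)) " (optimal)" else " (incumbent)"))
  invisible(x)
}

#' Exhaustive optimal-DAG oracle for small instances
#'
#' Independent check of [solve_ilp()]: every DAG is consistent with some
#' topological order, and for a fixed order the best selection picks,
#' for each node independently, its cheapest candidate parent set drawn
#' from the node's predecessors (plus exogenous variables). Minimizing
#' over all orders of the scored nodes therefore yields the global
#' optimum. Only intended for small instances.
#'
#' @inheritParams solve_ilp
#' @param max_nodes refuse instances with more scored nodes than this
#'   (default 6).
#' @return a `"layered_network"`.
#' @export
exhaustive_dag_search <- function(scores, layer = NULL, max_nodes = 6L) {
  inst <- build_instance(scores)
  m <- inst$m
  if (m > max_nodes)
    stop2("exhaustive search limited to ", max_nodes, " scored nodes")
  perms <- all_permutations(m)
  best_score <- Inf; best_chosen <- NULL
  for (ord in perms) {
    chosen <- integer(m)
    total <- 0
    pred <- logical(m)
    for (v in ord) {
      ## cheapest candidate whose scored parents are all predecessors
      ok <- vapply(inst$pa_scored[[v]], function(p) all(pred[p]), logical(1))
      k <- which(ok)[1L]          # candidates sorted by score
      chosen[v] <- k
      total <- total + inst$score[[v]][k]
      pred[v] <- TRUE
    }
    if (total < best_score - 1e-12) { best_score <- total; best_chosen <- chosen }
  }
  build_network(inst, best_chosen, best_score, layer, optimal = TRUE,
                stats = list(branches = length(perms), cycle_cuts = 0L,
                             seconds = NA_real_))
}

## all permutations of 1..m as a list of integer vectors
all_permutations <- function(m) {
  if (m == 1L) return(list(1L))
  out <- list()
  for (sub in all_permutations(m - 1L)) {
    for (pos in seq_len(m)) {
      out[[length(out) + 1L]] <- append(sub, values = m, after = pos - 1L)
    }
  }
  out
}
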