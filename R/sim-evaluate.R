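## Power / FDR scoring of an estimated network against the simulated truth.

## Coerce the various network representations used across the package
## (true_model, sem_network, layered_network, cor_network, edge data frame,
## adjacency matrix) to a 0/1 adjacency matrix over a given node set.
as_adjacency <- function(x, nodes = NULL) {
  if (inherits(x, "true_model")) return(x$adj != 0)
  if (inherits(x, c("sem_network", "layered_network", "cor_network"))) {
    nodes <- nodes %||% x$nodes
    adj <- matrix(FALSE, length(nodes), length(nodes),
                  dimnames = list(nodes, nodes))
    e <- x$edges
    if (!is.null(e) && nrow(e)) {
      adj[cbind(match(e$parent, nodes), match(e$child, nodes))] <- TRUE
      if (inherits(x, "cor_network"))
        adj[cbind(match(e$child, nodes), match(e$parent, nodes))] <- TRUE
    }
    return(adj)
  }
  if (is.data.frame(x)) {
    if (is.null(nodes)) nodes <- sort(unique(c(x[[1L]], x[[2L]])))
    adj <- matrix(FALSE, length(nodes), length(nodes),
                  dimnames = list(nodes, nodes))
    if (nrow(x)) adj[cbind(match(x[[1L]], nodes), match(x[[2L]], nodes))] <- TRUE
    return(adj)
  }
  if (is.matrix(x)) {
    adj <- x != 0
    if (!is.null(nodes) && !is.null(rownames(adj))) {
      if (!setequal(rownames(adj), nodes))
        stop2("truth and estimate node sets differ")
      adj <- adj[nodes, nodes, drop = FALSE]
    }
    return(adj)
  }
  stop2("cannot interpret object of class '", paste(class(x), collapse = "/"),
        "' as a network")
}

#' Score an estimated network against a simulated true DAG
#'
#' Compares an estimated graph with the true DAG and returns the benchmark
#' confusion counts and rates. With `n` nodes, `N_t` true edges and, in
#' directed mode, `N_0 = n(n-1) - N_t` absent ordered pairs (skeleton pairs
#' in undirected mode), the power of detection is `N_True / N_t` and two
#' false-discovery summaries are reported: `fdr_ref = N_False / N_0` (a
#' false positive rate over absent edges) and the conventional
#' `fdr_conventional = N_False / (N_True + N_False)` (0 when nothing is
#' detected).
#'
#' @param truth the simulated truth: a `"true_model"`, adjacency matrix or
#'   edge data frame.
#' @param estimate the estimated network: any representation accepted by
#'   the package (`"sem_network"`, `"layered_network"`, `"cor_network"`,
#'   adjacency matrix, or a parent/child edge data frame).
#' @param mode `"directed"` compares ordered node pairs; `"undirected"`
#'   compares skeletons (unordered pairs).
#' @return an object of class `"power_fdr"`: one-row data frame with
#'   columns `n_t`, `n_0`, `n_true`, `n_false`, `power`, `fdr_ref`,
#'   `fdr_conventional` and `mode`.
#' @examples
#' truth <- matrix(0, 3, 3, dimnames = rep(list(c("A", "B", "C")), 2))
#' truth["A", "B"] <- truth["B", "C"] <- 1
#' est <- truth; est["B", "C"] <- 0; est["C", "B"] <- 1
#' evaluate_network(truth, est, mode = "directed")
#' @export
evaluate_network <- function(truth, estimate,
                             mode = c("directed", "undirected")) {
  mode <- match.arg(mode)
  tadj <- as_adjacency(truth)
  nodes <- rownames(tadj)
  eadj <- as_adjacency(estimate, nodes = nodes)
  if (!identical(dim(tadj), dim(eadj)))
    stop2("truth and estimate must share one node set")
  if (!is.null(rownames(eadj)) && !is.null(nodes) &&
      !identical(rownames(eadj), nodes))
    stop2("truth and estimate node sets differ")
  n <- nrow(tadj)
  diag(tadj) <- FALSE; diag(eadj) <- FALSE
  if (mode == "undirected") {
    tadj <- tadj | t(tadj); eadj <- eadj | t(eadj)
    ut <- upper.tri(tadj)
    n_t <- sum(tadj[ut]); n_0 <- n * (n - 1) / 2 - n_t
    n_true <- sum((tadj & eadj)[ut]); n_false <- sum((!tadj & eadj)[ut])
  } else {
    off <- !diag(n)
    n_t <- sum(tadj[off]); n_0 <- n * (n - 1) - n_t
    n_true <- sum((tadj & eadj)[off]); n_false <- sum((!tadj & eadj)[off])
  }
  out <- data.frame(
    n_t = n_t, n_0 = n_0, n_true = n_true, n_false = n_false,
    power = if (n_t > 0) n_true / n_t else NA_real_,
    fdr_ref = if (n_0 > 0) n_false / n_0 else NA_real_,
    fdr_conventional = if (n_true + n_false > 0)
      n_false / (n_true + n_false) else 0,
    mode = mode, stringsAsFactors = FALSE
  )
  class(out) <- c("power_fdr", class(out))
  out
}
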