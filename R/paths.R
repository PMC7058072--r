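## Causal-path enumeration and disease-connectivity classification on an
## inferred multilevel network.

## children adjacency list (lexicographically sorted) from any network
## representation accepted by as_adjacency().
children_list <- function(network, terminal = character(0)) {
  adj <- as_adjacency(network)
  nodes <- rownames(adj) %||% paste0("V", seq_len(nrow(adj)))
  rownames(adj) <- colnames(adj) <- nodes
  ch <- lapply(nodes, function(v) {
    if (v %in% terminal) return(character(0))
    sort(nodes[adj[v, ]])
  })
  names(ch) <- nodes
  ch
}

#' Enumerate all simple causal paths between two nodes
#'
#' Depth-first search with an explicit iterative stack (no recursion
#' limit) enumerating every simple directed path from `source` to
#' `target` of length at most `max_length`, in lexicographic node order.
#' By default nodes of the `"disease"` layer other than the target are
#' terminal (paths do not traverse a disease as an intermediate).
#'
#' @param network a `"layered_network"`, `"sem_network"`, adjacency
#'   matrix, or parent/child edge data frame.
#' @param source,target node names (`source != target`).
#' @param max_length maximum number of edges per path (default 10).
#' @param max_paths cap on the number of returned paths (default 1e5);
#'   when exceeded the result is truncated and flagged via attribute
#'   `"truncated"`.
#' @param traverse_disease allow paths through intermediate disease
#'   nodes (default FALSE).
#' @return object of class `"causal_paths"`: list of character vectors
#'   (each a node sequence `source ... target`), with attributes
#'   `"truncated"` and `"lengths"`.
#' @examples
#' e <- data.frame(parent = c("A", "A", "B", "C"),
#'                 child  = c("B", "C", "D", "D"))
#' find_causal_paths(e, "A", "D")
#' @export
find_causal_paths <- function(network, source, target, max_length = 10L,
                              max_paths = 1e5, traverse_disease = FALSE) {
  if (identical(source, target)) stop2("source and target must differ")
  terminal <- character(0)
  if (!traverse_disease && inherits(network, "layered_network"))
    terminal <- setdiff(names(network$layer)[network$layer == "disease"],
                        source)
  ch <- children_list(network, terminal = terminal)
  if (!source %in% names(ch)) stop2("source node '", source, "' not in network")
  if (!target %in% names(ch)) stop2("target node '", target, "' not in network")
  paths <- list()
  truncated <- FALSE
  ## iterative DFS: stack of (node, next-child index); path mirrors stack
  stack_v <- source
  stack_i <- 0L
  onpath <- stats::setNames(FALSE, source); onpath[source] <- TRUE
  while (length(stack_v)) {
    d <- length(stack_v)
    v <- stack_v[d]
    i <- stack_i[d] + 1L
    kids <- ch[[v]]
    if (i > length(kids) || d > max_length) {
      onpath[v] <- FALSE
      stack_v <- stack_v[-d]; stack_i <- stack_i[-d]
      next
    }
    stack_i[d] <- i
    w <- kids[i]
    if (w == target) {
      if (length(paths) >= max_paths) { truncated <- TRUE; break }
      paths[[length(paths) + 1L]] <- c(stack_v, target)
      next
    }
    if (isTRUE(onpath[w])) next
    onpath[w] <- TRUE
    stack_v <- c(stack_v, w); stack_i <- c(stack_i, 0L)
  }
  structure(paths, class = "causal_paths", truncated = truncated,
            lengths = lengths(paths) - 1L)
}

#' @export
print.causal_paths <- function(x, ...) {
  cat(sprintf("%d causal path(s)%s\n", length(x),
              if (isTRUE(attr(x, "truncated"))) " (truncated)" else ""))
  for (p in utils::head(x, 10L)) cat(" ", paste(p, collapse = " -> "), "\n")
  if (length(x) > 10L) cat("  ...\n")
  invisible(x)
}

## does any simple path of length >= 2 run from src to target?
## src -> m -> ... -> target with m != target and src excluded from the
## continuation (a shortest walk avoiding src is itself simple).
has_indirect_path <- function(ch, src, target) {
  for (m in setdiff(ch[[src]], c(target, src))) {
    ## BFS from m over the graph with src removed
    seen <- stats::setNames(logical(length(ch)), names(ch))
    queue <- m; seen[m] <- TRUE
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (v == target) return(TRUE)
      for (w in ch[[v]]) {
        if (w != src && !seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
      }
    }
  }
  FALSE
}

#' Classify how nodes connect to a disease node
#'
#' A node is *directly* connected when the network contains the edge
#' node -> disease (or, when per-node causal-test results are supplied,
#' when its test p-value is below `alpha`); *indirectly* connected when a
#' simple directed path of length >= 2 leads from the node to the
#' disease; *both* when both hold; *none* when no directed path exists.
#'
#' @param network network representation (see [find_causal_paths()]).
#' @param query_nodes character vector of nodes to classify.
#' @param disease_node the disease node name.
#' @param direct_results optional data frame (`node`, `p_value`) of
#'   external causal tests; a p-value below `alpha` also counts as a
#'   direct connection (recorded in column `direct_test`).
#' @param alpha threshold applied to `direct_results`.
#' @param traverse_disease allow paths through other disease nodes.
#' @return data frame with columns `node`, `class`
#'   (`direct`/`indirect`/`both`/`none`), `direct_edge`, `direct_test`,
#'   `indirect`.
#' @export
classify_connectivity <- function(network, query_nodes, disease_node,
                                  direct_results = NULL, alpha = 0.05,
                                  traverse_disease = FALSE) {
  terminal <- character(0)
  if (!traverse_disease && inherits(network, "layered_network"))
    terminal <- setdiff(names(network$layer)[network$layer == "disease"],
                        query_nodes)
  terminal <- setdiff(terminal, disease_node)  # target stays reachable
  ch <- children_list(network, terminal = terminal)
  if (!disease_node %in% names(ch))
    stop2("disease node '", disease_node, "' not in network")
  rows <- lapply(query_nodes, function(g) {
    if (!g %in% names(ch))
      return(data.frame(node = g, class = "none", direct_edge = FALSE,
                        direct_test = FALSE, indirect = FALSE,
                        stringsAsFactors = FALSE))
    d_edge <- disease_node %in% ch[[g]]
    d_test <- FALSE
    if (!is.null(direct_results)) {
      i <- match(g, direct_results$node)
      d_test <- !is.na(i) && direct_results$p_value[i] < alpha
    }
    ind <- has_indirect_path(ch, g, disease_node)
    direct <- d_edge || d_test
    cls <- if (direct && ind) "both" else if (direct) "direct"
           else if (ind) "indirect" else "none"
    data.frame(node = g, class = cls, direct_edge = d_edge,
               direct_test = d_test, indirect = ind,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cross-tabulate connectivity of nodes to two diseases
#'
#' Classifies every query node against both disease nodes and returns the
#' 4 x 4 count table over `{direct, indirect, both, none}` plus the set
#' of nodes connected (any class except `none`) to both diseases.
#'
#' @inheritParams classify_connectivity
#' @param disease_a,disease_b the two disease node names.
#' @return object of class `"shared_connection"`: list with `table`
#'   (rows = classes w.r.t. `disease_a`, columns = w.r.t. `disease_b`),
#'   `shared_nodes`, and the two per-disease classifications.
#' @export
shared_connection_table <- function(network, query_nodes, disease_a,
                                    disease_b, direct_results = NULL,
                                    alpha = 0.05) {
  lv <- c("direct", "indirect", "both", "none")
  ca <- classify_connectivity(network, query_nodes, disease_a,
                              direct_results = direct_results, alpha = alpha)
  cb <- classify_connectivity(network, query_nodes, disease_b,
                              direct_results = direct_results, alpha = alpha)
  tab <- table(factor(ca$class, levels = lv), factor(cb$class, levels = lv),
               dnn = c(disease_a, disease_b))
  shared <- query_nodes[ca$class != "none" & cb$class != "none"]
  structure(list(table = tab, shared_nodes = shared,
                 class_a = ca, class_b = cb),
            class = "shared_connection")
}

#' @export
print.shared_connection <- function(x, ...) {
  print(x$table)
  cat(sprintf("%d node(s) connected to both diseases\n",
              length(x$shared_nodes)))
  invisible(x)
}
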