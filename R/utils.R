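## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
stop2 <- function(...) stop(..., call. = FALSE)

#' Check that a directed graph given as an adjacency matrix is acyclic.
#'
#' Kahn's algorithm; O(V + E).
#' @param adj square 0/1 adjacency matrix, `adj[i, j] == 1` meaning i -> j.
#' @return logical scalar.
#' @keywords internal
is_acyclic <- function(adj) {
  !is.null(topological_order(adj))
}

#' Topological order of an adjacency matrix, or NULL if cyclic.
#' @keywords internal
topological_order <- function(adj) {
  p <- nrow(adj)
  indeg <- colSums(adj != 0)
  queue <- which(indeg == 0L)
  order <- integer(0)
  indeg_work <- indeg
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    order <- c(order, v)
    ch <- which(adj[v, ] != 0)
    for (w in ch) {
      indeg_work[w] <- indeg_work[w] - 1L
      if (indeg_work[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(order) < p) NULL else order
}

## Find one directed cycle in a graph given as a parent map
## (list: for node v, integer vector of parents). Returns the node
## sequence of the cycle (v1 -> v2 -> ... -> v1) or NULL.
find_cycle <- function(parents, p) {
  ## children adjacency
  state <- integer(p)            # 0 unvisited, 1 on stack, 2 done
  pred <- integer(p)
  children <- vector("list", p)
  for (v in seq_len(p)) for (u in parents[[v]]) {
    children[[u]] <- c(children[[u]], v)
  }
  for (root in seq_len(p)) {
    if (state[root] != 0L) next
    stack <- list(list(v = root, i = 0L))
    state[root] <- 1L
    while (length(stack)) {
      top <- stack[[length(stack)]]
      v <- top$v
      i <- top$i + 1L
      ch <- children[[v]]
      if (i > length(ch)) {
        state[v] <- 2L
        stack[[length(stack)]] <- NULL
        next
      }
      stack[[length(stack)]]$i <- i
      w <- ch[i]
      if (state[w] == 1L) {
        ## unwind the stack to recover the cycle w -> ... -> v -> w
        seqv <- vapply(stack, function(s) s$v, integer(1))
        k <- max(which(seqv == w))
        return(seqv[k:length(seqv)])
      }
      if (state[w] == 0L) {
        state[w] <- 1L
        stack[[length(stack) + 1L]] <- list(v = w, i = 0L)
      }
    }
  }
  NULL
}

## Weighted median over values v with non-negative weights w.
weighted_median <- function(v, w) {
  o <- order(v)
  v <- v[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  v[which(cw >= 0.5)[1L]]
}

## Deterministic seed stream: derive sub-seeds from a master seed,
## kept within 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k * 1009) %% 2147483647)
}
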