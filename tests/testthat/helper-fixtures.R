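## Shared fixtures built in code.

## hand-built chain X1 -> Y1 -> Y2 with both coefficients 1.5
chain_model <- function(coef = 1.5, noise_sd = 1) {
  nodes <- c("X1", "Y1", "Y2")
  adj <- matrix(0L, 3, 3, dimnames = list(nodes, nodes))
  adj["X1", "Y1"] <- adj["Y1", "Y2"] <- 1L
  cf <- matrix(0, 3, 3, dimnames = list(nodes, nodes))
  cf["X1", "Y1"] <- cf["Y1", "Y2"] <- coef
  structure(list(
    nodes = nodes,
    layer = c(X1 = "genotype", Y1 = "endogenous", Y2 = "endogenous"),
    adj = adj, coef = cf, order = 1:3, noise_sd = noise_sd, config = NULL
  ), class = "true_model")
}

## adjacency matrix helper
adj_from_edges <- function(nodes, edges) {
  adj <- matrix(0, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  for (e in edges) adj[e[1L], e[2L]] <- 1
  adj
}

## random candidate parent-set instance for the ILP solver
random_ilp_instance <- function(m, max_parents = 3L, score_range = c(-10, 10)) {
  nodes <- LETTERS[seq_len(m)]
  scores <- list()
  for (v in nodes) {
    cand <- setdiff(nodes, v)
    sets <- list(character(0))
    for (k in seq_len(min(max_parents, length(cand))))
      sets <- c(sets, utils::combn(cand, k, simplify = FALSE))
    scores[[v]] <- lapply(sets, function(s)
      list(parents = s, score = stats::runif(1, score_range[1], score_range[2])))
  }
  scores
}

## brute-force two-sided Fisher p-value by enumerating all tables with
## the observed margins (independent oracle for independence_delta)
fisher_oracle <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  lp_table <- function(m) {
    sum(lfactorial(rs)) + sum(lfactorial(cs)) - lfactorial(n) -
      sum(lfactorial(m))
  }
  lp_obs <- lp_table(tab)
  total <- 0
  ## recursive enumeration over all non-negative integer matrices with
  ## the given margins
  enum <- function(m, row, colrem) {
    if (row > length(rs)) {
      lp <- lp_table(m)
      if (lp <= lp_obs + 1e-7) total <<- total + exp(lp)
      return(invisible())
    }
    cells <- expand_row(rs[row], colrem)
    for (i in seq_len(nrow(cells))) {
      m[row, ] <- cells[i, ]
      enum(m, row + 1L, colrem - cells[i, ])
    }
  }
  expand_row <- function(rtot, colrem) {
    k <- length(colrem)
    if (k == 1L) {
      if (rtot <= colrem) return(matrix(rtot, 1, 1)) else
        return(matrix(numeric(0), 0, 1))
    }
    out <- NULL
    for (x in 0:min(rtot, colrem[1L])) {
      rest <- expand_row(rtot - x, colrem[-1L])
      if (nrow(rest)) out <- rbind(out, cbind(x, rest))
    }
    out %||% matrix(numeric(0), 0, k)
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  enum(tab * 0, 1L, cs)
  min(total, 1)
}
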