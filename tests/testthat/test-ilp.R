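test_that("node scores equal an independent normal-equations oracle", {
  set.seed(91)
  for (k in 1:60) {
    n <- sample(5:15, 1); p <- sample(0:3, 1)
    y <- rnorm(n)
    D <- if (p > 0) matrix(rnorm(n * p), n) else NULL
    got <- node_score(y, D, penalty_c = 0)
    X <- cbind(rep(1, n), D)
    beta <- solve(crossprod(X), crossprod(X, y))   # normal equations
    expect_equal(got, sum((y - X %*% beta)^2), tolerance = 1e-10)
  }
  ## empty set is the centered TSS; a child in the span scores ~0 fit
  y <- rnorm(20)
  expect_equal(node_score(y, NULL), sum((y - mean(y))^2))
  D <- cbind(a = rnorm(20))
  expect_equal(node_score(3 * D[, 1] - 2, D, penalty_c = 0), 0,
               tolerance = 1e-18)
  ## penalty adds c * |parents| * log(n)
  expect_equal(node_score(y, D, penalty_c = 2) -
                 node_score(y, D, penalty_c = 0), 2 * log(20))
  expect_warning(node_score(y, cbind(D, D)), "singular")
  expect_error(node_score(y, matrix(1, 20, 25)), "fewer columns")
})

test_that("parent-set enumeration counts, prunes and orders correctly", {
  set.seed(92)
  dat <- matrix(rnorm(40 * 5), 40, 5,
                dimnames = list(NULL, c("y", "a", "b", "c", "d")))
  ## 0 candidates: only the empty set
  e0 <- enumerate_parent_sets("y", character(0), dat)
  expect_length(e0, 1); expect_length(e0[[1]]$parents, 0)
  ## 4 candidates, max 2: at most 1 + 4 + 6 entries
  e2 <- enumerate_parent_sets("y", c("a", "b", "c", "d"), dat,
                              max_parents = 2, prune = FALSE)
  expect_length(e2, 11)
  expect_lte(length(enumerate_parent_sets("y", c("a", "b", "c", "d"), dat,
                                          max_parents = 2)), 11)
  ## ordering: scores are non-decreasing
  sc <- vapply(e2, `[[`, numeric(1), "score")
  expect_true(all(diff(sc) >= -1e-12))
  expect_error(enumerate_parent_sets("y", c("y", "a"), dat), "child")

  ## pruning never changes the ILP optimum
  for (k in 1:50) {
    dat_k <- matrix(rnorm(30 * 5), 30, 5,
                    dimnames = list(NULL, LETTERS[1:5]))
    s_pruned <- lapply(stats::setNames(LETTERS[1:5], LETTERS[1:5]),
      function(v) enumerate_parent_sets(v, setdiff(LETTERS[1:5], v), dat_k,
                                        max_parents = 2, prune = TRUE))
    s_full <- lapply(stats::setNames(LETTERS[1:5], LETTERS[1:5]),
      function(v) enumerate_parent_sets(v, setdiff(LETTERS[1:5], v), dat_k,
                                        max_parents = 2, prune = FALSE))
    expect_equal(solve_ilp(s_pruned)$total_score,
                 solve_ilp(s_full)$total_score, tolerance = 1e-9)
  }
})

test_that("solve_ilp equals exhaustive search and always returns DAGs", {
  set.seed(93)
  for (i in 1:40) {
    m <- sample(3:5, 1)
    sc <- random_ilp_instance(m, max_parents = min(3, m - 1))
    a <- solve_ilp(sc)
    b <- exhaustive_dag_search(sc)
    expect_equal(a$total_score, b$total_score, tolerance = 1e-9)
    expect_true(a$optimal)
    adj <- semip:::as_adjacency(a) * 1
    expect_false(is.null(semip:::topological_order(adj)))
    ## decomposability: total equals the sum of chosen parent-set scores
    chosen <- vapply(names(a$parent_sets), function(v) {
      key <- paste(sort(a$parent_sets[[v]]), collapse = ",")
      hits <- vapply(sc[[v]], function(e)
        paste(sort(e$parents), collapse = ",") == key, logical(1))
      sc[[v]][hits][[1]]$score
    }, numeric(1))
    expect_equal(a$total_score, sum(chosen), tolerance = 1e-9)
    ## convexity: exactly one parent set per scored node
    expect_setequal(names(a$parent_sets), names(sc))
  }
})

test_that("solver handles canonical tiny instances by hand", {
  ## empty parent set cheapest everywhere: empty graph
  sc <- list(A = list(list(parents = character(0), score = 0),
                      list(parents = "B", score = 5)),
             B = list(list(parents = character(0), score = 0),
                      list(parents = "A", score = 5)))
  net <- solve_ilp(sc)
  expect_equal(nrow(net$edges), 0)

  ## scores favoring a chain pick exactly the chain
  sc <- list(A = list(list(parents = character(0), score = 0),
                      list(parents = "B", score = 2)),
             B = list(list(parents = character(0), score = 10),
                      list(parents = "A", score = 0),
                      list(parents = "C", score = 4)),
             C = list(list(parents = character(0), score = 10),
                      list(parents = "B", score = 0),
                      list(parents = "A", score = 6)))
  net <- solve_ilp(sc)
  expect_equal(paste(net$edges$parent, net$edges$child),
               c("A B", "B C"))

  ## mutually reinforcing cycle scores: best acyclic subset, never a cycle
  sc <- list(A = list(list(parents = character(0), score = 10),
                      list(parents = "C", score = 0)),
             B = list(list(parents = character(0), score = 10),
                      list(parents = "A", score = 0)),
             C = list(list(parents = character(0), score = 10),
                      list(parents = "B", score = 0)))
  net <- solve_ilp(sc)
  expect_equal(nrow(net$edges), 2)   # a cluster constraint forces a root
  expect_equal(net$total_score, 10)
  expect_equal(net$total_score, exhaustive_dag_search(sc)$total_score)
  expect_true(net$optimal)

  ## exogenous parents never cycle and are labeled genotype by default
  sc <- list(Y = list(list(parents = character(0), score = 5),
                      list(parents = "X9", score = 0)))
  net <- solve_ilp(sc)
  expect_equal(unname(net$layer["X9"]), "genotype")

  ## missing empty set is rejected
  bad <- list(A = list(list(parents = "B", score = 1)),
              B = list(list(parents = character(0), score = 0)))
  expect_error(solve_ilp(bad), "empty parent set")
  expect_error(exhaustive_dag_search(random_ilp_instance(7)), "limited")
})

test_that("semip learner recovers planted structure and stays near-empty on noise", {
  set.seed(94)
  cfg <- sim_config(n_nodes = 5, n_genotype = 2, target_edges = 4,
                    n_samples = 1000, seed = 1)
  pows <- replicate(15, {
    m <- random_dag(cfg)
    d <- simulate_dataset(m, 1000)
    net <- learn_semip_network(d)
    evaluate_network(m, net, mode = "directed")$power
  })
  expect_gte(mean(pows), 0.8)

  ## pure noise: the penalty keeps the graph near-empty
  set.seed(95)
  sizes <- replicate(10, {
    dat <- new_omics_dataset(
      matrix(rnorm(400 * 6), 400, 6,
             dimnames = list(NULL, c("X1", "X2", paste0("Y", 1:4)))),
      c("genotype", "genotype", rep("endogenous", 4)))
    nrow(learn_semip_network(dat)$edges)
  })
  expect_lte(mean(sizes), 1)

  ## deterministic given the data
  m <- random_dag(cfg, seed = 6); d <- simulate_dataset(m, 500, seed = 7)
  n1 <- learn_semip_network(d); n2 <- learn_semip_network(d)
  expect_identical(n1$edges, n2$edges)
})

test_that("multilevel learner respects layers and reduces to the single-layer case", {
  set.seed(96)
  n <- 800
  snp <- matrix(rnorm(2 * n), n, dimnames = list(NULL, c("s1", "s2")))
  meth <- matrix(1.4 * snp[, 1] + rnorm(n), ncol = 1,
                 dimnames = list(NULL, "m1"))
  expr <- matrix(1.4 * meth[, 1] + rnorm(n), ncol = 1,
                 dimnames = list(NULL, "e1"))
  dis <- matrix(1.4 * expr[, 1] + rnorm(n), ncol = 1,
                dimnames = list(NULL, "d1"))
  net <- learn_multilevel_network(snp, methylation = meth, expression = expr,
                                  disease = dis)
  got <- paste(net$edges$parent, net$edges$child)
  expect_true(all(c("s1 m1", "m1 e1", "e1 d1") %in% got))
  ## layer invariants on every edge
  up <- list(methylation = c("methylation", "genotype"),
             expression = c("expression", "methylation", "genotype"),
             disease = c("phenotype", "expression", "methylation", "genotype"))
  for (i in seq_len(nrow(net$edges)))
    expect_true(net$edges$parent_layer[i] %in% up[[net$edges$child_layer[i]]])
  expect_false(is.null(semip:::topological_order(semip:::as_adjacency(net) * 1)))

  ## misaligned matrices are refused with the matrix named
  expect_error(learn_multilevel_network(snp, expression = expr[1:100, ,
                                                               drop = FALSE]),
               "expression")

  ## single-layer input reduces exactly to learn_semip_network
  cfg <- sim_config(n_nodes = 7, n_genotype = 3, target_edges = 6, seed = 4)
  m <- random_dag(cfg, seed = 4)
  d <- simulate_dataset(m, 400, seed = 5)
  a <- learn_semip_network(d)
  b <- learn_multilevel_network(
    genotype = d$data[, m$layer == "genotype"],
    expression = d$data[, m$layer == "endogenous"])
  expect_identical(paste(a$edges$parent, a$edges$child),
                   paste(b$edges$parent, b$edges$child))
})
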