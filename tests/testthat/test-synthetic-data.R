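test_that("sim_config validates its inputs", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_genotype = 20, n_nodes = 20), "n_genotype")
  expect_error(sim_config(coeff_low = 2, coeff_high = 1), "coeff_low")
  expect_error(sim_config(n_nodes = 4, n_genotype = 1, target_edges = 100),
               "exceeds the maximum")
  expect_error(sim_config(n_replicates = 0), "n_replicates")
})

test_that("a 2-node config admits exactly one edge with the stated effect", {
  cfg <- sim_config(n_nodes = 2, n_genotype = 1, target_edges = 1,
                    random_sign = FALSE)
  m <- random_dag(cfg, seed = 11)
  expect_equal(sum(m$adj), 1)
  expect_equal(unname(which(m$adj != 0, arr.ind = TRUE)[1, ]), c(1, 2))
  b <- m$coef[m$adj != 0]
  expect_gte(abs(b), 1); expect_lte(abs(b), 2)
})

test_that("random DAGs are acyclic with the right mean edge count and layout", {
  cfg <- sim_config(n_nodes = 20, n_genotype = 5, target_edges = 30)
  set.seed(21)
  ne <- replicate(1000, {
    m <- random_dag(cfg)
    ## genotype nodes never receive edges
    expect_equal(sum(m$adj[, m$layer == "genotype"]), 0)
    ## acyclic by construction
    expect_false(is.null(semip:::topological_order(m$adj)))
    sum(m$adj)
  })
  expect_lt(abs(mean(ne) - 30), 3)
  ## coefficient magnitudes live in [coeff_low, coeff_high]
  m <- random_dag(cfg, seed = 5)
  mags <- abs(m$coef[m$adj != 0])
  expect_true(all(mags >= 1 & mags <= 2))
})

test_that("simulate_dataset follows the linear recursion and is reproducible", {
  ## no edges: every column standard normal-ish, independent
  cfg <- sim_config(n_nodes = 4, n_genotype = 2, target_edges = 1)
  m0 <- random_dag(cfg, seed = 3)
  m0$adj[] <- 0L; m0$coef[] <- 0
  d0 <- simulate_dataset(m0, 5000, seed = 4)
  expect_lt(max(abs(colMeans(d0$data))), 0.1)
  expect_lt(max(abs(apply(d0$data, 2, stats::sd) - 1)), 0.1)

  ## chain moments: Cov(Y2, Y1) = 1.5 Var(Y1) within 2 percent
  d <- simulate_dataset(chain_model(), 50000, seed = 6)
  r <- stats::cov(d$data[, "Y2"], d$data[, "Y1"]) /
    (1.5 * stats::var(d$data[, "Y1"]))
  expect_lt(abs(r - 1), 0.02)

  ## fixed seed: bit-identical repeat
  expect_identical(simulate_dataset(chain_model(), 50, seed = 7)$data,
                   simulate_dataset(chain_model(), 50, seed = 7)$data)
  expect_error(simulate_dataset(chain_model(), 0), "n_samples")
})

test_that("hwe genotype mode yields standardized 0/1/2-derived columns", {
  cfg <- sim_config(n_nodes = 3, n_genotype = 2, target_edges = 1,
                    genotype_mode = "hwe", maf = 0.3)
  m <- random_dag(cfg, seed = 8)
  d <- simulate_dataset(m, 2000, seed = 9)
  g <- d$data[, 1]
  expect_equal(length(unique(round(diff(sort(unique(g))), 6))), 1) # 3 levels, equal spacing
  expect_lt(abs(mean(g)), 1e-8)
  expect_lt(abs(stats::sd(g) - 1), 1e-8)
})

test_that("evaluate_network counts edges the way the benchmark defines them", {
  nodes <- c("A", "B", "C")
  truth <- adj_from_edges(nodes, list(c("A", "B"), c("B", "C")))

  ## perfect recovery
  pf <- evaluate_network(truth, truth, mode = "directed")
  expect_equal(pf$power, 1); expect_equal(pf$fdr_ref, 0)
  expect_equal(pf$fdr_conventional, 0)

  ## hand-enumerated: estimate {A->B, C->B}
  est <- adj_from_edges(nodes, list(c("A", "B"), c("C", "B")))
  pf <- evaluate_network(truth, est, mode = "directed")
  expect_equal(pf$n_t, 2); expect_equal(pf$n_true, 1)
  expect_equal(pf$power, 0.5)
  expect_equal(pf$n_false, 1); expect_equal(pf$n_0, 4)
  expect_equal(pf$fdr_ref, 0.25); expect_equal(pf$fdr_conventional, 0.5)

  ## same graphs, skeleton comparison
  pu <- evaluate_network(truth, est, mode = "undirected")
  expect_equal(pu$power, 1); expect_equal(pu$fdr_conventional, 0)

  ## count conservation on random pairs
  set.seed(31)
  for (k in 1:20) {
    t_adj <- matrix(rbinom(25, 1, 0.3), 5, 5); diag(t_adj) <- 0
    e_adj <- matrix(rbinom(25, 1, 0.3), 5, 5); diag(e_adj) <- 0
    dimnames(t_adj) <- dimnames(e_adj) <- rep(list(letters[1:5]), 2)
    pf <- evaluate_network(t_adj, e_adj, mode = "directed")
    expect_equal(pf$n_t + pf$n_0, 20)
    expect_lte(pf$n_true, pf$n_t); expect_lte(pf$n_false, pf$n_0)
    ## every estimated edge is either a detected true edge or a false one
    expect_equal(pf$n_true + pf$n_false, sum(e_adj))
  }

  ## node-set mismatch
  bad <- adj_from_edges(c("A", "B"), list(c("A", "B")))
  expect_error(evaluate_network(truth, bad), "node set")
})

test_that("correlation baseline finds real edges and is calibrated on noise", {
  set.seed(41)
  x <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("A", "B", "C")))
  x[, "B"] <- x[, "A"]
  net <- correlation_baseline(x)
  expect_true(any(net$edges$parent == "A" & net$edges$child == "B"))
  expect_error(correlation_baseline(x[1:2, ]), "3 samples")
  expect_warning(correlation_baseline(cbind(x, D = rep(1, 100))), "constant")

  ## type-I calibration: independent columns connect ~5% of the time
  set.seed(42)
  rate <- mean(replicate(400, {
    z <- matrix(rnorm(60 * 2), 60)
    nrow(correlation_baseline(z, alpha = 0.05)$edges) > 0
  }))
  expect_gt(rate, 0.02); expect_lt(rate, 0.09)
})

test_that("power rises with effect size in a fixed 2-node design", {
  set.seed(51)
  recover_rate <- vapply(c(0.2, 0.6, 1.5), function(beta) {
    mean(replicate(30, {
      m <- chain_model(coef = beta)
      m$adj["Y1", "Y2"] <- 0L; m$coef["Y1", "Y2"] <- 0   # single edge X1 -> Y1
      d <- simulate_dataset(m, 120)
      net <- correlation_baseline(d$data[, c("X1", "Y1")], alpha = 0.05)
      nrow(net$edges) > 0
    }))
  }, numeric(1))
  expect_true(all(diff(recover_rate) >= 0) || recover_rate[3] > recover_rate[1])
  expect_equal(recover_rate[3], 1)
})

test_that("run_benchmark summarizes per method and writes a TSV", {
  cfg <- sim_config(n_nodes = 5, n_genotype = 2, target_edges = 4,
                    n_samples = 150, n_replicates = 2, seed = 9)
  bench <- run_benchmark(cfg, methods = c("correlation_baseline", "semip"),
                         seed = 2)
  expect_s3_class(bench, "semip_benchmark")
  expect_setequal(bench$mode[bench$method == "semip"],
                  c("directed", "undirected"))
  expect_equal(bench$mode[bench$method == "correlation_baseline"],
               "undirected")
  expect_true(all(bench$power >= 0 & bench$power <= 1))
  tsv <- file.path(tempdir(), "bench.tsv")
  write_benchmark_tsv(bench, tsv)
  lines <- readLines(tsv)
  expect_match(lines[1], "^# ")
  expect_match(lines[2], "method\tnodes")
  expect_error(run_benchmark(cfg, methods = "magic"), "arg")

  ## a 2-node chain with a strong edge is found by semip at n = 1000
  cfg2 <- sim_config(n_nodes = 2, n_genotype = 1, target_edges = 1,
                     n_samples = 1000, n_replicates = 1, seed = 3,
                     random_sign = FALSE)
  b2 <- run_benchmark(cfg2, methods = "semip", seed = 5)
  expect_equal(b2$power[b2$mode == "directed"], 1)
})
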