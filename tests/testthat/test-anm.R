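test_that("conditional-mode regression fits and tie-breaks as documented", {
  ## deterministic copy
  f <- fit_discrete_regression(c(0, 1, 2, 0, 1, 2), c(0, 1, 2, 0, 1, 2))
  expect_equal(unname(f$fit), c(0, 1, 2))
  expect_true(all(f$residuals == 0))

  ## mode by counting: y|x=0 in {0,0,1}, y|x=1 in {2,2,3}
  f <- fit_discrete_regression(c(0, 0, 0, 1, 1, 1), c(0, 0, 1, 2, 2, 3))
  expect_equal(unname(f$fit), c(0, 2))
  expect_equal(f$residuals, c(0, 0, 1, 0, 0, 1))

  ## constant response
  f <- fit_discrete_regression(c(0, 1, 0, 1), c(5, 5, 5, 5))
  expect_true(all(f$fit == 5)); expect_true(all(f$residuals == 0))

  expect_error(fit_discrete_regression(1:3, 1:4), "equal length")
})

test_that("independence delta matches a brute-force Fisher oracle", {
  ## degenerate table
  expect_equal(as.numeric(independence_delta(rep(0, 10), rep(0:1, 5))), 0)
  d <- independence_delta(rep(0, 10), rep(0:1, 5))
  expect_true(attr(d, "degenerate"))

  ## perfectly dependent 2x2: [[10,0],[0,10]]
  res <- rep(c(0, 1), each = 10); cause <- rep(c(0, 1), each = 10)
  tab <- table(res, cause)
  expect_equal(as.numeric(independence_delta(res, cause)),
               -log10(fisher_oracle(unclass(tab))), tolerance = 1e-10)

  ## all 2x2 and 2x3 tables with n <= 20 against exhaustive enumeration,
  ## through the compiled path as well
  set.seed(61)
  for (k in 1:25) {
    nr <- 2L; nc <- sample(2:3, 1)
    repeat {
      tab <- matrix(rmultinom(1, sample(6:20, 1), rep(1, nr * nc)), nr, nc)
      if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) break
    }
    expect_equal(semip:::delta_from_table(tab),
                 -log10(fisher_oracle(tab)), tolerance = 1e-8)
    expect_equal(semip:::.fisher_exact_small(tab), fisher_oracle(tab),
                 tolerance = 1e-8)
  }

  ## chi-square fallback above the cell cap
  res <- rep(0:3, 25); cause <- rep(0:1, 50)
  tab <- unclass(table(res, cause))
  expect_equal(as.numeric(independence_delta(res, cause)),
               -log10(stats::chisq.test(tab, correct = FALSE)$p.value),
               tolerance = 1e-10)
})

test_that("compiled T_C engine agrees with the R reference", {
  set.seed(62)
  for (k in 1:40) {
    nx <- sample(2:4, 1); ny <- sample(2:5, 1)
    tab <- as.table(matrix(rpois(nx * ny, 6), nx, ny,
                           dimnames = list(sort(sample(0:9, nx)),
                                           sort(sample(0:9, ny)))))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    for (refine in c(TRUE, FALSE)) {
      a <- semip:::.tc_engine(unclass(tab), as.numeric(rownames(tab)),
                              as.numeric(colnames(tab)), refine, 6L)
      b <- semip:::tc_from_table(tab, 6L, refine)
      expect_equal(unname(a), unname(b), tolerance = 1e-9)
    }
  }
})

test_that("causation test is symmetric and refuses degenerate input", {
  set.seed(63)
  x <- sample(0:2, 300, TRUE)
  y <- (2 * x) %% 3 + rbinom(300, 1, 0.2)
  a <- causation_test(x, y, n_permutations = 99, seed = 7)
  b <- causation_test(y, x, n_permutations = 99, seed = 7)
  expect_equal(a$t_c, b$t_c)
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$delta_xy, b$delta_yx)
  swap <- c(x_to_y = "y_to_x", y_to_x = "x_to_y", undecided = "undecided")
  expect_equal(unname(swap[a$direction]), b$direction)
  expect_equal(a$t_c, abs(a$delta_xy - a$delta_yx))
  expect_gte(a$p_value, 1 / 100)

  ## identical variables: zero statistic, no decision
  z <- rep(0:1, 50)
  r <- causation_test(z, z, n_permutations = 99, seed = 1)
  expect_equal(r$t_c, 0)
  expect_equal(r$direction, "undecided")

  expect_error(causation_test(rep(1, 50), rep(0:1, 25), 99), "2 occupied")
  expect_error(causation_test(0:1, 0:1, n_permutations = 0),
               "n_permutations")
})

test_that("planted discrete mechanism is detected with the right direction", {
  set.seed(64)
  hits <- replicate(30, {
    x <- sample(0:2, 500, TRUE)
    y <- (2 * x) %% 3 + sample(c(-1, 0, 1), 500, TRUE, prob = c(.1, .8, .1))
    ct <- causation_test(x, y, n_permutations = 999)
    ct$p_value < 0.05 && ct$direction == "x_to_y"
  })
  expect_gte(mean(hits), 0.9)
})

test_that("permutation p-values are calibrated under independence", {
  set.seed(65)
  rej <- replicate(120, {
    x <- sample(0:2, 200, TRUE); y <- sample(0:2, 200, TRUE)
    causation_test(x, y, n_permutations = 199)$p_value < 0.05
  })
  ## nominal 5%, allow 2 Monte-Carlo standard errors (~2%) either way
  expect_lte(mean(rej), 0.05 + 2 * sqrt(0.05 * 0.95 / 120) + 0.01)
})

test_that("gene-level causation picks up a planted burden signal", {
  set.seed(66)
  n <- 300; p <- 8
  g <- matrix(rbinom(n * p, 2, 0.08), n, p)
  burden <- as.integer(rowSums(g) > 0)
  disease <- ifelse(runif(n) < 0.9, burden, 1 - burden)
  res <- gene_level_causation(g, positions = seq_len(p) * 100, disease,
                              n_permutations = 199, seed = 3)
  expect_s3_class(res, "causal_test")
  expect_lt(res$p_value, 0.05)
  expect_equal(res$direction, "x_to_y")
  expect_error(gene_level_causation(g, seq_len(p) * 100, disease,
                                    n_bins = 1), "n_bins")
  expect_error(gene_level_causation(matrix(0L, n, p), seq_len(p) * 100,
                                    disease), "monomorphic")
})

test_that("gwcs scan ranks a planted gene first and handles edge cases", {
  set.seed(67)
  n <- 250; n_genes <- 8; p_per <- 6
  genos <- NULL; vi <- NULL; regions <- NULL
  for (g in seq_len(n_genes)) {
    gm <- matrix(rbinom(n * p_per, 2, 0.1), n, p_per)
    genos <- cbind(genos, gm)
    vi <- rbind(vi, data.frame(chrom = "1",
                               pos = (g - 1) * 10000 + seq_len(p_per) * 100))
    regions <- rbind(regions, data.frame(chrom = "1",
                                         start = (g - 1) * 10000,
                                         end = (g - 1) * 10000 + 5000,
                                         name = paste0("gene", g)))
  }
  causal <- rowSums(genos[, 1:p_per]) > 0
  disease <- ifelse(runif(n) < 0.92, as.integer(causal),
                    1L - as.integer(causal))
  scan <- gwcs_scan(genos, vi, regions, disease, n_permutations = 199,
                    seed = 5)
  expect_equal(nrow(scan), n_genes)
  expect_equal(scan$name[which.min(scan$p)], "gene1")
  expect_true(all(scan$fdr >= scan$p, na.rm = TRUE))

  ## empty region -> NA row with warning; empty region list -> error
  regions2 <- rbind(regions[1, ],
                    data.frame(chrom = "1", start = 9e6, end = 9.1e6,
                               name = "desert"))
  expect_warning(scan2 <- gwcs_scan(genos, vi, regions2, disease,
                                    n_permutations = 99), "no variants")
  expect_true(is.na(scan2$p[scan2$name == "desert"]))
  expect_error(gwcs_scan(genos, vi, regions[0, ], disease), "empty")
})
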