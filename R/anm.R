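## Bivariate causal discovery for discrete variables by additive noise
## models: fit integer regressions in both directions, measure dependence
## of residuals on the putative cause, and contrast the two directions.

#' Conditional-mode integer regression
#'
#' Fits the discrete regression `y = f(x) + N` by mapping each level of
#' `x` to the conditional mode of `y` at that level. Modal ties are broken
#' toward the conditional median, then toward the smaller level, so the
#' fit is deterministic.
#'
#' @param x,y integer-valued vectors of equal length (cause candidate and
#'   response).
#' @return list with `fit` (named vector: prediction per occupied `x`
#'   level), `residuals` (`y - f(x)`), and `levels` (the occupied levels
#'   of `x`).
#' @examples
#' fit_discrete_regression(c(0, 0, 0, 1, 1, 1), c(0, 0, 1, 2, 2, 3))
#' @export
fit_discrete_regression <- function(x, y) {
  if (length(x) != length(y)) stop2("x and y must have equal length")
  tab <- table(x, y)
  yv <- as.numeric(colnames(tab))
  fhat <- apply(tab, 1L, function(cnt) mode_by_median(cnt, yv))
  res <- y - fhat[as.character(x)]
  names(res) <- NULL
  list(fit = fhat, residuals = res, levels = as.numeric(rownames(tab)))
}

## Tie-broken mode of a discrete conditional distribution given as counts
## over values `yv`: among maximal counts choose the value closest to the
## weighted median, then the smaller value.
mode_by_median <- function(cnt, yv) {
  mx <- max(cnt)
  cand <- yv[cnt == mx]
  if (length(cand) == 1L) return(cand)
  med <- weighted_median(yv, cnt)
  d <- abs(cand - med)
  min(cand[d == min(d)])
}

#' Residual-cause dependence on the -log10 p scale
#'
#' Builds the residual-by-cause contingency table and returns
#' `Delta = -log10(p)` for the test of independence: Fisher's exact test
#' when the table is small, a chi-square test otherwise. Larger values
#' mean stronger dependence. A degenerate table (a single occupied row or
#' column) carries no dependence information and returns 0 with attribute
#' `degenerate = TRUE`.
#'
#' @param residuals,cause equal-length discrete vectors.
#' @param fisher_max_cells Fisher's exact test is used when the (trimmed)
#'   table has at most this many cells; above it the chi-square test
#'   without continuity correction is used. Default 6 (2x2 and 2x3 tables
#'   stay exact).
#' @return non-negative numeric scalar.
#' @export
independence_delta <- function(residuals, cause, fisher_max_cells = 6L) {
  if (length(residuals) != length(cause))
    stop2("residuals and cause must have equal length")
  tab <- table(residuals, cause)
  delta_from_table(unclass(tab), fisher_max_cells)
}

## Core: Delta from a count matrix.
delta_from_table <- function(tab, fisher_max_cells = 6L) {
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  p <- if (length(tab) <= fisher_max_cells) {
    pf <- tryCatch(stats::fisher.test(tab)$p.value, error = function(e) NA_real_)
    if (is.na(pf)) chisq_p(tab) else pf
  } else chisq_p(tab)
  -log10(max(p, .Machine$double.xmin))
}

## Pearson chi-square p-value without continuity correction; assumes the
## table has no all-zero row/column.
chisq_p <- function(tab) {
  n <- sum(tab)
  e <- outer(rowSums(tab), colSums(tab)) / n
  stat <- sum((tab - e)^2 / e)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  stats::pchisq(stat, df, lower.tail = FALSE)
}

## T_C and the two direction deltas computed from the x-by-y contingency
## table alone. Both the integer regression and the residual-by-cause
## table are functions of the joint counts, which makes the permutation
## null cheap (random tables with fixed margins). This is the pure-R
## reference of the compiled engine (.tc_engine); tests compare the two.
tc_from_table <- function(tab, fisher_max_cells = 6L, refine = TRUE) {
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  ## canonical ascending level order (descent sweeps follow it)
  tab <- tab[order(as.numeric(rownames(tab))),
             order(as.numeric(colnames(tab))), drop = FALSE]
  xv <- as.numeric(rownames(tab))
  yv <- as.numeric(colnames(tab))
  d_xy <- direction_delta(unclass(tab), yv, fisher_max_cells, refine)
  d_yx <- direction_delta(t(unclass(tab)), xv, fisher_max_cells, refine)
  c(delta_xy = d_xy, delta_yx = d_yx, t_c = abs(d_xy - d_yx))
}

## Delta of residuals response - f(cause) on the cause, for the fit
## f(cause level i) = rv[a[i]] given as indices into the response values.
delta_for_assignment <- function(tab, rv, a, fisher_max_cells) {
  resv <- outer(-rv[a], rv, `+`)         # residual value per (cause, response)
  ru <- sort(unique(as.vector(resv)))
  m <- matrix(0, length(ru), nrow(tab))
  idx <- cbind(match(as.vector(resv), ru), rep(seq_len(nrow(tab)), ncol(tab)))
  counts <- as.vector(tab)
  for (k in seq_along(counts)) m[idx[k, 1L], idx[k, 2L]] <-
      m[idx[k, 1L], idx[k, 2L]] + counts[k]
  as.numeric(delta_from_table(m, fisher_max_cells))
}

## Delta for direction cause -> response from the cause-by-response count
## matrix (rows = cause levels, cols = response values `rv`). The fit
## starts at the conditional mode; with refine = TRUE a deterministic
## coordinate descent then adjusts each f value to the response value
## minimizing the residual-cause dependence (sweeps in row order, updates
## only on strict improvement), so that under independence the fit can
## reach a constant map and the residuals decouple from the cause.
direction_delta <- function(tab, rv, fisher_max_cells, refine = TRUE) {
  keep <- rowSums(tab) > 0
  tab <- tab[keep, , drop = FALSE]
  fhat <- apply(tab, 1L, function(cnt) mode_by_median(cnt, rv))
  a <- match(fhat, rv)
  d <- delta_for_assignment(tab, rv, a, fisher_max_cells)
  if (refine) {
    for (sweep in 1:10) {
      changed <- FALSE
      for (i in seq_len(nrow(tab))) {
        bi <- a[i]; best <- d
        for (cc in seq_along(rv)) {
          if (cc == a[i]) next
          a2 <- a; a2[i] <- cc
          d2 <- delta_for_assignment(tab, rv, a2, fisher_max_cells)
          if (d2 < best - 1e-12) { best <- d2; bi <- cc }
        }
        if (bi != a[i]) { a[i] <- bi; d <- best; changed <- TRUE }
      }
      if (!changed) break
    }
  }
  d
}

#' Bivariate causation test for discrete variables
#'
#' Fits the additive noise model in both directions, forms the causation
#' statistic `T_C = |Delta_{X->Y} - Delta_{Y->X}|`, and calibrates it by a
#' permutation null: permuting `y` against `x` is realized by drawing
#' contingency tables with the observed margins, from which the permuted
#' `T_C` is recomputed. The p-value uses the add-one estimator
#' `(1 + #\{T_perm >= T_obs\}) / (n_permutations + 1)`.
#'
#' A direction is called only when the test rejects at `alpha`: the causal
#' direction is the one whose residuals are the more independent of the
#' putative cause (the smaller Delta). When `T_C` is near zero no causal
#' decision can be made and the direction is `"undecided"`.
#'
#' The integer regressions start at the conditional mode
#' ([fit_discrete_regression()]) and are then refined by a deterministic
#' coordinate descent that re-assigns fitted values to minimize the
#' residual-cause dependence, so that under independence the fit can
#' reach a constant map and the statistic concentrates near zero (set
#' `refine = FALSE` for the plain conditional-mode fit).
#'
#' @param x,y equal-length integer-valued vectors.
#' @param n_permutations number of permutation draws (default 999).
#' @param alpha significance level for the direction call.
#' @param fisher_max_cells see [independence_delta()].
#' @param refine refine the integer regressions toward minimal
#'   residual-cause dependence (default TRUE).
#' @param seed optional integer seed for the permutation draws.
#' @return object of class `"causal_test"`: list with `delta_xy`,
#'   `delta_yx`, `t_c`, `p_value`, `direction` (`"x_to_y"`, `"y_to_x"` or
#'   `"undecided"`) and `n_permutations`.
#' @examples
#' set.seed(1)
#' x <- sample(0:2, 300, replace = TRUE)
#' y <- (2 * x) %% 3 + rbinom(300, 1, 0.2)
#' causation_test(x, y, n_permutations = 199, seed = 1)
#' @export
causation_test <- function(x, y, n_permutations = 999L, alpha = 0.05,
                           fisher_max_cells = 6L, refine = TRUE,
                           seed = NULL) {
  if (length(x) != length(y)) stop2("x and y must have equal length")
  n_permutations <- as.integer(n_permutations)
  if (n_permutations < 1L) stop2("n_permutations must be at least 1")
  tab <- table(x, y)
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop2("both variables need at least 2 occupied levels")
  if (!is.null(seed)) set.seed(seed)
  obs <- .tc_engine(unclass(tab), as.numeric(rownames(tab)),
                    as.numeric(colnames(tab)), refine, fisher_max_cells)
  ## canonical orientation so that the permutation stream (and hence the
  ## p-value) is identical when x and y are swapped: T_C itself is
  ## transpose-symmetric
  ptab <- tab
  if (nrow(tab) > ncol(tab) ||
      (nrow(tab) == ncol(tab) &&
       paste(rowSums(tab), collapse = ",") >
       paste(colSums(tab), collapse = ","))) ptab <- t(tab)
  perm_tabs <- stats::r2dtable(n_permutations, rowSums(ptab), colSums(ptab))
  t_perm <- .tc_perm_engine(perm_tabs, as.numeric(rownames(ptab)),
                            as.numeric(colnames(ptab)), refine,
                            fisher_max_cells)
  pval <- (1 + sum(t_perm >= obs[["t_c"]])) / (n_permutations + 1)
  direction <- "undecided"
  if (pval < alpha && obs[["t_c"]] > 0) {
    direction <- if (obs[["delta_xy"]] < obs[["delta_yx"]]) "x_to_y" else "y_to_x"
  }
  structure(list(
    delta_xy = obs[["delta_xy"]], delta_yx = obs[["delta_yx"]],
    t_c = obs[["t_c"]], p_value = pval, direction = direction,
    n_permutations = n_permutations
  ), class = "causal_test")
}

#' @export
print.causal_test <- function(x, ...) {
  cat(sprintf(
    "ANM causation test: T_C = %.3f (Delta_xy %.3f, Delta_yx %.3f)\n",
    x$t_c, x$delta_xy, x$delta_yx))
  cat(sprintf("  permutation p = %.4g (%d permutations), direction: %s\n",
              x$p_value, x$n_permutations, x$direction))
  invisible(x)
}

#' Gene-level causation test from rare-variant genotypes
#'
#' Summarizes the rare variants of one gene region into functional
#' principal component scores, discretizes the leading score into
#' `n_bins` quantile bins (mimicking a genotype-like coding), and runs the
#' discrete ANM causation test against the disease status.
#'
#' @param rare_genotypes samples x variants matrix of 0/1/2 genotypes.
#' @param positions genomic positions of the variants (sorted).
#' @param disease integer-valued disease status vector (e.g. 0/1).
#' @param n_bins number of quantile bins for the leading score (>= 2).
#' @param n_permutations,alpha,seed passed to [causation_test()].
#' @return a `"causal_test"` object (with attribute `fpc` holding the
#'   score summary).
#' @export
gene_level_causation <- function(rare_genotypes, positions, disease,
                                 n_bins = 3L, n_permutations = 999L,
                                 alpha = 0.05, seed = NULL) {
  rare_genotypes <- as.matrix(rare_genotypes)
  if (nrow(rare_genotypes) != length(disease))
    stop2("disease length must equal the sample count")
  if (n_bins < 2L) stop2("n_bins must be at least 2")
  if (all(rare_genotypes == rare_genotypes[1L][1L], na.rm = TRUE) ||
      sum(apply(rare_genotypes, 2, stats::var, na.rm = TRUE) > 0) == 0)
    stop2("monomorphic gene: no genotype variation to summarize")
  gfm <- code_genotype_function(rare_genotypes, positions = positions)
  fpc <- fpc_scores(gfm)
  score <- fpc$scores[, 1L]
  xbin <- quantile_bin(score, n_bins)
  if (length(unique(xbin)) < 2L)
    stop2("leading score collapses to a single bin; cannot test")
  res <- causation_test(xbin, disease, n_permutations = n_permutations,
                        alpha = alpha, seed = seed)
  attr(res, "fpc") <- fpc
  res
}

## Quantile binning of a continuous score into at most n_bins levels
## coded 0, 1, ...; duplicate quantiles are collapsed.
quantile_bin <- function(x, n_bins) {
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1L)))
  if (length(br) < 2L) return(rep(0L, length(x)))
  as.integer(cut(x, breaks = br, include.lowest = TRUE)) - 1L
}

#' Genome-wide causation scan
#'
#' Tests the causation of each gene region (rare-variant mode, via FPC
#' scores) or each single variant (common mode) against the disease with
#' the discrete ANM test, and adjusts the p-values for multiple testing.
#'
#' @param genotypes samples x variants matrix of 0/1/2 genotypes.
#' @param variant_info data frame with one row per variant column:
#'   `chrom`, `pos`.
#' @param regions data frame of gene regions: `chrom`, `start`, `end`,
#'   `name` (BED-style 0-based half-open intervals).
#' @param disease integer-valued disease status vector.
#' @param mode `"rare"` (per-region FPCS test) or `"common"`
#'   (per-variant test within the regions).
#' @param n_permutations,alpha,n_bins,seed test settings.
#' @param adjust `"BH"` (Benjamini-Hochberg, default) or `"none"` for a
#'   raw-threshold workflow.
#' @return data frame sorted by genomic coordinate with columns `name`,
#'   `chrom`, `start`, `end`, `n_variants`, `delta_xy`, `delta_yx`,
#'   `t_c`, `p`, `direction`, `fdr`.
#' @export
gwcs_scan <- function(genotypes, variant_info, regions, disease,
                      mode = c("rare", "common"), n_permutations = 999L,
                      alpha = 0.05, n_bins = 3L, seed = NULL,
                      adjust = c("BH", "none")) {
  mode <- match.arg(mode); adjust <- match.arg(adjust)
  genotypes <- as.matrix(genotypes)
  if (nrow(regions) == 0L) stop2("region list is empty")
  stopifnot(nrow(variant_info) == ncol(genotypes))
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (i in seq_len(nrow(regions))) {
    rg <- regions[i, ]
    sel <- which(variant_info$chrom == rg$chrom &
                 variant_info$pos >= rg$start & variant_info$pos < rg$end)
    na_row <- data.frame(name = rg$name, chrom = rg$chrom, start = rg$start,
                         end = rg$end, n_variants = length(sel),
                         delta_xy = NA_real_, delta_yx = NA_real_,
                         t_c = NA_real_, p = NA_real_,
                         direction = NA_character_, stringsAsFactors = FALSE)
    if (length(sel) == 0L) {
      warning("region ", rg$name, " contains no variants")
      rows[[length(rows) + 1L]] <- na_row
      next
    }
    res <- tryCatch({
      if (mode == "rare") {
        gene_level_causation(genotypes[, sel, drop = FALSE],
                             variant_info$pos[sel], disease,
                             n_bins = n_bins,
                             n_permutations = n_permutations, alpha = alpha)
      } else {
        ## common mode: best single-variant test in the region
        fits <- lapply(sel, function(j)
          tryCatch(causation_test(genotypes[, j], disease,
                                  n_permutations = n_permutations,
                                  alpha = alpha),
                   error = function(e) NULL))
        fits <- Filter(Negate(is.null), fits)
        if (!length(fits)) stop2("no testable variant")
        fits[[which.min(vapply(fits, `[[`, numeric(1), "p_value"))]]
      }
    }, error = function(e) NULL)
    rows[[length(rows) + 1L]] <- if (is.null(res)) {
      warning("region ", rg$name, " could not be tested")
      na_row
    } else {
      transform(na_row, delta_xy = res$delta_xy, delta_yx = res$delta_yx,
                t_c = res$t_c, p = res$p_value, direction = res$direction)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out$fdr <- if (adjust == "BH") stats::p.adjust(out$p, "BH") else out$p
  rownames(out) <- NULL
  out
}
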