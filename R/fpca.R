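## Functional representation of genotypes along a gene region and
## functional principal component scores, plus plain PCA summaries of
## feature groups.

#' Allele-frequency-centered genotype function coding
#'
#' Codes a samples x positions matrix of 0/1/2 genotype counts of allele Q
#' into the genotype-function values
#' `2 P_q` (QQ), `P_q - P_Q` (Qq), `-2 P_Q` (qq), where `P_Q`, `P_q` are
#' the allele frequencies at the position. Positions are rescaled to
#' `[0, 1]`. Missing genotypes are imputed to the per-position mean of the
#' coded values and flagged.
#'
#' @param genotypes samples x positions matrix with entries in 0/1/2 (count
#'   of allele Q) or `NA`.
#' @param allele_freq optional vector of `P_Q` per position; estimated
#'   from the sample when `NULL`.
#' @param positions optional genomic positions (sorted, one per column);
#'   defaults to an equally spaced grid.
#' @return object of class `"genotype_function"`: list with `values`
#'   (coded matrix), `positions` (rescaled to `[0, 1]`), `allele_freq`
#'   (`P_Q` per position) and `imputed` (logical: any missing entries
#'   imputed).
#' @examples
#' g <- matrix(c(2, 1, 0, 1), 2, 2)
#' code_genotype_function(g, allele_freq = c(0.5, 0.9))$values
#' @export
code_genotype_function <- function(genotypes, allele_freq = NULL,
                                   positions = NULL) {
  g <- as.matrix(genotypes)
  if (!all(g %in% c(0, 1, 2) | is.na(g)))
    stop2("genotype entries must be 0, 1, 2 or NA")
  p <- ncol(g)
  if (is.null(positions)) positions <- seq_len(p)
  if (is.unsorted(positions)) stop2("positions must be sorted")
  if (length(positions) != p) stop2("one position per genotype column required")
  if (is.null(allele_freq)) {
    allele_freq <- colMeans(g, na.rm = TRUE) / 2      # P_Q
  }
  if (any(allele_freq %in% c(0, 1)))
    warning("monomorphic position(s): coded column is constant zero")
  ## coded value equals genotype count minus 2 P_Q for all three branches
  coded <- sweep(g, 2L, 2 * allele_freq)
  imputed <- anyNA(coded)
  if (imputed) {
    cm <- colMeans(coded, na.rm = TRUE)
    idx <- which(is.na(coded), arr.ind = TRUE)
    coded[idx] <- cm[idx[, 2L]]
  }
  rng <- range(positions)
  pos01 <- if (diff(rng) > 0) (positions - rng[1L]) / diff(rng)
           else rep(0.5, p)
  structure(list(values = coded, positions = pos01,
                 allele_freq = cbind(P_Q = allele_freq,
                                     P_q = 1 - allele_freq),
                 imputed = imputed),
            class = "genotype_function")
}

#' Functional principal component scores of genotype functions
#'
#' Expands each sample's genotype function in an orthonormal eigenbasis of
#' the sample covariance operator and returns the per-sample scores. The
#' covariance operator is discretized either on a cubic B-spline basis
#' (default, `min(15, n_positions)` basis functions on the rescaled
#' positions) or on the raw grid; the quadrature inner product uses
#' trapezoid weights on the position grid. Eigenfunction signs are fixed
#' by making each eigenfunction's largest-magnitude grid value positive.
#'
#' @param gfm a `"genotype_function"` (or any list with numeric `values`
#'   and `positions` in `[0, 1]`).
#' @param n_components number of components to keep; when `NULL` the
#'   smallest number whose cumulative variance reaches
#'   `variance_threshold`.
#' @param variance_threshold cumulative-variance cutoff (default 0.8).
#' @param basis `"bspline"` (default; falls back to the raw grid when
#'   there are fewer than 5 positions) or `"raw"`.
#' @param n_basis number of B-spline basis functions.
#' @return object of class `"fpc_result"`: list with `scores` (samples x
#'   components), `eigenfunctions` (components x positions, orthonormal
#'   under the quadrature inner product), `variance_explained`, and
#'   `positions`.
#' @export
fpc_scores <- function(gfm, n_components = NULL, variance_threshold = 0.8,
                       basis = c("bspline", "raw"), n_basis = 15L) {
  basis <- match.arg(basis)
  x <- as.matrix(gfm$values)
  pos <- gfm$positions
  n <- nrow(x); p <- ncol(x)
  if (n < 2L || p < 2L) stop2("need at least 2 samples and 2 positions")
  if (!is.null(n_components) && n_components < 1L)
    stop2("n_components must be positive")
  if (all(apply(x, 2, stats::var) == 0)) stop2("zero-variance genotype matrix")
  xc <- scale(x, center = TRUE, scale = FALSE)

  ## trapezoid quadrature weights on the position grid
  w <- quad_weights(pos)

  use_spline <- basis == "bspline" && p >= 5L
  if (use_spline) {
    K <- min(n_basis, p)
    B <- splines::bs(pos, df = K, degree = 3L, intercept = TRUE)  # p x K
    B <- unclass(B)
    ## least-squares basis coefficients per sample curve
    C <- t(qr.coef(qr(B), t(xc)))                                # n x K
    C[is.na(C)] <- 0
    J <- crossprod(B * w, B)                                     # Gram matrix
    J <- (J + t(J)) / 2
    L <- tryCatch(chol(J), error = function(e) NULL)
    if (is.null(L)) { use_spline <- FALSE } else {
      S <- stats::cov(C)                                         # K x K
      M <- L %*% S %*% t(L)
      eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
      lam <- pmax(eg$values, 0)
      bcoef <- backsolve(L, eg$vectors)                          # K x K
      efun <- t(B %*% bcoef)                                     # K x p grid
      scores <- C %*% J %*% bcoef                                # n x K
    }
  }
  if (!use_spline) {
    ## raw-grid weighted PCA: eigenfunctions on the observation grid
    xw <- xc %*% diag(sqrt(w), p)
    S <- crossprod(xw) / (n - 1)
    eg <- eigen((S + t(S)) / 2, symmetric = TRUE)
    lam <- pmax(eg$values, 0)
    efun <- t(diag(1 / sqrt(w), p) %*% eg$vectors)               # p x p -> comp x pos
    scores <- (xc * rep(w, each = n)) %*% t(efun)
  }

  ve <- lam / sum(lam)
  L_keep <- if (!is.null(n_components)) min(as.integer(n_components), length(lam))
            else max(1L, which(cumsum(ve) >= variance_threshold)[1L])
  keep <- seq_len(L_keep)
  efun <- efun[keep, , drop = FALSE]
  scores <- scores[, keep, drop = FALSE]
  ## deterministic sign: largest-magnitude grid loading positive
  for (l in keep) {
    j <- which.max(abs(efun[l, ]))
    if (efun[l, j] < 0) { efun[l, ] <- -efun[l, ]; scores[, l] <- -scores[, l] }
  }
  colnames(scores) <- paste0("FPC", keep)
  structure(list(scores = scores, eigenfunctions = efun,
                 variance_explained = ve[keep], positions = pos,
                 quad_weights = w),
            class = "fpc_result")
}

## Trapezoid quadrature weights for a sorted grid in [0, 1]; degenerate
## (all-equal) grids fall back to equal weights.
quad_weights <- function(pos) {
  p <- length(pos)
  if (p < 2L || diff(range(pos)) == 0) return(rep(1 / p, p))
  d <- diff(pos)
  w <- c(d[1L] / 2, (d[-length(d)] + d[-1L]) / 2, d[length(d)] / 2)
  ## guard repeated positions
  w[w <= 0] <- min(w[w > 0]) / 2
  w
}

#' @export
print.fpc_result <- function(x, ...) {
  cat(sprintf("FPC scores: %d samples x %d components (%.1f%% variance)\n",
              nrow(x$scores), ncol(x$scores),
              100 * sum(x$variance_explained)))
  invisible(x)
}

#' PCA summaries of feature groups
#'
#' Summarizes each group of features (a pathway or cluster) by the leading
#' principal component scores of its standardized member features,
#' retaining components up to a cumulative-variance threshold.
#'
#' @param feature_matrix samples x features numeric matrix with column
#'   names.
#' @param group_map data frame (`feature`, `group`) or named list of
#'   feature-name vectors.
#' @param variance_threshold cumulative-variance cutoff (default 0.8).
#' @return samples x summary-columns matrix; columns named `group::PCk`.
#'   The per-group variance fractions are in attribute
#'   `"variance_explained"`.
#' @export
group_summary_pca <- function(feature_matrix, group_map,
                              variance_threshold = 0.8) {
  x <- as.matrix(feature_matrix)
  if (is.null(colnames(x))) stop2("feature_matrix needs column names")
  if (is.data.frame(group_map)) {
    group_map <- split(as.character(group_map$feature),
                       as.character(group_map$group))
  }
  if (!length(group_map)) stop2("group_map is empty")
  out <- list(); ve_out <- list()
  for (gname in names(group_map)) {
    feats <- intersect(group_map[[gname]], colnames(x))
    if (!length(feats)) { warning("group ", gname, " has no matched feature"); next }
    sub <- x[, feats, drop = FALSE]
    keep <- apply(sub, 2, stats::sd) > 0
    if (!all(keep)) warning("dropping constant feature(s) in group ", gname)
    sub <- sub[, keep, drop = FALSE]
    if (!ncol(sub)) { warning("group ", gname, " dropped: all features constant"); next }
    pc <- stats::prcomp(sub, center = TRUE, scale. = TRUE)
    ve <- pc$sdev^2 / sum(pc$sdev^2)
    k <- max(1L, which(cumsum(ve) >= variance_threshold)[1L])
    sc <- pc$x[, seq_len(k), drop = FALSE]
    ## deterministic sign convention as in fpc_scores
    for (l in seq_len(k)) {
      j <- which.max(abs(pc$rotation[, l]))
      if (pc$rotation[j, l] < 0) sc[, l] <- -sc[, l]
    }
    colnames(sc) <- paste0(gname, "::PC", seq_len(k))
    out[[gname]] <- sc
    ve_out[[gname]] <- ve[seq_len(k)]
  }
  if (!length(out)) stop2("no usable group")
  res <- do.call(cbind, out)
  attr(res, "variance_explained") <- ve_out
  res
}
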