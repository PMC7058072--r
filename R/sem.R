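## Sparse structural equation models estimated node by node with the
## two-stage least squares quadratic-form objective and an L1 penalty.
##
## For node i with response y_i, candidate design W_i = [Y_{-i}, X] and
## instruments X (all exogenous variables), the objective is
##   f(D) = (X'y_i - X'W_i D)' (X'X)^{-1} (X'y_i - X'W_i D),
## minimized plus lambda * ||D||_1 by ADMM.

#' Two-stage least squares quadratic-form objective
#'
#' Builds the exact quadratic form
#' `f(D) = (X'y - X'W D)' (X'X)^{-1} (X'y - X'W D)` used to estimate one
#' structural equation, expanded as `f(D) = D'PD - 2 q'D + c0`. All
#' variables are centered internally, so no intercept column is needed.
#'
#' @param y response vector of one endogenous variable.
#' @param W candidate design matrix (other endogenous + exogenous columns).
#' @param X instrument matrix (exogenous variables).
#' @param ridge relative ridge added to `X'X` when it is numerically
#'   singular (flagged via attribute `"ridged"`); set 0 to error instead.
#' @return object of class `"tsls_objective"`: list with `eval`
#'   (function of D), `P`, `q`, `c0`, `minimizer` (an unpenalized
#'   least-norm minimizer) and dimensions.
#' @examples
#' n <- 50; X <- matrix(rnorm(n * 2), n)
#' y <- X %*% c(1, -1) + rnorm(n)
#' obj <- two_stage_objective(y, W = X, X = X)
#' obj$eval(c(0, 0))   # equals y'X (X'X)^{-1} X'y
#' @export
two_stage_objective <- function(y, W, X, ridge = 1e-8) {
  y <- as.numeric(y); W <- as.matrix(W); X <- as.matrix(X)
  n <- length(y)
  if (nrow(W) != n || nrow(X) != n) stop2("sample counts of y, W, X differ")
  yc <- y - mean(y)
  Wc <- scale(W, center = TRUE, scale = FALSE)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  A <- crossprod(Xc)
  ridged <- FALSE
  if (rcond_sym(A) < 1e-12) {
    if (ridge <= 0) stop2("X'X is rank deficient and ridge = 0")
    A <- A + diag(ridge * sum(diag(A)) / ncol(A), ncol(A))
    ridged <- TRUE
  }
  Ainv <- chol2inv(chol(A))
  r <- crossprod(Xc, yc)                  # X'y
  M <- crossprod(Xc, Wc)                  # X'W
  P <- t(M) %*% Ainv %*% M
  P <- (P + t(P)) / 2
  q <- as.numeric(t(M) %*% Ainv %*% r)
  c0 <- as.numeric(t(r) %*% Ainv %*% r)
  eval_f <- function(D) {
    D <- as.numeric(D)
    as.numeric(t(D) %*% P %*% D - 2 * sum(q * D) + c0)
  }
  ## least-norm unpenalized minimizer (P may be rank deficient when there
  ## are more candidates than instruments)
  minimizer <- as.numeric(pinv_solve(P, q))
  out <- list(eval = eval_f, P = P, q = q, c0 = c0, minimizer = minimizer,
              n = n, p = ncol(W), A = A, M = M, r = r, yc = yc, Wc = Wc,
              col_names = colnames(W) %||% paste0("w", seq_len(ncol(W))))
  attr(out, "ridged") <- ridged
  class(out) <- "tsls_objective"
  out
}

## reciprocal condition estimate for a symmetric PSD matrix
rcond_sym <- function(A) {
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  if (max(ev) <= 0) return(0)
  max(min(ev), 0) / max(ev)
}

## Minimum-norm solution of P d = q via eigendecomposition.
pinv_solve <- function(P, q, tol = 1e-10) {
  eg <- eigen(P, symmetric = TRUE)
  pos <- eg$values > tol * max(eg$values, 0)
  if (!any(pos)) return(rep(0, length(q)))
  V <- eg$vectors[, pos, drop = FALSE]
  as.numeric(V %*% (crossprod(V, q) / eg$values[pos]))
}

## Exact-solution attempt from a candidate support: solve the reduced
## smooth KKT system and certify the full optimality conditions
## |2PD - 2q|_j <= lambda off-support, = -lambda*sign on support.
kkt_polish <- function(P, q, lambda, supp, sgn, tol = 1e-9) {
  p <- length(q)
  d <- rep(0, p)
  if (length(supp)) {
    ds <- pinv_solve(2 * P[supp, supp, drop = FALSE],
                     2 * q[supp] - lambda * sgn)
    if (any(sign(ds) * sgn < 0)) return(NULL)
    d[supp] <- ds
  }
  g <- 2 * as.numeric(P %*% d) - 2 * q
  tol_s <- tol * max(1, lambda)
  if (length(supp) && any(abs(g[supp] + lambda * sgn) > tol_s))
    return(NULL)
  off <- setdiff(seq_len(p), supp)
  if (length(off) && any(abs(g[off]) > lambda + tol_s)) return(NULL)
  d
}

## ADMM for min D'PD - 2 q'D + lambda ||D||_1.
## Splitting D = z; scaled dual u. x-update solves (2P + rho I) D = 2q +
## rho (z - u); z-update is soft thresholding. Every 100 iterations the
## current support is polished by solving the reduced KKT system exactly;
## a verified KKT certificate ends the iteration early with the exact
## solution (this also handles the slow tail along rank-deficient
## directions of P).
admm_lasso_quad <- function(P, q, lambda, rho = NULL, max_iter = 10000L,
                            tol_abs = 1e-9, tol_rel = 1e-7, init = NULL) {
  p <- length(q)
  if (is.null(rho)) rho <- max(mean(diag(P)), lambda, 1e-3)
  R <- chol(2 * P + diag(rho, p))
  z <- init %||% rep(0, p)
  u <- rep(0, p)
  d <- z
  for (it in seq_len(max_iter)) {
    d <- backsolve(R, forwardsolve(t(R), 2 * q + rho * (z - u)))
    z_old <- z
    v <- d + u
    z <- sign(v) * pmax(abs(v) - lambda / rho, 0)
    u <- u + d - z
    pri <- sqrt(sum((d - z)^2))
    dua <- rho * sqrt(sum((z - z_old)^2))
    eps_pri <- sqrt(p) * tol_abs + tol_rel * max(sqrt(sum(d^2)), sqrt(sum(z^2)))
    eps_dua <- sqrt(p) * tol_abs + tol_rel * rho * sqrt(sum(u^2))
    if (pri < eps_pri && dua < eps_dua) {
      return(list(coef = z, iterations = it, converged = TRUE))
    }
    if (it %% 100L == 0L) {
      supp <- which(z != 0)
      pol <- kkt_polish(P, q, lambda, supp, sign(z[supp]))
      if (!is.null(pol))
        return(list(coef = pol, iterations = it, converged = TRUE))
    }
    ## residual balancing (Boyd et al.): keep primal and dual residuals
    ## within a factor of 10 by rescaling rho; only during the early
    ## phase, so late rescaling cannot stall convergence
    if (it %% 50L == 0L && it <= 1000L) {
      if (pri > 10 * dua) {
        rho <- rho * 2; u <- u / 2
        R <- chol(2 * P + diag(rho, p))
      } else if (dua > 10 * pri) {
        rho <- rho / 2; u <- u * 2
        R <- chol(2 * P + diag(rho, p))
      }
    }
  }
  list(coef = z, iterations = max_iter, converged = FALSE)
}

#' Fit one sparse structural equation by penalized 2SLS
#'
#' Minimizes `f(D) + lambda ||D||_1` over a grid of penalties by ADMM,
#' selects the penalty by a BIC-style criterion `f(D_refit) + |S| log(n)`
#' on the debiased refit, and reports unpenalized 2SLS coefficients with
#' asymptotic normal p-values on the selected support.
#'
#' @param y response vector (one endogenous variable).
#' @param W candidate design (other endogenous + exogenous columns).
#' @param X instrument matrix (all exogenous variables).
#' @param lambda_grid penalty grid; by default a 20-point log-spaced grid
#'   from `lambda_max` (smallest penalty with an all-zero solution) down
#'   to `1e-3 lambda_max`.
#' @param n_lambda,lambda_min_ratio grid shape when `lambda_grid` is NULL.
#' @param select `"bic"` (default) or `"all"` to return the full path
#'   without selection.
#' @param max_iter,tol_abs,tol_rel ADMM controls.
#' @return object of class `"sem_node_fit"`: list with `coef` (named,
#'   debiased on support, 0 elsewhere), `support`, `p_values` (on the
#'   support), `lambda`, `objective` (f at the penalized solution),
#'   `path` (per-lambda summary) and `converged`.
#' @export
fit_sparse_sem_node <- function(y, W, X, lambda_grid = NULL, n_lambda = 20L,
                                lambda_min_ratio = 1e-3,
                                select = c("bic", "all"),
                                max_iter = 20000L, tol_abs = 1e-9,
                                tol_rel = 1e-7) {
  select <- match.arg(select)
  obj <- two_stage_objective(y, W, X)
  ## standardize internally (unit-variance response and candidates) so the
  ## penalty acts evenly and the ADMM subproblems are well conditioned;
  ## coefficients are transformed back to the original scale
  s_w <- apply(as.matrix(W), 2, stats::sd); s_w[s_w == 0] <- 1
  s_y <- stats::sd(y); if (s_y == 0) s_y <- 1
  obj_s <- obj
  obj_s$P <- t(obj$P / s_w) / s_w
  obj_s$q <- obj$q / (s_w * s_y)
  obj_s$c0 <- obj$c0 / s_y^2
  obj_s$yc <- obj$yc / s_y
  obj_s$Wc <- sweep(obj$Wc, 2L, s_w, "/")
  obj_s$eval <- function(D) {
    D <- as.numeric(D)
    as.numeric(t(D) %*% obj_s$P %*% D - 2 * sum(obj_s$q * D) + obj_s$c0)
  }
  P <- obj_s$P; q <- obj_s$q
  if (is.null(lambda_grid)) {
    lambda_max <- max(abs(2 * q))      # subgradient condition for D = 0
    if (lambda_max <= 0) lambda_max <- 1
    lambda_grid <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                           length.out = n_lambda))
  }
  if (!length(lambda_grid)) stop2("lambda_grid must be non-empty")
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)
  n <- obj$n
  fits <- vector("list", length(lambda_grid))
  init <- NULL
  for (k in seq_along(lambda_grid)) {
    fit <- admm_lasso_quad(P, q, lambda_grid[k], max_iter = max_iter,
                           tol_abs = tol_abs, tol_rel = tol_rel, init = init)
    if (!fit$converged)
      stop2("ADMM did not converge at lambda = ", signif(lambda_grid[k], 3),
            " after ", max_iter, " iterations")
    init <- fit$coef
    supp <- which(fit$coef != 0)
    refit <- refit_support(obj_s, supp)
    fits[[k]] <- list(lambda = lambda_grid[k], coef_pen = fit$coef,
                      support = supp, refit = refit,
                      bic = refit$objective + length(supp) * log(n),
                      iterations = fit$iterations)
  }
  path <- data.frame(
    lambda = vapply(fits, `[[`, numeric(1), "lambda"),
    df = vapply(fits, function(f) length(f$support), integer(1)),
    bic = vapply(fits, `[[`, numeric(1), "bic"))
  if (select == "all") {
    return(structure(list(path = path, fits = fits, objective_spec = obj),
                     class = "sem_node_path"))
  }
  best <- which.min(path$bic)
  sel <- fits[[best]]
  coef <- rep(0, obj$p); names(coef) <- obj$col_names
  coef[sel$support] <- sel$refit$coef * s_y / s_w[sel$support]
  pv <- sel$refit$p_values
  names(pv) <- obj$col_names[sel$support]
  structure(list(
    coef = coef, support = obj$col_names[sel$support],
    p_values = pv, lambda = sel$lambda,
    objective = obj$eval(coef),
    coef_penalized = sel$coef_pen * s_y / s_w,
    path = path, n = n, converged = TRUE,
    support_union = obj$col_names[sort(unique(unlist(
      lapply(fits, `[[`, "support"))))]
  ), class = "sem_node_fit")
}

## Unpenalized 2SLS refit restricted to a support set, with asymptotic
## standard errors from the classical 2SLS covariance
## sigma^2 (W_S' X (X'X)^{-1} X' W_S)^{-1}, sigma^2 estimated from the
## structural residuals y - W_S coef.
refit_support <- function(obj, supp) {
  if (!length(supp)) {
    return(list(coef = numeric(0), p_values = numeric(0),
                objective = obj$c0))
  }
  Ps <- obj$P[supp, supp, drop = FALSE]
  qs <- obj$q[supp]
  coef <- pinv_solve(Ps, qs)
  full <- rep(0, obj$p); full[supp] <- coef
  fobj <- as.numeric(t(full) %*% obj$P %*% full - 2 * sum(obj$q * full) +
                     obj$c0)
  resid <- obj$yc - as.numeric(obj$Wc[, supp, drop = FALSE] %*% coef)
  sigma2 <- max(sum(resid^2) / max(obj$n - length(supp), 1),
                .Machine$double.eps)
  covm <- tryCatch(solve(Ps), error = function(e) NULL)
  if (is.null(covm)) covm <- MASS_ginv(Ps)
  se <- sqrt(pmax(diag(covm) * sigma2, 0))
  z <- ifelse(se > 0, coef / se, 0)
  pv <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  list(coef = coef, se = se, p_values = pv, objective = fobj,
       sigma2 = sigma2)
}

## Moore-Penrose inverse (small symmetric matrices).
MASS_ginv <- function(A, tol = 1e-10) {
  eg <- eigen((A + t(A)) / 2, symmetric = TRUE)
  pos <- abs(eg$values) > tol * max(abs(eg$values), 1e-300)
  if (!any(pos)) return(matrix(0, nrow(A), ncol(A)))
  V <- eg$vectors[, pos, drop = FALSE]
  V %*% (t(V) / eg$values[pos])
}

#' @export
print.sem_node_fit <- function(x, ...) {
  cat(sprintf("Sparse SEM node fit: %d/%d nonzero (lambda %.3g, f = %.3g)\n",
              length(x$support), length(x$coef), x$lambda, x$objective))
  invisible(x)
}

#' Estimate a directed SEM network over all endogenous nodes
#'
#' Fits [fit_sparse_sem_node()] for every endogenous node with all other
#' endogenous nodes plus all exogenous nodes as candidate parents and the
#' exogenous variables as instruments, and retains a directed edge
#' parent -> node for every coefficient that is nonzero and significant at
#' `alpha`. No acyclicity is enforced: this is the unconstrained "SEM"
#' estimator, whose output may be cyclic.
#'
#' @param dataset an `"omics_dataset"`; columns with layer `"genotype"`
#'   (or any layer named in `exogenous_layers`) are exogenous.
#' @param alpha edge-retention significance level (default 0.05).
#' @param exogenous_layers layer labels treated as exogenous.
#' @param ... passed to [fit_sparse_sem_node()].
#' @return object of class `"sem_network"`: list with `nodes`, `layer`,
#'   `edges` (data frame `parent`, `child`, `coefficient`, `p_value`) and
#'   per-node `fits`.
#' @export
fit_sem_network <- function(dataset, alpha = 0.05,
                            exogenous_layers = "genotype", ...) {
  stopifnot(inherits(dataset, "omics_dataset"))
  dat <- dataset$data
  exo <- names(dataset$layer)[dataset$layer %in% exogenous_layers]
  endo <- setdiff(colnames(dat), exo)
  if (length(endo) < 2L) stop2("need at least 2 endogenous variables")
  if (length(exo) < 1L) stop2("2SLS needs at least one exogenous instrument")
  X <- dat[, exo, drop = FALSE]
  edges <- list(); fits <- list()
  for (node in endo) {
    Wn <- dat[, c(setdiff(endo, node), exo), drop = FALSE]
    fit <- fit_sparse_sem_node(dat[, node], Wn, X, ...)
    fits[[node]] <- fit
    sig <- fit$support[fit$p_values[fit$support] < alpha]
    if (length(sig)) {
      edges[[node]] <- data.frame(
        parent = sig, child = node,
        coefficient = unname(fit$coef[sig]),
        p_value = unname(fit$p_values[sig]), stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(parent = character(0), child = character(0),
               coefficient = numeric(0), p_value = numeric(0))
  rownames(edges) <- NULL
  structure(list(nodes = colnames(dat), layer = dataset$layer,
                 edges = edges, fits = fits, alpha = alpha),
            class = "sem_network")
}

#' @export
print.sem_network <- function(x, ...) {
  cat(sprintf("SEM network: %d nodes, %d directed edges (alpha %g)\n",
              length(x$nodes), nrow(x$edges), x$alpha))
  invisible(x)
}
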