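# REML estimation of the variance components.
#
# Restricted log-likelihood for V(theta) = sum_r theta_r K_r + diag(v):
#   l_R = -1/2 [ log|V| + log|X' V^-1 X| + y' P y + (n - p) log 2pi ]
# with P = V^-1 - V^-1 X (X' V^-1 X)^-1 X' V^-1. The gradient is
#   dl/dtheta_r = -1/2 [ tr(P K_r) - (P y)' K_r (P y) ].
# theta is optimized directly on the variance scale under box constraints
# theta_r >= 0 (PORT/nlminb), so boundary solutions come out as exact zeros.

reml_objective <- function(theta, spec, want_grad = FALSE) {
  n <- spec$n; p <- spec$p
  V <- diag(spec$v, n)
  for (r in seq_along(spec$K)) V <- V + theta[r] * spec$K[[r]]
  U <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(U)) {
    # numerically indefinite trial point: nudge with a relative jitter
    U <- tryCatch(chol(V + diag(1e-10 * mean(diag(V)), n)),
                  error = function(e) NULL)
    if (is.null(U)) return(list(nll = Inf, grad = rep(NA_real_, length(theta))))
  }
  Vi <- chol2inv(U)
  ViX <- Vi %*% spec$X
  XtViX <- crossprod(spec$X, ViX)
  cXtViX <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(cXtViX)) return(list(nll = Inf,
                                   grad = rep(NA_real_, length(theta))))
  XtViX_inv <- chol2inv(cXtViX)
  beta <- XtViX_inv %*% crossprod(ViX, spec$y)
  r <- spec$y - spec$X %*% beta
  Pr <- Vi %*% r                       # equals P %*% y
  ld_V <- 2 * sum(log(diag(U)))
  ld_X <- 2 * sum(log(diag(cXtViX)))
  # +log|X'X| makes the restricted likelihood invariant to reparameterization
  # of the fixed effects (the convention of standard meta-analytic software)
  ld_XtX <- as.numeric(determinant(crossprod(spec$X), logarithm = TRUE)$modulus)
  quad <- drop(crossprod(r, Pr))
  nll <- 0.5 * (ld_V + ld_X - ld_XtX + quad + (n - p) * log(2 * pi))
  out <- list(nll = nll, beta = drop(beta), vcov_beta = XtViX_inv,
              Vi = Vi, Pr = drop(Pr), U = U)
  if (want_grad) {
    P <- Vi - ViX %*% tcrossprod(XtViX_inv, ViX)
    g <- vapply(spec$K, function(Kr) {
      0.5 * (sum(P * Kr) - drop(crossprod(out$Pr, Kr %*% out$Pr)))
    }, numeric(1))
    out$grad <- g
  }
  out
}

#' REML optimizer settings
#'
#' @param starts Number of deterministic starting points (1-3): a
#'   method-of-moments start, an equal split of the marginal variance, and a
#'   near-zero start, tried in that order.
#' @param rel_tol Relative convergence tolerance passed to [stats::nlminb()].
#' @param max_iter Iteration budget per start.
#' @param zero_tol Components below `zero_tol * var(y)` at the optimum are
#'   snapped to exactly 0 (boundary convention).
#' @return A list of settings for [fit_reml()].
#' @export
reml_opts <- function(starts = 3L, rel_tol = 1e-12, max_iter = 500L,
                      zero_tol = 1e-8) {
  list(starts = starts, rel_tol = rel_tol, max_iter = max_iter,
       zero_tol = zero_tol)
}

#' Fit the multilevel meta-analytic model by REML
#'
#' Maximizes the restricted log-likelihood over non-negative variance
#' components with known heteroscedastic sampling variances, then returns
#' the generalized least squares fixed effects at the optimum with
#' model-based standard errors.
#'
#' @param spec An `"mlmeta_spec"` from [build_model()] or [model_spec()].
#' @param opts Settings from [reml_opts()].
#' @return An object of class `"mlmeta_fit"`: `sigma2` (named variance
#'   components), `beta`, `se`, `vcov_beta`, `logLik` (restricted),
#'   `fitted`, `residuals` (marginal, `y - X beta`), `converged`, and the
#'   `spec`.
#' @export
fit_reml <- function(spec, opts = reml_opts()) {
  stopifnot(inherits(spec, "mlmeta_spec"))
  nr <- length(spec$K)

  if (nr == 0L) {
    # no free variance components: plain GLS with V = diag(v)
    obj <- reml_objective(numeric(0), spec)
    return(finish_fit(spec, numeric(0), obj, converged = TRUE))
  }

  s2y <- stats::var(spec$y)
  if (!is.finite(s2y) || s2y <= 0) s2y <- mean(spec$v)
  # method-of-moments-style start: excess of marginal variance over the
  # average sampling variance, split equally across components
  excess <- max(s2y - mean(spec$v), 0.01 * s2y)
  starts <- list(
    rep(excess / nr, nr),
    rep(s2y / nr, nr),
    rep(1e-4 * s2y, nr)
  )[seq_len(max(1L, min(3L, opts$starts)))]

  fn <- function(th) reml_objective(th, spec)$nll
  gr <- function(th) {
    g <- reml_objective(th, spec, want_grad = TRUE)$grad
    if (any(!is.finite(g))) rep(0, nr) else g
  }

  best <- NULL
  for (st in starts) {
    res <- tryCatch(
      stats::nlminb(st, fn, gradient = gr, lower = rep(0, nr),
                    upper = rep(1e3 * max(s2y, mean(spec$v)), nr),
                    control = list(rel.tol = opts$rel_tol,
                                   iter.max = opts$max_iter,
                                   eval.max = 4L * opts$max_iter)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$objective)) next
    if (is.null(best) || res$objective < best$objective - 1e-12) best <- res
  }
  if (is.null(best)) {
    stop("REML optimization failed from every starting point")
  }

  theta <- best$par
  theta[theta < opts$zero_tol * max(s2y, 1e-12)] <- 0
  obj <- reml_objective(theta, spec)
  converged <- best$convergence == 0 || is.finite(obj$nll)
  finish_fit(spec, theta, obj, converged = converged)
}

finish_fit <- function(spec, theta, obj, converged) {
  names(theta) <- names(spec$K)
  beta <- obj$beta
  names(beta) <- colnames(spec$X)
  se <- sqrt(diag(as.matrix(obj$vcov_beta)))
  names(se) <- colnames(spec$X)
  fitted <- drop(spec$X %*% beta)
  structure(list(
    sigma2 = theta,
    beta = beta, se = se, vcov_beta = obj$vcov_beta,
    logLik = -obj$nll,
    fitted = fitted,
    residuals = spec$y - fitted,
    converged = converged,
    spec = spec
  ), class = "mlmeta_fit")
}

#' @export
print.mlmeta_fit <- function(x, ...) {
  cat("Multilevel meta-analytic model (REML)\n")
  cat(sprintf("  records: %d   fixed effects: %d   restricted logLik: %.4f\n",
              x$spec$n, x$spec$p, x$logLik))
  if (length(x$sigma2)) {
    cat("  variance components:\n")
    for (nm in names(x$sigma2)) {
      cat(sprintf("    %-10s %.6f\n", nm, x$sigma2[[nm]]))
    }
  }
  cat("  fixed effects:\n")
  print(round(cbind(estimate = x$beta, se = x$se), 4))
  invisible(x)
}
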