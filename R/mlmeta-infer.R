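# Heterogeneity decomposition, Wald tests and likelihood-ratio tests.

#' Typical sampling-error variance
#'
#' Single-number summary of the known sampling variances used in the
#' I-squared denominator. With weights `w_i = 1/v_i`:
#' `sigma_m^2 = (k - 1) * sum(w) / (sum(w)^2 - sum(w^2))`.
#' Equal variances return the common value exactly.
#'
#' @param v Vector of sampling variances (length >= 2, all positive).
#' @return The typical sampling-error variance.
#' @export
typical_sampling_variance <- function(v) {
  if (length(v) < 2L) stop("need at least 2 sampling variances")
  if (any(!is.finite(v)) || any(v <= 0)) stop("all sampling variances must be > 0")
  w <- 1 / v
  (length(v) - 1) * sum(w) / (sum(w)^2 - sum(w^2))
}

#' Heterogeneity decomposition (I-squared and variance proportions)
#'
#' Expresses each variance component as a proportion of the total variance
#' (components plus typical sampling-error variance), and the total
#' heterogeneity as
#' `I2 = (sum of components) / (sum of components + sigma_m^2)`.
#'
#' @param fit An `"mlmeta_fit"`.
#' @param sigma_m2 Typical sampling-error variance; computed from the fit's
#'   sampling variances when omitted.
#' @return A list of class `"heterogeneity_report"`: `sigma_m2`, `I2`, and
#'   `proportions` (named, including `"sampling_error"`, summing to 1).
#' @export
heterogeneity <- function(fit, sigma_m2 = NULL) {
  stopifnot(inherits(fit, "mlmeta_fit"))
  if (is.null(sigma_m2)) sigma_m2 <- typical_sampling_variance(fit$spec$v)
  comp <- fit$sigma2
  total <- sum(comp) + sigma_m2
  if (total <= 0) stop("total variance is zero; heterogeneity undefined")
  proportions <- c(comp, sampling_error = sigma_m2) / total
  structure(list(
    sigma_m2 = sigma_m2,
    I2 = sum(comp) / total,
    proportions = proportions
  ), class = "heterogeneity_report")
}

#' Wald tests for the fixed effects
#'
#' Per-coefficient normal-theory tests: `z = beta/SE`,
#' `p = 2 * pnorm(-|z|)`, 95% CI `beta +/- 1.96 SE`.
#'
#' @param fit An `"mlmeta_fit"`.
#' @return Data.frame with columns `term`, `estimate`, `se`, `z`, `p`,
#'   `ci_lower`, `ci_upper`.
#' @export
wald_tests <- function(fit) {
  stopifnot(inherits(fit, "mlmeta_fit"))
  z <- fit$beta / fit$se
  data.frame(
    term = names(fit$beta),
    estimate = unname(fit$beta),
    se = unname(fit$se),
    z = unname(z),
    p = unname(2 * stats::pnorm(-abs(z))),
    ci_lower = unname(fit$beta - 1.96 * fit$se),
    ci_upper = unname(fit$beta + 1.96 * fit$se),
    stringsAsFactors = FALSE
  )
}

#' Likelihood-ratio test for one random term
#'
#' Compares the full model to a reduced model dropping exactly one random
#' term: `statistic = max(0, 2 * (ll_full - ll_reduced))`, referred to a
#' chi-square with 1 df by default. Because the null value lies on the
#' boundary of the parameter space, a 50:50 mixture reference
#' (`0.5 * chi2_0 + 0.5 * chi2_1`) is available via `boundary_mixture`.
#'
#' @param full Fit of the full model.
#' @param reduced Fit of the model without one random term (same data and
#'   fixed-effect design).
#' @param boundary_mixture Use the boundary mixture reference distribution.
#' @return List: `statistic`, `df`, `p`, `logLik_reduced`, `dropped`.
#' @export
lrt_random_effect <- function(full, reduced, boundary_mixture = FALSE) {
  stopifnot(inherits(full, "mlmeta_fit"), inherits(reduced, "mlmeta_fit"))
  if (!isTRUE(all.equal(full$spec$y, reduced$spec$y)) ||
      !isTRUE(all.equal(full$spec$X, reduced$spec$X))) {
    stop("full and reduced fits must share the same data and fixed design")
  }
  dropped <- setdiff(full$spec$random, reduced$spec$random)
  if (length(dropped) != 1L) {
    stop("reduced model must drop exactly one random term (dropped: ",
         paste(dropped, collapse = ", "), ")")
  }
  stat <- max(0, 2 * (full$logLik - reduced$logLik))
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  if (boundary_mixture) p <- ifelse(stat == 0, 1, p / 2)
  list(statistic = stat, df = 1L, p = p,
       logLik_reduced = reduced$logLik, dropped = dropped)
}

#' Likelihood-ratio tests for every random term
#'
#' Refits the model dropping each random term in turn and tests it against
#' the full fit.
#'
#' @param fit Full-model `"mlmeta_fit"`.
#' @param opts Optimizer settings for the reduced fits.
#' @param boundary_mixture Passed to [lrt_random_effect()].
#' @return Data.frame with one row per random term: `term`, `statistic`,
#'   `logLik_reduced`, `p`.
#' @export
lrt_all_random_effects <- function(fit, opts = reml_opts(),
                                   boundary_mixture = FALSE) {
  stopifnot(inherits(fit, "mlmeta_fit"))
  rows <- lapply(fit$spec$random, function(term) {
    reduced <- fit_reml(drop_random_term(fit$spec, term), opts)
    lr <- lrt_random_effect(fit, reduced, boundary_mixture)
    data.frame(term = term, statistic = lr$statistic,
               logLik_reduced = lr$logLik_reduced, p = lr$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
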