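# Publication-bias diagnostics: funnel data, the multilevel Egger variant
# (effect size regressed on its sampling variance, with study and species
# random intercepts and an estimate-level residual), and the time-lag model
# (publication year as the predictor).

#' Funnel-plot data from a meta-regression fit
#'
#' Returns the marginal residuals `y - X beta` of the full moderator
#' meta-regression with the precision `1/se` of each estimate. Residuals of
#' the meta-regression are used so that heterogeneity attributable to the
#' moderators does not masquerade as funnel asymmetry; marginal (rather than
#' conditional) residuals retain the between-study spread the funnel is
#' meant to display. Set `conditional = TRUE` for residuals with predicted
#' random effects removed as well.
#'
#' @param fit An `"mlmeta_fit"` from the moderator meta-regression.
#' @param conditional Subtract empirical BLUPs of the random effects.
#' @return Data.frame: `estimate_id`, `residual`, `precision`.
#' @export
funnel_data <- function(fit, conditional = FALSE) {
  stopifnot(inherits(fit, "mlmeta_fit"))
  resid <- fit$residuals
  if (conditional) {
    # BLUP of the combined random effects: C V^-1 (y - X beta), where C is
    # the random-effect part of the marginal covariance
    spec <- fit$spec
    n <- spec$n
    Cmat <- matrix(0, n, n)
    for (r in seq_along(spec$K)) {
      Cmat <- Cmat + fit$sigma2[[r]] * spec$K[[r]]
    }
    V <- Cmat + diag(spec$v, n)
    resid <- resid - drop(Cmat %*% solve(V, fit$residuals))
  }
  data.frame(
    estimate_id = fit$spec$estimate_id,
    residual = unname(resid),
    precision = unname(1 / sqrt(fit$spec$v)),
    stringsAsFactors = FALSE
  )
}

subset_by_method <- function(records, subset) {
  switch(subset,
    all  = records,
    TRF  = records[records$laboratory_method %in%
                     c("TRF_southern", "TRF_ingel"), , drop = FALSE],
    qPCR = records[records$laboratory_method == "qPCR", , drop = FALSE]
  )
}

fit_bias_model <- function(records, predictor, predictor_name, opts) {
  X <- cbind("(intercept)" = 1, predictor)
  colnames(X)[2] <- predictor_name
  spec <- model_spec(
    y = records$h2, v = records$sampling_variance, X = X,
    study = records$study_id, species = records$species,
    random = c("study", "species", "estimate"),
    estimate_id = records$estimate_id
  )
  fit_reml(spec, opts)
}

bias_result <- function(fit, predictor_name, subset, n, warning = NULL) {
  wt <- wald_tests(fit)
  sl <- wt[wt$term == predictor_name, ]
  structure(list(
    subset = subset,
    predictor = predictor_name,
    slope = sl$estimate, slope_se = sl$se, z = sl$z, p = sl$p,
    intercept = unname(fit$beta[["(intercept)"]]),
    sigma2 = fit$sigma2,
    n = n,
    warning = warning,
    fit = fit
  ), class = "bias_test_result")
}

#' Multilevel Egger regression for funnel asymmetry
#'
#' Regresses the effect sizes on their sampling variances in a mixed model
#' with study and species random intercepts and an estimate-level residual,
#' weighted by the known sampling variances. A statistically significant
#' slope is evidence of small-study (outcome-reporting) bias. Can be run on
#' the whole dataset or on the TRF / qPCR laboratory-method subsets.
#'
#' @param records Validated effect-size table.
#' @param subset `"all"`, `"TRF"` (Southern blot + in-gel) or `"qPCR"`.
#' @param predictor `"v"` (sampling variance, the default) or `"se"`
#'   (standard error).
#' @param opts Optimizer settings.
#' @return A `"bias_test_result"`: slope with SE/z/p, intercept, variance
#'   components, subset label and record count. Subsets with fewer than 10
#'   records carry a warning field.
#' @export
egger_test <- function(records, subset = c("all", "TRF", "qPCR"),
                       predictor = c("v", "se"), opts = reml_opts()) {
  records <- validate_effect_table(records)
  subset <- match.arg(subset)
  predictor <- match.arg(predictor)
  sub <- subset_by_method(records, subset)
  if (nrow(sub) == 0L) stop("subset '", subset, "' is empty")
  warn <- if (nrow(sub) < 10L) {
    sprintf("only %d records in subset '%s'; slope unstable", nrow(sub), subset)
  }
  pred <- if (predictor == "v") sub$sampling_variance else sub$se
  fit <- fit_bias_model(sub, pred,
                        if (predictor == "v") "sampling_variance" else "se",
                        opts)
  bias_result(fit, if (predictor == "v") "sampling_variance" else "se",
              subset, nrow(sub), warn)
}

#' Time-lag (decline-effect) test
#'
#' Same multilevel model as [egger_test()] with mean-centered publication
#' year as the predictor; a significant negative slope indicates a decline
#' of effect magnitudes with time. Centering keeps the intercept
#' interpretable and does not affect the slope.
#'
#' @param records Validated effect-size table with `publication_year`.
#' @param opts Optimizer settings.
#' @return A `"bias_test_result"` with `predictor = "publication_year"`.
#' @export
time_lag_test <- function(records, opts = reml_opts()) {
  records <- validate_effect_table(records)
  yr <- records$publication_year
  if (any(is.na(yr))) stop("publication_year missing for some records")
  if (length(unique(yr)) < 2L) stop("need at least two distinct publication years")
  fit <- fit_bias_model(records, yr - mean(yr), "publication_year",
                        opts)
  bias_result(fit, "publication_year", "all", nrow(records))
}

#' @export
print.bias_test_result <- function(x, ...) {
  cat(sprintf("Multilevel bias test (%s, subset %s, n = %d)\n",
              x$predictor, x$subset, x$n))
  cat(sprintf("  slope = %.4f (SE %.4f), z = %.3f, p = %.4f\n",
              x$slope, x$slope_se, x$z, x$p))
  if (!is.null(x$warning)) cat("  warning:", x$warning, "\n")
  invisible(x)
}

#' Serialize a bias test result to JSON
#' @param x A `"bias_test_result"`.
#' @param path Output path.
#' @export
write_bias_json <- function(x, path) {
  jsonlite::write_json(
    list(subset = x$subset, predictor = x$predictor, slope = x$slope,
         slope_se = x$slope_se, z = x$z, p = x$p, intercept = x$intercept,
         sigma2 = as.list(x$sigma2), n = x$n,
         warning = if (is.null(x$warning)) NA else x$warning),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
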