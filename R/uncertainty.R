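# Nonparametric percentile bootstrap for the variance components.

#' Percentile bootstrap confidence intervals for variance components
#'
#' Resamples the data with replacement — at the record level (rows with
#' their sampling variances) or the study level (whole clusters, resampled
#' copies treated as independent studies) — refits the model by REML for
#' each replicate, and forms 95% intervals from the order statistics at
#' positions `ceiling((R+1) * 0.025)` and `floor((R+1) * 0.975)` of each
#' component's replicate distribution.
#'
#' One master seed drives everything: replicate b uses the substream seed
#' `seed + b`, so results do not depend on execution order.
#'
#' @param spec An `"mlmeta_spec"`.
#' @param R Number of bootstrap replicates (>= 1).
#' @param seed Master integer seed.
#' @param unit `"record"` or `"study"`.
#' @param opts Optimizer settings (a single start keeps the refits fast; the
#'   replicate likelihoods are well conditioned at these sizes).
#' @return Object of class `"bootstrap_result"`: `replicates` (R_eff x
#'   n_components matrix), `ci` (2 x n_components), `R`, `R_eff`,
#'   `failures`, `seed`, `unit`.
#' @export
bootstrap_components <- function(spec, R = 1000L, seed = 1L,
                                 unit = c("record", "study"),
                                 opts = reml_opts(starts = 1L)) {
  stopifnot(inherits(spec, "mlmeta_spec"))
  if (R < 1L) stop("R must be >= 1")
  unit <- match.arg(unit)
  comp_names <- names(spec$K)
  studies <- unique(spec$study)

  one_rep <- function(b) {
    set.seed((seed + b) %% .Machine$integer.max)
    if (unit == "record") {
      idx <- sample.int(spec$n, spec$n, replace = TRUE)
      rspec <- respec_rows(spec, idx)
    } else {
      picked <- sample(studies, length(studies), replace = TRUE)
      idx <- integer(0); new_study <- character(0)
      for (ci in seq_along(picked)) {
        rows <- which(spec$study == picked[ci])
        idx <- c(idx, rows)
        new_study <- c(new_study, paste0(picked[ci], "#", ci))
      }
      new_study <- rep(paste0(picked, "#", seq_along(picked)),
                       times = vapply(picked,
                                      function(s) sum(spec$study == s),
                                      integer(1)))
      rspec <- respec_rows(spec, idx, study = new_study)
    }
    fit_reml(rspec, opts)$sigma2
  }

  reps <- vector("list", R)
  failures <- 0L
  for (b in seq_len(R)) {
    reps[[b]] <- tryCatch(one_rep(b), error = function(e) NULL)
    if (is.null(reps[[b]])) failures <- failures + 1L
  }
  if (failures > 0.2 * R) {
    stop("bootstrap unstable: ", failures, " of ", R, " replicates failed")
  }
  mat <- do.call(rbind, reps[!vapply(reps, is.null, logical(1))])
  colnames(mat) <- comp_names
  R_eff <- nrow(mat)

  lo_i <- max(1L, min(R_eff, ceiling((R_eff + 1) * 0.025)))
  hi_i <- max(1L, min(R_eff, floor((R_eff + 1) * 0.975)))
  ci <- apply(mat, 2, function(x) sort(x)[c(lo_i, hi_i)])
  rownames(ci) <- c("lower", "upper")

  structure(list(replicates = mat, ci = ci, R = R, R_eff = R_eff,
                 failures = failures, seed = seed, unit = unit),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("Percentile bootstrap (%s-level, R = %d, %d failures)\n",
              x$unit, x$R, x$failures))
  print(round(t(x$ci), 5))
  invisible(x)
}

#' Dump bootstrap replicates as TSV for audit
#' @param x A `"bootstrap_result"`.
#' @param path Output path.
#' @export
write_bootstrap_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x$replicates), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
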