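# End-to-end orchestration of the published analysis sequence: intercept-only
# model, moderator meta-regression (with and without the parental-sex by
# statistical-method interaction), Fisher-z and trimming sensitivity models,
# species-specific forest estimates, publication-bias tests, and the
# bootstrap — from one config, with a run log and table outputs.

#' Analysis configuration
#'
#' @param csv Path to an effect-size CSV (canonical schema or mapped via
#'   `schema`), or a data.frame.
#' @param newick Path to (or string of) the species phylogeny in Newick
#'   format.
#' @param models Character vector of stages to run; any of
#'   `"intercept_only"`, `"moderated"`, `"interaction"`, `"transformed"`,
#'   `"trimmed"`, `"species_forest"`, `"egger"`, `"egger_by_method"`,
#'   `"time_lag"`, `"bootstrap"`.
#' @param schema Optional column mapping for [parse_effect_table()].
#' @param bootstrap_R,seed Bootstrap replicate count and master seed.
#' @param out_dir Output directory (created if absent).
#' @return List of class `"analysis_config"`.
#' @export
analysis_config <- function(csv, newick,
                            models = c("intercept_only", "moderated",
                                       "interaction", "transformed",
                                       "trimmed", "species_forest", "egger",
                                       "egger_by_method", "time_lag",
                                       "bootstrap"),
                            schema = NULL, bootstrap_R = 1000L, seed = 1L,
                            out_dir = tempfile("telometa_run_")) {
  allowed <- c("intercept_only", "moderated", "interaction", "transformed",
               "trimmed", "species_forest", "egger", "egger_by_method",
               "time_lag", "bootstrap")
  bad <- setdiff(models, allowed)
  if (length(bad) > 0L) stop("unknown model stage(s): ",
                             paste(bad, collapse = ", "))
  if (length(models) == 0L) stop("at least one model stage must be requested")
  structure(list(csv = csv, newick = newick, models = models, schema = schema,
                 bootstrap_R = as.integer(bootstrap_R),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "analysis_config")
}

#' Read an analysis configuration from YAML
#' @param path YAML file with fields matching [analysis_config()].
#' @return An `"analysis_config"`.
#' @export
read_analysis_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(analysis_config, y)
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in order, writing a Table-1-style variance
#' component report (components, proportions, I-squared, LRT p-values,
#' bootstrap CIs when run), a Table-2-style moderator report, bias-test
#' JSONs, funnel TSV, species forest TSV and a run log with record counts
#' at every filter step. All numbers are kept at full precision in the
#' returned bundle; tables are printed at 3 decimals.
#'
#' @param config An [analysis_config()].
#' @param opts Optimizer settings.
#' @return Invisibly, a named list of stage results (the "report bundle").
#' @export
run_analysis <- function(config, opts = reml_opts()) {
  stopifnot(inherits(config, "analysis_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run_log.txt")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)
  logf("telometa run | seed %d | %s", config$seed,
       format(Sys.time(), "%Y-%m-%d %H:%M:%S"))

  stage <- "ingest"
  bundle <- list()
  result <- tryCatch({
    parsed <- parse_effect_table(config$csv, config$schema)
    records <- parsed$records
    logf("ingest: %d records retained, %d rejected", nrow(records),
         nrow(parsed$rejected))
    if (nrow(parsed$rejected) > 0L) {
      write_rejection_report(parsed$rejected,
                             file.path(config$out_dir, "rejected.tsv"))
    }
    tree <- grafen_lengths(parse_newick(config$newick))
    A <- phylo_correlation(tree)
    check_species_coverage(records, A)
    logf("phylogeny: %d tips, correlation matrix %dx%d",
         length(tree$tip.label), nrow(A), ncol(A))
    bundle$records <- records
    bundle$A <- A

    if ("intercept_only" %in% config$models) {
      stage <- "intercept_only"
      spec0 <- build_model(records, A = A)
      fit0 <- fit_reml(spec0, opts)
      het <- heterogeneity(fit0)
      lrt <- lrt_all_random_effects(fit0, opts)
      tab1 <- data.frame(
        component = c(names(fit0$sigma2), "sampling_error"),
        estimate = c(unname(fit0$sigma2), het$sigma_m2),
        proportion = unname(het$proportions),
        logLik_reduced = c(lrt$logLik_reduced, NA),
        lrt_p = c(lrt$p, NA)
      )
      utils::write.table(format(tab1, digits = 3),
                         file.path(config$out_dir, "table1.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      logf("intercept_only: mean %.3f, I2 %.3f", fit0$beta[["(intercept)"]],
           het$I2)
      bundle$intercept_only <- list(fit = fit0, heterogeneity = het,
                                    lrt = lrt, table = tab1)
      if ("bootstrap" %in% config$models) {
        stage <- "bootstrap"
        bt <- bootstrap_components(spec0, R = config$bootstrap_R,
                                   seed = config$seed)
        write_bootstrap_tsv(bt, file.path(config$out_dir,
                                          "bootstrap_replicates.tsv"))
        logf("bootstrap: R = %d, %d failures", bt$R, bt$failures)
        bundle$bootstrap <- bt
      }
    }

    if ("interaction" %in% config$models) {
      stage <- "interaction"
      spec_int <- build_model(records, default_moderators(),
                              interaction = TRUE, A = A, drop_aliased = TRUE)
      bundle$interaction <- fit_reml(spec_int, opts)
      logf("interaction: %d fixed-effect columns", ncol(spec_int$X))
    }

    if ("moderated" %in% config$models) {
      stage <- "moderated"
      spec_m <- build_model(records, default_moderators(), A = A)
      fit_m <- fit_reml(spec_m, opts)
      tab2 <- wald_tests(fit_m)
      utils::write.table(format(tab2, digits = 3),
                         file.path(config$out_dir, "table2.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      logf("moderated: %d coefficients", nrow(tab2))
      bundle$moderated <- list(fit = fit_m, table = tab2)

      stage <- "funnel"
      fd <- funnel_data(fit_m)
      fd$laboratory_method <- records$laboratory_method
      utils::write.table(fd, file.path(config$out_dir, "funnel.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      bundle$funnel <- fd
    }

    if (any(c("transformed", "trimmed") %in% config$models)) {
      stage <- "trimming"
      tr <- apply_trimming(records)
      logf("trimming: %d in, %d removed, %d retained", nrow(records),
           nrow(tr$removed), nrow(tr$retained))
      bundle$trimming <- tr
      if ("transformed" %in% config$models) {
        stage <- "transformed"
        fz <- fisher_z_transform(records)
        spec_t <- build_model(fz$transformed, default_moderators(), A = A,
                              response = "z")
        bundle$transformed <- list(fit = fit_reml(spec_t, opts),
                                   excluded = fz$excluded)
        logf("transformed: %d records on the z scale", nrow(fz$transformed))
      }
      if ("trimmed" %in% config$models) {
        stage <- "trimmed"
        spec_tr <- build_model(tr$retained, default_moderators(), A = A)
        bundle$trimmed <- list(fit = fit_reml(spec_tr, opts),
                               removed = tr$removed)
      }
    }

    if ("species_forest" %in% config$models) {
      stage <- "species_forest"
      sf <- species_forest(records, opts = opts)
      utils::write.table(format(sf, digits = 4),
                         file.path(config$out_dir, "species_forest.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      logf("species_forest: %d species", nrow(sf))
      bundle$species_forest <- sf
    }

    if ("egger" %in% config$models) {
      stage <- "egger"
      eg <- egger_test(records, "all", opts = opts)
      write_bias_json(eg, file.path(config$out_dir, "egger_all.json"))
      logf("egger: slope %.4f (p %.3f)", eg$slope, eg$p)
      bundle$egger <- eg
    }
    if ("egger_by_method" %in% config$models) {
      stage <- "egger_by_method"
      bundle$egger_by_method <- lapply(c(TRF = "TRF", qPCR = "qPCR"),
        function(ss) {
          r <- egger_test(records, ss, opts = opts)
          write_bias_json(r, file.path(config$out_dir,
                                       paste0("egger_", ss, ".json")))
          r
        })
    }
    if ("time_lag" %in% config$models) {
      stage <- "time_lag"
      tl <- time_lag_test(records, opts = opts)
      write_bias_json(tl, file.path(config$out_dir, "time_lag.json"))
      logf("time_lag: slope %.4f (p %.3f)", tl$slope, tl$p)
      bundle$time_lag <- tl
    }
    bundle
  }, error = function(e) {
    logf("ERROR in stage %s: %s", stage, conditionMessage(e))
    stop("pipeline failed in stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}

#' Species-specific mean heritabilities (forest-plot data)
#'
#' For each species, fits an intercept-only model to that species' records
#' with study and estimate random terms only (phylogeny and species terms
#' are meaningless within one species) and returns the mean with its Wald
#' 95% CI. A species with a single record degenerates to that estimate
#' `+/- 1.96 se` and is flagged.
#'
#' @param records Validated effect-size table.
#' @param species_list Species to fit (default: all present).
#' @param opts Optimizer settings.
#' @return Data.frame: `species`, `n_records`, `estimate`, `ci_lower`,
#'   `ci_upper`, `flagged` (single-record passthrough).
#' @export
species_forest <- function(records, species_list = NULL, opts = reml_opts()) {
  records <- validate_effect_table(records)
  if (is.null(species_list)) species_list <- unique(records$species)
  absent <- setdiff(species_list, records$species)
  if (length(absent) > 0L) {
    stop("no records for species: ", paste(absent, collapse = ", "))
  }
  rows <- lapply(species_list, function(sp) {
    sub <- records[records$species == sp, , drop = FALSE]
    if (nrow(sub) == 1L) {
      return(data.frame(species = sp, n_records = 1L, estimate = sub$h2,
                        ci_lower = sub$h2 - 1.96 * sub$se,
                        ci_upper = sub$h2 + 1.96 * sub$se, flagged = TRUE,
                        stringsAsFactors = FALSE))
    }
    spec <- build_model(sub, random = c("study", "estimate"))
    fit <- fit_reml(spec, opts)
    wt <- wald_tests(fit)
    data.frame(species = sp, n_records = nrow(sub), estimate = wt$estimate,
               ci_lower = wt$ci_lower, ci_upper = wt$ci_upper,
               flagged = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Serialize a fit to JSON
#' @param fit An `"mlmeta_fit"`.
#' @param path Output path.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(
    list(sigma2 = as.list(fit$sigma2), beta = as.list(fit$beta),
         se = as.list(fit$se), logLik = fit$logLik, n = fit$spec$n),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
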