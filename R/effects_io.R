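# Canonical effect-size table schema ------------------------------------------

#' Canonical columns and factor levels of the effect-size table
#'
#' An effect-size table holds one row per heritability estimate: the estimate
#' value `h2` (dimensionless; may fall outside \[0, 1\]), its standard error
#' `se`, the derived `sampling_variance = se^2`, grouping labels
#' (`estimate_id`, `study_id`, `species`), sample size `n`,
#' `publication_year`, and six categorical moderators.
#'
#' @format A named list with elements `required` (character vector of column
#'   names) and `levels` (named list of allowed factor levels; the first level
#'   of each moderator is the reference level used in meta-regression design
#'   matrices).
#' @export
effect_schema <- function() {
  list(
    required = c(
      "estimate_id", "study_id", "species", "h2", "se",
      "n", "publication_year",
      "environmental_setting", "age_at_measurement", "laboratory_method",
      "statistical_method", "parental_sex", "repeated_measurement"
    ),
    levels = list(
      environmental_setting = c("artificial", "natural"),
      age_at_measurement    = c("adult", "mixed", "juvenile"),
      laboratory_method     = c("TRF_southern", "TRF_ingel", "qPCR", "other"),
      statistical_method    = c("correlation", "pedigree", "mixed_model",
                                "SNP", "twin"),
      parental_sex          = c("nonspecific", "fathers_only", "mothers_only"),
      repeated_measurement  = c("yes", "no")
    )
  )
}

#' Standard error from a 95% confidence interval upper limit
#'
#' Recovers a missing standard error from the upper 95% confidence limit as
#' `(ci_upper - estimate) / 1.96`. Only the upper limit is used; the two
#' half-widths are never averaged.
#'
#' @param estimate Numeric vector of point estimates.
#' @param ci_upper Numeric vector of upper 95% confidence limits; must be
#'   `>= estimate` elementwise.
#' @return Numeric vector of standard errors.
#' @examples
#' se_from_ci(0.449, 0.647) # ~0.101
#' @export
se_from_ci <- function(estimate, ci_upper) {
  stopifnot(is.numeric(estimate), is.numeric(ci_upper))
  bad <- !is.na(estimate) & !is.na(ci_upper) & ci_upper < estimate
  if (any(bad)) {
    stop("malformed interval: ci_upper < estimate at position(s) ",
         paste(which(bad), collapse = ", "))
  }
  (ci_upper - estimate) / 1.96
}

#' Heritability from a parent-offspring regression slope
#'
#' Mid-parent regressions give heritability as the slope; single-parent
#' (sex-specific) regressions as twice the slope. Negative slopes yield
#' negative heritabilities, which are retained.
#'
#' @param slope Numeric vector of regression slopes.
#' @param parent_type `"midparent"` or `"single_parent"` (recycled).
#' @return Numeric vector of heritability values.
#' @export
h2_from_regression <- function(slope, parent_type) {
  stopifnot(is.numeric(slope))
  parent_type <- rep_len(as.character(parent_type), length(slope))
  ok <- parent_type %in% c("midparent", "single_parent")
  if (!all(ok)) {
    stop("unknown parent_type: ",
         paste(unique(parent_type[!ok]), collapse = ", "))
  }
  ifelse(parent_type == "midparent", slope, 2 * slope)
}

# Parsing and validation ------------------------------------------------------

#' Read and validate an effect-size table
#'
#' Reads a CSV of heritability estimates, optionally renaming columns through
#' `schema`, validates every row, computes `sampling_variance = se^2`, and
#' fills missing standard errors from 95% CI upper limits when `ci_upper` is
#' available. Rows that fail validation are not dropped silently: they are
#' returned in a rejection report with one reason per row.
#'
#' @param path Path to a CSV file, or a `data.frame` already in memory.
#' @param schema Optional named character vector mapping canonical column
#'   names to the file's column names, e.g. `c(h2 = "heritability")`.
#' @return A list of class `"effect_table_read"` with elements `records`
#'   (validated data.frame) and `rejected` (data.frame with `estimate_id`,
#'   `reason`).
#' @export
parse_effect_table <- function(path, schema = NULL) {
  df <- if (is.data.frame(path)) {
    path
  } else {
    if (!file.exists(path)) stop("file not found: ", path)
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      src <- schema[[canon]]
      if (!src %in% names(df)) {
        stop("schema error: mapped column '", src, "' (for '", canon,
             "') not present in file")
      }
      names(df)[names(df) == src] <- canon
    }
  }
  sch <- effect_schema()
  required_now <- setdiff(sch$required, "se") # se may be recoverable from CI
  missing_cols <- setdiff(required_now, names(df))
  if (length(missing_cols) > 0L) {
    stop("schema error: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!"se" %in% names(df)) df$se <- NA_real_
  if (anyDuplicated(df$estimate_id)) {
    stop("duplicate estimate_id: ",
         paste(unique(df$estimate_id[duplicated(df$estimate_id)]),
               collapse = ", "))
  }

  df$h2 <- suppressWarnings(as.numeric(df$h2))
  df$se <- suppressWarnings(as.numeric(df$se))
  has_ci <- "ci_upper" %in% names(df)
  if (has_ci) df$ci_upper <- suppressWarnings(as.numeric(df$ci_upper))

  reasons <- character(nrow(df))
  for (i in seq_len(nrow(df))) {
    if (is.na(df$h2[i])) {
      reasons[i] <- "non-numeric h2"
      next
    }
    if (is.na(df$se[i]) && has_ci && !is.na(df$ci_upper[i])) {
      if (df$ci_upper[i] < df$h2[i]) {
        reasons[i] <- "malformed interval"
        next
      }
      df$se[i] <- se_from_ci(df$h2[i], df$ci_upper[i])
    }
    if (is.na(df$se[i])) {
      reasons[i] <- "no SE or CI"
      next
    }
    if (df$se[i] <= 0) {
      reasons[i] <- "non-positive SE"
      next
    }
    for (mod in names(sch$levels)) {
      val <- as.character(df[[mod]][i])
      if (is.na(val) || !val %in% sch$levels[[mod]]) {
        reasons[i] <- paste0("invalid or missing ", mod)
        break
      }
    }
  }

  keep <- reasons == ""
  records <- df[keep, , drop = FALSE]
  records$sampling_variance <- records$se^2
  records$n <- suppressWarnings(as.integer(records$n))
  records$publication_year <- suppressWarnings(
    as.integer(records$publication_year))
  rownames(records) <- NULL
  rejected <- data.frame(
    estimate_id = as.character(df$estimate_id[!keep]),
    reason = reasons[!keep],
    stringsAsFactors = FALSE
  )
  structure(list(records = records, rejected = rejected),
            class = "effect_table_read")
}

#' Validate an in-memory effect-size table
#'
#' Checks the invariants of the canonical schema: required columns present,
#' positive standard errors, `sampling_variance == se^2`, unique estimate
#' IDs, and enumerated moderator levels. Errors on the first violation.
#'
#' @param records A data.frame of effect-size records.
#' @return `records`, invisibly, with `sampling_variance` filled if absent.
#' @export
validate_effect_table <- function(records) {
  sch <- effect_schema()
  missing_cols <- setdiff(sch$required, names(records))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(records$estimate_id)) stop("duplicate estimate_id")
  if (any(!is.finite(records$se)) || any(records$se <= 0)) {
    stop("all retained records must have finite se > 0")
  }
  if (!"sampling_variance" %in% names(records)) {
    records$sampling_variance <- records$se^2
  } else if (any(abs(records$sampling_variance - records$se^2) >
                 1e-12 * pmax(1, records$se^2))) {
    stop("sampling_variance must equal se^2")
  }
  for (mod in names(sch$levels)) {
    bad <- !as.character(records[[mod]]) %in% sch$levels[[mod]]
    if (any(bad)) {
      stop("invalid level(s) in ", mod, ": ",
           paste(unique(records[[mod]][bad]), collapse = ", "))
    }
  }
  invisible(records)
}

# Fisher-z sensitivity transform ----------------------------------------------

#' Default Fisher-z sampling-variance rule
#'
#' The standard large-sample variance of Fisher's z, `1 / (n - 3)`. Kept as a
#' separate function so an alternative rule can be supplied to
#' [fisher_z_transform()].
#'
#' @param n Sample sizes.
#' @return Sampling variances of z.
#' @export
fisher_z_var <- function(n) 1 / (n - 3)

#' Fisher-z transform of heritability estimates
#'
#' Computes `z = arctanh(h2)` with sampling variance from `var_rule`
#' (default `1/(n-3)`). Records with `|h2| >= 1` (undefined after
#' transformation), missing `n`, or `n <= 3` are excluded with a recorded
#' reason rather than transformed.
#'
#' @param records Validated effect-size table.
#' @param var_rule Function of `n` returning the sampling variance of z.
#' @return List with `transformed` (records plus columns `z`, `var_z`) and
#'   `excluded` (data.frame `estimate_id`, `reason`).
#' @export
fisher_z_transform <- function(records, var_rule = fisher_z_var) {
  records <- validate_effect_table(records)
  reason <- character(nrow(records))
  reason[abs(records$h2) >= 1] <- "h2 outside (-1, 1): undefined after transformation"
  reason[reason == "" & is.na(records$n)] <- "missing sample size"
  reason[reason == "" & records$n <= 3] <- "variance undefined (n <= 3)"
  keep <- reason == ""
  transformed <- records[keep, , drop = FALSE]
  transformed$z <- atanh(transformed$h2)
  transformed$var_z <- var_rule(transformed$n)
  rownames(transformed) <- NULL
  list(
    transformed = transformed,
    excluded = data.frame(
      estimate_id = as.character(records$estimate_id[!keep]),
      reason = reason[!keep],
      stringsAsFactors = FALSE
    )
  )
}

#' Trim records that cannot be Fisher-z transformed
#'
#' Removes exactly the records failing the Fisher-z preconditions
#' (`|h2| >= 1`, missing `n`, or `n <= 3`). The retained set feeds both the
#' transformed sensitivity model (on z) and the trimmed sensitivity model
#' (untransformed h2 on the same subset).
#'
#' @param records Validated effect-size table.
#' @return List with `retained` and `removed` (the latter carrying a
#'   `reason` column).
#' @export
apply_trimming <- function(records) {
  records <- validate_effect_table(records)
  fz <- fisher_z_transform(records)
  removed <- records[records$estimate_id %in% fz$excluded$estimate_id, ,
                     drop = FALSE]
  removed$reason <- fz$excluded$reason[
    match(removed$estimate_id, fz$excluded$estimate_id)]
  retained <- records[!records$estimate_id %in% fz$excluded$estimate_id, ,
                      drop = FALSE]
  rownames(retained) <- rownames(removed) <- NULL
  list(retained = retained, removed = removed)
}

# Serialization ----------------------------------------------------------------

#' Write an effect-size table to CSV
#' @param records Effect-size table.
#' @param path Output path.
#' @export
write_effect_table <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a rejection report to TSV
#' @param rejected Data.frame with `estimate_id` and `reason`.
#' @param path Output path.
#' @export
write_rejection_report <- function(rejected, path) {
  utils::write.table(rejected, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
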