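# Model specification for the multilevel meta-analytic model
#
#   y_i = x_i' beta + u_{study(i)} + a_{species(i)} + s_{species(i)} + e_i + m_i
#
# with u ~ N(0, sigma_u^2 I) over studies, a ~ N(0, sigma_a^2 A) over species
# (A the phylogenetic correlation matrix), s ~ N(0, sigma_s^2 I) over species,
# e ~ N(0, sigma_e^2 I) over estimates, and m_i ~ N(0, v_i) the known
# heteroscedastic sampling errors. Marginally
#   V = sigma_u^2 K_u + sigma_a^2 K_a + sigma_s^2 K_s + sigma_e^2 I + diag(v)
# where each K is the n x n kernel induced by the grouping.

RANDOM_TERMS <- c("study", "phylogeny", "species", "estimate")

#' Low-level model specification constructor
#'
#' Assembles the response, known sampling variances, fixed-effect design and
#' random-effect kernels into a fittable specification. Most users should
#' call [build_model()]; this constructor is the entry point for
#' non-standard designs (e.g. the Egger regression's sampling-variance
#' covariate).
#'
#' @param y Numeric response vector (heritability or Fisher-z values).
#' @param v Known sampling variances, all positive, same length as `y`.
#' @param X Fixed-effect design matrix with column names; full column rank.
#' @param study Factor/character of study IDs per record.
#' @param species Factor/character of species per record.
#' @param random Character subset of
#'   `c("study", "phylogeny", "species", "estimate")`.
#' @param A Phylogenetic correlation matrix (required iff `"phylogeny"` is in
#'   `random`), dimnames covering every species present.
#' @param estimate_id Optional record labels, carried into outputs.
#' @return An object of class `"mlmeta_spec"`.
#' @export
model_spec <- function(y, v, X, study, species,
                       random = RANDOM_TERMS, A = NULL,
                       estimate_id = NULL) {
  n <- length(y)
  stopifnot(is.numeric(y), is.numeric(v), length(v) == n,
            is.matrix(X), nrow(X) == n)
  if (any(!is.finite(v)) || any(v <= 0)) stop("all sampling variances must be > 0")
  if (any(!is.finite(y))) stop("non-finite response values")
  random <- match.arg(random, RANDOM_TERMS, several.ok = TRUE)
  study <- as.character(study)
  species <- as.character(species)
  stopifnot(length(study) == n, length(species) == n)

  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("fixed-effect design is rank deficient; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }

  indicator <- function(g) {
    # works for single-level groupings, unlike model.matrix contrasts
    vapply(unique(g), function(l) as.numeric(g == l), numeric(length(g)))
  }
  K <- list()
  if ("study" %in% random) {
    K$study <- tcrossprod(indicator(study))
  }
  if ("phylogeny" %in% random) {
    if (is.null(A)) stop("the phylogeny term requires a correlation matrix A")
    missing_sp <- setdiff(unique(species), rownames(A))
    if (length(missing_sp) > 0L) {
      stop("species missing from A: ", paste(missing_sp, collapse = ", "))
    }
    K$phylogeny <- A[species, species, drop = FALSE]
    dimnames(K$phylogeny) <- NULL
  }
  if ("species" %in% random) {
    K$species <- tcrossprod(indicator(species))
  }
  if ("estimate" %in% random) {
    K$estimate <- diag(n)
  }

  structure(list(
    y = as.numeric(y), v = as.numeric(v), X = X,
    study = study, species = species,
    random = random, K = K, A = A,
    estimate_id = if (is.null(estimate_id)) paste0("rec", seq_len(n))
                  else as.character(estimate_id),
    n = n, p = ncol(X)
  ), class = "mlmeta_spec")
}

#' Build the meta-analytic model specification from an effect-size table
#'
#' Constructs the intercept-only model or a moderator meta-regression with
#' treatment (dummy) coding against fixed reference levels: environmental
#' setting (artificial), age at measurement (adult), laboratory method (TRF
#' Southern blot), statistical method (correlation-based) and repeated
#' measurement (yes). Optionally adds parental sex specificity interacting
#' with statistical method.
#'
#' @param records Validated effect-size table.
#' @param moderators Character vector of moderator columns to include as
#'   fixed effects, or `NULL` for the intercept-only model. Use
#'   [default_moderators()] for the standard five.
#' @param interaction If `TRUE`, add `parental_sex` and its interaction with
#'   `statistical_method`.
#' @param random Random terms to include (default all four).
#' @param A Phylogenetic correlation matrix (needed for the phylogeny term).
#' @param response `"h2"` (with `sampling_variance`) or `"z"` (with `var_z`,
#'   from [fisher_z_transform()]).
#' @param reference_levels Named list overriding the default reference level
#'   per factor.
#' @param drop_aliased If `TRUE`, columns made collinear by empty or
#'   confounded moderator cells (typically sparse interaction contrasts) are
#'   dropped with a message instead of raising the rank-deficiency error.
#' @return An `"mlmeta_spec"` object.
#' @export
build_model <- function(records, moderators = NULL, interaction = FALSE,
                        random = RANDOM_TERMS, A = NULL,
                        response = c("h2", "z"),
                        reference_levels = NULL, drop_aliased = FALSE) {
  records <- validate_effect_table(records)
  response <- match.arg(response)
  if (response == "z") {
    if (!all(c("z", "var_z") %in% names(records))) {
      stop("response 'z' requires columns z and var_z; run fisher_z_transform()")
    }
    y <- records$z; v <- records$var_z
  } else {
    y <- records$h2; v <- records$sampling_variance
  }

  sch <- effect_schema()
  refs <- sch$levels # first level of each = reference
  if (!is.null(reference_levels)) {
    for (f in names(reference_levels)) {
      refs[[f]] <- union(reference_levels[[f]], refs[[f]])
    }
  }

  dat <- records
  for (f in names(refs)) {
    if (f %in% names(dat)) dat[[f]] <- factor(dat[[f]], levels = refs[[f]])
  }

  if (is.null(moderators) && !interaction) {
    X <- matrix(1, nrow(records), 1, dimnames = list(NULL, "(intercept)"))
  } else {
    terms <- moderators
    if (interaction) {
      terms <- union(terms, c("parental_sex",
                              "parental_sex:statistical_method"))
      if (!"statistical_method" %in% terms) {
        terms <- union(terms, "statistical_method")
      }
    }
    for (f in setdiff(terms, grep(":", terms, value = TRUE))) {
      observed <- unique(as.character(records[[f]]))
      if (length(observed) < 2L) {
        stop("moderator '", f, "' has a single observed level ('",
             observed, "'); design would be rank deficient")
      }
      missing_ref <- setdiff(levels(dat[[f]])[1L], observed)
      if (length(missing_ref) > 0L) {
        stop("reference level '", missing_ref, "' of '", f,
             "' is absent from the data")
      }
    }
    fml <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
    X <- stats::model.matrix(fml, data = dat)
    colnames(X)[colnames(X) == "(Intercept)"] <- "(intercept)"
    if (drop_aliased) {
      qrX <- qr(X)
      if (qrX$rank < ncol(X)) {
        aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
        message("dropping aliased column(s): ", paste(aliased, collapse = ", "))
        X <- X[, setdiff(colnames(X), aliased), drop = FALSE]
      }
    }
  }

  model_spec(y = y, v = v, X = X,
             study = records$study_id, species = records$species,
             random = random, A = A, estimate_id = records$estimate_id)
}

#' The five standard moderators of the meta-regression
#' @return Character vector of column names.
#' @export
default_moderators <- function() {
  c("environmental_setting", "age_at_measurement", "laboratory_method",
    "statistical_method", "repeated_measurement")
}

#' Drop one random term from a specification
#'
#' Returns the same model with a single random term removed — the reduced
#' model of a likelihood-ratio test.
#'
#' @param spec An `"mlmeta_spec"`.
#' @param term One of the spec's random terms.
#' @return A reduced `"mlmeta_spec"`.
#' @export
drop_random_term <- function(spec, term) {
  stopifnot(inherits(spec, "mlmeta_spec"))
  term <- match.arg(term, spec$random)
  model_spec(y = spec$y, v = spec$v, X = spec$X,
             study = spec$study, species = spec$species,
             random = setdiff(spec$random, term), A = spec$A,
             estimate_id = spec$estimate_id)
}

# Subset a spec to rows idx, optionally relabelling studies (used by the
# cluster bootstrap, where resampled copies of a study must be independent).
respec_rows <- function(spec, idx, study = NULL) {
  model_spec(
    y = spec$y[idx], v = spec$v[idx],
    X = spec$X[idx, , drop = FALSE],
    study = if (is.null(study)) spec$study[idx] else study,
    species = spec$species[idx],
    random = spec$random, A = spec$A,
    estimate_id = spec$estimate_id[idx]
  )
}
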