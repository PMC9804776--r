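# Shared fixtures and an independent brute-force REML oracle.

# A small, fully valid effect-size table built in code.
make_records <- function(n = 12L, seed = 42L, n_studies = 4L,
                         species = c("sp_a", "sp_b", "sp_c")) {
  set.seed(seed)
  study <- sprintf("study%d", rep_len(seq_len(n_studies), n))
  sp <- rep_len(species, n)
  se <- round(runif(n, 0.05, 0.3), 3)
  data.frame(
    estimate_id = sprintf("est%02d", seq_len(n)),
    study_id = study,
    species = sp,
    h2 = round(rnorm(n, 0.45, 0.3), 3),
    se = se,
    sampling_variance = se^2,
    n = sample(20:500, n, replace = TRUE),
    publication_year = sample(2000:2020, n, replace = TRUE),
    environmental_setting = sample(c("artificial", "natural"), n, TRUE),
    age_at_measurement = sample(c("adult", "mixed", "juvenile"), n, TRUE),
    laboratory_method = sample(c("TRF_southern", "TRF_ingel", "qPCR", "other"),
                               n, TRUE),
    statistical_method = sample(c("correlation", "pedigree", "mixed_model",
                                  "SNP", "twin"), n, TRUE),
    parental_sex = sample(c("nonspecific", "fathers_only", "mothers_only"),
                          n, TRUE),
    repeated_measurement = sample(c("yes", "no"), n, TRUE),
    stringsAsFactors = FALSE
  )
}

# Independent restricted log-likelihood: direct determinant/solve route,
# no Cholesky reuse, no gradient — deliberately naive.
oracle_restricted_ll <- function(theta, y, v, X, K) {
  n <- length(y); p <- ncol(X)
  V <- diag(v, n)
  for (r in seq_along(K)) V <- V + theta[r] * K[[r]]
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  res <- y - X %*% beta
  quad <- drop(t(res) %*% Vi %*% res)
  -0.5 * (determinant(V, logarithm = TRUE)$modulus +
            determinant(XtViX, logarithm = TRUE)$modulus -
            determinant(t(X) %*% X, logarithm = TRUE)$modulus +
            quad + (n - p) * log(2 * pi))
}

# Brute-force REML: coarse grid over each component then two rounds of local
# refinement around the best grid point.
oracle_reml <- function(y, v, X, K) {
  nr <- length(K)
  stopifnot(nr <= 2L)
  upper <- 3 * stats::var(y)
  grid1 <- seq(0, upper, length.out = 41L)
  pts <- if (nr == 1L) matrix(grid1, ncol = 1) else
    as.matrix(expand.grid(grid1, grid1))
  ll <- apply(pts, 1, function(th) oracle_restricted_ll(th, y, v, X, K))
  best <- pts[which.max(ll), , drop = TRUE]
  width <- upper / 40
  for (round in 1:3) {
    lo <- pmax(0, best - width); hi <- best + width
    axes <- lapply(seq_len(nr), function(r) seq(lo[r], hi[r],
                                                length.out = 21L))
    pts <- as.matrix(expand.grid(axes))
    ll <- apply(pts, 1, function(th) oracle_restricted_ll(th, y, v, X, K))
    best <- pts[which.max(ll), , drop = TRUE]
    width <- width / 10
  }
  beta_at <- function(th) {
    V <- diag(v, length(y))
    for (r in seq_along(K)) V <- V + th[r] * K[[r]]
    Vi <- solve(V)
    drop(solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y))
  }
  list(theta = unname(best), beta = beta_at(best))
}
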