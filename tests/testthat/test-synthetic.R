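test_that("simulated trees are reproducible, ultrametric and correctly sized", {
  t1 <- simulate_tree(18, seed = 5)
  t2 <- simulate_tree(18, seed = 5)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_equal(length(t1$tip.label), 18L)
  expect_true(ape::is.ultrametric(t1, tol = 1e-9))
  expect_equal(length(simulate_tree(2, seed = 1)$tip.label), 2L)
  expect_error(simulate_tree(1), "at least 2")
})

test_that("the zero-variance limit returns the fixed part exactly", {
  cfg <- sim_config(sigma2 = c(study = 0, phylogeny = 0, species = 0,
                               estimate = 0),
                    v_range = c(1e-12, 1.0000001e-12),
                    beta = c("(intercept)" = 0.449), seed = 2)
  sim <- simulate_dataset(cfg)
  expect_equal(sim$records$h2, rep(0.449, 104), tolerance = 1e-5)
})

test_that("the same config yields the identical dataset; the schema validates", {
  cfg <- sim_config(seed = 8)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$records, s2$records)
  expect_silent(validate_effect_table(s1$records))
  expect_equal(nrow(s1$records), 104L)
  expect_equal(length(unique(s1$records$study_id)), 43L)
  expect_equal(length(unique(s1$records$species)), 18L)
  # truth record stores every latent parameter
  expect_named(s1$truth, c("beta", "sigma2", "u", "a", "s", "e", "v",
                           "config"))
  expect_equal(length(s1$truth$u), 43L)
})

test_that("generative moments match the analytic variance decomposition", {
  cfg <- sim_config(seed = 300)
  tree <- simulate_tree(18, seed = 300)
  B <- 400
  zs <- vapply(seq_len(B), function(b) {
    cfg_b <- cfg; cfg_b$seed <- 300L + b
    sim <- simulate_dataset(cfg_b, tree = tree)
    i <- 1L
    total <- sum(cfg$sigma2) + sim$truth$v[i]
    (sim$records$h2[i] - 0.449) / sqrt(total)
  }, numeric(1))
  # standardized draws should have unit variance; sampling band ~ 3 SE
  expect_lt(abs(mean(zs)), 3 / sqrt(B))
  expect_lt(abs(stats::var(zs) - 1), 3 * sqrt(2 / (B - 1)))
})

test_that("phylogenetic effects correlate more for closely related tips", {
  tree <- simulate_tree(10, seed = 77)
  A <- phylo_correlation(tree)
  off <- A; diag(off) <- NA
  hi <- which(off == max(off, na.rm = TRUE), arr.ind = TRUE)[1, ]
  lo <- which(off == min(off, na.rm = TRUE), arr.ind = TRUE)[1, ]
  cfg <- sim_config(n_species = 10, n_studies = 12, n_estimates = 24,
                    sigma2 = c(study = 0, phylogeny = 0.2, species = 0,
                               estimate = 0), seed = 1)
  a_mat <- t(vapply(1:200, function(b) {
    cfg_b <- cfg; cfg_b$seed <- 1000L + b
    simulate_dataset(cfg_b, tree = tree)$truth$a
  }, numeric(10)))
  cor_hi <- cor(a_mat[, hi[1]], a_mat[, hi[2]])
  cor_lo <- cor(a_mat[, lo[1]], a_mat[, lo[2]])
  expect_gt(cor_hi, cor_lo)
  expect_equal(cor_hi, max(off, na.rm = TRUE), tolerance = 0.25)
})

test_that("the censoring hook and missing-n injection reach the records", {
  cfg <- sim_config(prop_missing_n = 0.2, seed = 12,
                    censor_fn = function(rec) rec[rec$h2 > 0, , drop = FALSE])
  sim <- simulate_dataset(cfg)
  expect_true(anyNA(sim$records$n))
  expect_true(all(sim$records$h2 > 0))
})

test_that("config invariants are enforced", {
  expect_error(sim_config(n_estimates = 10, n_studies = 20), "n_estimates")
  expect_error(sim_config(sigma2 = c(study = -1, phylogeny = 0, species = 0,
                                     estimate = 0)), ">= 0")
  expect_error(sim_config(moderator_probs = list(
    environmental_setting = c(artificial = 0.5, natural = 0.1))), "sum to 1")
})

test_that("a zero-variance recovery experiment is unbiased for the mean", {
  cfg <- sim_config(n_studies = 10L, n_estimates = 30L,
                    sigma2 = c(study = 0, phylogeny = 0, species = 0,
                               estimate = 0),
                    v_range = c(1e-6, 2e-6), seed = 5)
  rec <- recovery_experiment(cfg, n_replicates = 10L)
  b0 <- rec$summary[rec$summary$parameter == "beta0", ]
  expect_lt(abs(b0$bias), 1e-2)
  expect_lt(b0$rmse, 1e-2)
})
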