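test_that("the design matrix follows the stated reference levels", {
  rec <- make_records(40, seed = 3)
  A <- diag(3)
  dimnames(A) <- list(unique(rec$species), unique(rec$species))
  spec0 <- build_model(rec, A = A)
  expect_equal(ncol(spec0$X), 1L)
  expect_true(all(spec0$X == 1))
  expect_equal(length(spec0$K), 4L)

  spec <- build_model(rec, default_moderators(), A = A)
  # 1 intercept + 1 + 2 + 3 + 4 + 1 non-reference columns
  expect_equal(ncol(spec$X), 12L)
  expect_false(any(grepl("artificial|adult|TRF_southern|correlation|yes$",
                         colnames(spec$X))))

  rec1 <- rec
  rec1$environmental_setting <- "natural"
  expect_error(build_model(rec1, default_moderators(), A = A),
               "single observed level")
})

test_that("the interaction adds parental sex by statistical method columns", {
  rec <- make_records(80, seed = 9)
  spec <- build_model(rec, default_moderators(), interaction = TRUE,
                      random = c("study", "species", "estimate"))
  expect_true(any(grepl("parental_sex.*:", colnames(spec$X))) ||
                any(grepl(":.*parental_sex", colnames(spec$X))))
  expect_gt(ncol(spec$X), 12L)
})

test_that("two-record REML hits the closed form exactly", {
  spec <- model_spec(y = c(0.4, 0.6), v = c(0.01, 0.01),
                     X = matrix(1, 2, 1, dimnames = list(NULL, "(intercept)")),
                     study = c("s1", "s2"), species = c("a", "b"),
                     random = "estimate")
  fit <- fit_reml(spec)
  expect_equal(unname(fit$beta), 0.5, tolerance = 1e-8)
  # tau^2 = (y1 - y2)^2 / 2 - v
  expect_equal(unname(fit$sigma2), 0.2^2 / 2 - 0.01, tolerance = 1e-6)
})

test_that("identical responses give zero components and the common value", {
  spec <- model_spec(y = rep(0.3, 6), v = rep(0.02, 6),
                     X = matrix(1, 6, 1, dimnames = list(NULL, "(intercept)")),
                     study = rep(c("s1", "s2"), 3),
                     species = rep("sp", 6),
                     random = c("study", "estimate"))
  fit <- fit_reml(spec)
  expect_equal(unname(fit$sigma2), c(0, 0))
  expect_equal(unname(fit$beta), 0.3, tolerance = 1e-10)
})

test_that("REML matches an independent multilevel meta-analysis implementation", {
  sim <- simulate_dataset(sim_config(seed = 7))
  spec <- build_model(sim$records, A = sim$A)
  fit <- fit_reml(spec)

  d <- sim$records
  d$sp_phylo <- d$species
  m <- metafor::rma.mv(h2, sampling_variance,
                       random = list(~1 | study_id, ~1 | sp_phylo,
                                     ~1 | species, ~1 | estimate_id),
                       R = list(sp_phylo = sim$A), data = d, method = "REML")
  expect_equal(unname(fit$sigma2), m$sigma2, tolerance = 1e-5)
  expect_equal(unname(fit$beta), unname(coef(m)), tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(m$se), tolerance = 1e-6)
  expect_equal(fit$logLik, as.numeric(logLik(m)), tolerance = 1e-5)
})

test_that("a phylogeny term with identity correlation equals a species term", {
  rec <- make_records(30, seed = 5, n_studies = 8,
                      species = c("sp_a", "sp_b", "sp_c", "sp_d"))
  I4 <- diag(4)
  dimnames(I4) <- list(unique(rec$species), unique(rec$species))
  f_phylo <- fit_reml(build_model(rec, random = c("study", "phylogeny",
                                                  "estimate"), A = I4))
  f_species <- fit_reml(build_model(rec, random = c("study", "species",
                                                    "estimate")))
  expect_equal(unname(f_phylo$sigma2), unname(f_species$sigma2),
               tolerance = 1e-6)
  expect_equal(f_phylo$logLik, f_species$logLik, tolerance = 1e-8)
})

test_that("location shifts move the intercept; scaling scales components", {
  rec <- make_records(40, seed = 13, n_studies = 10)
  spec <- build_model(rec, random = c("study", "estimate"))
  fit <- fit_reml(spec)

  rec_shift <- rec
  rec_shift$h2 <- rec$h2 + 0.7
  fit_shift <- fit_reml(build_model(rec_shift, random = c("study", "estimate")))
  expect_equal(unname(fit_shift$beta), unname(fit$beta) + 0.7,
               tolerance = 1e-6)
  expect_equal(fit_shift$sigma2, fit$sigma2, tolerance = 1e-6)

  cc <- 2.5
  rec_scale <- rec
  rec_scale$h2 <- rec$h2 * cc
  rec_scale$se <- rec$se * cc
  rec_scale$sampling_variance <- rec_scale$se^2
  fit_scale <- fit_reml(build_model(rec_scale, random = c("study", "estimate")))
  expect_equal(fit_scale$sigma2, fit$sigma2 * cc^2, tolerance = 1e-5)
  expect_equal(unname(fit_scale$beta), unname(fit$beta) * cc,
               tolerance = 1e-6)
})

test_that("typical sampling-error variance matches the weight-based formula", {
  expect_equal(typical_sampling_variance(rep(0.01, 4)), 0.01)
  expect_equal(typical_sampling_variance(c(0.01, 0.04)), 0.025) # hand value
  expect_equal(typical_sampling_variance(rep(0.37, 9)), 0.37)
  expect_error(typical_sampling_variance(0.01), "at least 2")
  expect_error(typical_sampling_variance(c(0.01, -0.1)), "> 0")
})

test_that("heterogeneity decomposition follows the variance-proportion identity", {
  fake <- structure(list(
    sigma2 = c(study = 0.6, phylogeny = 0.2, species = 0.1, estimate = 0.05),
    spec = list(v = c(0.05, 0.05))), class = "mlmeta_fit")
  het <- heterogeneity(fake, sigma_m2 = 0.05)
  expect_equal(het$I2, 0.95)
  expect_equal(unname(het$proportions),
               c(0.6, 0.2, 0.1, 0.05, 0.05) / 1)
  expect_equal(sum(het$proportions), 1, tolerance = 1e-10)

  fake0 <- structure(list(sigma2 = c(study = 0, estimate = 0),
                          spec = list(v = c(0.1, 0.1))),
                     class = "mlmeta_fit")
  expect_equal(heterogeneity(fake0)$I2, 0)
  fake_bad <- structure(list(sigma2 = c(study = 0), spec = list(v = 0.1)),
                        class = "mlmeta_fit")
  expect_error(heterogeneity(fake_bad, sigma_m2 = 0), "undefined")
})

test_that("Wald tests reproduce normal-theory z, p and CI", {
  fake <- structure(list(
    beta = c(a = 0.390, b = 0, c = 1.96 * 0.1),
    se = c(a = 0.182, b = 0.2, c = 0.1),
    spec = list()), class = "mlmeta_fit")
  wt <- wald_tests(fake)
  expect_equal(wt$z[1], 2.1428571, tolerance = 1e-6)
  expect_lt(abs(wt$p[1] - 0.032), 1e-3)
  expect_lt(abs(wt$ci_lower[1] - 0.033), 2e-3)
  expect_lt(abs(wt$ci_upper[1] - 0.747), 2e-3)
  expect_equal(wt$z[2], 0)
  expect_equal(wt$p[2], 1)
  expect_lt(abs(wt$p[3] - 0.05), 1e-4)
})

test_that("likelihood-ratio tests separate real from null random effects", {
  cfg <- sim_config(n_studies = 30L, n_estimates = 90L,
                    sigma2 = c(study = 0.2, phylogeny = 0, species = 0,
                               estimate = 0.002),
                    seed = 21L)
  sim <- simulate_dataset(cfg)
  spec <- build_model(sim$records, random = c("study", "species", "estimate"))
  full <- fit_reml(spec)

  red_study <- fit_reml(drop_random_term(spec, "study"))
  lr1 <- lrt_random_effect(full, red_study)
  expect_gt(lr1$statistic, 3.84)
  expect_lt(lr1$p, 0.05)

  red_sp <- fit_reml(drop_random_term(spec, "species"))
  lr2 <- lrt_random_effect(full, red_sp)
  expect_lt(lr2$statistic, 0.2)
  expect_gt(lr2$p, 0.5)
  # boundary mixture halves the non-zero p
  lr2m <- lrt_random_effect(full, red_sp, boundary_mixture = TRUE)
  if (lr2$statistic > 0) expect_equal(lr2m$p, lr2$p / 2)

  expect_error(lrt_random_effect(full, full), "exactly one")
  tab <- lrt_all_random_effects(full)
  expect_equal(tab$term, c("study", "species", "estimate"))
  expect_true(all(tab$p >= 0 & tab$p <= 1))
})
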