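test_that("standard errors are recovered from the CI upper limit", {
  # hand arithmetic: (0.647 - 0.449) / 1.96
  expect_equal(se_from_ci(0.449, 0.647), 0.198 / 1.96, tolerance = 1e-12)
  expect_equal(se_from_ci(0.5, 0.5), 0)
  expect_equal(se_from_ci(0, 1.96), 1)
  expect_error(se_from_ci(0.5, 0.4), "malformed interval")
})

test_that("CI round trip reconstructs the upper limit to machine precision", {
  set.seed(1)
  est <- rnorm(50); upper <- est + abs(rnorm(50))
  se <- se_from_ci(est, upper)
  expect_equal(est + 1.96 * se, upper, tolerance = 1e-14)
})

test_that("regression slopes convert to heritability by parent type", {
  expect_equal(h2_from_regression(0.3, "midparent"), 0.3)
  expect_equal(h2_from_regression(0.3, "single_parent"), 0.6)
  expect_equal(h2_from_regression(-0.078, "single_parent"), -0.156)
  expect_equal(h2_from_regression(c(0.2, 0.2), c("midparent", "single_parent")),
               c(0.2, 0.4))
  expect_error(h2_from_regression(0.3, "grandparent"), "unknown parent_type")
})

test_that("a well-formed table parses with an empty rejection report", {
  rec <- make_records(3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_effect_table(rec, path)
  out <- parse_effect_table(path)
  expect_equal(nrow(out$records), 3L)
  expect_equal(nrow(out$rejected), 0L)
  expect_equal(out$records$sampling_variance, out$records$se^2)
})

test_that("parse -> serialize -> parse is lossless", {
  rec <- make_records(8)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_effect_table(rec, p1)
  r1 <- parse_effect_table(p1)$records
  write_effect_table(r1, p2)
  r2 <- parse_effect_table(p2)$records
  expect_equal(r1, r2)
})

test_that("rows without SE or CI are rejected with a reason, not dropped silently", {
  rec <- make_records(4)
  rec$se[2] <- NA
  out <- parse_effect_table(rec)
  expect_equal(nrow(out$records), 3L)
  expect_equal(out$rejected$estimate_id, "est02")
  expect_equal(out$rejected$reason, "no SE or CI")

  # with a CI column the same row is recoverable
  rec$ci_upper <- rec$h2 + 1.96 * 0.12
  out2 <- parse_effect_table(rec)
  expect_equal(nrow(out2$records), 4L)
  expect_equal(out2$records$se[out2$records$estimate_id == "est02"], 0.12,
               tolerance = 1e-12)
  # explicit SE wins over CI elsewhere
  expect_equal(out2$records$se[out2$records$estimate_id == "est01"],
               rec$se[1])
})

test_that("schema mapping, duplicate IDs and bad values are handled", {
  rec <- make_records(3)
  names(rec)[names(rec) == "h2"] <- "heritability"
  out <- parse_effect_table(rec, schema = c(h2 = "heritability"))
  expect_equal(nrow(out$records), 3L)
  expect_error(parse_effect_table(rec, schema = c(h2 = "nope")),
               "schema error")
  rec2 <- make_records(3)
  rec2$estimate_id[2] <- rec2$estimate_id[1]
  expect_error(parse_effect_table(rec2), "duplicate estimate_id")
  rec3 <- make_records(3)
  rec3$h2 <- as.character(rec3$h2); rec3$h2[3] <- "high"
  out3 <- parse_effect_table(rec3)
  expect_equal(out3$rejected$reason, "non-numeric h2")
  rec4 <- make_records(3)
  rec4$laboratory_method[1] <- "flow_fish"
  out4 <- parse_effect_table(rec4)
  expect_match(out4$rejected$reason, "laboratory_method")
  rec5 <- make_records(3)[, setdiff(names(make_records(3)), "species")]
  expect_error(parse_effect_table(rec5), "species")
})

test_that("Fisher-z transform matches hand values and excludes by rule", {
  rec <- make_records(4)
  rec$h2 <- c(0, 0.5, 1.38, 0.3)
  rec$n <- c(50L, 28L, 100L, NA)
  fz <- fisher_z_transform(rec)
  expect_equal(fz$transformed$z, atanh(c(0, 0.5)), tolerance = 1e-12)
  expect_equal(fz$transformed$z[2], 0.5493061, tolerance = 1e-6)
  expect_equal(fz$transformed$var_z, c(1 / 47, 0.04), tolerance = 1e-12)
  expect_setequal(fz$excluded$estimate_id, c("est03", "est04"))
  expect_match(fz$excluded$reason[fz$excluded$estimate_id == "est03"],
               "outside")
  expect_match(fz$excluded$reason[fz$excluded$estimate_id == "est04"],
               "missing sample size")

  rec$n[1] <- 3L
  fz2 <- fisher_z_transform(rec)
  expect_match(fz2$excluded$reason[fz2$excluded$estimate_id == "est01"],
               "n <= 3")
})

test_that("Fisher-z is strictly monotone and inverts to h2", {
  h2 <- round(seq(-0.95, 0.95, by = 0.05), 2)
  rec <- make_records(length(h2))
  rec$h2 <- h2
  rec$n <- rep(50L, length(h2))
  z <- fisher_z_transform(rec)$transformed$z
  expect_true(all(diff(z) > 0))
  expect_equal(tanh(z), h2, tolerance = 1e-12)
  expect_equal(z[h2 == 0], 0)
})

test_that("trimming removes exactly the untransformable records and is idempotent", {
  rec <- make_records(10)
  rec$h2 <- pmin(pmax(rec$h2, -0.9), 0.9)
  tr0 <- apply_trimming(rec)
  expect_equal(nrow(tr0$removed), 0L)

  rec$h2[c(2, 5)] <- 1.2
  rec$n[7] <- NA
  tr <- apply_trimming(rec)
  expect_equal(nrow(tr$removed), 3L)
  expect_setequal(tr$removed$estimate_id, c("est02", "est05", "est07"))
  expect_true(all(nchar(tr$removed$reason) > 0))

  again <- apply_trimming(tr$retained)
  expect_equal(again$retained, tr$retained)
  expect_equal(nrow(again$removed), 0L)
})
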