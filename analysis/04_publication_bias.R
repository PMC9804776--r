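#!/usr/bin/env Rscript
# Publication-bias diagnostics: funnel data from the meta-regression
# residuals, the multilevel Egger regression (all records and the TRF / qPCR
# subsets), and the time-lag model with publication year. Writes
# results/funnel.tsv and results/bias_tests.tsv.

library(telometa)

records <- parse_effect_table("results/data/records.csv")$records
A <- phylo_correlation(grafen_lengths(parse_newick("results/data/tree.nwk")))

fit_mod <- fit_reml(build_model(records, default_moderators(), A = A))
fd <- funnel_data(fit_mod)
fd$laboratory_method <- records$laboratory_method
write.table(fd, "results/funnel.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)

tests <- list(
  egger_all = egger_test(records, "all"),
  egger_TRF = egger_test(records, "TRF"),
  egger_qPCR = egger_test(records, "qPCR"),
  time_lag = time_lag_test(records)
)
tab <- do.call(rbind, lapply(names(tests), function(nm) {
  x <- tests[[nm]]
  data.frame(test = nm, predictor = x$predictor, n = x$n,
             slope = round(x$slope, 3), se = round(x$slope_se, 3),
             z = round(x$z, 3), p = round(x$p, 3))
}))
write.table(tab, "results/bias_tests.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
print(tab, row.names = FALSE)
for (nm in names(tests)) {
  x <- tests[[nm]]
  verdict <- if (x$p < 0.05) "evidence of bias" else "no evidence of bias"
  cat(sprintf("%s: slope %.3f (p = %.3f) -> %s\n", nm, x$slope, x$p, verdict))
}
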