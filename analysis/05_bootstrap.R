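#!/usr/bin/env Rscript
# Percentile-bootstrap 95% confidence intervals for the four variance
# components, at both resampling units (records; whole studies). Writes
# results/bootstrap_ci.tsv. Usage: Rscript analysis/05_bootstrap.R [R] [seed]

library(telometa)

args <- commandArgs(trailingOnly = TRUE)
R_boot <- if (length(args) >= 1) as.integer(args[1]) else 1000L
seed <- if (length(args) >= 2) as.integer(args[2]) else 1L

records <- parse_effect_table("results/data/records.csv")$records
A <- phylo_correlation(grafen_lengths(parse_newick("results/data/tree.nwk")))
spec <- build_model(records, A = A)
fit <- fit_reml(spec)

rows <- list()
for (unit in c("record", "study")) {
  bt <- bootstrap_components(spec, R = R_boot, seed = seed, unit = unit)
  rows[[unit]] <- data.frame(
    unit = unit, component = colnames(bt$ci),
    point = round(unname(fit$sigma2), 3),
    ci_lower = round(bt$ci["lower", ], 3),
    ci_upper = round(bt$ci["upper", ], 3),
    failures = bt$failures
  )
  cat(sprintf("%s-level bootstrap (R = %d): %d failures\n", unit, R_boot,
              bt$failures))
}
tab <- do.call(rbind, rows)
rownames(tab) <- NULL
write.table(tab, "results/bootstrap_ci.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
print(tab, row.names = FALSE)
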