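#!/usr/bin/env Rscript
# Moderator meta-regression: environmental setting, age at measurement,
# laboratory method, statistical method and repeated measurement, first with
# the parental-sex by statistical-method interaction, then without it when
# the interaction finds no support. Also runs the two sensitivity models:
# Fisher-z transformed response and the untransformed trimmed subset.
# Writes results/table2.tsv and results/sensitivity.tsv.

library(telometa)

records <- parse_effect_table("results/data/records.csv")$records
A <- phylo_correlation(grafen_lengths(parse_newick("results/data/tree.nwk")))

fit_int <- fit_reml(build_model(records, default_moderators(),
                                interaction = TRUE, A = A,
                                drop_aliased = TRUE))
wt_int <- wald_tests(fit_int)
int_rows <- grepl(":", wt_int$term)
cat(sprintf("interaction model: %d coefficients, min interaction p = %.3f\n",
            nrow(wt_int), min(wt_int$p[int_rows])))

fit_mod <- fit_reml(build_model(records, default_moderators(), A = A))
tab2 <- wald_tests(fit_mod)
tab2[, -1] <- round(tab2[, -1], 3)
write.table(tab2, "results/table2.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
cat("\nmoderator estimates (treatment coding against artificial / adult /",
    "TRF Southern / correlation / yes):\n")
print(tab2, row.names = FALSE)

# sensitivity: transformed (Fisher z) and trimmed (same subset, raw scale)
fz <- fisher_z_transform(records)
trim <- apply_trimming(records)
cat(sprintf("\nsensitivity subset: %d of %d records retained (%d removed)\n",
            nrow(trim$retained), nrow(records), nrow(trim$removed)))
fit_z <- fit_reml(build_model(fz$transformed, default_moderators(), A = A,
                              response = "z"))
fit_tr <- fit_reml(build_model(trim$retained, default_moderators(), A = A))
sens <- rbind(
  cbind(model = "transformed", wald_tests(fit_z)),
  cbind(model = "trimmed", wald_tests(fit_tr))
)
sens[, -(1:2)] <- round(sens[, -(1:2)], 3)
write.table(sens, "results/sensitivity.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
cat(sprintf("wrote %d sensitivity coefficients to results/sensitivity.tsv\n",
            nrow(sens)))
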