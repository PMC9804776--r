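#!/usr/bin/env Rscript
# Generate the working dataset: an ultrametric 18-species tree and a
# 104-estimate / 43-study effect-size table with variance components at the
# magnitudes reported for the vertebrate telomere-length heritability
# literature. Writes results/data/.

library(telometa)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = seed)
sim <- simulate_dataset(cfg)

write_effect_table(sim$records, file.path(out, "records.csv"))
ape::write.tree(sim$tree, file.path(out, "tree.nwk"))
write_correlation_tsv(sim$A, file.path(out, "phylo_correlation.tsv"))
jsonlite::write_json(
  list(seed = seed, beta = as.list(sim$truth$beta),
       sigma2 = as.list(sim$truth$sigma2)),
  file.path(out, "truth.json"), auto_unbox = TRUE, digits = NA)

cat(sprintf("simulated %d estimates, %d studies, %d species (seed %d)\n",
            nrow(sim$records), length(unique(sim$records$study_id)),
            length(unique(sim$records$species)), seed))
cat(sprintf("raw mean h2 = %.1f%% (SD %.1f%%), range %.1f%% to %.1f%%\n",
            100 * mean(sim$records$h2), 100 * sd(sim$records$h2),
            100 * min(sim$records$h2), 100 * max(sim$records$h2)))
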