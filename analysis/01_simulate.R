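#!/usr/bin/env Rscript
# Generate the synthetic study dataset: voxel patterns for 19 conditions
# (random/canonical 2-8, dice 2-6), percent-signal-change records per
# subject x hemisphere x condition, and 336 behavioral trials per subject.
# Defaults are calibrated to the published condition statistics; this driver
# runs at the package's "analysis scale" (24 subjects, 80 voxels, 12
# exemplars, SNR-preserving noise) so the whole workflow completes in
# minutes.
#
# Writes: results/patterns.csv, results/psc.csv, results/trials.csv,
#         results/manifest_simulate.yaml

suppressMessages(library(numerotune))

seed <- 20260923L
dir.create("results", showWarnings = FALSE)

config <- scale_config(generator_config(), n_voxels = 80)
dataset <- generate_dataset(config, seed = seed)

write_patterns(dataset$pattern_sets, "results/patterns.csv")
write_table_csv(dataset$psc_records, "results/psc.csv")
write_table_csv(dataset$trial_records, "results/trials.csv")
write_manifest("simulate", config, seed,
               c(patterns = "results/patterns.csv", psc = "results/psc.csv",
                 trials = "results/trials.csv"),
               "results/manifest_simulate.yaml")

cat(sprintf("Simulated %d subjects: %d pattern sets, %d PSC records, %d trials.\n",
            config$n_subjects, length(dataset$pattern_sets),
            nrow(dataset$psc_records), nrow(dataset$trial_records)))
cat("Ground-truth tuning widths:",
    paste(names(config$widths), round(config$widths, 3), sep = "=", collapse = ", "),
    "\n")
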