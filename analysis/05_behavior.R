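#!/usr/bin/env Rscript
# Behavioral analysis: RT trimming (errors, <200 ms fast guesses, +/-3 SD
# model residuals), per-condition summaries on the analysis scales (log RT,
# error log odds) with their back-transforms (geometric-mean ms, percent),
# and per-cell log-RT slopes on centered numerosity.
#
# Reads:  results/trials.csv
# Writes: results/behavior_summaries.csv, results/behavior_slopes.csv,
#         results/trim_report.csv

suppressMessages(library(numerotune))

trials <- read_table_csv("results/trials.csv")
trials$correct <- as.logical(trials$correct)

trim <- trim_rts(trials)
print(trim$report)
rep <- trim$report
write_table_csv(data.frame(
  n_input = rep$n_input, n_removed_error = rep$n_removed_error,
  n_removed_fast = rep$n_removed_fast,
  n_removed_residual = rep$n_removed_residual,
  n_retained = rep$n_retained, fraction_removed = rep$fraction_removed
), "results/trim_report.csv")

summaries <- condition_summaries(trials)
write_table_csv(summaries, "results/behavior_summaries.csv")
cat("\nCondition summaries (back-transformed):\n")
print(as.data.frame(summaries[c("arrangement", "range",
                                "er_backtransformed_percent",
                                "rt_backtransformed")]))

slopes <- behavioral_slopes(trials)
write_table_csv(slopes[setdiff(names(slopes), "per_subject")],
                "results/behavior_slopes.csv")
cat("\nLog-RT slopes (log-ms per dot):\n")
print(as.data.frame(slopes[c("arrangement", "range", "slope", "se", "n_subjects")]))
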