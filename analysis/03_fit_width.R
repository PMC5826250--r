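#!/usr/bin/env Rscript
# Tuning-width estimation: fit the scalar-variability Gaussian tuning model
# to each arrangement's similarity curves (diagonal pinned at chance error
# 0.5) and compare the fitted widths with the generator's ground truth
# (dice 0.094 < canonical 0.241 < random 0.276). Recovery is ordinal: the
# fitted values are attenuated by the chance anchor, but their ordering
# tracks the precision of the underlying representation.
#
# Reads:  results/similarity.csv
# Writes: results/tuning_widths.csv

suppressMessages(library(numerotune))

m <- read_similarity("results/similarity.csv")
fits <- setNames(lapply(c("random", "canonical", "dice"),
                        function(a) estimate_arrangement_width(m, a)),
                 c("random", "canonical", "dice"))
write_fits(fits, "results/tuning_widths.csv")

for (a in c("dice", "canonical", "random")) {
  f <- fits[[a]]
  cat(sprintf("%-10s w_hat = %.3f (scale %.2f, sse %.4f, %s)\n", a, f$w_hat,
              f$scale_hat, f$sse, if (f$converged) "converged" else "NOT converged"))
}
ok <- fits$dice$w_hat < fits$canonical$w_hat &&
  fits$canonical$w_hat < fits$random$w_hat
cat(if (ok) "Width ordering matches ground truth (dice < canonical < random).\n"
    else "Width ordering does NOT match ground truth on this seed.\n")
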