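#!/usr/bin/env Rscript
# Step 4: where do the genotypes differ? Reads the dynamics table written by
# step 2 and reports, per spin label x growth temperature x metric, the
# measurement temperatures at which the pooled-variance Student's t-test
# flags Delisa vs 522DK at p <= 0.05.

library(eprdyn)

path <- "results/pipeline/comparisons.csv"
if (!file.exists(path)) stop("run analysis/02_extract_dynamics.R first")
cmp <- read.csv(path)

sig <- cmp[cmp$significant & !cmp$degenerate, ]
if (nrow(sig) == 0) {
  message("no significant genotype differences at p <= 0.05")
} else {
  agg <- aggregate(measurement_temperature_C ~ growth_temperature_C +
                     spin_label + metric, sig,
                   function(v) paste(sort(v), collapse = ", "))
  names(agg)[4] <- "significant_at_degC"
  message("Delisa vs 522DK, temperatures with p <= 0.05:")
  print(agg, row.names = FALSE)
}
write.csv(sig, "results/significant_differences.csv", row.names = FALSE)
message(sprintf("%d of %d per-temperature comparisons significant",
                nrow(sig), nrow(cmp)))
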