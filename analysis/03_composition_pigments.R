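#!/usr/bin/env Rscript
# Step 3: membrane-composition computations -- fatty-acid unsaturation
# summaries from the packaged barley chloroplast GC-FAME table, and the
# chlorophyll/carotenoid equations on a worked absorbance triple.

library(eprdyn)

dir.create("results", showWarnings = FALSE)

ratios <- fatty_acid_ratios(barley_fatty_acids())
write.csv(ratios, "results/fatty_acid_ratios.csv", row.names = FALSE)
message("U/S and 18:3/18:2 per genotype x growth temperature:")
print(ratios, row.names = FALSE)

# Example absorbance triples (80% acetone extract, 1 cm path).
abs_tbl <- data.frame(sample = c("demo_a", "demo_b", "demo_c"),
                      A663_2 = c(0.50, 0.62, 0.45),
                      A664_8 = c(0.30, 0.35, 0.28),
                      A470 = c(0.80, 0.95, 0.70))
pig <- cbind(abs_tbl["sample"],
             pigment_concentrations(abs_tbl$A663_2, abs_tbl$A664_8,
                                    abs_tbl$A470, per_sample = TRUE))
write.csv(pig, "results/pigment_concentrations.csv", row.names = FALSE)
message("pigment concentrations (ug/mL extract):")
print(pig[, 1:6], row.names = FALSE)
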