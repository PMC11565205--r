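#!/usr/bin/env Rscript
# Stage 2: derive leaf-level physiology (iWUE, hydraulic conductances and
# resistances, LMA, RWC) for every replicate, then aggregate to genotype
# x treatment means and apply the collapsed-gas-exchange exclusion rule.

suppressPackageStartupMessages(library(sorghumWUE))

records <- read_phenotype_table("results/records.csv")
derived <- derive_physiology(records)
write_phenotype_table(derived, "results/derived.csv")

means <- aggregate_means(derived)
filt <- apply_exclusion_filter(means)
write_phenotype_table(filt$retained, "results/means.csv")
write_phenotype_table(
  if (nrow(filt$excluded)) filt$excluded[, c("genotype_id", "treatment",
                                             "reason")]
  else data.frame(genotype_id = character(0), treatment = character(0),
                  reason = character(0)),
  "results/excluded.csv")

for (trt in c("WW", "WS")) {
  m <- filt$retained[filt$retained$treatment == trt, ]
  message(sprintf(
    "%s: %d genotype means; A_n %.1f-%.1f, g_s %.3f-%.3f, iWUE %.0f-%.0f, psi_midday mean %.2f MPa",
    trt, nrow(m), min(m$A_n), max(m$A_n), min(m$g_s), max(m$g_s),
    min(m$iwue), max(m$iwue), mean(m$psi_midday)))
}
message(sprintf("excluded %d genotype x treatment mean(s)",
                nrow(filt$excluded)))
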