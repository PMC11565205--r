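#!/usr/bin/env Rscript
# Stage 5: genetic-variation summary per trait - grand means, fold
# changes of genotype means within treatment, ANOVA variance components,
# broad-sense heritability, GCV and PCV - plus the pairwise trait
# correlation matrix on genotype means.

suppressPackageStartupMessages(library(sorghumWUE))

derived <- read_phenotype_table("results/derived.csv")
means <- read_phenotype_table("results/means.csv", required = c("genotype_id", "treatment"))

traits <- c("A_n", "g_s", "iwue", "C_i", "phi_PSII", "SPAD",
            "psi_midday", "psi_predawn", "leaf_width", "LMA", "RWC",
            "biomass")
summ <- suppressWarnings(
  trait_summary_table(derived, means, traits))
write_phenotype_table(summ, "results/genetic_variation.csv")
message("genetic-variation summary (paper-literal convention):")
for (j in seq_len(nrow(summ))) {
  message(sprintf(
    "  %-12s mean %8.2f  fold WW %5.2f  H_b2 %4.2f  GCV %5.1f%%  PCV %5.1f%%",
    summ$trait[j], summ$mean[j], summ$fold_change_WW[j], summ$H_b2[j],
    summ$GCV_pct[j], summ$PCV_pct[j]))
}

corr <- correlation_matrix(means, traits)
write_phenotype_table(corr, "results/correlations.csv")
top <- corr[order(-abs(corr$r)), ][1:5, ]
message("strongest trait correlations (genotype means):")
for (j in seq_len(nrow(top))) {
  message(sprintf("  %s ~ %s: r = %.2f (p = %.2g)", top$trait_x[j],
                  top$trait_y[j], top$r[j], top$p[j]))
}
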