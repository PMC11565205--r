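#!/usr/bin/env Rscript
# Stage 6: aquaporin haplotype-group contrasts - split-plot ANOVA of
# RP vs NRP populations across treatments for the key traits, and Tukey
# HSD letter displays over the four population x treatment cells.

suppressPackageStartupMessages(library(sorghumWUE))

derived <- read_phenotype_table("results/derived.csv")
assignments <- read_phenotype_table("results/assignments.csv", required = "genotype_id")
aqp <- assignments$aquaporin_id[1]

traits <- c("A_n", "g_s", "iwue", "K_leaf", "SPAD", "biomass")
rows <- list(); letter_rows <- list()
for (tr in traits) {
  at <- haplotype_anova(derived, tr, aqp, assignments)
  keep <- at$source %in% c("population", "treatment",
                           "population:treatment")
  rows[[tr]] <- data.frame(aquaporin = aqp, trait = tr,
                           comparison = at$source[keep],
                           df = at$df[keep], F = at$F[keep],
                           p = at$p[keep])
  # Tukey letters over the four population x treatment cells, on
  # genotype means (the independent units)
  gm <- aggregate(derived[[tr]],
                  by = list(genotype_id = derived$genotype_id,
                            treatment = derived$treatment),
                  FUN = mean, na.rm = TRUE)
  gm$group <- assignments$group[match(gm$genotype_id,
                                      assignments$genotype_id)]
  cell <- interaction(gm$group, gm$treatment, sep = "x")
  cm <- tapply(gm$x, cell, mean)
  cn <- tapply(gm$x, cell, length)
  ms_e <- mean(tapply(gm$x, cell, var))
  th <- tukey_hsd(cm, cn, ms_e, df_error = nrow(gm) - length(cm))
  letter_rows[[tr]] <- cbind(trait = tr, th$groups)
}
anova_tab <- do.call(rbind, rows)
letters_tab <- do.call(rbind, letter_rows)
write_phenotype_table(anova_tab, "results/haplotype_anova.csv")
write_phenotype_table(letters_tab, "results/haplotype_letters.csv")

message(sprintf("haplotype contrasts for %s:", aqp))
pop <- anova_tab[anova_tab$comparison == "population", ]
for (j in seq_len(nrow(pop))) {
  message(sprintf("  %-8s population p = %.3f %s", pop$trait[j], pop$p[j],
                  ifelse(pop$p[j] < 0.05, "*", "")))
}
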