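#!/usr/bin/env Rscript
# Stage 4: per-genotype phenotypic-change vectors in the A_n-C_i plane
# between watering regimes, and the association of their direction
# (theta) with the shift in each iWUE component under stress.

suppressPackageStartupMessages(library(sorghumWUE))

means <- read_phenotype_table("results/means.csv", required = c("genotype_id", "treatment"))
part <- read_phenotype_table("results/partition.csv", required = c("genotype_id", "treatment"))

vecs <- change_vectors(means)
write_phenotype_table(vecs, "results/vectors.csv")
message(sprintf(
  "%d change vectors; theta median %.1f deg (IQR %.1f-%.1f), magnitude median %.1f",
  nrow(vecs), median(vecs$theta), quantile(vecs$theta, 0.25),
  quantile(vecs$theta, 0.75), median(vecs$magnitude)))

assoc <- theta_component_association(vecs, part)
write_phenotype_table(assoc, "results/theta_associations.csv")
for (j in seq_len(nrow(assoc))) {
  message(sprintf("theta vs %s: r = %.3f (r^2 = %.2f, p = %.3g, n = %d)",
                  assoc$component[j], assoc$r[j], assoc$r_squared[j],
                  assoc$p[j], assoc$n[j]))
}
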