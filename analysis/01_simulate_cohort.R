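#!/usr/bin/env Rscript
# Stage 1: generate the synthetic admixed case-control cohort every later
# stage analyses. A two-way admixed population (Inuit-like / European-like
# components, mean ancestry ~75/25), 2948 individuals to mirror the size
# of the case-control analysis set, a recessive-effect causal variant
# (EAF 0.25, homozygote OR 3 on a baseline risk of 0.1, component
# frequencies 0.31 / 0.03), and OGTT phenotypes consistent with status.
#
# Writes results/cohort.{bed,bim,fam} and results/cohort.pheno.tsv.

suppressPackageStartupMessages(library(recessmap))
dir.create("results", showWarnings = FALSE)

sim <- simulate_cohort(
  n = 2948, m = 2000,
  spec = disease_spec(eaf = 0.25, or_effect = 3, baseline_risk = 0.1,
                      n = 2948),
  mix_params = c(3, 1), divergence = 0.15, missing_rate = 0.002,
  causal_F = c(0.31, 0.03), seed = 1
)
write_cohort(sim, "results/cohort")
write.table(data.frame(iid = sim$G$iids, round(sim$Q, 6)),
            "results/cohort.Q.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

# 50 unadmixed European-like anchor individuals drawn from the same
# ancestral frequencies: ancestry estimation needs reference individuals
# near the minority-component vertex (the cohort itself has none), so the
# admixture step is run in supervised mode with this panel clamped.
anchor_Q <- matrix(c(0, 1), 50, 2, byrow = TRUE)
G_anchor <- sample_genotypes(anchor_Q, sim$F_mat, seed = 2)
write.table(G_anchor$dosages, "results/anchors.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE, col.names = FALSE)
cat(sprintf("cohort: %d individuals x %d SNPs; causal SNP %s (index %d)\n",
            nrow(sim$G$dosages), ncol(sim$G$dosages),
            sim$G$snp_ids[sim$causal_index], sim$causal_index))
cat(sprintf("cases: %d, prevalence %.3f\n", sum(sim$pheno$status),
            mean(sim$pheno$status)))
writeLines(sim$G$snp_ids[sim$causal_index], "results/causal_snp.txt")
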