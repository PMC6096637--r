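#!/usr/bin/env Rscript
# Stage 2: derive the analysis phenotypes from the raw OGTT table -
# glucose-tolerance class (T2D / NGT / INDETERMINATE), HOMA-IR,
# ISI(0,120), and within sex-by-cohort rank-based inverse normal
# transforms of the quantitative traits.

suppressPackageStartupMessages(library(recessmap))

pheno <- read_phenotypes("results/cohort.pheno.tsv")
pheno <- derive_traits(pheno)
write_phenotypes(pheno, "results/cohort.derived.tsv")

cat("glucose tolerance classes:\n")
print(table(pheno$gt_class))
cat(sprintf("cases by simulated status: %d; cases by OGTT classification: %d\n",
            sum(pheno$status), sum(pheno$gt_class == "T2D")))
cat(sprintf("HOMA-IR median %.2f; ISI(0,120) median %.1f\n",
            median(pheno$homa_ir, na.rm = TRUE),
            median(pheno$isi_0_120, na.rm = TRUE)))
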