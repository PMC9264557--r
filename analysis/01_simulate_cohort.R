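#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study cohort.
#
# Emulates the structure of the oral-cancer study data: 390 tumor and 32
# normal expression profiles with planted differential genes, survival
# times driven by five planted gene-pair indicators under proportional
# hazards with independent censoring, simple clinical covariates, and a
# somatic mutation table (MAF). The truth set (planted effects) is saved
# so later stages can measure recovery.

library(irgpair)

outdir <- "results/cohort"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

cfg <- simulation_config(seed = 20260922)
coh <- simulate_cohort(cfg)
maf <- simulate_maf(cfg)

write_expression(coh$expression, file.path(outdir, "expression.tsv"),
                 group_file = file.path(outdir, "groups.tsv"))
write_clinical(coh$clinical, file.path(outdir, "clinical.tsv"))
writeLines(cfg$immune_genes, file.path(outdir, "immune_genes.txt"))
write_maf(maf, file.path(outdir, "mutations.maf"))

truth <- cfg$planted_pairs
truth$pair <- pair_token(truth$gene1, truth$gene2)
write.table(truth, file.path(outdir, "truth_pairs.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(coh$truth$de_genes, file.path(outdir, "truth_de_genes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf(
  "Simulated %d tumor / %d normal samples, %d genes (%d immune-labeled).\n",
  cfg$n_tumor, cfg$n_normal, cfg$n_genes, length(cfg$immune_genes)))
cat(sprintf("Planted %d differential genes and %d prognostic pairs: %s\n",
            nrow(coh$truth$de_genes), nrow(truth),
            paste(truth$pair, collapse = ", ")))
cat(sprintf("Event rate among tumor samples: %.2f (censoring %.2f)\n",
            mean(coh$clinical$event), 1 - mean(coh$clinical$event)))
cat(sprintf("MAF records: %d\n", nrow(maf)))
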