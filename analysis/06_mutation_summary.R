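#!/usr/bin/env Rscript
# Stage 6: mutation summary of the signature genes in the high-risk group.
#
# Restricts the cohort MAF to the genes appearing in the fitted signature
# and to the samples assigned high risk, then summarizes variant
# classifications, variant types, the strand-collapsed SNV substitution
# spectrum, per-sample burden and the top mutated genes.

library(irgpair)

outdir <- "results/mutation"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

maf <- read_maf("results/cohort/mutations.maf")
sig <- load_signature("results/signature/signature.tsv")
risk <- read.delim("results/risk/risk_assignment.tsv")

high <- risk$sample_id[risk$group == "high"]
maf_hr <- restrict_to_genes(
  maf[maf$Tumor_Sample_Barcode %in% high, , drop = FALSE],
  signature_genes(sig))
s <- summarize_mutations(maf_hr)

write.table(s$genes, file.path(outdir, "gene_summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(class = names(s$snv_class),
                       count = as.integer(s$snv_class)),
            file.path(outdir, "snv_classes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(classification = names(s$classification),
                       count = as.integer(s$classification)),
            file.path(outdir, "classifications.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf(
  "%d mutation records in %d high-risk samples across %d signature genes.\n",
  s$n_records, length(s$per_sample), nrow(s$genes)))
cat(sprintf("Per-sample burden: median %g, max %g.\n",
            s$per_sample_median, s$per_sample_max))
if (sum(s$snv_class) > 0)
  cat(sprintf("Dominant SNV class: %s (%.0f%% of classified SNPs).\n",
              names(which.max(s$snv_class)),
              100 * max(s$snv_class) / sum(s$snv_class)))
print(top_genes(s, 10))
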