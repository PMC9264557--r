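#!/usr/bin/env Rscript
# Stage 2: tumor-vs-normal differential expression and the immune overlap.
#
# Normalizes to log2 counts-per-million, tests each gene with a Welch
# t-test, applies the |log2FC| > 1 and P < 0.05 screen, and intersects
# the differential genes with the immune-annotated list. Reports how many
# planted differential genes the screen recovered.

library(irgpair)

indir <- "results/cohort"
outdir <- "results/diffexpr"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

em <- load_expression(file.path(indir, "expression.tsv"),
                      group_file = file.path(indir, "groups.tsv"))
immune <- load_gene_list(file.path(indir, "immune_genes.txt"), "immune")
truth_de <- read.delim(file.path(indir, "truth_de_genes.tsv"))

norm <- normalize_log2cpm(em)
de <- differential_expression(norm)
degs <- filter_degs(de, lfc_min = 1, p_max = 0.05)
immune_degs <- intersect_immune(degs, immune)

write.table(de, file.path(outdir, "de_table.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
writeLines(as.character(degs), file.path(outdir, "degs.txt"))
writeLines(as.character(immune_degs), file.path(outdir, "immune_degs.txt"))

recovered <- mean(truth_de$gene %in% degs)
cat(sprintf("%d of %d genes pass |log2FC| > 1 and P < 0.05.\n",
            length(degs), nrow(de)))
cat(sprintf("Planted differential genes recovered: %.0f%%\n",
            100 * recovered))
cat(sprintf("%d immune-annotated differential genes carried forward.\n",
            length(immune_degs)))
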