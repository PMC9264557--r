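#!/usr/bin/env Rscript
# Stage 3: candidate gene-pair features.
#
# Forms all unordered pairs of the immune-differential genes, binarizes
# each pair per tumor sample (1 when the former gene's expression
# strictly exceeds the latter's), and removes pairs whose indicator is
# constant in more than 80% of samples.

library(irgpair)

outdir <- "results/pairs"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

em <- load_expression("results/cohort/expression.tsv",
                      group_file = "results/cohort/groups.tsv")
immune_degs <- load_gene_list("results/diffexpr/immune_degs.txt")
truth <- read.delim("results/cohort/truth_pairs.tsv")

pairs <- enumerate_pairs(immune_degs)
tumor <- names(em$group)[em$group == "tumor"]
pm_all <- pair_indicators(em, pairs, samples = tumor)
pm <- prevalence_filter(pm_all, lo = 0.2, hi = 0.8)

write.table(data.frame(pair = rownames(pm), pm, check.names = FALSE),
            file.path(outdir, "pair_indicators.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("%d genes -> %d unordered pairs; %d pass the 80%% prevalence filter.\n",
            length(immune_degs), nrow(pm_all), nrow(pm)))
planted_present <- truth$pair %in% rownames(pm) |
  pair_token(truth$gene2, truth$gene1) %in% rownames(pm)
cat(sprintf("Planted pairs surviving the filter: %d of %d\n",
            sum(planted_present), nrow(truth)))
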