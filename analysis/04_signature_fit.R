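#!/usr/bin/env Rscript
# Stage 4: signature construction.
#
# Splits the tumor cohort 1:1 into training and test sets, screens each
# candidate pair with a univariate Cox model (P < 0.01), fits the
# L1-penalized Cox model over the screened pairs with 10-fold
# cross-validated lambda selection, and writes the resulting signature
# (nonzero pairs with their coefficients).

library(irgpair)

outdir <- "results/signature"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

clin <- load_clinical("results/cohort/clinical.tsv")
pm <- local({
  df <- read.delim("results/pairs/pair_indicators.tsv",
                   check.names = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$pair
  m
})
truth <- read.delim("results/cohort/truth_pairs.tsv")

seed <- 20260922
split <- split_cohort(clin, ratio = 0.5, seed = seed)
train <- intersect(split$train, colnames(pm))
clin_tr <- as.data.frame(clin)[match(train, clin$sample_id), ]

scr <- univariate_screen(pm[, train, drop = FALSE], clin_tr$time,
                         clin_tr$event, alpha = 0.01)
write.table(scr$table, file.path(outdir, "univariate_screen.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("Univariate screen: %d of %d pairs at P < 0.01.\n",
            length(scr$selected), nrow(pm)))

cv <- cv_select(t(pm[scr$selected, train, drop = FALSE]), clin_tr$time,
                clin_tr$event, folds = 10, seed = seed)
write.table(data.frame(lambda = cv$lambda, cvm = cv$cvm, cvse = cv$cvse,
                       df = cv$path$df),
            file.path(outdir, "cv_path.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

nz <- cv$nonzero
gp <- do.call(rbind, strsplit(nz, "|", fixed = TRUE))
sig <- signature_model(data.frame(gene_former = gp[, 1],
                                  gene_latter = gp[, 2]),
                       cv$coefficients[nz])
write_signature(sig, file.path(outdir, "signature.tsv"))
writeLines(c(paste(split$train, collapse = "\t"),
             paste(split$test, collapse = "\t")),
           file.path(outdir, "split.txt"))

cat(sprintf("Selected lambda = %.4g; signature has %d pairs.\n",
            cv$lambda_selected, length(sig)))
hit <- truth$pair %in% nz
cat(sprintf("Planted pairs in the signature: %d of %d (%s)\n",
            sum(hit), nrow(truth),
            paste(truth$pair[hit], collapse = ", ")))
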