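#!/usr/bin/env Rscript
# Stage 5: risk scores, cutoff, survival comparison, independence.
#
# Scores every tumor sample with the fitted signature, selects the
# optimal cutoff on the training set's 1-year ROC curve (Youden's J),
# freezes that cutoff for the test set, compares survival between the
# high- and low-risk groups (Kaplan-Meier + log-rank), and tests whether
# the risk score predicts survival independently of age, gender, grade,
# stage and nodal status.

library(irgpair)

outdir <- "results/risk"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

clin <- load_clinical("results/cohort/clinical.tsv")
sig <- load_signature("results/signature/signature.tsv")
pm <- local({
  df <- read.delim("results/pairs/pair_indicators.tsv",
                   check.names = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$pair
  m
})
split <- strsplit(readLines("results/signature/split.txt"), "\t")
train <- split[[1]]; test <- split[[2]]

scores <- risk_score(sig, pm)
roc <- one_year_roc(scores[train], clin, horizon = 365)
cutoff <- select_cutoff(roc)
cat(sprintf("Training 1-year AUC = %.3f; optimal cutoff = %.3f.\n",
            roc$auc, cutoff))

strat_tr <- stratify_and_compare(scores[train], cutoff, clin)
strat_te <- stratify_and_compare(scores[test], cutoff, clin)
for (nm in c("train", "test")) {
  st <- if (nm == "train") strat_tr else strat_te
  cat(sprintf(
    "%s set: %d high / %d low risk; death %.0f%% vs %.0f%%; log-rank p = %.3g\n",
    nm, st$n["high"], st$n["low"], 100 * st$death_fraction["high"],
    100 * st$death_fraction["low"], st$logrank$p))
}

write.table(rbind(cbind(strat_tr$assignment, set = "train"),
                  cbind(strat_te$assignment, set = "test")),
            file.path(outdir, "risk_assignment.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(threshold = roc$thresholds,
                       sensitivity = roc$sensitivity,
                       specificity = roc$specificity),
            file.path(outdir, "roc.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

forest <- suppressWarnings(
  multivariate_independence(scores[train], clin))
write.table(forest, file.path(outdir, "forest_table.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
rs <- forest[forest$model == "multivariate" & forest$term == "riskScore", ]
cat(sprintf(
  "Multivariate: riskScore HR = %.2f (95%% CI %.2f-%.2f), p = %.3g\n",
  rs$hr, rs$ci_lower, rs$ci_upper, rs$p))
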