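# Differential expression between tumor and normal samples.
#
# The pair-based signature downstream depends only on within-sample gene
# orderings, so a simple, transparent DE screen suffices here: library-size
# normalization to log2 counts-per-million followed by a per-gene Welch
# two-sample t-test. Thresholds follow the common |log2FC| > 1, P < 0.05
# convention with strict inequalities and raw (unadjusted) p-values;
# Benjamini-Hochberg adjustment is available as an opt-in.

#' Normalize to log2 counts-per-million
#'
#' Each column is scaled so that its pre-log sum equals 1e6, then
#' transformed as `log2(cpm + pseudocount)`.
#'
#' @param em An [expression_matrix()] of non-negative values.
#' @param pseudocount Positive offset added before the log (default 1).
#' @return An [expression_matrix()] in log2-CPM units.
#' @export
normalize_log2cpm <- function(em, pseudocount = 1) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (!is.numeric(pseudocount) || pseudocount <= 0)
    stop("`pseudocount` must be > 0")
  tot <- colSums(em$values)
  if (any(tot == 0))
    stop("all-zero expression column for sample(s): ",
         paste(colnames(em$values)[tot == 0], collapse = ", "))
  cpm <- sweep(em$values, 2, tot, "/") * 1e6
  out <- em
  out$values <- log2(cpm + pseudocount)
  out
}

#' Per-gene tumor-vs-normal differential expression
#'
#' Welch two-sample t-test per gene on (normalized) expression, two-sided.
#' `log2fc` is mean(tumor) minus mean(normal); for a gene with zero
#' variance in both groups and equal means the test is degenerate and
#' reported as `statistic = 0`, `p = 1`.
#'
#' @param em An [expression_matrix()], normally in log2 units (see
#'   [normalize_log2cpm()]).
#' @return Data.frame with one row per gene: `gene`, `mean_tumor`,
#'   `mean_normal`, `log2fc`, `statistic`, `df`, `p`.
#' @export
differential_expression <- function(em) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  tum <- em$values[, em$group == "tumor", drop = FALSE]
  nor <- em$values[, em$group == "normal", drop = FALSE]
  n1 <- ncol(tum); n0 <- ncol(nor)
  if (n1 < 2 || n0 < 2)
    stop("each group needs at least 2 samples (tumor: ", n1,
         ", normal: ", n0, ")")
  m1 <- rowMeans(tum); m0 <- rowMeans(nor)
  v1 <- rowSums((tum - m1)^2) / (n1 - 1)
  v0 <- rowSums((nor - m0)^2) / (n0 - 1)
  se2 <- v1 / n1 + v0 / n0
  diff <- m1 - m0
  stat <- diff / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  p <- 2 * pt(-abs(stat), df)
  zero_se <- se2 == 0
  if (any(zero_se)) {
    # both groups constant: identical means -> no evidence; unequal -> certain
    stat[zero_se] <- ifelse(diff[zero_se] == 0, 0,
                            sign(diff[zero_se]) * Inf)
    p[zero_se] <- ifelse(diff[zero_se] == 0, 1, 0)
    df[zero_se] <- NA_real_
  }
  data.frame(gene = rownames(em$values), mean_tumor = m1, mean_normal = m0,
             log2fc = diff, statistic = stat, df = df, p = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Threshold a DE table into a differential gene set
#'
#' Retains genes with `|log2fc| > lfc_min` and `p < p_max`, both strict.
#'
#' @param de_table Output of [differential_expression()].
#' @param lfc_min Minimum absolute log2 fold-change (default 1).
#' @param p_max Maximum p-value (default 0.05).
#' @param fdr If `TRUE`, apply Benjamini-Hochberg adjustment to `p` before
#'   thresholding (off by default; the conventional screen uses raw p).
#' @return A [gene_set()] with provenance `"DEG"`.
#' @export
filter_degs <- function(de_table, lfc_min = 1, p_max = 0.05, fdr = FALSE) {
  stopifnot(lfc_min > 0, p_max > 0)
  p <- if (fdr) stats::p.adjust(de_table$p, method = "BH") else de_table$p
  keep <- abs(de_table$log2fc) > lfc_min & p < p_max
  keep[is.na(keep)] <- FALSE
  gene_set(de_table$gene[keep], provenance = "DEG")
}

#' Intersect a DEG set with an immune gene list
#'
#' @param degs,immune [gene_set()]s (or plain character vectors).
#' @return A [gene_set()] with provenance `"immune-DEG"`, ordered by
#'   appearance in `degs`.
#' @export
intersect_immune <- function(degs, immune) {
  gene_set(degs[degs %in% normalize_symbols(immune)],
           provenance = "immune-DEG")
}
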