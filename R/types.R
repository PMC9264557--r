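#' Expression matrix with tumor/normal group labels
#'
#' Container for a genes-by-samples expression matrix. Values may be raw
#' counts or normalized units; they must be finite and non-negative. Every
#' sample carries a `"tumor"` or `"normal"` label.
#'
#' @param values Numeric matrix, genes as rows (rownames = gene symbols),
#'   samples as columns (colnames = sample ids).
#' @param group Character vector of `"tumor"`/`"normal"` labels, either
#'   named by sample id or in column order.
#' @return An object of class `ExpressionMatrix` with elements `values`
#'   (the matrix, symbols uppercased) and `group` (named character vector).
#' @export
expression_matrix <- function(values, group) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene rownames and sample colnames")
  rownames(values) <- normalize_symbols(rownames(values))
  genes <- rownames(values)
  samples <- colnames(values)
  dup_g <- genes[duplicated(genes)]
  if (length(dup_g))
    stop("duplicate gene id(s): ", paste(unique(dup_g), collapse = ", "))
  dup_s <- samples[duplicated(samples)]
  if (length(dup_s))
    stop("duplicate sample id(s): ", paste(unique(dup_s), collapse = ", "))
  if (anyNA(values) || any(!is.finite(values)))
    stop("expression values must be finite and non-missing")
  if (any(values < 0))
    stop("expression values must be non-negative")
  group <- as.character(group)
  if (!is.null(names(group))) {
    missing <- setdiff(samples, names(group))
    if (length(missing))
      stop("no group label for sample(s): ", paste(missing, collapse = ", "))
    group <- group[samples]
  } else if (length(group) != length(samples)) {
    stop("`group` must have one label per sample")
  }
  names(group) <- samples
  bad <- setdiff(unique(group), c("tumor", "normal"))
  if (length(bad))
    stop("group labels must be 'tumor' or 'normal'; found: ",
         paste(bad, collapse = ", "))
  structure(list(values = values, group = group),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (%d tumor, %d normal)\n",
              nrow(x$values), ncol(x$values),
              sum(x$group == "tumor"), sum(x$group == "normal")))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Clinical/survival table
#'
#' Validates a clinical table: unique sample ids, strictly positive
#' follow-up times (days) and 0/1 event indicators (1 = death). Clinical
#' covariates (`age`, `gender`, `grade`, `stage`, `t_stage`, `n_stage`) are
#' optional and may contain missing values; they are never imputed.
#'
#' @param df A data.frame with at least `sample_id`, `time`, `event`.
#' @return The validated data.frame with class `ClinicalTable` prepended.
#' @export
clinical_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("sample_id", "time", "event")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("clinical table lacks column(s): ", paste(missing, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup))
    stop("duplicate sample id(s): ", paste(unique(dup), collapse = ", "))
  ok_surv <- !is.na(df$time) & !is.na(df$event)
  if (any(df$time[ok_surv] <= 0))
    stop("follow-up times must be > 0")
  if (!all(df$event[ok_surv] %in% c(0, 1)))
    stop("event must be 0 (censored) or 1 (death)")
  class(df) <- c("ClinicalTable", "data.frame")
  df
}

#' Gene-pair signature model
#'
#' An ordered list of gene pairs with one coefficient per pair and an
#' optional risk-score cutoff. The risk score of a sample is
#' `sum_k alpha_k * I(expr[former_k] > expr[latter_k])`.
#'
#' @param pairs Data.frame with columns `gene_former`, `gene_latter`.
#' @param coefficients Numeric vector, one per pair.
#' @param cutoff Optional risk-score threshold (strictly-greater assigns
#'   high risk).
#' @return An object of class `SignatureModel`.
#' @export
signature_model <- function(pairs, coefficients, cutoff = NULL) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (!all(c("gene_former", "gene_latter") %in% names(pairs)))
    stop("`pairs` needs columns gene_former and gene_latter")
  pairs$gene_former <- normalize_symbols(pairs$gene_former)
  pairs$gene_latter <- normalize_symbols(pairs$gene_latter)
  if (nrow(pairs) != length(coefficients))
    stop("pairs and coefficients must have the same length")
  if (any(pairs$gene_former == pairs$gene_latter))
    stop("a pair may not contain the same gene twice")
  tok <- pair_token(pairs$gene_former, pairs$gene_latter)
  if (anyDuplicated(tok))
    stop("duplicate pair(s): ", paste(unique(tok[duplicated(tok)]),
                                      collapse = ", "))
  if (!is.null(cutoff)) stopifnot(is.numeric(cutoff), length(cutoff) == 1L)
  structure(list(pairs = pairs,
                 coefficients = as.numeric(coefficients),
                 cutoff = cutoff),
            class = "SignatureModel")
}

#' @export
print.SignatureModel <- function(x, ...) {
  cat(sprintf("SignatureModel: %d gene pairs (%d negative, %d positive)%s\n",
              nrow(x$pairs), sum(x$coefficients < 0),
              sum(x$coefficients > 0),
              if (is.null(x$cutoff)) ""
              else sprintf(", cutoff %.4g", x$cutoff)))
  invisible(x)
}

#' @export
length.SignatureModel <- function(x) nrow(x$pairs)

#' Genes appearing in a signature
#'
#' The union of both members of every pair, in first-appearance order.
#'
#' @param sig A [signature_model()].
#' @return Character vector of unique gene symbols.
#' @export
signature_genes <- function(sig) {
  stopifnot(inherits(sig, "SignatureModel"))
  unique(as.vector(rbind(sig$pairs$gene_former, sig$pairs$gene_latter)))
}

#' Gene set with provenance
#'
#' @param genes Character vector of symbols (uppercased, de-duplicated,
#'   first occurrence kept).
#' @param provenance Short label, e.g. `"DEG"`, `"immune"`, `"immune-DEG"`.
#' @return Character vector with a `provenance` attribute.
#' @export
gene_set <- function(genes, provenance = "custom") {
  genes <- normalize_symbols(genes)
  genes <- genes[nzchar(genes)]
  genes <- genes[!duplicated(genes)]
  attr(genes, "provenance") <- provenance
  genes
}
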