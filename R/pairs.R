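# Rank-based gene-pair features. A pair (former, latter) contributes a
# binary indicator per sample: 1 when the former gene's expression strictly
# exceeds the latter's, 0 otherwise (ties are 0). Because the indicator
# depends only on the within-sample ordering of two genes it is invariant
# to any strictly monotone per-sample transformation of expression, which
# is what makes the features robust across measurement platforms.

#' Enumerate candidate gene pairs
#'
#' All `n*(n-1)/2` unordered pairs of the input genes, each emitted once in
#' canonical orientation: the former gene is the one appearing earlier in
#' the input ordering. (The reversed orientation would carry the complement
#' indicator and is therefore redundant.)
#'
#' @param genes Character vector of at least two unique gene symbols.
#' @return Data.frame with columns `gene_former`, `gene_latter`.
#' @export
enumerate_pairs <- function(genes) {
  genes <- gene_set(genes, attr(genes, "provenance") %||% "custom")
  n <- length(genes)
  if (n < 2) stop("need at least 2 genes to form pairs (got ", n, ")")
  idx <- utils::combn(n, 2)
  data.frame(gene_former = genes[idx[1, ]], gene_latter = genes[idx[2, ]],
             stringsAsFactors = FALSE)
}

#' Binarize one gene pair across samples
#'
#' @param em An [expression_matrix()].
#' @param pair Character vector of two gene symbols `(former, latter)`.
#' @return Named integer vector over samples: 1 where
#'   `expr[former] > expr[latter]` (strict), else 0.
#' @export
binarize_pair <- function(em, pair) {
  stopifnot(inherits(em, "ExpressionMatrix"), length(pair) == 2L)
  pair <- normalize_symbols(pair)
  missing <- setdiff(pair, rownames(em$values))
  if (length(missing))
    stop("gene(s) not in expression matrix: ",
         paste(missing, collapse = ", "))
  as.integer(em$values[pair[1], ] > em$values[pair[2], ])
}

#' Build a pair-indicator matrix
#'
#' @param em An [expression_matrix()].
#' @param pairs Data.frame with `gene_former`/`gene_latter` columns (see
#'   [enumerate_pairs()]).
#' @param samples Optional subset of sample ids (default: all).
#' @return A `PairIndicatorMatrix`: binary matrix with pair tokens `A|B`
#'   as rownames and sample ids as colnames, plus a `pairs` attribute.
#' @export
pair_indicators <- function(em, pairs, samples = NULL) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  pairs$gene_former <- normalize_symbols(pairs$gene_former)
  pairs$gene_latter <- normalize_symbols(pairs$gene_latter)
  genes <- unique(c(pairs$gene_former, pairs$gene_latter))
  missing <- setdiff(genes, rownames(em$values))
  if (length(missing))
    stop("gene(s) not in expression matrix: ",
         paste(missing, collapse = ", "))
  key <- paste(pmin(pairs$gene_former, pairs$gene_latter),
               pmax(pairs$gene_former, pairs$gene_latter))
  if (anyDuplicated(key))
    stop("the same unordered pair appears twice")
  vals <- em$values
  if (!is.null(samples)) {
    missing_s <- setdiff(samples, colnames(vals))
    if (length(missing_s))
      stop("sample(s) not in expression matrix: ",
           paste(missing_s, collapse = ", "))
    vals <- vals[, samples, drop = FALSE]
  }
  ind <- (vals[pairs$gene_former, , drop = FALSE] >
          vals[pairs$gene_latter, , drop = FALSE]) * 1L
  rownames(ind) <- pair_token(pairs$gene_former, pairs$gene_latter)
  structure(ind, pairs = pairs, class = c("PairIndicatorMatrix", "matrix"))
}

#' Prevalence filter for pair indicators
#'
#' Removes pairs whose indicator is (almost) constant: a pair is retained
#' exactly when its indicator mean across samples lies in the closed
#' interval `[lo, hi]`. With the defaults this drops pairs that are 0 in
#' more than 80% of samples or 1 in more than 80% of samples; a pair
#' constant in exactly 80% sits on the boundary and is kept.
#'
#' @param pm A [pair_indicators()] matrix.
#' @param lo,hi Prevalence bounds, `0 < lo < hi < 1` (defaults 0.2, 0.8).
#' @return The filtered `PairIndicatorMatrix`.
#' @export
prevalence_filter <- function(pm, lo = 0.2, hi = 0.8) {
  stopifnot(inherits(pm, "PairIndicatorMatrix"))
  if (!(is.numeric(lo) && is.numeric(hi) && 0 < lo && lo < hi && hi < 1))
    stop("need 0 < lo < hi < 1")
  prev <- rowMeans(pm)
  keep <- prev >= lo & prev <= hi
  out <- pm[keep, , drop = FALSE]
  structure(out, pairs = attr(pm, "pairs")[keep, , drop = FALSE],
            class = c("PairIndicatorMatrix", "matrix"))
}

#' @export
print.PairIndicatorMatrix <- function(x, ...) {
  cat(sprintf("PairIndicatorMatrix: %d pairs x %d samples\n",
              nrow(x), ncol(x)))
  invisible(x)
}
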