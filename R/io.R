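# Readers and writers for the tab-separated formats the pipeline exchanges.
# All tables use a header row, tab separators and a plain decimal point.

#' Read a gene-by-sample expression matrix
#'
#' The file's first row holds sample ids and its first column gene symbols.
#' Tumor/normal labels come from a two-column sidecar file
#' (`sample_id<TAB>group`) or from a named `groups` vector.
#'
#' @param path Tab-separated expression file.
#' @param group_file Optional sidecar path assigning `tumor`/`normal` per
#'   sample.
#' @param groups Optional character vector of labels (named by sample id or
#'   in column order); ignored when `group_file` is given.
#' @return An [expression_matrix()].
#' @export
load_expression <- function(path, group_file = NULL, groups = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read_tsv(path)
  if (ncol(df) < 2) stop("expression file needs a gene column plus samples")
  genes <- normalize_symbols(df[[1]])
  mat <- df[, -1, drop = FALSE]
  for (j in seq_along(mat)) {
    col <- mat[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad))
        stop(sprintf("non-numeric cell at row %d, column '%s'",
                     bad[1], names(mat)[j]))
      mat[[j]] <- num
    }
  }
  values <- as.matrix(mat)
  rownames(values) <- genes
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1, ]
    stop(sprintf("missing value at row %d, column '%s'",
                 idx[1], colnames(values)[idx[2]]))
  }
  if (!is.null(group_file)) {
    g <- read_tsv(group_file)
    if (ncol(g) < 2) stop("group sidecar needs columns sample_id and group")
    groups <- stats::setNames(as.character(g[[2]]), as.character(g[[1]]))
  }
  if (is.null(groups))
    stop("tumor/normal labels required: supply `group_file` or `groups`")
  expression_matrix(values, groups)
}

#' Write an expression matrix (and optional group sidecar)
#'
#' @param em An [expression_matrix()].
#' @param path Output path for the matrix.
#' @param group_file Optional path for the `sample_id`/`group` sidecar.
#' @return `path`, invisibly.
#' @export
write_expression <- function(em, path, group_file = NULL) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  df <- data.frame(gene = rownames(em$values), em$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
  if (!is.null(group_file))
    write_tsv(data.frame(sample_id = names(em$group), group = em$group),
              group_file)
  invisible(path)
}

#' Read a clinical/survival table
#'
#' @param path Tab-separated file with columns `sample_id`, `time` (days),
#'   `event` (1 = death, 0 = censored) and optional covariates.
#' @return A [clinical_table()].
#' @export
load_clinical <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  clinical_table(read_tsv(path))
}

#' @rdname load_clinical
#' @param clin A [clinical_table()] to write.
#' @export
write_clinical <- function(clin, path) {
  stopifnot(inherits(clin, "ClinicalTable"))
  write_tsv(as.data.frame(clin), path)
}

#' Read a gene-pair signature
#'
#' Two tab-separated columns: a pair token `FORMER|LATTER` and a real
#' coefficient. A header line is detected and skipped. Coefficients may use
#' either the ASCII hyphen-minus or the typographic Unicode minus sign, as
#' published signature tables sometimes do.
#'
#' @param path Signature file.
#' @return A [signature_model()] with pairs in file order.
#' @export
load_signature <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parse_coef <- function(x) {
    x <- gsub("−", "-", x)
    suppressWarnings(as.numeric(gsub("[[:space:]]", "", x)))
  }
  if (length(lines)) {
    # a header row has no pair token and a non-numeric second field
    first <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    if (length(first) >= 2 && !grepl("|", first[1], fixed = TRUE) &&
        is.na(parse_coef(first[2])))
      lines <- lines[-1]
  }
  if (!length(lines)) stop("no pairs in signature file: ", path)
  former <- latter <- character(length(lines))
  coef <- numeric(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 2)
      stop(sprintf("line %d: expected pair<TAB>coefficient", i))
    genes <- strsplit(fields[1], "|", fixed = TRUE)[[1]]
    if (length(genes) != 2 || !all(nzchar(trimws(genes))))
      stop(sprintf("line %d: malformed pair token '%s'", i, fields[1]))
    former[i] <- genes[1]
    latter[i] <- genes[2]
    coef[i] <- parse_coef(fields[2])
    if (is.na(coef[i]))
      stop(sprintf("line %d: non-numeric coefficient '%s'", i, fields[2]))
  }
  signature_model(data.frame(gene_former = former, gene_latter = latter,
                             stringsAsFactors = FALSE), coef)
}

#' @rdname load_signature
#' @param sig A [signature_model()] to write.
#' @export
write_signature <- function(sig, path) {
  stopifnot(inherits(sig, "SignatureModel"))
  df <- data.frame(pair = pair_token(sig$pairs$gene_former,
                                     sig$pairs$gene_latter),
                   coefficient = sig$coefficients)
  write_tsv(df, path)
}

#' Read a gene list (one symbol per line)
#'
#' @param path Text file, one symbol per line; blanks and `#` comments are
#'   skipped.
#' @param provenance Provenance label for the resulting set.
#' @return A [gene_set()].
#' @export
load_gene_list <- function(path, provenance = "custom") {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x <- x[nzchar(x) & !startsWith(x, "#")]
  gene_set(x, provenance)
}

#' The packaged 17-pair oral-cancer signature
#'
#' Loads the published 17 immune-related gene-pair signature (pair tokens
#' and penalized-Cox coefficients) shipped with the package.
#'
#' @return A [signature_model()] with 17 pairs.
#' @export
irgp_signature <- function() {
  load_signature(system.file("extdata", "irgp_signature_oral17.tsv",
                             package = "irgpair", mustWork = TRUE))
}

#' Packaged immune gene list (synthetic subset)
#'
#' A small, synthetic subset of immune-annotated gene symbols used by the
#' examples and tests. It contains all genes of the packaged signature plus
#' additional well-known immune genes; it is not the full immune-gene
#' repository list.
#'
#' @return A [gene_set()] with provenance `"immune"`.
#' @export
immune_gene_fixture <- function() {
  load_gene_list(system.file("extdata", "immune_genes_synthetic_subset.txt",
                             package = "irgpair", mustWork = TRUE),
                 provenance = "immune")
}
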