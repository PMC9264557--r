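# Minimal Mutation Annotation Format (MAF) handling: reading the standard
# tab-separated table and computing the usual cohort summaries (variant
# classifications, variant types, six-class SNV substitution spectrum on
# the pyrimidine reference frame, per-sample burden, top mutated genes).

MAF_REQUIRED <- c("Hugo_Symbol", "Tumor_Sample_Barcode",
                  "Variant_Classification", "Variant_Type",
                  "Reference_Allele", "Tumor_Seq_Allele2")
MAF_TYPES <- c("SNP", "INS", "DEL", "DNP", "TNP", "ONP")

#' Read a MAF file
#'
#' Expects the standard MAF header (matched case-insensitively); lines
#' starting with `#` are skipped. Only the required columns are kept.
#'
#' @param path MAF file (uncompressed, tab-separated).
#' @return Data.frame of records with the canonical column names.
#' @export
read_maf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                   check.names = FALSE, stringsAsFactors = FALSE)
  lookup <- stats::setNames(names(df), tolower(names(df)))
  out <- list()
  for (col in MAF_REQUIRED) {
    src <- lookup[tolower(col)]
    if (is.na(src)) stop("MAF is missing required column: ", col)
    out[[col]] <- as.character(df[[src]])
  }
  out <- as.data.frame(out, stringsAsFactors = FALSE)
  if (nrow(out)) {
    if (any(!nzchar(out$Hugo_Symbol)) || any(!nzchar(out$Tumor_Sample_Barcode)))
      stop("MAF records must have non-empty gene and sample fields")
    bad <- setdiff(unique(out$Variant_Type), MAF_TYPES)
    if (length(bad))
      stop("unknown Variant_Type value(s): ", paste(bad, collapse = ", "))
  }
  out
}

#' @rdname read_maf
#' @param records MAF records to write.
#' @export
write_maf <- function(records, path) {
  write_tsv(records, path)
}

#' Restrict MAF records to a gene set
#'
#' For a [signature_model()] the relevant set is [signature_genes()] (the
#' union of both members of every pair).
#'
#' @param records MAF records (see [read_maf()]).
#' @param genes Character vector of gene symbols.
#' @return The matching records.
#' @export
restrict_to_genes <- function(records, genes) {
  records[records$Hugo_Symbol %in% normalize_symbols(genes), , drop = FALSE]
}

#' Summarize MAF records
#'
#' Computes: variant-classification counts; variant-type counts; the
#' six-class SNV substitution spectrum, with purine-reference SNPs
#' complemented onto the pyrimidine frame (so e.g. G>A counts as C>T); SNP
#' records whose alleles are not single A/C/G/T bases are tallied as
#' `invalid` with a warning and excluded from the spectrum; per-sample
#' mutation counts with their median and maximum; and per-gene totals
#' (raw mutation count, and the number/fraction of samples mutated — a
#' gene mutated repeatedly in one sample counts once for the frequency,
#' fully for the burden).
#'
#' @param records MAF records (see [read_maf()]).
#' @return A `MutationSummary` list.
#' @export
summarize_mutations <- function(records) {
  cls <- table(records$Variant_Classification)
  typ <- table(records$Variant_Type)
  snv_levels <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  snv <- stats::setNames(integer(6), snv_levels)
  invalid <- 0L
  snp <- records[records$Variant_Type == "SNP", , drop = FALSE]
  if (nrow(snp)) {
    ref <- toupper(snp$Reference_Allele)
    alt <- toupper(snp$Tumor_Seq_Allele2)
    ok <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") &
      ref != alt
    invalid <- sum(!ok)
    if (invalid)
      warning(invalid, " SNP record(s) with non-single-base alleles ",
              "counted as invalid and excluded from SNV classes")
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    purine <- ref %in% c("A", "G")
    ref2 <- ifelse(purine, comp[ref], ref)
    alt2 <- ifelse(purine, comp[alt], alt)
    tab <- table(factor(paste0(ref2, ">", alt2)[ok], levels = snv_levels))
    snv[names(tab)] <- as.integer(tab)
  }
  per_sample <- table(records$Tumor_Sample_Barcode)
  per_sample <- sort(per_sample, decreasing = TRUE)
  n_samples <- length(per_sample)
  gene_burden <- table(records$Hugo_Symbol)
  mut_samples <- tapply(records$Tumor_Sample_Barcode, records$Hugo_Symbol,
                        function(x) length(unique(x)))
  genes <- data.frame(
    gene = names(gene_burden),
    n_mutations = as.integer(gene_burden),
    n_mutated_samples = as.integer(mut_samples[names(gene_burden)]),
    stringsAsFactors = FALSE)
  genes$frequency <- if (n_samples > 0)
    genes$n_mutated_samples / n_samples else numeric(nrow(genes))
  ord <- order(-genes$n_mutated_samples, genes$gene)
  genes <- genes[ord, , drop = FALSE]
  rownames(genes) <- NULL
  structure(list(
    n_records = nrow(records),
    classification = cls,
    type = typ,
    snv_class = snv,
    snv_invalid = invalid,
    per_sample = per_sample,
    per_sample_median = if (n_samples) median(as.numeric(per_sample))
                        else NA_real_,
    per_sample_max = if (n_samples) max(as.numeric(per_sample))
                     else NA_real_,
    genes = genes),
    class = "MutationSummary")
}

#' @export
print.MutationSummary <- function(x, ...) {
  cat(sprintf(
    "MutationSummary: %d records, %d samples, %d genes (median %g, max %g per sample)\n",
    x$n_records, length(x$per_sample), nrow(x$genes),
    x$per_sample_median, x$per_sample_max))
  invisible(x)
}

#' Top mutated genes
#'
#' Genes ranked by the number of mutated samples (descending), ties broken
#' alphabetically, truncated to `n`.
#'
#' @param summary A [summarize_mutations()] result.
#' @param n Maximum genes to return (default 10).
#' @return Data.frame of the top genes (a prefix of the full ranking).
#' @export
top_genes <- function(summary, n = 10) {
  stopifnot(inherits(summary, "MutationSummary"), n >= 1)
  head(summary$genes, n)
}
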