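# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so seeded package functions do not perturb user scripts.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Canonical tabular dialect: tab-separated, header row, plain decimal point.
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
             stringsAsFactors = FALSE, ...)
}

#' Canonical pair token
#'
#' The `FORMER|LATTER` string used to name gene pairs in indicator
#' matrices and signature files.
#'
#' @param gene_former,gene_latter Gene symbols.
#' @return Character vector of pair tokens.
#' @export
pair_token <- function(gene_former, gene_latter) {
  paste0(gene_former, "|", gene_latter)
}

# Gene symbols are case-normalized to uppercase and stripped of surrounding
# whitespace at every entry point.
normalize_symbols <- function(x) toupper(trimws(as.character(x)))

`%||%` <- function(a, b) if (is.null(a)) b else a
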