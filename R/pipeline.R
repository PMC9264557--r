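# End-to-end orchestration: expression + clinical + immune list in,
# signature + risk stratification + reports out, every intermediate
# written as tab-separated text and a machine-readable run log recording
# seeds, thresholds and counts at each stage.

#' Pipeline configuration
#'
#' Validates the paths and tuning parameters of [run_pipeline()] before
#' any computation starts.
#'
#' @param expression Path to the gene-by-sample expression TSV.
#' @param group_file Path to the `sample_id`/`group` sidecar.
#' @param clinical Path to the clinical TSV.
#' @param immune_genes Path to the immune gene list.
#' @param maf Optional path to a MAF file for the mutation summary.
#' @param outdir Output directory (created if absent).
#' @param seed Integer seed for the split and CV fold assignment.
#' @param split_ratio Training fraction (default 0.5).
#' @param pseudocount Log2-CPM pseudocount (> 0).
#' @param lfc_min,p_max DEG thresholds (strict; defaults 1 and 0.05).
#' @param prevalence_lo,prevalence_hi Pair prevalence bounds
#'   (`0 < lo < hi < 1`).
#' @param univariate_alpha Univariate screen threshold (default 0.01).
#' @param cv_folds Cross-validation folds (>= 2; default 10).
#' @param n_lambda,lambda_min_ratio Lambda grid specification.
#' @param roc_horizon ROC horizon in days (default 365).
#' @return A validated `PipelineConfig` list.
#' @export
pipeline_config <- function(expression, group_file, clinical, immune_genes,
                            maf = NULL, outdir = tempfile("irgp_run_"),
                            seed = 1L, split_ratio = 0.5, pseudocount = 1,
                            lfc_min = 1, p_max = 0.05,
                            prevalence_lo = 0.2, prevalence_hi = 0.8,
                            univariate_alpha = 0.01, cv_folds = 10,
                            n_lambda = 100, lambda_min_ratio = 0.01,
                            roc_horizon = 365) {
  if (!(prevalence_lo > 0 && prevalence_lo < prevalence_hi &&
        prevalence_hi < 1))
    stop("need 0 < prevalence_lo < prevalence_hi < 1")
  if (cv_folds < 2) stop("`cv_folds` must be >= 2")
  if (!(split_ratio > 0 && split_ratio < 1))
    stop("`split_ratio` must be in (0, 1)")
  stopifnot(pseudocount > 0, lfc_min > 0, p_max > 0, univariate_alpha > 0,
            roc_horizon > 0, n_lambda >= 2,
            lambda_min_ratio > 0, lambda_min_ratio < 1)
  structure(list(expression = expression, group_file = group_file,
                 clinical = clinical, immune_genes = immune_genes,
                 maf = maf, outdir = outdir, seed = as.integer(seed),
                 split_ratio = split_ratio, pseudocount = pseudocount,
                 lfc_min = lfc_min, p_max = p_max,
                 prevalence_lo = prevalence_lo,
                 prevalence_hi = prevalence_hi,
                 univariate_alpha = univariate_alpha, cv_folds = cv_folds,
                 n_lambda = n_lambda, lambda_min_ratio = lambda_min_ratio,
                 roc_horizon = roc_horizon),
            class = "PipelineConfig")
}

#' Run the full gene-pair signature pipeline
#'
#' Stages: load inputs; log2-CPM normalization and tumor-vs-normal
#' differential expression; intersection with the immune gene list;
#' candidate pair construction and prevalence filtering; a seeded 1:1
#' training/test split; univariate Cox screening on the training set;
#' cross-validated lasso Cox fitting; risk scoring; ROC-based cutoff
#' selection on the training set (frozen for the test set); per-set
#' survival comparison; multivariate independence testing; and, when a
#' MAF is configured, a mutation summary of the signature genes in the
#' high-risk samples. Any stage failure aborts with the stage name and
#' cause.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the result bundle: every stage's main object plus
#'   the path of each written file and the run log.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  log <- list(seed = config$seed,
              thresholds = config[c("split_ratio", "pseudocount", "lfc_min",
                                    "p_max", "prevalence_lo",
                                    "prevalence_hi", "univariate_alpha",
                                    "cv_folds", "n_lambda",
                                    "lambda_min_ratio", "roc_horizon")],
              counts = list(),
              notes = c("differential expression: Welch t-test on log2-CPM"))
  out <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  emit <- function(df, file) {
    path <- file.path(config$outdir, file)
    write_tsv(df, path)
    path
  }

  stage("load", {
    out$expression <- load_expression(config$expression, config$group_file)
    out$clinical <- load_clinical(config$clinical)
    out$immune <- load_gene_list(config$immune_genes, provenance = "immune")
    log$counts$n_genes <- nrow(out$expression$values)
    log$counts$n_tumor <- sum(out$expression$group == "tumor")
    log$counts$n_normal <- sum(out$expression$group == "normal")
    log$counts$n_immune_list <- length(out$immune)
  })

  stage("differential_expression", {
    norm <- normalize_log2cpm(out$expression, config$pseudocount)
    out$de_table <- differential_expression(norm)
    out$degs <- filter_degs(out$de_table, config$lfc_min, config$p_max)
    out$immune_degs <- intersect_immune(out$degs, out$immune)
    out$normalized <- norm
    emit(out$de_table, "de_table.tsv")
    emit(data.frame(gene = as.character(out$degs)), "degs.tsv")
    emit(data.frame(gene = as.character(out$immune_degs)),
         "immune_degs.tsv")
    log$counts$n_deg <- length(out$degs)
    log$counts$n_immune_deg <- length(out$immune_degs)
  })

  stage("candidate_pairs", {
    pairs <- enumerate_pairs(out$immune_degs)
    tumor_ids <- names(out$expression$group)[out$expression$group == "tumor"]
    pm_all <- pair_indicators(out$expression, pairs, samples = tumor_ids)
    out$pm <- prevalence_filter(pm_all, config$prevalence_lo,
                                config$prevalence_hi)
    emit(data.frame(pair = rownames(out$pm), out$pm, check.names = FALSE),
         "pair_indicators.tsv")
    log$counts$n_pairs_enumerated <- nrow(pm_all)
    log$counts$n_pairs_candidate <- nrow(out$pm)
  })

  stage("split", {
    surv_ids <- intersect(colnames(out$pm), out$clinical$sample_id)
    clin <- as.data.frame(out$clinical)
    clin <- clinical_table(clin[clin$sample_id %in% surv_ids, ])
    out$split <- split_cohort(clin, config$split_ratio, config$seed)
    out$clin_used <- clin
    emit(data.frame(sample_id = c(out$split$train, out$split$test),
                    set = rep(c("train", "test"),
                              c(length(out$split$train),
                                length(out$split$test)))),
         "split.tsv")
    log$counts$n_train <- length(out$split$train)
    log$counts$n_test <- length(out$split$test)
  })

  clin_of <- function(ids) {
    df <- as.data.frame(out$clin_used)
    clinical_table(df[match(ids, df$sample_id), ])
  }

  stage("univariate_screen", {
    tr <- clin_of(out$split$train)
    scr <- univariate_screen(out$pm[, out$split$train, drop = FALSE],
                             tr$time, tr$event, config$univariate_alpha)
    out$screen <- scr
    emit(scr$table, "univariate_screen.tsv")
    log$counts$n_screened <- length(scr$selected)
    if (length(scr$selected) < 2)
      stop("fewer than 2 pairs passed the univariate screen")
  })

  stage("lasso_fit", {
    tr <- clin_of(out$split$train)
    Xtr <- t(out$pm[out$screen$selected, out$split$train, drop = FALSE])
    out$cv <- cv_select(Xtr, tr$time, tr$event, folds = config$cv_folds,
                        seed = config$seed, n_lambda = config$n_lambda,
                        lambda_min_ratio = config$lambda_min_ratio)
    nz <- out$cv$nonzero
    if (length(nz) == 0) stop("lasso selected an empty model")
    gp <- do.call(rbind, strsplit(nz, "|", fixed = TRUE))
    out$signature <- signature_model(
      data.frame(gene_former = gp[, 1], gene_latter = gp[, 2],
                 stringsAsFactors = FALSE),
      out$cv$coefficients[nz])
    emit(data.frame(lambda = out$cv$lambda, cvm = out$cv$cvm,
                    cvse = out$cv$cvse, df = out$cv$path$df),
         "cv_path.tsv")
    write_signature(out$signature,
                    file.path(config$outdir, "signature.tsv"))
    log$counts$n_signature_pairs <- length(nz)
    log$counts$lambda_min <- out$cv$lambda_min
  })

  stage("risk_stratification", {
    out$scores <- risk_score(out$signature, out$pm, em = out$expression)
    tr_scores <- out$scores[out$split$train]
    te_scores <- out$scores[out$split$test]
    out$roc <- one_year_roc(tr_scores, out$clin_used, config$roc_horizon)
    cutoff <- select_cutoff(out$roc)
    out$signature$cutoff <- cutoff
    out$strat_train <- stratify_and_compare(tr_scores, cutoff, out$clin_used)
    out$strat_test <- stratify_and_compare(te_scores, cutoff, out$clin_used)
    emit(rbind(cbind(out$strat_train$assignment, set = "train"),
               cbind(out$strat_test$assignment, set = "test")),
         "risk_assignment.tsv")
    emit(data.frame(threshold = out$roc$thresholds,
                    sensitivity = out$roc$sensitivity,
                    specificity = out$roc$specificity), "roc.tsv")
    emit(data.frame(
      set = c("train", "test"),
      auc = c(out$roc$auc, NA),
      cutoff = cutoff,
      logrank_p = c(out$strat_train$logrank$p, out$strat_test$logrank$p),
      death_fraction_high = c(out$strat_train$death_fraction["high"],
                              out$strat_test$death_fraction["high"]),
      death_fraction_low = c(out$strat_train$death_fraction["low"],
                             out$strat_test$death_fraction["low"])),
      "survival_comparison.tsv")
    log$counts$cutoff <- cutoff
    log$counts$train_auc <- out$roc$auc
  })

  stage("multivariate_independence", {
    tr_scores <- out$scores[out$split$train]
    out$forest <- multivariate_independence(tr_scores, out$clin_used)
    emit(out$forest, "forest_table.tsv")
  })

  if (!is.null(config$maf)) stage("mutation_summary", {
    maf <- read_maf(config$maf)
    high_ids <- c(
      out$strat_train$assignment$sample_id[
        out$strat_train$assignment$group == "high"],
      out$strat_test$assignment$sample_id[
        out$strat_test$assignment$group == "high"])
    maf <- maf[maf$Tumor_Sample_Barcode %in% high_ids, , drop = FALSE]
    maf <- restrict_to_genes(maf, signature_genes(out$signature))
    out$mutation <- summarize_mutations(maf)
    emit(out$mutation$genes, "mutation_genes.tsv")
    emit(data.frame(class = names(out$mutation$snv_class),
                    count = as.integer(out$mutation$snv_class)),
         "mutation_snv_class.tsv")
    emit(data.frame(classification = names(out$mutation$classification),
                    count = as.integer(out$mutation$classification)),
         "mutation_classification.tsv")
    log$counts$n_mutation_records <- out$mutation$n_records
  })

  log_path <- file.path(config$outdir, "run_log.json")
  jsonlite::write_json(log, log_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  out$log <- log
  out$outdir <- config$outdir
  invisible(out)
}
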