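# Synthetic cohort generator. Emulates the statistical structure the
# pair-signature analysis assumes: tumor/normal expression with planted
# differential genes, survival times from a proportional-hazards model
# whose covariates are the binary pair-order indicators, independent
# exponential censoring with an administrative cutoff, simple clinical
# covariates, and a Poisson mutation process written as MAF. A truth set
# records every planted effect so recovery can be tested.

#' Simulation configuration
#'
#' Defaults mirror the cohort the signature analyses target: 390 tumor and
#' 32 normal samples, log-normal expression, 100 planted differential
#' genes at log2FC 2, five planted prognostic pairs at |log hazard ratio|
#' 1, an exponential baseline with rates chosen to censor roughly 50-70%
#' of samples under a 5-year administrative cutoff.
#'
#' @param n_tumor,n_normal Sample counts.
#' @param n_genes Total genes simulated.
#' @param immune_fraction Share of genes labeled immune (the planted pairs
#'   draw from this subset).
#' @param n_de_genes Number of planted tumor/normal differential genes.
#' @param de_log2fc Planted mean log2 shift in tumor samples (sign
#'   alternates across planted genes).
#' @param planted_pairs Data.frame `gene1`, `gene2`, `beta` (log hazard
#'   ratio per pair indicator), or `NULL` to plant `n_planted_pairs`
#'   default pairs.
#' @param n_planted_pairs Planted pair count when `planted_pairs` is NULL.
#' @param pair_beta Absolute log hazard ratio for default planted pairs
#'   (signs alternate).
#' @param baseline_hazard Exponential event rate per day.
#' @param censor_rate Exponential censoring rate per day (0 = none).
#' @param admin_censor_time Administrative cutoff in days.
#' @param noise_sd Log2-scale expression dispersion.
#' @param age_effect Log hazard ratio per year of age (default 0: clinical
#'   covariates independent of the hazard; set > 0 as a positive control).
#' @param mutation_rate Poisson mean mutation count per tumor sample.
#' @param seed Integer seed governing all generators.
#' @return A validated `SimulationConfig` list.
#' @export
simulation_config <- function(n_tumor = 390, n_normal = 32, n_genes = 1000,
                              immune_fraction = 0.25, n_de_genes = 100,
                              de_log2fc = 2, planted_pairs = NULL,
                              n_planted_pairs = 5, pair_beta = 1,
                              baseline_hazard = 5.5e-4, censor_rate = 8e-4,
                              admin_censor_time = 1825, noise_sd = 1,
                              age_effect = 0, mutation_rate = 1,
                              seed = 1L) {
  stopifnot(n_tumor >= 1, n_normal >= 0, n_genes >= 2,
            immune_fraction > 0, immune_fraction <= 1,
            n_de_genes >= 0, n_de_genes <= n_genes,
            baseline_hazard > 0, censor_rate >= 0, admin_censor_time > 0,
            noise_sd >= 0, mutation_rate >= 0)
  n_immune <- max(2L, ceiling(n_genes * immune_fraction))
  genes <- sprintf("GENE%04d", seq_len(n_genes))
  immune_genes <- genes[seq_len(n_immune)]
  if (is.null(planted_pairs)) {
    n_planted_pairs <- min(n_planted_pairs, floor(n_immune / 2))
    if (n_planted_pairs > 0) {
      g1 <- immune_genes[2 * seq_len(n_planted_pairs) - 1]
      g2 <- immune_genes[2 * seq_len(n_planted_pairs)]
      beta <- pair_beta * (-1)^(seq_len(n_planted_pairs) + 1)
      planted_pairs <- data.frame(gene1 = g1, gene2 = g2, beta = beta,
                                  stringsAsFactors = FALSE)
    } else {
      planted_pairs <- data.frame(gene1 = character(), gene2 = character(),
                                  beta = numeric())
    }
  } else {
    planted_pairs <- as.data.frame(planted_pairs, stringsAsFactors = FALSE)
    stopifnot(all(c("gene1", "gene2", "beta") %in% names(planted_pairs)))
    if (any(planted_pairs$gene1 == planted_pairs$gene2))
      stop("planted pair genes must be distinct")
    unknown <- setdiff(c(planted_pairs$gene1, planted_pairs$gene2),
                       immune_genes)
    if (length(unknown))
      stop("planted pair gene(s) not in the immune-labeled set: ",
           paste(unknown, collapse = ", "))
  }
  structure(list(n_tumor = n_tumor, n_normal = n_normal, n_genes = n_genes,
                 immune_fraction = immune_fraction, n_de_genes = n_de_genes,
                 de_log2fc = de_log2fc, planted_pairs = planted_pairs,
                 baseline_hazard = baseline_hazard,
                 censor_rate = censor_rate,
                 admin_censor_time = admin_censor_time,
                 noise_sd = noise_sd, age_effect = age_effect,
                 mutation_rate = mutation_rate, seed = as.integer(seed),
                 genes = genes, immune_genes = immune_genes),
            class = "SimulationConfig")
}

#' Simulate tumor/normal expression with planted effects
#'
#' Log-normal expression: `log2(x) ~ Normal(mu_g + group_effect,
#' noise_sd)` with gene baselines `mu_g ~ Uniform(3, 10)`. Planted
#' differential genes receive the signed `de_log2fc` shift in tumor
#' samples. Genes of every planted pair share one baseline mean (so the
#' pair indicator is balanced before the hazard acts) and receive one
#' common tumor shift of magnitude `de_log2fc`, making them differential
#' without disturbing their within-sample order. The truth set
#' records the planted differential genes and, per tumor sample, the
#' realized pair indicators `I(x_gene1 > x_gene2)`.
#'
#' @param cfg A [simulation_config()].
#' @return List: `expression` (an [expression_matrix()]), `truth` (list
#'   `de_genes`, `pairs`, `indicators` pairs x tumor samples).
#' @export
simulate_expression <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  with_seed(cfg$seed, {
    n <- cfg$n_tumor + cfg$n_normal
    samples <- c(sprintf("TUMOR%03d", seq_len(cfg$n_tumor)),
                 if (cfg$n_normal > 0)
                   sprintf("NORMAL%03d", seq_len(cfg$n_normal)))
    group <- rep(c("tumor", "normal"), c(cfg$n_tumor, cfg$n_normal))
    mu <- runif(cfg$n_genes, 3, 10)
    names(mu) <- cfg$genes
    pp <- cfg$planted_pairs
    if (nrow(pp)) mu[pp$gene2] <- mu[pp$gene1]
    # planted DE genes come after the pair genes so the two plantings
    # never collide
    pair_genes <- unique(c(pp$gene1, pp$gene2))
    de_pool <- setdiff(cfg$genes, pair_genes)
    de_genes <- utils::head(de_pool, cfg$n_de_genes)
    de_sign <- (-1)^(seq_along(de_genes) + 1)
    log2x <- matrix(rnorm(cfg$n_genes * n, mean = mu, sd = cfg$noise_sd),
                    nrow = cfg$n_genes, ncol = n,
                    dimnames = list(cfg$genes, samples))
    if (length(de_genes) && cfg$n_tumor > 0)
      log2x[de_genes, group == "tumor"] <-
        log2x[de_genes, group == "tumor"] + de_sign * cfg$de_log2fc
    # planted pair genes are differential too (both members of a pair get
    # the same tumor shift, which leaves the pair indicator untouched);
    # this embeds the prognostic pairs inside the immune-DEG candidate
    # space, as in the real analysis
    pg_shift <- numeric(0)
    if (nrow(pp) && cfg$de_log2fc != 0 && cfg$n_tumor > 0) {
      pair_sign <- (-1)^(seq_len(nrow(pp)) + 1)
      pg <- unique(c(rbind(pp$gene1, pp$gene2)))
      pg_shift <- vapply(pg, function(g) {
        k <- which(pp$gene1 == g | pp$gene2 == g)[1]
        pair_sign[k] * cfg$de_log2fc
      }, numeric(1))
      log2x[pg, group == "tumor"] <-
        log2x[pg, group == "tumor"] + pg_shift
    }
    em <- expression_matrix(2^log2x, stats::setNames(group, samples))
    tumor_ids <- samples[group == "tumor"]
    ind <- if (nrow(pp)) {
      (em$values[pp$gene1, tumor_ids, drop = FALSE] >
       em$values[pp$gene2, tumor_ids, drop = FALSE]) * 1L
    } else {
      matrix(0L, 0, length(tumor_ids),
             dimnames = list(NULL, tumor_ids))
    }
    if (nrow(pp)) rownames(ind) <- pair_token(pp$gene1, pp$gene2)
    de_truth <- data.frame(gene = de_genes,
                           log2fc = de_sign * cfg$de_log2fc,
                           stringsAsFactors = FALSE)
    if (length(pg_shift))
      de_truth <- rbind(de_truth,
                        data.frame(gene = names(pg_shift),
                                   log2fc = unname(pg_shift),
                                   stringsAsFactors = FALSE))
    truth <- list(de_genes = de_truth, pairs = pp, indicators = ind)
    list(expression = em, truth = truth)
  })
}

#' Simulate survival and clinical covariates under proportional hazards
#'
#' Event times are exponential with rate `baseline_hazard * exp(lp)` where
#' the linear predictor `lp = sum_k beta_k * indicator_k` (plus
#' `age_effect * (age - mean age)` when configured). Censoring times are
#' exponential with `censor_rate`, truncated at the administrative cutoff;
#' `time = min(T, C, admin)` and `event = I(T <= min(C, admin))`. Clinical
#' covariates are drawn from simple categorical/uniform laws independent
#' of expression.
#'
#' @param cfg A [simulation_config()].
#' @param indicators Planted-pair indicator matrix over tumor samples
#'   (from [simulate_expression()]; rows must match the planted pairs).
#' @return List: `clinical` (a [clinical_table()] for the tumor samples)
#'   and `truth` (`linear_predictor` per sample).
#' @export
simulate_survival <- function(cfg, indicators) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  pp <- cfg$planted_pairs
  if (nrow(pp) != nrow(indicators))
    stop("indicator rows must match the planted pairs")
  samples <- colnames(indicators)
  if (is.null(samples) || length(samples) != cfg$n_tumor)
    stop("indicators must cover every tumor sample")
  with_seed(cfg$seed + 1L, {
    n <- length(samples)
    lp <- if (nrow(pp)) drop(crossprod(indicators, pp$beta)) else rep(0, n)
    age <- round(pmin(pmax(rnorm(n, 61, 12), 25), 90))
    # the recorded truth is the pair part only; an age effect (positive
    # control for the independence analysis) enters the hazard separately
    lp_hazard <- lp
    if (cfg$age_effect != 0)
      lp_hazard <- lp_hazard + cfg$age_effect * (age - mean(age))
    rate <- cfg$baseline_hazard * exp(lp_hazard)
    t_event <- rexp(n, rate)
    t_cens <- if (cfg$censor_rate > 0) rexp(n, cfg$censor_rate)
              else rep(Inf, n)
    t_cens <- pmin(t_cens, cfg$admin_censor_time)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
    time <- pmax(time, 1 / 24)  # follow-up is strictly positive
    clin <- clinical_table(data.frame(
      sample_id = samples, time = time, event = event, age = age,
      gender = sample(c("male", "female"), n, TRUE, prob = c(0.7, 0.3)),
      grade = sample(paste0("G", 1:4), n, TRUE,
                     prob = c(0.10, 0.60, 0.25, 0.05)),
      stage = sample(c("I", "II", "III", "IV"), n, TRUE,
                     prob = c(0.10, 0.15, 0.20, 0.55)),
      t_stage = sample(paste0("T", 1:4), n, TRUE,
                       prob = c(0.15, 0.30, 0.25, 0.30)),
      n_stage = sample(paste0("N", 0:3), n, TRUE,
                       prob = c(0.45, 0.20, 0.30, 0.05)),
      stringsAsFactors = FALSE))
    list(clinical = clin,
         truth = list(linear_predictor = stats::setNames(lp, samples)))
  })
}

#' Simulate a somatic mutation table (MAF)
#'
#' Per tumor sample the mutation count is Poisson(`mutation_rate`); genes
#' are drawn proportional to `gene_weights`; the variant type, its
#' classification and (for SNPs) the substitution class come from
#' configurable categorical laws. SNP alleles are written on a random
#' strand so summaries must collapse onto the pyrimidine reference frame.
#'
#' @param cfg A [simulation_config()].
#' @param gene_weights Named non-negative vector of relative mutation
#'   propensities (default: uniform over the immune-labeled genes).
#' @param type_probs Named probabilities over `SNP`, `INS`, `DEL`.
#' @param snv_class_probs Named probabilities over the six pyrimidine-frame
#'   substitution classes.
#' @return Data.frame of MAF records (standard column names).
#' @export
simulate_maf <- function(cfg, gene_weights = NULL,
                         type_probs = c(SNP = 1, INS = 0, DEL = 0),
                         snv_class_probs = c("C>A" = 0.12, "C>G" = 0.08,
                                             "C>T" = 0.50, "T>A" = 0.07,
                                             "T>C" = 0.15, "T>G" = 0.08)) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  if (is.null(gene_weights))
    gene_weights <- stats::setNames(rep(1, length(cfg$immune_genes)),
                                    cfg$immune_genes)
  if (any(gene_weights < 0) || all(gene_weights == 0))
    stop("gene weights must be non-negative and not all zero")
  gene_weights <- gene_weights[gene_weights > 0]
  type_probs <- type_probs / sum(type_probs)
  snv_class_probs <- snv_class_probs / sum(snv_class_probs)
  class_by_type <- list(
    SNP = c(Missense_Mutation = 0.62, Nonsense_Mutation = 0.12,
            Splice_Site = 0.10, Silent = 0.16),
    INS = c(Frame_Shift_Ins = 0.8, In_Frame_Ins = 0.2),
    DEL = c(Frame_Shift_Del = 0.8, In_Frame_Del = 0.2))
  with_seed(cfg$seed + 2L, {
    samples <- sprintf("TUMOR%03d", seq_len(cfg$n_tumor))
    counts <- rpois(cfg$n_tumor, cfg$mutation_rate)
    total <- sum(counts)
    if (total == 0)
      return(data.frame(Hugo_Symbol = character(),
                        Tumor_Sample_Barcode = character(),
                        Variant_Classification = character(),
                        Variant_Type = character(),
                        Reference_Allele = character(),
                        Tumor_Seq_Allele2 = character(),
                        stringsAsFactors = FALSE))
    barcode <- rep(samples, counts)
    gene <- sample(names(gene_weights), total, TRUE, prob = gene_weights)
    vtype <- sample(names(type_probs), total, TRUE, prob = type_probs)
    vclass <- vapply(vtype, function(tp)
      sample(names(class_by_type[[tp]]), 1,
             prob = class_by_type[[tp]]), character(1))
    ref <- alt <- character(total)
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    is_snp <- vtype == "SNP"
    if (any(is_snp)) {
      cls <- sample(names(snv_class_probs), sum(is_snp), TRUE,
                    prob = snv_class_probs)
      r <- substr(cls, 1, 1); a <- substr(cls, 3, 3)
      flip <- runif(sum(is_snp)) < 0.5  # random strand of report
      ref[is_snp] <- ifelse(flip, comp[r], r)
      alt[is_snp] <- ifelse(flip, comp[a], a)
    }
    ref[vtype == "INS"] <- "-"
    alt[vtype == "INS"] <- "A"
    ref[vtype == "DEL"] <- "A"
    alt[vtype == "DEL"] <- "-"
    data.frame(Hugo_Symbol = gene, Tumor_Sample_Barcode = barcode,
               Variant_Classification = unname(vclass),
               Variant_Type = vtype, Reference_Allele = ref,
               Tumor_Seq_Allele2 = alt, row.names = NULL,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a full cohort
#'
#' Convenience wrapper chaining [simulate_expression()] and
#' [simulate_survival()]; the truth set additionally records the
#' per-sample true linear predictor (which equals `sum beta * indicator`
#' exactly).
#'
#' @param cfg A [simulation_config()].
#' @return List: `expression`, `clinical`, `truth` (`de_genes`, `pairs`,
#'   `indicators`, `linear_predictor`).
#' @export
simulate_cohort <- function(cfg) {
  ex <- simulate_expression(cfg)
  sv <- simulate_survival(cfg, ex$truth$indicators)
  list(expression = ex$expression, clinical = sv$clinical,
       truth = c(ex$truth, sv$truth))
}
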