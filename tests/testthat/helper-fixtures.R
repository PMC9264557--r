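# Shared in-code fixtures. Everything is built programmatically; nothing
# is read from disk except the packaged signature and gene-list files.

# 3 genes x 4 samples, two groups
toy_expression <- function() {
  vals <- matrix(c(10, 30, 60,
                   20, 20, 60,
                   5, 45, 50,
                   12, 28, 60),
                 nrow = 3,
                 dimnames = list(c("GA", "GB", "GC"),
                                 c("T1", "T2", "N1", "N2")))
  expression_matrix(vals, c(T1 = "tumor", T2 = "tumor",
                            N1 = "normal", N2 = "normal"))
}

# deterministic 20-sample survival fixture with tied event times and two
# covariates (one binary, one continuous)
surv_fixture_20 <- function() {
  list(
    time = c(5, 5, 8, 10, 10, 10, 12, 15, 15, 18,
             20, 22, 22, 25, 30, 30, 34, 40, 45, 50),
    event = c(1, 1, 0, 1, 1, 0, 1, 0, 1, 1,
              0, 1, 1, 1, 0, 1, 1, 0, 1, 1),
    x = cbind(grp = c(1, 0, 1, 1, 0, 0, 1, 0, 1, 0,
                      1, 0, 1, 1, 0, 1, 0, 0, 1, 0),
              age = c(61, 54, 70, 66, 48, 59, 72, 50, 63, 67,
                      55, 62, 71, 58, 49, 64, 69, 53, 60, 65)))
}

# cohort with survival driven only by planted pair indicators
quick_cohort <- function(seed, n_tumor = 300, n_pairs = 5, beta = 1,
                         ...) {
  cfg <- simulation_config(n_tumor = n_tumor, n_normal = 4, n_genes = 40,
                           immune_fraction = 0.5, n_de_genes = 0,
                           n_planted_pairs = n_pairs, pair_beta = beta,
                           seed = seed, ...)
  simulate_cohort(cfg)
}

# null survival data: exponential event times, independent censoring
null_surv <- function(n, baseline = 5.5e-4, censor = 8e-4, admin = 1825) {
  te <- rexp(n, baseline)
  tc <- pmin(rexp(n, censor), admin)
  list(time = pmax(pmin(te, tc), 1e-6), event = as.integer(te <= tc))
}

# independent naive Cox log partial likelihood (no tied event times):
# direct risk-set summation, used as a brute-force oracle
naive_cox_loglik <- function(eta, time, event) {
  s <- 0
  for (i in which(event == 1)) {
    rs <- time >= time[i]
    s <- s + eta[i] - log(sum(exp(eta[rs])))
  }
  s
}

# 10-record MAF toy with fully hand-countable composition
toy_maf <- function() {
  data.frame(
    Hugo_Symbol = c("TNC", "TNC", "TNC", "TP53", "TP53", "MUC16",
                    "MUC16", "TNC", "TP53", "TNC"),
    Tumor_Sample_Barcode = c("S1", "S1", "S2", "S2", "S3", "S3",
                             "S3", "S4", "S4", "S4"),
    Variant_Classification = c("Missense_Mutation", "Missense_Mutation",
                               "Nonsense_Mutation", "Missense_Mutation",
                               "Splice_Site", "Frame_Shift_Del",
                               "Missense_Mutation", "Silent",
                               "Missense_Mutation", "In_Frame_Ins"),
    Variant_Type = c("SNP", "SNP", "SNP", "SNP", "SNP", "DEL",
                     "SNP", "SNP", "SNP", "INS"),
    Reference_Allele = c("C", "G", "A", "T", "G", "A", "C", "TT", "G",
                         "-"),
    Tumor_Seq_Allele2 = c("T", "A", "C", "C", "C", "-", "A", "A", "T",
                          "A"),
    stringsAsFactors = FALSE)
}
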