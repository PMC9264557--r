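make_clin <- function(time, event, ids = NULL) {
  ids <- ids %||% paste0("s", seq_along(time))
  clinical_table(data.frame(sample_id = ids, time = time, event = event))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("cohort splitting reproduces the published 194/193 arithmetic", {
  clin <- make_clin(rep(100, 387), rep(1, 387))
  sp <- split_cohort(clin, ratio = 0.5, seed = 1)
  expect_identical(sort(c(length(sp$train), length(sp$test))),
                   c(193L, 194L))
  expect_length(intersect(sp$train, sp$test), 0L)

  sp10 <- split_cohort(make_clin(rep(10, 10), rep(1, 10)), seed = 2)
  expect_identical(c(length(sp10$train), length(sp10$test)), c(5L, 5L))

  expect_identical(split_cohort(clin, seed = 7), split_cohort(clin, seed = 7))
  expect_error(split_cohort(make_clin(rep(1, 9), rep(1, 9))), "fewer than 10")

  # samples without survival information are excluded first
  df <- data.frame(sample_id = paste0("s", 1:20),
                   time = c(rep(50, 18), NA, 60),
                   event = c(rep(1, 18), 1, NA))
  sp2 <- split_cohort(clinical_table(df), seed = 3)
  expect_length(c(sp2$train, sp2$test), 18L)
})

test_that("risk scores are the coefficient-weighted indicator sums", {
  sig <- irgp_signature()
  tok <- pair_token(sig$pairs$gene_former, sig$pairs$gene_latter)
  ones <- matrix(1L, 17, 3, dimnames = list(tok, c("a", "b", "c")))
  zeros <- matrix(0L, 17, 3, dimnames = list(tok, c("a", "b", "c")))
  expect_equal(unname(risk_score(sig, ones)),
               rep(sum(sig$coefficients), 3))
  expect_equal(unname(risk_score(sig, zeros)), rep(0, 3))

  one <- signature_model(data.frame(gene_former = "A", gene_latter = "B"),
                         0.5)
  pm1 <- matrix(c(1L, 0L), 1, 2, dimnames = list("A|B", c("x", "y")))
  expect_equal(risk_score(one, pm1), c(x = 0.5, y = 0))
  # linearity in the coefficients
  two <- signature_model(one$pairs, 1.2)
  sum_sig <- signature_model(one$pairs, 1.7)
  expect_equal(risk_score(one, pm1) + risk_score(two, pm1),
               risk_score(sum_sig, pm1))
  expect_error(risk_score(one, matrix(0L, 1, 1,
                                      dimnames = list("C|D", "x"))),
               "A\\|B")
})

test_that("the 1-year ROC handles labels, exclusions and equals pair counting", {
  # perfect ordering: positives all score above negatives
  scores <- c(a = 5, b = 4, c = 3, d = 2, e = 1, f = 0)
  clin <- make_clin(c(100, 200, 300, 300, 500, 600),
                    c(1, 1, 1, 0, 0, 0), names(scores))
  roc <- one_year_roc(scores, clin, horizon = 365)
  expect_equal(roc$auc, 1)
  expect_identical(roc$n_pos, 3L)
  # d is censored before the horizon: excluded; e, f followed beyond it
  expect_identical(roc$n_neg, 2L)
  expect_identical(roc$n_excluded, 1L)

  # 6-sample toy: AUC equals the exhaustive concordant-pair fraction
  sc2 <- c(a = 1.0, b = 3.0, c = 2.0, d = 2.0, e = 0.5, f = 2.5)
  clin2 <- make_clin(c(90, 180, 270, 400, 500, 600),
                     c(1, 1, 1, 0, 1, 0), names(sc2))
  roc2 <- one_year_roc(sc2, clin2, horizon = 365)
  pos <- sc2[c("a", "b", "c")]; neg <- sc2[c("d", "e", "f")]
  conc <- 0
  for (p in pos) for (q in neg)
    conc <- conc + (p > q) + 0.5 * (p == q)
  expect_equal(roc2$auc, conc / (length(pos) * length(neg)))
  # curve is monotone along thresholds
  expect_true(all(diff(roc2$sensitivity) <= 0))
  expect_true(all(diff(roc2$specificity) >= 0))

  expect_error(one_year_roc(scores, make_clin(rep(500, 6), rep(0, 6),
                                              names(scores))),
               "no positives")
})

test_that("the null-score 1-year AUC concentrates on 0.5", {
  withr::with_seed(47, {
    n <- 1000
    s0 <- null_surv(n)
    scores <- stats::setNames(rnorm(n), paste0("s", 1:n))
    clin <- make_clin(s0$time, s0$event, names(scores))
    expect_lt(abs(one_year_roc(scores, clin)$auc - 0.5), 0.05)
  })
})

test_that("the Youden cutoff matches exhaustive search and handles degeneracy", {
  scores <- c(a = 5, b = 4, c = 3, d = 2, e = 1, f = 0)
  clin <- make_clin(c(100, 200, 300, 300, 500, 600),
                    c(1, 1, 1, 0, 0, 0), names(scores))
  roc <- one_year_roc(scores, clin)
  cut <- select_cutoff(roc)
  # perfect separation: cutoff strictly between the two groups
  expect_gt(cut, max(c(1, 0)))  # negatives at risk horizon: e=1, f=0
  expect_lt(cut, min(c(5, 4, 3)))

  sc2 <- c(a = 1.0, b = 3.0, c = 2.0, d = 2.0, e = 0.5, f = 2.5)
  clin2 <- make_clin(c(90, 180, 270, 400, 500, 600),
                     c(1, 1, 1, 0, 1, 0), names(sc2))
  roc2 <- one_year_roc(sc2, clin2)
  cut2 <- select_cutoff(roc2)
  pos <- sc2[c("a", "b", "c")]; neg <- sc2[c("d", "e", "f")]
  brute_j <- function(thr) mean(pos > thr) + mean(neg <= thr) - 1
  cand <- roc2$thresholds[is.finite(roc2$thresholds)]
  best <- cand[which.max(vapply(cand, brute_j, numeric(1)))]
  expect_equal(cut2, best)

  flat <- stats::setNames(rep(2, 6), names(sc2))
  rocf <- one_year_roc(flat, clin2)
  expect_warning(cutf <- select_cutoff(rocf), "degenerate")
  expect_equal(cutf, 2)
})

test_that("stratification separates risk groups in the planted simulation", {
  coh <- quick_cohort(seed = 51, n_tumor = 500)
  scores <- coh$truth$linear_predictor
  roc <- one_year_roc(scores, coh$clinical)
  cut <- select_cutoff(roc)
  strat <- stratify_and_compare(scores, cut, coh$clinical)
  expect_gt(strat$death_fraction["high"], strat$death_fraction["low"])
  expect_lt(strat$logrank$p, 0.001)
  expect_identical(unname(strat$n["high"] + strat$n["low"]), 500L)
  # a cutoff below every score leaves no low-risk group
  expect_error(stratify_and_compare(scores, min(scores) - 1, coh$clinical),
               "cutoff")
})

test_that("risk analysis is invariant to monotone transforms", {
  coh <- quick_cohort(seed = 57, n_tumor = 200)
  em <- coh$expression
  pp <- coh$truth$pairs
  pairs <- enumerate_pairs(unique(c(pp$gene1, pp$gene2)))
  pm <- pair_indicators(em, pairs,
                        samples = colnames(coh$truth$indicators))
  sig <- signature_model(data.frame(gene_former = pp$gene1,
                                    gene_latter = pp$gene2), pp$beta)
  scores <- risk_score(sig, pm)
  # monotone per-sample transform of expression: identical indicators,
  # identical scores, hence identical downstream results
  em2 <- expression_matrix(em$values^2, em$group)
  pm2 <- pair_indicators(em2, pairs,
                         samples = colnames(coh$truth$indicators))
  expect_identical(unclass(pm2)[, ], unclass(pm)[, ])
  expect_identical(risk_score(sig, pm2), scores)

  # strictly increasing transform of the scores: ROC, AUC and grouping
  # are preserved
  roc <- one_year_roc(scores, coh$clinical)
  cut <- select_cutoff(roc)
  g1 <- stratify_and_compare(scores, cut, coh$clinical)
  f <- function(x) exp(2 * x) + x
  roc2 <- one_year_roc(f(scores), coh$clinical)
  cut2 <- select_cutoff(roc2)
  g2 <- stratify_and_compare(f(scores), cut2, coh$clinical)
  expect_equal(roc2$auc, roc$auc)
  expect_equal(roc2$sensitivity, roc$sensitivity)
  expect_equal(roc2$specificity, roc$specificity)
  expect_identical(g2$assignment$group, g1$assignment$group)
  expect_equal(g2$logrank$p, g1$logrank$p)
})

test_that("the risk score tests independent of clinical covariates", {
  res <- vapply(1:20, function(s) {
    coh <- quick_cohort(seed = 300 + s, n_tumor = 300)
    tab <- suppressWarnings(
      multivariate_independence(coh$truth$linear_predictor, coh$clinical))
    m <- tab[tab$model == "multivariate", ]
    c(risk_sig = m$p[m$term == "riskScore"] < 0.01,
      n_false = sum(m$p[m$term != "riskScore"] < 0.05),
      n_cov = sum(m$term != "riskScore"))
  }, numeric(3))
  # power: the true risk term is detected in (almost) every run
  expect_gte(mean(res["risk_sig", ]), 0.8)
  # calibration: clinical covariates independent of the hazard reject at
  # about their nominal 5% rate across all runs and covariates
  expect_lt(sum(res["n_false", ]) / sum(res["n_cov", ]), 0.12)
})

test_that("a simulated age effect shows up in the joint model", {
  cfg <- simulation_config(n_tumor = 500, n_normal = 4, n_genes = 40,
                           immune_fraction = 0.5, n_de_genes = 0,
                           age_effect = 0.06, seed = 42)
  coh <- simulate_cohort(cfg)
  tab <- suppressWarnings(
    multivariate_independence(coh$truth$linear_predictor, coh$clinical))
  m <- tab[tab$model == "multivariate", ]
  expect_lt(m$p[m$term == "age"], 0.01)
  expect_equal(m$coef[m$term == "age"], 0.06, tolerance = 0.5)
  # a constant risk term is dropped with a warning
  const <- stats::setNames(rep(1, nrow(coh$clinical)),
                           coh$clinical$sample_id)
  w <- testthat::capture_warnings(
    multivariate_independence(const, coh$clinical))
  expect_true(any(grepl("constant.*riskScore", w)))
})
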