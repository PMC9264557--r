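test_that("generators are deterministic under a fixed seed", {
  cfg <- simulation_config(n_tumor = 30, n_normal = 10, n_genes = 50,
                           immune_fraction = 0.5, n_de_genes = 5, seed = 9)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$expression$values, b$expression$values)
  expect_identical(as.data.frame(a$clinical), as.data.frame(b$clinical))
  expect_identical(simulate_maf(cfg), simulate_maf(cfg))
})

test_that("planted differential effects are recovered and null genes are flat", {
  cfg <- simulation_config(n_tumor = 200, n_normal = 200, n_genes = 100,
                           immune_fraction = 0.5, n_de_genes = 10,
                           de_log2fc = 2, noise_sd = 1, seed = 3)
  sim <- simulate_expression(cfg)
  log2x <- log2(sim$expression$values)
  tum <- sim$expression$group == "tumor"
  diff <- rowMeans(log2x[, tum]) - rowMeans(log2x[, !tum])
  planted <- sim$truth$de_genes
  expect_true(all(abs(diff[planted$gene] - planted$log2fc) < 0.3))
  # null effect: an unplanted gene's mean difference is within 3 SE of 0
  unplanted <- setdiff(rownames(log2x),
                       c(planted$gene, unlist(cfg$planted_pairs[, 1:2])))
  se <- 1 * sqrt(1 / 200 + 1 / 200)
  expect_true(mean(abs(diff[unplanted]) < 3 * se) > 0.95)
})

test_that("recorded pair indicators equal recomputation from expression", {
  cfg <- simulation_config(n_tumor = 50, n_normal = 5, n_genes = 30,
                           immune_fraction = 0.5, n_de_genes = 5,
                           seed = 11)
  sim <- simulate_expression(cfg)
  pp <- cfg$planted_pairs
  recomputed <- (sim$expression$values[pp$gene1,
                                       colnames(sim$truth$indicators)] >
                 sim$expression$values[pp$gene2,
                                       colnames(sim$truth$indicators)]) * 1L
  rownames(recomputed) <- rownames(sim$truth$indicators)
  expect_identical(unname(sim$truth$indicators), unname(recomputed))
  # linear predictor identity is exact
  coh <- simulate_cohort(cfg)
  lp <- drop(crossprod(coh$truth$indicators, pp$beta))
  expect_identical(unname(coh$truth$linear_predictor), unname(lp))
})

test_that("null survival is exponential at the baseline rate with 100% events", {
  cfg <- simulation_config(n_tumor = 1000, n_normal = 2, n_genes = 10,
                           immune_fraction = 1, n_planted_pairs = 0,
                           n_de_genes = 0, censor_rate = 0,
                           admin_censor_time = 1e9, seed = 5)
  coh <- simulate_cohort(cfg)
  expect_equal(mean(coh$clinical$event), 1)
  ks <- suppressWarnings(
    stats::ks.test(coh$clinical$time, "pexp", cfg$baseline_hazard))
  expect_gt(ks$p.value, 0.01)
})

test_that("a planted pair's hazard ratio is recovered by a Cox fit", {
  cfg <- simulation_config(n_tumor = 1000, n_normal = 2, n_genes = 20,
                           immune_fraction = 1, n_planted_pairs = 1,
                           pair_beta = 1, n_de_genes = 0, seed = 21)
  coh <- simulate_cohort(cfg)
  x <- as.numeric(coh$truth$indicators[1, ])
  fit <- cox_fit(x, coh$clinical$time, coh$clinical$event)
  hr <- fit$coefficients$hr[1]
  expect_gt(hr, 2.0)
  expect_lt(hr, 3.7)
  # effect calibration at larger n: log-HR within 0.15 of the truth
  cfg2 <- simulation_config(n_tumor = 2000, n_normal = 2, n_genes = 20,
                            immune_fraction = 1, n_planted_pairs = 1,
                            pair_beta = 1, n_de_genes = 0, seed = 22)
  coh2 <- simulate_cohort(cfg2)
  fit2 <- cox_fit(as.numeric(coh2$truth$indicators[1, ]),
                  coh2$clinical$time, coh2$clinical$event)
  expect_lt(abs(fit2$coefficients$coef[1] - 1), 0.15)
})

test_that("an immediate administrative cutoff censors every sample", {
  cfg <- simulation_config(n_tumor = 50, n_normal = 2, n_genes = 10,
                           immune_fraction = 1, n_planted_pairs = 0,
                           n_de_genes = 0, admin_censor_time = 1e-6,
                           seed = 2)
  coh <- simulate_cohort(cfg)
  expect_true(all(coh$clinical$event == 0))
})

test_that("the MAF generator honors degenerate laws", {
  cfg0 <- simulation_config(n_tumor = 30, n_normal = 2, n_genes = 10,
                            immune_fraction = 1, n_de_genes = 0,
                            mutation_rate = 0, seed = 4)
  expect_identical(nrow(simulate_maf(cfg0)), 0L)

  cfg <- simulation_config(n_tumor = 30, n_normal = 2, n_genes = 10,
                           immune_fraction = 1, n_de_genes = 0,
                           mutation_rate = 2, seed = 4)
  one_gene <- simulate_maf(cfg, gene_weights = c(GENE0003 = 1))
  expect_true(all(one_gene$Hugo_Symbol == "GENE0003"))

  ct_only <- simulate_maf(cfg, snv_class_probs = c("C>T" = 1))
  s <- summarize_mutations(ct_only)
  expect_identical(unname(s$snv_class["C>T"]),
                   sum(ct_only$Variant_Type == "SNP"))
  expect_true(all(s$snv_class[setdiff(names(s$snv_class), "C>T")] == 0))
})
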