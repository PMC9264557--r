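test_that("log2-CPM normalization follows its closed form and rescales to 1e6", {
  em <- expression_matrix(matrix(c(10, 30, 60), 3, 1,
                                 dimnames = list(c("A", "B", "C"), "S1")),
                          c(S1 = "tumor"))
  norm <- normalize_log2cpm(em, pseudocount = 1)
  expect_equal(norm$values[, 1],
               log2(c(A = 1e5, B = 3e5, C = 6e5) + 1))

  set.seed(1)
  m <- matrix(rexp(200, 0.01), 20, 10,
              dimnames = list(paste0("G", 1:20), paste0("S", 1:10)))
  em2 <- expression_matrix(m, stats::setNames(rep(c("tumor", "normal"), 5),
                                              paste0("S", 1:10)))
  norm2 <- normalize_log2cpm(em2)
  # inverting the transform recovers per-sample totals of exactly 1e6
  expect_equal(colSums(2^norm2$values - 1), rep(1e6, 10),
               tolerance = 1e-6, ignore_attr = TRUE)
  # idempotent up to the pseudocount: re-normalizing CPM leaves CPM fixed
  cpm <- sweep(m, 2, colSums(m), "/") * 1e6
  em3 <- expression_matrix(cpm, em2$group)
  expect_equal(normalize_log2cpm(em3)$values, log2(cpm + 1))

  m0 <- m; m0[, 3] <- 0
  expect_error(normalize_log2cpm(expression_matrix(m0, em2$group)), "S3")
})

test_that("the Welch test matches stats::t.test and handles degenerate genes", {
  vals <- rbind(GX = c(5.1, 6.3, 5.8, 4.0, 4.4, 3.6),
                GFLAT = rep(2.5, 6))
  colnames(vals) <- paste0("S", 1:6)
  em <- expression_matrix(vals, stats::setNames(
    rep(c("tumor", "normal"), each = 3), paste0("S", 1:6)))
  de <- differential_expression(em)
  oracle <- stats::t.test(vals["GX", 1:3], vals["GX", 4:6],
                          var.equal = FALSE)
  expect_equal(de$statistic[de$gene == "GX"], unname(oracle$statistic),
               tolerance = 1e-10)
  expect_equal(de$p[de$gene == "GX"], oracle$p.value, tolerance = 1e-10)
  expect_equal(de$log2fc[de$gene == "GX"],
               mean(vals["GX", 1:3]) - mean(vals["GX", 4:6]))
  # identical values in both groups: no difference, p = 1
  expect_equal(de$log2fc[de$gene == "GFLAT"], 0)
  expect_equal(de$statistic[de$gene == "GFLAT"], 0)
  expect_equal(de$p[de$gene == "GFLAT"], 1)

  expect_error(differential_expression(toy_expression()[["values"]]))
  one <- expression_matrix(vals[, 1:3],
                           stats::setNames(c("tumor", "tumor", "normal"),
                                           paste0("S", 1:3)))
  expect_error(differential_expression(one), "at least 2")
})

test_that("a planted log2FC of 2 is detected at n=200 per group", {
  cfg <- simulation_config(n_tumor = 200, n_normal = 200, n_genes = 60,
                           immune_fraction = 0.5, n_de_genes = 6,
                           de_log2fc = 2, seed = 8)
  sim <- simulate_expression(cfg)
  lv <- log2(sim$expression$values)
  lv <- lv - min(lv) + 1  # affine shift: t statistics and log2FC unchanged
  de <- differential_expression(
    expression_matrix(lv, sim$expression$group))
  hit <- de[match(sim$truth$de_genes$gene, de$gene), ]
  expect_true(all(abs(abs(hit$log2fc) - 2) < 0.3))
  expect_true(all(hit$p < 1e-6))
})

test_that("DEG filtering is strict at both thresholds and matches enumeration", {
  tab <- data.frame(
    gene = paste0("G", 1:6),
    log2fc = c(1.0, 1.5, -2.0, 0.5, 3.0, -1.2),
    p = c(0.01, 0.01, 0.04, 0.001, 0.05, 0.20))
  got <- filter_degs(tab, lfc_min = 1, p_max = 0.05)
  brute <- tab$gene[vapply(seq_len(6), function(i)
    abs(tab$log2fc[i]) > 1 && tab$p[i] < 0.05, logical(1))]
  expect_identical(as.character(got), brute)
  # boundary: |lfc| = 1 exactly and p = 0.05 exactly are both excluded
  expect_false("G1" %in% got)
  expect_false("G5" %in% got)
  expect_true(all(c("G2", "G3") %in% got))
  expect_identical(attr(got, "provenance"), "DEG")
})

test_that("DEG count is monotone in both thresholds", {
  set.seed(5)
  tab <- data.frame(gene = paste0("G", 1:200),
                    log2fc = rnorm(200, 0, 1.5),
                    p = runif(200))
  lfcs <- c(0.5, 1, 1.5, 2)
  sizes_lfc <- vapply(lfcs, function(l)
    length(filter_degs(tab, lfc_min = l, p_max = 0.05)), numeric(1))
  expect_true(all(diff(sizes_lfc) <= 0))
  ps <- c(0.01, 0.05, 0.1, 0.5)
  sizes_p <- vapply(ps, function(p)
    length(filter_degs(tab, lfc_min = 1, p_max = p)), numeric(1))
  expect_true(all(diff(sizes_p) >= 0))
})

test_that("immune intersection is order-preserving and membership-exact", {
  expect_length(intersect_immune(gene_set(c("A", "B")),
                                 gene_set(c("C", "D"))), 0L)
  degs <- gene_set(c("E", "C", "A", "D"))
  imm <- gene_set(c("A", "C"))
  expect_identical(as.character(intersect_immune(degs, imm)), c("C", "A"))

  set.seed(2)
  g1 <- gene_set(sample(sprintf("G%03d", 1:120), 50))
  g2 <- gene_set(sample(sprintf("G%03d", 1:120), 50))
  brute <- sum(vapply(g1, function(g) any(g2 == g), logical(1)))
  expect_length(intersect_immune(g1, g2), brute)
  # membership-commutative even though ordering follows the first set
  expect_setequal(as.character(intersect_immune(g1, g2)),
                  as.character(intersect_immune(g2, g1)))
})
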