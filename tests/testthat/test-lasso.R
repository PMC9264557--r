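make_lasso_data <- function(seed, n = 200, p = 10, beta = NULL) {
  withr::with_seed(seed, {
    if (is.null(beta)) beta <- c(1, -1, 0.8, rep(0, p - 3))
    X <- matrix(rbinom(n * p, 1, 0.5), n, p,
                dimnames = list(NULL, sprintf("P%02d", seq_len(p))))
    lp <- drop(X %*% beta)
    te <- rexp(n, 5.5e-4 * exp(lp))
    tc <- pmin(rexp(n, 8e-4), 1825)
    list(X = X, time = pmax(pmin(te, tc), 1e-6),
         event = as.integer(te <= tc), beta = beta)
  })
}

test_that("the path starts all-zero at lambda_max and ends at the MLE", {
  d <- make_lasso_data(101, p = 5, beta = c(1, -1, 0.8, 0, 0))
  path <- lasso_cox_path(d$X, d$time, d$event, n_lambda = 30)
  expect_identical(unname(path$df[1]), 0)
  expect_true(all(path$beta[, 1] == 0))
  # just above lambda_max nothing enters; just below something does
  eps <- lasso_cox_path(d$X, d$time, d$event,
                        lambda = c(path$lambda_max * 1.01,
                                   path$lambda_max * 0.97))
  expect_true(all(eps$beta[, 1] == 0))
  expect_gt(sum(eps$beta[, 2] != 0), 0)

  mle <- cox_fit(d$X, d$time, d$event)
  tiny <- lasso_cox_path(d$X, d$time, d$event,
                         lambda = c(0.1, 0.01, 1e-4, 1e-7))
  expect_lt(max(abs(tiny$beta[, 4] - mle$coefficients$coef)), 1e-4)
})

test_that("the penalized objective matches brute-force lattice minimization", {
  # two covariates, continuous times (no ties), fixed lambda
  d <- make_lasso_data(7, n = 40, p = 2, beta = c(1, -1))
  lambda <- 0.08
  n <- nrow(d$X)
  ctr <- colMeans(d$X)
  scl <- sqrt(colMeans(d$X^2) - ctr^2)
  Xs <- sweep(sweep(d$X, 2, ctr, "-"), 2, scl, "/")
  objective <- function(b1, b2) {
    eta <- Xs %*% c(b1, b2)
    -naive_cox_loglik(eta, d$time, d$event) / n +
      lambda * (abs(b1) + abs(b2))
  }
  # coarse lattice then local refinement around its argmin
  coarse <- seq(-1.5, 1.5, by = 0.05)
  og <- outer(coarse, coarse, Vectorize(objective))
  i0 <- which(og == min(og), arr.ind = TRUE)[1, ]
  fine1 <- seq(coarse[i0[1]] - 0.05, coarse[i0[1]] + 0.05, by = 0.002)
  fine2 <- seq(coarse[i0[2]] - 0.05, coarse[i0[2]] + 0.05, by = 0.002)
  of <- outer(fine1, fine2, Vectorize(objective))
  brute_min <- min(of)
  i1 <- which(of == brute_min, arr.ind = TRUE)[1, ]

  fit <- lasso_cox_path(d$X, d$time, d$event, lambda = c(0.3, lambda))
  b_std <- fit$beta[, 2] * scl  # back to the standardized scale
  fit_obj <- objective(b_std[1], b_std[2])
  # the fit cannot beat the lattice by more than numerical noise, nor
  # trail it by more than the lattice resolution allows
  expect_lt(fit_obj, brute_min + 1e-6)
  expect_lt(brute_min - fit_obj, 1e-4)
  expect_lt(max(abs(b_std - c(fine1[i1[1]], fine2[i1[2]]))), 0.004)
})

test_that("the path agrees with glmnet at matched lambdas", {
  d <- make_lasso_data(19, n = 250, p = 20,
                       beta = c(1, -1, 0.8, rep(0, 17)))
  path <- lasso_cox_path(d$X, d$time, d$event, n_lambda = 40)
  g <- glmnet::glmnet(d$X, survival::Surv(d$time, d$event), family = "cox",
                      lambda = path$lambda[c(10, 20, 30)],
                      standardize = TRUE, thresh = 1e-12)
  ours <- path$beta[, c(10, 20, 30)]
  theirs <- as.matrix(g$beta)
  expect_lt(max(abs(ours - theirs)), 5e-4)
  expect_equal(path$lambda_max,
               max(glmnet::glmnet(d$X, survival::Surv(d$time, d$event),
                                  family = "cox")$lambda),
               tolerance = 1e-6)
})

test_that("coefficients move continuously along the lambda grid", {
  d <- make_lasso_data(23, n = 200, p = 10)
  path <- lasso_cox_path(d$X, d$time, d$event, n_lambda = 50)
  jumps <- apply(abs(path$beta[, -1] - path$beta[, -ncol(path$beta)]),
                 2, max)
  expect_lt(max(jumps), 0.25)
})

test_that("cross-validated selection is seeded-deterministic", {
  d <- make_lasso_data(29, n = 150, p = 10)
  cv1 <- cv_select(d$X, d$time, d$event, folds = 5, seed = 4,
                   n_lambda = 40)
  cv2 <- cv_select(d$X, d$time, d$event, folds = 5, seed = 4,
                   n_lambda = 40)
  expect_identical(cv1$fold, cv2$fold)
  expect_identical(cv1$coefficients, cv2$coefficients)
  expect_identical(cv1$nonzero, cv2$nonzero)
  expect_error(cv_select(d$X, d$time, d$event, folds = 1), ">= 2")
})

test_that("the 1-SE rule stays sparse on pure-noise designs", {
  nz <- vapply(1:20, function(s) {
    withr::with_seed(2000 + s, {
      n <- 300; p <- 50
      X <- matrix(rbinom(n * p, 1, 0.5), n, p,
                  dimnames = list(NULL, sprintf("P%03d", 1:p)))
      s0 <- null_surv(n)
      cv <- cv_select(X, s0$time, s0$event, folds = 10, seed = s,
                      rule = "1se")
      length(cv$nonzero)
    })
  }, numeric(1))
  expect_gte(mean(nz <= 5), 0.9)
})

test_that("recovered planted pairs keep the sign of their generating effect", {
  d <- make_lasso_data(37, n = 500, p = 100,
                       beta = c(1, -1, 1, -1, 1, rep(0, 95)))
  cv <- cv_select(d$X, d$time, d$event, folds = 10, seed = 37)
  planted <- sprintf("P%02d", 1:5)
  found <- intersect(planted, cv$nonzero)
  expect_gte(length(found), 4L)
  expect_true(all(sign(cv$coefficients[found]) == sign(d$beta[1:5])[
    match(found, planted)]))
})
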