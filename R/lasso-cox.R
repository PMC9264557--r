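# L1-penalized Cox regression by cyclic coordinate descent.
#
# Outer loop: iteratively reweighted least squares on the partial
# likelihood — at the current linear predictor the per-sample gradient and
# diagonal curvature define a weighted least-squares working problem whose
# L1-penalized solution is found by compiled coordinate descent with warm
# starts along a geometric lambda grid. Covariates are standardized
# internally (mean 0, variance 1 with the 1/n convention) so the penalty
# treats them symmetrically; reported coefficients are on the original
# scale. The objective is -(1/n) * log partial likelihood + lambda * ||b||_1.

cox_sorted_data <- function(X, time, event) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  stopifnot(nrow(X) == length(time), length(time) == length(event),
            all(time > 0), all(event %in% c(0, 1)))
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  ord <- order(time)
  list(X = X[ord, , drop = FALSE], time = time[ord],
       event = as.integer(event[ord]), ord = ord)
}

standardize_columns <- function(X) {
  n <- nrow(X)
  center <- colMeans(X)
  scale <- sqrt(colMeans(X^2) - center^2)  # 1/n variance
  if (any(scale == 0))
    stop("constant covariate column(s): ",
         paste(colnames(X)[scale == 0], collapse = ", "))
  Xs <- sweep(sweep(X, 2, center, "-"), 2, scale, "/")
  list(Xs = Xs, center = center, scale = scale)
}

#' L1-penalized Cox regression path
#'
#' Fits the lasso Cox model along a decreasing lambda grid running from
#' `lambda_max` — the smallest penalty with an all-zero solution, computed
#' from the null-model score — down geometrically to
#' `lambda_max * lambda_min_ratio`, with warm starts between consecutive
#' grid points.
#'
#' @param X Covariate matrix (samples x covariates); binary pair
#'   indicators in the signature workflow.
#' @param time,event Survival data.
#' @param n_lambda Grid size (default 100).
#' @param lambda_min_ratio Ratio of the smallest to the largest lambda
#'   (default 0.01).
#' @param lambda Optional explicit grid (decreasing); overrides the
#'   automatic one.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param outer_tol Relative-objective tolerance of the outer IRLS loop
#'   (default 1e-9, tight enough that the small-lambda path endpoint
#'   agrees with the unpenalized Newton fit to about 1e-4).
#' @return A `LassoPath`: `lambda`, `beta` (covariates x lambda, original
#'   scale), `df` (nonzero count per lambda), `lambda_max`, `converged`
#'   per lambda, and the standardization used.
#' @export
lasso_cox_path <- function(X, time, event, n_lambda = 100,
                           lambda_min_ratio = 0.01, lambda = NULL,
                           ties = c("efron", "breslow"),
                           outer_tol = 1e-9) {
  ties <- match.arg(ties)
  efron <- ties == "efron"
  d <- cox_sorted_data(X, time, event)
  n <- nrow(d$X)
  std <- standardize_columns(d$X)
  # null-model score determines lambda_max
  gw0 <- cox_grad_weight_cpp(rep(0, n), d$time, d$event, efron)
  lambda_max <- max(abs(crossprod(std$Xs, gw0$grad))) / n
  if (is.null(lambda)) {
    stopifnot(n_lambda >= 1, lambda_min_ratio > 0, lambda_min_ratio < 1)
    lambda <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                      length.out = n_lambda))
  } else {
    lambda <- sort(as.numeric(lambda), decreasing = TRUE)
  }
  sol <- lasso_cox_path_cpp(std$Xs, d$time, d$event, efron, lambda,
                            lambda_max, outer_tol, 1e-9, 100L, 10000L)
  betas <- sol$beta / std$scale
  dimnames(betas) <- list(colnames(d$X), NULL)
  conv <- as.logical(sol$converged)
  if (!all(conv))
    warning(sum(!conv), " lambda value(s) did not converge; path returned")
  structure(list(lambda = lambda, beta = betas,
                 df = colSums(betas != 0), lambda_max = lambda_max,
                 converged = conv, center = std$center, scale = std$scale,
                 ties = ties),
            class = "LassoPath")
}

#' @export
print.LassoPath <- function(x, ...) {
  cat(sprintf(
    "LassoPath: %d lambdas in [%.4g, %.4g], df range %d-%d (%s ties)\n",
    length(x$lambda), min(x$lambda), max(x$lambda), min(x$df), max(x$df),
    x$ties))
  invisible(x)
}

# Held-out partial-likelihood deviance of fold `idx` at each column of
# `betas` (original scale), in the Verweij-Van Houwelingen form standard
# for Cox cross-validation: -2 * (ll_all(beta) - ll_train(beta)). Because
# the partial likelihood does not factor over samples, this is the proper
# way to credit a fold with its held-out contribution.
heldout_deviance <- function(X, time, event, idx, betas, efron) {
  prep <- function(keep) {
    o <- order(time[keep])
    list(X = X[keep, , drop = FALSE][o, , drop = FALSE],
         t = time[keep][o], e = as.integer(event[keep][o]))
  }
  all <- prep(rep(TRUE, length(time)))
  tr <- prep(setdiff(seq_along(time), idx))
  apply(betas, 2, function(b)
    -2 * (cox_loglik_cpp(drop(all$X %*% b), all$t, all$e, efron) -
          cox_loglik_cpp(drop(tr$X %*% b), tr$t, tr$e, efron)))
}

#' Cross-validated lambda selection for the lasso Cox model
#'
#' Samples are assigned to folds by a seeded permutation into near-equal
#' blocks. For every lambda of the full-data path, each fold's model is
#' refit on the remaining folds and scored by the held-out
#' partial-likelihood deviance; the selected lambda minimizes the mean CV
#' deviance (the CV-minimum rule). The final model is the full-data fit at
#' the selected lambda; its nonzero coefficients define the signature.
#'
#' @inheritParams lasso_cox_path
#' @param folds Number of CV folds (default 10; must be >= 2).
#' @param seed Seed for the fold assignment (optional but recommended).
#' @param rule `"min"` (default): the lambda minimizing the mean CV
#'   deviance; `"1se"`: the largest lambda whose mean CV deviance is
#'   within one standard error of that minimum (more conservative, yields
#'   sparser models).
#' @return List: `lambda` grid, `cvm`/`cvse` (mean and standard error of
#'   the fold deviances), `lambda_min`, `coefficients` (original scale, at
#'   `lambda_min`), `nonzero` (names of nonzero coefficients), `path`
#'   (the full-data [lasso_cox_path()]), `fold` assignment.
#' @export
cv_select <- function(X, time, event, folds = 10, seed = NULL,
                      n_lambda = 100, lambda_min_ratio = 0.01,
                      ties = c("efron", "breslow"),
                      rule = c("min", "1se")) {
  ties <- match.arg(ties)
  rule <- match.arg(rule)
  efron <- ties == "efron"
  if (folds < 2) stop("`folds` must be >= 2")
  X <- as.matrix(X)
  n <- nrow(X)
  if (folds > n) stop("more folds than samples")
  path <- lasso_cox_path(X, time, event, n_lambda = n_lambda,
                         lambda_min_ratio = lambda_min_ratio, ties = ties)
  fold <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  ev_per_fold <- vapply(seq_len(folds), function(k)
    sum(event[fold == k]), numeric(1))
  if (any(ev_per_fold == 0))
    warning("fold(s) with zero events skipped: ",
            paste(which(ev_per_fold == 0), collapse = ", "))
  else if (any(ev_per_fold < 3))
    warning("fold(s) with fewer than 3 events: ",
            paste(which(ev_per_fold < 3), collapse = ", "))
  dev <- matrix(NA_real_, folds, length(path$lambda))
  for (k in seq_len(folds)) {
    if (ev_per_fold[k] == 0) next
    train <- fold != k
    pk <- suppressWarnings(
      lasso_cox_path(X[train, , drop = FALSE], time[train], event[train],
                     lambda = path$lambda, ties = ties))
    dev[k, ] <- heldout_deviance(X, time, event, which(!train), pk$beta,
                                 efron)
  }
  used <- which(ev_per_fold > 0)
  cvm <- colMeans(dev[used, , drop = FALSE])
  cvse <- apply(dev[used, , drop = FALSE], 2, sd) / sqrt(length(used))
  imin <- which.min(cvm)  # first minimum = largest such lambda
  best <- if (rule == "1se")
    which(cvm <= cvm[imin] + cvse[imin])[1] else imin
  coefs <- path$beta[, best]
  structure(list(lambda = path$lambda, cvm = cvm, cvse = cvse,
                 lambda_min = path$lambda[imin],
                 lambda_1se = path$lambda[which(cvm <= cvm[imin] +
                                                  cvse[imin])[1]],
                 lambda_selected = path$lambda[best], rule = rule,
                 index_min = best,
                 coefficients = coefs,
                 nonzero = names(coefs)[coefs != 0],
                 path = path, fold = fold),
            class = "CVLassoCox")
}

#' @export
print.CVLassoCox <- function(x, ...) {
  cat(sprintf(
    "CVLassoCox: lambda_min = %.4g, %d nonzero of %d covariates\n",
    x$lambda_min, length(x$nonzero), nrow(x$path$beta)))
  invisible(x)
}
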