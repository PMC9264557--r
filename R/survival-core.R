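# Self-contained survival statistics: Kaplan-Meier product-limit curves,
# the two-group log-rank test, and Cox proportional-hazards regression by
# Newton-Raphson on the partial likelihood with Efron's tie correction
# (Breslow available). Partial-likelihood internals are compiled; see
# src/cox_core.cpp.

#' Kaplan-Meier product-limit estimate
#'
#' @param time Positive follow-up durations.
#' @param event 1 = death, 0 = censored.
#' @return A `KMCurve`: data.frame of distinct event times with `n_risk`,
#'   `n_event` and the survival step function `surv`
#'   (`S(t) = prod (1 - d_i/n_i)` over event times `t_i <= t`), plus
#'   attributes `n` and `n_event_total`.
#' @export
km_estimate <- function(time, event) {
  if (length(time) == 0) stop("empty survival input")
  stopifnot(length(time) == length(event), all(time > 0),
            all(event %in% c(0, 1)))
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  etimes <- unique(time[event == 1])
  n_risk <- vapply(etimes, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(etimes, function(t) sum(time == t & event == 1),
                    numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  out <- data.frame(time = etimes, n_risk = n_risk, n_event = n_event,
                    surv = surv)
  structure(out, n = length(time), n_event_total = sum(event),
            class = c("KMCurve", "data.frame"))
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' @param km A [km_estimate()] result.
#' @param t Times at which to evaluate `S(t)` (right-continuous step).
#' @return Numeric vector of survival probabilities.
#' @export
km_surv_at <- function(km, t) {
  vapply(t, function(ti) {
    below <- km$time <= ti
    if (!any(below)) 1 else km$surv[max(which(below))]
  }, numeric(1))
}

#' Two-group log-rank test
#'
#' Standard log-rank statistic over the pooled distinct event times, with a
#' 1-df chi-square p-value. If neither group has any event the comparison
#' is vacuous: the test returns `p = 1` with a warning.
#'
#' @param time_a,event_a Survival data for group A.
#' @param time_b,event_b Survival data for group B.
#' @return List with `chisq`, `df` (= 1), `p`, and the observed/expected
#'   event counts per group.
#' @export
logrank_test <- function(time_a, event_a, time_b, event_b) {
  if (!length(time_a) || !length(time_b)) stop("both groups must be non-empty")
  stopifnot(all(c(time_a, time_b) > 0),
            all(c(event_a, event_b) %in% c(0, 1)))
  if (sum(event_a) + sum(event_b) == 0) {
    warning("no events in either group; log-rank test is vacuous")
    return(list(chisq = 0, df = 1L, p = 1,
                observed = c(a = 0, b = 0), expected = c(a = 0, b = 0)))
  }
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  grp_a <- rep(c(TRUE, FALSE), c(length(time_a), length(time_b)))
  etimes <- sort(unique(time[event == 1]))
  o_a <- e_a <- v <- 0
  obs_a <- obs_b <- exp_a <- exp_b <- 0
  for (t in etimes) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n_a <- sum(at_risk & grp_a)
    d <- sum(time == t & event == 1)
    d_a <- sum(time == t & event == 1 & grp_a)
    obs_a <- obs_a + d_a
    obs_b <- obs_b + (d - d_a)
    e <- d * n_a / n
    exp_a <- exp_a + e
    exp_b <- exp_b + (d - e)
    if (n > 1)
      v <- v + d * (n_a / n) * (1 - n_a / n) * (n - d) / (n - 1)
  }
  chisq <- if (v > 0) (obs_a - exp_a)^2 / v else 0
  list(chisq = chisq, df = 1L, p = pchisq(chisq, 1, lower.tail = FALSE),
       observed = c(a = obs_a, b = obs_b),
       expected = c(a = exp_a, b = exp_b))
}

# Newton-Raphson on pre-sorted data. Returns the raw optimizer state.
cox_newton <- function(X, time, event, efron = TRUE, tol = 1e-9,
                       max_iter = 50L, beta_cap = 15) {
  p <- ncol(X)
  beta <- rep(0, p)
  fit <- cox_ll_grad_info_cpp(X, drop(X %*% beta), time, event, efron)
  ll <- fit$loglik
  ll_null <- ll
  converged <- FALSE
  diverged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    step <- tryCatch(solve(fit$info, fit$score), error = function(e) NULL)
    if (is.null(step))
      step <- solve(fit$info + diag(1e-8, p), fit$score)
    # step-halving keeps the partial likelihood monotone
    fac <- 1
    repeat {
      cand <- beta + fac * step
      fit_new <- cox_ll_grad_info_cpp(X, drop(X %*% cand), time, event, efron)
      if (fit_new$loglik >= ll - 1e-12 || fac < 1e-6) break
      fac <- fac / 2
    }
    beta <- cand
    ll <- fit_new$loglik
    fit <- fit_new
    if (any(abs(beta) > beta_cap)) {
      diverged <- TRUE
      beta <- pmin(pmax(beta, -beta_cap), beta_cap)
      break
    }
    if (max(abs(fac * step)) < tol) {
      converged <- TRUE
      break
    }
  }
  list(beta = beta, info = fit$info, loglik = ll, loglik_null = ll_null,
       converged = converged, diverged = diverged, iterations = iter)
}

#' Cox proportional-hazards regression
#'
#' Maximizes the Cox partial likelihood by Newton-Raphson with step-halving
#' and Efron's correction for tied event times (Breslow optional).
#' Covariates that are constant across samples are flagged and reported
#' with `se = Inf` rather than fit. A monotone partial likelihood (perfect
#' separation) is detected by coefficient divergence; the run is flagged
#' non-converged with the coefficient capped, and a warning is issued.
#'
#' @param X Covariate matrix (samples x covariates) or a single vector.
#' @param time Positive follow-up durations.
#' @param event 1 = death, 0 = censored.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param tol Convergence threshold on the Newton step (max absolute
#'   update; default 1e-9).
#' @param max_iter Iteration cap (default 50).
#' @return A `CoxFit`: data.frame `coefficients` with one row per
#'   covariate (`coef`, `se`, `hr`, `ci_lower`, `ci_upper` from
#'   `exp(coef +/- 1.96 se)`, Wald `z`, `p`), plus `loglik`,
#'   `loglik_null`, `converged`, `iterations`, `n`, `n_event`.
#' @export
cox_fit <- function(X, time, event, ties = c("efron", "breslow"),
                    tol = 1e-9, max_iter = 50L) {
  ties <- match.arg(ties)
  if (is.null(dim(X))) X <- matrix(X, ncol = 1)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X)))
    colnames(X) <- if (ncol(X) == 1) "x" else paste0("x", seq_len(ncol(X)))
  stopifnot(nrow(X) == length(time), length(time) == length(event),
            all(time > 0), all(event %in% c(0, 1)))
  ord <- order(time)
  cox_fit_sorted(X[ord, , drop = FALSE], time[ord], event[ord],
                 efron = ties == "efron", tol = tol, max_iter = max_iter,
                 ties_label = ties)
}

# Core fit on already time-sorted data (used directly by the univariate
# screen to avoid re-sorting per pair).
cox_fit_sorted <- function(X, time, event, efron = TRUE, tol = 1e-9,
                           max_iter = 50L, ties_label = "efron") {
  p <- ncol(X)
  const <- apply(X, 2, function(col) max(col) == min(col))
  if (any(const))
    warning("constant covariate(s): ",
            paste(colnames(X)[const], collapse = ", "),
            " (reported with se = Inf)")
  coef <- se <- rep(NA_real_, p)
  names(coef) <- names(se) <- colnames(X)
  res <- NULL
  if (any(!const)) {
    Xf <- X[, !const, drop = FALSE]
    res <- cox_newton(Xf, time, event, efron = efron, tol = tol,
                      max_iter = max_iter)
    if (res$diverged)
      warning("monotone partial likelihood (perfect separation); ",
              "coefficient capped, fit flagged non-converged")
    cov <- tryCatch(solve(res$info), error = function(e)
      matrix(NA_real_, ncol(Xf), ncol(Xf)))
    coef[!const] <- res$beta
    se[!const] <- sqrt(pmax(diag(cov), 0))
  }
  coef[const] <- 0
  se[const] <- Inf
  z <- ifelse(is.finite(se) & se > 0, coef / se, NA_real_)
  pval <- 2 * pnorm(-abs(z))
  tab <- data.frame(
    term = colnames(X), coef = coef, se = se, hr = exp(coef),
    ci_lower = exp(coef - 1.96 * se), ci_upper = exp(coef + 1.96 * se),
    z = z, p = pval, row.names = NULL, stringsAsFactors = FALSE)
  structure(list(
    coefficients = tab,
    loglik = if (is.null(res)) NA_real_ else res$loglik,
    loglik_null = if (is.null(res)) NA_real_ else res$loglik_null,
    converged = if (is.null(res)) FALSE else res$converged,
    iterations = if (is.null(res)) 0L else res$iterations,
    n = length(time), n_event = sum(event), ties = ties_label),
    class = "CoxFit")
}

#' @export
print.CoxFit <- function(x, ...) {
  cat(sprintf("CoxFit (%s ties): n = %d, events = %d, loglik = %.4f%s\n",
              x$ties, x$n, x$n_event, x$loglik,
              if (x$converged) "" else " [not converged]"))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Univariate Cox screen over pair indicators
#'
#' Fits one single-covariate Cox model per pair indicator and retains the
#' pairs with Wald `p < alpha` (strict). Pairs whose indicator is constant
#' in the screened samples are reported with `p = NA` and never retained.
#'
#' @param pm A [pair_indicators()] matrix (pairs x samples).
#' @param time,event Survival data aligned with the columns of `pm`.
#' @param alpha Retention threshold on the Wald p-value (default 0.01).
#' @param ties Tie handling passed to the Cox fit.
#' @return List with `table` (per-pair `coef`, `se`, `hr`, `ci_lower`,
#'   `ci_upper`, `z`, `p`, `selected`) and `selected` (retained pair
#'   tokens, screen order).
#' @export
univariate_screen <- function(pm, time, event, alpha = 0.01,
                              ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (nrow(pm) == 0) stop("no pairs to screen")
  stopifnot(ncol(pm) == length(time), length(time) == length(event))
  ord <- order(time)
  time_s <- time[ord]; event_s <- event[ord]
  rows <- vector("list", nrow(pm))
  for (i in seq_len(nrow(pm))) {
    x <- matrix(as.numeric(pm[i, ord]), ncol = 1,
                dimnames = list(NULL, rownames(pm)[i]))
    fit <- suppressWarnings(
      cox_fit_sorted(x, time_s, event_s, efron = ties == "efron",
                     ties_label = ties))
    rows[[i]] <- fit$coefficients
  }
  tab <- do.call(rbind, rows)
  names(tab)[names(tab) == "term"] <- "pair"
  tab$selected <- !is.na(tab$p) & tab$p < alpha
  list(table = tab, selected = tab$pair[tab$selected])
}
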