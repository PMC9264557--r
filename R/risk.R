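# Risk-score composition and cohort stratification. A signature's risk
# score is the coefficient-weighted sum of its binary pair indicators; the
# high/low cutoff is chosen on a 1-year ROC curve by Youden's J and is
# applied with a strict greater-than rule.

#' Split a cohort into training and test sets
#'
#' Samples lacking survival information (missing time or event) are
#' excluded first, then a seeded random partition is drawn. At ratio 0.5
#' the two sizes differ by at most one (training gets the extra sample).
#'
#' @param clinical A [clinical_table()].
#' @param ratio Training fraction in (0, 1); default 0.5 (a 1:1 split).
#' @param seed Seed for the shuffle.
#' @return List with `train` and `test` sample-id vectors.
#' @export
split_cohort <- function(clinical, ratio = 0.5, seed = NULL) {
  stopifnot(inherits(clinical, "ClinicalTable"))
  if (!(is.numeric(ratio) && ratio > 0 && ratio < 1))
    stop("`ratio` must be in (0, 1)")
  ids <- clinical$sample_id[!is.na(clinical$time) & !is.na(clinical$event)]
  n <- length(ids)
  if (n < 10) stop("fewer than 10 samples with survival information")
  n_train <- ceiling(n * ratio)
  shuffled <- with_seed(seed, sample(ids))
  list(train = sort(shuffled[seq_len(n_train)]),
       test = sort(shuffled[-seq_len(n_train)]))
}

#' Risk score of a signature over pair indicators
#'
#' `score_s = sum_k alpha_k * indicator_{k,s}`. Signature pairs missing
#' from `pm` are computed from `em` when it is supplied; otherwise a
#' missing pair is an error.
#'
#' @param sig A [signature_model()].
#' @param pm A [pair_indicators()] matrix.
#' @param em Optional [expression_matrix()] used to binarize missing pairs.
#' @return Named numeric vector of per-sample risk scores.
#' @export
risk_score <- function(sig, pm, em = NULL) {
  stopifnot(inherits(sig, "SignatureModel"))
  tok <- pair_token(sig$pairs$gene_former, sig$pairs$gene_latter)
  ind <- matrix(0, length(tok), ncol(pm),
                dimnames = list(tok, colnames(pm)))
  for (i in seq_along(tok)) {
    if (tok[i] %in% rownames(pm)) {
      ind[i, ] <- pm[tok[i], ]
    } else if (!is.null(em)) {
      ind[i, ] <- binarize_pair(em, c(sig$pairs$gene_former[i],
                                      sig$pairs$gene_latter[i]))[colnames(pm)]
    } else {
      stop("signature pair not in indicator matrix: ", tok[i])
    }
  }
  scores <- drop(crossprod(ind, sig$coefficients))
  names(scores) <- colnames(pm)
  scores
}

#' Time-dependent (1-year) ROC curve for a risk score
#'
#' Positives are samples that died by the horizon (`event == 1` and
#' `time <= horizon`); negatives are samples followed beyond the horizon
#' (`time > horizon`, whatever their later status). Samples censored
#' before the horizon carry no label and are excluded. The curve is
#' evaluated at midpoints between consecutive distinct scores (plus
#' infinite endpoints), with the predicted-positive rule `score >
#' threshold`; the AUC is the trapezoid area, equal to the Mann-Whitney
#' concordance with ties counted 1/2.
#'
#' @param scores Named per-sample risk scores.
#' @param clinical A [clinical_table()] covering the scored samples.
#' @param horizon Evaluation horizon in days (default 365).
#' @return A `ROCCurve`: `thresholds`, `sensitivity`, `specificity`,
#'   `auc`, counts, and the distinct `score_values`.
#' @export
one_year_roc <- function(scores, clinical, horizon = 365) {
  stopifnot(inherits(clinical, "ClinicalTable"))
  clin <- as.data.frame(clinical)
  clin <- clin[match(names(scores), clin$sample_id), ]
  if (anyNA(clin$sample_id))
    stop("scored sample(s) missing from the clinical table")
  ok <- !is.na(clin$time) & !is.na(clin$event)
  pos <- ok & clin$event == 1 & clin$time <= horizon
  neg <- ok & clin$time > horizon
  excluded <- ok & clin$event == 0 & clin$time <= horizon
  if (!any(pos)) stop("no positives (deaths by the horizon)")
  if (!any(neg)) stop("no negatives (follow-up beyond the horizon)")
  s_pos <- scores[pos]; s_neg <- scores[neg]
  uniq <- sort(unique(c(s_pos, s_neg)))
  thr <- if (length(uniq) > 1)
    c(-Inf, (uniq[-1] + uniq[-length(uniq)]) / 2, Inf) else c(-Inf, Inf)
  sens <- vapply(thr, function(c) mean(s_pos > c), numeric(1))
  spec <- vapply(thr, function(c) mean(s_neg <= c), numeric(1))
  # Mann-Whitney AUC with ties counted 1/2 (equals the trapezoid area)
  r <- rank(c(s_pos, s_neg), ties.method = "average")
  n1 <- length(s_pos); n0 <- length(s_neg)
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc, n_pos = n1, n_neg = n0,
                 n_excluded = sum(excluded), horizon = horizon,
                 score_values = uniq),
            class = "ROCCurve")
}

#' @export
print.ROCCurve <- function(x, ...) {
  cat(sprintf(
    "ROCCurve (horizon %g days): AUC = %.3f (%d positives, %d negatives, %d excluded)\n",
    x$horizon, x$auc, x$n_pos, x$n_neg, x$n_excluded))
  invisible(x)
}

#' Optimal risk-score cutoff from an ROC curve
#'
#' The finite threshold maximizing Youden's J = sensitivity + specificity
#' - 1; ties are broken toward the smaller threshold. A degenerate curve
#' (a single distinct score) returns that score with a warning.
#'
#' @param roc A [one_year_roc()] result.
#' @return The cutoff value.
#' @export
select_cutoff <- function(roc) {
  stopifnot(inherits(roc, "ROCCurve"))
  finite <- is.finite(roc$thresholds)
  if (!any(finite)) {
    warning("degenerate ROC curve (single score value); returning it")
    return(roc$score_values[1])
  }
  j <- roc$sensitivity[finite] + roc$specificity[finite] - 1
  roc$thresholds[finite][which.max(j)]  # first max = smallest threshold
}

#' Stratify a cohort by risk score and compare survival
#'
#' Assigns `high` to samples with `score > cutoff` (strict) and `low`
#' otherwise, then compares the groups with Kaplan-Meier curves, a
#' log-rank test, and per-group death fractions.
#'
#' @param scores Named per-sample risk scores.
#' @param cutoff Risk-score threshold (see [select_cutoff()]).
#' @param clinical A [clinical_table()] covering the scored samples.
#' @return List: `assignment` (data.frame `sample_id`, `score`, `group`),
#'   `cutoff`, `km` (per-group [km_estimate()]), `logrank`,
#'   `death_fraction` (`high`, `low`), `n` per group.
#' @export
stratify_and_compare <- function(scores, cutoff, clinical) {
  stopifnot(inherits(clinical, "ClinicalTable"))
  clin <- as.data.frame(clinical)
  clin <- clin[match(names(scores), clin$sample_id), ]
  ok <- !is.na(clin$time) & !is.na(clin$event)
  scores <- scores[ok]; clin <- clin[ok, ]
  group <- ifelse(scores > cutoff, "high", "low")
  if (!any(group == "high"))
    stop("no high-risk samples at this cutoff; choose a lower cutoff")
  if (!any(group == "low"))
    stop("no low-risk samples at this cutoff; choose a higher cutoff")
  hi <- group == "high"
  km <- list(high = km_estimate(clin$time[hi], clin$event[hi]),
             low = km_estimate(clin$time[!hi], clin$event[!hi]))
  lr <- logrank_test(clin$time[hi], clin$event[hi],
                     clin$time[!hi], clin$event[!hi])
  list(assignment = data.frame(sample_id = clin$sample_id, score = scores,
                               group = group, row.names = NULL,
                               stringsAsFactors = FALSE),
       cutoff = cutoff, km = km, logrank = lr,
       death_fraction = c(high = mean(clin$event[hi]),
                          low = mean(clin$event[!hi])),
       n = c(high = sum(hi), low = sum(!hi)))
}

# Ordinal/binary encodings for the clinical covariates. The published
# analyses rarely state their encodings; these are config-visible choices:
# gender male = 1 / female = 0; grade G1-G4 (or I-IV) -> 1-4; stage I-IV
# -> 1-4; T1-T4 -> 1-4; N0-N3 -> 0-3. Unparseable levels become NA.
encode_clinical_covariates <- function(clin) {
  roman <- c(I = 1, II = 2, III = 3, IV = 4)
  enc_ord <- function(x, prefix, offset = 0) {
    if (is.numeric(x)) return(as.numeric(x))
    x <- toupper(trimws(as.character(x)))
    x <- sub("^STAGE\\s*", "", x)
    out <- rep(NA_real_, length(x))
    hit <- x %in% names(roman)
    out[hit] <- roman[x[hit]]
    num <- grepl(paste0("^", prefix, "[0-9]$"), x)
    out[num] <- as.numeric(sub(prefix, "", x[num])) + offset
    out
  }
  out <- data.frame(row.names = seq_len(nrow(clin)))
  if ("age" %in% names(clin)) out$age <- as.numeric(clin$age)
  if ("gender" %in% names(clin)) {
    g <- toupper(trimws(as.character(clin$gender)))
    out$gender <- ifelse(g %in% c("MALE", "M", "1"), 1,
                         ifelse(g %in% c("FEMALE", "F", "0"), 0, NA_real_))
  }
  if ("grade" %in% names(clin)) out$grade <- enc_ord(clin$grade, "G")
  if ("stage" %in% names(clin)) out$stage <- enc_ord(clin$stage, "STAGE")
  if ("t_stage" %in% names(clin)) out$t_stage <- enc_ord(clin$t_stage, "T")
  if ("n_stage" %in% names(clin)) out$n_stage <- enc_ord(clin$n_stage, "N")
  out
}

#' Univariate and multivariate Cox analysis of the risk score
#'
#' Tests whether the signature risk score predicts survival independently
#' of the clinical covariates: one univariate Cox fit per variable, then a
#' joint multivariate fit including the risk term. Missing covariate
#' values are dropped per-model (complete cases; counts are reported, no
#' imputation). A constant risk term is dropped with a warning, as are
#' collinear covariates (later columns lose).
#'
#' @param scores Named per-sample risk scores, or a named `"high"`/`"low"`
#'   group vector when `use = "group"`.
#' @param clinical A [clinical_table()] with covariate columns among
#'   `age`, `gender`, `grade`, `stage`, `t_stage`, `n_stage`.
#' @param use `"score"` (continuous risk score, default) or `"group"`
#'   (binary high = 1 / low = 0).
#' @param ties Tie handling for the Cox fits.
#' @return Data.frame with one row per (model, term): `model`
#'   (`"univariate"`/`"multivariate"`), `term`, `n`, `coef`, `hr`,
#'   `ci_lower`, `ci_upper`, `p`.
#' @export
multivariate_independence <- function(scores, clinical,
                                      use = c("score", "group"),
                                      ties = c("efron", "breslow")) {
  use <- match.arg(use)
  ties <- match.arg(ties)
  stopifnot(inherits(clinical, "ClinicalTable"))
  clin <- as.data.frame(clinical)
  clin <- clin[match(names(scores), clin$sample_id), ]
  if (anyNA(clin$sample_id))
    stop("scored sample(s) missing from the clinical table")
  ok <- !is.na(clin$time) & !is.na(clin$event)
  clin <- clin[ok, ]; scores <- scores[ok]
  risk <- if (use == "group") as.numeric(scores == "high")
          else as.numeric(scores)
  cov <- encode_clinical_covariates(clin)
  cov$riskScore <- risk
  fit_one <- function(Xdf, label) {
    cc <- complete.cases(Xdf)
    Xm <- as.matrix(Xdf[cc, , drop = FALSE])
    const <- apply(Xm, 2, function(v) max(v) == min(v))
    if (any(const)) {
      warning("dropping constant covariate(s) from ", label, " model: ",
              paste(colnames(Xm)[const], collapse = ", "))
      Xm <- Xm[, !const, drop = FALSE]
    }
    if (ncol(Xm) == 0) return(NULL)
    # centering first makes dependence-up-to-a-constant show as rank loss
    qr_x <- qr(scale(Xm, scale = FALSE))
    if (qr_x$rank < ncol(Xm)) {
      keep <- sort(qr_x$pivot[seq_len(qr_x$rank)])
      warning("dropping collinear covariate(s) from ", label, " model: ",
              paste(setdiff(colnames(Xm), colnames(Xm)[keep]),
                    collapse = ", "))
      Xm <- Xm[, keep, drop = FALSE]
    }
    fit <- cox_fit(Xm, clin$time[cc], clin$event[cc], ties = ties)
    cbind(model = label, fit$coefficients[, c("term", "coef", "hr",
                                              "ci_lower", "ci_upper", "p")],
          n = sum(cc), stringsAsFactors = FALSE)
  }
  uni <- lapply(names(cov), function(v)
    fit_one(cov[, v, drop = FALSE], "univariate"))
  multi <- fit_one(cov, "multivariate")
  out <- do.call(rbind, c(uni, list(multi)))
  rownames(out) <- NULL
  out[, c("model", "term", "n", "coef", "hr", "ci_lower", "ci_upper", "p")]
}
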