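#' Two-group comparison table (Student t-tests)
#'
#' Per-feature comparison of the two outcome groups: group sizes, means
#' and SDs, the classical pooled-variance (Student) two-sample t statistic
#' and its two-sided p-value. Missing values are excluded per feature; a
#' feature with fewer than two observations in either group gets a
#' missing p with the reason recorded.
#'
#' @param cohort Cohort data frame with a binary `neoatherosclerosis`
#'   column (or the column named in `outcome`).
#' @param features Feature columns to compare (default: the canonical 17
#'   present in `cohort`).
#' @param outcome Name of the 0/1 outcome column.
#' @param welch Use the Welch (unequal-variance) test instead of the
#'   pooled-variance Student test.
#' @return Data frame of class `oct_group_comparison`: one row per
#'   feature with `n_pos`, `mean_pos`, `sd_pos`, `n_neg`, `mean_neg`,
#'   `sd_neg`, `t`, `p`, `note`.
#' @export
ttest_table <- function(cohort, features = NULL,
                        outcome = "neoatherosclerosis", welch = FALSE) {
  if (is.null(features))
    features <- intersect(oct_feature_names(), names(cohort))
  y <- cohort[[outcome]]
  if (is.null(y) || !all(y %in% c(0, 1)))
    oct_value_error("outcome column must be 0/1")
  rows <- lapply(features, function(f) {
    x <- cohort[[f]]
    xp <- x[y == 1 & !is.na(x)]; xn <- x[y == 0 & !is.na(x)]
    row <- data.frame(feature = f,
                      n_pos = length(xp), mean_pos = mean(xp), sd_pos = sd(xp),
                      n_neg = length(xn), mean_neg = mean(xn), sd_neg = sd(xn),
                      t = NA_real_, p = NA_real_, note = "",
                      stringsAsFactors = FALSE)
    if (length(xp) < 2L || length(xn) < 2L) {
      row$note <- "fewer than 2 observations in a group"
      return(row)
    }
    tt <- t.test(xp, xn, var.equal = !welch)
    row$t <- unname(tt$statistic); row$p <- tt$p.value
    row
  })
  out <- do.call(rbind, rows)
  class(out) <- c("oct_group_comparison", class(out))
  out
}

# Firth bias-reduced logistic regression (adjusted-score IRLS); used when
# the plain MLE is unstable, e.g. quasi-separation with few events.
firth_logistic <- function(X, y, maxit = 100L, eps = 1e-8) {
  p <- ncol(X)
  beta <- rep(0, p)
  for (it in seq_len(maxit)) {
    eta <- as.numeric(X %*% beta)
    mu <- plogis(eta)
    W <- mu * (1 - mu)
    XW <- X * sqrt(W)
    XtWX <- crossprod(XW)
    XtWXinv <- solve(XtWX)
    h <- rowSums((X %*% XtWXinv) * X) * W
    U <- as.numeric(crossprod(X, y - mu + h * (0.5 - mu)))
    delta <- as.numeric(XtWXinv %*% U)
    beta <- beta + delta
    if (max(abs(U)) < eps || max(abs(delta)) < 1e-10) break
  }
  se <- sqrt(diag(solve(XtWX)))
  list(coefficients = beta, se = se, iterations = it,
       converged = max(abs(U)) < eps)
}

#' Logistic regression with odds ratios and Wald confidence intervals
#'
#' Maximum-likelihood logistic fit (iteratively reweighted least squares
#' via [stats::glm()]) on the complete cases of the requested predictors.
#' Reports per predictor the coefficient, odds ratio, exponentiated Wald
#' confidence interval and Wald p-value. Predictors with zero variance
#' are dropped (with a warning) as aliased; any remaining rank deficiency
#' is an error naming the aliased columns. Quasi-separation is detected
#' as a standardized coefficient drifting beyond 15 and flagged; a Firth
#' bias-reduced fit is available for that situation.
#'
#' @param cohort Cohort data frame.
#' @param predictors Character vector of predictor columns.
#' @param outcome Name of the 0/1 outcome column.
#' @param conf_level Confidence level for the Wald intervals.
#' @param firth Use Firth penalized likelihood instead of the plain MLE.
#' @return Data frame of class `oct_logistic_fit` (one row per predictor,
#'   intercept excluded) with `term`, `estimate`, `se`, `or`, `ci_lo`,
#'   `ci_hi`, `p`. Attributes: `converged`, `iterations`, `separation`,
#'   `dropped`, `n`, `model`.
#' @export
fit_logistic <- function(cohort, predictors,
                         outcome = "neoatherosclerosis",
                         conf_level = 0.95, firth = FALSE) {
  stopifnot(length(predictors) >= 1L)
  miss <- setdiff(c(predictors, outcome), names(cohort))
  if (length(miss)) oct_value_error(paste0("missing columns: ",
                                           paste(miss, collapse = ", ")))
  dat <- cohort[, c(outcome, predictors), drop = FALSE]
  dat <- dat[complete.cases(dat), , drop = FALSE]
  y <- dat[[outcome]]
  if (!all(y %in% c(0, 1)) || length(unique(y)) < 2L)
    oct_value_error("outcome must be binary with both classes present")

  dropped <- predictors[vapply(predictors, function(f)
    sd(dat[[f]]) == 0 || !is.finite(sd(dat[[f]])), logical(1L))]
  if (length(dropped)) {
    warning("dropping zero-variance predictor(s): ",
            paste(dropped, collapse = ", "))
    predictors <- setdiff(predictors, dropped)
  }
  form <- if (length(predictors) == 0L) y ~ 1 else
    stats::reformulate(sprintf("`%s`", predictors), response = "y")
  dat$y <- y
  mm <- model.matrix(form, dat)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    aliased <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1L):ncol(mm)]]
    oct_value_error(paste0("rank-deficient design; aliased columns: ",
                           paste(aliased, collapse = ", ")))
  }

  z <- qnorm(1 - (1 - conf_level) / 2)
  if (firth && length(predictors) > 0L) {
    ff <- firth_logistic(mm, y)
    est <- ff$coefficients; se <- ff$se
    names(est) <- names(se) <- colnames(mm)
    converged <- ff$converged; iters <- ff$iterations
  } else {
    fit <- glm(form, data = dat, family = binomial(),
               control = glm.control(epsilon = 1e-10, maxit = 100L))
    est <- coef(fit); se <- sqrt(diag(vcov(fit)))
    converged <- fit$converged; iters <- fit$iter
  }

  terms <- setdiff(names(est), "(Intercept)")
  sdx <- vapply(predictors, function(f) sd(dat[[f]]), numeric(1L))
  separation <- length(terms) > 0L &&
    any(abs(est[terms] * sdx[match(gsub("`", "", terms), predictors)]) > 15,
        na.rm = TRUE)
  if (separation)
    warning("possible quasi-separation: standardized coefficient beyond 15")

  wald <- est / se
  out <- data.frame(term = gsub("`", "", terms),
                    estimate = unname(est[terms]),
                    se = unname(se[terms]),
                    or = unname(exp(est[terms])),
                    ci_lo = unname(exp(est[terms] - z * se[terms])),
                    ci_hi = unname(exp(est[terms] + z * se[terms])),
                    p = unname(2 * pnorm(-abs(wald[terms]))),
                    stringsAsFactors = FALSE)
  attr(out, "intercept") <- unname(est["(Intercept)"])
  attr(out, "converged") <- converged
  attr(out, "iterations") <- iters
  attr(out, "separation") <- separation
  attr(out, "dropped") <- dropped
  attr(out, "n") <- nrow(dat)
  class(out) <- c("oct_logistic_fit", class(out))
  out
}

#' Univariate logistic screen
#'
#' Fits a single-predictor logistic regression for each candidate feature
#' and returns those with Wald p-value below `alpha`, preserving the
#' canonical feature order -- the inclusion rule for the subsequent
#' multivariate model.
#'
#' @param cohort Cohort data frame.
#' @param features Candidate features (e.g. the retained set from
#'   [prune_collinear()]).
#' @param alpha Inclusion threshold on the Wald p-value.
#' @param outcome Name of the 0/1 outcome column.
#' @return List of class `oct_univariate_screen`: `table` (one row per
#'   feature: `or`, `ci_lo`, `ci_hi`, `p`, `separation`), `significant`
#'   (character vector), `alpha`.
#' @export
univariate_screen <- function(cohort, features, alpha = 0.05,
                              outcome = "neoatherosclerosis") {
  canon <- oct_feature_names()
  features <- features[order(match(features, canon))]
  rows <- lapply(features, function(f) {
    fit <- withCallingHandlers(
      fit_logistic(cohort, f, outcome = outcome),
      warning = function(w) invokeRestart("muffleWarning"))
    data.frame(feature = f, or = fit$or, ci_lo = fit$ci_lo,
               ci_hi = fit$ci_hi, p = fit$p,
               separation = attr(fit, "separation"),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  structure(list(table = tab,
                 significant = tab$feature[!is.na(tab$p) & tab$p < alpha],
                 alpha = alpha),
            class = "oct_univariate_screen")
}

#' ROC analysis with AUC, DeLong CI and Youden-type cutoff
#'
#' Empirical ROC curve of a continuous score against a binary outcome
#' (higher score predicts the positive class). The AUC is the tie-
#' corrected Mann-Whitney rank statistic; its confidence interval comes
#' from DeLong's method (default) or a seeded stratified bootstrap. The
#' optimal cutoff maximizes sensitivity + specificity (the Youden rule);
#' cutoff ties are broken toward the higher specificity, then toward the
#' higher threshold.
#'
#' @param score Numeric score vector.
#' @param outcome Binary 0/1 outcome vector.
#' @param conf_level Confidence level of the AUC interval.
#' @param ci_method `"delong"` or `"bootstrap"`.
#' @param boot_n Bootstrap resamples when `ci_method = "bootstrap"`.
#' @param seed Seed for the bootstrap.
#' @return List of class `oct_roc`: `auc`, `ci` (length 2), `cutoff`,
#'   `sensitivity`, `specificity`, `curve` (data frame with `threshold`,
#'   `sensitivity`, `specificity`), `n_pos`, `n_neg`, `degenerate`.
#' @export
roc_analysis <- function(score, outcome, conf_level = 0.95,
                         ci_method = c("delong", "bootstrap"),
                         boot_n = 2000L, seed = 1L) {
  ci_method <- match.arg(ci_method)
  ok <- !is.na(score) & !is.na(outcome)
  score <- score[ok]; outcome <- outcome[ok]
  if (!all(outcome %in% c(0, 1)) || length(unique(outcome)) < 2L)
    oct_value_error("outcome must be binary with both classes present")
  npos <- sum(outcome == 1); nneg <- sum(outcome == 0)

  if (sd(score) == 0) {
    warning("constant score: AUC is 0.5 by convention")
    return(structure(list(auc = 0.5, ci = c(NA_real_, NA_real_),
                          cutoff = NA_real_, sensitivity = NA_real_,
                          specificity = NA_real_,
                          curve = data.frame(threshold = c(Inf, -Inf),
                                             sensitivity = c(0, 1),
                                             specificity = c(1, 0)),
                          n_pos = npos, n_neg = nneg, degenerate = TRUE),
                     class = "oct_roc"))
  }

  # tie-corrected Mann-Whitney AUC from average ranks
  r <- rank(score)
  auc <- (sum(r[outcome == 1]) - npos * (npos + 1) / 2) / (npos * nneg)

  proc <- pROC::roc(response = outcome, predictor = score,
                    levels = c(0, 1), direction = "<", quiet = TRUE)
  ci <- if (ci_method == "delong") {
    as.numeric(pROC::ci.auc(proc, conf.level = conf_level,
                            method = "delong"))[c(1L, 3L)]
  } else {
    set.seed(seed)
    as.numeric(pROC::ci.auc(proc, conf.level = conf_level,
                            method = "bootstrap", boot.n = boot_n,
                            boot.stratified = TRUE))[c(1L, 3L)]
  }

  # candidate thresholds: midpoints between consecutive distinct scores
  s <- sort(unique(score))
  thr <- c(-Inf, (head(s, -1L) + s[-1L]) / 2, Inf)
  sens <- vapply(thr, function(t) mean(score[outcome == 1] > t), numeric(1L))
  spec <- vapply(thr, function(t) mean(score[outcome == 0] <= t), numeric(1L))
  j <- sens + spec
  best <- which(abs(j - max(j)) < 1e-12)
  best <- best[order(-spec[best], -thr[best])][1L]

  structure(list(auc = auc, ci = ci, cutoff = thr[best],
                 sensitivity = sens[best], specificity = spec[best],
                 curve = data.frame(threshold = thr, sensitivity = sens,
                                    specificity = spec),
                 n_pos = npos, n_neg = nneg, degenerate = FALSE),
            class = "oct_roc")
}
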