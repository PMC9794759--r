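test_that("the group-comparison table matches the pooled-variance formula", {
  coh <- data.frame(lesion_length = c(1, 2, 3, 4, 5, 6),
                    neoatherosclerosis = c(1, 1, 1, 0, 0, 0))
  tt <- ttest_table(coh, features = "lesion_length")
  oracle <- hand_student_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(tt$t, oracle$t, tolerance = 1e-12)
  expect_equal(tt$p, oracle$p, tolerance = 1e-12)
  expect_equal(tt$t, -3.674235, tolerance = 1e-6)
  expect_equal(tt$p, 0.0213, tolerance = 1e-2)
  # identical groups: t = 0, p = 1
  coh2 <- data.frame(lesion_length = c(1, 2, 3, 1, 2, 3),
                     neoatherosclerosis = c(1, 1, 1, 0, 0, 0))
  tt2 <- ttest_table(coh2, features = "lesion_length")
  expect_equal(tt2$t, 0); expect_equal(tt2$p, 1)
})

test_that("a group with fewer than two observations yields a missing p with reason", {
  coh <- data.frame(max_fc_area = c(3, NA, NA, 4, 5, 6),
                    neoatherosclerosis = c(1, 1, 1, 0, 0, 0))
  tt <- ttest_table(coh, features = "max_fc_area")
  expect_true(is.na(tt$p))
  expect_match(tt$note, "fewer than 2")
  expect_equal(tt$n_pos, 1)
})

test_that("the binary-predictor logistic MLE equals the 2x2 cross-product ratio", {
  coh <- data.frame(
    x = rep(c(1, 1, 0, 0), c(10, 40, 9, 121)),
    neoatherosclerosis = rep(c(1, 0, 1, 0), c(10, 40, 9, 121)))
  fit <- fit_logistic(coh, "x", outcome = "neoatherosclerosis")
  expect_equal(fit$or, (10 * 121) / (40 * 9), tolerance = 1e-6)
  expect_true(attr(fit, "converged"))
  expect_true(fit$ci_lo <= fit$or && fit$or <= fit$ci_hi)
})

test_that("zero-variance predictors are dropped; the intercept carries the prevalence", {
  coh <- data.frame(x = rep(0, 50),
                    neoatherosclerosis = rep(c(1, 0), c(10, 40)))
  expect_warning(fit <- fit_logistic(coh, "x"), "zero-variance")
  expect_equal(nrow(fit), 0)
  expect_equal(attr(fit, "intercept"), qlogis(10 / 50), tolerance = 1e-8)
})

test_that("rank-deficient designs and single-class outcomes are errors", {
  set.seed(2)
  coh <- data.frame(x = rnorm(40), neoatherosclerosis = rep(c(0, 1), 20))
  coh$y2 <- 2 * coh$x
  expect_error(fit_logistic(coh, c("x", "y2")),
               class = "octplaq_value_error", regexp = "aliased")
  coh$neoatherosclerosis <- 0
  expect_error(fit_logistic(coh, "x"), class = "octplaq_value_error",
               regexp = "both classes")
})

test_that("IRLS estimates match a direct likelihood-maximization oracle", {
  set.seed(33)
  done <- 0
  while (done < 30) {
    n <- sample(15:30, 1)
    k <- sample(1:2, 1)
    X <- cbind(1, matrix(rnorm(n * k), n))
    y <- rbinom(n, 1, plogis(X %*% c(0.2, rep(0.5, k))))
    if (length(unique(y)) < 2) next
    Xr <- X[, -1, drop = FALSE]
    colnames(Xr) <- paste0("p", seq_len(k))
    df <- data.frame(neoatherosclerosis = y, Xr)
    preds <- colnames(Xr)
    fit <- tryCatch(
      suppressWarnings(fit_logistic(df, preds)),
      octplaq_input_error = function(e) NULL)
    if (is.null(fit) || !attr(fit, "converged")) next
    beta <- c(attr(fit, "intercept"), fit$estimate)
    if (max(abs(beta)) > 10) next  # boundary/separated: MLE not interior
    dev_fit <- 2 * logistic_nll(beta, X, y)
    expect_lt(abs(dev_fit - oracle_deviance(X, y)), 1e-6)
    done <- done + 1
  }
})

test_that("quasi-separation is detected and the Firth option stays finite", {
  coh <- data.frame(x = c(1:10, 11:20),
                    neoatherosclerosis = rep(c(0, 1), each = 10))
  fit <- NULL
  w <- capture_warnings(fit <- fit_logistic(coh, "x"))
  expect_true(any(grepl("separation", w)))
  expect_true(attr(fit, "separation"))
  ff <- fit_logistic(coh, "x", firth = TRUE)
  expect_true(is.finite(ff$estimate) && is.finite(ff$se))
  expect_lt(abs(ff$estimate), abs(fit$estimate))
})

test_that("the univariate screen applies the inclusion rule in canonical order", {
  set.seed(12)
  n <- 400
  coh <- data.frame(
    fc_surface_area = c(rnorm(n / 2, 12, 3), rnorm(n / 2, 8, 3)),
    lesion_length = rnorm(n, 30, 10),
    neoatherosclerosis = rep(c(1, 0), each = n / 2))
  sc <- univariate_screen(coh, c("fc_surface_area", "lesion_length"))
  expect_equal(sc$significant, "fc_surface_area")
  expect_equal(sc$table$feature, c("lesion_length", "fc_surface_area"))
  sc_all <- univariate_screen(coh, c("fc_surface_area", "lesion_length"),
                              alpha = 1.0)
  expect_equal(sc_all$significant, c("lesion_length", "fc_surface_area"))
})

test_that("AUC equals exhaustive pair counting, including ties", {
  r1 <- suppressWarnings(roc_analysis(c(1, 2, 3, 4), c(0, 0, 1, 1)))
  expect_equal(r1$auc, 1)
  expect_equal(r1$sensitivity, 1); expect_equal(r1$specificity, 1)
  expect_true(r1$cutoff > 2 && r1$cutoff < 3)
  r2 <- roc_analysis(c(1, 3, 2, 4), c(0, 0, 1, 1))
  expect_equal(r2$auc, 0.75)
  set.seed(21)
  for (i in 1:20) {
    n <- sample(10:50, 1)
    score <- sample(1:8, n, replace = TRUE)  # heavy ties
    outcome <- rbinom(n, 1, 0.4)
    if (length(unique(outcome)) < 2) next
    r <- suppressWarnings(roc_analysis(score, outcome))
    expect_equal(r$auc, pair_auc(score, outcome), tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly increasing transforms", {
  set.seed(5)
  score <- rnorm(200); outcome <- rbinom(200, 1, plogis(score))
  a <- roc_analysis(score, outcome)$auc
  expect_equal(roc_analysis(exp(score), outcome)$auc, a)
  expect_equal(roc_analysis(qlogis(plogis(score)), outcome)$auc, a,
               tolerance = 1e-12)
})

test_that("degenerate and null scores behave as documented", {
  expect_warning(r <- roc_analysis(rep(1, 40), rep(c(0, 1), 20)), "constant")
  expect_equal(r$auc, 0.5)
  expect_true(r$degenerate)
  set.seed(9)
  rnull <- roc_analysis(rnorm(20000), rep(c(0, 1), each = 10000))
  expect_lt(abs(rnull$auc - 0.5), 0.01)
  expect_error(roc_analysis(rnorm(10), rep(1, 10)),
               class = "octplaq_value_error")
})

test_that("the cutoff maximizes sensitivity + specificity with the stated tie rule", {
  score <- c(1, 2, 3, 4, 5, 6)
  outcome <- c(0, 0, 1, 0, 1, 1)
  r <- roc_analysis(score, outcome)
  j <- r$curve$sensitivity + r$curve$specificity
  expect_equal(r$sensitivity + r$specificity, max(j))
  best <- r$curve[abs(j - max(j)) < 1e-12, ]
  expect_equal(r$specificity, max(best$specificity))
})

test_that("Wald intervals bracket the odds ratio and DeLong CI brackets the AUC", {
  set.seed(14)
  coh <- generate_cohort(demo_cohort_config(seed = 14))
  fit <- suppressWarnings(fit_logistic(coh, "fc_surface_area"))
  expect_true(fit$ci_lo <= fit$or && fit$or <= fit$ci_hi)
  r <- roc_analysis(coh$fc_surface_area, coh$neoatherosclerosis)
  expect_true(r$ci[1] <= r$auc && r$auc <= r$ci[2])
  rb <- roc_analysis(coh$fc_surface_area, coh$neoatherosclerosis,
                     ci_method = "bootstrap", boot_n = 200, seed = 3)
  expect_true(rb$ci[1] <= rb$auc && rb$auc <= rb$ci[2])
})
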