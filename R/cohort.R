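#' Configuration of a synthetic lesion cohort
#'
#' Defines the statistical structure of a lesion-level feature table with
#' a binary neoatherosclerosis outcome: per-feature Gaussian moments in
#' each outcome group, and collinearity blocks realized through a Gaussian
#' copula so that target Spearman rank correlations are exact in
#' distribution (a Spearman target rho maps to a latent Pearson
#' correlation 2 sin(pi rho / 6)). Features are physically non-negative;
#' negative draws are truncated at 0 (deterministically, preserving seed
#' reproducibility) and the truncated fraction is reported.
#'
#' @param features Data frame with columns `name`, `pos_mean`, `pos_sd`,
#'   `neg_mean`, `neg_sd` (one row per feature; `pos` = outcome 1 group).
#' @param n_pos,n_neg Group sizes (outcome 1 / outcome 0).
#' @param blocks List of collinearity blocks; each a list with `features`
#'   (indices or names), `rho` (target within-block Spearman correlation
#'   in \[-1, 1\]), and optionally `signs` (+1/-1 per member; the latent
#'   correlation between members i and j is `signs[i] * signs[j]` times
#'   the block level, so one anti-correlated member is expressible).
#' @param outcome_model `"group-labels"` (features drawn conditional on
#'   the group label; default) or `"logistic"` (features drawn from the
#'   `neg` moments for all rows, labels drawn from a logistic link).
#' @param logistic_intercept,logistic_coef Link parameters for
#'   `outcome_model = "logistic"`; `logistic_coef` is a named vector over
#'   (a subset of) feature names.
#' @param seed Integer seed.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(features, n_pos, n_neg, blocks = list(),
                          outcome_model = c("group-labels", "logistic"),
                          logistic_intercept = 0,
                          logistic_coef = NULL,
                          seed = 1L) {
  outcome_model <- match.arg(outcome_model)
  req <- c("name", "pos_mean", "pos_sd", "neg_mean", "neg_sd")
  if (!is.data.frame(features) || !all(req %in% names(features)))
    oct_config_error("features must be a data frame with columns name, pos_mean, pos_sd, neg_mean, neg_sd")
  if (anyDuplicated(features$name))
    oct_config_error("duplicated feature names")
  if (any(features$pos_sd < 0) || any(features$neg_sd < 0))
    oct_config_error("feature SDs must be >= 0")
  if (n_pos < 0 || n_neg < 0 || n_pos + n_neg < 1)
    oct_config_error("group sizes must be non-negative and sum to >= 1")
  p <- nrow(features)
  for (b in seq_along(blocks)) {
    bl <- blocks[[b]]
    idx <- if (is.character(bl$features)) match(bl$features, features$name)
           else as.integer(bl$features)
    if (anyNA(idx) || any(idx < 1L | idx > p))
      oct_config_error(sprintf("block %d references unknown features", b))
    if (abs(bl$rho) > 1)
      oct_config_error(sprintf("block %d: target rho must be in [-1, 1]", b))
    blocks[[b]]$features <- idx
    if (is.null(bl$signs)) blocks[[b]]$signs <- rep(1, length(idx))
    else if (length(bl$signs) != length(idx) || !all(abs(bl$signs) == 1))
      oct_config_error(sprintf("block %d: signs must be +/-1 per member", b))
  }
  cfg <- structure(list(features = features, n_pos = as.integer(n_pos),
                        n_neg = as.integer(n_neg), blocks = blocks,
                        outcome_model = outcome_model,
                        logistic_intercept = logistic_intercept,
                        logistic_coef = logistic_coef,
                        seed = as.integer(seed)),
                   class = "cohort_config")
  latent_correlation(cfg)  # fail early on infeasible structure
  cfg
}

# Latent normal correlation matrix implied by the Spearman block targets.
latent_correlation <- function(config) {
  p <- nrow(config$features)
  S <- diag(p)
  for (b in seq_along(config$blocks)) {
    bl <- config$blocks[[b]]
    r <- 2 * sin(pi * bl$rho / 6)
    idx <- bl$features; sg <- bl$signs
    for (i in seq_along(idx)) for (j in seq_along(idx)) {
      if (i != j) S[idx[i], idx[j]] <- sg[i] * sg[j] * r
    }
  }
  ev <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-8) {
    bad <- which(vapply(config$blocks, function(bl) {
      m <- length(bl$features)
      m > 1 && 2 * sin(pi * bl$rho / 6) < -1 / (m - 1) + 1e-12
    }, logical(1L)))
    oct_config_error(paste0(
      "correlation structure is not positive semidefinite",
      if (length(bad)) paste0(" (block ", paste(bad, collapse = ", "), ")")))
  }
  S
}

#' Generate a synthetic lesion cohort table
#'
#' Draws a lesion feature table from a [cohort_config()]: latent
#' multivariate normal scores with the block correlation structure, scaled
#' to the per-group moments, truncated at 0. The fraction of truncated
#' draws (overall and per feature) is attached as attribute `truncation`.
#'
#' @param config A [cohort_config()].
#' @return Data frame with columns `lesion_id`, the configured features,
#'   and `neoatherosclerosis` (0/1); rows are positives first under
#'   `"group-labels"`. Attribute `truncation` reports the clipping.
#' @export
#' @examples
#' cc <- reference_cohort_config(seed = 1)
#' coh <- generate_cohort(cc)
#' table(coh$neoatherosclerosis)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  S <- latent_correlation(config)
  p <- nrow(config$features)
  fnames <- config$features$name
  n <- config$n_pos + config$n_neg

  draw <- function(nn, mu, sdv) {
    Z <- MASS::mvrnorm(nn, mu = rep(0, p), Sigma = S, tol = 1e-6)
    if (nn == 1L) Z <- matrix(Z, nrow = 1L)
    sweep(sweep(Z, 2L, sdv, `*`), 2L, mu, `+`)
  }

  if (config$outcome_model == "group-labels") {
    Xp <- if (config$n_pos > 0)
      draw(config$n_pos, config$features$pos_mean, config$features$pos_sd)
    Xn <- if (config$n_neg > 0)
      draw(config$n_neg, config$features$neg_mean, config$features$neg_sd)
    X <- rbind(if (config$n_pos > 0) Xp, if (config$n_neg > 0) Xn)
    y <- rep(c(1L, 0L), c(config$n_pos, config$n_neg))
  } else {
    X <- draw(n, config$features$neg_mean, config$features$neg_sd)
    co <- rep(0, p)
    if (!is.null(config$logistic_coef)) {
      idx <- match(names(config$logistic_coef), fnames)
      if (anyNA(idx)) oct_config_error("logistic_coef names unknown")
      co[idx] <- config$logistic_coef
    }
    eta <- config$logistic_intercept + as.numeric(X %*% co)
    y <- rbinom(n, 1L, plogis(eta))
  }

  truncated <- X < 0
  X[truncated] <- 0
  out <- data.frame(lesion_id = sprintf("lesion_%03d", seq_len(n)), X,
                    neoatherosclerosis = y, stringsAsFactors = FALSE)
  names(out) <- c("lesion_id", fnames, "neoatherosclerosis")
  attr(out, "truncation") <- list(
    overall = mean(truncated),
    per_feature = setNames(colMeans(truncated), fnames))
  out
}

# Table of two-group feature moments used by the reference configurations:
# neoatherosclerosis (pos, n = 19) vs no-neoatherosclerosis (neg, n = 161).
reference_feature_moments <- function() {
  data.frame(
    name = oct_feature_names(),
    pos_mean = c(35.19, 1.70, 4.81, 0.99, 2.39, 193.75, 18.63, 1.28, 0.16,
                 0.50, 0.02, 256.63, 20.50, 0.01, 7.31, 27.27, 2836.81),
    pos_sd   = c(8.15, 0.93, 1.93, 0.49, 0.50, 100.45, 12.37, 0.19, 0.12,
                 0.13, 0.02, 70.97, 4.00, 0.00, 1.30, 7.76, 1967.20),
    neg_mean = c(28.12, 2.45, 6.02, 1.13, 2.68, 128.13, 16.03, 1.06, 0.28,
                 0.44, 0.04, 135.68, 27.69, 0.03, 3.64, 7.53, 715.92),
    neg_sd   = c(12.09, 1.40, 2.19, 0.41, 0.48, 79.90, 9.04, 0.40, 0.13,
                 0.23, 0.06, 88.10, 19.26, 0.03, 2.29, 7.43, 713.78),
    stringsAsFactors = FALSE)
}

# Six planted feature blocks: four tightly collinear groups above the 0.9
# pruning threshold, one fibrous-cap bulk group just below it (with the
# minimum cap thickness anti-correlated to cap size), and lesion length
# as a singleton.
reference_blocks <- function() {
  list(
    list(features = c("min_lumen_area", "mean_lumen_area",
                      "min_lumen_diameter", "mean_lumen_diameter"),
         rho = 0.95),
    list(features = c("max_calcium_angle", "min_calcium_angle"), rho = 0.95),
    list(features = c("max_calcium_thickness", "min_calcium_thickness",
                      "max_calcium_depth", "min_calcium_depth"), rho = 0.95),
    list(features = c("max_fc_angle", "min_fc_angle"), rho = 0.95),
    list(features = c("min_fc_thickness", "max_fc_area",
                      "fc_surface_area", "fc_burden"),
         rho = 0.85, signs = c(-1, 1, 1, 1)))
}

#' Reference cohort configuration: a realistic 180-lesion two-group cohort
#'
#' All 17 features carry the package's reference two-group moments --
#' values typical of a neoatherosclerosis study with 19 event and 161
#' control lesions (see `reference_feature_moments` in the source) --
#' with the six planted collinearity blocks of [demo_cohort_config()].
#'
#' @param n_pos,n_neg Group sizes.
#' @param seed Integer seed.
#' @return A [cohort_config()].
#' @export
reference_cohort_config <- function(n_pos = 19L, n_neg = 161L, seed = 1L) {
  cohort_config(reference_feature_moments(), n_pos = n_pos, n_neg = n_neg,
                blocks = reference_blocks(), seed = seed)
}

#' Demo cohort configuration: one truly predictive feature
#'
#' Cohort with the six planted collinearity blocks in which only
#' fibrous-cap surface area differs between outcome groups (it keeps its
#' reference two-group moments); every other feature carries the
#' control-group moments in both groups. This is the configuration whose analysis outcome is
#' known by construction: pruning at |rho| > 0.9 eliminates 8 features,
#' and fibrous-cap surface area is the only genuinely predictive one.
#'
#' @inheritParams reference_cohort_config
#' @return A [cohort_config()].
#' @export
demo_cohort_config <- function(n_pos = 19L, n_neg = 161L, seed = 7L) {
  m <- reference_feature_moments()
  keep <- m$name == "fc_surface_area"
  m$pos_mean[!keep] <- m$neg_mean[!keep]
  m$pos_sd[!keep] <- m$neg_sd[!keep]
  cohort_config(m, n_pos = n_pos, n_neg = n_neg,
                blocks = reference_blocks(), seed = seed)
}
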