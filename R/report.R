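#' Assemble the analysis report
#'
#' Collects the results of every statistical stage into one serializable
#' report object mirroring the study's outputs: the two-group comparison
#' table, the correlation/clustering summary, the retained feature set,
#' univariate and multivariate odds-ratio tables, and the ROC summary.
#' Every block names its source stage, and a provenance block (package
#' version, seed, configuration hash) is mandatory.
#'
#' @param comparison [ttest_table()] result.
#' @param correlation [spearman_matrix()] result.
#' @param clusters [cluster_features()] result.
#' @param pruning [prune_collinear()] result.
#' @param screen [univariate_screen()] result.
#' @param multivariate [fit_logistic()] result for the multivariate model,
#'   or `NULL` when no feature passed the univariate screen.
#' @param roc [roc_analysis()] result (or `NULL`).
#' @param provenance List with at least `seed`; `config_md5` and
#'   `package_version` are filled in if absent.
#' @return List of class `oct_report`.
#' @export
build_report <- function(comparison, correlation, clusters, pruning,
                         screen, multivariate, roc, provenance = list()) {
  stopifnot(inherits(comparison, "oct_group_comparison"),
            inherits(correlation, "oct_correlation"),
            inherits(clusters, "oct_feature_clusters"),
            inherits(pruning, "oct_pruning"),
            inherits(screen, "oct_univariate_screen"))
  if (is.null(provenance$package_version))
    provenance$package_version <- as.character(packageVersion("octplaq"))
  if (is.null(provenance$seed)) provenance$seed <- NA_integer_
  if (is.null(provenance$config_md5)) provenance$config_md5 <- ""

  mv <- NULL
  if (!is.null(multivariate)) {
    stopifnot(inherits(multivariate, "oct_logistic_fit"))
    mv <- list(stage = "multivariate_logistic",
               table = as.data.frame(unclass(multivariate))[
                 , c("term", "estimate", "or", "ci_lo", "ci_hi", "p")],
               converged = attr(multivariate, "converged"),
               separation = attr(multivariate, "separation"),
               n = attr(multivariate, "n"))
  }
  rc <- NULL
  if (!is.null(roc)) {
    stopifnot(inherits(roc, "oct_roc"))
    rc <- list(stage = "roc_analysis",
               auc = roc$auc, ci = roc$ci, cutoff = roc$cutoff,
               sensitivity = roc$sensitivity, specificity = roc$specificity,
               n_pos = roc$n_pos, n_neg = roc$n_neg,
               degenerate = roc$degenerate,
               curve = roc$curve)
  }
  structure(list(
    schema_version = SCHEMA_VERSION,
    provenance = provenance,
    group_comparison = list(stage = "ttest_table",
                            table = as.data.frame(unclass(comparison))),
    correlation = list(stage = "spearman_matrix",
                       features = rownames(correlation$rho),
                       rho = unname(correlation$rho),
                       zero_variance = correlation$zero_variance),
    clustering = list(stage = "cluster_features", k = clusters$k,
                      clusters = as.list(clusters$clusters),
                      excluded = clusters$excluded),
    selection = list(stage = "prune_collinear",
                     threshold = pruning$threshold,
                     retained = pruning$retained,
                     eliminated = pruning$eliminated),
    univariate = list(stage = "univariate_screen", alpha = screen$alpha,
                      table = screen$table,
                      significant = screen$significant),
    multivariate = mv,
    roc = rc), class = "oct_report")
}
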