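#' Spearman rank correlation matrix of the plaque features
#'
#' Pairwise-complete Spearman rank correlations (ties get average ranks)
#' over the feature columns of a cohort table, together with the
#' elementwise squared matrix ("explained variance", the quantity shown in
#' correlation heatmaps). A feature with zero variance has no defined rank
#' correlation; its row and column are set to missing and its name
#' reported.
#'
#' @param cohort Cohort data frame (from [generate_cohort()] /
#'   [read_cohort()]), or any data frame containing the feature columns.
#' @param features Character vector of feature columns (default: the 17
#'   canonical features present in `cohort`).
#' @return List of class `oct_correlation`: `rho`, `rho2` (p x p
#'   matrices), `zero_variance` (character), `n` (rows used).
#' @export
spearman_matrix <- function(cohort, features = NULL) {
  if (is.null(features))
    features <- intersect(oct_feature_names(), names(cohort))
  if (length(features) < 2L)
    oct_value_error("need at least two feature columns")
  X <- as.matrix(cohort[, features, drop = FALSE])
  storage.mode(X) <- "double"
  zv <- features[apply(X, 2L, function(x) {
    x <- x[!is.na(x)]
    length(x) < 3L || length(unique(x)) < 2L
  })]
  rho <- suppressWarnings(
    cor(X, method = "spearman", use = "pairwise.complete.obs"))
  rho[zv, ] <- NA_real_; rho[, zv] <- NA_real_
  diag(rho) <- ifelse(features %in% zv, NA_real_, 1)
  structure(list(rho = rho, rho2 = rho^2, zero_variance = zv,
                 n = nrow(X)),
            class = "oct_correlation")
}

#' Hierarchical clustering of features on their correlation profiles
#'
#' Agglomerative clustering of the features using the squared Euclidean
#' distance between rows of the squared-correlation (explained variance)
#' matrix, cut into `k` clusters. Features whose correlations are missing
#' (zero variance) are excluded and reported.
#'
#' @param correlation An `oct_correlation` from [spearman_matrix()].
#' @param k Number of clusters to cut to.
#' @param linkage Agglomeration method passed to [stats::hclust()]
#'   (`"complete"` by default; `"average"` and `"ward.D2"` are sensible
#'   alternatives).
#' @return List of class `oct_feature_clusters`: `clusters` (named integer
#'   vector), `hclust` (the merge tree), `k`, `excluded`.
#' @export
cluster_features <- function(correlation, k = 6L, linkage = "complete") {
  stopifnot(inherits(correlation, "oct_correlation"))
  r2 <- correlation$rho2
  keep <- setdiff(rownames(r2), correlation$zero_variance)
  r2 <- r2[keep, keep, drop = FALSE]
  if (nrow(r2) < 2L) oct_value_error("fewer than two usable features")
  k <- min(as.integer(k), nrow(r2))
  d <- dist(r2)^2  # squared Euclidean between correlation profiles
  hc <- hclust(d, method = linkage)
  structure(list(clusters = cutree(hc, k = k), hclust = hc, k = k,
                 excluded = correlation$zero_variance),
            class = "oct_feature_clusters")
}

#' Collinearity pruning by Spearman threshold
#'
#' Greedy elimination of collinear features: features are visited in
#' order of ascending univariate p-value (ties broken by the canonical
#' feature order), and a feature is retained only if its absolute rank
#' correlation with every already-retained feature is at or below the
#' threshold. Equivalently, of every pair with |rho| above the threshold
#' the feature with the larger p-value is eliminated, iterated to a fixed
#' point, which makes the procedure idempotent and leaves no retained
#' pair above the threshold.
#'
#' @param correlation An `oct_correlation` from [spearman_matrix()] (or a
#'   plain correlation matrix).
#' @param p_values Named numeric vector of univariate p-values covering
#'   the features of `correlation` (e.g. the `p` column of
#'   [ttest_table()]).
#' @param threshold Absolute Spearman correlation above which a pair is
#'   considered collinear.
#' @return List of class `oct_pruning`: `retained`, `eliminated`
#'   (character vectors in canonical order), `threshold`.
#' @export
prune_collinear <- function(correlation, p_values, threshold = 0.9) {
  rho <- if (inherits(correlation, "oct_correlation")) correlation$rho
         else as.matrix(correlation)
  feats <- rownames(rho)
  if (is.null(feats)) oct_value_error("correlation matrix must have feature names")
  if (!all(feats %in% names(p_values)))
    oct_value_error(paste0("p_values missing for: ",
                           paste(setdiff(feats, names(p_values)), collapse = ", ")))
  p <- p_values[feats]
  p[is.na(p)] <- Inf
  canon <- match(feats, oct_feature_names())
  canon[is.na(canon)] <- length(oct_feature_names()) + seq_len(sum(is.na(canon)))
  ord <- order(p, canon)
  retained <- character(0)
  for (f in feats[ord]) {
    r <- abs(rho[f, retained])
    r[is.na(r)] <- 0
    if (all(r <= threshold)) retained <- c(retained, f)
  }
  retained <- feats[order(canon)][feats[order(canon)] %in% retained]
  structure(list(retained = retained,
                 eliminated = setdiff(feats, retained),
                 threshold = threshold),
            class = "oct_pruning")
}
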