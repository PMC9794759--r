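# End-to-end driver: simulate -> extract -> select -> analyze.

run_config_keys <- function() {
  list(top = c("schema_version", "seed", "phantom", "cohort", "selection",
               "analysis"),
       phantom = c("n_frames", "a_lines_per_frame", "radial_samples",
                   "pixel_size_radial", "frame_pitch", "lumen_radius",
                   "calcium", "fc", "noise_sd", "decay_half_width"),
       cohort = c("preset", "n_pos", "n_neg"),
       selection = c("threshold", "k", "linkage"),
       analysis = c("alpha", "roc_feature", "welch", "ci_method"))
}

#' Build a pipeline run configuration
#'
#' A serializable description of one end-to-end run: global seed, phantom
#' geometry, cohort preset and sizes, selection and analysis parameters.
#' The defaults describe the package demo: a 10-frame phantom with one
#' 90-degree fibrous cap and one calcium deposit, and the
#' one-predictive-feature cohort of [demo_cohort_config()].
#' Unknown keys anywhere in the configuration are rejected.
#'
#' @param seed Global seed; per-stage substreams are derived from it
#'   deterministically so stages can be re-run alone.
#' @param phantom List of phantom settings (see [phantom_config()]);
#'   `calcium` and `fc` are lists of plain spec lists.
#' @param cohort List: `preset` (`"demo"` or `"reference"`), `n_pos`, `n_neg`.
#' @param selection List: `threshold`, `k`, `linkage`.
#' @param analysis List: `alpha`, `roc_feature`, `welch`, `ci_method`.
#' @return A validated `oct_run_config` list.
#' @export
run_config <- function(seed = 7L,
                       phantom = list(),
                       cohort = list(),
                       selection = list(),
                       analysis = list()) {
  keys <- run_config_keys()
  cfg <- list(schema_version = SCHEMA_VERSION,
              seed = as.integer(seed),
              phantom = modifyList(list(
                n_frames = 10L, a_lines_per_frame = 360L,
                radial_samples = 500L, pixel_size_radial = 0.005,
                frame_pitch = 0.2, lumen_radius = 1.5,
                calcium = list(list(frames = c(2L, 6L), arc_deg = 60,
                                    center_deg = 200, depth_mm = 0.15,
                                    thickness_mm = 0.4)),
                fc = list(list(frames = c(1L, 10L), arc_deg = 90,
                               center_deg = 45, thickness_mm = c(0.05, 0.15))),
                noise_sd = 0.01, decay_half_width = 4), phantom),
              cohort = modifyList(list(preset = "demo", n_pos = 19L,
                                       n_neg = 161L), cohort),
              selection = modifyList(list(threshold = 0.9, k = 6L,
                                          linkage = "complete"), selection),
              analysis = modifyList(list(alpha = 0.05,
                                         roc_feature = "fc_surface_area",
                                         welch = FALSE,
                                         ci_method = "delong"), analysis))
  validate_run_config(cfg)
  structure(cfg, class = "oct_run_config")
}

validate_run_config <- function(cfg) {
  keys <- run_config_keys()
  reject <- function(sub, allowed, where) {
    unknown <- setdiff(names(sub), allowed)
    if (length(unknown))
      oct_config_error(paste0("unknown ", where, " key(s): ",
                              paste(unknown, collapse = ", ")))
  }
  reject(cfg, keys$top, "configuration")
  reject(cfg$phantom, keys$phantom, "phantom")
  reject(cfg$cohort, keys$cohort, "cohort")
  reject(cfg$selection, keys$selection, "selection")
  reject(cfg$analysis, keys$analysis, "analysis")
  if (!cfg$cohort$preset %in% c("demo", "reference"))
    oct_config_error("cohort preset must be 'demo' or 'reference'")
  if (cfg$cohort$n_pos < 1L || cfg$cohort$n_neg < 1L)
    oct_config_error("both outcome groups must be non-empty (n_pos, n_neg >= 1)")
  if (!cfg$analysis$roc_feature %in% oct_feature_names())
    oct_config_error("analysis$roc_feature is not a known feature")
  invisible(cfg)
}

#' Save / load a run configuration (JSON)
#'
#' Round-trip safe: `load_run_config(save_run_config(cfg, path))`
#' reproduces `cfg`. Unknown keys in a loaded file are rejected.
#'
#' @param config An `oct_run_config`.
#' @param path JSON path.
#' @return `path` (save) or the validated `oct_run_config` (load).
#' @export
save_run_config <- function(config, path) {
  stopifnot(inherits(config, "oct_run_config"))
  write_atomic(path, function(p)
    jsonlite::write_json(unclass(config), p, digits = NA, auto_unbox = TRUE,
                         pretty = TRUE))
  invisible(path)
}

#' @rdname save_run_config
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) oct_schema_error(paste0("no such file: ", path))
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  raw$seed <- as.integer(raw$seed)
  validate_run_config(raw)
  structure(raw, class = "oct_run_config")
}

# Deterministic per-stage substream of the global seed, kept below 2^31.
stage_seed <- function(seed, stage) {
  (as.numeric(seed) * 10007 + stage * 101) %% 2147483647
}

phantom_config_from_run <- function(cfg) {
  ph <- cfg$phantom
  mk_frames <- function(fr) if (length(fr) == 2L) fr[1L]:fr[2L] else as.integer(fr)
  phantom_config(
    n_frames = ph$n_frames, a_lines_per_frame = ph$a_lines_per_frame,
    radial_samples = ph$radial_samples,
    pixel_size_radial = ph$pixel_size_radial, frame_pitch = ph$frame_pitch,
    lumen_radius = unlist(ph$lumen_radius),
    calcium_specs = lapply(ph$calcium, function(s)
      calcium_spec(mk_frames(s$frames), s$arc_deg,
                   center_deg = s$center_deg %||% 0,
                   depth_mm = s$depth_mm, thickness_mm = s$thickness_mm)),
    fc_specs = lapply(ph$fc, function(s)
      fc_spec(mk_frames(s$frames), s$arc_deg,
              center_deg = s$center_deg %||% 0,
              thickness_mm = unlist(s$thickness_mm))),
    noise_sd = ph$noise_sd, decay_half_width = ph$decay_half_width,
    seed = stage_seed(cfg$seed, 1L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Executes every stage in order on synthetic inputs: (1) render the
#' phantom pullback, trace the fibrous cap and extract its 17-feature
#' vector; (2) generate the lesion cohort; (3) group comparison, Spearman
#' correlation, hierarchical clustering, collinearity pruning, univariate
#' screen, multivariate logistic model, and ROC analysis of the
#' configured score feature; (4) assemble and persist the report.
#' Identical configuration + seed produces a byte-identical report file.
#'
#' @param config An `oct_run_config` from [run_config()].
#' @param out_dir Output directory; receives `pullback/`, `features.csv`,
#'   `cohort.csv`, `selection.json`, `report.json`.
#' @param figures_dir Optional directory for a box plot of the score
#'   feature and the ROC curve (PNG).
#' @param quiet Suppress progress messages.
#' @return The `oct_report`, invisibly.
#' @export
#' @examples
#' \donttest{
#' out <- tempfile("octplaq-run-")
#' rep <- run_pipeline(run_config(seed = 7), out_dir = out, quiet = TRUE)
#' rep$roc$auc
#' }
run_pipeline <- function(config, out_dir, figures_dir = NULL,
                         quiet = FALSE) {
  stopifnot(inherits(config, "oct_run_config"))
  validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  with_stage <- function(stage, expr) {
    tryCatch(expr, octplaq_error = function(e) {
      oct_stop(paste0("stage '", stage, "' failed: ", conditionMessage(e)),
               class(e)[1L])
    })
  }

  # -- stage 1: phantom pullback + feature extraction ---------------------
  oct_log(quiet, "stage simulate-pullback: rendering phantom")
  pcfg <- with_stage("simulate-pullback", phantom_config_from_run(config))
  pb <- with_stage("simulate-pullback", generate_pullback(pcfg))
  feats <- with_stage("extract", extract_lesion_features(pb))
  write_pullback(pb, file.path(out_dir, "pullback"),
                 traces = attr(feats, "traces"))
  write_features_csv(feats, file.path(out_dir, "features.csv"))
  oct_log(quiet, sprintf("stage extract: %d frames, %d traced cap windows",
                         pcfg$n_frames, length(attr(feats, "traces"))))

  # -- stage 2: cohort ----------------------------------------------------
  ccfg <- with_stage("simulate-cohort", {
    mk <- if (config$cohort$preset == "demo") demo_cohort_config
          else reference_cohort_config
    mk(n_pos = config$cohort$n_pos, n_neg = config$cohort$n_neg,
       seed = stage_seed(config$seed, 2L))
  })
  cohort <- with_stage("simulate-cohort", generate_cohort(ccfg))
  write_cohort(cohort, file.path(out_dir, "cohort.csv"))
  tr <- attr(cohort, "truncation")
  oct_log(quiet, sprintf(
    "stage simulate-cohort: %d lesions (%d pos / %d neg), %.2f%% draws truncated at 0",
    nrow(cohort), sum(cohort$neoatherosclerosis == 1),
    sum(cohort$neoatherosclerosis == 0), 100 * tr$overall))

  # -- stage 3: statistics ------------------------------------------------
  comparison <- with_stage("analyze",
    ttest_table(cohort, welch = config$analysis$welch))
  correlation <- with_stage("analyze", spearman_matrix(cohort))
  clusters <- with_stage("analyze",
    cluster_features(correlation, k = config$selection$k,
                     linkage = config$selection$linkage))
  pvals <- setNames(comparison$p, comparison$feature)
  pruning <- with_stage("analyze",
    prune_collinear(correlation, pvals,
                    threshold = config$selection$threshold))
  oct_log(quiet, sprintf(
    "stage select-features: %d retained, %d eliminated (|rho| > %.2f)",
    length(pruning$retained), length(pruning$eliminated),
    config$selection$threshold))
  screen <- with_stage("analyze",
    univariate_screen(cohort, pruning$retained,
                      alpha = config$analysis$alpha))
  multivariate <- NULL
  if (length(screen$significant) >= 1L)
    multivariate <- with_stage("analyze", suppressWarnings(
      fit_logistic(cohort, screen$significant)))
  roc <- with_stage("analyze", suppressWarnings(
    roc_analysis(cohort[[config$analysis$roc_feature]],
                 cohort$neoatherosclerosis,
                 ci_method = config$analysis$ci_method,
                 seed = stage_seed(config$seed, 3L))))
  oct_log(quiet, sprintf(
    "stage analyze: %d univariate-significant feature(s); AUC(%s) = %.3f",
    length(screen$significant), config$analysis$roc_feature, roc$auc))

  # -- stage 4: report ----------------------------------------------------
  cfg_json <- tempfile(fileext = ".json")
  on.exit(unlink(cfg_json), add = TRUE)
  jsonlite::write_json(unclass(config), cfg_json, digits = NA,
                       auto_unbox = TRUE)
  provenance <- list(seed = config$seed,
                     config_md5 = unname(tools::md5sum(cfg_json)),
                     package_version = as.character(packageVersion("octplaq")))
  report <- build_report(comparison, correlation, clusters, pruning, screen,
                         multivariate, roc, provenance = provenance)
  report$phantom <- list(
    stage = "extract",
    features = as.list(feats[1L, c("lesion_id", oct_feature_names())]),
    ground_truth = as.list(pb$ground_truth))
  write_atomic(file.path(out_dir, "selection.json"), function(p)
    jsonlite::write_json(unclass(pruning), p, digits = 10,
                         auto_unbox = TRUE, pretty = TRUE))
  write_report(report, file.path(out_dir, "report.json"))

  if (!is.null(figures_dir)) {
    dir.create(figures_dir, showWarnings = FALSE, recursive = TRUE)
    sc <- cohort[[config$analysis$roc_feature]]
    png(file.path(figures_dir, "score_boxplot.png"), width = 480, height = 480)
    boxplot(sc ~ cohort$neoatherosclerosis,
            names = c("no event", "event"), col = c("seagreen", "firebrick"),
            ylab = config$analysis$roc_feature, xlab = "")
    dev.off()
    png(file.path(figures_dir, "roc_curve.png"), width = 480, height = 480)
    plot(1 - roc$curve$specificity, roc$curve$sensitivity, type = "s",
         xlab = "1 - specificity", ylab = "sensitivity",
         main = sprintf("AUC = %.3f", roc$auc))
    abline(0, 1, lty = 2)
    dev.off()
  }
  oct_log(quiet, "report written to ", file.path(out_dir, "report.json"))
  invisible(report)
}
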