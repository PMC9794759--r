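#' Canonical plaque feature names
#'
#' The 17 lesion-level IVOCT plaque features, in their canonical order:
#' lesion length; minimum/mean lumen area and diameter; maximum/minimum
#' calcium angle, thickness and depth; maximum/minimum fibrous-cap (FC)
#' angle; minimum FC thickness; maximum FC area; FC surface area; FC
#' burden. This order is used for tie-breaking in feature selection and as
#' the fixed column order of cohort tables.
#'
#' @return Character vector of length 17.
#' @export
#' @examples
#' oct_feature_names()
oct_feature_names <- function() {
  c("lesion_length",
    "min_lumen_area", "mean_lumen_area",
    "min_lumen_diameter", "mean_lumen_diameter",
    "max_calcium_angle", "min_calcium_angle",
    "max_calcium_thickness", "min_calcium_thickness",
    "max_calcium_depth", "min_calcium_depth",
    "max_fc_angle", "min_fc_angle",
    "min_fc_thickness", "max_fc_area",
    "fc_surface_area", "fc_burden")
}

#' Units of the canonical plaque features
#'
#' @return Named character vector mapping each feature of
#'   [oct_feature_names()] to its unit (`mm`, `mm2`, `deg`, or `ratio`).
#' @export
oct_feature_units <- function() {
  setNames(
    c("mm", "mm2", "mm2", "mm", "mm",
      "deg", "deg", "mm", "mm", "mm", "mm",
      "deg", "deg", "mm", "mm2", "mm2", "ratio"),
    oct_feature_names())
}

# Fixed cohort CSV column contract.
oct_cohort_columns <- function() {
  c("lesion_id", oct_feature_names(), "neoatherosclerosis")
}
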