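#' Lumen geometry of one polar frame
#'
#' Converts the per-A-line lumen boundary to a closed Cartesian polygon
#' and measures it: area by the shoelace rule, perimeter by summed segment
#' lengths, diameter as the area-equivalent circle diameter (or the
#' minimum caliper width), and the polygon centroid. Per-A-line polar
#' contours with positive radii are star-shaped and cannot
#' self-intersect, so validity reduces to a vertex-count and radius check.
#'
#' @param lumen Lumen boundary, 0-based radial pixels per A-line
#'   (length = A-lines per frame, >= 3).
#' @param calibration List with at least `pixel_size_radial` (mm/pixel).
#' @param diameter_method `"area"` (area-equivalent, default) or
#'   `"caliper"` (minimum width over directions).
#' @return List: `area_mm2`, `diameter_mm`, `perimeter_mm`, `centroid_mm`
#'   (x, y in mm relative to the catheter center).
#' @export
compute_lumen <- function(lumen, calibration,
                          diameter_method = c("area", "caliper")) {
  diameter_method <- match.arg(diameter_method)
  A <- length(lumen)
  if (A < 3L)
    oct_annotation_error(sprintf(
      "frame rejected: lumen contour has %d vertices (need >= 3)", A))
  if (any(!is.finite(lumen)) || any(lumen <= 0))
    oct_annotation_error("frame rejected: lumen radii must be positive and finite")
  psr <- calibration$pixel_size_radial
  xy <- polar_to_xy(lumen * psr, aline_angle_rad(0:(A - 1L), A))
  area <- polygon_area(xy)
  diam <- if (diameter_method == "area") 2 * sqrt(area / pi)
          else min_caliper_width(xy)
  list(area_mm2 = area,
       diameter_mm = diam,
       perimeter_mm = polygon_perimeter(xy),
       centroid_mm = polygon_centroid(xy))
}

#' Calcium measurements of one polar frame
#'
#' Measures each annotated calcific deposit (given as per-A-line inner and
#' outer radial boundaries) and aggregates to frame level: total angular
#' extent subtended at the lumen centroid (summed over disjoint deposits),
#' and max/min radial thickness and depth (inner boundary minus lumen)
#' over all covered A-lines.
#'
#' @param calcium List of deposits; each a list with `a_lines` (0-based,
#'   ordered along the arc), `inner`, `outer` (0-based radial pixels), and
#'   optionally `closed` (full-circumference flag).
#' @param lumen Lumen boundary per A-line, 0-based radial pixels.
#' @param centroid Lumen centroid (mm), from [compute_lumen()].
#' @param calibration List with `pixel_size_radial`.
#' @return List with `present`, `angle_deg`, `thickness_max_mm`,
#'   `thickness_min_mm`, `depth_max_mm`, `depth_min_mm` (all `NA` when the
#'   frame has no calcium).
#' @export
compute_calcium <- function(calcium, lumen, centroid, calibration) {
  if (length(calcium) == 0L)
    return(list(present = FALSE, angle_deg = NA_real_,
                thickness_max_mm = NA_real_, thickness_min_mm = NA_real_,
                depth_max_mm = NA_real_, depth_min_mm = NA_real_))
  psr <- calibration$pixel_size_radial
  A <- length(lumen)
  ang <- 0; tk <- numeric(0); dp <- numeric(0)
  for (dep in calcium) {
    idx1 <- dep$a_lines + 1L
    below <- dep$inner < lumen[idx1] - 1e-9
    if (any(below))
      oct_annotation_error(paste0(
        "calcium inner boundary luminal to the lumen contour at A-line(s) ",
        paste(dep$a_lines[below], collapse = ", ")))
    tk <- c(tk, (dep$outer - dep$inner) * psr)
    dp <- c(dp, (dep$inner - lumen[idx1]) * psr)
    xy <- polar_to_xy(dep$inner * psr, aline_angle_rad(dep$a_lines, A))
    ang <- ang + subtended_angle_deg(xy, centroid, closed = isTRUE(dep$closed))
  }
  list(present = TRUE, angle_deg = ang,
       thickness_max_mm = max(tk), thickness_min_mm = min(tk),
       depth_max_mm = max(dp), depth_min_mm = min(dp))
}

#' Fibrous-cap measurements of one polar frame
#'
#' Measures the fibrous cap bounded by the luminal boundary (the lumen
#' contour inside the cap's angular window) and the abluminal boundary
#' (annotated, or traced with [trace_abluminal()]): angular extent at the
#' lumen centroid, minimum radial cap thickness, cap cross-sectional area
#' (polygon bounded by the two boundaries and the end radii; annular
#' difference for full-circumference caps), and the covered lumen arc
#' length.
#'
#' @param fc List of cap regions; each a list with `a_lines` (0-based,
#'   ordered), `abluminal` (0-based radial pixels), optionally `closed`.
#' @param abluminal Optional list of replacement abluminal boundaries
#'   (same shape as `fc`), e.g. traced ones; `NULL` uses the annotation.
#' @inheritParams compute_calcium
#' @return List with `present`, `angle_deg`, `thickness_min_mm`,
#'   `area_mm2`, `covered_arc_mm` (all `NA` when the frame has no cap).
#' @export
compute_fc <- function(fc, lumen, centroid, calibration, abluminal = NULL) {
  if (length(fc) == 0L)
    return(list(present = FALSE, angle_deg = NA_real_,
                thickness_min_mm = NA_real_, area_mm2 = NA_real_,
                covered_arc_mm = NA_real_))
  psr <- calibration$pixel_size_radial
  A <- length(lumen)
  ang <- 0; tmin <- Inf; area <- 0; arc <- 0
  for (k in seq_along(fc)) {
    reg <- fc[[k]]
    ab <- if (is.null(abluminal)) reg$abluminal else abluminal[[k]]
    idx1 <- reg$a_lines + 1L
    if (length(ab) != length(idx1))
      oct_annotation_error("abluminal boundary length does not match the window")
    thick <- (ab - lumen[idx1]) * psr
    if (any(thick <= 0))
      oct_annotation_error(paste0(
        "abluminal boundary crosses the luminal boundary at A-line(s) ",
        paste(reg$a_lines[thick <= 0], collapse = ", ")))
    theta <- aline_angle_rad(reg$a_lines, A)
    lxy <- polar_to_xy(lumen[idx1] * psr, theta)
    axy <- polar_to_xy(ab * psr, theta)
    closed <- isTRUE(reg$closed)
    ang <- ang + subtended_angle_deg(lxy, centroid, closed = closed)
    tmin <- min(tmin, thick)
    if (closed) {
      area <- area + polygon_area(axy) - polygon_area(lxy)
      arc <- arc + polygon_perimeter(lxy)
    } else {
      area <- area + polygon_area(rbind(lxy, axy[rev(seq_len(nrow(axy))), ]))
      arc <- arc + polyline_length(lxy)
    }
  }
  list(present = TRUE, angle_deg = ang, thickness_min_mm = tmin,
       area_mm2 = area, covered_arc_mm = arc)
}

# Per-frame measurement row used by the lesion aggregator. `abluminal`
# optionally replaces the annotated abluminal boundaries (traced caps).
compute_frame_features <- function(frame_ann, calibration,
                                   abluminal = NULL,
                                   diameter_method = "area") {
  lum <- compute_lumen(frame_ann$lumen, calibration, diameter_method)
  ca <- compute_calcium(frame_ann$calcium, frame_ann$lumen,
                        lum$centroid_mm, calibration)
  fc <- compute_fc(frame_ann$fc, frame_ann$lumen, lum$centroid_mm,
                   calibration, abluminal = abluminal)
  data.frame(
    lumen_area = lum$area_mm2, lumen_diameter = lum$diameter_mm,
    lumen_perimeter = lum$perimeter_mm,
    calcium_angle = ca$angle_deg,
    calcium_thickness_max = ca$thickness_max_mm,
    calcium_thickness_min = ca$thickness_min_mm,
    calcium_depth_max = ca$depth_max_mm,
    calcium_depth_min = ca$depth_min_mm,
    fc_angle = fc$angle_deg, fc_thickness_min = fc$thickness_min_mm,
    fc_area = fc$area_mm2, fc_covered_arc = fc$covered_arc_mm)
}

# Lesion-level aggregation of a per-frame measurement table. Frames
# without calcium (or cap) are excluded from -- not zeroed into -- the
# calcium (cap) aggregates; lesions without the component carry NA.
aggregate_frame_table <- function(frames, frame_pitch) {
  nf <- nrow(frames)
  ca <- frames[!is.na(frames$calcium_angle), , drop = FALSE]
  fc <- frames[!is.na(frames$fc_angle), , drop = FALSE]
  fcsa <- if (nrow(fc) > 0L) sum(fc$fc_covered_arc) * frame_pitch else NA_real_
  fcb <- if (nrow(fc) > 0L)
    sum(fc$fc_area * frame_pitch) / sum(frames$lumen_perimeter * frame_pitch)
  else NA_real_
  v <- c(
    lesion_length = nf * frame_pitch,
    min_lumen_area = min(frames$lumen_area),
    mean_lumen_area = mean(frames$lumen_area),
    min_lumen_diameter = min(frames$lumen_diameter),
    mean_lumen_diameter = mean(frames$lumen_diameter),
    max_calcium_angle = if (nrow(ca)) max(ca$calcium_angle) else NA_real_,
    min_calcium_angle = if (nrow(ca)) min(ca$calcium_angle) else NA_real_,
    max_calcium_thickness = if (nrow(ca)) max(ca$calcium_thickness_max) else NA_real_,
    min_calcium_thickness = if (nrow(ca)) min(ca$calcium_thickness_min) else NA_real_,
    max_calcium_depth = if (nrow(ca)) max(ca$calcium_depth_max) else NA_real_,
    min_calcium_depth = if (nrow(ca)) min(ca$calcium_depth_min) else NA_real_,
    max_fc_angle = if (nrow(fc)) max(fc$fc_angle) else NA_real_,
    min_fc_angle = if (nrow(fc)) min(fc$fc_angle) else NA_real_,
    min_fc_thickness = if (nrow(fc)) min(fc$fc_thickness_min) else NA_real_,
    max_fc_area = if (nrow(fc)) max(fc$fc_area) else NA_real_,
    fc_surface_area = fcsa,
    fc_burden = fcb)
  v[oct_feature_names()]
}

#' Aggregate per-frame measurements into the 17 lesion-level features
#'
#' Lesion length is frame count times frame pitch; lumen features are the
#' min/mean over all lesion frames; calcium and cap extrema are taken over
#' component-bearing frames only (a frame without the component is
#' excluded, not counted as zero). Fibrous-cap surface area is the covered
#' lumen arc length integrated along the pullback
#' (sum of per-frame covered arc x pitch); fibrous-cap burden is the
#' integrated cap cross-sectional area divided by the lumen surface area
#' of the lesion (see the package vignette for the scale convention; the
#' value x 1000 is attached as attribute `fc_burden_x1000`).
#'
#' @param frames Data frame of per-frame measurements (as produced
#'   internally by the extraction driver), one row per lesion frame.
#' @param frame_pitch Longitudinal frame spacing, mm.
#' @return Named numeric vector of the 17 features (class
#'   `lesion_features`), `NA` for components absent from every frame.
#' @export
aggregate_lesion <- function(frames, frame_pitch) {
  if (is.null(frames) || nrow(frames) < 1L)
    oct_value_error("empty lesion frame range")
  stopifnot(frame_pitch > 0)
  v <- aggregate_frame_table(frames, frame_pitch)
  attr(v, "fc_burden_x1000") <- unname(v["fc_burden"] * 1000)
  attr(v, "n_frames") <- nrow(frames)
  class(v) <- c("lesion_features", class(v))
  v
}

#' Extract the 17 lesion-level features from a pullback
#'
#' End-to-end per-lesion feature extraction: for every frame in the lesion
#' range, lumen geometry and calcium measurements are computed from the
#' annotation; the fibrous-cap abluminal boundary is traced on the image
#' with [edge_cost()] + [trace_abluminal()] (or taken from the annotation
#' when `use_trace = FALSE`), and the per-frame measurements are
#' aggregated with [aggregate_lesion()].
#'
#' @param pullback An `oct_pullback` (from [generate_pullback()] or
#'   [read_pullback()]).
#' @param lesion_frames Integer range of frames forming the lesion
#'   (default: all frames).
#' @param lesion_id Identifier placed in the output row.
#' @param use_trace Trace the abluminal boundary from the image (`TRUE`)
#'   or trust the annotated abluminal boundary (`FALSE`).
#' @param sigma,smoothness_cap,subpixel Passed to [edge_cost()] /
#'   [trace_abluminal()].
#' @param diameter_method Passed to [compute_lumen()].
#' @return One-row data frame: `lesion_id` + the 17 features. The
#'   per-frame measurement table is attached as attribute
#'   `frame_features`, and traced boundaries (if any) as `traces`.
#' @export
extract_lesion_features <- function(pullback, lesion_frames = NULL,
                                    lesion_id = "lesion_1",
                                    use_trace = TRUE, sigma = 2,
                                    smoothness_cap = 2L, subpixel = TRUE,
                                    diameter_method = "area") {
  stopifnot(inherits(pullback, "oct_pullback"))
  ann <- pullback$annotation
  calib <- ann$calibration
  nf <- length(ann$frames)
  if (is.null(lesion_frames)) lesion_frames <- seq_len(nf)
  if (length(lesion_frames) < 1L || any(lesion_frames < 1L | lesion_frames > nf))
    oct_value_error("lesion_frames outside the pullback")

  rows <- vector("list", length(lesion_frames))
  traces <- list()
  for (k in seq_along(lesion_frames)) {
    f <- lesion_frames[k]
    fr <- ann$frames[[f]]
    ab <- NULL
    if (use_trace && length(fr$fc) > 0L) {
      cost <- edge_cost(pullback$stack[, , f], sigma = sigma)
      ab <- lapply(fr$fc, function(reg) {
        tr <- trace_abluminal(cost, fr$lumen, window = reg$a_lines + 1L,
                              smoothness_cap = smoothness_cap,
                              wrap = isTRUE(reg$closed), subpixel = subpixel)
        traces[[length(traces) + 1L]] <<- list(frame = f, trace = tr)
        tr$radial_px
      })
    }
    rows[[k]] <- compute_frame_features(fr, calib, abluminal = ab,
                                        diameter_method = diameter_method)
  }
  frames_df <- do.call(rbind, rows)
  feats <- aggregate_lesion(frames_df, calib$frame_pitch)
  out <- data.frame(lesion_id = lesion_id, as.list(unclass(feats)[seq_len(17L)]),
                    stringsAsFactors = FALSE)
  names(out) <- c("lesion_id", oct_feature_names())
  attr(out, "frame_features") <- frames_df
  attr(out, "fc_burden_x1000") <- attr(feats, "fc_burden_x1000")
  attr(out, "traces") <- traces
  out
}
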