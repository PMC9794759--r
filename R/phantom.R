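#' Calcium deposit specification for a phantom pullback
#'
#' Describes one calcific deposit planted into a synthetic pullback: a
#' signal-poor region with sharply delineated borders occupying an angular
#' arc over a contiguous frame range, at a given depth below the lumen
#' surface and with a given radial thickness.
#'
#' @param frames Integer vector (1-based, contiguous) of frames covered.
#' @param arc_deg Angular extent in degrees, in (0, 360].
#' @param center_deg Angular position of the deposit center (degrees
#'   clockwise from 12 o'clock).
#' @param depth_mm Radial distance from the lumen boundary to the inner
#'   (luminal) edge of the deposit, mm.
#' @param thickness_mm Radial extent of the deposit, mm.
#' @return A `calcium_spec` list.
#' @export
calcium_spec <- function(frames, arc_deg, center_deg = 0,
                         depth_mm = 0.1, thickness_mm = 0.3) {
  stopifnot(length(frames) >= 1L, all(frames >= 1L))
  if (!(arc_deg > 0 && arc_deg <= 360))
    oct_config_error("calcium_spec: arc_deg must be in (0, 360]")
  if (depth_mm < 0 || thickness_mm <= 0)
    oct_config_error("calcium_spec: depth_mm must be >= 0 and thickness_mm > 0")
  structure(list(frames = as.integer(frames), arc_deg = arc_deg,
                 center_deg = center_deg, depth_mm = depth_mm,
                 thickness_mm = thickness_mm),
            class = "calcium_spec")
}

#' Fibrous-cap specification for a phantom pullback
#'
#' Describes one fibrous cap planted into a synthetic pullback: bright
#' tissue over an angular arc whose abluminal boundary sits `thickness_mm`
#' beyond the lumen, with intensity decaying smoothly (sigmoidally) from
#' bright to dark past that boundary. `thickness_mm` of length 2 plants a
#' cap whose thickness varies linearly across the angular window.
#'
#' @inheritParams calcium_spec
#' @param thickness_mm Cap thickness in mm; scalar for a constant cap or
#'   length-2 `c(start, end)` for a linear profile across the arc.
#' @return An `fc_spec` list.
#' @export
fc_spec <- function(frames, arc_deg, center_deg = 0, thickness_mm = 0.08) {
  stopifnot(length(frames) >= 1L, all(frames >= 1L))
  if (!(arc_deg > 0 && arc_deg <= 360))
    oct_config_error("fc_spec: arc_deg must be in (0, 360]")
  if (any(thickness_mm <= 0) || !length(thickness_mm) %in% 1:2)
    oct_config_error("fc_spec: thickness_mm must be positive, length 1 or 2")
  structure(list(frames = as.integer(frames), arc_deg = arc_deg,
                 center_deg = center_deg,
                 thickness_mm = rep(thickness_mm, length.out = 2L)),
            class = "fc_spec")
}

#' Configuration of a synthetic polar IVOCT pullback phantom
#'
#' Defines the full geometry of a phantom: image grid, physical
#' calibration, a lumen radius per frame, and any planted calcium deposits
#' and fibrous caps. Defaults approximate frequency-domain IVOCT sampling
#' (1-degree A-lines, 5 micron radial pixels, 0.2 mm frame pitch).
#'
#' @param n_frames Number of frames in the pullback.
#' @param a_lines_per_frame A-lines (angular samples) per frame.
#' @param radial_samples Radial samples per A-line.
#' @param pixel_size_radial Radial calibration, mm per pixel.
#' @param frame_pitch Longitudinal distance between frames, mm.
#' @param lumen_radius Lumen radius in mm: a scalar (constant), or a
#'   vector of length `n_frames` (e.g. a linear taper or sinusoid).
#' @param calcium_specs List of [calcium_spec()] objects.
#' @param fc_specs List of [fc_spec()] objects.
#' @param noise_sd Additive Gaussian intensity noise (intensity units on
#'   the \[0, 1\] display scale).
#' @param decay_half_width Half-width (pixels) of the sigmoidal
#'   bright-to-dark transition beyond the abluminal boundary.
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   output.
#' @return A validated `phantom_config` list.
#' @export
#' @examples
#' cfg <- phantom_config(n_frames = 5, lumen_radius = 1,
#'                       fc_specs = list(fc_spec(1:5, 90)))
phantom_config <- function(n_frames,
                           a_lines_per_frame = 360L,
                           radial_samples = 500L,
                           pixel_size_radial = 0.005,
                           frame_pitch = 0.2,
                           lumen_radius = 1.0,
                           calcium_specs = list(),
                           fc_specs = list(),
                           noise_sd = 0,
                           decay_half_width = 4,
                           seed = 1L) {
  if (n_frames < 1L) oct_config_error("n_frames must be >= 1")
  if (a_lines_per_frame < 8L || radial_samples < 8L)
    oct_config_error("image grid too small")
  if (pixel_size_radial <= 0 || frame_pitch <= 0)
    oct_config_error("pixel_size_radial and frame_pitch must be > 0")
  if (noise_sd < 0) oct_config_error("noise_sd must be >= 0")
  lumen_radius <- rep(lumen_radius, length.out = n_frames)
  if (any(lumen_radius <= 0)) oct_config_error("lumen_radius must be > 0")
  max_r_mm <- (radial_samples - 1) * pixel_size_radial
  if (any(lumen_radius >= max_r_mm))
    oct_config_error("lumen_radius exceeds the radial field of view")
  for (i in seq_along(fc_specs)) {
    s <- fc_specs[[i]]
    if (!inherits(s, "fc_spec")) oct_config_error("fc_specs must be fc_spec objects")
    if (any(s$frames > n_frames))
      oct_config_error(sprintf("fc spec %d references frames beyond n_frames", i))
    span <- max(lumen_radius[s$frames]) + max(s$thickness_mm) +
      4 * decay_half_width * pixel_size_radial
    if (span >= max_r_mm)
      oct_config_error(sprintf(
        "fc spec %d exceeds the image radial extent (needs %.3f mm of %.3f mm)",
        i, span, max_r_mm))
  }
  for (i in seq_along(calcium_specs)) {
    s <- calcium_specs[[i]]
    if (!inherits(s, "calcium_spec"))
      oct_config_error("calcium_specs must be calcium_spec objects")
    if (any(s$frames > n_frames))
      oct_config_error(sprintf("calcium spec %d references frames beyond n_frames", i))
    span <- max(lumen_radius[s$frames]) + s$depth_mm + s$thickness_mm
    if (span >= max_r_mm)
      oct_config_error(sprintf(
        "calcium spec %d exceeds the image radial extent (needs %.3f mm of %.3f mm)",
        i, span, max_r_mm))
  }
  structure(list(
    n_frames = as.integer(n_frames),
    a_lines_per_frame = as.integer(a_lines_per_frame),
    radial_samples = as.integer(radial_samples),
    pixel_size_radial = pixel_size_radial,
    frame_pitch = frame_pitch,
    lumen_radius = lumen_radius,
    calcium_specs = calcium_specs,
    fc_specs = fc_specs,
    noise_sd = noise_sd,
    decay_half_width = decay_half_width,
    seed = as.integer(seed)), class = "phantom_config")
}

# A-line window (0-based indices, ordered along the arc) of an angular
# spec; `closed` marks a full-circumference window.
spec_window <- function(arc_deg, center_deg, n_alines) {
  if (arc_deg >= 360)
    return(list(a_lines0 = 0:(n_alines - 1L), closed = TRUE,
                arc_deg = 360))
  n_arc <- max(1L, round(arc_deg / 360 * n_alines))
  start <- round((center_deg - arc_deg / 2) / 360 * n_alines)
  list(a_lines0 = as.integer((start + 0:n_arc) %% n_alines), closed = FALSE,
       arc_deg = n_arc * 360 / n_alines)
}

# Linear cap-thickness profile across a window (mm per covered A-line).
fc_thickness_profile <- function(spec, n_pts) {
  t0 <- spec$thickness_mm[1L]; t1 <- spec$thickness_mm[2L]
  if (n_pts == 1L) return((t0 + t1) / 2)
  t0 + (t1 - t0) * seq(0, 1, length.out = n_pts)
}

#' Generate a synthetic polar IVOCT pullback with known ground truth
#'
#' Renders the intensity stack implied by a [phantom_config()]: dark lumen,
#' bright fibrous-cap tissue decaying sigmoidally beyond the planted
#' abluminal boundary, attenuating vessel wall elsewhere, and signal-poor
#' sharply-bordered calcium, plus additive Gaussian noise. Alongside the
#' stack it returns the exact planted annotation (lumen contour, calcium
#' inner/outer boundaries, fibrous-cap windows and abluminal boundaries,
#' all in 0-based A-line / radial-pixel coordinates) and the analytic
#' 17-feature ground-truth vector for oracle testing.
#'
#' @param config A [phantom_config()].
#' @return A list of class `oct_pullback` with elements `stack` (array
#'   A-lines x radial x frames, intensities in \[0, 1\]), `annotation`
#'   (planted geometry + calibration), and `ground_truth` (named numeric
#'   vector of the 17 features; entries are `NA` where the phantom has no
#'   calcium or no fibrous cap).
#' @export
#' @examples
#' pb <- generate_pullback(phantom_config(n_frames = 3, lumen_radius = 1))
#' pb$ground_truth[["min_lumen_area"]]  # pi * 1^2
generate_pullback <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(config$seed)
  A <- config$a_lines_per_frame
  R <- config$radial_samples
  psr <- config$pixel_size_radial
  nf <- config$n_frames
  r_px <- matrix(rep(0:(R - 1L), each = A), nrow = A)  # radial pixel index

  i_lumen <- 0.05; i_bright <- 0.80; i_dark <- 0.05
  atten_px <- 60  # generic wall attenuation length, pixels

  stack <- array(0, dim = c(A, R, nf))
  frames_ann <- vector("list", nf)

  for (f in seq_len(nf)) {
    lum_px <- rep(config$lumen_radius[f] / psr, A)
    beyond <- sweep(r_px, 1L, lum_px, `-`)
    img <- ifelse(beyond < 0, i_lumen,
                  i_dark + (i_bright - i_dark) * exp(-pmax(beyond, 0) / atten_px))

    fc_ann <- list()
    for (s in config$fc_specs) {
      if (!f %in% s$frames) next
      w <- spec_window(s$arc_deg, s$center_deg, A)
      idx1 <- w$a_lines0 + 1L
      tmm <- fc_thickness_profile(s, length(idx1))
      ab_px <- lum_px[idx1] + tmm / psr
      # bright cap with sigmoidal bright-to-dark decay past the abluminal edge
      for (k in seq_along(idx1)) {
        i <- idx1[k]
        prof <- i_dark + (i_bright - i_dark) /
          (1 + exp((r_px[i, ] - ab_px[k]) / config$decay_half_width))
        img[i, ] <- ifelse(r_px[i, ] < lum_px[i], i_lumen, prof)
      }
      fc_ann[[length(fc_ann) + 1L]] <-
        list(a_lines = w$a_lines0, abluminal = ab_px, closed = w$closed)
    }

    ca_ann <- list()
    for (s in config$calcium_specs) {
      if (!f %in% s$frames) next
      w <- spec_window(s$arc_deg, s$center_deg, A)
      idx1 <- w$a_lines0 + 1L
      inner <- lum_px[idx1] + s$depth_mm / psr
      outer <- inner + s$thickness_mm / psr
      for (k in seq_along(idx1)) {
        i <- idx1[k]
        sel <- r_px[i, ] >= inner[k] & r_px[i, ] <= outer[k]
        img[i, sel] <- img[i, sel] * 0.25  # signal-poor, sharp border
      }
      ca_ann[[length(ca_ann) + 1L]] <-
        list(a_lines = w$a_lines0, inner = inner, outer = outer,
             closed = w$closed)
    }

    if (config$noise_sd > 0)
      img <- img + matrix(rnorm(A * R, 0, config$noise_sd), nrow = A)
    stack[, , f] <- pmin(pmax(img, 0), 1)
    frames_ann[[f]] <- list(lumen = lum_px, calcium = ca_ann, fc = fc_ann)
  }

  annotation <- list(
    schema_version = "1.0",
    calibration = list(pixel_size_radial = psr,
                       frame_pitch = config$frame_pitch,
                       a_lines_per_frame = A,
                       radial_samples = R),
    frames = frames_ann)

  structure(list(stack = stack, annotation = annotation,
                 ground_truth = phantom_ground_truth(config)),
            class = "oct_pullback")
}

# Analytic 17-feature vector implied by a phantom config; independent of
# the image-based extraction path (closed-form circle/annulus geometry).
phantom_ground_truth <- function(config) {
  A <- config$a_lines_per_frame
  nf <- config$n_frames
  r <- config$lumen_radius
  gt_frames <- data.frame(
    lumen_area = pi * r^2, lumen_diameter = 2 * r,
    lumen_perimeter = 2 * pi * r,
    calcium_angle = NA_real_, calcium_thickness_max = NA_real_,
    calcium_thickness_min = NA_real_, calcium_depth_max = NA_real_,
    calcium_depth_min = NA_real_,
    fc_angle = NA_real_, fc_thickness_min = NA_real_,
    fc_area = NA_real_, fc_covered_arc = NA_real_)

  for (f in seq_len(nf)) {
    ang <- 0; tmax <- -Inf; tmin <- Inf; dmax <- -Inf; dmin <- Inf; any_ca <- FALSE
    for (s in config$calcium_specs) {
      if (!f %in% s$frames) next
      any_ca <- TRUE
      w <- spec_window(s$arc_deg, s$center_deg, A)
      ang <- ang + w$arc_deg
      tmax <- max(tmax, s$thickness_mm); tmin <- min(tmin, s$thickness_mm)
      dmax <- max(dmax, s$depth_mm); dmin <- min(dmin, s$depth_mm)
    }
    if (any_ca) {
      gt_frames$calcium_angle[f] <- ang
      gt_frames$calcium_thickness_max[f] <- tmax
      gt_frames$calcium_thickness_min[f] <- tmin
      gt_frames$calcium_depth_max[f] <- dmax
      gt_frames$calcium_depth_min[f] <- dmin
    }
    fang <- 0; ftmin <- Inf; farea <- 0; farc <- 0; any_fc <- FALSE
    for (s in config$fc_specs) {
      if (!f %in% s$frames) next
      any_fc <- TRUE
      w <- spec_window(s$arc_deg, s$center_deg, A)
      th <- w$arc_deg * pi / 180
      t0 <- s$thickness_mm[1L]; t1 <- s$thickness_mm[2L]
      int_t <- th * (t0 + t1) / 2
      int_t2 <- th * (t0^2 + t0 * t1 + t1^2) / 3
      fang <- fang + w$arc_deg
      ftmin <- min(ftmin, t0, t1)
      farea <- farea + r[f] * int_t + int_t2 / 2
      farc <- farc + r[f] * th
    }
    if (any_fc) {
      gt_frames$fc_angle[f] <- fang
      gt_frames$fc_thickness_min[f] <- ftmin
      gt_frames$fc_area[f] <- farea
      gt_frames$fc_covered_arc[f] <- farc
    }
  }
  aggregate_frame_table(gt_frames, config$frame_pitch)
}
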