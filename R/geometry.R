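# Polar/Cartesian helpers shared by the feature-extraction routines.
#
# Convention: A-line index a (0-based) maps to the angle a * 360 / A with
# 0 degrees at 12 o'clock, increasing clockwise; radial pixel p (0-based)
# maps to the physical radius p * pixel_size_radial mm measured from the
# catheter center.

aline_angle_rad <- function(a_lines0, n_alines) {
  a_lines0 * 2 * pi / n_alines
}

# radius in mm, angle in radians (clockwise from 12 o'clock)
polar_to_xy <- function(radius_mm, angle_rad) {
  cbind(x = radius_mm * sin(angle_rad), y = radius_mm * cos(angle_rad))
}

# Shoelace area of a closed polygon (vertices not repeated). Absolute value.
polygon_area <- function(xy) {
  x <- xy[, 1L]; y <- xy[, 2L]
  j <- c(seq_len(nrow(xy))[-1L], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

polygon_perimeter <- function(xy) {
  j <- c(seq_len(nrow(xy))[-1L], 1L)
  sum(sqrt((xy[j, 1L] - xy[, 1L])^2 + (xy[j, 2L] - xy[, 2L])^2))
}

polyline_length <- function(xy) {
  if (nrow(xy) < 2L) return(0)
  d <- diff(xy)
  sum(sqrt(d[, 1L]^2 + d[, 2L]^2))
}

polygon_centroid <- function(xy) {
  x <- xy[, 1L]; y <- xy[, 2L]
  j <- c(seq_len(nrow(xy))[-1L], 1L)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(c(x = mean(x), y = mean(y)))
  c(x = sum((x + x[j]) * cr) / (6 * a), y = sum((y + y[j]) * cr) / (6 * a))
}

# Total angle (degrees) subtended at `vertex` by an ordered polyline.
# Successive angular steps are wrapped to (-pi, pi] and summed, so arcs
# crossing the 0-degree A-line are handled; a full closed contour gives 360.
subtended_angle_deg <- function(xy, vertex, closed = FALSE) {
  ang <- atan2(xy[, 1L] - vertex[1L], xy[, 2L] - vertex[2L])
  if (closed) return(360)
  d <- diff(ang)
  d <- (d + pi) %% (2 * pi) - pi
  abs(sum(d)) * 180 / pi
}

# Minimum caliper width of a convex-or-not polygon by direction scanning;
# used for the optional minimum-diameter definition of lumen diameter.
min_caliper_width <- function(xy, n_dir = 360L) {
  th <- seq(0, pi, length.out = n_dir + 1L)[-(n_dir + 1L)]
  w <- vapply(th, function(t) {
    p <- xy[, 1L] * cos(t) + xy[, 2L] * sin(t)
    max(p) - min(p)
  }, numeric(1L))
  min(w)
}
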