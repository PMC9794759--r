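#' Edge cost grid for abluminal boundary tracing
#'
#' Builds a per-pixel cost image from a polar intensity frame. The
#' fibrous-cap abluminal boundary shows a gradual bright-to-dark radial
#' intensity transition, so the cost is low where the radially outward
#' gradient of the (Gaussian-smoothed) intensity is most negative. Costs
#' are min-max normalized to \[0, 1\] per frame.
#'
#' @param intensity Numeric matrix, A-lines x radial samples, non-negative.
#' @param sigma Gaussian smoothing scale along the radial direction,
#'   pixels.
#' @return Matrix of the same dimension, class `oct_edge_cost`, with
#'   attribute `uniform = TRUE` (plus a warning) when the frame has no
#'   intensity variation at all.
#' @export
edge_cost <- function(intensity, sigma = 2) {
  stopifnot(is.matrix(intensity), all(is.finite(intensity)))
  if (any(intensity < 0)) oct_value_error("intensity must be non-negative")
  R <- ncol(intensity)
  K <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-K, K), sd = sigma)
  k <- k / sum(k)
  sm <- t(apply(intensity, 1L, function(x) {
    xp <- c(rep(x[1L], K), x, rep(x[R], K))
    as.numeric(stats::filter(xp, k, sides = 2))[(K + 1L):(K + R)]
  }))
  g <- cbind(sm[, 2L] - sm[, 1L],
             (sm[, 3:R, drop = FALSE] - sm[, 1:(R - 2L), drop = FALSE]) / 2,
             sm[, R] - sm[, R - 1L])
  rng <- range(g)
  if (diff(rng) < 1e-12) {
    warning("constant-intensity frame: edge cost is uniform")
    cost <- matrix(0.5, nrow(intensity), R)
    attr(cost, "uniform") <- TRUE
  } else {
    cost <- (g - rng[1L]) / diff(rng)
    attr(cost, "uniform") <- FALSE
  }
  class(cost) <- c("oct_edge_cost", class(cost))
  cost
}

#' Trace the fibrous-cap abluminal boundary by dynamic programming
#'
#' Finds the global-minimum-cost radial path across the A-lines of an
#' angular window, subject to a smoothness constraint (at most
#' `smoothness_cap` pixels of radial change per A-line step) and to the
#' admissibility constraint that the path stays strictly abluminal to the
#' lumen (radial pixel > lumen + 1). Cost ties are broken toward the
#' smaller radius, i.e. toward the thinner -- riskier -- cap, so the result
#' is deterministic. Optionally the integer path is refined to sub-pixel
#' precision by a parabolic fit around each path point (the refinement is
#' rescaled if needed so the smoothness constraint still holds).
#'
#' @param cost Cost matrix from [edge_cost()] (A-lines x radial samples).
#' @param lumen Lumen boundary per A-line of the full frame, in 0-based
#'   radial pixels (fractional allowed).
#' @param window Integer vector of 1-based A-line rows, ordered along the
#'   arc (may wrap past the last A-line). Default: all A-lines.
#' @param smoothness_cap Maximum |radial change| per A-line step, pixels.
#' @param wrap Treat the window as circular (use for full 360-degree
#'   windows): the window is padded cyclically on both sides before the
#'   path is solved and the pads are discarded, an approximate periodic
#'   closure.
#' @param subpixel Apply parabolic sub-pixel refinement.
#' @return An object of class `oct_boundary_trace`: list with `a_lines`
#'   (the window, 1-based), `radial_px` (0-based radial position per
#'   A-line, fractional when `subpixel`), `cost` (accumulated path cost of
#'   the integer path), `smoothness_cap`.
#' @export
trace_abluminal <- function(cost, lumen, window = NULL,
                            smoothness_cap = 2L, wrap = FALSE,
                            subpixel = TRUE) {
  stopifnot(is.matrix(cost))
  A <- nrow(cost); R <- ncol(cost)
  stopifnot(length(lumen) == A)
  if (is.null(window)) window <- seq_len(A)
  if (length(window) < 1L) oct_value_error("angular window is empty")
  cap <- as.integer(smoothness_cap)
  stopifnot(cap >= 0L)

  pad <- 0L
  win <- window
  if (wrap && length(window) > 1L) {
    pad <- min(length(window) - 1L, 3L * max(cap, 1L) + 6L)
    win <- c(window[(length(window) - pad + 1L):length(window)],
             window, window[seq_len(pad)])
  }
  n <- length(win)
  C <- cost[win, , drop = FALSE]
  lum <- lumen[win]

  # admissible radii: strictly abluminal to lumen + 1 pixel
  adm <- outer(rep(1, n), 0:(R - 1L)) > (lum + 1)
  bad <- which(rowSums(adm) == 0L)
  if (length(bad) > 0L)
    oct_annotation_error(paste0(
      "no admissible radius on A-line(s) ",
      paste(win[bad] - 1L, collapse = ", "),
      " (lumen at the image edge)"))

  shifts <- (-cap):cap
  D <- matrix(Inf, n, R)
  ptr <- matrix(NA_integer_, n, R)
  D[1L, adm[1L, ]] <- C[1L, adm[1L, ]]
  if (n > 1L) {
    for (i in 2:n) {
      prev <- D[i - 1L, ]
      cand <- vapply(shifts, function(s) {
        j <- seq_len(R) + s
        v <- rep(Inf, R)
        ok <- j >= 1L & j <= R
        v[ok] <- prev[j[ok]]
        v
      }, numeric(R))
      best <- max.col(-cand, ties.method = "first")  # smallest predecessor on ties
      bv <- cand[cbind(seq_len(R), best)]
      D[i, ] <- ifelse(adm[i, ] & is.finite(bv), C[i, ] + bv, Inf)
      ptr[i, ] <- seq_len(R) + shifts[best]
    }
  }
  if (!any(is.finite(D[n, ])))
    oct_annotation_error("no admissible path through the window")

  path <- integer(n)
  path[n] <- which.min(D[n, ])  # first minimum = smallest radius
  if (n > 1L) for (i in (n - 1L):1L) path[i] <- ptr[i + 1L, path[i + 1L]]

  keep <- if (pad > 0L) (pad + 1L):(pad + length(window)) else seq_len(n)
  pj <- path[keep]
  lum_w <- lumen[window]
  total_cost <- sum(cost[cbind(window, pj)])
  px <- pj - 1  # 0-based radial pixel

  if (isTRUE(subpixel)) {
    off <- numeric(length(pj))
    for (k in seq_along(pj)) {
      j <- pj[k]
      if (j > 1L && j < R) {
        cm <- cost[window[k], j - 1L]; c0 <- cost[window[k], j]
        cp <- cost[window[k], j + 1L]
        den <- cm - 2 * c0 + cp
        if (is.finite(den) && den > 1e-12)
          off[k] <- max(-0.5, min(0.5, 0.5 * (cm - cp) / den))
      }
    }
    # keep |delta| <= cap after refinement by shrinking offsets if needed
    if (length(pj) > 1L) {
      dint <- diff(px); doff <- diff(off)
      s <- 1
      for (k in seq_along(dint)) {
        if (abs(dint[k] + doff[k]) > cap && abs(doff[k]) > 1e-12)
          s <- min(s, max(0, (cap - abs(dint[k])) / abs(doff[k])))
      }
      off <- off * s
    }
    px <- pmax(px + off, lum_w + 1 + 1e-9)
  }

  structure(list(a_lines = window, radial_px = px, cost = total_cost,
                 smoothness_cap = cap, subpixel = isTRUE(subpixel)),
            class = "oct_boundary_trace")
}
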