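# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: exhaustive enumeration for the dynamic program,
# direct pair counting for the AUC, direct likelihood maximization for the
# logistic MLE, and closed-form geometry for the phantoms.

# Exhaustive minimum-cost admissible path: every admissible path is
# enumerated by breadth-first extension (no dynamic-programming pruning),
# with costs accumulated left to right.
brute_min_path <- function(cost, lumen, cap) {
  A <- nrow(cost); R <- ncol(cost)
  adm <- lapply(seq_len(A), function(i) which(seq_len(R) - 1 > lumen[i] + 1))
  stopifnot(all(lengths(adm) > 0L))
  paths <- matrix(adm[[1L]], ncol = 1L)
  costs <- cost[1L, adm[[1L]]]
  if (A > 1L) for (i in 2:A) {
    last <- paths[, i - 1L]
    ext <- lapply(adm[[i]], function(j) which(abs(last - j) <= cap))
    reps <- lengths(ext)
    stopifnot(sum(reps) > 0L)
    paths <- cbind(paths[unlist(ext), , drop = FALSE],
                   rep(adm[[i]], reps))
    costs <- costs[unlist(ext)] + rep(cost[i, adm[[i]]], reps)
  }
  k <- which.min(costs)
  list(cost = costs[k], path = paths[k, ], n_paths = length(costs))
}

# AUC by exhaustive concordant/discordant pair counting (ties get 1/2).
pair_auc <- function(score, outcome) {
  pos <- score[outcome == 1]; neg <- score[outcome == 0]
  mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
}

# Logistic negative log-likelihood, for a direct-optimization oracle.
logistic_nll <- function(beta, X, y) {
  eta <- as.numeric(X %*% beta)
  sum(log1p(exp(eta))) - sum(y * eta)
}

oracle_deviance <- function(X, y) {
  opt <- optim(rep(0, ncol(X)), logistic_nll, X = X, y = y,
               method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  2 * opt$value
}

# Pooled-variance two-sample t statistic and two-sided p, by the textbook
# formula (independent of stats::t.test).
hand_student_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = t, p = 2 * pt(-abs(t), nx + ny - 2))
}

# Rotate a pullback (annotation + stack) by k A-lines.
rotate_pullback <- function(pb, k) {
  A <- pb$annotation$calibration$a_lines_per_frame
  rot <- function(a) (a + k) %% A
  pb2 <- pb
  for (f in seq_along(pb$annotation$frames)) {
    fr <- pb$annotation$frames[[f]]
    newl <- numeric(A)
    newl[rot(0:(A - 1)) + 1L] <- fr$lumen
    fr$lumen <- newl
    fr$calcium <- lapply(fr$calcium, function(d) { d$a_lines <- rot(d$a_lines); d })
    fr$fc <- lapply(fr$fc, function(d) { d$a_lines <- rot(d$a_lines); d })
    pb2$annotation$frames[[f]] <- fr
    new <- pb$stack[, , f]
    new[rot(0:(A - 1)) + 1L, ] <- pb$stack[, , f]
    pb2$stack[, , f] <- new
  }
  pb2
}

# Elliptical lumen annotation (semi-axis a along x, b along y), in pixels.
ellipse_lumen_px <- function(a_mm, b_mm, A, pixel_size) {
  th <- aline_angles <- (0:(A - 1)) * 2 * pi / A
  r <- a_mm * b_mm / sqrt((b_mm * sin(th))^2 + (a_mm * cos(th))^2)
  r / pixel_size
}
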