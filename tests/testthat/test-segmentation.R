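test_that("a bright-to-dark step edge has its cost minimum at the step", {
  A <- 24; R <- 300
  img <- matrix(10, A, R); img[, 1:200] <- 100
  cost <- edge_cost(img)
  mins <- apply(cost, 1, which.min) - 1  # 0-based radial pixel
  expect_true(all(abs(mins - 200) <= 1))
  expect_false(attr(cost, "uniform"))
})

test_that("degenerate intensity profiles are handled explicitly", {
  A <- 8; R <- 50
  ramp <- matrix(rep(seq_len(R), each = A), A, R)  # radially increasing
  expect_no_warning(cost <- edge_cost(ramp))
  expect_false(attr(cost, "uniform"))
  flat <- matrix(1, A, R)
  expect_warning(cflat <- edge_cost(flat), "uniform")
  expect_true(attr(cflat, "uniform"))
  expect_true(all(cflat == 0.5))
})

test_that("per-A-line cost minima sit on planted sigmoid centers", {
  set.seed(42)
  A <- 60; R <- 400
  centers <- 180 + round(40 * sin(2 * pi * (1:A) / A))
  img <- matrix(0, A, R)
  for (i in 1:A)
    img[i, ] <- 0.1 + 0.7 / (1 + exp(((1:R) - 1 - centers[i]) / 3))
  cost <- edge_cost(img)
  mins <- apply(cost, 1, which.min) - 1
  expect_true(all(abs(mins - centers) <= 1))
})

test_that("the dynamic program matches brute-force enumeration exactly", {
  set.seed(101)
  for (rep in 1:25) {
    A <- sample(3:6, 1); R <- sample(4:8, 1); cap <- sample(1:2, 1)
    cost <- matrix(runif(A * R), A, R)
    lumen <- runif(A, -1, R / 3)  # leaves admissible radii everywhere
    bf <- brute_min_path(cost, lumen, cap)
    tr <- trace_abluminal(cost, lumen, smoothness_cap = cap, subpixel = FALSE)
    expect_identical(tr$cost, bf$cost)
    expect_equal(tr$radial_px + 1, unname(bf$path))  # optimum unique a.s.
  }
})

test_that("all-zero costs return the minimal-radius admissible path", {
  A <- 10; R <- 20
  cost <- matrix(0, A, R)
  lumen <- rep(5, A)
  tr <- trace_abluminal(cost, lumen, smoothness_cap = 2, subpixel = FALSE)
  expect_equal(tr$radial_px, rep(7, A))  # smallest radius with px > lumen + 1
  expect_equal(tr$cost, 0)
})

test_that("adding a constant to all costs does not change the argmin path", {
  set.seed(7)
  cost <- matrix(runif(8 * 12), 8, 12)
  lumen <- rep(1, 8)
  t1 <- trace_abluminal(cost, lumen, smoothness_cap = 1, subpixel = FALSE)
  t2 <- trace_abluminal(cost + 3.5, lumen, smoothness_cap = 1, subpixel = FALSE)
  expect_equal(t1$radial_px, t2$radial_px)
})

test_that("traces respect the smoothness cap and the lumen margin", {
  cfg <- phantom_config(n_frames = 1, lumen_radius = 1.0, noise_sd = 0.03,
                        seed = 31,
                        fc_specs = list(fc_spec(1, 180,
                                                thickness_mm = c(0.05, 0.2))))
  pb <- generate_pullback(cfg)
  fr <- pb$annotation$frames[[1]]
  cost <- edge_cost(pb$stack[, , 1])
  for (sp in c(TRUE, FALSE)) {
    tr <- trace_abluminal(cost, fr$lumen, window = fr$fc[[1]]$a_lines + 1,
                          smoothness_cap = 2, subpixel = sp)
    expect_true(all(abs(diff(tr$radial_px)) <= 2 + 1e-9))
    expect_true(all(tr$radial_px > fr$lumen[fr$fc[[1]]$a_lines + 1] + 1))
  }
})

test_that("planted boundaries are recovered within a pixel on noiseless caps", {
  cfg <- phantom_config(n_frames = 2, lumen_radius = 1.2, seed = 1,
                        fc_specs = list(fc_spec(1:2, 120, center_deg = 30,
                                                thickness_mm = c(0.06, 0.18))))
  pb <- generate_pullback(cfg)
  for (f in 1:2) {
    fr <- pb$annotation$frames[[f]]
    reg <- fr$fc[[1]]
    cost <- edge_cost(pb$stack[, , f])
    tr <- trace_abluminal(cost, fr$lumen, window = reg$a_lines + 1)
    rms <- sqrt(mean((tr$radial_px - reg$abluminal)^2))
    expect_lt(rms, 1)
  }
})

test_that("recovery degrades gracefully as noise rises", {
  rms_at <- function(noise_sd, seed) {
    cfg <- phantom_config(n_frames = 1, lumen_radius = 1.0, seed = seed,
                          noise_sd = noise_sd,
                          fc_specs = list(fc_spec(1, 120,
                                                  thickness_mm = 0.1)))
    pb <- generate_pullback(cfg)
    fr <- pb$annotation$frames[[1]]
    reg <- fr$fc[[1]]
    tr <- trace_abluminal(edge_cost(pb$stack[, , 1]), fr$lumen,
                          window = reg$a_lines + 1)
    sqrt(mean((tr$radial_px - reg$abluminal)^2))
  }
  med <- vapply(c(0, 0.1, 0.3), function(ns)
    median(vapply(1:5, function(s) rms_at(ns, s), numeric(1))), numeric(1))
  expect_true(all(diff(med) >= -0.05))
  expect_lt(med[1], 1)
})

test_that("a window with no admissible radius names the offending A-lines", {
  cost <- matrix(0, 4, 10)
  lumen <- c(2, 2, 9, 2)  # lumen at the image edge on A-line 3 (0-based 2)
  expect_error(trace_abluminal(cost, lumen, smoothness_cap = 1),
               class = "octplaq_annotation_error", regexp = "2")
  expect_error(trace_abluminal(cost, lumen, window = integer(0)),
               class = "octplaq_value_error")
})
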