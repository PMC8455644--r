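test_that("intensity surfaces conserve mass and peak at the data", {
  w <- c(100, 100)
  one <- data.frame(x = 50, y = 50)
  s1 <- estimate_intensity(one, w, bandwidth = 30)
  expect_equal(intensity_integral(s1), 1, tolerance = 0.01)
  peak <- arrayInd(which.max(s1$v), dim(s1$v))
  expect_equal(s1$xc[peak[1]], 50, tolerance = 2)
  expect_equal(s1$yc[peak[2]], 50, tolerance = 2)
  expect_error(estimate_intensity(one[0, ], w),
               class = "forestcndd_invalid")

  p <- sample_point_pattern(500, w, seed = 31)
  s <- estimate_intensity(p, w, bandwidth = 30)
  expect_equal(intensity_integral(s), 500, tolerance = 0.01 * 500)
  expect_equal(mean(s$v), 0.05, tolerance = 0.01)
  ## smoothing monotonicity: wider bandwidth, flatter surface
  s5 <- estimate_intensity(p, w, bandwidth = 5)
  cv <- function(x) sd(x$v) / mean(x$v)
  expect_lt(cv(s), cv(s5))
})

test_that("intensity surfaces are translation-equivariant away from edges", {
  ## equivariance holds where the edge correction is inactive, i.e. for
  ## patterns several bandwidths from the boundary
  w <- c(120, 120)
  p0 <- sample_point_pattern(60, c(30, 30), seed = 32)
  p0$x <- p0$x + 30; p0$y <- p0$y + 30          # pattern in [30, 60]^2
  s0 <- estimate_intensity(p0, w, bandwidth = 5, cell = 2)
  p1 <- p0; p1$x <- p1$x + 20; p1$y <- p1$y + 20
  s1 <- estimate_intensity(p1, w, bandwidth = 5, cell = 2)
  ## the surface shifts by exactly 10 grid cells
  expect_lt(max(abs(s1$v[11:60, 11:60] - s0$v[1:50, 1:50])), 1e-10)
})

test_that("Ripley edge weights match a numeric arc oracle", {
  w <- c(100, 80)
  withr::with_seed(33, {
    x <- runif(30, 1, 99); y <- runif(30, 1, 79); t <- runif(30, 1, 19)
  })
  th <- seq(0, 2 * pi, length.out = 40001)[-1]
  for (i in seq_along(x)) {
    inside <- mean(x[i] + t[i] * cos(th) >= 0 &
                     x[i] + t[i] * cos(th) <= w[1] &
                     y[i] + t[i] * sin(th) >= 0 &
                     y[i] + t[i] * sin(th) <= w[2])
    expect_equal(ripley_edge_weight(x[i], y[i], t[i], w), 1 / inside,
                 tolerance = 1e-3)
  }
  ## >= 1 everywhere, exactly 1 far from the boundary
  expect_gte(min(ripley_edge_weight(x, y, t, w)), 1)
  expect_equal(ripley_edge_weight(50, 40, 10, w), 1)
})

test_that("the PCF is ~1 under CSR and scale-equivariant", {
  w <- c(100, 100)
  r <- seq(25 / 513, 25, length.out = 513)
  gm <- rowMeans(sapply(1:30, function(i) {
    p <- sample_point_pattern(400, w, seed = 300 + i)
    pcf_inhom(p, 0.04, w, r)
  }))
  sel <- r >= 5 & r <= 20
  expect_lt(max(abs(gm[sel] - 1)), 0.05)

  ## doubling coordinates, window, grid and bandwidth leaves g unchanged
  p <- sample_point_pattern(300, w, seed = 41)
  g1 <- pcf_inhom(p, 0.03, w, r, h = 1)
  p2 <- data.frame(x = 2 * p$x, y = 2 * p$y)
  g2 <- pcf_inhom(p2, 0.03 / 4, c(200, 200), 2 * r, h = 2)
  expect_equal(g1, g2, tolerance = 1e-10)

  expect_error(pcf_inhom(p[1, ], 0.03, w), class = "forestcndd_invalid")
  expect_error(pcf_inhom(p, 0.03, w, r = c(0, 1, 2)),
               class = "forestcndd_invalid")
})

test_that("the mean PCF tracks the closed-form Thomas expression", {
  w <- c(100, 100)
  cl <- list(kappa = 0.005, sigma = 5, mu = 4)
  r <- seq(25 / 513, 25, length.out = 513)
  gm <- rowMeans(sapply(1:40, function(i) {
    p <- sample_point_pattern(200, w, cl, seed = 500 + i)
    pcf_inhom(p, 200 / 1e4, w, r)
  }))
  sel <- r >= 2 & r <= 15
  rel <- gm[sel] / thomas_pcf(r[sel], cl$kappa, cl$sigma) - 1
  expect_lt(max(abs(rel)), 0.1)
})

test_that("inhomogeneous Poisson simulation respects the surface", {
  w <- c(100, 100)
  p <- sample_point_pattern(500, w, seed = 51)
  s <- estimate_intensity(p, w)
  counts <- sapply(1:100, function(i)
    nrow(simulate_inhom_poisson(s, seed = 600 + i)))
  expect_equal(mean(counts), intensity_integral(s),
               tolerance = 5 * sqrt(500 / 100))
  expect_lt(abs(var(counts) / mean(counts) - 1), 0.5)

  ## zero intensity on half the window leaves it empty
  s0 <- s
  s0$v[s0$xc > 50, ] <- 0
  pts <- simulate_inhom_poisson(s0, seed = 7)
  expect_true(all(pts$x <= 50))

  ## strongly bimodal surface: per-half counts track intensity ratios
  s2 <- s
  s2$v[, ] <- 0.02
  s2$v[s2$xc > 50, ] <- 0.08
  draws <- sapply(1:200, function(i) {
    q <- simulate_inhom_poisson(s2, seed = 800 + i)
    c(sum(q$x <= 50), sum(q$x > 50))
  })
  expect_equal(mean(draws[2, ]) / mean(draws[1, ]), 4, tolerance = 0.15)
})

test_that("GOF envelopes classify patterns with exchangeable-rank p-values", {
  w <- c(100, 100)
  ## small pattern is skipped, not an error
  expect_message(
    res <- gof_envelope_test(sample_point_pattern(24, w, seed = 1), w),
    "skipped")
  expect_null(res)

  ## CSR pattern: p on the 1/(n_sim+1) grid, typically not significant
  p <- sample_point_pattern(100, w, seed = 61)
  g <- gof_envelope_test(p, w, intensity = 0.01, n_sim = 199, seed = 62)
  expect_equal(g$p_value * 200, round(g$p_value * 200))
  expect_gte(g$p_value, 1 / 200)

  ## strongly clustered pattern: smallest attainable p and "aggregated"
  cl <- list(kappa = 0.001, sigma = 3, mu = 50)
  pc <- sample_point_pattern(150, w, cl, seed = 63)
  gc <- gof_envelope_test(pc, w, n_sim = 199, seed = 64)
  expect_equal(gc$p_value, 1 / 200)
  expect_equal(gc$classification, "aggregated")
  expect_gt(gc$mean_deviation, 0)
})

test_that("aggregation summaries count only eligible species", {
  mk <- function(p) structure(list(p_value = p,
                                   classification = if (p <= 0.05)
                                     "aggregated" else "random"),
                              class = "pcf_envelope")
  res <- c(lapply(c(0.01, 0.02, 0.04), mk),
           lapply(rep(0.5, 7), mk), list(NULL))
  agg <- plot_aggregation_summary(res)
  expect_equal(agg$proportion, 0.3)
  expect_equal(agg$n_eligible, 10)
  empty <- plot_aggregation_summary(list(NULL, NULL))
  expect_true(is.na(empty$proportion))
})

test_that("per-plot aggregation analysis is reproducible and complete", {
  plots <- toy_plots(1, width = 60, height = 60)
  stems <- withr::with_seed(71, data.frame(
    plot_id = "p01",
    species = rep(c("big", "small"), c(40, 24)),
    x = runif(64, 0, 60), y = runif(64, 0, 60), gbh = 50))
  a1 <- aggregation_by_plot(stems, plots, n_sim = 39, seed = 5)
  a2 <- aggregation_by_plot(stems, plots, n_sim = 39, seed = 5)
  expect_identical(a1, a2)
  ## the 24-individual species is not in the denominator
  expect_equal(a1$plots$n_eligible, 1)
  expect_equal(a1$species$species, "big")
})
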