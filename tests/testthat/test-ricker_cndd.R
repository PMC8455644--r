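test_that("the likelihood matches the closed-form NegBin pmf", {
  ## one quadrat, A = 1, S = 0, everything zero, gamma = 1:
  ## log NegBin(0; mu = 1, size = 1) = -log 2
  ll <- negbin_ricker_loglik(
    list(r = 0, cndd = 0, hndd_adult = 0, hndd_sap = 0, gamma = 1),
    data.frame(S = 0, A = 1, a = 0, s = 0))
  expect_equal(ll, -log(2))
  expect_error(
    negbin_ricker_loglik(list(r = 0, cndd = 0, hndd_adult = 0,
                              hndd_sap = 0, gamma = -1),
                         data.frame(S = 0, A = 1, a = 0, s = 0)),
    class = "forestcndd_invalid")
  expect_error(
    negbin_ricker_loglik(list(r = 0, cndd = 0, hndd_adult = 0,
                              hndd_sap = 0, gamma = 1),
                         data.frame(S = c(1, 2), A = c(0, 0),
                                    a = 0, s = 0)),
    class = "forestcndd_degenerate")
})

test_that("the likelihood equals term-by-term oracle summation", {
  for (seed in 1:25) {
    cnt <- random_counts(8, seed)
    th <- withr::with_seed(seed, list(
      r = rnorm(1, 0, 0.5), cndd = rnorm(1, 0, 0.1),
      hndd_adult = rnorm(1, 0, 0.02), hndd_sap = rnorm(1, 0, 0.02),
      gamma = runif(1, 0.3, 5)))
    mu <- cnt$A * exp(th$r + th$cndd * cnt$A + th$hndd_adult * cnt$a +
                        th$hndd_sap * cnt$s)
    oracle <- sum(negbin_lpmf_oracle(cnt$S, mu, th$gamma))
    expect_equal(negbin_ricker_loglik(th, cnt), oracle,
                 tolerance = 1e-12)
  }
})

test_that("the likelihood approaches the Poisson limit for large gamma", {
  cnt <- random_counts(10, 99)
  th <- list(r = 0.3, cndd = -0.08, hndd_adult = 0.01,
             hndd_sap = -0.01, gamma = 1e6)
  mu <- cnt$A * exp(th$r + th$cndd * cnt$A + th$hndd_adult * cnt$a +
                      th$hndd_sap * cnt$s)
  expect_lt(abs(negbin_ricker_loglik(th, cnt) -
                  sum(dpois(cnt$S, mu, log = TRUE))), 1e-3)
})

test_that("the floor policy keeps zero-adult quadrats with a small offset", {
  cnt <- data.frame(S = c(1, 2), A = c(0, 2), a = 0, s = 0)
  th <- list(r = 0.2, cndd = -0.05, hndd_adult = 0, hndd_sap = 0,
             gamma = 2)
  ll <- negbin_ricker_loglik(th, cnt, zero_adult_policy = "floor",
                             floor_epsilon = 1e-3)
  expect_true(is.finite(ll))
  mu <- (cnt$A + 1e-3) * exp(th$r + th$cndd * cnt$A)
  expect_equal(ll, sum(negbin_lpmf_oracle(cnt$S, mu, 2)))
})

test_that("the MLE agrees with a profiled grid-search oracle", {
  ## 30 quadrats, no heterospecific structure, so the likelihood is a
  ## function of (r, cndd, gamma); gamma profiled by optimize()
  withr::with_seed(4, {
    A <- rpois(30, 3) + 1L
    S <- simulate_ricker_counts(A, 0, 0,
                                list(r = 0.5, cndd = -0.1,
                                     hndd_adult = 0, hndd_sap = 0,
                                     gamma = 2))
  })
  cnt <- data.frame(S = S, A = A, a = 0L, s = 0L)
  fit <- fit_ricker(cnt)
  prof <- function(r, cndd) {
    f <- function(lg) -negbin_ricker_loglik(
      list(r = r, cndd = cndd, hndd_adult = 0, hndd_sap = 0,
           gamma = exp(lg)), cnt)
    optimize(f, c(-4, 8))$objective
  }
  rs <- seq(fit$r_hat - 0.1, fit$r_hat + 0.1, by = 0.01)
  cs <- seq(fit$cndd_hat - 0.1, fit$cndd_hat + 0.1, by = 0.01)
  grid <- outer(rs, cs, Vectorize(prof))
  best <- arrayInd(which.min(grid), dim(grid))
  expect_lt(abs(rs[best[1]] - fit$r_hat), 0.01 + 1e-9)
  expect_lt(abs(cs[best[2]] - fit$cndd_hat), 0.01 + 1e-9)
})

test_that("the fit matches the offset NegBin GLM route", {
  skip_if_not_installed("MASS")
  truth <- list(r = 0.5, cndd = -0.06, hndd_adult = 0.005,
                hndd_sap = -0.004, gamma = 2)
  withr::with_seed(8, {
    A <- rpois(400, 3)
    a <- rpois(400, 8)
    s <- rpois(400, 10)
    S <- simulate_ricker_counts(A, a, s, truth)
  })
  cnt <- data.frame(S = S, A = A, a = a, s = s)[A > 0, ]
  fit <- fit_ricker(cnt)
  gnb <- MASS::glm.nb(S ~ A + a + s + offset(log(A)), data = cnt)
  expect_equal(fit$r_hat, unname(coef(gnb)[1]), tolerance = 1e-3)
  expect_equal(fit$cndd_hat, unname(coef(gnb)[2]), tolerance = 1e-3)
  expect_equal(fit$gamma_hat, gnb$theta, tolerance = 1e-2)
})

test_that("fits are invariant to quadrat order", {
  cnt <- random_counts(60, 17)
  cnt$S <- withr::with_seed(18, simulate_ricker_counts(
    cnt$A, cnt$a, cnt$s, list(r = 0.4, cndd = -0.08, hndd_adult = 0,
                              hndd_sap = 0, gamma = 2)))
  f1 <- fit_ricker(cnt)
  f2 <- fit_ricker(cnt[rev(seq_len(nrow(cnt))), ])
  expect_equal(f1$cndd_hat, f2$cndd_hat, tolerance = 1e-6)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
})

test_that("constant adult counts are flagged, not silently estimated", {
  ## A constant across included quadrats confounds r and cndd
  cnt <- data.frame(S = rpois(40, 3), A = 2L, a = rpois(40, 5),
                    s = rpois(40, 5))
  fit <- fit_ricker(cnt)
  expect_false(isTRUE(fit$converged) && is.finite(fit$se_cndd))
})

test_that("estimator error shrinks with the number of quadrats", {
  truth <- list(r = 0.5, cndd = -0.05, hndd_adult = 0, hndd_sap = 0,
                gamma = 2)
  rmse <- sapply(c(100, 400, 1600), function(n) {
    err <- sapply(1:25, function(i)
      sim_and_fit(n, truth, seed = 3000 + 7 * i + n)$cndd_hat -
        truth$cndd)
    sqrt(mean(err^2))
  })
  expect_true(rmse[3] < rmse[1])
  expect_lt(rmse[3], 0.02)
})

test_that("species are excluded by occupancy and CNDD standard error", {
  mk_counts <- function(occ_a, occ_s, n = 100) {
    data.frame(S = c(rep(1L, occ_s), rep(0L, n - occ_s)),
               A = c(rep(1L, occ_a), rep(0L, n - occ_a)),
               a = 0L, s = 0L)
  }
  ## adults occupy 9 quadrats: dropped
  d1 <- species_filter(mk_counts(9, 30))
  expect_false(d1$keep)
  expect_match(d1$reason, "fewer than 10 quadrats")
  ## saplings occupy 9 quadrats: dropped under the "both" rule,
  ## retained under "either"
  expect_false(species_filter(mk_counts(30, 9))$keep)
  expect_true(species_filter(mk_counts(30, 9),
                             occupancy_rule = "either")$keep)
  ## SE rules need a fit row
  fit_ok <- data.frame(converged = TRUE, se_cndd = 4.0)
  fit_bad <- data.frame(converged = TRUE, se_cndd = 4.5)
  expect_true(species_filter(mk_counts(12, 15), fit_ok)$keep)
  d2 <- species_filter(mk_counts(12, 15), fit_bad)
  expect_false(d2$keep)
  expect_match(d2$reason, "standard error above 4")
  expect_false(species_filter(mk_counts(12, 15),
                              data.frame(converged = FALSE,
                                         se_cndd = 1))$keep)
})

test_that("plot means average retained species coefficients", {
  fits <- data.frame(plot_id = "p01", species = c("a", "b"), scale = 10,
                     cndd_hat = c(-0.1, -0.3),
                     hndd_adult_hat = c(0.01, -0.01),
                     hndd_sap_hat = c(0, 0))
  m <- plot_mean_cndd(fits)
  expect_equal(m$mean_cndd, -0.2)
  expect_equal(m$cndd_strength, 0.2)
  expect_equal(m$n_species_retained, 2)
  single <- plot_mean_cndd(fits[1, ])
  expect_equal(single$mean_cndd, -0.1)
  five <- data.frame(plot_id = "p", species = letters[1:5], scale = 10,
                     cndd_hat = c(-0.05, -0.12, 0.02, -0.4, -0.07),
                     hndd_adult_hat = 0, hndd_sap_hat = 0)
  expect_equal(plot_mean_cndd(five)$mean_cndd,
               mean(c(-0.05, -0.12, 0.02, -0.4, -0.07)))
  expect_error(plot_mean_cndd(fits[0, ]),
               class = "forestcndd_degenerate")
})

test_that("fit_cndd produces consistent fits, means and exclusions", {
  cfg <- simulation_config(n_plots = 2, species_pool = 20,
                           adults_per_plot = 400, seed = 31)
  d <- generate_multiplot_dataset(cfg)
  res <- fit_cndd(d$stems, d$plots, quadrat_sizes = c(10, 20),
                  n_starts = 2)
  expect_setequal(unique(res$fits$scale), c(10, 20))
  expect_setequal(unique(res$plot_cndd$scale), c(10, 20))
  ## plot means recompute from retained fits
  ret <- res$fits[res$fits$retained & res$fits$scale == 10 &
                    res$fits$plot_id == "plot01", ]
  m <- res$plot_cndd[res$plot_cndd$scale == 10 &
                       res$plot_cndd$plot_id == "plot01", ]
  expect_equal(m$mean_cndd, mean(ret$cndd_hat))
  expect_equal(m$n_species_retained, nrow(ret))
  expect_true(all(res$fits$gamma_hat[res$fits$converged] > 0))
})
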