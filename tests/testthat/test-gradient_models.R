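test_that("Spearman correlation handles monotone and tied data", {
  x <- 1:10
  expect_equal(spearman_correlation(x, 2 * x + 3)$rho, 1)
  expect_equal(spearman_correlation(x, -x)$rho, -1)
  expect_equal(spearman_correlation(x, 2 * x)$p, 0)
  ## tied fixture against brute-force average ranks
  tx <- c(1, 2, 3, 4); ty <- c(2, 2, 5, 4)
  brute_rank <- function(v) {
    sapply(v, function(vi) mean(which(sort(v) == vi)))
  }
  rho_brute <- cor(brute_rank(tx), brute_rank(ty))
  sp <- spearman_correlation(tx, ty)
  expect_equal(sp$rho, rho_brute)
  ## agrees with the standard library implementation
  ct <- suppressWarnings(cor.test(tx, ty, method = "spearman",
                                  exact = FALSE))
  expect_equal(sp$rho, unname(ct$estimate))
  expect_equal(sp$p, ct$p.value, tolerance = 1e-10)
  ## degenerate inputs
  expect_true(is.na(spearman_correlation(c(1, 1, 1), c(1, 2, 3))$rho))
  expect_true(is.na(spearman_correlation(1:2, 2:1)$rho))
})

test_that("the Poisson GLM reproduces closed forms and an IRLS oracle", {
  d0 <- data.frame(S = c(3, 5, 4, 8, 6, 2, 7, 5))
  f0 <- fit_poisson_glm(S ~ 1, d0)
  expect_equal(unname(f0$coefficients$estimate), log(mean(d0$S)),
               tolerance = 1e-9)
  expect_equal(f0$pseudo_r2, 0, tolerance = 1e-12)

  ## independent Newton/IRLS iteration written in the test
  d <- data.frame(S = c(4, 7, 2, 9, 12, 3, 6, 8),
                  x = c(-1.2, 0.3, -0.7, 0.9, 1.4, -1.0, 0.1, 0.8))
  X <- cbind(1, d$x)
  beta <- c(log(mean(d$S)), 0)
  for (it in 1:50) {
    mu <- exp(X %*% beta)
    W <- as.numeric(mu)
    z <- X %*% beta + (d$S - mu) / mu
    beta <- solve(t(X) %*% (X * W), t(X) %*% (W * z))
  }
  fit <- fit_poisson_glm(S ~ x, d)
  expect_equal(unname(fit$coefficients$estimate), as.numeric(beta),
               tolerance = 1e-8)
  expect_error(fit_poisson_glm(S ~ x + I(2 * x), d),
               class = "forestcndd_invalid")
})

test_that("GLM coverage: estimates fall within 3 SE of truth", {
  beta <- c(3.0, -0.3, 0.5)
  hits <- sapply(1:100, function(i) withr::with_seed(4000 + i, {
    env <- runif(32, -1.5, 1.5)
    cndd <- runif(32, -1, 1)
    d <- data.frame(S = rpois(32, exp(beta[1] + beta[2] * env +
                                        beta[3] * cndd)),
                    ENV = env, CNDD = cndd)
    f <- fit_poisson_glm(S ~ ENV + CNDD, d)
    all(abs(f$coefficients$estimate - beta) <=
          3 * f$coefficients$se)
  }))
  expect_gte(mean(hits), 0.9)
})

test_that("the likelihood-ratio test is coherent for nested models", {
  withr::with_seed(5, {
    d <- data.frame(S = rpois(32, 40), ENV = runif(32), CNDD = runif(32))
  })
  m0 <- fit_poisson_glm(S ~ ENV + CNDD, d)
  m1 <- fit_poisson_glm(S ~ ENV * CNDD, d)
  same <- interaction_lr_test(m0, m0)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  lr <- interaction_lr_test(m0, m1)
  expect_equal(lr$df, 1L)
  expect_gte(lr$statistic, 0)
  ## statistic equals twice the Poisson log-likelihood difference
  ll <- function(fit) sum(dpois(d$S, fitted(fit$fit), log = TRUE))
  expect_equal(lr$statistic, 2 * (ll(m1) - ll(m0)), tolerance = 1e-8)
  expect_error(interaction_lr_test(m1, m0),
               class = "forestcndd_invalid")
})

test_that("pseudo-R2 is monotone over the nested model sequence", {
  for (i in 1:10) {
    d <- withr::with_seed(600 + i, data.frame(
      S = rpois(20, 30), ENV = rnorm(20), CNDD = rnorm(20)))
    r2 <- c(fit_poisson_glm(S ~ ENV, d)$pseudo_r2,
            fit_poisson_glm(S ~ ENV + CNDD, d)$pseudo_r2,
            fit_poisson_glm(S ~ ENV * CNDD, d)$pseudo_r2)
    expect_true(all(diff(r2) >= -1e-12))
    expect_true(all(r2 >= 0 & r2 <= 1))
  }
})

## a small synthetic plot-summary table with a built-in signal
toy_summary <- function(n = 24, seed = 1) {
  withr::with_seed(seed, {
    alt <- runif(n, 0, 1500)
    strength <- 0.3 - 1.5e-4 * alt + rnorm(n, 0, 0.02)
    S <- rpois(n, exp(3.2 + 0.8 * strength))
    data.frame(plot_id = sprintf("p%02d", 1:n), scale = 10,
               mean_cndd = -strength, cndd_strength = strength,
               S = S, H = log(S) * 0.8, e = runif(n, 0.5, 0.9),
               altitude = alt, temperature = 20 - alt / 100,
               precipitation = 1500 + rnorm(n, 0, 100),
               snow_ln = log(alt / 1500 + 1),
               snow_depth = alt / 1500,
               forest_type = rep(c("EB", "DB"), n / 2),
               succession = rep(c("OG", "OS", "S"), length.out = n),
               n_trees = 1200)
  })
}

test_that("gradient blocks report nested pseudo-R2 and the LR test", {
  gt <- gradient_table(toy_summary(), "altitude", 10)
  expect_equal(names(gt$pseudo_r2), c("env", "additive", "interaction"))
  expect_true(all(diff(gt$pseudo_r2) >= -1e-12))
  expect_equal(gt$lr_test$df, 1L)
  expect_equal(nrow(gt$coefficients), 4)
  expect_true(all(gt$coefficients$star %in% c("", "x", "*")))
  expect_error(gradient_table(toy_summary(4), "altitude", 10),
               class = "forestcndd_degenerate")
  expect_error(gradient_table(toy_summary(), "no_such", 10),
               class = "forestcndd_invalid")
})

test_that("the correlation suite covers pairs, subsets and small-n rules", {
  co <- correlation_suite(toy_summary())
  expect_true(all(c("all", "old-growth", "type:EB", "type:DB") %in%
                    co$subset))
  ## built-in signal: strength falls with altitude, rises with richness
  alt_row <- co[co$var1 == "cndd_strength" & co$var2 == "altitude" &
                  co$subset == "all", ]
  expect_lt(alt_row$rho, 0)
  expect_lt(alt_row$p, 0.05)
  expect_false(is.na(alt_row$linear_r2))
  s_row <- co[co$var1 == "cndd_strength" & co$var2 == "S" &
                co$subset == "all", ]
  expect_gt(s_row$rho, 0)
  ## subsets with n < 3 are reported missing
  tiny <- toy_summary()
  tiny$forest_type <- c("EC", "EC", rep("EB", 22))
  co2 <- correlation_suite(tiny)
  ec <- co2[co2$subset == "type:EC", ]
  expect_true(all(is.na(ec$rho)))
  expect_true(all(ec$n == 2))
})

test_that("renaming forest types permutes but does not change values", {
  s1 <- toy_summary()
  s2 <- s1
  s2$forest_type <- ifelse(s1$forest_type == "EB", "EC", "BC")
  c1 <- correlation_suite(s1)
  c2 <- correlation_suite(s2)
  eb <- c1[c1$subset == "type:EB", c("var1", "var2", "rho", "p")]
  ec <- c2[c2$subset == "type:EC", c("var1", "var2", "rho", "p")]
  expect_equal(eb$rho, ec$rho)
  expect_equal(eb$p, ec$p)
})

test_that("species-level correlations enforce the six-site rule", {
  mk_fits <- function(n_plots, sp) data.frame(
    plot_id = sprintf("p%02d", seq_len(n_plots)), species = sp,
    scale = 10, cndd_hat = rnorm(n_plots, -0.2, 0.05),
    retained = TRUE)
  fits <- withr::with_seed(9, rbind(mk_fits(8, "common"),
                                    mk_fits(5, "scarce")))
  sc <- species_level_correlations(fits, toy_summary(), min_sites = 6)
  expect_true("common" %in% sc$table$species)
  expect_false("scarce" %in% sc$table$species)
  expect_true(all(sc$table$sign %in% c("", "+", "-")))
})

test_that("pooled CNDD vs basal area recovers a built-in coupling", {
  ## species-plot fits where stronger CNDD sits at lower basal area
  withr::with_seed(10, {
    n <- 80
    ba <- exp(rnorm(n, -1, 0.8))
    strength <- 0.4 - 0.25 * (log(ba) - mean(log(ba))) + rnorm(n, 0, 0.05)
    fits <- data.frame(plot_id = rep(sprintf("p%02d", 1:8), 10),
                       species = rep(sprintf("s%02d", 1:10), each = 8),
                       scale = 10, cndd_hat = -strength, retained = TRUE)
    bat <- data.frame(plot_id = fits$plot_id, species = fits$species,
                      basal_area = ba)
  })
  sc <- species_level_correlations(fits, toy_summary(8, seed = 2),
                                   basal_area = bat, min_sites = 6)
  expect_lt(sc$pooled_ba$rho, 0)
  expect_lt(sc$pooled_ba$p, 0.05)
})
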