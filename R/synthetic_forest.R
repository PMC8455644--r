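#' Configuration for the synthetic multi-plot forest generator
#'
#' Bundles every knob of the generator together with its ground truth.
#' Defaults emulate the statistical structure of a 32-plot temperate
#' forest-plot network spanning a wide altitude gradient: ~1 ha plots,
#' a log-series species pool, several hundred adults per plot, sapling
#' recruitment following the Ricker model with negative-binomial error,
#' and plot-level true mean CNDD varying linearly along standardized
#' altitude (stronger density dependence — more negative coefficients —
#' at low altitude).  Expected plot richness is log-linear in altitude,
#' CNDD strength and their interaction, so that downstream gradient
#' analyses have a recoverable signal.
#'
#' @param n_plots number of plots.
#' @param plot_width,plot_height plot dimensions in metres.
#' @param species_pool number of species in the regional pool.
#' @param abundance_shape log-series parameter in (0, 1); species k in the
#'   pool receives sampling weight `shape^k / k`.
#' @param adults_per_plot total adult stems placed in each plot.
#' @param altitude_range altitude range (m a.s.l.) of the latent gradient.
#' @param temperature_range mean annual temperature (deg C) at the lowest
#'   and highest altitude; plots interpolate linearly with Gaussian noise.
#' @param temperature_sd,precipitation_sd,snow_sd noise SDs of the derived
#'   climate variables.
#' @param precipitation_base,precipitation_per_degree linear map from
#'   temperature to mean annual precipitation (mm).
#' @param snow_max mean maximum snow depth (m) reached at the top of the
#'   altitude range.
#' @param cndd_intercept,cndd_slope linear map from standardized altitude
#'   to true plot-mean CNDD coefficient.
#' @param cndd_sd between-species SD of true CNDD within a plot.
#' @param cndd_ba_slope optional coupling of species CNDD to (centred)
#'   log abundance; negative values make common, high-basal-area species
#'   have weaker (less negative) density dependence. Default 0.
#' @param recruitment_rate_range range of true per-species recruitment
#'   rates r (uniform).
#' @param hndd_adult,hndd_sap true heterospecific coefficients (default 0;
#'   see Details).
#' @param negbin_gamma true negative-binomial size parameter
#'   (Var = mu + mu^2 / gamma).
#' @param richness_base,richness_env,richness_cndd,richness_interaction
#'   coefficients of the log-linear model for expected plot richness:
#'   `base * exp(env * alt_std + cndd * z + interaction * alt_std * z)`
#'   where z is the standardized true plot CNDD strength.
#' @param min_species lower clamp on realized plot richness.
#' @param sim_quadrat quadrat size (m) at which sapling counts are
#'   generated; the model's own generative scale.
#' @param clustering Thomas-process parameters for adult placement, a
#'   list with `kappa` (parents per m^2), `sigma` (m) and `mu` (mean
#'   offspring per parent); `NULL` places adults uniformly (CSR).  The
#'   default mild clustering emulates the intraspecific aggregation of
#'   real stem maps and is what makes per-quadrat adult counts vary
#'   enough to identify CNDD for mid-abundance species.
#' @param seed master seed; fixes the full output.
#'
#' @details With the default `hndd_sap = 0` the generated data follow the
#'   fitted model family exactly.  A non-zero `hndd_adult` is also exact
#'   (adults are placed before saplings); a non-zero `hndd_sap` is applied
#'   to heterospecific sapling counts generated in the same pass and is
#'   therefore only approximate — kept at 0 for recovery studies.
#'
#' @return an object of class `"simulation_config"` (a validated list).
#' @seealso [generate_multiplot_dataset()]
#' @export
simulation_config <- function(n_plots = 32L,
                              plot_width = 100, plot_height = 100,
                              species_pool = 300L,
                              abundance_shape = 0.995,
                              adults_per_plot = 1200L,
                              altitude_range = c(33, 1730),
                              temperature_range = c(21.3, 3.5),
                              temperature_sd = 0.8,
                              precipitation_base = 800,
                              precipitation_per_degree = 110,
                              precipitation_sd = 300,
                              snow_max = 1.17,
                              snow_sd = 0.15,
                              cndd_intercept = -0.21,
                              cndd_slope = 0.12,
                              cndd_sd = 0.04,
                              cndd_ba_slope = 0,
                              recruitment_rate_range = c(0.3, 0.8),
                              hndd_adult = 0,
                              hndd_sap = 0,
                              negbin_gamma = 3,
                              richness_base = 45,
                              richness_env = -0.12,
                              richness_cndd = 0.18,
                              richness_interaction = -0.18,
                              min_species = 5L,
                              sim_quadrat = 10,
                              clustering = list(kappa = 8e-4, sigma = 7, mu = 5),
                              seed = 1L) {
  check_number(n_plots, "n_plots", lower = 1)
  check_number(plot_width, "plot_width", lower = 0, strict_lower = TRUE)
  check_number(plot_height, "plot_height", lower = 0, strict_lower = TRUE)
  check_number(species_pool, "species_pool", lower = 2)
  check_number(abundance_shape, "abundance_shape", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_number(negbin_gamma, "negbin_gamma", lower = 0, strict_lower = TRUE)
  check_number(adults_per_plot, "adults_per_plot", lower = 0)
  check_number(sim_quadrat, "sim_quadrat", lower = 0, strict_lower = TRUE)
  if (!is.null(clustering)) validate_thomas(clustering)
  cfg <- list(
    n_plots = as.integer(n_plots), plot_width = plot_width,
    plot_height = plot_height, species_pool = as.integer(species_pool),
    abundance_shape = abundance_shape,
    adults_per_plot = as.integer(adults_per_plot),
    altitude_range = altitude_range, temperature_range = temperature_range,
    temperature_sd = temperature_sd,
    precipitation_base = precipitation_base,
    precipitation_per_degree = precipitation_per_degree,
    precipitation_sd = precipitation_sd,
    snow_max = snow_max, snow_sd = snow_sd,
    cndd_intercept = cndd_intercept, cndd_slope = cndd_slope,
    cndd_sd = cndd_sd, cndd_ba_slope = cndd_ba_slope,
    recruitment_rate_range = recruitment_rate_range,
    hndd_adult = hndd_adult, hndd_sap = hndd_sap,
    negbin_gamma = negbin_gamma,
    richness_base = richness_base, richness_env = richness_env,
    richness_cndd = richness_cndd,
    richness_interaction = richness_interaction,
    min_species = as.integer(min_species),
    sim_quadrat = sim_quadrat, clustering = clustering,
    seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  cfg
}

validate_thomas <- function(clustering) {
  for (nm in c("kappa", "sigma", "mu")) {
    if (is.null(clustering[[nm]]))
      abort_invalid("clustering must supply '", nm, "'")
    check_number(clustering[[nm]], paste0("clustering$", nm),
                 lower = 0, strict_lower = TRUE)
  }
  invisible(clustering)
}

#' Sample species abundances from a log-series pool
#'
#' Distributes `total_adults` individuals over `species_pool` species by a
#' multinomial draw with log-series weights `shape^k / k` for species
#' `k = 1, ..., species_pool`, the classic skewed abundance structure of
#' tree communities (few dominants, many rare species).
#'
#' @param species_pool number of species (>= 1).
#' @param shape log-series parameter in (0, 1).
#' @param total_adults total number of individuals to distribute.
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return integer vector of length `species_pool` summing to
#'   `total_adults` (species may receive 0).
#' @export
sample_species_abundances <- function(species_pool, shape, total_adults,
                                      seed = NULL) {
  check_number(species_pool, "species_pool", lower = 1)
  check_number(shape, "shape", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_number(total_adults, "total_adults", lower = 0)
  w <- logseries_weights(species_pool, shape)
  with_seed(seed, {
    if (total_adults == 0) return(integer(species_pool))
    as.integer(stats::rmultinom(1L, size = total_adults, prob = w))
  })
}

## unnormalized log-series weights x^k / k, computed on log scale
logseries_weights <- function(n, x) {
  k <- seq_len(n)
  w <- exp(k * log(x) - log(k))
  w / sum(w)
}

#' Sample a point pattern in a rectangular window
#'
#' Uniform (complete spatial randomness) or Thomas cluster process,
#' conditioned on the exact number of points.  Thomas parents are placed
#' on the window extended by `4 * sigma` so that edge clusters are not
#' under-represented; generation is repeated (supplemented) until at least
#' `n_points` fall inside the window, then thinned uniformly at random to
#' exactly `n_points`.
#'
#' @param n_points number of points (>= 0).
#' @param window `c(width, height)` in metres.
#' @param clustering `NULL` for CSR, or a list with Thomas parameters
#'   `kappa` (parent intensity per m^2), `sigma` (offspring SD, m) and
#'   `mu` (mean offspring per parent).
#' @param seed optional seed.
#' @return data.frame with columns `x`, `y`; all points strictly inside
#'   the window.
#' @export
sample_point_pattern <- function(n_points, window = c(100, 100),
                                 clustering = NULL, seed = NULL) {
  check_number(n_points, "n_points", lower = 0)
  if (length(window) != 2L || any(!is.finite(window)) || any(window <= 0))
    abort_invalid("window must be c(width, height), both > 0")
  n_points <- as.integer(n_points)
  with_seed(seed, {
    if (n_points == 0L)
      return(data.frame(x = numeric(0), y = numeric(0)))
    if (is.null(clustering)) {
      return(data.frame(x = runif(n_points, 0, window[1]),
                        y = runif(n_points, 0, window[2])))
    }
    validate_thomas(clustering)
    ## condition on n by inflating the offspring intensity and thinning
    ## uniformly at random: both leave the Thomas pair correlation
    ## function unchanged (g does not depend on mu, and independent
    ## thinning preserves g), unlike superposing extra realizations
    cl <- clustering
    cl$mu <- cl$mu * 1.25
    repeat {
      pts <- rthomas_window(window, cl)
      if (nrow(pts) >= n_points) break
      cl$mu <- cl$mu * 1.3
    }
    pts <- pts[sample.int(nrow(pts), n_points), , drop = FALSE]
    rownames(pts) <- NULL
    pts
  })
}

## one realization of a Thomas process clipped to the window;
## parents on the 4*sigma-extended window
rthomas_window <- function(window, clustering) {
  kappa <- clustering$kappa; sigma <- clustering$sigma; mu <- clustering$mu
  ext <- 4 * sigma
  area <- (window[1] + 2 * ext) * (window[2] + 2 * ext)
  n_par <- rpois(1L, kappa * area)
  if (n_par == 0L) return(data.frame(x = numeric(0), y = numeric(0)))
  px <- runif(n_par, -ext, window[1] + ext)
  py <- runif(n_par, -ext, window[2] + ext)
  n_off <- rpois(n_par, mu)
  cx <- rep(px, n_off) + rnorm(sum(n_off), 0, sigma)
  cy <- rep(py, n_off) + rnorm(sum(n_off), 0, sigma)
  keep <- cx > 0 & cx < window[1] & cy > 0 & cy < window[2]
  data.frame(x = cx[keep], y = cy[keep])
}

#' Simulate sapling counts from the Ricker recruitment model
#'
#' Draws per-quadrat sapling counts `S_i ~ NegBin(mu_i, gamma)` with mean
#' `mu_i = A_i * exp(r + cndd * A_i + hndd_adult * a_i + hndd_sap * s_i)`
#' and variance `mu_i + mu_i^2 / gamma` (gamma is the negative-binomial
#' size parameter).  Quadrats without conspecific adults (`A_i = 0`) have
#' mean zero and yield exactly zero saplings.
#'
#' @param adults_per_quadrat integer vector `A_i` of conspecific adults.
#' @param het_adults,het_saps heterospecific adult and sapling counts
#'   (recycled scalars allowed).
#' @param params named list or vector with `r`, `cndd`, `hndd_adult`,
#'   `hndd_sap`, `gamma`.
#' @param seed optional seed.
#' @return integer vector of sapling counts, same length as
#'   `adults_per_quadrat`.
#' @export
simulate_ricker_counts <- function(adults_per_quadrat, het_adults = 0,
                                   het_saps = 0, params, seed = NULL) {
  p <- as.list(params)
  for (nm in c("r", "cndd", "hndd_adult", "hndd_sap", "gamma"))
    if (is.null(p[[nm]])) abort_invalid("params must supply '", nm, "'")
  check_number(p$gamma, "gamma", lower = 0, strict_lower = TRUE)
  A <- adults_per_quadrat
  n <- length(A)
  a <- rep_len(het_adults, n)
  s <- rep_len(het_saps, n)
  if (any(A < 0) || any(a < 0) || any(s < 0))
    abort_invalid("counts must be non-negative")
  mu <- ricker_mean(A, a, s, p$r, p$cndd, p$hndd_adult, p$hndd_sap)
  with_seed(seed, {
    out <- integer(n)
    pos <- mu > 0
    if (any(pos))
      out[pos] <- rnbinom(sum(pos), size = p$gamma, mu = mu[pos])
    as.integer(out)
  })
}

## Ricker mean mu_i = A exp(r + cndd A + ha a + hs s); exactly 0 when A = 0
ricker_mean <- function(A, a, s, r, cndd, ha, hs) {
  mu <- A * exp(r + cndd * A + ha * a + hs * s)
  mu[A == 0] <- 0
  mu
}

#' Generate a synthetic multi-plot stem-map dataset with known truth
#'
#' Builds `n_plots` stem maps: a latent altitude gradient with linked
#' temperature, precipitation and snow depth; plot-level true mean CNDD
#' linear in standardized altitude; species drawn from a log-series pool
#' with plot richness log-linear in altitude, CNDD strength and their
#' interaction; adults placed uniformly (or as a Thomas process) and
#' binned into generation quadrats; sapling counts drawn per quadrat from
#' the Ricker/negative-binomial model and placed uniformly inside their
#' quadrat.  Adults receive DBH in [15, 60] cm, saplings in [5, 10) cm
#' (GBH = pi * DBH), so the census and staging rules downstream recover
#' the generated life stages.
#'
#' @param config a [simulation_config()].
#' @return list with components `stems` (plot_id, species, x, y, gbh),
#'   `plots` (plot metadata), and `truth` — a list with `species`
#'   (per plot x species true parameters) and `plots` (per-plot true mean
#'   CNDD, strength, expected richness and gradients).
#' @export
generate_multiplot_dataset <- function(config) {
  if (!inherits(config, "simulation_config"))
    config <- do.call(simulation_config, as.list(config))
  cfg <- config
  n <- cfg$n_plots
  seed0 <- cfg$seed

  plots <- with_seed(derive_seed(seed0, 1L), {
    alt <- runif(n, cfg$altitude_range[1], cfg$altitude_range[2])
    rel <- (alt - cfg$altitude_range[1]) / diff(cfg$altitude_range)
    temperature <- cfg$temperature_range[1] +
      diff(cfg$temperature_range) * rel + rnorm(n, 0, cfg$temperature_sd)
    precipitation <- pmax(200, cfg$precipitation_base +
      cfg$precipitation_per_degree * temperature +
      rnorm(n, 0, cfg$precipitation_sd))
    snow <- pmax(0, cfg$snow_max * rel + rnorm(n, 0, cfg$snow_sd))
    ## functional type follows the temperature zone
    ft <- cut(temperature, breaks = c(-Inf, 6, 9, 14, Inf),
              labels = c("EC", "BC", "DB", "EB"))
    succ <- sample(c("OG", "OS", "S"), n, replace = TRUE,
                   prob = c(0.5, 0.25, 0.25))
    data.frame(plot_id = sprintf("plot%02d", seq_len(n)),
               width = cfg$plot_width, height = cfg$plot_height,
               altitude = alt, temperature = temperature,
               precipitation = precipitation, snow_depth = snow,
               forest_type = as.character(ft), succession = succ,
               stringsAsFactors = FALSE)
  })
  alt_std <- if (n > 1) as.numeric(scale(plots$altitude)) else 0
  mean_coef <- cfg$cndd_intercept + cfg$cndd_slope * alt_std
  strength <- -mean_coef
  z <- if (n > 1 && sd(strength) > 0) as.numeric(scale(strength)) else
    rep(0, n)
  mu_S <- cfg$richness_base * exp(cfg$richness_env * alt_std +
    cfg$richness_cndd * z + cfg$richness_interaction * alt_std * z)
  n_species <- with_seed(derive_seed(seed0, 2L),
    pmin(cfg$species_pool, pmax(cfg$min_species, rpois(n, mu_S))))

  pool_w <- logseries_weights(cfg$species_pool, cfg$abundance_shape)
  q <- cfg$sim_quadrat
  nqx <- floor(cfg$plot_width / q)
  nqy <- floor(cfg$plot_height / q)
  if (nqx < 1 || nqy < 1)
    abort_invalid("sim_quadrat larger than the plot")

  stems_list <- vector("list", n)
  truth_list <- vector("list", n)
  for (p in seq_len(n)) {
    res <- with_seed(derive_seed(seed0, 3L, p),
      simulate_one_plot(cfg, plots$plot_id[p], n_species[p], pool_w,
                        mean_coef[p], nqx, nqy))
    stems_list[[p]] <- res$stems
    truth_list[[p]] <- res$truth
  }
  stems <- do.call(rbind, stems_list)
  truth_species <- do.call(rbind, truth_list)
  rownames(stems) <- rownames(truth_species) <- NULL

  true_plot_cndd <- tapply(truth_species$true_cndd, truth_species$plot_id,
                           mean)
  truth_plots <- data.frame(
    plot_id = plots$plot_id,
    altitude = plots$altitude,
    alt_std = alt_std,
    true_mean_cndd = as.numeric(true_plot_cndd[plots$plot_id]),
    true_gradient_cndd = mean_coef,
    true_strength = strength,
    expected_richness = mu_S,
    n_species = n_species,
    stringsAsFactors = FALSE)

  list(stems = stems, plots = plots,
       truth = list(species = truth_species, plots = truth_plots),
       config = cfg)
}

## community + point placement + Ricker saplings for one plot;
## assumes the caller has already fixed the RNG stream
simulate_one_plot <- function(cfg, plot_id, n_sp, pool_w, mean_coef,
                              nqx, nqy) {
  q <- cfg$sim_quadrat
  ids <- sort(sample.int(cfg$species_pool, n_sp, prob = pool_w))
  ## every community species gets one founder adult so that observed
  ## richness equals the generated richness; the log-series multinomial
  ## distributes the remaining adults
  extra <- max(0L, cfg$adults_per_plot - n_sp)
  ab <- 1L + sample_species_abundances(n_sp, cfg$abundance_shape, extra)
  sp_names <- sprintf("sp%03d", ids)

  true_cndd <- rnorm(n_sp, mean_coef, cfg$cndd_sd)
  if (cfg$cndd_ba_slope != 0) {
    lba <- log1p(ab)
    true_cndd <- true_cndd + cfg$cndd_ba_slope * (lba - mean(lba))
  }
  true_r <- runif(n_sp, cfg$recruitment_rate_range[1],
                  cfg$recruitment_rate_range[2])

  ## adults: place, then bin at the generation scale
  adult_pts <- lapply(ab, sample_point_pattern,
                      window = c(cfg$plot_width, cfg$plot_height),
                      clustering = cfg$clustering)
  n_quad <- nqx * nqy
  A_mat <- matrix(0L, n_sp, n_quad)
  for (k in seq_len(n_sp)) {
    pts <- adult_pts[[k]]
    qi <- pmin(floor(pts$x / q), nqx - 1L) +
      nqx * pmin(floor(pts$y / q), nqy - 1L)
    tab <- tabulate(qi + 1L, nbins = n_quad)
    A_mat[k, ] <- tab
  }
  tot_adults_q <- colSums(A_mat)

  ## saplings: Ricker/NegBin counts per quadrat, then uniform placement
  sap_list <- vector("list", n_sp)
  S_mat <- matrix(0L, n_sp, n_quad)
  for (k in seq_len(n_sp)) {
    A <- A_mat[k, ]
    a <- tot_adults_q - A
    S_cnt <- simulate_ricker_counts(A, a, 0, list(
      r = true_r[k], cndd = true_cndd[k], hndd_adult = cfg$hndd_adult,
      hndd_sap = cfg$hndd_sap, gamma = cfg$negbin_gamma))
    S_mat[k, ] <- S_cnt
    if (sum(S_cnt) > 0) {
      qi <- rep(seq_len(n_quad) - 1L, S_cnt)
      qx <- qi %% nqx; qy <- qi %/% nqx
      sap_list[[k]] <- data.frame(
        x = runif(length(qi), qx * q, (qx + 1) * q),
        y = runif(length(qi), qy * q, (qy + 1) * q))
    } else {
      sap_list[[k]] <- data.frame(x = numeric(0), y = numeric(0))
    }
  }

  mk_stems <- function(pts, sp, stage) {
    m <- nrow(pts)
    if (m == 0) return(NULL)
    dbh <- if (stage == "adult") runif(m, 15, 60) else runif(m, 5, 10)
    data.frame(plot_id = plot_id, species = sp, x = pts$x, y = pts$y,
               gbh = dbh * pi, stringsAsFactors = FALSE)
  }
  stems <- do.call(rbind, c(
    lapply(seq_len(n_sp), function(k)
      mk_stems(adult_pts[[k]], sp_names[k], "adult")),
    lapply(seq_len(n_sp), function(k)
      mk_stems(sap_list[[k]], sp_names[k], "sapling"))))

  truth <- data.frame(
    plot_id = plot_id, species = sp_names,
    n_adults = ab, n_saplings = as.integer(rowSums(S_mat)),
    true_r = true_r, true_cndd = true_cndd,
    true_hndd_adult = cfg$hndd_adult, true_hndd_sap = cfg$hndd_sap,
    true_gamma = cfg$negbin_gamma, stringsAsFactors = FALSE)
  list(stems = stems, truth = truth)
}
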