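#' Pipeline configuration
#'
#' One object driving the full analysis: either paths to stem/plot tables
#' (or the tables themselves) or a [simulation_config()] for synthetic
#' input, plus the knobs of every stage with their standard defaults
#' (quadrat sizes 10 and 20 m; adaptive 15/10/5 cm staging thresholds
#' with the 20% adult rule; occupancy >= 10 quadrats and CNDD SE <= 4
#' filters; 30 m intensity bandwidth, 199 null simulations and the
#' 25-individual rule for the spatial stage).
#'
#' @param stems stem table (data.frame) or path to one.
#' @param plots plot metadata (data.frame) or path.
#' @param simulation optional [simulation_config()]; generates the input
#'   and keeps the truth tables in the result.
#' @param quadrat_sizes quadrat scales in metres.
#' @param stage_policy a [stage_threshold_policy()].
#' @param min_occupancy,max_se,occupancy_rule see [species_filter()].
#' @param zero_adult_policy,n_starts see [fit_ricker()].
#' @param gradients gradient columns for the statistical layer.
#' @param spatial run the spatial-aggregation stage?
#' @param spatial_n_sim,spatial_bandwidth,spatial_min_points,spatial_r_max
#'   spatial-stage settings.
#' @param min_sites species-level correlation site rule (default 6).
#' @param seed master seed; all stage sub-seeds derive from it.
#' @param out_dir optional output directory for tables + manifest.
#' @return object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(stems = NULL, plots = NULL, simulation = NULL,
                            quadrat_sizes = c(10, 20),
                            stage_policy = stage_threshold_policy(),
                            min_occupancy = 10L, max_se = 4,
                            occupancy_rule = "both",
                            zero_adult_policy = "drop", n_starts = 5L,
                            gradients = GRADIENTS,
                            spatial = TRUE, spatial_n_sim = 199L,
                            spatial_bandwidth = 30,
                            spatial_min_points = 25L, spatial_r_max = 20,
                            min_sites = 6L, seed = 1L, out_dir = NULL) {
  if (is.null(simulation) && (is.null(stems) || is.null(plots)))
    abort_invalid("supply either stems+plots or a simulation config")
  if (any(quadrat_sizes <= 0))
    abort_invalid("quadrat sizes must be positive")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full CNDD pipeline
#'
#' Stages: input (read or simulate) -> staging/binning/Ricker fits per
#' quadrat scale -> diversity indices -> plot summary -> gradient GLM
#' blocks and correlation tables -> species-level correlations ->
#' optional spatial-aggregation stage.  When `out_dir` is set, every
#' table is written as TSV together with a run manifest (seed, software
#' version, per-stage row counts and an MD5 checksum per file).
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list with `stems`, `plots`, `truth` (simulation
#'   only), `cndd` (fits/plot_cndd/exclusions), `diversity`, `summary`,
#'   `glm_tables`, `correlations`, `species_correlations`, `basal_area`,
#'   `aggregation` (or `NULL`) and `manifest`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    abort_invalid("config must come from pipeline_config()")
  cfg <- config

  if (!is.null(cfg$simulation)) {
    sim <- cfg$simulation
    sim$seed <- derive_seed(cfg$seed, 101L)
    data <- generate_multiplot_dataset(sim)
    stems <- data$stems; plots <- data$plots; truth <- data$truth
  } else {
    plots <- if (is.character(cfg$plots)) read_plot_metadata(cfg$plots)
      else cfg$plots
    stems <- if (is.character(cfg$stems))
      read_stem_table(cfg$stems, plots = plots) else cfg$stems
    truth <- NULL
  }

  cndd <- fit_cndd(stems, plots, cfg$quadrat_sizes, cfg$stage_policy,
                   cfg$min_occupancy, cfg$max_se, cfg$occupancy_rule,
                   cfg$zero_adult_policy, n_starts = cfg$n_starts)
  diversity <- diversity_by_plot(stems)
  summary_df <- build_plot_summary(plots, diversity, cndd$plot_cndd)

  glm_tables <- list()
  for (sc in cfg$quadrat_sizes) {
    for (gr in cfg$gradients) {
      res <- tryCatch(gradient_table(summary_df, gr, sc),
                      forestcndd_degenerate = function(e) NULL)
      if (!is.null(res))
        glm_tables[[paste(gr, sc, sep = "_")]] <- res
    }
  }
  correlations <- correlation_suite(summary_df, cfg$gradients)
  basal_area <- compute_basal_area(stems)
  species_corr <- species_level_correlations(
    cndd$fits, summary_df, basal_area, cfg$min_sites)

  aggregation <- NULL
  if (isTRUE(cfg$spatial)) {
    aggregation <- aggregation_by_plot(
      stems, plots, min_points = cfg$spatial_min_points,
      n_sim = cfg$spatial_n_sim, bandwidth = cfg$spatial_bandwidth,
      r_max = cfg$spatial_r_max, seed = derive_seed(cfg$seed, 202L))
    summary_df <- merge(summary_df, aggregation$plots, by = "plot_id",
                        all.x = TRUE)
  }

  result <- list(stems = stems, plots = plots, truth = truth,
                 cndd = cndd, diversity = diversity,
                 summary = summary_df, glm_tables = glm_tables,
                 correlations = correlations,
                 species_correlations = species_corr,
                 basal_area = basal_area, aggregation = aggregation,
                 manifest = NULL)
  if (!is.null(cfg$out_dir)) result$manifest <- write_outputs(result, cfg)
  invisible(result)
}

## flatten the per-gradient GLM blocks into one table for writing
flatten_glm_tables <- function(glm_tables) {
  if (!length(glm_tables)) return(NULL)
  do.call(rbind, lapply(glm_tables, function(g) {
    cf <- g$coefficients
    data.frame(gradient = g$gradient, scale = g$scale, term = cf$term,
               estimate = cf$estimate, se = cf$se, p = cf$p,
               star = cf$star,
               pseudo_r2_env = g$pseudo_r2[["env"]],
               pseudo_r2_additive = g$pseudo_r2[["additive"]],
               pseudo_r2_interaction = g$pseudo_r2[["interaction"]],
               lr_statistic = g$lr_test$statistic,
               lr_p = g$lr_test$p, stringsAsFactors = FALSE)
  }))
}

write_outputs <- function(result, cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- list(
    stems = result$stems, plots = result$plots,
    ricker_fits = result$cndd$fits, plot_cndd = result$cndd$plot_cndd,
    exclusions = result$cndd$exclusions, diversity = result$diversity,
    plot_summary = result$summary,
    glm_table = flatten_glm_tables(result$glm_tables),
    correlations = result$correlations,
    species_correlations = result$species_correlations$table,
    basal_area = result$basal_area)
  if (!is.null(result$truth)) {
    tabs$truth_species <- result$truth$species
    tabs$truth_plots <- result$truth$plots
  }
  if (!is.null(result$aggregation)) {
    tabs$aggregation_species <- result$aggregation$species
    tabs$aggregation_plots <- result$aggregation$plots
  }
  files <- list()
  for (nm in names(tabs)) {
    if (is.null(tabs[[nm]])) next
    path <- file.path(cfg$out_dir, paste0(nm, ".tsv"))
    write_table(tabs[[nm]], path, allow_empty = TRUE)
    files[[nm]] <- data.frame(
      name = nm, file = basename(path), n_rows = nrow(tabs[[nm]]),
      md5 = unname(tools::md5sum(path)), stringsAsFactors = FALSE)
  }
  manifest <- list(
    package = "forestcndd",
    version = as.character(utils::packageVersion("forestcndd")),
    seed = cfg$seed, quadrat_sizes = cfg$quadrat_sizes,
    zero_adult_policy = cfg$zero_adult_policy,
    timestamp = format(Sys.time(), tz = "UTC"),
    files = do.call(rbind, files))
  jsonlite::write_json(manifest,
                       file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  manifest
}

#' Calibration studies for the estimation and testing layers
#'
#' Reproducible simulation studies quantifying the statistical behaviour
#' of the pipeline:
#' \describe{
#'   \item{`"estimator"`}{bias and 3 SE coverage of the CNDD estimate on
#'     data simulated from the fitted family (default truth: r = 0.5,
#'     CNDD = -0.05, HNDDs = 0, gamma = 2; 400 quadrats).}
#'   \item{`"glm"`}{type-I error of the likelihood-ratio interaction test
#'     under a null Poisson model, and its power under a known
#'     interaction, next to the analytic noncentral chi-square
#'     approximation.}
#'   \item{`"recovery"`}{end-to-end runs of the pipeline on synthetic
#'     multi-plot datasets: rates of recovering the negative
#'     CNDD-altitude correlation, the positive CNDD-richness correlation
#'     and the significant CNDD x altitude interaction.}
#' }
#'
#' @param scenario one of `"estimator"`, `"glm"`, `"recovery"`.
#' @param n_replicates number of Monte-Carlo replicates (>= 10).
#' @param seed master seed.
#' @param ... scenario-specific overrides: `truth` (named list) and
#'   `n_quadrats` for `"estimator"`; `beta` (named vector `b0`, `bE`,
#'   `bC`, `bI`) and `n_plots` for `"glm"`; `sim_config` (a
#'   [simulation_config()]) for `"recovery"`.
#' @return list with the scenario name, the per-replicate table and the
#'   summary statistics.
#' @export
run_calibration <- function(scenario = c("estimator", "glm", "recovery"),
                            n_replicates = 100L, seed = 1L, ...) {
  scenario <- match.arg(scenario)
  if (n_replicates < 10L) abort_invalid("n_replicates must be >= 10")
  opts <- list(...)
  switch(scenario,
         estimator = calibrate_estimator(n_replicates, seed, opts),
         glm = calibrate_glm(n_replicates, seed, opts),
         recovery = calibrate_recovery(n_replicates, seed, opts))
}

calibrate_estimator <- function(n_rep, seed, opts) {
  truth <- opts$truth %||% list(r = 0.5, cndd = -0.05, hndd_adult = 0,
                                hndd_sap = 0, gamma = 2)
  n_quad <- opts$n_quadrats %||% 400L
  adult_mean <- opts$adult_mean %||% 2
  rows <- lapply(seq_len(n_rep), function(i) {
    with_seed(derive_seed(seed, 11L, i), {
      A <- rpois(n_quad, adult_mean)
      a <- rpois(n_quad, 5)
      s <- rpois(n_quad, 5)
      S <- simulate_ricker_counts(A, a, s, truth)
      cnt <- data.frame(S = S, A = A, a = a, s = s)
      fit <- fit_ricker(cnt)
      data.frame(replicate = i, cndd_hat = fit$cndd_hat,
                 se_cndd = fit$se_cndd, r_hat = fit$r_hat,
                 gamma_hat = fit$gamma_hat, converged = fit$converged)
    })
  })
  tab <- do.call(rbind, rows)
  ok <- tab$converged & is.finite(tab$se_cndd)
  err <- tab$cndd_hat[ok] - truth$cndd
  list(scenario = "estimator", truth = truth, replicates = tab,
       summary = list(
         n_converged = sum(ok),
         mean_bias = mean(err),
         mc_se_bias = sd(err) / sqrt(sum(ok)),
         coverage_3se = mean(abs(err) <= 3 * tab$se_cndd[ok])))
}

calibrate_glm <- function(n_rep, seed, opts) {
  beta <- opts$beta %||% c(b0 = 3.5, bE = -0.15, bC = 0.15, bI = 0)
  n_plots <- opts$n_plots %||% 32L
  rows <- lapply(seq_len(n_rep), function(i) {
    with_seed(derive_seed(seed, 12L, i), {
      env <- runif(n_plots, -sqrt(3), sqrt(3))   # mean 0, var 1
      cndd <- -env + rnorm(n_plots, 0, 0.4)
      eta <- beta["b0"] + beta["bE"] * env + beta["bC"] * cndd +
        beta["bI"] * env * cndd
      d <- data.frame(S = rpois(n_plots, exp(eta)), ENV = env,
                      CNDD = cndd)
      m0 <- fit_poisson_glm(S ~ ENV + CNDD, d)
      m1 <- fit_poisson_glm(S ~ ENV * CNDD, d)
      lr <- interaction_lr_test(m0, m1)
      ## analytic noncentrality of the interaction Wald/LR test
      X <- stats::model.matrix(~ ENV * CNDD, d)
      W <- exp(eta)
      I_mat <- crossprod(X, X * W)
      v <- tryCatch(solve(I_mat)[4, 4], error = function(e) NA)
      lambda_nc <- if (is.finite(v)) beta["bI"]^2 / v else NA
      data.frame(replicate = i, p = lr$p, lambda_nc = lambda_nc)
    })
  })
  tab <- do.call(rbind, rows)
  lambda_bar <- mean(tab$lambda_nc, na.rm = TRUE)
  crit <- stats::qchisq(0.95, 1)
  list(scenario = "glm", beta = beta, replicates = tab,
       summary = list(
         rejection_rate = mean(tab$p <= 0.05),
         mc_se = sqrt(0.05 * 0.95 / n_rep),
         analytic_power = pchisq(crit, 1, ncp = lambda_bar,
                                 lower.tail = FALSE)))
}

calibrate_recovery <- function(n_rep, seed, opts) {
  base_cfg <- opts$sim_config %||% simulation_config()
  quadrat_sizes <- opts$quadrat_sizes %||% 10
  rows <- lapply(seq_len(n_rep), function(i) {
    cfg <- base_cfg
    cfg$seed <- derive_seed(seed, 13L, i)
    pc <- pipeline_config(simulation = cfg, spatial = FALSE,
                          quadrat_sizes = quadrat_sizes,
                          seed = cfg$seed)
    res <- run_pipeline(pc)
    co <- res$correlations
    sc <- quadrat_sizes[1]
    alt <- co[co$scale == sc & co$var1 == "cndd_strength" &
                co$var2 == "altitude" & co$subset == "all", ]
    rich <- co[co$scale == sc & co$var1 == "cndd_strength" &
                 co$var2 == "S" & co$subset == "all", ]
    g <- res$glm_tables[[paste0("altitude_", sc)]]
    data.frame(replicate = i,
               rho_altitude = alt$rho, p_altitude = alt$p,
               rho_richness = rich$rho, p_richness = rich$p,
               lr_p = if (is.null(g)) NA else g$lr_test$p,
               mean_abs_cndd_err = mean(abs(
                 res$summary$mean_cndd[res$summary$scale == sc] -
                   res$truth$plots$true_mean_cndd[
                     match(res$summary$plot_id[res$summary$scale == sc],
                           res$truth$plots$plot_id)])))
  })
  tab <- do.call(rbind, rows)
  list(scenario = "recovery", replicates = tab,
       summary = list(
         rate_negative_altitude = mean(tab$rho_altitude < 0 &
                                         tab$p_altitude <= 0.05),
         rate_positive_richness = mean(tab$rho_richness > 0 &
                                         tab$p_richness <= 0.05),
         rate_interaction = mean(tab$lr_p <= 0.05, na.rm = TRUE),
         mean_abs_cndd_err = mean(tab$mean_abs_cndd_err)))
}
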