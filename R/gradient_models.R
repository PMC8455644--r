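## Statistical layer relating plot-level CNDD and diversity to
## environmental gradients: Spearman correlations (overall, by forest
## type, old-growth only), Poisson GLMs of species number on
## gradient x CNDD with likelihood-ratio interaction tests, and
## deviance-based pseudo-R^2.  The CNDD variable used throughout is
## cndd_strength = -(plot mean Ricker coefficient), so that larger
## values mean stronger conspecific density dependence.

GRADIENTS <- c("altitude", "temperature", "precipitation", "snow_ln")

#' Assemble the per-plot, per-scale summary table
#'
#' Joins plot metadata (with `snow_ln = log(snow_depth + 1)`, the
#' transform used because snow depth is highly skewed), diversity
#' indices, and plot-mean CNDD into one row per plot and quadrat scale.
#'
#' @param plots plot metadata (see [read_plot_metadata()]).
#' @param diversity per-plot diversity from [diversity_by_plot()].
#' @param plot_cndd per plot x scale CNDD means from [fit_cndd()].
#' @return data.frame, one row per plot x scale.
#' @export
build_plot_summary <- function(plots, diversity, plot_cndd) {
  meta <- plots
  meta$snow_ln <- log(meta$snow_depth + 1)
  base <- merge(meta, diversity, by = "plot_id")
  out <- merge(plot_cndd, base, by = "plot_id", all.x = TRUE)
  out[order(out$scale, out$plot_id), ]
}

#' Spearman rank correlation with t-approximation p-value
#'
#' `rho` is the Pearson correlation of average ranks (ties get average
#' ranks); the two-sided p-value uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` with `n - 2` degrees of
#' freedom.
#'
#' @param x,y paired numeric vectors; incomplete pairs are dropped.
#' @return list with `rho`, `p`, `n` (`rho`/`p` are `NA` for `n < 3` or a
#'   constant vector).
#' @export
spearman_correlation <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || sd(x) == 0 || sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n))
  rho <- cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tval), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Poisson GLM for species counts
#'
#' Log-link Poisson fit (IRLS, convergence tolerance `1e-10`) with the
#' deviance pseudo-R^2 `1 - residual deviance / null deviance`.
#'
#' @param formula model formula, e.g. `S ~ altitude * cndd_strength`.
#' @param data data.frame with the response and predictors.
#' @return object of class `"cndd_glm"`: the `glm` fit plus
#'   `coefficients` (estimate, se, z, p), `null_deviance`, `deviance`,
#'   `pseudo_r2`, `df_residual`, `n`.
#' @export
fit_poisson_glm <- function(formula, data) {
  fit <- glm(formula, family = poisson(), data = data,
             control = glm.control(epsilon = 1e-10, maxit = 100))
  if (!fit$converged) abort_invalid("Poisson GLM did not converge")
  if (any(is.na(coef(fit))))
    abort_invalid("rank-deficient design; aliased: ",
                  paste(names(coef(fit))[is.na(coef(fit))],
                        collapse = ", "))
  sm <- summary(fit)$coefficients
  structure(list(
    fit = fit, formula = formula,
    coefficients = data.frame(term = rownames(sm),
                              estimate = sm[, 1], se = sm[, 2],
                              z = sm[, 3], p = sm[, 4],
                              row.names = NULL),
    null_deviance = fit$null.deviance, deviance = fit$deviance,
    pseudo_r2 = 1 - fit$deviance / fit$null.deviance,
    df_residual = fit$df.residual, n = nrow(fit$model)),
    class = "cndd_glm")
}

#' Likelihood-ratio (chi-square) test between nested Poisson GLMs
#'
#' The statistic is the drop in residual deviance from the additive to
#' the interaction model, referred to a chi-square distribution with the
#' difference in parameters as degrees of freedom.
#'
#' @param fit_additive,fit_interaction nested [fit_poisson_glm()] fits on
#'   the same data (the additive model must not have more parameters).
#' @return list with `statistic`, `df`, `p`.
#' @export
interaction_lr_test <- function(fit_additive, fit_interaction) {
  f0 <- fit_additive; f1 <- fit_interaction
  if (!inherits(f0, "cndd_glm") || !inherits(f1, "cndd_glm"))
    abort_invalid("both arguments must come from fit_poisson_glm()")
  if (f0$n != f1$n || f0$fit$df.null != f1$fit$df.null)
    abort_invalid("models were fitted to different data")
  df <- f0$df_residual - f1$df_residual
  stat <- max(0, f0$deviance - f1$deviance)
  if (df < 0) abort_invalid("models are not nested as (additive, interaction)")
  if (df == 0) {
    if (stat > 1e-6) abort_invalid("models differ but have equal df")
    return(list(statistic = 0, df = 0L, p = 1))
  }
  list(statistic = stat, df = as.integer(df),
       p = pchisq(stat, df, lower.tail = FALSE))
}

signif_star <- function(p) {
  ifelse(is.na(p), "", ifelse(p <= 0.05, "*", ifelse(p <= 0.1, "x", "")))
}

#' Nested GLM block for one environmental gradient
#'
#' Fits the three nested Poisson models of species number — gradient
#' only, gradient + CNDD, gradient x CNDD — reports the full-model
#' coefficients with significance marks (`*` for P <= 0.05, `x` for
#' P <= 0.1), the three pseudo-R^2 values, and the likelihood-ratio test
#' of the interaction.
#'
#' @param summary_df plot summary from [build_plot_summary()].
#' @param gradient one of `"altitude"`, `"temperature"`,
#'   `"precipitation"`, `"snow_ln"`.
#' @param scale quadrat scale (m) to subset.
#' @param cndd_var CNDD column to use (default `"cndd_strength"`).
#' @param include_n_trees add `n_trees` as an extra additive predictor.
#' @param min_plots minimum complete plots required (default 6).
#' @return list with `gradient`, `scale`, `coefficients` (full model,
#'   with stars), `pseudo_r2` (named: env, additive, interaction),
#'   `lr_test`, and the three `"cndd_glm"` fits.
#' @export
gradient_table <- function(summary_df, gradient, scale,
                           cndd_var = "cndd_strength",
                           include_n_trees = FALSE, min_plots = 6L) {
  if (!gradient %in% names(summary_df))
    abort_invalid("unknown gradient: ", gradient)
  d <- summary_df[summary_df$scale == scale, , drop = FALSE]
  d <- d[is.finite(d$S) & is.finite(d[[gradient]]) &
           is.finite(d[[cndd_var]]), , drop = FALSE]
  if (nrow(d) < min_plots)
    abort_degenerate("fewer than ", min_plots, " complete plots")
  d$ENV <- d[[gradient]]; d$CNDD <- d[[cndd_var]]
  extra <- if (include_n_trees) " + n_trees" else ""
  f_env <- stats::as.formula(paste0("S ~ ENV", extra))
  f_add <- stats::as.formula(paste0("S ~ ENV + CNDD", extra))
  f_int <- stats::as.formula(paste0("S ~ ENV * CNDD", extra))
  m_env <- fit_poisson_glm(f_env, d)
  m_add <- fit_poisson_glm(f_add, d)
  m_int <- fit_poisson_glm(f_int, d)
  lr <- interaction_lr_test(m_add, m_int)
  cf <- m_int$coefficients
  cf$star <- signif_star(cf$p)
  list(gradient = gradient, scale = scale, n = nrow(d),
       coefficients = cf,
       pseudo_r2 = c(env = m_env$pseudo_r2, additive = m_add$pseudo_r2,
                     interaction = m_int$pseudo_r2),
       lr_test = lr,
       models = list(env = m_env, additive = m_add, interaction = m_int))
}

#' Correlation table of CNDD, diversity and gradients
#'
#' Spearman correlations (with linear-model r^2 for the overall fits) of
#' CNDD strength against each gradient and each diversity index, and of
#' the diversity indices against the gradients — overall, within each
#' forest type, and restricted to old-growth plots; per quadrat scale.
#'
#' @param summary_df plot summary from [build_plot_summary()].
#' @param gradients gradient columns to use.
#' @param cndd_var CNDD column (default `"cndd_strength"`).
#' @return long data.frame: `scale`, `var1`, `var2`, `subset`, `n`,
#'   `rho`, `p`, `linear_r2` (overall rows only), `star`.
#' @export
correlation_suite <- function(summary_df, gradients = GRADIENTS,
                              cndd_var = "cndd_strength") {
  pairs <- rbind(
    expand.grid(var1 = cndd_var, var2 = c(gradients, "S", "H", "e"),
                stringsAsFactors = FALSE),
    expand.grid(var1 = c("S", "H", "e"), var2 = gradients,
                stringsAsFactors = FALSE))
  rows <- list()
  for (sc in sort(unique(summary_df$scale))) {
    dsc <- summary_df[summary_df$scale == sc, , drop = FALSE]
    subsets <- c(list(all = dsc, `old-growth` =
                        dsc[dsc$succession == "OG", , drop = FALSE]),
                 setNames(
                   lapply(sort(unique(dsc$forest_type)), function(ft)
                     dsc[dsc$forest_type == ft, , drop = FALSE]),
                   paste0("type:", sort(unique(dsc$forest_type)))))
    for (sub_name in names(subsets)) {
      d <- subsets[[sub_name]]
      for (k in seq_len(nrow(pairs))) {
        v1 <- pairs$var1[k]; v2 <- pairs$var2[k]
        sp <- spearman_correlation(d[[v1]], d[[v2]])
        r2 <- NA_real_
        if (sub_name == "all" && sp$n >= 3 && is.finite(sp$rho)) {
          ok <- is.finite(d[[v1]]) & is.finite(d[[v2]])
          r2 <- summary(lm(d[[v2]][ok] ~ d[[v1]][ok]))$r.squared
        }
        rows[[length(rows) + 1L]] <- data.frame(
          scale = sc, var1 = v1, var2 = v2, subset = sub_name,
          n = sp$n, rho = sp$rho, p = sp$p, linear_r2 = r2,
          star = signif_star(sp$p), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Species-level correlations of CNDD across plots
#'
#' For every species retained in at least `min_sites` plots, correlates
#' its per-plot CNDD strength with the gradients and the plot diversity
#' indices (sign and significance flags, per scale).  Also reports the
#' pooled Spearman correlation of species-plot CNDD strength with
#' log basal area.
#'
#' @param fits retained `RickerFit` rows (see [fit_cndd()]).
#' @param summary_df plot summary from [build_plot_summary()].
#' @param basal_area per plot x species basal area from
#'   [compute_basal_area()] (for the pooled test; optional).
#' @param min_sites minimum number of plots per species (default 6).
#' @return list with `table` (species x variable x scale rows: `n`,
#'   `rho`, `p`, `sign`, `star`) and `pooled_ba` (per scale: `rho`, `p`,
#'   `n` of the CNDD-strength vs log basal area test).
#' @export
species_level_correlations <- function(fits, summary_df,
                                       basal_area = NULL,
                                       min_sites = 6L) {
  fits <- fits[isTRUE_vec(fits$retained), , drop = FALSE]
  fits$cndd_strength_sp <- -fits$cndd_hat
  vars <- c(GRADIENTS, "S", "H", "e")
  rows <- list()
  for (sc in sort(unique(fits$scale))) {
    fs <- fits[fits$scale == sc, , drop = FALSE]
    psc <- summary_df[summary_df$scale == sc, , drop = FALSE]
    m <- merge(fs, psc[, c("plot_id", vars)], by = "plot_id")
    for (sp_name in sort(unique(m$species))) {
      ms <- m[m$species == sp_name, , drop = FALSE]
      if (nrow(ms) < min_sites) next
      for (v in vars) {
        spc <- spearman_correlation(ms$cndd_strength_sp, ms[[v]])
        rows[[length(rows) + 1L]] <- data.frame(
          species = sp_name, scale = sc, variable = v, n = spc$n,
          rho = spc$rho, p = spc$p,
          sign = ifelse(is.na(spc$rho), "",
                        ifelse(spc$rho >= 0, "+", "-")),
          star = signif_star(spc$p), stringsAsFactors = FALSE)
      }
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(species = character(0), scale = numeric(0),
               variable = character(0), n = integer(0), rho = numeric(0),
               p = numeric(0), sign = character(0), star = character(0))

  pooled <- NULL
  if (!is.null(basal_area)) {
    mba <- merge(fits, basal_area, by = c("plot_id", "species"))
    pooled <- do.call(rbind, lapply(sort(unique(mba$scale)), function(sc) {
      ms <- mba[mba$scale == sc, ]
      spc <- spearman_correlation(ms$cndd_strength_sp,
                                  log(ms$basal_area))
      data.frame(scale = sc, rho = spc$rho, p = spc$p, n = spc$n)
    }))
  }
  list(table = tab, pooled_ba = pooled)
}

isTRUE_vec <- function(x) !is.na(x) & x
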