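## Species-by-species maximum-likelihood fitting of the Ricker
## recruitment model with negative-binomial error:
##   S_i ~ NegBin(mu_i, gamma),  Var = mu + mu^2/gamma
##   mu_i = A_i * exp(r + CNDD*A_i + HNDD_adult*a_i + HNDD_sap*s_i)
## Quadrats without conspecific adults have mu = 0 under this model, so
## the default likelihood excludes them ("drop" policy); a "floor" policy
## (mu = (A + eps) * exp(...)) is available for sensitivity analysis.

include_rows <- function(counts, zero_adult_policy) {
  if (zero_adult_policy == "drop") counts$A > 0 else
    rep(TRUE, nrow(counts))
}

#' Log-likelihood of the Ricker/negative-binomial recruitment model
#'
#' @param params named vector or list with `r`, `cndd`, `hndd_adult`,
#'   `hndd_sap`, `gamma` (gamma > 0).
#' @param counts quadrat count rows for one focal species, with columns
#'   `S`, `A`, `a`, `s` (see [build_quadrat_counts()]).
#' @param zero_adult_policy `"drop"` excludes quadrats with `A = 0` from
#'   the likelihood (the model gives them zero mean); `"floor"` replaces
#'   `A` by `A + floor_epsilon` in the mean.
#' @param floor_epsilon additive floor for the `"floor"` policy.
#' @return the summed negative-binomial log-likelihood over the included
#'   quadrats.
#' @export
negbin_ricker_loglik <- function(params, counts,
                                 zero_adult_policy = c("drop", "floor"),
                                 floor_epsilon = 1e-3) {
  zero_adult_policy <- match.arg(zero_adult_policy)
  p <- as.list(params)
  check_number(p$gamma, "gamma", lower = 0, strict_lower = TRUE)
  keep <- include_rows(counts, zero_adult_policy)
  if (!any(keep))
    abort_degenerate("all quadrats excluded by the zero-adult policy")
  cc <- counts[keep, , drop = FALSE]
  A_eff <- if (zero_adult_policy == "floor") cc$A + floor_epsilon else cc$A
  mu <- A_eff * exp(p$r + p$cndd * cc$A + p$hndd_adult * cc$a +
                      p$hndd_sap * cc$s)
  sum(dnbinom(cc$S, size = p$gamma, mu = mu, log = TRUE))
}

#' Fit the Ricker/negative-binomial model for one species
#'
#' Maximum likelihood via multi-start BFGS on the unconstrained scale
#' `(r, cndd, hndd_adult, hndd_sap, log gamma)`.  The first start comes
#' from a Poisson GLM with offset `log(A)` (method-of-moments gamma);
#' the remaining starts jitter it with fixed sub-seeds.  Standard errors
#' come from the inverse observed information (numerical Hessian at the
#' optimum); `se(gamma)` uses the delta method from `se(log gamma)`.
#' The `converged` flag requires optimizer success *and* positive-definite
#' curvature — with `A` constant across included quadrats, `r` and `cndd`
#' are confounded and the fit is flagged rather than returning arbitrary
#' numbers.
#'
#' @param counts quadrat counts for one focal species (one plot, one
#'   scale), as from [build_quadrat_counts()].
#' @param zero_adult_policy,floor_epsilon see [negbin_ricker_loglik()].
#' @param n_starts number of optimizer starts (>= 1).
#' @param start_seed seed for the jittered starts (fixed by default so
#'   fits are reproducible).
#' @return one-row data.frame (a `RickerFit`): estimates, standard
#'   errors, log-likelihood, `n_quadrats_used`, `converged`.
#' @export
fit_ricker <- function(counts, zero_adult_policy = c("drop", "floor"),
                       floor_epsilon = 1e-3, n_starts = 5L,
                       start_seed = 1L) {
  zero_adult_policy <- match.arg(zero_adult_policy)
  keep <- include_rows(counts, zero_adult_policy)
  cc <- counts[keep, , drop = FALSE]
  out <- data.frame(
    plot_id = counts$plot_id[1] %||% NA_character_,
    species = counts$species[1] %||% NA_character_,
    scale = counts$quadrat_size[1] %||% NA_real_,
    r_hat = NA_real_, cndd_hat = NA_real_, hndd_adult_hat = NA_real_,
    hndd_sap_hat = NA_real_, gamma_hat = NA_real_,
    se_r = NA_real_, se_cndd = NA_real_, se_hndd_adult = NA_real_,
    se_hndd_sap = NA_real_, se_gamma = NA_real_,
    loglik = NA_real_, n_quadrats_used = nrow(cc),
    converged = FALSE, exclusion_reason = NA_character_,
    stringsAsFactors = FALSE)
  if (nrow(cc) < 6L) {
    out$exclusion_reason <- "fewer included quadrats than parameters + 1"
    return(out)
  }

  A_eff <- if (zero_adult_policy == "floor") cc$A + floor_epsilon else cc$A
  nll <- function(th) {
    mu <- A_eff * exp(th[1] + th[2] * cc$A + th[3] * cc$a + th[4] * cc$s)
    if (any(!is.finite(mu))) return(1e10)
    v <- suppressWarnings(
      -sum(dnbinom(cc$S, size = exp(th[5]), mu = mu, log = TRUE)))
    if (!is.finite(v)) 1e10 else v
  }

  ## moment/GLM-informed first start
  st <- c(0, 0, 0, 0, 0)
  glm0 <- tryCatch(
    glm(S ~ A + a + s, offset = log(A_eff), family = poisson(),
        data = cc),
    error = function(e) NULL, warning = function(w) NULL)
  if (!is.null(glm0)) {
    cf <- coef(glm0); cf[!is.finite(cf)] <- 0
    st[1:4] <- pmax(pmin(cf[c("(Intercept)", "A", "a", "s")], 5), -5)
    mu0 <- pmax(fitted(glm0), 1e-8)
    excess <- mean((cc$S - mu0)^2 - mu0)
    g0 <- if (is.finite(excess) && excess > 0)
      mean(mu0^2) / excess else 10
    st[5] <- log(min(max(g0, 0.05), 100))
  }
  starts <- list(st)
  if (n_starts > 1L) {
    jit <- with_seed(derive_seed(start_seed, 17L), {
      lapply(seq_len(n_starts - 1L), function(i)
        st + rnorm(5L, 0, c(0.5, 0.05, 0.02, 0.02, 0.7)))
    })
    starts <- c(starts, jit)
  }

  ## analytic score of the NegBin log-likelihood (gamma on log scale)
  ngr <- function(th) {
    gam <- exp(th[5])
    mu <- A_eff * exp(th[1] + th[2] * cc$A + th[3] * cc$a + th[4] * cc$s)
    if (any(!is.finite(mu)) || !is.finite(gam)) return(rep(0, 5))
    dmu <- (cc$S / mu - (cc$S + gam) / (mu + gam)) * mu
    dlg <- digamma(cc$S + gam) - digamma(gam) + log(gam) + 1 -
      log(mu + gam) - (cc$S + gam) / (mu + gam)
    g <- -c(sum(dmu), sum(dmu * cc$A), sum(dmu * cc$a), sum(dmu * cc$s),
            gam * sum(dlg))
    if (any(!is.finite(g))) rep(0, 5) else g
  }

  best <- NULL
  for (s0 in starts) {
    op <- tryCatch(
      optim(s0, nll, gr = ngr, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(op) || !is.finite(op$value)) next
    if (is.null(best) || op$value < best$value) best <- op
  }
  if (is.null(best)) {
    out$exclusion_reason <- "optimization failed for all starts"
    return(out)
  }

  th <- best$par
  out$r_hat <- th[1]; out$cndd_hat <- th[2]
  out$hndd_adult_hat <- th[3]; out$hndd_sap_hat <- th[4]
  out$gamma_hat <- exp(th[5])
  out$loglik <- -best$value

  H <- tryCatch(optimHess(th, nll), error = function(e) NULL)
  pd <- FALSE
  if (!is.null(H) && all(is.finite(H))) {
    ev <- tryCatch(eigen(H, symmetric = TRUE, only.values = TRUE)$values,
                   error = function(e) NA)
    pd <- all(is.finite(ev)) && min(ev) > max(abs(ev)) * 1e-10
  }
  if (pd) {
    vc <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(vc) && all(is.finite(diag(vc))) && all(diag(vc) > 0)) {
      se <- sqrt(diag(vc))
      out$se_r <- se[1]; out$se_cndd <- se[2]
      out$se_hndd_adult <- se[3]; out$se_hndd_sap <- se[4]
      out$se_gamma <- out$gamma_hat * se[5]   # delta method
      out$converged <- best$convergence == 0
    }
  }
  if (!out$converged && is.na(out$exclusion_reason))
    out$exclusion_reason <- "non-convergence or singular curvature"
  out
}

#' Exclusion rules for fitted species
#'
#' A species is dropped when (1) its adults or its saplings occupy fewer
#' than `min_occupancy` quadrats (both occupancies must reach the
#' threshold), (2) the standard error of its CNDD estimate exceeds
#' `max_se` (strictly above; `se = 4` is retained), or (3) the fit did not
#' converge.
#'
#' @param counts quadrat counts for the species (all quadrats, zeros
#'   included).
#' @param fit optional `RickerFit` row (needed for the SE and convergence
#'   rules).
#' @param min_occupancy occupancy threshold (default 10 quadrats).
#' @param max_se maximum CNDD standard error (default 4).
#' @param occupancy_rule `"both"` (default) requires adult *and* sapling
#'   occupancy `>= min_occupancy`; `"either"` requires only one of them.
#' @return list with `keep` (logical) and `reason` (`NA` when kept).
#' @export
species_filter <- function(counts, fit = NULL, min_occupancy = 10L,
                           max_se = 4, occupancy_rule = c("both", "either")) {
  occupancy_rule <- match.arg(occupancy_rule)
  occ_a <- sum(counts$A > 0)
  occ_s <- sum(counts$S > 0)
  occ_ok <- if (occupancy_rule == "both")
    occ_a >= min_occupancy && occ_s >= min_occupancy
  else occ_a >= min_occupancy || occ_s >= min_occupancy
  if (!occ_ok)
    return(list(keep = FALSE,
                reason = sprintf(
                  "adults or saplings occupied fewer than %d quadrats (%d/%d)",
                  min_occupancy, occ_a, occ_s)))
  if (!is.null(fit)) {
    if (!isTRUE(fit$converged))
      return(list(keep = FALSE, reason = "fit did not converge"))
    if (!is.finite(fit$se_cndd))
      return(list(keep = FALSE, reason = "CNDD standard error unavailable"))
    if (fit$se_cndd > max_se)
      return(list(keep = FALSE,
                  reason = sprintf("CNDD standard error above %g", max_se)))
  }
  list(keep = TRUE, reason = NA_character_)
}

#' Plot-level mean CNDD from retained species fits
#'
#' @param fits `RickerFit` rows for one plot and one scale, already
#'   filtered (see [species_filter()]).
#' @return one-row data.frame with `mean_cndd`, `cndd_strength`
#'   (`-mean_cndd`; higher = stronger density dependence), mean HNDD
#'   coefficients and `n_species_retained`.
#' @export
plot_mean_cndd <- function(fits) {
  if (nrow(fits) < 1L)
    abort_degenerate("no retained species for this plot/scale")
  data.frame(
    plot_id = fits$plot_id[1], scale = fits$scale[1],
    mean_cndd = mean(fits$cndd_hat),
    cndd_strength = -mean(fits$cndd_hat),
    mean_hndd_adult = mean(fits$hndd_adult_hat),
    mean_hndd_sap = mean(fits$hndd_sap_hat),
    n_species_retained = nrow(fits),
    stringsAsFactors = FALSE)
}

#' Fit CNDD for every species, plot and quadrat scale
#'
#' End-to-end driver for the estimation layer: stages stems with the
#' adaptive threshold policy, bins them at each quadrat scale, screens
#' species by quadrat occupancy before fitting, fits the
#' Ricker/negative-binomial model for the remainder, applies the
#' post-fit exclusion rules and aggregates retained CNDD to plot means.
#'
#' @param stems stem table (validated; `gbh` and/or `dbh`).
#' @param plots plot metadata.
#' @param quadrat_sizes quadrat sides in metres (default `c(10, 20)`).
#' @param policy a [stage_threshold_policy()].
#' @param min_occupancy,max_se,occupancy_rule see [species_filter()].
#' @param zero_adult_policy,floor_epsilon,n_starts see [fit_ricker()].
#' @return list with `fits` (one row per fitted or screened species),
#'   `plot_cndd` (per plot x scale means) and `exclusions` (species,
#'   scale, reason).
#' @export
fit_cndd <- function(stems, plots, quadrat_sizes = c(10, 20),
                     policy = stage_threshold_policy(),
                     min_occupancy = 10L, max_se = 4,
                     occupancy_rule = "both",
                     zero_adult_policy = "drop", floor_epsilon = 1e-3,
                     n_starts = 5L) {
  staged <- classify_life_stage(stems, policy)
  all_fits <- list(); all_means <- list(); excl <- list()
  for (qs in quadrat_sizes) {
    binned <- assign_quadrats(staged, qs, plots)
    counts <- build_quadrat_counts(binned)
    key <- interaction(counts$plot_id, counts$species, drop = TRUE)
    for (cnt in split(counts, key)) {
      pre <- species_filter(cnt, NULL, min_occupancy, max_se,
                            occupancy_rule)
      if (!pre$keep) {
        excl[[length(excl) + 1L]] <- data.frame(
          plot_id = cnt$plot_id[1], species = cnt$species[1], scale = qs,
          reason = pre$reason, stringsAsFactors = FALSE)
        next
      }
      fit <- fit_ricker(cnt, zero_adult_policy, floor_epsilon, n_starts)
      post <- species_filter(cnt, fit, min_occupancy, max_se,
                             occupancy_rule)
      fit$retained <- post$keep
      if (!post$keep) {
        fit$exclusion_reason <- post$reason
        excl[[length(excl) + 1L]] <- data.frame(
          plot_id = cnt$plot_id[1], species = cnt$species[1], scale = qs,
          reason = post$reason, stringsAsFactors = FALSE)
      }
      all_fits[[length(all_fits) + 1L]] <- fit
    }
  }
  fits <- do.call(rbind, all_fits)
  if (is.null(fits))
    abort_degenerate("no species passed the occupancy screen")
  retained <- fits[fits$retained, , drop = FALSE]
  means <- lapply(split(retained,
                        interaction(retained$plot_id, retained$scale,
                                    drop = TRUE)),
                  plot_mean_cndd)
  plot_cndd <- do.call(rbind, means)
  rownames(plot_cndd) <- NULL
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(plot_id = character(0), species = character(0),
               scale = numeric(0), reason = character(0))
  list(fits = fits, plot_cndd = plot_cndd, exclusions = exclusions,
       zero_adult_policy = zero_adult_policy)
}
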