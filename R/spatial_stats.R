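## Spatial-aggregation diagnostics: Gaussian kernel intensity surfaces,
## the inhomogeneous pair correlation function (PCF) with Ripley
## isotropic edge correction, simulation of the inhomogeneous Poisson
## null model, and the DCLF (Diggle-Cressie-Loosmore-Ford) Monte-Carlo
## goodness-of-fit test with 199 simulations.

#' Gaussian kernel intensity surface
#'
#' Non-parametric intensity estimate on a grid: each point contributes a
#' bivariate Gaussian kernel with SD `bandwidth`, renormalized by its
#' kernel mass inside the window (uniform edge correction), so the
#' surface integrates to the number of points.
#'
#' @param points data.frame with `x`, `y` (metres).
#' @param window `c(width, height)` in metres.
#' @param bandwidth Gaussian SD in metres (default 30).
#' @param cell target grid cell size in metres (default 2; actual cells
#'   divide the window exactly).
#' @return object of class `"intensity_surface"`: `v` (nx x ny matrix of
#'   intensities, points per m^2), cell centres `xc`, `yc`, cell sizes,
#'   `window`, `bandwidth`, `n`.
#' @export
estimate_intensity <- function(points, window, bandwidth = 30, cell = 2) {
  n <- nrow(points)
  if (n < 1) abort_invalid("at least one point is required")
  check_number(bandwidth, "bandwidth", lower = 0, strict_lower = TRUE)
  w <- window[1]; h <- window[2]
  nx <- max(1L, round(w / cell)); ny <- max(1L, round(h / cell))
  cx <- w / nx; cy <- h / ny
  xc <- (seq_len(nx) - 0.5) * cx
  yc <- (seq_len(ny) - 0.5) * cy
  s <- bandwidth
  mass <- (pnorm((w - points$x) / s) - pnorm((0 - points$x) / s)) *
    (pnorm((h - points$y) / s) - pnorm((0 - points$y) / s))
  Dx <- outer(xc, points$x, function(g, p) dnorm((g - p) / s) / s)
  Dy <- outer(yc, points$y, function(g, p) dnorm((g - p) / s) / s)
  v <- Dx %*% (t(Dy) / mass)   # nx x ny
  structure(list(v = v, xc = xc, yc = yc, cellx = cx, celly = cy,
                 window = c(w, h), bandwidth = bandwidth, n = n),
            class = "intensity_surface")
}

#' Integral of an intensity surface over its window
#' @param surface an [estimate_intensity()] result.
#' @return expected point count (should match `surface$n` to ~1%).
#' @export
intensity_integral <- function(surface) {
  sum(surface$v) * surface$cellx * surface$celly
}

#' Intensity values at point locations (nearest grid cell)
#' @param surface an [estimate_intensity()] result.
#' @param x,y coordinates.
#' @return numeric vector of intensities.
#' @export
lambda_at <- function(surface, x, y) {
  i <- pmin(pmax(floor(x / surface$cellx) + 1, 1), length(surface$xc))
  j <- pmin(pmax(floor(y / surface$celly) + 1, 1), length(surface$yc))
  surface$v[cbind(i, j)]
}

#' Inhomogeneous pair correlation function
#'
#' Kernel estimate of g(r) for a point pattern in a rectangular window:
#' Epanechnikov kernel smoothing of pair distances, Ripley isotropic
#' edge-correction weights, divisor `2 pi r |W|`, each ordered pair
#' weighted by `1 / (lambda(x_i) lambda(x_j))`.  The default kernel
#' half-width follows Stoyan's rule of thumb `h = stoyan / sqrt(n/|W|)`
#' with coefficient 0.15.
#'
#' @param points data.frame with `x`, `y` (>= 2 points).
#' @param lambda intensity: an `"intensity_surface"`, a single number
#'   (homogeneous), or a vector of per-point intensities.
#' @param window `c(width, height)`.
#' @param r strictly positive, uniformly spaced distance grid (default
#'   513 values on (0, 25]).
#' @param stoyan Stoyan coefficient for the default bandwidth.
#' @param h Epanechnikov kernel half-width (overrides `stoyan`).
#' @return numeric vector g(r), same length as `r`.
#' @export
pcf_inhom <- function(points, lambda, window, r = NULL, stoyan = 0.15,
                      h = NULL) {
  n <- nrow(points)
  if (n < 2) abort_invalid("pcf requires at least 2 points")
  if (is.null(r)) r <- seq(25 / 513, 25, length.out = 513)
  if (any(r <= 0)) abort_invalid("r grid must be strictly positive")
  if (length(r) > 1 &&
      max(abs(diff(r) - (r[2] - r[1]))) > 1e-8 * (r[2] - r[1]))
    abort_invalid("r grid must be uniformly spaced")
  lam <- if (inherits(lambda, "intensity_surface"))
    lambda_at(lambda, points$x, points$y)
  else rep_len(as.numeric(lambda), n)
  if (any(!is.finite(lam)) || any(lam <= 0))
    abort_invalid("intensities must be positive at all points")
  if (is.null(h)) h <- stoyan / sqrt(n / prod(window))
  pcf_inhom_cpp(points$x, points$y, lam, 0, window[1], 0, window[2],
                r, h)
}

#' Ripley isotropic edge-correction weight
#'
#' Reciprocal of the fraction of the circle of radius `t` centred at each
#' point that lies inside the window; >= 1, equal to 1 far from the
#' boundary.
#'
#' @param x,y point coordinates.
#' @param t circle radii (recycled).
#' @param window `c(width, height)`.
#' @return numeric vector of weights.
#' @export
ripley_edge_weight <- function(x, y, t, window) {
  t <- rep_len(t, length(x))
  ripley_weight_cpp(x, y, t, 0, window[1], 0, window[2])
}

#' Simulate an inhomogeneous Poisson process from an intensity surface
#'
#' Cell-wise simulation (exact for the piecewise-constant surface):
#' Poisson counts per grid cell with mean `lambda * cell area`, points
#' uniform within their cell.
#'
#' @param surface an [estimate_intensity()] result.
#' @param seed optional seed.
#' @return data.frame with `x`, `y`.
#' @export
simulate_inhom_poisson <- function(surface, seed = NULL) {
  with_seed(seed, {
    mu <- as.numeric(surface$v) * surface$cellx * surface$celly
    cnt <- rpois(length(mu), pmax(mu, 0))
    if (sum(cnt) == 0) return(data.frame(x = numeric(0), y = numeric(0)))
    idx <- rep(seq_along(mu), cnt)
    nx <- length(surface$xc)
    i <- (idx - 1) %% nx          # row (x cell), column-major layout
    j <- (idx - 1) %/% nx         # y cell
    data.frame(x = (i + runif(length(idx))) * surface$cellx,
               y = (j + runif(length(idx))) * surface$celly)
  })
}

#' Closed-form pair correlation function of a Thomas process
#'
#' `g(r) = 1 + exp(-r^2 / (4 sigma^2)) / (4 pi sigma^2 kappa)`; used as
#' an analytic oracle for the PCF estimator.
#'
#' @param r distances (m).
#' @param kappa parent intensity per m^2.
#' @param sigma offspring SD (m).
#' @return g(r).
#' @export
thomas_pcf <- function(r, kappa, sigma) {
  1 + exp(-r^2 / (4 * sigma^2)) / (4 * pi * sigma^2 * kappa)
}

#' Monte-Carlo goodness-of-fit test of spatial randomness
#'
#' DCLF test of an observed pattern against the inhomogeneous Poisson
#' null model: the intensity surface is estimated once from the observed
#' pattern (Gaussian kernel, 30 m default bandwidth), `n_sim` null
#' patterns are simulated from it, and each pattern's summary
#' `u = sum_r (g(r) - gbar_-(r))^2 dr` integrates the squared deviation
#' of its inhomogeneous PCF from the mean PCF of the *other* patterns
#' over `r <= r_max`.  The Monte-Carlo p-value is
#' `(1 + #\{u_sim >= u_obs\}) / (n_sim + 1)` (smallest attainable p with
#' 199 simulations: 0.005).  Classification is `"aggregated"` when
#' `p <= alpha` and the mean PCF deviation is positive, `"regular"` when
#' negative, otherwise `"random"`.
#'
#' @param points data.frame with `x`, `y`.
#' @param window `c(width, height)`.
#' @param intensity null-model intensity: `NULL` (estimate a surface
#'   from `points`), a single number (homogeneous null), or an
#'   `"intensity_surface"`.  Each pattern's PCF always uses that
#'   pattern's own intensity estimate (count/area when homogeneous,
#'   otherwise its own kernel surface).
#' @param bandwidth Gaussian SD (m) for intensity estimation.
#' @param n_sim number of null simulations (default 199).
#' @param r_max upper integration limit (m; default 20, the larger
#'   quadrat size).
#' @param r distance grid (default 513 values on (0, 25]).
#' @param alpha significance level.
#' @param min_points patterns with fewer points are skipped (returns
#'   `NULL` with a message; default 25).
#' @param stoyan Stoyan coefficient for the PCF bandwidth.
#' @param seed optional seed.
#' @return object of class `"pcf_envelope"`: `r`, `g_obs`, `sim_mean`,
#'   `sim_lo`, `sim_hi` (pointwise envelope), `u_obs`, `p_value`,
#'   `classification`, `mean_deviation`, `n_points`; or `NULL` if the
#'   pattern is too small.
#' @export
gof_envelope_test <- function(points, window, intensity = NULL,
                              bandwidth = 30, n_sim = 199L, r_max = 20,
                              r = NULL, alpha = 0.05, min_points = 25L,
                              stoyan = 0.15, seed = NULL) {
  n <- nrow(points)
  if (n < min_points) {
    message("pattern with ", n, " < ", min_points, " points skipped")
    return(NULL)
  }
  if (is.null(r)) r <- seq(25 / 513, 25, length.out = 513)
  if (r_max > max(r)) abort_invalid("r_max exceeds the r grid")
  homogeneous <- is.numeric(intensity) && length(intensity) == 1L
  surface <- NULL
  if (is.null(intensity)) {
    surface <- estimate_intensity(points, window, bandwidth)
  } else if (inherits(intensity, "intensity_surface")) {
    surface <- intensity
  } else if (!homogeneous) {
    abort_invalid("intensity must be NULL, a number or a surface")
  }

  ## the observed surface (or the supplied constant) is the *simulation*
  ## intensity; each pattern's PCF uses that pattern's own intensity
  ## estimate (count/area when homogeneous, its own kernel surface
  ## otherwise), so that count fluctuations between simulations do not
  ## inflate the goodness-of-fit statistic
  lam_fun <- function(pts, is_obs) {
    if (homogeneous) return(nrow(pts) / prod(window))
    if (is_obs) surface else estimate_intensity(pts, window, bandwidth)
  }
  sim_fun <- function() {
    if (homogeneous) {
      m <- rpois(1L, intensity * prod(window))
      data.frame(x = runif(m, 0, window[1]), y = runif(m, 0, window[2]))
    } else simulate_inhom_poisson(surface)
  }

  with_seed(seed, {
    G <- matrix(NA_real_, n_sim + 1L, length(r))
    G[1L, ] <- pcf_inhom(points, lam_fun(points, TRUE), window, r,
                         stoyan = stoyan)
    for (k in seq_len(n_sim)) {
      pts <- sim_fun()
      tries <- 0L
      while (nrow(pts) < 2L && tries < 100L) {
        pts <- sim_fun(); tries <- tries + 1L
      }
      G[k + 1L, ] <- pcf_inhom(pts, lam_fun(pts, FALSE), window, r,
                               stoyan = stoyan)
    }
    sel <- r <= r_max
    dr <- r[2] - r[1]
    cs <- colSums(G[, sel, drop = FALSE])
    u <- vapply(seq_len(n_sim + 1L), function(k) {
      ref <- (cs - G[k, sel]) / n_sim
      sum((G[k, sel] - ref)^2) * dr
    }, numeric(1))
    p <- (1 + sum(u[-1L] >= u[1L])) / (n_sim + 1L)
    ref_obs <- (cs - G[1L, sel]) / n_sim
    mean_dev <- mean(G[1L, sel] - ref_obs)
    classification <- if (p <= alpha && mean_dev > 0) "aggregated"
      else if (p <= alpha && mean_dev < 0) "regular" else "random"
    structure(list(
      r = r, g_obs = G[1L, ],
      sim_mean = colMeans(G[-1L, , drop = FALSE]),
      sim_lo = apply(G[-1L, , drop = FALSE], 2, min),
      sim_hi = apply(G[-1L, , drop = FALSE], 2, max),
      u_obs = u[1L], p_value = p, classification = classification,
      mean_deviation = mean_dev, n_points = n, r_max = r_max,
      alpha = alpha), class = "pcf_envelope")
  })
}

#' Proportion of significantly aggregated species in a plot
#'
#' @param results list of `"pcf_envelope"` results (or `NULL`s for
#'   skipped species) for one plot.
#' @param alpha significance level (default 0.05).
#' @return list with `proportion` (`NA` when no species was eligible),
#'   `n_aggregated`, `n_eligible`.
#' @export
plot_aggregation_summary <- function(results, alpha = 0.05) {
  results <- Filter(Negate(is.null), results)
  n_elig <- length(results)
  if (n_elig == 0)
    return(list(proportion = NA_real_, n_aggregated = 0L,
                n_eligible = 0L))
  agg <- vapply(results, function(x)
    x$classification == "aggregated" && x$p_value <= alpha, logical(1))
  list(proportion = mean(agg), n_aggregated = sum(agg),
       n_eligible = n_elig)
}

#' Spatial-aggregation analysis for every species and plot
#'
#' Runs [gof_envelope_test()] for every species with at least
#' `min_points` individuals in a plot and summarizes the per-plot
#' proportion of significantly aggregated species.
#'
#' @param stems stem table.
#' @param plots plot metadata.
#' @param min_points minimum individuals per species (default 25).
#' @param n_sim,bandwidth,r_max,alpha,stoyan see [gof_envelope_test()].
#' @param seed master seed; per-(plot, species) sub-seeds are derived
#'   from it.
#' @return list with `species` (one row per eligible species: `plot_id`,
#'   `species`, `n_points`, `u_obs`, `p_value`, `classification`) and
#'   `plots` (per-plot `prop_aggregated`, `n_aggregated`, `n_eligible`).
#' @export
aggregation_by_plot <- function(stems, plots, min_points = 25L,
                                n_sim = 199L, bandwidth = 30,
                                r_max = 20, alpha = 0.05, stoyan = 0.15,
                                seed = 1L) {
  sp_rows <- list(); plot_rows <- list()
  for (p in seq_len(nrow(plots))) {
    pid <- plots$plot_id[p]
    window <- c(plots$width[p], plots$height[p])
    ps <- stems[stems$plot_id == pid, , drop = FALSE]
    tab <- table(ps$species)
    eligible <- names(tab)[tab >= min_points]
    results <- list()
    for (sp in eligible) {
      pts <- ps[ps$species == sp, c("x", "y")]
      res <- gof_envelope_test(pts, window, n_sim = n_sim,
                               bandwidth = bandwidth, r_max = r_max,
                               alpha = alpha, stoyan = stoyan,
                               min_points = min_points,
                               seed = derive_seed(seed, 5L, p,
                                                  which(eligible == sp)))
      results[[sp]] <- res
      if (!is.null(res))
        sp_rows[[length(sp_rows) + 1L]] <- data.frame(
          plot_id = pid, species = sp, n_points = res$n_points,
          u_obs = res$u_obs, p_value = res$p_value,
          classification = res$classification, stringsAsFactors = FALSE)
    }
    agg <- plot_aggregation_summary(results, alpha)
    plot_rows[[length(plot_rows) + 1L]] <- data.frame(
      plot_id = pid, prop_aggregated = agg$proportion,
      n_aggregated = agg$n_aggregated, n_eligible = agg$n_eligible,
      stringsAsFactors = FALSE)
  }
  species <- if (length(sp_rows)) do.call(rbind, sp_rows) else
    data.frame(plot_id = character(0), species = character(0),
               n_points = integer(0), u_obs = numeric(0),
               p_value = numeric(0), classification = character(0))
  list(species = species, plots = do.call(rbind, plot_rows))
}
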