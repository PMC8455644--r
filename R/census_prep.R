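#' Convert girth to diameter at breast height
#'
#' `DBH = GBH / pi` (both in cm); the census rule GBH >= 15 cm corresponds
#' to DBH >= 4.8 cm.
#'
#' @param gbh girth at breast height in cm (vectorized, all > 0).
#' @return DBH in cm.
#' @export
gbh_to_dbh <- function(gbh) {
  if (!is.numeric(gbh) || any(!is.finite(gbh)) || any(gbh <= 0))
    abort_invalid("gbh must be positive and finite")
  gbh / pi
}

#' Adaptive adult/sapling threshold policy
#'
#' Saplings are trees with DBH below a threshold, adults at or above it.
#' The threshold starts at `thresholds[1]` (15 cm); if fewer than
#' `min_adult_fraction` (20%) of the individuals in a scope unit would be
#' adults, the next threshold is tried, falling back to the last one
#' unconditionally.  The scope unit is each species within a plot by
#' default (`"species"`), or each whole plot (`"plot"`).
#'
#' The 10 cm sapling-threshold sensitivity analysis is obtained with
#' `thresholds = c(10, 5)`.
#'
#' @param thresholds strictly decreasing DBH thresholds in cm.
#' @param min_adult_fraction minimum proportion classified as adults.
#' @param scope `"species"` (per species per plot) or `"plot"`.
#' @return an object of class `"stage_threshold_policy"`.
#' @export
stage_threshold_policy <- function(thresholds = c(15, 10, 5),
                                   min_adult_fraction = 0.2,
                                   scope = c("species", "plot")) {
  if (length(thresholds) < 1 || any(diff(thresholds) >= 0))
    abort_invalid("thresholds must be strictly decreasing")
  check_number(min_adult_fraction, "min_adult_fraction", lower = 0,
               upper = 1, strict_lower = TRUE, strict_upper = TRUE)
  structure(list(thresholds = thresholds,
                 min_adult_fraction = min_adult_fraction,
                 scope = match.arg(scope)),
            class = "stage_threshold_policy")
}

#' Classify stems into adults and saplings
#'
#' Applies a [stage_threshold_policy()] to a stem table.  A `dbh` column
#' is derived from `gbh` where absent.  Each tree's stage uses its own
#' scope unit's threshold (so heterospecific adult/sapling status later
#' reflects each species' threshold, not the focal species').
#'
#' @param stems stem data.frame with `plot_id`, `species` and `gbh`
#'   and/or `dbh` columns.
#' @param policy a [stage_threshold_policy()].
#' @return `stems` with added columns `dbh`, `stage`
#'   (`"adult"`/`"sapling"`) and `stage_threshold` (cm).
#' @export
classify_life_stage <- function(stems, policy = stage_threshold_policy()) {
  if (!inherits(policy, "stage_threshold_policy"))
    abort_invalid("policy must come from stage_threshold_policy()")
  stems <- ensure_dbh(stems)
  unit <- if (policy$scope == "species")
    interaction(stems$plot_id, stems$species, drop = TRUE)
  else factor(stems$plot_id)
  thr <- vapply(split(stems$dbh, unit), choose_threshold,
                numeric(1), policy = policy)
  stems$stage_threshold <- thr[as.character(unit)]
  stems$stage <- ifelse(stems$dbh >= stems$stage_threshold,
                        "adult", "sapling")
  stems
}

choose_threshold <- function(dbh, policy) {
  n <- length(dbh)
  if (n == 0) {
    warning("empty scope unit skipped")
    return(policy$thresholds[1])
  }
  for (t in policy$thresholds) {
    if (sum(dbh >= t) / n >= policy$min_adult_fraction) return(t)
  }
  policy$thresholds[length(policy$thresholds)]
}

ensure_dbh <- function(stems) {
  if (!("dbh" %in% names(stems))) stems$dbh <- NA_real_
  need <- !is.finite(stems$dbh)
  if (any(need)) {
    if (!("gbh" %in% names(stems)) || any(!is.finite(stems$gbh[need])))
      abort_invalid("stems without dbh must carry gbh")
    stems$dbh[need] <- gbh_to_dbh(stems$gbh[need])
  }
  stems
}

#' Bin stems into square quadrats
#'
#' Half-open binning: a stem at coordinate `c` falls in quadrat
#' `floor(c / quadrat_size)`; stems exactly on the upper plot boundary are
#' clamped into the last quadrat.  When the plot dimensions are not
#' multiples of the quadrat size, the residual strip is dropped together
#' with its stems (recorded in the `"dropped"` attribute) so that all
#' quadrats have equal area, as the recruitment model assumes.
#'
#' @param stems stem data.frame with `plot_id`, `x`, `y`.
#' @param quadrat_size quadrat side in metres (e.g. 10 or 20).
#' @param plots plot metadata with `plot_id`, `width`, `height`.
#' @return `stems` with added integer columns `qx`, `qy` and `quadrat`
#'   (zero-based row-major index); attributes `"dropped"` (stems in
#'   truncated strips) and `"quadrat_grid"` (per-plot nqx/nqy).
#' @export
assign_quadrats <- function(stems, quadrat_size, plots) {
  check_number(quadrat_size, "quadrat_size", lower = 0, strict_lower = TRUE)
  wmap <- setNames(plots$width, plots$plot_id)
  hmap <- setNames(plots$height, plots$plot_id)
  w <- wmap[stems$plot_id]; h <- hmap[stems$plot_id]
  if (any(is.na(w)))
    abort_invalid("stems reference plot_id absent from metadata")
  if (any(stems$x < 0 | stems$y < 0 | stems$x > w | stems$y > h))
    abort_invalid("stem coordinates outside plot dimensions")
  nqx <- floor(w / quadrat_size); nqy <- floor(h / quadrat_size)
  qx <- pmin(floor(stems$x / quadrat_size), nqx - 1)
  qy <- pmin(floor(stems$y / quadrat_size), nqy - 1)
  inside <- stems$x < nqx * quadrat_size & stems$y < nqy * quadrat_size
  ## boundary clamp: points exactly on the retained upper edge stay
  on_edge <- (stems$x == nqx * quadrat_size & stems$x == w) |
    (stems$y == nqy * quadrat_size & stems$y == h)
  keep <- inside | on_edge
  out <- stems[keep, , drop = FALSE]
  out$qx <- as.integer(qx[keep]); out$qy <- as.integer(qy[keep])
  out$quadrat <- out$qx + as.integer(nqx[keep]) * out$qy
  dropped <- stems[!keep, , drop = FALSE]
  if (nrow(dropped))
    message(nrow(dropped), " stems dropped from truncated edge strips")
  grid <- unique(data.frame(plot_id = plots$plot_id,
                            nqx = floor(plots$width / quadrat_size),
                            nqy = floor(plots$height / quadrat_size),
                            quadrat_size = quadrat_size))
  rownames(out) <- NULL
  structure(out, dropped = dropped, quadrat_grid = grid)
}

#' Build per-focal-species quadrat count tables
#'
#' For every species with at least one stem in a plot, returns one row per
#' quadrat of that plot (zeros included) with the four counts entering the
#' Ricker model: conspecific saplings `S` and adults `A`, heterospecific
#' adults `a` and saplings `s` (complements of the conspecific counts
#' against the quadrat totals).
#'
#' @param stems staged (see [classify_life_stage()]) and binned (see
#'   [assign_quadrats()]) stem table; its `"quadrat_grid"` attribute
#'   supplies the grid dimensions.
#' @return data.frame with columns `plot_id`, `species`, `quadrat`, `S`,
#'   `A`, `a`, `s`, `quadrat_size`.
#' @export
build_quadrat_counts <- function(stems) {
  grid <- attr(stems, "quadrat_grid")
  if (is.null(grid))
    abort_invalid("stems must come from assign_quadrats()")
  if (!("stage" %in% names(stems)))
    abort_invalid("stems must come from classify_life_stage()")
  out <- lapply(split(stems, stems$plot_id), function(ps) {
    g <- grid[grid$plot_id == ps$plot_id[1], ]
    n_quad <- g$nqx * g$nqy
    sp <- sort(unique(ps$species))
    qf <- factor(ps$quadrat, levels = 0:(n_quad - 1))
    sf <- factor(ps$species, levels = sp)
    ad <- ps$stage == "adult"
    A <- as.matrix(table(sf[ad], qf[ad]))
    S <- as.matrix(table(sf[!ad], qf[!ad]))
    tot_a <- colSums(A); tot_s <- colSums(S)
    data.frame(
      plot_id = ps$plot_id[1],
      species = rep(sp, each = n_quad),
      quadrat = rep(0:(n_quad - 1), times = length(sp)),
      S = as.integer(t(S)), A = as.integer(t(A)),
      a = as.integer(rep(tot_a, length(sp)) - t(A)),
      s = as.integer(rep(tot_s, length(sp)) - t(S)),
      quadrat_size = g$quadrat_size,
      stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Basal area per species per plot
#'
#' Basal area of a stem is `pi * (dbh / 200)^2` m^2 (DBH in cm); species
#' basal area is the sum over its stems.
#'
#' @param stems stem table with `plot_id`, `species` and `dbh` (or `gbh`).
#' @return data.frame with `plot_id`, `species`, `basal_area` (m^2) and
#'   `n_stems`.
#' @export
compute_basal_area <- function(stems) {
  stems <- ensure_dbh(stems)
  ba <- pi * (stems$dbh / 200)^2
  agg <- aggregate(cbind(basal_area = ba,
                         n_stems = rep(1, nrow(stems))),
                   by = list(plot_id = stems$plot_id,
                             species = stems$species), FUN = sum)
  agg$n_stems <- as.integer(agg$n_stems)
  agg[order(agg$plot_id, agg$species), ]
}
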