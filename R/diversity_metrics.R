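#' Species diversity indices for one community
#'
#' Richness `S` (species with abundance > 0), Shannon index
#' `H = -sum(p_i log p_i)` (natural logarithm) and Pielou's evenness
#' `e = H / log(S)`.  Evenness is undefined (`NA`) for a monoculture.
#' All censused stems enter the computation — diversity is not restricted
#' to the CNDD-filtered species subset.
#'
#' @param abundances non-negative abundance vector (one entry per
#'   species); at least one must be positive.
#' @return one-row data.frame with `S`, `H`, `e`.
#' @export
diversity_indices <- function(abundances) {
  if (!is.numeric(abundances) || any(!is.finite(abundances)) ||
      any(abundances < 0))
    abort_invalid("abundances must be finite and non-negative")
  ab <- abundances[abundances > 0]
  if (length(ab) == 0)
    abort_degenerate("all abundances are zero")
  S <- length(ab)
  H <- as.numeric(vegan::diversity(ab, index = "shannon"))
  e <- if (S >= 2) H / log(S) else NA_real_
  data.frame(S = S, H = H, e = e)
}

#' Per-plot diversity from a stem table
#'
#' @param stems stem table with `plot_id` and `species`.
#' @return data.frame with one row per plot: `plot_id`, `S`, `H`, `e`,
#'   `n_trees`.
#' @export
diversity_by_plot <- function(stems) {
  out <- lapply(split(stems$species, stems$plot_id), function(sp) {
    d <- diversity_indices(as.numeric(table(sp)))
    d$n_trees <- length(sp)
    d
  })
  res <- do.call(rbind, out)
  res$plot_id <- names(out)
  rownames(res) <- NULL
  res[, c("plot_id", "S", "H", "e", "n_trees")]
}
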