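## shared fixtures, built in code

## independent NegBin log-pmf written from the Gamma-function formula
## (oracle for the likelihood; deliberately not dnbinom)
negbin_lpmf_oracle <- function(S, mu, gamma) {
  lgamma(S + gamma) - lgamma(gamma) - lfactorial(S) +
    gamma * log(gamma / (gamma + mu)) + S * log(mu / (gamma + mu))
}

## random small quadrat-count fixture for likelihood tests
random_counts <- function(n, seed) {
  withr::with_seed(seed, data.frame(
    S = rpois(n, 2), A = rpois(n, 2) + 1L,
    a = rpois(n, 6), s = rpois(n, 8)))
}

## simulate counts for one species and fit, returning the fit row
sim_and_fit <- function(n_quad, truth, seed, adult_mean = 2) {
  withr::with_seed(seed, {
    A <- rpois(n_quad, adult_mean)
    a <- rpois(n_quad, 5)
    s <- rpois(n_quad, 5)
    S <- simulate_ricker_counts(A, a, s, truth)
    fit_ricker(data.frame(S = S, A = A, a = a, s = s))
  })
}

## minimal valid plot metadata for n plots of 100 x 100 m
toy_plots <- function(n = 1, width = 100, height = 100) {
  data.frame(plot_id = sprintf("p%02d", seq_len(n)),
             width = width, height = height,
             altitude = seq(100, 1500, length.out = n),
             temperature = seq(18, 5, length.out = n),
             precipitation = seq(2500, 1000, length.out = n),
             snow_depth = seq(0, 1, length.out = n),
             forest_type = rep(c("EB", "DB", "BC", "EC"),
                               length.out = n),
             succession = rep(c("OG", "OS", "S"), length.out = n),
             stringsAsFactors = FALSE)
}
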