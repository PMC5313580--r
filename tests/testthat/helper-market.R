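# Shared fixtures built in code.

small_config <- function(n = 5000, J = 5, seed = 1, ...) {
  market_config(n_persons = n, n_insurers = J, seed = seed, ...)
}

# Load a packaged toy panel with its adjuster columns as factors.
toy_panel <- function(which = c("6", "50")) {
  which <- match.arg(which)
  path <- system.file("extdata",
                      paste0("toy_panel_", which, ".csv"),
                      package = "riskselect")
  read_panel_csv(path)
}

# A fixed intercept-only model: every person predicted `mu`.
flat_model <- function(mu, p_share = 50, overall_mean = mu) {
  equalization_model(c("(Intercept)" = mu), character(0), list(),
                     p_share = p_share, overall_mean = overall_mean)
}

# 99% two-sided binomial tolerance for a sample share around p0.
binom_tol99 <- function(p0, n) qnorm(0.995) * sqrt(p0 * (1 - p0) / n)
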