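#' Default risk-adjuster specification
#'
#' A compact set of categorical risk adjusters mimicking the structure of
#' operational equalization models: age bands, sex, region clusters, and a
#' morbidity flag ("at least one chronic condition", population share 31.5%).
#' Each adjuster carries per-level cost multipliers on the positive-expense
#' mean and per-level multipliers on the zero-expense probability.
#'
#' The defaults are calibrated so that under the default
#' [market_config()] the population share with zero annual utilization is
#' 19.5% and mean annual expenses are 1570 currency units.
#'
#' @return A list of adjuster definitions. Each element has fields `name`,
#'   `levels`, `probs` (category probabilities, summing to 1),
#'   `cost_multipliers` (positive, one per level) and `zero_multipliers`
#'   (multiplies the baseline zero-expense probability, one per level).
#' @export
default_adjuster_spec <- function() {
  list(
    list(name = "age_band",
         levels = c("0-17", "18-34", "35-54", "55-69", "70+"),
         probs = c(0.20, 0.22, 0.28, 0.18, 0.12),
         cost_multipliers = c(0.45, 0.55, 0.80, 1.30, 2.40),
         zero_multipliers = c(1, 1, 1, 1, 1)),
    list(name = "sex",
         levels = c("M", "F"),
         probs = c(0.5, 0.5),
         cost_multipliers = c(0.90, 1.10),
         zero_multipliers = c(1, 1)),
    list(name = "region",
         levels = c("north", "east", "west", "south"),
         probs = c(0.30, 0.30, 0.25, 0.15),
         cost_multipliers = c(0.95, 1.00, 1.02, 1.08),
         zero_multipliers = c(1, 1, 1, 1)),
    list(name = "chronic",
         levels = c("no", "yes"),
         probs = c(0.685, 0.315),
         cost_multipliers = c(0.60, 3.20),
         zero_multipliers = c(1, 0.2))
  )
}

#' Market configuration for the synthetic two-year insurance market
#'
#' Bundles every parameter of the simulator: population size, insurers and
#' their market shares, the risk-adjuster mix, the unpriced health component
#' excluded from the equalization formula, the two-part expense distribution,
#' insurer efficiency multipliers, and the switching / selection mechanism.
#' The configuration is the simulator's ground truth: estimators are
#' validated by recovering quantities implied by it.
#'
#' @param n_persons Number of persons in the panel (each contributes two
#'   person-years).
#' @param n_insurers Number of insurers (default 25, the size of the Dutch
#'   market the defaults emulate).
#' @param years Ordered pair of calendar years `(t-1, t)`.
#' @param adjuster_spec List of adjuster definitions, see
#'   [default_adjuster_spec()].
#' @param unpriced_effect Mixture specification of the per-person monetary
#'   shift (currency/year) attributable to health variation *excluded* from
#'   the risk adjusters. A list with numeric vectors `share`, `mean`, `sd`
#'   (one entry per continuous mixture component); the remaining probability
#'   mass is a point mass at 0 ("fully priced" persons). Default: 18.9% of
#'   the population carries a shift of mean 826 (sd 300), so that the
#'   positive-shift group is undercompensated by roughly 670 on average.
#' @param zero_prob_base Baseline probability of zero annual expenses before
#'   per-level `zero_multipliers` are applied; in `[0, 1)`.
#' @param expense_shape List with `mean` (target population mean annual
#'   expenses, currency; default 1570) and `gamma_shape` (shape of the Gamma
#'   positive-expense part; `Inf` yields a degenerate, noiseless
#'   distribution).
#' @param efficiency_multipliers Positive factor per insurer scaling expenses
#'   incurred while enrolled there (1 = average efficiency).
#' @param market_shares Baseline market share per insurer (sums to 1).
#' @param switch_rate Annual probability of switching insurer (default 0.031,
#'   roughly 500,000 switchers in a market of 16 million).
#' @param selection_strength Per-insurer coefficient linking a person's
#'   unpriced effect to the propensity to join (and, with
#'   `exit_selection`, to leave) that insurer. Positive values attract
#'   persons with a *low* unpriced effect (overcompensated, "healthy"
#'   risks). 0 = no selection.
#' @param selection_on Per-insurer character, `"health"` (default; the
#'   logistic tilt acts on the signed standardized unpriced effect) or
#'   `"magnitude"` (the tilt acts on its absolute value, so the insurer
#'   attracts both over- and undercompensated tails simultaneously —
#'   positive and negative selection in one portfolio).
#' @param exit_selection Logical; if `TRUE` the decision to leave an insurer
#'   is also tilted by that insurer's selection coefficient (attractive
#'   persons are retained). Default `FALSE`: only the destination choice is
#'   tilted.
#' @param select_baseline Logical; if `TRUE` the year-(t-1) baseline
#'   assignment uses the same selection-tilted weights as destination
#'   choice, so selection shows up in the insurers' standing portfolios, not
#'   only in the switcher flows. Default `FALSE` (baseline follows market
#'   shares).
#' @param seed Integer RNG seed. Population, switching and expense draws use
#'   independent streams derived from it.
#'
#' @return An object of class `market_config` (a validated list).
#' @examples
#' cfg <- market_config(n_persons = 1000, n_insurers = 5, seed = 1)
#' cfg
#' @export
market_config <- function(n_persons,
                          n_insurers = 25L,
                          years = c(2008L, 2009L),
                          adjuster_spec = default_adjuster_spec(),
                          unpriced_effect = list(share = 0.189, mean = 826,
                                                 sd = 300),
                          zero_prob_base = 0.2607,
                          expense_shape = list(mean = 1570, gamma_shape = 0.8),
                          efficiency_multipliers = rep(1, n_insurers),
                          market_shares = rep(1 / n_insurers, n_insurers),
                          switch_rate = 0.031,
                          selection_strength = rep(0, n_insurers),
                          selection_on = rep("health", n_insurers),
                          exit_selection = FALSE,
                          select_baseline = FALSE,
                          seed = 1L) {
  cfg <- list(
    n_persons = as.integer(n_persons),
    n_insurers = as.integer(n_insurers),
    years = as.integer(years),
    adjuster_spec = adjuster_spec,
    unpriced_effect = lapply(unpriced_effect, as.numeric),
    zero_prob_base = as.numeric(zero_prob_base),
    expense_shape = expense_shape,
    efficiency_multipliers = as.numeric(efficiency_multipliers),
    market_shares = as.numeric(market_shares),
    switch_rate = as.numeric(switch_rate),
    selection_strength = as.numeric(selection_strength),
    selection_on = as.character(selection_on),
    exit_selection = isTRUE(exit_selection),
    select_baseline = isTRUE(select_baseline),
    seed = as.integer(seed)
  )
  class(cfg) <- "market_config"
  validate_market_config(cfg)
}

#' @rdname market_config
#' @param x A `market_config` to validate.
#' @export
validate_market_config <- function(x) {
  stopifnot(inherits(x, "market_config"))
  if (is.na(x$n_persons) || x$n_persons < 0)
    stop("`n_persons` must be a non-negative count", call. = FALSE)
  if (is.na(x$n_insurers) || x$n_insurers < 1)
    stop("`n_insurers` must be a positive count", call. = FALSE)
  if (length(x$years) != 2L || anyNA(x$years) || x$years[1] >= x$years[2])
    stop("`years` must be an ordered pair of calendar years (t-1, t)",
         call. = FALSE)
  for (adj in x$adjuster_spec) {
    need <- c("name", "levels", "probs", "cost_multipliers",
              "zero_multipliers")
    if (!all(need %in% names(adj)))
      stop("adjuster definition is missing fields: ",
           paste(setdiff(need, names(adj)), collapse = ", "), call. = FALSE)
    k <- length(adj$levels)
    if (length(adj$probs) != k || length(adj$cost_multipliers) != k ||
        length(adj$zero_multipliers) != k)
      stop("adjuster '", adj$name, "': levels, probs and multipliers must ",
           "have equal length", call. = FALSE)
    if (any(adj$probs < 0) || abs(sum(adj$probs) - 1) > 1e-8)
      stop("adjuster '", adj$name,
           "': category probabilities must be non-negative and sum to 1",
           call. = FALSE)
    if (any(adj$cost_multipliers <= 0))
      stop("adjuster '", adj$name, "': cost multipliers must be positive",
           call. = FALSE)
  }
  up <- x$unpriced_effect
  if (!all(c("share", "mean", "sd") %in% names(up)))
    stop("`unpriced_effect` needs fields share, mean, sd", call. = FALSE)
  if (length(unique(lengths(up[c("share", "mean", "sd")]))) != 1L)
    stop("`unpriced_effect` share/mean/sd must have equal length",
         call. = FALSE)
  if (any(up$share < 0) || sum(up$share) > 1 + 1e-8)
    stop("`unpriced_effect` component shares must be non-negative and sum ",
         "to at most 1", call. = FALSE)
  if (any(up$sd < 0))
    stop("`unpriced_effect` component sds must be non-negative",
         call. = FALSE)
  if (x$zero_prob_base < 0 || x$zero_prob_base >= 1)
    stop("`zero_prob_base` must lie in [0, 1)", call. = FALSE)
  es <- x$expense_shape
  if (!is.numeric(es$mean) || es$mean <= 0)
    stop("`expense_shape$mean` must be positive", call. = FALSE)
  if (!is.numeric(es$gamma_shape) || es$gamma_shape <= 0)
    stop("`expense_shape$gamma_shape` must be positive (Inf allowed)",
         call. = FALSE)
  if (es$mean <= sum(up$share * up$mean))
    stop("`expense_shape$mean` must exceed the mean unpriced shift",
         call. = FALSE)
  if (length(x$efficiency_multipliers) != x$n_insurers ||
      any(x$efficiency_multipliers <= 0))
    stop("`efficiency_multipliers` must be positive, one per insurer",
         call. = FALSE)
  if (length(x$market_shares) != x$n_insurers ||
      any(x$market_shares < 0) || abs(sum(x$market_shares) - 1) > 1e-8)
    stop("`market_shares` must be non-negative, one per insurer, summing ",
         "to 1", call. = FALSE)
  if (x$switch_rate < 0 || x$switch_rate > 1)
    stop("`switch_rate` must lie in [0, 1]", call. = FALSE)
  if (length(x$selection_strength) != x$n_insurers)
    stop("`selection_strength` must have one value per insurer",
         call. = FALSE)
  if (length(x$selection_on) != x$n_insurers ||
      !all(x$selection_on %in% c("health", "magnitude")))
    stop("`selection_on` must be 'health' or 'magnitude', one per insurer",
         call. = FALSE)
  x
}

#' @export
print.market_config <- function(x, ...) {
  cat("Synthetic market configuration\n")
  cat(sprintf("  persons: %d   insurers: %d   years: %d/%d\n",
              x$n_persons, x$n_insurers, x$years[1], x$years[2]))
  cat(sprintf("  adjusters: %s\n",
              paste(vapply(x$adjuster_spec, `[[`, "", "name"),
                    collapse = ", ")))
  cat(sprintf("  mean expenses %.0f, gamma shape %s, zero prob base %.3f\n",
              x$expense_shape$mean,
              format(x$expense_shape$gamma_shape),
              x$zero_prob_base))
  cat(sprintf("  switch rate %.3f; selection active for %d insurer(s)\n",
              x$switch_rate, sum(x$selection_strength != 0)))
  eff <- x$efficiency_multipliers
  cat(sprintf("  efficiency multipliers in [%.2f, %.2f]\n",
              min(eff), max(eff)))
  invisible(x)
}

# ---- internal helpers on the configuration -------------------------------

# Moments of the unpriced-effect mixture (population level, exact).
unpriced_moments <- function(config) {
  up <- config$unpriced_effect
  m1 <- sum(up$share * up$mean)
  m2 <- sum(up$share * (up$sd^2 + up$mean^2))
  v <- max(m2 - m1^2, 0)
  list(mean = m1, var = v, sd = sqrt(v),
       scale = if (v > 0) sqrt(v) else 1)
}

# Expected product of cost multipliers over the adjuster distribution.
expected_cost_multiplier <- function(config) {
  prod(vapply(config$adjuster_spec,
              function(a) sum(a$probs * a$cost_multipliers), 0))
}

# The multiplicative baseline scale chosen so that population mean annual
# expenses equal expense_shape$mean (the unpriced shift is additive on top).
baseline_scale <- function(config) {
  um <- unpriced_moments(config)
  target <- config$expense_shape$mean - um$mean
  if (target <= 0)
    stop("expense_shape$mean must exceed the mean unpriced shift",
         call. = FALSE)
  target / expected_cost_multiplier(config)
}

# Per-person baseline expected annual expenses implied by the adjusters
# (deterministic given the profiles; excludes the unpriced shift).
baseline_means <- function(profiles, config) {
  out <- rep(baseline_scale(config), nrow(profiles))
  for (adj in config$adjuster_spec) {
    idx <- match(as.character(profiles[[adj$name]]), adj$levels)
    out <- out * adj$cost_multipliers[idx]
  }
  out
}

# Per-person probability of zero annual expenses.
zero_probs <- function(profiles, config) {
  out <- rep(config$zero_prob_base, nrow(profiles))
  for (adj in config$adjuster_spec) {
    idx <- match(as.character(profiles[[adj$name]]), adj$levels)
    out <- out * adj$zero_multipliers[idx]
  }
  pmin(out, 1 - 1e-12)
}

# Three independent sub-seeds (population, switching, expenses) derived from
# the configuration seed, so that changing one simulation block leaves the
# draws of the others bit-identical.
stage_seeds <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, 3L)
  list(population = s[1], switching = s[2], expenses = s[3])
}
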