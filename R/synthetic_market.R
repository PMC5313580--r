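#' Generate the person-level population
#'
#' Draws `n_persons` person profiles: categorical risk adjusters per the
#' configuration's adjuster specification, and the unpriced health effect
#' (a monetary shift on expected annual expenses that the equalization
#' model never sees). The unpriced effect is a mixture of a point mass at 0
#' and one or more normal components; continuous draws are truncated below
#' so that each person's implied positive-expense mean stays positive.
#'
#' Deterministic given the configuration seed; uses an RNG stream
#' independent of the switching and expense stages.
#'
#' @param config A [market_config()].
#' @return A data.frame with `person_id`, one factor column per adjuster,
#'   and `unpriced_effect`.
#' @export
generate_population <- function(config) {
  config <- validate_market_config(config)
  n <- config$n_persons
  adj_names <- vapply(config$adjuster_spec, `[[`, "", "name")
  if (n == 0L) {
    out <- data.frame(person_id = integer(0))
    for (adj in config$adjuster_spec)
      out[[adj$name]] <- factor(character(0), levels = adj$levels)
    out$unpriced_effect <- numeric(0)
    return(out)
  }
  set.seed(stage_seeds(config$seed)$population)
  out <- data.frame(person_id = seq_len(n))
  for (adj in config$adjuster_spec) {
    idx <- sample.int(length(adj$levels), n, replace = TRUE,
                      prob = adj$probs)
    out[[adj$name]] <- factor(adj$levels[idx], levels = adj$levels)
  }
  base <- baseline_means(out, config)
  up <- config$unpriced_effect
  k <- length(up$share)
  comp <- sample.int(k + 1L, n, replace = TRUE,
                     prob = c(1 - sum(up$share), up$share))
  u_unif <- runif(n)
  u <- numeric(n)
  lower <- -0.98 * base   # keep implied positive-part mean > 0
  for (j in seq_len(k)) {
    sel <- comp == j + 1L
    if (!any(sel)) next
    m <- up$mean[j]; s <- up$sd[j]
    if (s > 0) {
      pa <- pnorm((lower[sel] - m) / s)
      u[sel] <- m + s * qnorm(pa + u_unif[sel] * (1 - pa))
    } else {
      u[sel] <- pmax(m, lower[sel])
    }
  }
  out$unpriced_effect <- u
  out
}

# Logistic attraction tilt eta[i, j]: how attractive person i is to insurer
# j's selection actions. "health" acts on the signed standardized unpriced
# effect (positive strength attracts low-effect, overcompensated persons);
# "magnitude" acts on |z| centered at its population mean, attracting both
# tails at once.
selection_eta <- function(u, config) {
  n <- length(u)
  J <- config$n_insurers
  um <- unpriced_moments(config)
  z <- (u - um$mean) / um$scale
  eta <- matrix(0, n, J)
  if (all(config$selection_strength == 0)) return(eta)
  gw <- unpriced_grid(config)
  mean_abs_z <- sum(gw$w * abs((gw$u - um$mean) / um$scale))
  for (j in seq_len(J)) {
    s <- config$selection_strength[j]
    if (s == 0) next
    eta[, j] <- if (config$selection_on[j] == "magnitude")
      s * (abs(z) - mean_abs_z) else -s * z
  }
  eta
}

#' Assign insurers for both years and realize switching
#'
#' Year-(t-1) assignment follows the configured market shares (optionally
#' tilted by the selection weights when `select_baseline` is on). Each
#' person then switches with probability `switch_rate`; under
#' `exit_selection` the decision to leave is tilted by the origin insurer's
#' selection coefficient, and the destination is always drawn among the
#' *other* insurers with share-times-logistic-attraction weights. With all
#' selection strengths zero, switching is independent of the unpriced
#' effect by construction.
#'
#' @param profiles Output of [generate_population()].
#' @param config The same [market_config()].
#' @return A list with `assignments` (data.frame: `person_id`,
#'   `insurer_y1`, `insurer_y2`, `switched`) and `ground_truth` (see
#'   [ground_truth_from_assignments()]).
#' @export
assign_and_switch <- function(profiles, config) {
  config <- validate_market_config(config)
  n <- nrow(profiles)
  J <- config$n_insurers
  if (n == 0L) {
    assignments <- data.frame(person_id = integer(0),
                              insurer_y1 = integer(0),
                              insurer_y2 = integer(0),
                              switched = logical(0))
    return(list(assignments = assignments,
                ground_truth = ground_truth_from_assignments(
                  profiles, assignments, config)))
  }
  set.seed(stage_seeds(config$seed)$switching)
  u <- profiles$unpriced_effect
  no_selection <- all(config$selection_strength == 0)
  eta <- if (no_selection) NULL else selection_eta(u, config)

  # weights share_j * plogis(eta_j); rows normalized at draw time
  weight_matrix <- function(zero_col = NULL) {
    W <- matrix(rep(config$market_shares, each = n), n, J)
    if (!no_selection) W <- W * stats::plogis(eta)
    if (!is.null(zero_col)) W[cbind(seq_len(n), zero_col)] <- 0
    W
  }
  draw_from_weights <- function(W, unif) {
    for (j in 2:J) W[, j] <- W[, j] + W[, j - 1L]
    tot <- W[, J]
    dest <- rep(1L, n)
    for (j in seq_len(J - 1L))
      dest <- dest + as.integer(W[, j] < unif * tot)
    dest
  }

  u1 <- runif(n)
  insurer_y1 <- if (config$select_baseline && !no_selection) {
    draw_from_weights(weight_matrix(), u1)
  } else if (J == 1L) {
    rep(1L, n)
  } else {
    cum <- cumsum(config$market_shares)
    findInterval(u1, cum[-J]) + 1L
  }

  u_switch <- runif(n)
  if (config$exit_selection && !no_selection) {
    leave_p <- stats::plogis(stats::qlogis(config$switch_rate) -
                               eta[cbind(seq_len(n), insurer_y1)])
  } else {
    leave_p <- config$switch_rate
  }
  switched <- u_switch < leave_p

  u_dest <- runif(n)   # drawn for everyone: constant RNG consumption
  insurer_y2 <- insurer_y1
  if (any(switched) && J > 1L) {
    W <- weight_matrix(zero_col = insurer_y1)
    dest <- draw_from_weights(W, u_dest)
    insurer_y2[switched] <- dest[switched]
  }
  assignments <- data.frame(person_id = profiles$person_id,
                            insurer_y1 = insurer_y1,
                            insurer_y2 = insurer_y2,
                            switched = switched & insurer_y2 != insurer_y1)
  list(assignments = assignments,
       ground_truth = ground_truth_from_assignments(profiles, assignments,
                                                    config))
}

#' Ground truth implied by realized assignments
#'
#' Records, per insurer, the realized mean unpriced effect of its inflow
#' (persons who joined at year t) and outflow (persons who left), and the
#' implied true over/undercompensation of those flows: population mean
#' unpriced effect minus the flow's mean unpriced effect. This is the
#' recovery target for the switcher estimator.
#'
#' @param profiles,assignments,config As in [assign_and_switch()].
#' @return A data.frame of class `ground_truth` with one row per insurer
#'   and attribute `population_mean_unpriced`.
#' @export
ground_truth_from_assignments <- function(profiles, assignments, config) {
  J <- config$n_insurers
  sw <- assignments[assignments$switched, , drop = FALSE]
  u <- profiles$unpriced_effect[match(sw$person_id, profiles$person_id)]
  pop_mean_u <- if (nrow(profiles)) mean(profiles$unpriced_effect) else NA_real_
  grp_mean <- function(ids) {
    out <- rep(NA_real_, J)
    if (length(ids)) {
      s <- vapply(split(u, factor(ids, levels = seq_len(J))),
                  function(v) if (length(v)) mean(v) else NA_real_, 0)
      out <- unname(s)
    }
    out
  }
  inflow_mean <- grp_mean(sw$insurer_y2)
  outflow_mean <- grp_mean(sw$insurer_y1)
  gt <- data.frame(
    insurer_id = seq_len(J),
    efficiency = config$efficiency_multipliers,
    n_inflow = tabulate(sw$insurer_y2, J),
    inflow_mean_unpriced = inflow_mean,
    inflow_true_overcompensation = pop_mean_u - inflow_mean,
    n_outflow = tabulate(sw$insurer_y1, J),
    outflow_mean_unpriced = outflow_mean,
    outflow_true_overcompensation = pop_mean_u - outflow_mean
  )
  attr(gt, "population_mean_unpriced") <- pop_mean_u
  class(gt) <- c("ground_truth", "data.frame")
  gt
}

#' Realize annual expenses for both panel years
#'
#' Two-part expense model: zero expenses with a per-person probability
#' (baseline modulated by the adjusters' zero multipliers), otherwise a
#' Gamma draw whose conditional mean equals
#' `(baseline(adjusters) + unpriced_effect) / (1 - P(zero))`, so the
#' unconditional expected annual expenses are exactly
#' `baseline + unpriced_effect`. The enrolled insurer's efficiency
#' multiplier scales the realized positive expenses *after* the draw, so
#' changing efficiency leaves every underlying random draw bit-identical
#' (common random numbers by construction).
#'
#' @param profiles Output of [generate_population()].
#' @param assignments `assignments` component of [assign_and_switch()].
#' @param config The same [market_config()].
#' @return A `data.frame` panel, one row per person-year: `person_id`,
#'   `year`, `insurer_id`, the adjuster columns, `unpriced_effect`,
#'   `expenses`.
#' @export
realize_expenses <- function(profiles, assignments, config) {
  config <- validate_market_config(config)
  n <- nrow(profiles)
  adj_names <- vapply(config$adjuster_spec, `[[`, "", "name")
  if (n == 0L) {
    out <- data.frame(person_id = integer(0), year = integer(0),
                      insurer_id = integer(0))
    for (adj in config$adjuster_spec)
      out[[adj$name]] <- factor(character(0), levels = adj$levels)
    out$unpriced_effect <- numeric(0)
    out$expenses <- numeric(0)
    return(out)
  }
  base <- baseline_means(profiles, config)
  p0 <- zero_probs(profiles, config)
  mean_pos <- (base + profiles$unpriced_effect) / (1 - p0)
  if (any(mean_pos <= 0)) {
    bad <- sum(mean_pos <= 0)
    stop("implied positive-part mean expenses are non-positive for ", bad,
         " person(s); check adjuster cost multipliers and the unpriced ",
         "component", call. = FALSE)
  }
  shape <- config$expense_shape$gamma_shape
  set.seed(stage_seeds(config$seed)$expenses)
  one_year <- function(insurer) {
    zu <- runif(n)
    g <- if (is.finite(shape)) rgamma(n, shape = shape, rate = 1) / shape
         else rep(1, n)
    zero <- zu < p0
    exp_raw <- ifelse(zero, 0, g * mean_pos)
    exp_raw * config$efficiency_multipliers[insurer]
  }
  e1 <- one_year(assignments$insurer_y1)
  e2 <- one_year(assignments$insurer_y2)
  build_year <- function(year, insurer, expenses) {
    out <- data.frame(person_id = profiles$person_id, year = year,
                      insurer_id = insurer)
    for (a in adj_names) out[[a]] <- profiles[[a]]
    out$unpriced_effect <- profiles$unpriced_effect
    out$expenses <- expenses
    out
  }
  panel <- rbind(build_year(config$years[1], assignments$insurer_y1, e1),
                 build_year(config$years[2], assignments$insurer_y2, e2))
  rownames(panel) <- NULL
  attr(panel, "adjusters") <- adj_names
  panel
}

#' Simulate a complete two-year market panel
#'
#' Convenience wrapper chaining [generate_population()],
#' [assign_and_switch()] and [realize_expenses()].
#'
#' @param config A [market_config()].
#' @return A list with `panel`, `ground_truth`, `assignments` and `config`.
#' @examples
#' sim <- simulate_market(market_config(n_persons = 2000, n_insurers = 5,
#'                                      seed = 7))
#' head(sim$panel)
#' sim$ground_truth
#' @export
simulate_market <- function(config) {
  profiles <- generate_population(config)
  asg <- assign_and_switch(profiles, config)
  panel <- realize_expenses(profiles, asg$assignments, config)
  list(panel = panel, ground_truth = asg$ground_truth,
       assignments = asg$assignments, config = config)
}

# ---- expected switcher composition (no simulation) -----------------------

# Discrete approximation of the unpriced-effect mixture: point mass at 0
# plus a fine grid per normal component (truncation ignored; its mass is
# negligible for sensible configurations).
unpriced_grid <- function(config, points_per_component = 400L) {
  up <- config$unpriced_effect
  u <- 0; w <- 1 - sum(up$share)
  for (j in seq_along(up$share)) {
    if (up$share[j] == 0) next
    if (up$sd[j] > 0) {
      g <- seq(up$mean[j] - 8 * up$sd[j], up$mean[j] + 8 * up$sd[j],
               length.out = points_per_component)
      d <- dnorm(g, up$mean[j], up$sd[j])
      u <- c(u, g); w <- c(w, up$share[j] * d / sum(d))
    } else {
      u <- c(u, up$mean[j]); w <- c(w, up$share[j])
    }
  }
  list(u = u, w = w / sum(w))
}

#' Expected switcher-flow composition implied by a configuration
#'
#' Integrates the enrollment/switching mechanism over the unpriced-effect
#' distribution (no simulation) and returns, per insurer, the expected mean
#' unpriced effect of its inflow and the implied expected true inflow
#' overcompensation (population mean unpriced effect minus the inflow
#' mean). Used by [calibrate_selection()].
#'
#' @param config A [market_config()].
#' @return data.frame: `insurer_id`, `expected_inflow_mean_unpriced`,
#'   `expected_inflow_overcompensation`.
#' @export
expected_switcher_truth <- function(config) {
  config <- validate_market_config(config)
  J <- config$n_insurers
  gw <- unpriced_grid(config)
  G <- length(gw$u)
  eta <- selection_eta(gw$u, config)
  W <- matrix(rep(config$market_shares, each = G), G, J) *
    stats::plogis(eta)
  origin_w <- if (config$select_baseline) W else
    matrix(rep(config$market_shares, each = G), G, J)
  origin_p <- origin_w / rowSums(origin_w)
  leave_p <- if (config$exit_selection)
    stats::plogis(stats::qlogis(config$switch_rate) - eta)
  else matrix(config$switch_rate, G, J)
  # inflow weight of insurer t at grid point u:
  #   sum over origins o != t of P(origin=o) P(leave|o) W_t / sum_{k!=o} W_k
  rs <- rowSums(W)
  inflow <- matrix(0, G, J)
  for (o in seq_len(J)) {
    denom <- rs - W[, o]
    contrib <- origin_p[, o] * leave_p[, o] / denom
    inflow <- inflow + contrib * W
    inflow[, o] <- inflow[, o] - contrib * W[, o]
  }
  pop_mean <- sum(gw$w * gw$u)
  mass <- colSums(gw$w * inflow)
  mean_u <- colSums(gw$w * gw$u * inflow) / mass
  data.frame(insurer_id = seq_len(J),
             expected_inflow_mean_unpriced = mean_u,
             expected_inflow_overcompensation = pop_mean - mean_u)
}

#' Calibrate a selection strength to a target inflow overcompensation
#'
#' Solves for the selection coefficient of one insurer (holding the rest of
#' the configuration fixed) such that the expected true mean
#' overcompensation of that insurer's inflow equals `target` currency
#' units. Positive targets mean the insurer attracts overcompensated
#' (low unpriced-effect) switchers.
#'
#' @param config A [market_config()].
#' @param insurer Insurer index to calibrate.
#' @param target Target expected inflow mean overcompensation (currency).
#' @return The calibrated selection strength (numeric scalar).
#' @examples
#' cfg <- market_config(n_persons = 1000, n_insurers = 5, seed = 1)
#' s <- calibrate_selection(cfg, insurer = 1, target = 100)
#' @export
calibrate_selection <- function(config, insurer, target) {
  config <- validate_market_config(config)
  f <- function(s) {
    cfg <- config
    cfg$selection_strength[insurer] <- s
    et <- expected_switcher_truth(cfg)
    et$expected_inflow_overcompensation[insurer] - target
  }
  upper <- if (target >= 0) 100 else -100
  lo <- f(0); hi <- f(upper)
  if (sign(lo - 0) == sign(hi - 0) && abs(hi) > 1e-6)
    stop("target inflow overcompensation ", target,
         " is not attainable under this configuration (range limit ",
         signif(hi + target, 4), ")", call. = FALSE)
  uniroot(f, sort(c(0, upper)), tol = 1e-8)$root
}
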