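#' Named scenario presets
#'
#' Four study scenarios, each exercising one mechanism that complicates
#' the measurement of risk selection:
#'
#' * `"null-market"`: 25 equally efficient insurers, no selection. Every
#'   estimator should be near zero with roughly nominal (5%) rejection
#'   rates — the calibration benchmark.
#' * `"efficiency-bias"`: 5 insurers with efficiency multipliers 0.90,
#'   0.95, 1.00, 1.05, 1.10 and no selection. The naive per-insurer
#'   residual means flag the efficient and inefficient insurers as if they
#'   selected, while the switcher estimates stay null — the efficiency
#'   confound.
#' * `"cancel-out"`: one insurer attracts *both* over- and undercompensated
#'   tails of the unpriced-effect distribution (magnitude-mode selection,
#'   tilting its standing portfolio). The positive and negative selection
#'   effects cancel in the insurer's mean residual, so the naive estimate
#'   is near zero although each selected subgroup is strongly under- or
#'   overcompensated — the underestimation-by-cancellation mechanism.
#' * `"recovery"`: a concentrated 5-insurer market where insurer 1's
#'   destination tilt is calibrated (see [calibrate_selection()]) so that
#'   the true mean overcompensation of its inflow is +100 currency units;
#'   the switcher estimator should recover it.
#'
#' @param name One of [scenario_names()].
#' @param n_persons Panel size (default 200,000 persons).
#' @param seed RNG seed stored in the configuration.
#' @return A [market_config()] with attribute `scenario`.
#' @examples
#' cfg <- scenario_preset("efficiency-bias", n_persons = 5000, seed = 3)
#' attr(cfg, "scenario")
#' @export
scenario_preset <- function(name = scenario_names(), n_persons = 200000,
                            seed = 1L) {
  name <- match.arg(name)
  cfg <- switch(name,
    "null-market" = market_config(
      n_persons = n_persons, n_insurers = 25, seed = seed),
    "efficiency-bias" = market_config(
      n_persons = n_persons, n_insurers = 5,
      efficiency_multipliers = c(0.90, 0.95, 1.00, 1.05, 1.10),
      seed = seed),
    "cancel-out" = {
      spec <- default_adjuster_spec()
      # flatten the demographic cost gradient so the symmetric negative
      # unpriced component never implies negative expected expenses
      for (i in seq_along(spec))
        if (spec[[i]]$name != "chronic")
          spec[[i]]$cost_multipliers[] <- 1
      market_config(
        n_persons = n_persons, n_insurers = 5,
        adjuster_spec = spec,
        unpriced_effect = list(share = c(0.2, 0.2),
                               mean = c(250, -250),
                               sd = c(80, 80)),
        selection_strength = c(3, 0, 0, 0, 0),
        selection_on = c("magnitude", rep("health", 4)),
        select_baseline = TRUE,
        seed = seed)
    },
    "recovery" = {
      base <- market_config(
        n_persons = n_persons, n_insurers = 5,
        market_shares = c(0.35, 0.25, 0.20, 0.12, 0.08),
        seed = seed)
      s <- calibrate_selection(base, insurer = 1, target = 100)
      base$selection_strength[1] <- s
      base
    })
  attr(cfg, "scenario") <- name
  cfg
}

#' @rdname scenario_preset
#' @export
scenario_names <- function() {
  c("null-market", "efficiency-bias", "cancel-out", "recovery")
}

# Built-in selected-group definitions in the style of the compensation
# table: membership from year-(t-1) information, evaluated on year-t
# residual rows. Returns a named list of logical vectors aligned with
# `residuals_t`.
default_group_definitions <- function(panel, residuals_t) {
  yrs <- sort(unique(panel$year))
  p1 <- panel[panel$year == yrs[1], , drop = FALSE]
  idx <- match(residuals_t$person_id, p1$person_id)
  from_t1 <- function(x) { v <- x[idx]; v & !is.na(v) }
  groups <- list()
  if ("chronic" %in% names(p1)) {
    groups[["chronic condition (t-1)"]] <- from_t1(p1$chronic == "yes")
    groups[["no chronic condition (t-1)"]] <- from_t1(p1$chronic == "no")
  }
  groups[["no utilization (t-1)"]] <- from_t1(p1$expenses == 0)
  if ("unpriced_effect" %in% names(p1)) {
    groups[["positive unpriced effect"]] <-
      from_t1(p1$unpriced_effect > 0)
    groups[["no positive unpriced effect"]] <-
      from_t1(p1$unpriced_effect <= 0)
  }
  groups
}

#' Run the full measurement pipeline on a scenario
#'
#' Simulates the market, fits the equalization model separately per year,
#' residualizes both years, and computes every measurement: the selected-
#' group compensation table, the per-insurer switcher estimates, the naive
#' per-insurer estimates, overrepresentation indices for the positive-
#' unpriced-effect group, and the recovery report against the simulator's
#' ground truth. Fully deterministic given the scenario and seed. When
#' `out_dir` is given, every table is written as full-precision CSV (plus
#' a rendered Markdown view), the ground truth as JSON, and a run manifest
#' recording the configuration hash, seed, file paths and exclusion
#' tallies.
#'
#' @param scenario A scenario name (see [scenario_preset()]) or a
#'   [market_config()].
#' @param seed Seed overriding the configuration's.
#' @param n_persons Panel size when `scenario` is a name.
#' @param p_share Payment parameter p (percent) for the fitted models.
#' @param out_dir Output directory (created if needed), or `NULL` to skip
#'   writing.
#' @return A list: `tables` (`compensation`, `switcher`, `naive`,
#'   `overrepresentation`, `recovery`), `models` (per year),
#'   `ground_truth`, `manifest`, `config`.
#' @export
run_pipeline <- function(scenario, seed = NULL, n_persons = 200000,
                         p_share = 50, out_dir = NULL) {
  config <- if (is.character(scenario)) {
    scenario_preset(scenario, n_persons = n_persons,
                    seed = if (is.null(seed)) 1L else seed)
  } else {
    stopifnot(inherits(scenario, "market_config"))
    cfg <- scenario
    if (!is.null(seed)) cfg$seed <- as.integer(seed)
    cfg
  }
  sim <- simulate_market(config)
  panel <- sim$panel
  adjusters <- attr(panel, "adjusters")
  yrs <- config$years
  models <- lapply(yrs, function(y)
    fit_equalization_model(panel, adjusters, fit_year = y,
                           p_share = p_share))
  names(models) <- as.character(yrs)
  residuals <- do.call(rbind, lapply(seq_along(yrs), function(i)
    residualize(panel, models[[i]], target_year = yrs[i])))
  r_t <- residuals[residuals$year == yrs[2], , drop = FALSE]
  groups <- default_group_definitions(panel, r_t)
  compensation <- group_compensation_table(r_t, groups, models[[2]])
  switcher <- switcher_estimates(panel, residuals)
  naive <- naive_insurer_estimates(residuals, yrs[2])
  overrep <- do.call(rbind, lapply(seq_len(config$n_insurers), function(j)
    overrepresentation_index(panel[panel$year == yrs[2], , drop = FALSE],
                             j, function(p) p$unpriced_effect > 0)))
  recovery <- recovery_report(switcher, sim$ground_truth)
  tables <- list(compensation = compensation, switcher = switcher,
                 naive = naive, overrepresentation = overrep,
                 recovery = recovery)
  paths <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(f) file.path(out_dir, f)
    write_report_csv(compensation, fp("compensation_groups.csv"))
    write_report_csv(as.data.frame(switcher), fp("switcher_estimates.csv"))
    write_report_csv(naive, fp("naive_estimates.csv"))
    write_report_csv(overrep, fp("overrepresentation.csv"))
    write_report_csv(recovery, fp("recovery.csv"))
    write_ground_truth_json(sim$ground_truth, fp("ground_truth.json"))
    writeLines(render_table(compensation, "table2", "markdown"),
               fp("compensation_groups.md"))
    writeLines(render_table(switcher, "table4", "markdown"),
               fp("switcher_estimates.md"))
    paths <- c("compensation_groups.csv", "switcher_estimates.csv",
               "naive_estimates.csv", "overrepresentation.csv",
               "recovery.csv", "ground_truth.json",
               "compensation_groups.md", "switcher_estimates.md")
  }
  manifest <- make_manifest(config,
                            paths = paths,
                            exclusions = attr(switcher, "exclusions"))
  if (!is.null(out_dir))
    jsonlite::write_json(unclass(manifest),
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(tables = tables, models = models, ground_truth = sim$ground_truth,
       manifest = manifest, config = config)
}
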