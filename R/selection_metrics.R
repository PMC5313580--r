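#' Two-sided one-sample test of zero mean residual
#'
#' One-sample t-test of the null that the mean of a residual (or
#' overcompensation) sample is zero; for samples above 10,000 observations
#' the normal approximation is used. Degenerate samples (zero variance)
#' return p = 1 with a flag; samples with fewer than two observations are
#' marked unavailable.
#'
#' @param x Numeric sample.
#' @param normal_cutoff Sample size above which the normal approximation
#'   replaces the t reference distribution.
#' @return List with `n`, `mean`, `se`, `statistic`, `p_value`,
#'   `degenerate`, `available`.
#' @examples
#' residual_mean_test(c(-1, 1))  # t = 0, p = 1
#' @export
residual_mean_test <- function(x, normal_cutoff = 1e4) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2L)
    return(list(n = n, mean = if (n) mean(x) else NA_real_, se = NA_real_,
                statistic = NA_real_, p_value = NA_real_,
                degenerate = FALSE, available = FALSE))
  m <- mean(x)
  s2 <- stats::var(x)
  if (s2 == 0)
    return(list(n = n, mean = m, se = 0, statistic = NA_real_,
                p_value = 1, degenerate = TRUE, available = TRUE))
  se <- sqrt(s2 / n)
  stat <- m / se
  p <- if (n > normal_cutoff) 2 * stats::pnorm(-abs(stat))
       else 2 * stats::pt(-abs(stat), df = n - 1)
  list(n = n, mean = m, se = se, statistic = stat, p_value = p,
       degenerate = FALSE, available = TRUE)
}

#' Compensation statistics for a selected group
#'
#' For a caller-defined group of person-years, computes the mean
#' overcompensation (mean predicted minus mean actual; negative =
#' undercompensation), the predictive ratio (mean predicted over mean
#' actual; below 1 marks undercompensated groups), the reduction of the
#' under/overcompensation compared with no risk equalization (where every
#' prediction equals the overall mean m), and a two-sided one-sample test
#' of zero mean residual. Display conventions print the reduction with a
#' minus sign (a 75% reduction prints as "-75 %").
#'
#' @param residuals Output of [residualize()].
#' @param member Logical vector over the rows of `residuals` (or a function
#'   of `residuals` returning one) defining the group.
#' @param model The `equalization_model` used (source of `overall_mean`).
#' @param label Group label for reporting.
#' @return One-row data.frame of class `compensation_row`: `group`,
#'   `n_members`, `population_share`, `mean_actual`, `mean_predicted`,
#'   `mean_overcompensation`, `predictive_ratio`,
#'   `reduction_vs_no_equalization`, `se`, `p_value`, `sig_05`, `sig_01`.
#' @export
group_compensation <- function(residuals, member, model,
                               label = "group") {
  if (is.function(member)) member <- member(residuals)
  stopifnot(is.logical(member), length(member) == nrow(residuals))
  member <- member & !is.na(member)
  if (!any(member)) stop("empty group '", label, "'", call. = FALSE)
  g <- residuals[member, , drop = FALSE]
  mean_actual <- mean(g$actual)
  mean_pred <- mean(g$predicted)
  over <- mean_pred - mean_actual
  pr <- if (mean_actual > 0) mean_pred / mean_actual else NA_real_
  u_none <- model$overall_mean - mean_actual
  reduction <- if (abs(u_none) > 0) 1 - abs(over) / abs(u_none)
               else NA_real_
  tst <- residual_mean_test(g$residual)
  out <- data.frame(group = label,
                    n_members = nrow(g),
                    population_share = nrow(g) / nrow(residuals),
                    mean_actual = mean_actual,
                    mean_predicted = mean_pred,
                    mean_overcompensation = over,
                    predictive_ratio = pr,
                    reduction_vs_no_equalization = reduction,
                    se = tst$se,
                    p_value = tst$p_value,
                    sig_05 = isTRUE(tst$p_value < 0.05),
                    sig_01 = isTRUE(tst$p_value < 0.01))
  class(out) <- c("compensation_row", "data.frame")
  out
}

#' Compensation table over several groups
#'
#' @param residuals Output of [residualize()].
#' @param groups Named list of logical vectors or membership functions, see
#'   [group_compensation()].
#' @param model The `equalization_model` used.
#' @return A data.frame with one [group_compensation()] row per group.
#' @export
group_compensation_table <- function(residuals, groups, model) {
  stopifnot(length(groups) > 0, !is.null(names(groups)))
  out <- do.call(rbind, lapply(names(groups), function(nm)
    group_compensation(residuals, groups[[nm]], model, label = nm)))
  rownames(out) <- NULL
  out
}

#' Overrepresentation of a group within an insurer
#'
#' Ratio of the group's share within one insurer's portfolio to its share
#' in the whole population for that year, with an exact binomial test of
#' the insurer share against the population share. Values above 1 mean the
#' insurer over-represents the group.
#'
#' @param panel_year One year of the person-year panel.
#' @param insurer_id The insurer to examine.
#' @param member Logical vector over the rows of `panel_year` (or a
#'   function of it) defining the group.
#' @return One-row data.frame: `insurer_id`, `n_insurer`,
#'   `insurer_share`, `population_share`, `overrepresentation_index`,
#'   `p_value`, `sig_05`.
#' @export
overrepresentation_index <- function(panel_year, insurer_id, member) {
  if (is.function(member)) member <- member(panel_year)
  stopifnot(is.logical(member), length(member) == nrow(panel_year))
  in_ins <- panel_year$insurer_id == insurer_id
  n_ins <- sum(in_ins)
  if (n_ins == 0L)
    stop("insurer ", insurer_id, " has no enrollees in this year",
         call. = FALSE)
  pop_share <- mean(member)
  if (pop_share == 0)
    return(data.frame(insurer_id = insurer_id, n_insurer = n_ins,
                      insurer_share = NA_real_, population_share = 0,
                      overrepresentation_index = NA_real_,
                      p_value = NA_real_, sig_05 = NA))
  ins_share <- mean(member[in_ins])
  bt <- stats::binom.test(sum(member[in_ins]), n_ins, p = pop_share)
  data.frame(insurer_id = insurer_id, n_insurer = n_ins,
             insurer_share = ins_share, population_share = pop_share,
             overrepresentation_index = ins_share / pop_share,
             p_value = bt$p.value, sig_05 = bt$p.value < 0.05)
}

#' Naive per-insurer selection estimate (efficiency-confounded)
#'
#' Mean overcompensation over *all* enrollees of each insurer in one year,
#' with a two-sided one-sample test. This is the obvious measure of
#' selection, but it is biased: an insurer's residual expenses mix risk
#' selection with the insurer's own efficiency, so a negative mean
#' residual can reflect above-average efficiency rather than selection.
#' Use [switcher_estimates()] for the efficiency-unconfounded measure.
#'
#' @param residuals Output of [residualize()].
#' @param year Year to evaluate.
#' @return data.frame, one row per insurer: `insurer_id`, `n`,
#'   `mean_overcompensation`, `se`, `statistic`, `p_value`, `sig_05`.
#' @export
naive_insurer_estimates <- function(residuals, year) {
  rows <- residuals$year == year
  if (!any(rows)) stop("no residual rows for year ", year, call. = FALSE)
  sub <- residuals[rows, , drop = FALSE]
  ids <- sort(unique(sub$insurer_id))
  out <- do.call(rbind, lapply(ids, function(j) {
    tst <- residual_mean_test(sub$overcompensation[sub$insurer_id == j])
    data.frame(insurer_id = j, n = tst$n,
               mean_overcompensation = tst$mean, se = tst$se,
               statistic = tst$statistic, p_value = tst$p_value,
               sig_05 = isTRUE(tst$p_value < 0.05))
  }))
  rownames(out) <- NULL
  out
}

#' Identify switchers between the two panel years
#'
#' A switcher is a person present in both panel years who is enrolled with
#' a different insurer in year t than in year t-1. Persons present in only
#' one year (entrants, leavers) are excluded and tallied.
#'
#' @param panel Person-year data.frame with `person_id`, `year`,
#'   `insurer_id` covering exactly two years.
#' @return data.frame with one row per person present in both years:
#'   `person_id`, `origin` (year t-1 insurer), `destination` (year t
#'   insurer), `switched`. Attribute `exclusions` counts persons seen in
#'   one year only.
#' @export
identify_switchers <- function(panel) {
  yrs <- sort(unique(panel$year))
  if (length(yrs) != 2L)
    stop("panel must contain exactly two years, found: ",
         paste(yrs, collapse = ", "), call. = FALSE)
  if (anyDuplicated(panel[c("person_id", "year")]))
    stop("duplicate (person_id, year) rows in panel", call. = FALSE)
  y1 <- panel[panel$year == yrs[1], c("person_id", "insurer_id")]
  y2 <- panel[panel$year == yrs[2], c("person_id", "insurer_id")]
  idx <- match(y1$person_id, y2$person_id)
  both <- !is.na(idx)
  out <- data.frame(person_id = y1$person_id[both],
                    origin = y1$insurer_id[both],
                    destination = y2$insurer_id[idx[both]])
  out$switched <- out$origin != out$destination
  attr(out, "exclusions") <- c(
    only_first_year = sum(!both),
    only_second_year = sum(!y2$person_id %in% y1$person_id))
  out
}

#' Efficiency-unconfounded switcher estimates of risk selection
#'
#' For each insurer X, estimates selection from the residual expenses of
#' its switchers in the years those expenses were incurred at *other*
#' insurers: the inflow estimate is the mean year-(t-1) overcompensation
#' of persons who newly enrolled with X at year t (their expenses arose at
#' their origin insurers), and the outflow estimate is the mean year-t
#' overcompensation of persons who disenrolled from X (expenses at their
#' destination insurers). Neither quantity is touched by X's own
#' efficiency, which is what removes the efficiency confound of
#' [naive_insurer_estimates()]. Each estimate gets a standard error and a
#' two-sided one-sample test; estimates with fewer than two switchers are
#' marked unavailable.
#'
#' @param panel Two-year person-year panel.
#' @param residuals Output of [residualize()] covering both years (per-year
#'   fitted models row-bound, or one supplied model applied to both).
#' @param order_by Row ordering of the result: `"residual_desc"` (default;
#'   decreasing mean residual expenses of year-t non-switchers, so the
#'   insurer with the most overcompensated standing portfolio comes last),
#'   `"overcompensation_desc"` (the reverse), or `"insurer"` (by id).
#' @return data.frame of class `switcher_estimates`, one row per insurer:
#'   `insurer_id`, `n_inflow`, `inflow_overcompensation`, `inflow_se`,
#'   `inflow_p_value`, `inflow_sig_05`, the corresponding `outflow_*`
#'   columns, and `nonswitcher_mean_residual` (year t). Attribute
#'   `exclusions` is carried over from [identify_switchers()].
#' @export
switcher_estimates <- function(panel, residuals,
                               order_by = c("residual_desc",
                                            "overcompensation_desc",
                                            "insurer")) {
  order_by <- match.arg(order_by)
  yrs <- sort(unique(panel$year))
  if (length(yrs) != 2L)
    stop("panel must contain exactly two years", call. = FALSE)
  sw <- identify_switchers(panel)
  r1 <- residuals[residuals$year == yrs[1], , drop = FALSE]
  r2 <- residuals[residuals$year == yrs[2], , drop = FALSE]
  if (!nrow(r1) || !nrow(r2))
    stop("residuals must cover both panel years", call. = FALSE)
  movers <- sw[sw$switched, , drop = FALSE]
  oc_pre <- r1$overcompensation[match(movers$person_id, r1$person_id)]
  oc_post <- r2$overcompensation[match(movers$person_id, r2$person_id)]
  ids <- sort(unique(panel$insurer_id))
  stat_cols <- function(x) {
    tst <- residual_mean_test(x)
    if (!tst$available)
      data.frame(n = tst$n, estimate = NA_real_, se = NA_real_,
                 p_value = NA_real_, sig_05 = NA, available = FALSE)
    else
      data.frame(n = tst$n, estimate = tst$mean, se = tst$se,
                 p_value = tst$p_value,
                 sig_05 = isTRUE(tst$p_value < 0.05), available = TRUE)
  }
  nonsw_ids <- sw$person_id[!sw$switched]
  r2_nonsw <- r2[r2$person_id %in% nonsw_ids, , drop = FALSE]
  out <- do.call(rbind, lapply(ids, function(j) {
    inf <- stat_cols(oc_pre[movers$destination == j])
    outf <- stat_cols(oc_post[movers$origin == j])
    ns <- r2_nonsw$residual[r2_nonsw$insurer_id == j]
    data.frame(insurer_id = j,
               n_inflow = inf$n,
               inflow_overcompensation = inf$estimate,
               inflow_se = inf$se, inflow_p_value = inf$p_value,
               inflow_sig_05 = inf$sig_05,
               inflow_available = inf$available,
               n_outflow = outf$n,
               outflow_overcompensation = outf$estimate,
               outflow_se = outf$se, outflow_p_value = outf$p_value,
               outflow_sig_05 = outf$sig_05,
               outflow_available = outf$available,
               nonswitcher_mean_residual =
                 if (length(ns)) mean(ns) else NA_real_)
  }))
  out <- switch(order_by,
    residual_desc = out[order(-out$nonswitcher_mean_residual), ],
    overcompensation_desc = out[order(out$nonswitcher_mean_residual), ],
    insurer = out)
  rownames(out) <- NULL
  attr(out, "exclusions") <- attr(sw, "exclusions")
  class(out) <- c("switcher_estimates", "data.frame")
  out
}

#' Compare switcher estimates with simulator ground truth
#'
#' Joins the estimates with the realized ground truth of a synthetic
#' market and reports, per insurer and flow, the estimation error and
#' whether the 95% confidence interval covers the true value.
#'
#' @param estimates Output of [switcher_estimates()].
#' @param ground_truth A `ground_truth` object (or data.frame read back
#'   from its JSON form).
#' @return data.frame: per insurer, the inflow and outflow estimates,
#'   truths, errors and CI coverage flags.
#' @export
recovery_report <- function(estimates, ground_truth) {
  idx <- match(estimates$insurer_id, ground_truth$insurer_id)
  gt <- ground_truth[idx, , drop = FALSE]
  z <- stats::qnorm(0.975)
  data.frame(
    insurer_id = estimates$insurer_id,
    inflow_estimate = estimates$inflow_overcompensation,
    inflow_truth = gt$inflow_true_overcompensation,
    inflow_error = estimates$inflow_overcompensation -
      gt$inflow_true_overcompensation,
    inflow_ci_covers = abs(estimates$inflow_overcompensation -
                             gt$inflow_true_overcompensation) <=
      z * estimates$inflow_se,
    outflow_estimate = estimates$outflow_overcompensation,
    outflow_truth = gt$outflow_true_overcompensation,
    outflow_error = estimates$outflow_overcompensation -
      gt$outflow_true_overcompensation,
    outflow_ci_covers = abs(estimates$outflow_overcompensation -
                              gt$outflow_true_overcompensation) <=
      z * estimates$outflow_se)
}
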