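# Independent brute-force oracles: plain loops over rows, sharing no code
# with the package implementations. Used to pin down every estimator on
# small panels.

oracle_mean <- function(x) if (length(x)) mean(x) else NA_real_

oracle_naive <- function(residuals, year) {
  sub <- residuals[residuals$year == year, ]
  out <- NULL
  for (j in sort(unique(sub$insurer_id))) {
    oc <- c()
    for (i in seq_len(nrow(sub)))
      if (sub$insurer_id[i] == j) oc <- c(oc, sub$overcompensation[i])
    out <- rbind(out, data.frame(insurer_id = j, n = length(oc),
                                 mean_overcompensation = oracle_mean(oc)))
  }
  out
}

oracle_group <- function(residuals, member, overall_mean) {
  act <- pred <- c()
  for (i in seq_len(nrow(residuals)))
    if (member[i]) {
      act <- c(act, residuals$actual[i])
      pred <- c(pred, residuals$predicted[i])
    }
  over <- oracle_mean(pred) - oracle_mean(act)
  u_none <- overall_mean - oracle_mean(act)
  list(n = length(act),
       mean_overcompensation = over,
       predictive_ratio = oracle_mean(pred) / oracle_mean(act),
       reduction = 1 - abs(over) / abs(u_none))
}

oracle_overrep <- function(panel_year, insurer, member) {
  n_ins <- hit_ins <- n_pop <- hit_pop <- 0
  for (i in seq_len(nrow(panel_year))) {
    n_pop <- n_pop + 1
    if (member[i]) hit_pop <- hit_pop + 1
    if (panel_year$insurer_id[i] == insurer) {
      n_ins <- n_ins + 1
      if (member[i]) hit_ins <- hit_ins + 1
    }
  }
  (hit_ins / n_ins) / (hit_pop / n_pop)
}

# Switcher estimator by exhaustive enumeration: for each insurer, walk all
# persons, classify them as joiners/leavers, and average the relevant
# year's overcompensation.
oracle_switchers <- function(panel, residuals) {
  yrs <- sort(unique(panel$year))
  p1 <- panel[panel$year == yrs[1], ]
  p2 <- panel[panel$year == yrs[2], ]
  r1 <- residuals[residuals$year == yrs[1], ]
  r2 <- residuals[residuals$year == yrs[2], ]
  insurers <- sort(unique(panel$insurer_id))
  out <- NULL
  for (j in insurers) {
    inflow <- outflow <- c()
    for (pid in p1$person_id) {
      if (!pid %in% p2$person_id) next
      o <- p1$insurer_id[p1$person_id == pid]
      d <- p2$insurer_id[p2$person_id == pid]
      if (o == d) next
      if (d == j)
        inflow <- c(inflow, r1$overcompensation[r1$person_id == pid])
      if (o == j)
        outflow <- c(outflow, r2$overcompensation[r2$person_id == pid])
    }
    out <- rbind(out, data.frame(
      insurer_id = j,
      n_inflow = length(inflow),
      inflow_overcompensation =
        if (length(inflow) >= 2) oracle_mean(inflow) else NA_real_,
      n_outflow = length(outflow),
      outflow_overcompensation =
        if (length(outflow) >= 2) oracle_mean(outflow) else NA_real_))
  }
  out
}
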