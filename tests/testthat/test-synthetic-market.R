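test_that("degenerate and deterministic generation contracts hold", {
  cfg0 <- small_config(n = 0)
  pop0 <- generate_population(cfg0)
  expect_equal(nrow(pop0), 0L)
  expect_true(all(c("person_id", "chronic", "unpriced_effect") %in%
                    names(pop0)))
  sim0 <- simulate_market(cfg0)
  expect_equal(nrow(sim0$panel), 0L)

  cfg <- small_config(n = 2000, seed = 42)
  expect_identical(generate_population(cfg), generate_population(cfg))
  expect_identical(simulate_market(cfg)$panel, simulate_market(cfg)$panel)
})

test_that("population composition matches the configured mix", {
  cfg <- small_config(n = 50000, seed = 3)
  pop <- generate_population(cfg)
  expect_lt(abs(mean(pop$chronic == "yes") - 0.315),
            binom_tol99(0.315, 50000))
  # unpriced mixture: share of non-zero effects
  expect_lt(abs(mean(pop$unpriced_effect != 0) - 0.189),
            binom_tol99(0.189, 50000))
  # truncation keeps the implied positive-part mean positive
  base <- riskselect:::baseline_means(pop, cfg)
  expect_true(all(base + pop$unpriced_effect > 0))
})

test_that("switching is calibrated and independent of health when unselected", {
  n <- 200000
  cfg <- small_config(n = n, seed = 5)
  pop <- generate_population(cfg)
  asg <- assign_and_switch(pop, cfg)
  expect_lt(abs(mean(asg$assignments$switched) - 0.031),
            binom_tol99(0.031, n))
  r <- cor(asg$assignments$switched, pop$unpriced_effect)
  expect_lt(abs(r), 3 / sqrt(n))
})

test_that("positive selection strength attracts low unpriced-effect inflow", {
  cfg <- small_config(n = 50000, seed = 8,
                      selection_strength = c(8, 0, 0, 0, 0))
  pop <- generate_population(cfg)
  asg <- assign_and_switch(pop, cfg)
  gt <- asg$ground_truth
  pop_mean <- attr(gt, "population_mean_unpriced")
  inflow_ids <- asg$assignments$person_id[
    asg$assignments$switched & asg$assignments$insurer_y2 == 1]
  u_in <- pop$unpriced_effect[match(inflow_ids, pop$person_id)]
  tt <- t.test(u_in, mu = pop_mean, alternative = "less")
  expect_lt(tt$p.value, 0.01)
  expect_equal(gt$inflow_mean_unpriced[1], mean(u_in))
})

test_that("ground truth equals direct recomputation from the panel", {
  cfg <- small_config(n = 20000, seed = 13,
                      selection_strength = c(2, 0, 0, 0, -1))
  sim <- simulate_market(cfg)
  sw <- identify_switchers(sim$panel)
  movers <- sw[sw$switched, ]
  p1 <- sim$panel[sim$panel$year == 2008, ]
  u <- p1$unpriced_effect[match(movers$person_id, p1$person_id)]
  gt <- sim$ground_truth
  for (j in seq_len(cfg$n_insurers)) {
    expect_equal(gt$inflow_mean_unpriced[j],
                 mean(u[movers$destination == j]))
    expect_equal(gt$outflow_mean_unpriced[j],
                 mean(u[movers$origin == j]))
    expect_equal(gt$inflow_true_overcompensation[j],
                 mean(p1$unpriced_effect) - gt$inflow_mean_unpriced[j])
  }
})

test_that("null selection leaves realized flow composition centred", {
  # with selection off, per-insurer inflow/outflow mean unpriced effect
  # should sit within 4 standard errors of the population mean
  reps <- 12
  within <- total <- 0
  for (r in seq_len(reps)) {
    cfg <- small_config(n = 20000, seed = 1000 + r)
    sim_gt <- assign_and_switch(generate_population(cfg), cfg)$ground_truth
    pop_mean <- attr(sim_gt, "population_mean_unpriced")
    um <- riskselect:::unpriced_moments(cfg)
    for (j in seq_len(cfg$n_insurers)) {
      se <- um$sd / sqrt(sim_gt$n_inflow[j])
      total <- total + 1
      if (abs(sim_gt$inflow_mean_unpriced[j] - pop_mean) <= 4 * se)
        within <- within + 1
    }
  }
  expect_gte(within / total, 0.95)
})

test_that("expense model hits its calibration targets", {
  cfg <- small_config(n = 100000, seed = 21)
  sim <- simulate_market(cfg)
  p <- sim$panel
  expect_lt(abs(mean(p$expenses == 0) - 0.195), binom_tol99(0.195, 200000))
  expect_lt(abs(mean(p$expenses) - 1570) / 1570, 0.02)
  expect_true(all(p$expenses >= 0))
})

test_that("zero-dispersion expenses equal each person's expectation", {
  spec <- default_adjuster_spec()
  for (i in seq_along(spec)) spec[[i]]$zero_multipliers[] <- 1
  cfg <- small_config(n = 500, seed = 2, adjuster_spec = spec,
                      zero_prob_base = 0,
                      expense_shape = list(mean = 1570, gamma_shape = Inf))
  pop <- generate_population(cfg)
  sim <- simulate_market(cfg)
  expected <- riskselect:::baseline_means(pop, cfg) + pop$unpriced_effect
  y1 <- sim$panel[sim$panel$year == 2008, ]
  expect_equal(y1$expenses[order(y1$person_id)], expected,
               tolerance = 1e-12)
})

test_that("a negative implied expense mean is a configuration error", {
  cfg <- small_config(n = 50, seed = 1)
  pop <- generate_population(cfg)
  pop$unpriced_effect <- -1e6   # externally supplied, bypasses truncation
  asg <- assign_and_switch(pop, cfg)
  expect_error(realize_expenses(pop, asg$assignments, cfg),
               "non-positive")
})

test_that("efficiency acts post-draw: common random numbers are exact", {
  cfg1 <- small_config(n = 20000, seed = 31)
  cfg2 <- cfg1
  cfg2$efficiency_multipliers[3] <- 0.9
  s1 <- simulate_market(cfg1)
  s2 <- simulate_market(cfg2)
  # population and assignments identical
  expect_identical(s1$assignments, s2$assignments)
  # unaffected insurer-years bit-identical
  other <- s1$panel$insurer_id != 3
  expect_identical(s1$panel$expenses[other], s2$panel$expenses[other])
  # affected expenses scale exactly by the multiplier
  aff <- !other
  expect_equal(s2$panel$expenses[aff], 0.9 * s1$panel$expenses[aff],
               tolerance = 1e-12)
})

test_that("changing the switching block leaves population and expense draws", {
  cfg1 <- small_config(n = 5000, seed = 17)
  cfg2 <- cfg1
  cfg2$switch_rate <- 0.5
  expect_identical(generate_population(cfg1), generate_population(cfg2))
  # expenses at identical assignments are bit-identical: compare persons
  # whose insurer happens to agree in both runs
  s1 <- simulate_market(cfg1)
  s2 <- simulate_market(cfg2)
  same <- s1$panel$insurer_id == s2$panel$insurer_id
  expect_gt(mean(same), 0.4)
  expect_identical(s1$panel$expenses[same], s2$panel$expenses[same])
})

test_that("expected flow composition integrates to the simulated truth", {
  cfg <- small_config(n = 200000, seed = 91,
                      selection_strength = c(2, 0, 0, 0, 0))
  et <- expected_switcher_truth(cfg)
  # analytic expectation for untilted insurers is (near) zero
  expect_equal(et$expected_inflow_overcompensation[1] > 50, TRUE)
  sim_gt <- assign_and_switch(generate_population(cfg), cfg)$ground_truth
  um <- riskselect:::unpriced_moments(cfg)
  se1 <- um$sd / sqrt(sim_gt$n_inflow[1])
  expect_lt(abs(sim_gt$inflow_true_overcompensation[1] -
                  et$expected_inflow_overcompensation[1]), 4 * se1)
})

test_that("calibration solves the inverse problem it claims to", {
  cfg <- small_config(n = 1000, seed = 1)
  s <- calibrate_selection(cfg, insurer = 2, target = 80)
  cfg$selection_strength[2] <- s
  et <- expected_switcher_truth(cfg)
  expect_equal(et$expected_inflow_overcompensation[2], 80,
               tolerance = 1e-4)
  expect_error(calibrate_selection(cfg, insurer = 1, target = 1e5),
               "not attainable")
})
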