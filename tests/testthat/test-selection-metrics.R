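test_that("the one-sample mean test handles edge cases and stays calibrated", {
  t0 <- residual_mean_test(c(-1, 1))
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1)
  td <- residual_mean_test(rep(0, 5))
  expect_true(td$degenerate)
  expect_equal(td$p_value, 1)
  t1 <- residual_mean_test(7)
  expect_false(t1$available)

  # size under a heavy-tailed null: centered gamma draws
  set.seed(314)
  reps <- 2000; n <- 5000
  rejections <- 0
  for (b in seq_len(4)) {
    x <- matrix(rgamma(n * reps / 4, shape = 0.8) - 0.8, n)
    m <- colMeans(x)
    se <- sqrt(apply(x, 2, var) / n)
    rejections <- rejections + sum(2 * pt(-abs(m / se), n - 1) < 0.05)
  }
  expect_gte(rejections / reps, 0.03)
  expect_lte(rejections / reps, 0.07)
})

test_that("group compensation arithmetic and identities are exact", {
  res <- data.frame(person_id = 1:4, year = 2009, insurer_id = 1,
                    actual = c(900, 1100, 500, 700),
                    predicted = c(800, 900, 600, 500))
  res$residual <- res$actual - res$predicted
  res$overcompensation <- -res$residual
  m <- flat_model(1000, overall_mean = 1000)
  row <- group_compensation(res, rep(TRUE, 4), m, "all")
  expect_equal(row$mean_overcompensation, -100)
  expect_equal(row$predictive_ratio, 700 / 800)
  # identity: overcompensation = mean actual * (PR - 1)
  expect_equal(row$mean_overcompensation,
               row$mean_actual * (row$predictive_ratio - 1))
  # reduction example: no-equalization gap -200, model gap -100 -> 50%
  expect_equal(row$reduction_vs_no_equalization,
               1 - abs(-100) / abs(1000 - 800))
  expect_error(group_compensation(res, rep(FALSE, 4), m), "empty group")

  # hand pair: predicted 850, actual 1000
  res2 <- data.frame(person_id = 1:2, year = 2009, insurer_id = 1,
                     actual = c(950, 1050), predicted = c(800, 900))
  res2$residual <- res2$actual - res2$predicted
  res2$overcompensation <- -res2$residual
  row2 <- group_compensation(res2, rep(TRUE, 2), m)
  expect_equal(row2$mean_overcompensation, -150)
  expect_equal(row2$predictive_ratio, 0.85)
  # 75% reduction prints with the table's minus-sign convention
  u_none <- -1000; u_model <- -250
  expect_equal(1 - abs(u_model) / abs(u_none), 0.75)
})

test_that("overrepresentation index is a share ratio with a binomial test", {
  py <- data.frame(person_id = 1:100, year = 2009,
                   insurer_id = rep(1:2, each = 50))
  member <- c(rep(TRUE, 15), rep(FALSE, 35),   # insurer 1: 30%
              rep(TRUE, 5), rep(FALSE, 45))    # insurer 2: 10%
  r1 <- overrepresentation_index(py, 1, member)
  expect_equal(r1$overrepresentation_index, 0.30 / 0.20)
  expect_equal(r1$p_value,
               binom.test(15, 50, p = 0.20)$p.value)
  both <- overrepresentation_index(py, 2, rep(c(TRUE, FALSE), 50))
  expect_equal(both$overrepresentation_index, 1.0)
  none <- overrepresentation_index(py, 1, rep(FALSE, 100))
  expect_true(is.na(none$overrepresentation_index))
})

test_that("overrepresentation under random assignment is null-calibrated", {
  set.seed(99)
  n <- 100000
  py <- data.frame(person_id = seq_len(n), year = 2009,
                   insurer_id = sample.int(25, n, replace = TRUE))
  member <- runif(n) < 0.2
  rows <- do.call(rbind, lapply(1:25, function(j)
    overrepresentation_index(py, j, member)))
  expect_lt(max(abs(rows$overrepresentation_index - 1)), 0.15)
  expect_lte(sum(rows$sig_05), 5)   # ~5% of 25 tests, generous bound
})

test_that("naive estimates match hand arithmetic on a toy", {
  res <- data.frame(person_id = 1:4, year = 2009,
                    insurer_id = c(1, 1, 2, 2),
                    actual = 0, predicted = 0,
                    residual = c(10, -10, 30, 10))
  res$overcompensation <- -res$residual
  nv <- naive_insurer_estimates(res, 2009)
  expect_equal(nv$mean_overcompensation, c(0, -20))
})

test_that("switcher identification distinguishes movers, stayers, leavers", {
  panel <- data.frame(person_id = c(1, 2, 3, 1, 2),
                      year = c(2008, 2008, 2008, 2009, 2009),
                      insurer_id = c(1, 1, 2, 2, 1))
  sw <- identify_switchers(panel)
  expect_equal(nrow(sw), 2L)
  expect_true(sw$switched[sw$person_id == 1])
  expect_equal(sw$origin[sw$person_id == 1], 1)
  expect_equal(sw$destination[sw$person_id == 1], 2)
  expect_false(sw$switched[sw$person_id == 2])
  expect_equal(unname(attr(sw, "exclusions")["only_first_year"]), 1)
  dup <- rbind(panel, panel[1, ])
  expect_error(identify_switchers(dup), "duplicate")
  expect_error(identify_switchers(panel[panel$year == 2008, ]),
               "exactly two years")
})

test_that("all estimators equal brute-force enumeration on the toy panels", {
  for (which in c("6", "50")) {
    panel <- toy_panel(which)
    mu <- mean(panel$expenses)
    model <- flat_model(mu, overall_mean = mu)
    res <- residualize(panel, model)
    yr_t <- max(panel$year)

    # naive
    nv <- naive_insurer_estimates(res, yr_t)
    ov <- oracle_naive(res, yr_t)
    expect_identical(nv$mean_overcompensation, ov$mean_overcompensation)
    expect_equal(nv$n, ov$n)

    # group compensation on an arbitrary predicate
    r_t <- res[res$year == yr_t, ]
    member <- r_t$actual > mu
    g <- group_compensation(r_t, member, model)
    og <- oracle_group(r_t, member, mu)
    expect_identical(g$mean_overcompensation, og$mean_overcompensation)
    expect_identical(g$predictive_ratio, og$predictive_ratio)
    expect_identical(g$reduction_vs_no_equalization, og$reduction)

    # overrepresentation
    py <- panel[panel$year == yr_t, ]
    pmember <- py$expenses == 0
    if (any(pmember))
      for (j in sort(unique(py$insurer_id)))
        expect_identical(
          overrepresentation_index(py, j, pmember)$overrepresentation_index,
          oracle_overrep(py, j, pmember))

    # switcher estimates
    est <- switcher_estimates(panel, res, order_by = "insurer")
    osw <- oracle_switchers(panel, res)
    expect_equal(est$insurer_id, osw$insurer_id)
    expect_equal(est$n_inflow, osw$n_inflow)
    expect_identical(est$inflow_overcompensation,
                     osw$inflow_overcompensation)
    expect_identical(est$outflow_overcompensation,
                     osw$outflow_overcompensation)
  }
})

test_that("hand-enumerated switcher means on the 6-person panel", {
  # persons: 1 moves 1->2, 3 moves 2->1, 5 moves 1->2; 6 leaves the panel
  panel <- toy_panel("6")
  model <- flat_model(500, overall_mean = 500)
  res <- residualize(panel, model)
  est <- switcher_estimates(panel, res, order_by = "insurer")
  # insurer 2 inflow: persons 1 and 5, 2008 overcompensation 500-0, 500-900
  expect_equal(est$inflow_overcompensation[est$insurer_id == 2],
               mean(c(500, -400)))
  # insurer 1 outflow: persons 1 and 5, 2009 overcompensation 350, -200
  expect_equal(est$outflow_overcompensation[est$insurer_id == 1],
               mean(c(350, -200)))
  # insurer 1 inflow is person 3 alone -> unavailable
  expect_true(is.na(est$inflow_overcompensation[est$insurer_id == 1]))
  expect_false(est$inflow_available[est$insurer_id == 1])
  expect_equal(unname(attr(est, "exclusions")["only_first_year"]), 1)
})

test_that("stronger selection produces larger inflow estimates", {
  grid <- c(0, 1.5, 4)
  reps <- 8
  avg_abs <- sapply(grid, function(s) {
    vals <- sapply(seq_len(reps), function(r) {
      cfg <- small_config(n = 30000, seed = 7000 + r,
                          selection_strength = c(s, 0, 0, 0, 0))
      sim <- simulate_market(cfg)
      m1 <- fit_equalization_model(sim$panel,
                                   attr(sim$panel, "adjusters"), 2008)
      m2 <- fit_equalization_model(sim$panel,
                                   attr(sim$panel, "adjusters"), 2009)
      r <- rbind(residualize(sim$panel, m1, 2008),
                 residualize(sim$panel, m2, 2009))
      est <- switcher_estimates(sim$panel, r, order_by = "insurer")
      est$inflow_overcompensation[1]
    })
    mean(abs(vals))
  })
  expect_true(all(diff(avg_abs) > 0))
})
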