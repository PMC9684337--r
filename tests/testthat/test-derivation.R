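test_that("period conversion follows the constant-hazard formula", {
  # annual any-relapse recurrence of 21.9% on a quarterly cycle
  expect_equal(convert_probability_period(0.219, 0.25), 0.0599, tolerance = 5e-4)
  expect_equal(round(convert_probability_period(0.219, 0.25), 4), 0.0599)
  # frozen closed-form oracle: 1 - 0.32^0.25
  expect_equal(convert_probability_period(0.68, 0.25), 0.24787937,
               tolerance = 1e-7)
  expect_equal(convert_probability_period(0, 3), 0)
  expect_equal(convert_probability_period(1, 0.25), 1)
  expect_error(convert_probability_period(1.2, 0.25), "\\[0, 1\\]")
  expect_error(convert_probability_period(0.5, 0), "positive")
})

test_that("period conversion round-trips within 1e-12", {
  set.seed(11)
  for (i in 1:50) {
    p <- runif(1, 0, 0.999)
    f <- runif(1, 0.01, 4)
    back <- convert_probability_period(convert_probability_period(p, f), 1 / f)
    expect_equal(back, p, tolerance = 1e-12)
  }
})

test_that("relative risks calibrated from annual recurrences match the trial", {
  # 12-month depressive recurrence: 68% control vs 59% intervention
  expect_equal(round(relative_risk_from_recurrence(0.68, 0.59, 0.25), 2), 0.81)
  # 12-month (hypo)manic recurrence: 48% control vs 59% intervention
  expect_equal(round(relative_risk_from_recurrence(0.48, 0.59, 0.25), 2), 1.32)
  expect_equal(relative_risk_from_recurrence(0.37, 0.37, 0.5), 1.0)
  expect_error(relative_risk_from_recurrence(0, 0.5, 0.25), "strictly inside")
})

test_that("relapse splitting preserves the total exactly", {
  expect_equal(split_relapse_probability(0.12, 1.0),
               c(depression = 0.06, episode = 0.06))
  # frozen arithmetic oracle for the default BD-I ratio
  s <- split_relapse_probability(0.12, 4.7)
  expect_equal(unname(s), c(0.09894737, 0.02105263), tolerance = 1e-7)
  expect_equal(split_relapse_probability(0, 3), c(depression = 0, episode = 0))
  set.seed(5)
  for (i in 1:25) {
    p <- runif(1)
    r <- runif(1, 0.01, 50)
    expect_identical(sum(split_relapse_probability(p, r)), p)
  }
  expect_error(split_relapse_probability(0.1, 0), "positive")
})

test_that("exponential recovery fits reproduce published quantiles", {
  # single median: 50% still depressed at 15 weeks
  expect_equal(fit_exponential_recovery(15, 0.5), log(2) / 15,
               tolerance = 1e-12)
  # hypomania: 25% still in episode at 6 weeks; survival at cycle end
  rate <- fit_exponential_recovery(6, 0.25)
  expect_equal(survival_probability(rate, 13), 0.04960628, tolerance = 1e-7)
  # consistent exponential points give the single-point rate
  expect_equal(
    fit_exponential_recovery(c(15, 30), c(0.5, 0.25)),
    fit_exponential_recovery(15, 0.5),
    tolerance = 1e-12
  )
  expect_error(fit_exponential_recovery(numeric(0), numeric(0)), "at least one")
})

test_that("exponential fit recovers a known rate from exact points", {
  set.seed(21)
  for (i in 1:20) {
    lambda <- runif(1, 0.01, 0.3)
    t <- sort(runif(5, 1, 40))
    expect_equal(fit_exponential_recovery(t, exp(-lambda * t)), lambda,
                 tolerance = 1e-9)
  }
})

test_that("episode survival follows the exponential closed form", {
  expect_equal(survival_probability(0, 7), 1)
  expect_equal(survival_probability(log(2) / 15, 15), 0.5)
  # mania: 25% at 15 weeks, evaluated at the 13-week cycle
  expect_equal(survival_probability(log(4) / 15, 13), 0.3007563,
               tolerance = 1e-6)
})

test_that("transition matrices rebuild residuals and reject infeasible exits", {
  p <- default_parameters()
  m1 <- build_transition_matrix(p$subtypes$bd1)
  expect_equal(unname(m1["depression", ]), c(0.365, 0.561, 0.074))
  expect_row_stochastic(m1)
  m2 <- build_transition_matrix(p$subtypes$bd2)
  expect_equal(unname(m2["episode", ]), c(0.878, 0.074, 0.048))
  bad <- p$subtypes$bd1
  bad$transitions["remission", c("depression", "episode")] <- c(0.7, 0.4)
  expect_error(build_transition_matrix(bad), "remission.*> 1")
})

test_that("intervention effects scale episode entries and keep rows stochastic", {
  p <- default_parameters()
  m <- build_transition_matrix(p$subtypes$bd1)
  null_iv <- list(rr_depression = 1, rr_episode = 1, scope = "relapse_only")
  expect_equal(apply_intervention_effect(m, null_iv), m)
  # frozen arithmetic: default RRs on the BD-I remission row
  out <- apply_intervention_effect(m, p$intervention)
  expect_equal(unname(out["remission", ]), c(0.88954, 0.07614, 0.03432),
               tolerance = 1e-10)
  expect_equal(out["depression", ], m["depression", ]) # relapse-only scope
  expect_row_stochastic(out)
  # all-entries scope also scales the switch transitions
  iv_all <- p$intervention
  iv_all$scope <- "all_entries"
  out_all <- apply_intervention_effect(m, iv_all)
  expect_equal(out_all["depression", "episode"], 0.074 * 1.32)
  expect_equal(out_all["episode", "depression"], 0.074 * 0.81)
  expect_row_stochastic(out_all)
  # infeasible scaling
  iv_bad <- list(rr_depression = 12, rr_episode = 1, scope = "relapse_only")
  expect_error(apply_intervention_effect(m, iv_bad), "> 1")
})

test_that("intervention scaling preserves row-stochasticity over random cases", {
  set.seed(31)
  p <- default_parameters()
  m <- build_transition_matrix(p$subtypes$bd1)
  for (i in 1:40) {
    iv <- list(rr_depression = runif(1, 0.1, 5), rr_episode = runif(1, 0.1, 5),
               scope = sample(c("relapse_only", "all_entries"), 1))
    res <- tryCatch(apply_intervention_effect(m, iv), error = function(e) NULL)
    if (!is.null(res)) expect_row_stochastic(res)
  }
})

test_that("state death probabilities combine background mortality and MRRs", {
  mort1 <- list(mrr_all_states = 1, mrr_suicide_depression = 1,
                combination = "multiplicative")
  expect_equal(state_death_probability(0.01, "remission", mort1, 0.25),
               1 - 0.99^0.25, tolerance = 1e-12)
  mort <- default_parameters()$mortality
  # frozen closed-form oracles
  expect_equal(state_death_probability(0.01, "remission", mort, 0.25),
               0.005162551, tolerance = 1e-6)
  expect_equal(state_death_probability(0.01, "depression", mort, 0.25),
               0.04877002, tolerance = 1e-6)
  expect_equal(state_death_probability(1, "episode", mort, 0.25), 1)
  # additive-on-rate alternative is milder than multiplicative here
  mort_add <- mort
  mort_add$combination <- "additive"
  expect_lt(state_death_probability(0.01, "depression", mort_add, 0.25),
            state_death_probability(0.01, "depression", mort, 0.25))
})

test_that("death probability is monotone in each MRR and in cycle length", {
  grid <- expand.grid(mrr = c(1, 2.06, 5), suicide = c(1, 9.66, 20))
  prev <- -1
  for (m in sort(grid$mrr)) {
    q <- state_death_probability(
      0.02, "remission",
      list(mrr_all_states = m, mrr_suicide_depression = 1,
           combination = "multiplicative"), 0.25
    )
    expect_gte(q, prev)
    prev <- q
  }
  mort <- default_parameters()$mortality
  prev <- -1
  for (s in c(1, 5, 9.66, 20)) {
    mort$mrr_suicide_depression <- s
    q <- state_death_probability(0.02, "depression", mort, 0.25)
    expect_gte(q, prev)
    prev <- q
  }
  mort <- default_parameters()$mortality
  cls <- c(0.1, 0.25, 0.5, 1, 2)
  qs <- vapply(cls, function(cl) {
    state_death_probability(0.02, "episode", mort, cl)
  }, numeric(1))
  expect_true(all(diff(qs) >= 0))
})
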