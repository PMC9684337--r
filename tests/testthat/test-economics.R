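test_that("state cycle costs sum the components of the chosen perspective", {
  p <- default_parameters()
  expect_equal(
    state_cycle_cost("depression", 40, "control", 0, p$costs,
                     p$intervention, "societal"),
    10408
  )
  expect_equal(
    state_cycle_cost("depression", 40, "control", 0, p$costs,
                     p$intervention, "healthcare"),
    10408 - 3637 - 4996
  )
  # productivity losses stop at the retirement age of 67
  expect_equal(
    state_cycle_cost("depression", 70, "control", 0, p$costs,
                     p$intervention, "societal"),
    10408 - 3637
  )
  # intervention cost only inside its cost window and arm
  expect_equal(
    state_cycle_cost("remission", 40, "intervention", 0, p$costs,
                     p$intervention, "healthcare") -
      state_cycle_cost("remission", 40, "control", 0, p$costs,
                       p$intervention, "healthcare"),
    291
  )
  expect_equal(
    state_cycle_cost("remission", 40, "intervention", 1, p$costs,
                     p$intervention, "healthcare"),
    state_cycle_cost("remission", 40, "control", 1, p$costs,
                     p$intervention, "healthcare")
  )
})

test_that("healthcare costs never exceed societal costs for any arm", {
  p <- default_parameters()
  lt <- synthesize_lifetable()
  for (arm in c("control", "intervention")) {
    hc <- run_arm(p, lt, arm, perspective = "healthcare")
    soc <- run_arm(p, lt, arm, perspective = "societal")
    expect_true(all(hc$cost <= soc$cost))
    expect_true(all(hc$cost_undiscounted <= soc$cost_undiscounted))
  }
})

test_that("prevalence-weighted totals equal the weighted sum of subtypes", {
  p <- default_parameters()
  lt <- synthesize_lifetable()
  arm <- run_arm(p, lt, "control")
  for (col in c("ly", "qaly", "cost")) {
    expect_identical(
      arm[[col]][arm$subtype == "weighted"],
      0.600 * arm[[col]][arm$subtype == "bd1"] +
        0.400 * arm[[col]][arm$subtype == "bd2"]
    )
  }
})

test_that("incremental results classify dominance from the signs", {
  dominant <- incremental_results(
    tibble::tibble(cost = 9500, qaly = 10.018, ly = 14),
    tibble::tibble(cost = 10000, qaly = 10.000, ly = 14)
  )
  expect_equal(dominant$decision, "dominant")
  expect_true(is.na(dominant$icer))

  icer <- incremental_results(
    tibble::tibble(cost = 10100, qaly = 10.01, ly = 14),
    tibble::tibble(cost = 10000, qaly = 10.00, ly = 14)
  )
  expect_equal(icer$decision, "ICER")
  expect_equal(icer$icer, 10000)

  dominated <- incremental_results(
    tibble::tibble(cost = 10001, qaly = 9.99, ly = 14),
    tibble::tibble(cost = 10000, qaly = 10.00, ly = 14)
  )
  expect_equal(dominated$decision, "dominated")

  flat <- incremental_results(
    tibble::tibble(cost = 10001, qaly = 10, ly = 14),
    tibble::tibble(cost = 10000, qaly = 10, ly = 14)
  )
  expect_equal(flat$decision, "no QALY difference")
  expect_true(is.na(flat$icer))
})

test_that("the weighted ICER weights increments, not ratios", {
  inc <- tibble::tibble(delta_cost = c(-400, -600),
                        delta_qaly = c(0.019, 0.017))
  w <- weighted_icer(inc, c(0.6, 0.4))
  expect_equal(w$delta_cost, -480)
  expect_equal(w$delta_qaly, 0.0182)
  expect_equal(w$decision, "dominant")

  # counterexample where the mean of ICERs differs from the weighted ICER
  inc2 <- tibble::tibble(delta_cost = c(100, 900),
                         delta_qaly = c(0.1, 0.01))
  w2 <- weighted_icer(inc2, c(0.5, 0.5))
  ratio_of_means <- (0.5 * 100 + 0.5 * 900) / (0.5 * 0.1 + 0.5 * 0.01)
  mean_of_ratios <- mean(c(100 / 0.1, 900 / 0.01))
  expect_equal(w2$icer, ratio_of_means)
  expect_false(isTRUE(all.equal(w2$icer, mean_of_ratios)))

  # degenerate weights return one subtype exactly
  w3 <- weighted_icer(inc2, c(1, 0))
  expect_equal(w3$delta_cost, 100)
  expect_equal(w3$delta_qaly, 0.1)
  expect_error(weighted_icer(inc2, c(0.7, 0.5)), "sum to 1")
})

test_that("a zero-cost null intervention produces zero increments", {
  p <- default_parameters()
  p$intervention$rr_depression <- 1
  p$intervention$rr_episode <- 1
  p$intervention$cost_per_cycle <- 0
  res <- run_ce_analysis(p, synthesize_lifetable())
  expect_identical(res$increments$delta_cost, rep(0, 3))
  expect_identical(res$increments$delta_qaly, rep(0, 3))
})

test_that("the default analysis favors the relapse-preventing intervention", {
  res <- run_ce_analysis(default_parameters(), synthesize_lifetable())
  w <- glance(res)
  expect_gt(w$delta_qaly, 0)
  expect_lt(w$delta_cost, 0)
  expect_equal(w$decision, "dominant")
  td <- tidy(res)
  expect_setequal(unique(td$metric), c("ly", "qaly", "cost"))
  disc <- tidyr::pivot_wider(td, names_from = "discounted",
                             values_from = "value")
  expect_true(all(disc[["TRUE"]] <= disc[["FALSE"]]))
})

test_that("scenario analysis re-splits the remission exits by the given ratios", {
  p <- default_parameters()
  p$settings$horizon <- "fixed"
  p$settings$horizon_cycles <- 40L
  lt <- synthesize_lifetable()
  tab <- scenario_ratio_analysis(p, lt, ratios = list(c(6, 14)))
  expect_equal(nrow(tab), 6) # 2 scenarios x (2 subtypes + weighted)
  expect_setequal(unique(tab$scenario), c("base case", "ratio 6/14"))
  # the re-split BD-I remission exits under ratio 6 keep the 0.120 total
  split <- split_relapse_probability(0.094 + 0.026, 6)
  expect_equal(unname(split), c(0.10285714, 0.01714286), tolerance = 1e-7)
  # base-case row equals the plain analysis
  base <- run_ce_analysis(p, lt)
  expect_equal(
    tab$delta_qaly[tab$scenario == "base case" & tab$subtype == "weighted"],
    glance(base)$delta_qaly
  )
  expect_error(scenario_ratio_analysis(p, lt, ratios = list(c(0, 5))),
               "positive")
})

test_that("an extreme depression/mania ratio sends episode relapse toward zero", {
  split <- split_relapse_probability(0.12, 1e9)
  expect_lt(split[["episode"]], 1e-9)
  expect_equal(split[["depression"]], 0.12, tolerance = 1e-8)
})
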