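#' Per-cycle cost of occupying a health state
#'
#' Sums the cost components attached to a health state under the chosen
#' perspective. Productivity losses are zeroed once the cohort's age at cycle
#' start reaches the retirement age; the intervention's own cost is added in
#' the intervention arm while the cycle index is inside the intervention's
#' cost window.
#'
#' @param state One of `"remission"`, `"depression"`, `"episode"`.
#' @param age Cohort age in years at cycle start.
#' @param arm `"control"` or `"intervention"`.
#' @param cycle Cycle index (0-based).
#' @param costs The parameter set's `costs` list.
#' @param intervention The parameter set's `intervention` list.
#' @param perspective `"healthcare"` or `"societal"`.
#' @return Cost in euros for one cycle spent in `state`.
#' @examples
#' p <- default_parameters()
#' state_cycle_cost("depression", 40, "control", 0, p$costs,
#'                  p$intervention, "societal")
#' @export
state_cycle_cost <- function(state, age, arm, cycle, costs, intervention,
                             perspective) {
  state <- match.arg(state, ALIVE_STATES)
  arm <- match.arg(arm, c("control", "intervention"))
  perspective <- match.arg(perspective, c("healthcare", "societal"))
  comps <- perspective_components(costs, perspective)
  if (floor(age) >= costs$retirement_age) {
    comps <- setdiff(comps, "productivity_losses")
  }
  total <- sum(costs$components[comps, state])
  if (arm == "intervention" && cycle < intervention$cost_cycles) {
    total <- total + intervention$cost_per_cycle
  }
  total
}

# Discounted and undiscounted total cost of a trace for one arm.
value_trace_costs <- function(trace, params, arm, perspective) {
  settings <- params$settings
  eff <- effective_occupancy(trace, settings)
  n <- nrow(eff)
  ages <- trace$age[1:n]
  comps <- perspective_components(params$costs, perspective)
  base <- colSums(params$costs$components[comps, , drop = FALSE])
  prod_in <- "productivity_losses" %in% comps
  prod_cost <- if (prod_in) params$costs$components["productivity_losses", ] else rep(0, 3)
  retired <- floor(ages) >= params$costs$retirement_age
  # per-interval per-state cost: base minus productivity after retirement
  per_cycle <- matrix(base[ALIVE_STATES], nrow = n, ncol = 3, byrow = TRUE)
  if (prod_in && any(retired)) {
    per_cycle[retired, ] <- sweep(per_cycle[retired, , drop = FALSE], 2,
                                  prod_cost[ALIVE_STATES])
  }
  cost_t <- rowSums(eff[, ALIVE_STATES, drop = FALSE] * per_cycle)
  if (arm == "intervention" && params$intervention$cost_cycles > 0) {
    window <- seq_len(min(params$intervention$cost_cycles, n))
    alive <- rowSums(eff[window, ALIVE_STATES, drop = FALSE])
    cost_t[window] <- cost_t[window] + params$intervention$cost_per_cycle * alive
  }
  df <- discount_factors(n, settings$cycle_length, settings$discount_costs)
  tibble::tibble(cost = sum(cost_t * df), cost_undiscounted = sum(cost_t))
}

#' Run one arm of the model across both subtypes
#'
#' Runs the cohort trace for each subtype under the given arm, accumulates
#' life years, QALYs and costs, and appends the prevalence-weighted totals.
#'
#' @param params A `bd_parameters` object.
#' @param lifetable A `bd_lifetable`.
#' @param arm `"control"` (standard of care alone) or `"intervention"`.
#' @param perspective Cost perspective; defaults to the one in `params`.
#' @return A tibble with one row per subtype plus a `"weighted"` row and
#'   columns `arm`, `subtype`, `weight`, `ly`, `qaly`, `cost`,
#'   `ly_undiscounted`, `qaly_undiscounted`, `cost_undiscounted`.
#' @export
run_arm <- function(params, lifetable, arm = c("control", "intervention"),
                    perspective = NULL) {
  arm <- match.arg(arm)
  perspective <- perspective %||% params$settings$perspective
  iv <- if (arm == "intervention") params$intervention else NULL
  rows <- purrr::imap(params$subtypes, function(sub, tag) {
    trace <- run_cohort_trace(sub, iv, lifetable, params$settings,
                              params$mortality)
    dplyr::bind_cols(
      tibble::tibble(arm = arm, subtype = tag, weight = sub$weight),
      accumulate_outcomes(trace, sub$utilities, params$settings)[
        , c("ly", "qaly", "ly_undiscounted", "qaly_undiscounted")],
      value_trace_costs(trace, params, arm, perspective)
    )
  })
  out <- dplyr::bind_rows(rows)
  dplyr::bind_rows(out, weighted_row(out, arm = arm))
}

#' Incremental cost-effectiveness results for one comparison
#'
#' Computes incremental discounted costs and QALYs between the intervention
#' and control arms and classifies the result: `"dominant"` when the
#' intervention gains QALYs at lower cost, `"dominated"` when it loses QALYs
#' at higher cost, otherwise the incremental cost-effectiveness ratio
#' (incremental cost per QALY gained). No ratio is reported when the QALY
#' difference is zero.
#'
#' @param intervention,control One-row data frames with discounted `cost`,
#'   `qaly` and `ly` columns (as produced by [run_arm()]).
#' @return A one-row tibble with `delta_cost`, `delta_qaly`, `delta_ly`,
#'   `icer` and `decision` (`"dominant"`, `"dominated"`, `"ICER"` or
#'   `"no QALY difference"`).
#' @examples
#' incremental_results(
#'   tibble::tibble(cost = 9500, qaly = 10.018, ly = 14),
#'   tibble::tibble(cost = 10000, qaly = 10.000, ly = 14)
#' )
#' @export
incremental_results <- function(intervention, control) {
  dc <- intervention$cost - control$cost
  dq <- intervention$qaly - control$qaly
  dl <- intervention$ly - control$ly
  classify_increments(dc, dq, dl)
}

classify_increments <- function(dc, dq, dl = NA_real_) {
  if (dq == 0) {
    decision <- "no QALY difference"
    icer <- NA_real_
  } else if (dq > 0 && dc < 0) {
    decision <- "dominant"
    icer <- NA_real_
  } else if (dq < 0 && dc > 0) {
    decision <- "dominated"
    icer <- NA_real_
  } else {
    decision <- "ICER"
    icer <- dc / dq
  }
  tibble::tibble(delta_cost = dc, delta_qaly = dq, delta_ly = dl,
                 icer = icer, decision = decision)
}

#' Prevalence-weighted incremental results
#'
#' Combines per-subtype incremental costs and QALYs into a single result by
#' weighting the increments (not the ratios) by subtype prevalence, then
#' forming the ratio of the weighted increments.
#'
#' @param increments A data frame with one row per subtype and columns
#'   `delta_cost`, `delta_qaly` (and optionally `delta_ly`).
#' @param weights Prevalence weights summing to 1, one per row.
#' @return A one-row tibble as from [incremental_results()].
#' @examples
#' weighted_icer(
#'   tibble::tibble(delta_cost = c(-400, -600), delta_qaly = c(0.019, 0.017)),
#'   c(0.6, 0.4)
#' )
#' @export
weighted_icer <- function(increments, weights) {
  if (abs(sum(weights) - 1) > 1e-9) abort("weights must sum to 1")
  if (length(weights) != nrow(increments)) {
    abort("one weight per increment row is required")
  }
  dl <- if ("delta_ly" %in% names(increments)) {
    sum(increments$delta_ly * weights)
  } else {
    NA_real_
  }
  classify_increments(
    sum(increments$delta_cost * weights),
    sum(increments$delta_qaly * weights),
    dl
  )
}

#' Run the full deterministic cost-utility analysis
#'
#' Runs both arms over both subtypes, computes per-subtype and
#' prevalence-weighted incremental results, and returns them together with
#' the long-run (stationary) epidemiology implied by the control-arm
#' transition matrices.
#'
#' @param params A `bd_parameters` object.
#' @param lifetable A `bd_lifetable`; defaults to the synthetic
#'   Gompertz-Makeham table.
#' @param perspective Cost perspective; defaults to the one in `params`.
#' @return An object of class `bd_ce_result`: a list with `arms` (per-arm
#'   per-subtype totals), `increments` (per-subtype and weighted), the
#'   `perspective`, and `epidemiology` (stationary alive-state shares per
#'   subtype and weighted).
#' @examples
#' res <- run_ce_analysis(default_parameters(), synthesize_lifetable())
#' tidy(res)
#' glance(res)
#' @export
run_ce_analysis <- function(params, lifetable = synthesize_lifetable(),
                            perspective = NULL) {
  perspective <- perspective %||% params$settings$perspective
  control <- run_arm(params, lifetable, "control", perspective)
  intervention <- run_arm(params, lifetable, "intervention", perspective)
  tags <- names(params$subtypes)
  per_sub <- purrr::map(tags, function(tag) {
    incremental_results(
      intervention[intervention$subtype == tag, ],
      control[control$subtype == tag, ]
    )
  })
  weights <- vapply(params$subtypes, function(s) s$weight, numeric(1))
  increments <- dplyr::bind_rows(per_sub) |>
    dplyr::mutate(subtype = tags, .before = 1)
  weighted <- weighted_icer(increments, weights) |>
    dplyr::mutate(subtype = "weighted", .before = 1)
  structure(
    list(
      arms = dplyr::bind_rows(control, intervention),
      increments = dplyr::bind_rows(increments, weighted),
      perspective = perspective,
      epidemiology = stationary_epidemiology(params),
      settings = params$settings
    ),
    class = "bd_ce_result"
  )
}

#' Long-run epidemiology implied by the transition matrices
#'
#' Stationary alive-state distributions of each subtype's standard-of-care
#' chain and their prevalence-weighted combination: the model's long-run
#' shares of live patients in remission, depression and a mood episode.
#'
#' @param params A `bd_parameters` object.
#' @return A tibble with columns `subtype`, `remission`, `depression`,
#'   `episode`.
#' @examples
#' stationary_epidemiology(default_parameters())
#' @export
stationary_epidemiology <- function(params) {
  rows <- purrr::imap(params$subtypes, function(sub, tag) {
    pi <- steady_state(build_transition_matrix(sub))
    tibble::tibble(subtype = tag, weight = sub$weight,
                   remission = pi[["remission"]],
                   depression = pi[["depression"]],
                   episode = pi[["episode"]])
  })
  out <- dplyr::bind_rows(rows)
  dplyr::bind_rows(out, weighted_row(out))
}

# Prevalence-weighted summary row: weights each numeric column (other than
# the weight itself) by the subtype weights.
weighted_row <- function(df, ...) {
  num <- setdiff(names(df)[vapply(df, is.numeric, logical(1))], "weight")
  vals <- lapply(df[num], function(x) sum(x * df$weight))
  dplyr::bind_cols(
    tibble::tibble(..., subtype = "weighted", weight = 1),
    tibble::as_tibble(vals)
  )
}

#' Scenario analysis over the depression/mania time ratio
#'
#' Re-splits each subtype's total probability of leaving remission (held at
#' its default total) between depression and the mood-episode state according
#' to alternative depression/mania time ratios, rebuilds the transition
#' matrices, reruns both arms and reports the incremental results scenario by
#' scenario alongside the base case.
#'
#' @param params A `bd_parameters` object (the base case).
#' @param lifetable A `bd_lifetable`.
#' @param ratios A list of length-2 numeric vectors `c(bd1 = ..., bd2 = ...)`
#'   of alternative positive ratios; e.g.
#'   `list(c(6, 14), c(3.6, 38.7))`.
#' @param perspective Cost perspective; defaults to the one in `params`.
#' @return A tibble with one row per scenario and subtype (including the
#'   weighted combination) and columns `scenario`, `ratio_bd1`, `ratio_bd2`,
#'   `subtype`, `delta_cost`, `delta_qaly`, `delta_ly`, `icer`, `decision`.
#' @export
scenario_ratio_analysis <- function(params, lifetable = synthesize_lifetable(),
                                    ratios = list(c(6, 14), c(3.6, 38.7)),
                                    perspective = NULL) {
  for (r in ratios) {
    if (length(r) != 2 || any(!is.finite(r)) || any(r <= 0)) {
      abort("each scenario must give two positive ratios (BD-I, BD-II)")
    }
  }
  base_row <- function(res, label, r1, r2) {
    res$increments |>
      dplyr::mutate(scenario = label, ratio_bd1 = r1, ratio_bd2 = r2,
                    .before = 1)
  }
  base <- run_ce_analysis(params, lifetable, perspective)
  out <- list(base_row(
    base, "base case",
    params$subtypes$bd1$ratio_depression_mania,
    params$subtypes$bd2$ratio_depression_mania
  ))
  for (i in seq_along(ratios)) {
    r <- ratios[[i]]
    p <- params
    for (k in seq_along(p$subtypes)) {
      sub <- p$subtypes[[k]]
      total_exit <- sum(sub$transitions["remission", c("depression", "episode")])
      split <- split_relapse_probability(total_exit, r[[k]])
      sub$transitions["remission", "depression"] <- split[["depression"]]
      sub$transitions["remission", "episode"] <- split[["episode"]]
      sub$transitions["remission", "remission"] <- 1 - total_exit
      sub$ratio_depression_mania <- r[[k]]
      p$subtypes[[k]] <- sub
    }
    res <- run_ce_analysis(p, lifetable, perspective)
    out[[i + 1]] <- base_row(
      res, paste0("ratio ", r[[1]], "/", r[[2]]), r[[1]], r[[2]]
    )
  }
  dplyr::bind_rows(out)
}

#' @export
print.bd_ce_result <- function(x, ...) {
  cat("<bd_ce_result>  perspective:", x$perspective, "\n")
  w <- x$increments[x$increments$subtype == "weighted", ]
  cat(sprintf(
    "  weighted: delta cost %.0f EUR, delta QALY %.4f, %s%s\n",
    w$delta_cost, w$delta_qaly, w$decision,
    if (w$decision == "ICER") sprintf(" %.0f EUR/QALY", w$icer) else ""
  ))
  invisible(x)
}
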