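#' Convert a probability between time periods
#'
#' Converts an event probability observed over one period to the equivalent
#' probability over another period under a constant-hazard assumption:
#' `1 - (1 - p)^f`, where `f` is the ratio of target to source period. With
#' `f = 0.25` an annual probability becomes quarterly; the inverse conversion
#' uses `1/f`.
#'
#' @param p Probability over the source period, in \[0, 1\]. Vectorised.
#' @param fraction Positive ratio of target period to source period.
#' @return Probability over the target period.
#' @examples
#' convert_probability_period(0.219, 0.25) # annual 21.9% -> quarterly 5.99%
#' @export
convert_probability_period <- function(p, fraction) {
  if (any(p < 0 | p > 1)) abort("probability must lie in [0, 1]")
  if (any(fraction <= 0)) abort("period fraction must be positive")
  1 - (1 - p)^fraction
}

#' Relative risk on the cycle scale from period recurrence probabilities
#'
#' Converts control- and intervention-arm recurrence probabilities to the
#' model's cycle length and forms their ratio, giving the relative risk
#' applied to the corresponding transition probabilities.
#'
#' @param p_control,p_intervention Recurrence probabilities over the source
#'   period (e.g. 12-month trial recurrence rates), each in (0, 1).
#' @param fraction Ratio of cycle length to the source period (0.25 for
#'   annual rates and quarterly cycles).
#' @return The cycle-scale relative risk (intervention / control).
#' @examples
#' # 12-month depressive recurrence 68% (control) vs 59% (intervention)
#' relative_risk_from_recurrence(0.68, 0.59, 0.25)
#' @export
relative_risk_from_recurrence <- function(p_control, p_intervention, fraction) {
  if (any(p_control <= 0 | p_control >= 1) ||
      any(p_intervention <= 0 | p_intervention >= 1)) {
    abort("recurrence probabilities must lie strictly inside (0, 1)")
  }
  convert_probability_period(p_intervention, fraction) /
    convert_probability_period(p_control, fraction)
}

#' Split a total relapse probability between depression and (hypo)mania
#'
#' Distributes a per-cycle probability of leaving remission between the two
#' mood-episode destinations in proportion to the time spent in depression
#' relative to (hypo)mania.
#'
#' @param p_total Total per-cycle relapse probability, in \[0, 1\].
#' @param ratio Positive depression/mania time ratio.
#' @return Named numeric vector `c(depression = ..., episode = ...)` summing
#'   exactly to `p_total`.
#' @examples
#' split_relapse_probability(0.12, 4.7)
#' @export
split_relapse_probability <- function(p_total, ratio) {
  if (p_total < 0 || p_total > 1) abort("total probability must lie in [0, 1]")
  if (ratio <= 0) abort("depression/mania ratio must be positive")
  p_dep <- p_total * ratio / (1 + ratio)
  c(depression = p_dep, episode = p_total - p_dep)
}

#' Fit a constant episode-recovery rate to survival quantiles
#'
#' Fits an exponential time-to-recovery model to one or more published
#' survival quantiles (fraction of patients still in the episode after a
#' given number of weeks). A single point gives the closed form
#' `-log(S)/t`; several points give the least-squares slope of `-log(S)` on
#' `t` through the origin.
#'
#' @param time Weeks since episode onset (positive).
#' @param surviving Fraction still in the episode at `time`, strictly
#'   inside (0, 1). Same length as `time`.
#' @return Recovery rate per week.
#' @examples
#' fit_exponential_recovery(15, 0.5) # median depressive episode 15 weeks
#' @export
fit_exponential_recovery <- function(time, surviving) {
  if (length(time) == 0) abort("at least one survival quantile is required")
  if (length(time) != length(surviving)) {
    abort("time and surviving must have the same length")
  }
  if (any(time <= 0) || any(!is.finite(time))) abort("times must be positive and finite")
  if (any(surviving <= 0 | surviving >= 1)) {
    abort("surviving fractions must lie strictly inside (0, 1)")
  }
  y <- -log(surviving)
  sum(time * y) / sum(time^2)
}

#' Probability of remaining in an episode under a constant recovery rate
#'
#' @param rate Recovery rate per week (non-negative).
#' @param t Weeks elapsed (non-negative).
#' @return `exp(-rate * t)`.
#' @examples
#' survival_probability(log(2) / 15, 13) # still depressed at cycle end
#' @export
survival_probability <- function(rate, t) {
  if (any(rate < 0) || any(t < 0)) abort("rate and time must be non-negative")
  exp(-rate * t)
}

#' Build the alive-state transition matrix for a subtype
#'
#' Assembles the 3x3 row-stochastic matrix over (remission, depression,
#' episode) from a subtype's parameters. The residual entries — remaining in
#' remission, and returning to remission from each mood episode — are
#' recomputed as one minus the exit probabilities, so edited exit
#' probabilities always yield a stochastic matrix or an explicit
#' infeasibility error.
#'
#' @param subtype One element of `default_parameters()$subtypes` (a list with
#'   a `transitions` matrix).
#' @return A 3x3 row-stochastic matrix with dimnames over the alive states.
#' @examples
#' build_transition_matrix(default_parameters()$subtypes$bd1)
#' @export
build_transition_matrix <- function(subtype) {
  tm <- subtype$transitions
  out <- tm
  # residual destinations: diagonal for remission, return-to-remission for
  # the mood-episode rows
  exits <- list(
    remission = c("depression", "episode"),
    depression = c("depression", "episode"),
    episode = c("depression", "episode")
  )
  residual_col <- c(remission = "remission", depression = "remission",
                    episode = "remission")
  for (row in ALIVE_STATES) {
    keep <- setdiff(ALIVE_STATES, residual_col[[row]])
    s <- sum(tm[row, keep])
    if (s > 1 + 1e-9) {
      abort(paste0(
        "exit probabilities from '", row, "' sum to ",
        format(s, digits = 10), " > 1"
      ))
    }
    out[row, residual_col[[row]]] <- 1 - s
  }
  out
}

#' Apply an intervention's relative risks to a transition matrix
#'
#' Scales the probabilities of entering the mood-episode states by the
#' intervention's relative risks. Under the default `"relapse_only"` scope
#' only the relapse transitions out of remission are scaled; under
#' `"all_entries"` the switch transitions between depression and the episode
#' state are scaled too. The residual of each modified row is recomputed so
#' the row sums to 1 (remission row: remaining in remission; episode rows:
#' return to remission).
#'
#' @param matrix A 3x3 row-stochastic alive-state matrix.
#' @param intervention A list with `rr_depression`, `rr_episode` and `scope`
#'   (see `default_parameters()$intervention`).
#' @return The modified row-stochastic matrix.
#' @examples
#' m <- build_transition_matrix(default_parameters()$subtypes$bd1)
#' apply_intervention_effect(m, default_parameters()$intervention)
#' @export
apply_intervention_effect <- function(matrix, intervention) {
  rr_d <- intervention$rr_depression
  rr_e <- intervention$rr_episode
  if (rr_d <= 0 || rr_e <= 0) abort("relative risks must be positive")
  scope <- intervention$scope %||% "relapse_only"
  out <- matrix
  out["remission", "depression"] <- matrix["remission", "depression"] * rr_d
  out["remission", "episode"] <- matrix["remission", "episode"] * rr_e
  if (scope == "all_entries") {
    out["depression", "episode"] <- matrix["depression", "episode"] * rr_e
    out["episode", "depression"] <- matrix["episode", "depression"] * rr_d
  }
  exit_rem <- out["remission", "depression"] + out["remission", "episode"]
  if (exit_rem > 1 + 1e-12) {
    abort(paste0(
      "scaled exit probabilities from 'remission' sum to ",
      format(exit_rem, digits = 10), " > 1"
    ))
  }
  out["remission", "remission"] <- 1 - exit_rem
  if (scope == "all_entries") {
    for (row in c("depression", "episode")) {
      stay_and_switch <- sum(out[row, c("depression", "episode")])
      if (stay_and_switch > 1 + 1e-12) {
        abort(paste0(
          "scaled exit probabilities from '", row, "' sum to ",
          format(stay_and_switch, digits = 10), " > 1"
        ))
      }
      out[row, "remission"] <- 1 - stay_and_switch
    }
  }
  out
}

#' Per-cycle death probability for a health state
#'
#' Converts a general-population annual death probability to the rate scale,
#' multiplies by the all-state mortality rate ratio (comorbidity and
#' lifestyle excess), additionally combines the suicide mortality rate ratio
#' in the depression state (multiplicatively by default, or additively on the
#' rate scale), and converts back to a probability over one model cycle.
#'
#' @param q_annual Annual general-population death probability in \[0, 1\].
#' @param state One of `"remission"`, `"depression"`, `"episode"`.
#' @param mortality A list with `mrr_all_states`, `mrr_suicide_depression`
#'   and `combination` (`"multiplicative"` or `"additive"`).
#' @param cycle_length Cycle length in years.
#' @return Per-cycle death probability (capped at 1).
#' @examples
#' state_death_probability(0.01, "remission", default_parameters()$mortality, 0.25)
#' @export
state_death_probability <- function(q_annual, state, mortality, cycle_length) {
  if (any(q_annual < 0 | q_annual > 1)) {
    abort("annual death probability must lie in [0, 1]")
  }
  state <- match.arg(state, ALIVE_STATES)
  mrr <- mortality$mrr_all_states
  if (state == "depression") {
    mrr <- switch(mortality$combination %||% "multiplicative",
      multiplicative = mrr * mortality$mrr_suicide_depression,
      additive = mrr + mortality$mrr_suicide_depression,
      abort("unknown mortality combination rule")
    )
  }
  rate <- -log1p(-q_annual) * mrr
  q <- -expm1(-rate * cycle_length)
  pmin(q, 1)
}

#' Default treatment-intensity mix of the standard of care
#'
#' The standard of care assigns patients in each health state to treatment
#' intensity categories: outpatient low intensity, outpatient high intensity
#' and inpatient care. These weights describe how the per-state cost
#' aggregates were composed; they are applied by [blend_intensity_costs()]
#' when users supply costs per intensity category rather than per state.
#'
#' @return A tibble with columns `state`, `intensity` and `weight`; weights
#'   sum to 1 within each state.
#' @export
default_intensity_mix <- function() {
  tibble::tribble(
    ~state,        ~intensity,        ~weight,
    "remission",   "outpatient_low",  0.85,
    "remission",   "outpatient_high", 0.15,
    "depression",  "outpatient_low",  0.90,
    "depression",  "outpatient_high", 0.07,
    "depression",  "inpatient",       0.03,
    "episode",     "outpatient_low",  0.30,
    "episode",     "outpatient_high", 0.40,
    "episode",     "inpatient",       0.30
  )
}

#' Blend per-intensity costs into per-state costs
#'
#' Aggregates costs specified per treatment-intensity category into the
#' per-state amounts the model consumes, using an intensity mix such as
#' [default_intensity_mix()].
#'
#' @param unit_costs A data frame with columns `intensity` and `cost`
#'   (per-cycle euros for a patient in that category).
#' @param mix A data frame with columns `state`, `intensity`, `weight`;
#'   weights must sum to 1 within each state.
#' @return A tibble with columns `state` and `cost`.
#' @export
blend_intensity_costs <- function(unit_costs, mix = default_intensity_mix()) {
  sums <- tapply(mix$weight, mix$state, sum)
  if (any(abs(sums - 1) > 1e-9)) {
    abort("intensity weights must sum to 1 within each state")
  }
  dplyr::inner_join(mix, unit_costs, by = "intensity") |>
    dplyr::group_by(.data$state) |>
    dplyr::summarise(cost = sum(.data$weight * .data$cost), .groups = "drop")
}
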