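#' Embed per-state death probabilities into an alive-state row
#'
#' Combines a row of the alive-state transition matrix with that origin
#' state's per-cycle death probability under the competing-risk convention:
#' the death entry equals the death probability and each alive destination is
#' scaled by the survival complement, so the 4-state row sums to 1.
#'
#' @param alive_row Probability vector over the three alive states, summing
#'   to 1.
#' @param death_probability Per-cycle death probability for the origin state,
#'   in \[0, 1\].
#' @return Length-4 probability vector over (remission, depression, episode,
#'   death).
#' @examples
#' m <- build_transition_matrix(default_parameters()$subtypes$bd1)
#' embed_mortality(m["remission", ], 0.005)
#' @export
embed_mortality <- function(alive_row, death_probability) {
  if (death_probability < 0 || death_probability > 1) {
    abort("death probability must lie in [0, 1]")
  }
  c(alive_row * (1 - death_probability), death = death_probability)
}

#' Run a Markov cohort trace for one subtype and arm
#'
#' Advances the cohort's state occupancy cycle by cycle from the configured
#' start distribution and start age. Each cycle uses the intervention-scaled
#' alive matrix while the cycle index is inside the intervention's effect
#' window (`NULL` intervention means the standard-of-care arm), embeds the
#' age-specific per-state death probabilities, and moves the cohort forward.
#' A lifetime horizon runs until the cohort reaches the lifetable's terminal
#' age (where death is certain); a fixed horizon runs the configured number
#' of cycles.
#'
#' @param subtype One element of a parameter set's `subtypes` list.
#' @param intervention An intervention list (see
#'   `default_parameters()$intervention`) or `NULL` for the control arm.
#' @param lifetable A `bd_lifetable`.
#' @param settings The parameter set's `settings` list.
#' @param mortality The parameter set's `mortality` list.
#' @return A tibble of class `bd_trace` with columns `cycle`, `age`,
#'   `remission`, `depression`, `episode`, `death`; one row per cycle
#'   boundary, starting at cycle 0.
#' @examples
#' p <- default_parameters()
#' lt <- synthesize_lifetable()
#' tr <- run_cohort_trace(p$subtypes$bd1, NULL, lt, p$settings, p$mortality)
#' head(tr)
#' @export
run_cohort_trace <- function(subtype, intervention, lifetable, settings,
                             mortality) {
  cl <- settings$cycle_length
  base <- build_transition_matrix(subtype)
  has_effect <- !is.null(intervention) &&
    (intervention$effect_cycles %||% 0L) > 0L
  active <- if (has_effect) {
    apply_intervention_effect(base, intervention)
  } else {
    base
  }
  effect_cycles <- if (has_effect) intervention$effect_cycles else 0L

  n_cycles <- if (settings$horizon == "fixed") {
    as.integer(settings$horizon_cycles)
  } else {
    terminal <- max(lifetable$age)
    as.integer(ceiling((terminal + 1 - settings$start_age) / cl))
  }
  if (n_cycles < 1) abort("horizon must cover at least one cycle")

  occ <- matrix(0, nrow = n_cycles + 1, ncol = 4,
                dimnames = list(NULL, ALL_STATES))
  alive <- settings$start_state[ALIVE_STATES]
  occ[1, ] <- c(alive, 0)
  ages <- settings$start_age + (0:n_cycles) * cl
  # per-state death probability by integer age, precomputed once
  uniq_ages <- unique(floor(ages[seq_len(n_cycles)]))
  qx <- lifetable_qx(lifetable, uniq_ages)
  dmat <- vapply(ALIVE_STATES, function(s) {
    state_death_probability(qx, s, mortality, cl)
  }, numeric(length(uniq_ages)))
  if (length(uniq_ages) == 1L) dmat <- matrix(dmat, nrow = 1)
  rownames(dmat) <- as.character(uniq_ages)

  dead <- 0
  for (t in seq_len(n_cycles)) {
    d <- dmat[as.character(floor(ages[t])), ]
    P <- if (t - 1 < effect_cycles) active else base
    dead <- dead + sum(alive * d)
    alive <- as.numeric((alive * (1 - d)) %*% P)
    occ[t + 1, ] <- c(alive, dead)
  }
  out <- tibble::tibble(
    cycle = 0:n_cycles,
    age = ages,
    remission = occ[, "remission"],
    depression = occ[, "depression"],
    episode = occ[, "episode"],
    death = occ[, "death"]
  )
  tibble::new_tibble(out, class = "bd_trace",
                     subtype = subtype$label %||% NA_character_)
}

#' Stationary distribution of an alive-state transition matrix
#'
#' Solves `pi %*% P = pi` with `sum(pi) = 1` for the unique stationary
#' distribution of the 3-state chain over the alive states. Used to validate
#' the modeled epidemiology: the long-run shares of live patients in
#' remission, depression and a mood episode.
#'
#' @param matrix A 3x3 irreducible row-stochastic matrix.
#' @return Named probability vector over the alive states.
#' @examples
#' steady_state(build_transition_matrix(default_parameters()$subtypes$bd1))
#' @export
steady_state <- function(matrix) {
  n <- nrow(matrix)
  if (any(abs(rowSums(matrix) - 1) > 1e-9)) {
    abort("matrix rows must sum to 1")
  }
  A <- rbind(t(matrix) - diag(n), rep(1, n))
  pi <- tryCatch(
    qr.solve(A, c(rep(0, n), 1)),
    error = function(e) abort("stationary distribution is not unique (reducible or degenerate chain)")
  )
  if (any(pi < -1e-9)) {
    abort("stationary distribution is not unique (reducible or degenerate chain)")
  }
  setNames(pmax(pi, 0) / sum(pmax(pi, 0)), colnames(matrix))
}

#' Accumulate life years and QALYs from a trace
#'
#' Integrates state occupancy over the trace into (discounted and
#' undiscounted) life years and quality-adjusted life years. With the
#' half-cycle correction on, each cycle contributes the trapezoid mean of its
#' start and end occupancy, crediting transitions as if they occur mid-cycle;
#' off, the cycle-start occupancy is used. Discounting applies the annual
#' effects rate as `(1 + r)^(-years elapsed)` with cycle 0 undiscounted.
#'
#' @param trace A `bd_trace`.
#' @param utilities Named utility vector over the alive states, in \[0, 1\].
#' @param settings The parameter set's `settings` list (cycle length,
#'   discount rate for effects, half-cycle correction flag).
#' @return A one-row tibble with columns `ly`, `qaly`, `ly_undiscounted`,
#'   `qaly_undiscounted`.
#' @examples
#' p <- default_parameters()
#' tr <- run_cohort_trace(p$subtypes$bd1, NULL, synthesize_lifetable(),
#'                        p$settings, p$mortality)
#' accumulate_outcomes(tr, p$subtypes$bd1$utilities, p$settings)
#' @export
accumulate_outcomes <- function(trace, utilities, settings) {
  eff <- effective_occupancy(trace, settings)
  cl <- settings$cycle_length
  df <- discount_factors(nrow(eff), cl, settings$discount_effects)
  alive <- eff[, "remission"] + eff[, "depression"] + eff[, "episode"]
  uw <- eff[, ALIVE_STATES, drop = FALSE] %*% utilities[ALIVE_STATES]
  tibble::tibble(
    ly = sum(alive * cl * df),
    qaly = sum(uw * cl * df),
    ly_undiscounted = sum(alive * cl),
    qaly_undiscounted = sum(uw * cl)
  )
}

# Per-cycle effective occupancy matrix (one row per cycle interval):
# trapezoid of start and end occupancy under half-cycle correction.
effective_occupancy <- function(trace, settings) {
  occ <- as.matrix(trace[, ALL_STATES])
  n <- nrow(occ) - 1
  if (n < 1) abort("trace must span at least one cycle")
  if (isTRUE(settings$half_cycle_correction)) {
    (occ[1:n, , drop = FALSE] + occ[2:(n + 1), , drop = FALSE]) / 2
  } else {
    occ[1:n, , drop = FALSE]
  }
}

# Discount factors for cycle intervals 0..(n-1); cycle 0 undiscounted.
discount_factors <- function(n, cycle_length, rate) {
  (1 + rate)^(-(0:(n - 1)) * cycle_length)
}
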