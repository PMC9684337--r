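# Shared fixtures: parameter sets and lifetables built in code.

# A lifetable with zero mortality over [from, to] (no terminal closure), for
# isolating the alive-state dynamics from background death.
zero_mortality_lifetable <- function(from = 40L, to = 140L) {
  bdmarkov:::validate_lifetable(
    tibble::tibble(age = from:to, qx = 0)
  )
}

# Defaults with a fixed short horizon, for fast engine runs.
fixed_horizon_parameters <- function(cycles = 20L) {
  p <- default_parameters()
  p$settings$horizon <- "fixed"
  p$settings$horizon_cycles <- as.integer(cycles)
  p
}

# A degenerate subtype whose alive matrix is the identity.
identity_subtype <- function() {
  m <- diag(3)
  dimnames(m) <- list(bdmarkov:::ALIVE_STATES, bdmarkov:::ALIVE_STATES)
  list(
    label = "identity", weight = 1, transitions = m,
    ratio_depression_mania = 1,
    utilities = c(remission = 0.8, depression = 0.29, episode = 0.54)
  )
}

# A hand-built trace: full cohort in one state for a number of cycles.
constant_trace <- function(state, cycles, start_age = 40, cycle_length = 0.25) {
  occ <- matrix(0, nrow = cycles + 1, ncol = 4,
                dimnames = list(NULL, bdmarkov:::ALL_STATES))
  occ[, state] <- 1
  tibble::tibble(
    cycle = 0:cycles,
    age = start_age + (0:cycles) * cycle_length,
    remission = occ[, "remission"], depression = occ[, "depression"],
    episode = occ[, "episode"], death = occ[, "death"]
  )
}

expect_row_stochastic <- function(m, tol = 1e-12) {
  expect_true(all(abs(rowSums(m) - 1) < tol))
  expect_true(all(m >= -tol & m <= 1 + tol))
}
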