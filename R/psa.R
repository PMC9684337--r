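#' Beta-PERT random draws
#'
#' Draws from the beta-PERT distribution, the standard smooth distribution
#' for quantities bounded by an expert-given minimum, mode and maximum (for
#' example a guideline's minimum and maximum number of treatment sessions).
#' Degenerate bounds (`min == max`) return the common value.
#'
#' @param n Number of draws.
#' @param min,mode,max Bounds and most likely value, `min <= mode <= max`.
#' @param shape Concentration parameter (conventionally 4).
#' @return Numeric vector of draws in `[min, max]`.
#' @examples
#' set.seed(1)
#' summary(rpert(1000, 6, 8, 12))
#' @export
rpert <- function(n, min, mode, max, shape = 4) {
  if (min > mode || mode > max) abort("need min <= mode <= max")
  if (min == max) return(rep(min, n))
  a <- 1 + shape * (mode - min) / (max - min)
  b <- 1 + shape * (max - mode) / (max - min)
  min + (max - min) * rbeta(n, a, b)
}

# Beta draw matched to a mean and standard error; se = 0 is degenerate.
rbeta_meanse <- function(n, mean, se) {
  if (se == 0 || mean <= 0 || mean >= 1) return(rep(mean, n))
  v <- se^2
  if (v >= mean * (1 - mean)) {
    abort("beta dispersion too large for the given mean")
  }
  k <- mean * (1 - mean) / v - 1
  rbeta(n, mean * k, (1 - mean) * k)
}

# Gamma draw matched to a mean and coefficient of variation.
rgamma_meancv <- function(n, mean, cv) {
  if (cv == 0 || mean == 0) return(rep(mean, n))
  shape <- 1 / cv^2
  rgamma(n, shape = shape, rate = shape / mean)
}

# Dirichlet draw with concentration = mean row x effective sample size;
# zero-probability cells stay exactly zero.
rdirichlet_row <- function(mean_row, ess) {
  if (!is.finite(ess)) return(mean_row)
  g <- numeric(length(mean_row))
  pos <- mean_row > 0
  g[pos] <- rgamma(sum(pos), shape = mean_row[pos] * ess, rate = 1)
  out <- g / sum(g)
  names(out) <- names(mean_row)
  out
}

# Median-preserving lognormal draw for a relative risk or rate ratio.
rlnorm_rr <- function(n, point, log_sd) {
  if (log_sd == 0) return(rep(point, n))
  rlnorm(n, meanlog = log(point), sdlog = log_sd)
}

#' Draw one parameter set from its uncertainty distributions
#'
#' Samples a complete parameter set for one probabilistic-sensitivity
#' iteration: transition rows from Dirichlet distributions (concentration =
#' mean row times the effective sample size), utilities from beta
#' distributions matched to mean and standard error, costs from gamma
#' distributions matched to mean and coefficient of variation, and relative
#' risks / mortality rate ratios from median-preserving lognormal
#' distributions. Draws respect their domains by construction; a dispersion
#' of zero (or infinite effective sample size) leaves the corresponding
#' parameter at its point value. The draw order is fixed — per subtype:
#' transition rows (remission, depression, episode), then utilities; then
#' cost components column by column; then mortality ratios; then intervention
#' relative risks — so results are reproducible under a seeded generator.
#'
#' @param params The base `bd_parameters` object.
#' @param uncertainty Dispersion configuration; defaults to
#'   `params$uncertainty` (`transition_ess`, `cost_cv`, `utility_se`,
#'   `rr_log_sd`).
#' @return A `bd_parameters` object with sampled values.
#' @examples
#' set.seed(42)
#' draw <- sample_parameter_set(default_parameters())
#' rowSums(draw$subtypes$bd1$transitions)
#' @export
sample_parameter_set <- function(params, uncertainty = NULL) {
  un <- uncertainty %||% params$uncertainty
  if (un$transition_ess <= 0) abort("transition_ess must be positive")
  p <- params
  for (tag in names(p$subtypes)) {
    sub <- p$subtypes[[tag]]
    for (row in ALIVE_STATES) {
      sub$transitions[row, ] <-
        rdirichlet_row(sub$transitions[row, ],
                       if (un$transition_ess == Inf) Inf else un$transition_ess)
    }
    sub$utilities <- vapply(
      sub$utilities, function(u) rbeta_meanse(1, u, un$utility_se), numeric(1)
    )
    p$subtypes[[tag]] <- sub
  }
  cm <- p$costs$components
  for (st in colnames(cm)) {
    cm[, st] <- vapply(cm[, st], function(m) rgamma_meancv(1, m, un$cost_cv),
                       numeric(1))
  }
  p$costs$components <- cm
  p$mortality$mrr_all_states <-
    rlnorm_rr(1, p$mortality$mrr_all_states, un$rr_log_sd)
  p$mortality$mrr_suicide_depression <-
    rlnorm_rr(1, p$mortality$mrr_suicide_depression, un$rr_log_sd)
  p$intervention$rr_depression <-
    rlnorm_rr(1, p$intervention$rr_depression, un$rr_log_sd)
  p$intervention$rr_episode <-
    rlnorm_rr(1, p$intervention$rr_episode, un$rr_log_sd)
  p
}

#' Probabilistic sensitivity analysis
#'
#' Propagates parameter uncertainty through the model by Monte Carlo: each
#' iteration draws a parameter set with [sample_parameter_set()], runs both
#' arms for both subtypes, and records the prevalence-weighted incremental
#' discounted cost and QALYs. Results are deterministic given the seed.
#'
#' @param params The base `bd_parameters` object.
#' @param lifetable A `bd_lifetable`.
#' @param n Number of iterations (default from
#'   `params$settings$psa_iterations`, 5000).
#' @param seed Integer seed for the random generator.
#' @param uncertainty Optional dispersion overrides (see
#'   [sample_parameter_set()]).
#' @param perspective Cost perspective; defaults to the one in `params`.
#' @return An object of class `bd_psa`: a list with `draws` (a tibble of
#'   `iteration`, `delta_cost`, `delta_qaly`), `ceac` over the parameter
#'   set's willingness-to-pay grid, `n`, `seed` and the dispersions used.
#' @examples
#' psa <- run_psa(default_parameters(), synthesize_lifetable(),
#'                n = 10, seed = 1)
#' psa$draws
#' @export
run_psa <- function(params, lifetable = synthesize_lifetable(), n = NULL,
                    seed = 1L, uncertainty = NULL, perspective = NULL) {
  n <- as.integer(n %||% params$settings$psa_iterations)
  if (n < 1) abort("number of iterations must be at least 1")
  perspective <- perspective %||% params$settings$perspective
  un <- uncertainty %||% params$uncertainty
  set.seed(seed)
  weights <- vapply(params$subtypes, function(s) s$weight, numeric(1))
  dc <- numeric(n)
  dq <- numeric(n)
  for (i in seq_len(n)) {
    draw <- sample_parameter_set(params, un)
    inc_c <- 0
    inc_q <- 0
    for (k in seq_along(draw$subtypes)) {
      sub <- draw$subtypes[[k]]
      tr_c <- run_cohort_trace(sub, NULL, lifetable, draw$settings,
                               draw$mortality)
      tr_i <- run_cohort_trace(sub, draw$intervention, lifetable,
                               draw$settings, draw$mortality)
      out_c <- accumulate_outcomes(tr_c, sub$utilities, draw$settings)
      out_i <- accumulate_outcomes(tr_i, sub$utilities, draw$settings)
      cost_c <- value_trace_costs(tr_c, draw, "control", perspective)
      cost_i <- value_trace_costs(tr_i, draw, "intervention", perspective)
      inc_c <- inc_c + weights[[k]] * (cost_i$cost - cost_c$cost)
      inc_q <- inc_q + weights[[k]] * (out_i$qaly - out_c$qaly)
    }
    dc[i] <- inc_c
    dq[i] <- inc_q
  }
  draws <- tibble::tibble(iteration = seq_len(n), delta_cost = dc,
                          delta_qaly = dq)
  result <- structure(
    list(
      draws = draws, n = n, seed = seed, uncertainty = un,
      perspective = perspective, wtp_grid = params$settings$wtp_grid
    ),
    class = "bd_psa"
  )
  result$ceac <- ceac(result, params$settings$wtp_grid)
  result
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold, the probability that the
#' intervention is cost-effective: the fraction of Monte Carlo draws with
#' positive net monetary benefit, `wtp * delta_qaly - delta_cost > 0`. Ties
#' at exactly zero count as not cost-effective.
#'
#' @param psa A `bd_psa` object (or any list with a `draws` tibble).
#' @param wtp_grid Non-empty vector of non-negative thresholds (euros per
#'   QALY).
#' @return A tibble with columns `wtp` and `probability`.
#' @examples
#' psa <- run_psa(default_parameters(), synthesize_lifetable(),
#'                n = 10, seed = 1)
#' ceac(psa, c(0, 20000, 50000))
#' @export
ceac <- function(psa, wtp_grid) {
  if (length(wtp_grid) == 0) abort("willingness-to-pay grid must be non-empty")
  draws <- psa$draws
  probability <- vapply(wtp_grid, function(lambda) {
    mean(lambda * draws$delta_qaly - draws$delta_cost > 0)
  }, numeric(1))
  tibble::tibble(wtp = as.numeric(wtp_grid), probability = probability)
}

#' @export
print.bd_psa <- function(x, ...) {
  cat("<bd_psa> ", x$n, "iterations, seed", x$seed, "\n")
  cat(sprintf(
    "  mean delta cost %.0f EUR, mean delta QALY %.4f\n",
    mean(x$draws$delta_cost), mean(x$draws$delta_qaly)
  ))
  at50 <- x$ceac$probability[x$ceac$wtp == 50000]
  if (length(at50)) {
    cat(sprintf("  P(cost-effective at 50,000 EUR/QALY) = %.4f\n", at50[[1]]))
  }
  invisible(x)
}
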