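#' Tidy a deterministic cost-utility result
#'
#' Returns the result as a long tibble, one row per arm, subtype, discounting
#' flag and metric.
#'
#' @param x A `bd_ce_result`.
#' @param ... Unused.
#' @return A tibble with columns `arm`, `subtype`, `discounted`, `metric`
#'   (`ly`, `qaly`, `cost`) and `value`.
#' @export
tidy.bd_ce_result <- function(x, ...) {
  x$arms |>
    tidyr::pivot_longer(
      cols = c("ly", "qaly", "cost", "ly_undiscounted", "qaly_undiscounted",
               "cost_undiscounted"),
      names_to = "metric", values_to = "value"
    ) |>
    dplyr::mutate(
      discounted = !grepl("_undiscounted$", .data$metric),
      metric = sub("_undiscounted$", "", .data$metric)
    ) |>
    dplyr::select("arm", "subtype", "discounted", "metric", "value")
}

#' One-row summary of a cost-utility result
#'
#' @param x A `bd_ce_result`.
#' @param ... Unused.
#' @return A one-row tibble with the prevalence-weighted incremental
#'   discounted cost, QALYs, life years, ICER (when defined), decision label
#'   and perspective.
#' @export
glance.bd_ce_result <- function(x, ...) {
  x$increments |>
    dplyr::filter(.data$subtype == "weighted") |>
    dplyr::select("delta_cost", "delta_qaly", "delta_ly", "icer",
                  "decision") |>
    dplyr::mutate(perspective = x$perspective)
}

#' Tidy a probabilistic sensitivity analysis
#'
#' @param x A `bd_psa`.
#' @param ... Unused.
#' @return The per-iteration incremental draws: a tibble with `iteration`,
#'   `delta_cost`, `delta_qaly`.
#' @export
tidy.bd_psa <- function(x, ...) {
  x$draws
}

#' One-row summary of a probabilistic sensitivity analysis
#'
#' @param x A `bd_psa`.
#' @param ... Unused.
#' @return A one-row tibble with iteration count, seed, mean increments and
#'   the probability of cost-effectiveness at 50,000 euros per QALY (when on
#'   the grid).
#' @export
glance.bd_psa <- function(x, ...) {
  at50 <- x$ceac$probability[x$ceac$wtp == 50000]
  tibble::tibble(
    n = x$n, seed = x$seed,
    mean_delta_cost = mean(x$draws$delta_cost),
    mean_delta_qaly = mean(x$draws$delta_qaly),
    p_ce_at_50000 = if (length(at50)) at50[[1]] else NA_real_
  )
}
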