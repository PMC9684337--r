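#' Read a lifetable from a CSV file
#'
#' Reads an age-indexed table of annual general-population death
#' probabilities with header `age,qx`: integer ages in years, contiguous and
#' ascending, with `qx` in \[0, 1\]. Ages beyond the last row are treated as
#' certain death by the engine.
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `age` (integer) and `qx` (double), classed
#'   `bd_lifetable`.
#' @seealso [synthesize_lifetable()], [write_lifetable()]
#' @export
read_lifetable <- function(path) {
  lt <- readr::read_csv(path, col_types = readr::cols(
    age = readr::col_integer(), qx = readr::col_double()
  ))
  validate_lifetable(lt)
}

#' Write a lifetable to CSV
#'
#' @param lifetable A `bd_lifetable` (or any data frame with `age` and `qx`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lifetable <- function(lifetable, path) {
  readr::write_csv(lifetable[, c("age", "qx")], path)
  invisible(path)
}

validate_lifetable <- function(lt) {
  if (!all(c("age", "qx") %in% names(lt))) {
    abort("lifetable must have columns 'age' and 'qx'")
  }
  bad <- which(lt$qx < 0 | lt$qx > 1 | !is.finite(lt$qx))
  if (length(bad)) {
    abort(paste0(
      "lifetable row ", bad[[1]], ": qx = ", lt$qx[bad[[1]]],
      " outside [0, 1]"
    ))
  }
  if (nrow(lt) > 1 && any(diff(lt$age) != 1)) {
    gap <- which(diff(lt$age) != 1)[[1]]
    abort(paste0("lifetable ages must be contiguous; gap after row ", gap))
  }
  tibble::new_tibble(tibble::as_tibble(lt), class = "bd_lifetable")
}

#' Synthesize a background-mortality lifetable
#'
#' Generates a deterministic lifetable from the Gompertz-Makeham law of
#' mortality, `q(age) = 1 - exp(-(a + b * c^age))`: a constant
#' age-independent hazard `a` plus an exponentially increasing senescent
#' hazard. The defaults approximate a modern Western European lifetable
#' (implied life expectancy at birth of roughly 80 years), so the model is
#' runnable without external mortality data. The terminal age closes the
#' table with certain death.
#'
#' @param a Makeham (background) annual hazard, `>= 0`.
#' @param b Gompertz baseline annual hazard, `> 0`.
#' @param c Gompertz rate of ageing, `> 1`.
#' @param max_age Terminal age in years; `qx` is set to 1 there.
#' @return A `bd_lifetable` tibble with ages `0:max_age`.
#' @examples
#' lt <- synthesize_lifetable()
#' lt[lt$age %in% c(40, 80), ]
#' @export
synthesize_lifetable <- function(a = 5e-5, b = 3e-5, c = 1.094,
                                 max_age = 110L) {
  if (a < 0) abort("Makeham parameter 'a' must be non-negative")
  if (b <= 0) abort("Gompertz parameter 'b' must be positive")
  if (c <= 1) abort("Gompertz parameter 'c' must exceed 1")
  if (max_age < 1) abort("max_age must be at least 1")
  age <- 0:max_age
  qx <- -expm1(-(a + b * c^age))
  qx[length(qx)] <- 1
  validate_lifetable(tibble::tibble(age = as.integer(age), qx = qx))
}

#' Annual death probability at given ages
#'
#' Looks up `qx` for (integer) ages; ages past the table's last row return 1.
#'
#' @param lifetable A `bd_lifetable`.
#' @param age Ages in years (floored to integers).
#' @return Annual death probabilities.
#' @export
lifetable_qx <- function(lifetable, age) {
  age <- floor(age)
  idx <- match(age, lifetable$age)
  q <- lifetable$qx[idx]
  q[is.na(idx) & age > max(lifetable$age)] <- 1
  if (anyNA(q)) abort("age below the first lifetable row")
  q
}

#' Life expectancy implied by a lifetable
#'
#' Simple lifetable summation: expected years lived from a starting age,
#' crediting half a year in the year of death.
#'
#' @param lifetable A `bd_lifetable`.
#' @param from Starting age (default 0).
#' @return Expected remaining years of life.
#' @export
life_expectancy <- function(lifetable, from = 0) {
  ages <- lifetable$age[lifetable$age >= from]
  q <- lifetable$qx[lifetable$age >= from]
  surv <- cumprod(c(1, 1 - q))
  # person-years per age interval, half-year credit in the year of death
  sum((surv[-length(surv)] + surv[-1]) / 2)
}
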