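# Cost components and their perspective membership. Productivity losses and
# patient-and-family costs are societal-only; everything else is healthcare
# (healthcare is a strict subset of societal).
COST_COMPONENTS <- c(
  "drugs", "medical_services", "psychological_treatment",
  "home_based_treatment", "indirect_medical", "productivity_losses",
  "patient_family", "admission"
)
HEALTHCARE_COMPONENTS <- setdiff(
  COST_COMPONENTS, c("productivity_losses", "patient_family")
)

#' Default model parameterization
#'
#' Returns the packaged Dutch standard-of-care parameterization of the model:
#' quarterly transition probabilities, depression/mania time ratios, state
#' utilities and prevalence weights for both bipolar subtypes; mortality rate
#' ratios; per-state per-cycle costs by component (2021 euros); the
#' mindfulness-based cognitive therapy case-study intervention (relative
#' risks 0.81 for depression and 1.32 for (hypo)mania, 291 euro for one
#' cycle, effect persisting four cycles); run settings (quarterly cycles,
#' lifetime horizon, annual discount rates of 4% for costs and 1.5% for
#' effects, half-cycle correction on); and probabilistic-sensitivity
#' dispersion defaults.
#'
#' @return An object of class `bd_parameters`: a named list with elements
#'   `subtypes` (per-subtype weight, transition matrix, ratio, utilities),
#'   `mortality`, `costs`, `intervention`, `settings` and `uncertainty`.
#' @examples
#' p <- default_parameters()
#' p$subtypes$bd1$transitions
#' p$subtypes$bd2$utilities
#' @export
default_parameters <- function() {
  trans <- function(rr, rd, re, dr, dd, de, er, ed, ee) {
    matrix(c(rr, rd, re, dr, dd, de, er, ed, ee),
      nrow = 3, byrow = TRUE,
      dimnames = list(ALIVE_STATES, ALIVE_STATES)
    )
  }
  costs <- matrix(
    c(
      39,  53,  53,   # drugs
      161, 786, 804,  # medical services
      271, 126, 722,  # psychological treatment
      131, 153, 874,  # home-based treatment
      40,  40,  40,   # indirect medical
      443, 3637, 2182, # productivity losses
      0,   4996, 2997, # patient and family
      0,   617, 6166   # admission
    ),
    nrow = length(COST_COMPONENTS), byrow = TRUE,
    dimnames = list(COST_COMPONENTS, ALIVE_STATES)
  )
  params <- list(
    subtypes = list(
      bd1 = list(
        label = "BD-I",
        weight = 0.600,
        transitions = trans(
          0.880, 0.094, 0.026,
          0.365, 0.561, 0.074,
          0.628, 0.074, 0.298
        ),
        ratio_depression_mania = 4.7,
        time_depression = 0.744,
        time_mania = 0.256,
        utilities = c(remission = 0.800, depression = 0.290, episode = 0.540)
      ),
      bd2 = list(
        label = "BD-II",
        weight = 0.400,
        transitions = trans(
          0.880, 0.117, 0.003,
          0.365, 0.561, 0.074,
          0.878, 0.074, 0.048
        ),
        ratio_depression_mania = 10.7,
        time_depression = 0.792,
        time_mania = 0.208,
        utilities = c(remission = 0.800, depression = 0.290, episode = 0.800)
      )
    ),
    mortality = list(
      mrr_all_states = 2.06,
      mrr_suicide_depression = 9.66,
      combination = "multiplicative"
    ),
    costs = list(
      components = costs,
      healthcare_components = HEALTHCARE_COMPONENTS,
      retirement_age = 67
    ),
    intervention = list(
      rr_depression = 0.81,
      rr_episode = 1.32,
      cost_per_cycle = 291,
      cost_cycles = 1L,
      effect_cycles = 4L,
      scope = "relapse_only"
    ),
    settings = list(
      cycle_length = 0.25,
      horizon = "lifetime",
      horizon_cycles = 20L,
      discount_costs = 0.04,
      discount_effects = 0.015,
      start_age = 40,
      start_state = c(remission = 1, depression = 0, episode = 0),
      perspective = "societal",
      wtp_grid = sort(unique(c(seq(0, 150000, by = 5000), 50000, 147300))),
      half_cycle_correction = TRUE,
      psa_iterations = 5000L
    ),
    uncertainty = list(
      transition_ess = 100,
      cost_cv = 0.2,
      utility_se = 0.05,
      rr_log_sd = 0.1
    )
  )
  structure(params, class = "bd_parameters")
}

#' Read and validate a model configuration file
#'
#' Reads a YAML configuration whose nesting mirrors [default_parameters()].
#' Any field not present in the file keeps its packaged default; unknown keys
#' are an error, so typos cannot silently fall back to defaults. The merged
#' parameter set is validated (row-stochastic transition rows, utilities and
#' probabilities in \[0, 1\], prevalence weights summing to 1, non-negative
#' costs) before it is returned.
#'
#' @param path Path to a YAML configuration file. An empty file (or empty
#'   YAML mapping) yields the packaged defaults.
#' @return A validated `bd_parameters` object.
#' @seealso [write_parameters()] for the inverse, [validate_parameters()].
#' @examples
#' cfg <- tempfile(fileext = ".yaml")
#' writeLines("settings:\n  discount_costs: 0\n  discount_effects: 0", cfg)
#' p <- load_parameters(cfg)
#' p$settings$discount_costs
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("configuration file not found: ", path))
  }
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  if (!is.list(user)) abort("configuration must be a YAML mapping")
  defaults <- default_parameters()
  merged <- merge_config(unclass(defaults), user, path = "")
  merged <- canonicalize_parameters(merged)
  validate_parameters(structure(merged, class = "bd_parameters"))
}

#' Serialize a parameter set to YAML
#'
#' Writes a `bd_parameters` object as a YAML file that [load_parameters()]
#' reads back to an identical parameter set.
#'
#' @param params A `bd_parameters` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "bd_parameters"))
  serializable <- unclass(params)
  for (s in names(serializable$subtypes)) {
    tm <- serializable$subtypes[[s]]$transitions
    serializable$subtypes[[s]]$transitions <-
      lapply(setNames(ALIVE_STATES, ALIVE_STATES), function(r) as.list(tm[r, ]))
    serializable$subtypes[[s]]$utilities <-
      as.list(serializable$subtypes[[s]]$utilities)
  }
  cm <- serializable$costs$components
  serializable$costs$components <-
    lapply(setNames(rownames(cm), rownames(cm)), function(r) as.list(cm[r, ]))
  serializable$settings$start_state <-
    as.list(serializable$settings$start_state)
  yaml::write_yaml(serializable, path, precision = 15L)
  invisible(path)
}

# Recursive merge of a user config onto defaults. Unknown keys error with
# their full dotted path; scalar leaves are replaced wholesale.
merge_config <- function(defaults, user, path) {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults)) {
      abort(paste0("unknown configuration key: '", full, "'"))
    }
    dval <- defaults[[key]]
    uval <- user[[key]]
    leaf_list <- is.list(dval) &&
      key %in% c("transitions", "components", "utilities", "start_state")
    if (is.list(dval) && !leaf_list && !is.matrix(dval) &&
        !is.numeric(dval)) {
      if (!is.list(uval)) {
        abort(paste0("configuration key '", full, "' must be a mapping"))
      }
      defaults[[key]] <- merge_config(dval, uval, full)
    } else if (is.matrix(dval) || leaf_list ||
               (is.numeric(dval) && !is.null(names(dval)))) {
      defaults[[key]] <- merge_structured(dval, uval, full)
    } else {
      defaults[[key]] <- uval
    }
  }
  defaults
}

# Merge into a named numeric vector or matrix given as nested YAML mappings.
merge_structured <- function(dval, uval, full) {
  if (is.matrix(dval)) {
    if (!is.list(uval)) {
      abort(paste0("configuration key '", full, "' must be a mapping of rows"))
    }
    for (r in names(uval)) {
      if (!r %in% rownames(dval)) {
        abort(paste0("unknown configuration key: '", full, ".", r, "'"))
      }
      row <- uval[[r]]
      if (!is.list(row)) abort(paste0("'", full, ".", r, "' must be a mapping"))
      for (cn in names(row)) {
        if (!cn %in% colnames(dval)) {
          abort(paste0("unknown configuration key: '", full, ".", r, ".", cn, "'"))
        }
        dval[r, cn] <- as.numeric(row[[cn]])
      }
    }
    return(dval)
  }
  # named numeric vector leaf (utilities, start_state)
  if (is.list(uval)) uval <- unlist(uval)
  if (is.null(names(uval))) {
    abort(paste0("configuration key '", full, "' must be a named mapping"))
  }
  bad <- setdiff(names(uval), names(dval))
  if (length(bad)) {
    abort(paste0("unknown configuration key: '", full, ".", bad[[1]], "'"))
  }
  dval[names(uval)] <- as.numeric(uval)
  dval
}

# Normalise types after a YAML round trip (nested lists back to matrices).
canonicalize_parameters <- function(p) {
  for (s in names(p$subtypes)) {
    tm <- p$subtypes[[s]]$transitions
    if (is.list(tm)) {
      m <- do.call(rbind, lapply(tm[ALIVE_STATES], function(r) unlist(r)[ALIVE_STATES]))
      dimnames(m) <- list(ALIVE_STATES, ALIVE_STATES)
      p$subtypes[[s]]$transitions <- m
    }
    u <- p$subtypes[[s]]$utilities
    if (is.list(u)) p$subtypes[[s]]$utilities <- unlist(u)[ALIVE_STATES]
  }
  cm <- p$costs$components
  if (is.list(cm)) {
    m <- do.call(rbind, lapply(cm, function(r) unlist(r)[ALIVE_STATES]))
    dimnames(m) <- list(names(cm), ALIVE_STATES)
    p$costs$components <- m
  }
  ss <- p$settings$start_state
  if (is.list(ss)) p$settings$start_state <- unlist(ss)[ALIVE_STATES]
  p$settings$horizon_cycles <- as.integer(p$settings$horizon_cycles)
  p$settings$psa_iterations <- as.integer(p$settings$psa_iterations)
  p$intervention$cost_cycles <- as.integer(p$intervention$cost_cycles)
  p$intervention$effect_cycles <- as.integer(p$intervention$effect_cycles)
  p$settings$wtp_grid <- as.numeric(unlist(p$settings$wtp_grid))
  p
}

#' Validate a parameter set
#'
#' Checks the structural invariants of a `bd_parameters` object: each
#' transition row sums to 1 within 1e-9 with entries in \[0, 1\], prevalence
#' weights sum to 1, utilities lie in \[0, 1\], costs are non-negative,
#' mortality rate ratios are positive, discount rates are non-negative, the
#' start-state distribution sums to 1 and the willingness-to-pay grid is
#' non-negative ascending.
#'
#' @param params A `bd_parameters` object.
#' @return `params`, invisibly classed, if valid; otherwise an error naming
#'   the offending field.
#' @export
validate_parameters <- function(params) {
  p <- params
  tol <- 1e-9
  weights <- vapply(p$subtypes, function(s) s$weight, numeric(1))
  if (abs(sum(weights) - 1) > tol) {
    abort("subtype prevalence weights must sum to 1")
  }
  for (s in names(p$subtypes)) {
    sub <- p$subtypes[[s]]
    tm <- sub$transitions
    if (!is.matrix(tm) || !identical(dim(tm), c(3L, 3L))) {
      abort(paste0("subtypes.", s, ".transitions must be a 3x3 matrix"))
    }
    if (any(tm < -tol) || any(tm > 1 + tol)) {
      abort(paste0("subtypes.", s, ".transitions entries must lie in [0, 1]"))
    }
    sums <- rowSums(tm)
    off <- which(abs(sums - 1) > tol)
    if (length(off)) {
      abort(paste0(
        "transition row '", ALIVE_STATES[off[[1]]], "' of subtype '", s,
        "' sums to ", format(sums[off[[1]]], digits = 10), ", not 1"
      ))
    }
    if (sub$ratio_depression_mania <= 0) {
      abort(paste0("subtypes.", s, ".ratio_depression_mania must be positive"))
    }
    u <- sub$utilities
    if (any(u < 0 | u > 1)) {
      abort(paste0("subtypes.", s, ".utilities must lie in [0, 1]"))
    }
  }
  if (p$mortality$mrr_all_states <= 0 || p$mortality$mrr_suicide_depression <= 0) {
    abort("mortality rate ratios must be positive")
  }
  if (!p$mortality$combination %in% c("multiplicative", "additive")) {
    abort("mortality.combination must be 'multiplicative' or 'additive'")
  }
  if (any(p$costs$components < 0)) abort("cost amounts must be non-negative")
  bad <- setdiff(p$costs$healthcare_components, rownames(p$costs$components))
  if (length(bad)) {
    abort(paste0("unknown healthcare cost component: '", bad[[1]], "'"))
  }
  iv <- p$intervention
  if (iv$rr_depression <= 0 || iv$rr_episode <= 0) {
    abort("intervention relative risks must be positive")
  }
  if (iv$cost_per_cycle < 0) abort("intervention cost must be non-negative")
  if (iv$cost_cycles < 0 || iv$effect_cycles < 0) {
    abort("intervention durations must be non-negative integers")
  }
  if (!iv$scope %in% c("relapse_only", "all_entries")) {
    abort("intervention.scope must be 'relapse_only' or 'all_entries'")
  }
  st <- p$settings
  if (st$cycle_length <= 0) abort("settings.cycle_length must be positive")
  if (!st$horizon %in% c("lifetime", "fixed")) {
    abort("settings.horizon must be 'lifetime' or 'fixed'")
  }
  if (st$discount_costs < 0 || st$discount_effects < 0) {
    abort("discount rates must be non-negative")
  }
  if (abs(sum(st$start_state) - 1) > tol || any(st$start_state < 0)) {
    abort("settings.start_state must be a distribution over alive states")
  }
  if (!st$perspective %in% c("healthcare", "societal")) {
    abort("settings.perspective must be 'healthcare' or 'societal'")
  }
  if (any(st$wtp_grid < 0) || is.unsorted(st$wtp_grid)) {
    abort("settings.wtp_grid must be non-negative and ascending")
  }
  un <- p$uncertainty
  if (un$transition_ess <= 0 || un$cost_cv < 0 || un$utility_se < 0 ||
      un$rr_log_sd < 0) {
    abort("uncertainty dispersions must be non-negative (ESS positive)")
  }
  invisible(params)
}

#' @export
print.bd_parameters <- function(x, ...) {
  cat("<bd_parameters>\n")
  for (s in names(x$subtypes)) {
    sub <- x$subtypes[[s]]
    cat(sprintf(
      "  %s (weight %.3f): utilities R/D/E = %.2f/%.2f/%.2f\n",
      sub$label, sub$weight, sub$utilities[1], sub$utilities[2], sub$utilities[3]
    ))
  }
  cat(sprintf(
    "  horizon: %s, cycle %.2fy, perspective: %s, discounting %g%%/%g%%\n",
    x$settings$horizon, x$settings$cycle_length, x$settings$perspective,
    100 * x$settings$discount_costs, 100 * x$settings$discount_effects
  ))
  cat(sprintf(
    "  intervention: RR depression %.2f, RR episode %.2f, %.0f EUR x %d cycle(s), effect %d cycle(s)\n",
    x$intervention$rr_depression, x$intervention$rr_episode,
    x$intervention$cost_per_cycle, x$intervention$cost_cycles,
    x$intervention$effect_cycles
  ))
  invisible(x)
}

# Cost components counted under a perspective; intervention cost is handled
# separately by the valuation layer.
perspective_components <- function(costs, perspective) {
  if (perspective == "healthcare") costs$healthcare_components
  else rownames(costs$components)
}
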