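# Report writers behind the command-line interface: each command runs the
# model, writes CSV/JSON artifacts into an output directory and records a
# manifest (config hash, seed, package version, files written).

# Person-time share of each alive state among survivors of the control-arm
# trace: the mortality-bearing counterpart of the stationary shares, since
# excess depression mortality shifts prevalence among those still alive.
survivor_epidemiology <- function(params, lifetable) {
  rows <- purrr::imap(params$subtypes, function(sub, tag) {
    tr <- run_cohort_trace(sub, NULL, lifetable, params$settings,
                           params$mortality)
    occ <- as.matrix(tr[, ALIVE_STATES])
    share <- colSums(occ) / sum(occ)
    tibble::tibble(subtype = tag, weight = sub$weight,
                   remission = share[["remission"]],
                   depression = share[["depression"]],
                   episode = share[["episode"]])
  })
  out <- dplyr::bind_rows(rows)
  dplyr::bind_rows(out, weighted_row(out))
}

write_manifest <- function(dir, config_path, seed, files) {
  config_hash <- if (!is.null(config_path) && file.exists(config_path)) {
    unname(tools::md5sum(config_path))
  } else {
    "packaged-defaults"
  }
  manifest <- list(
    config = config_hash,
    seed = seed,
    package_version = as.character(utils::packageVersion("bdmarkov")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    files = files
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  missing <- files[!file.exists(file.path(dir, files))]
  if (length(missing)) {
    abort(paste0("manifest lists missing output file: ", missing[[1]]))
  }
  invisible(path)
}

#' Write the deterministic cost-utility report
#'
#' Runs the deterministic analysis and writes: per-arm totals and increments
#' as a tidy CSV, a JSON summary with the weighted incremental results, one
#' trace CSV per subtype and arm, an epidemiology validation CSV with the
#' long-run alive-state shares per subtype and weighted — both the stationary
#' shares of the mortality-free chain and the person-time shares among
#' survivors of the mortality-bearing trace — and a run manifest.
#'
#' @param params A `bd_parameters` object.
#' @param lifetable A `bd_lifetable`.
#' @param dir Output directory (created if needed).
#' @param config_path Optional path of the config the run came from, hashed
#'   into the manifest.
#' @return The `bd_ce_result`, invisibly.
#' @export
write_ce_report <- function(params, lifetable, dir,
                            config_path = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  res <- run_ce_analysis(params, lifetable)
  files <- character(0)
  readr::write_csv(tidy(res), file.path(dir, "arm_totals.csv"))
  readr::write_csv(res$increments, file.path(dir, "increments.csv"))
  files <- c(files, "arm_totals.csv", "increments.csv")
  for (tag in names(params$subtypes)) {
    for (arm in c("control", "intervention")) {
      iv <- if (arm == "intervention") params$intervention else NULL
      tr <- run_cohort_trace(params$subtypes[[tag]], iv, lifetable,
                             params$settings, params$mortality)
      f <- paste0("trace_", tag, "_", arm, ".csv")
      readr::write_csv(tr, file.path(dir, f))
      files <- c(files, f)
    }
  }
  epi <- dplyr::bind_rows(
    dplyr::mutate(stationary_epidemiology(params), basis = "stationary",
                  .before = 1),
    dplyr::mutate(survivor_epidemiology(params, lifetable),
                  basis = "survivor_person_time", .before = 1)
  )
  readr::write_csv(epi, file.path(dir, "epidemiology.csv"))
  files <- c(files, "epidemiology.csv")
  w <- res$increments[res$increments$subtype == "weighted", ]
  summary <- list(
    perspective = res$perspective,
    delta_cost = round(w$delta_cost),
    delta_qaly = round(w$delta_qaly, 4),
    decision = w$decision,
    icer = if (is.na(w$icer)) NULL else round(w$icer),
    stationary_weighted = as.list(round(
      epi[epi$subtype == "weighted" & epi$basis == "stationary",
          c("remission", "depression", "episode")],
      4
    ))
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  files <- c(files, "summary.json")
  write_manifest(dir, config_path, seed = NA, files = files)
  invisible(res)
}

#' Write the probabilistic sensitivity analysis report
#'
#' Runs the PSA and writes the cost-effectiveness plane CSV (iteration,
#' incremental cost, incremental QALYs), the acceptability curve CSV, a JSON
#' metadata file echoing the seed and dispersions, and a run manifest.
#'
#' @param params A `bd_parameters` object.
#' @param lifetable A `bd_lifetable`.
#' @param dir Output directory.
#' @param n Iterations (default from the parameter set, 5000).
#' @param seed Integer seed.
#' @param config_path Optional config path for the manifest.
#' @return The `bd_psa`, invisibly.
#' @export
write_psa_report <- function(params, lifetable, dir, n = NULL, seed = 1L,
                             config_path = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  psa <- run_psa(params, lifetable, n = n, seed = seed)
  readr::write_csv(psa$draws, file.path(dir, "ce_plane.csv"))
  curve <- psa$ceac
  curve$probability <- round(curve$probability, 4)
  readr::write_csv(curve, file.path(dir, "ceac.csv"))
  meta <- list(
    n = psa$n, seed = psa$seed, perspective = psa$perspective,
    uncertainty = psa$uncertainty
  )
  jsonlite::write_json(meta, file.path(dir, "psa_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  write_manifest(dir, config_path, seed = seed,
                 files = c("ce_plane.csv", "ceac.csv", "psa_metadata.json"))
  invisible(psa)
}

#' Write the scenario-analysis report
#'
#' Runs [scenario_ratio_analysis()] and writes the comparison table as CSV
#' with a run manifest.
#'
#' @param params A `bd_parameters` object.
#' @param lifetable A `bd_lifetable`.
#' @param dir Output directory.
#' @param ratios List of length-2 ratio vectors (see
#'   [scenario_ratio_analysis()]).
#' @param config_path Optional config path for the manifest.
#' @return The scenario tibble, invisibly.
#' @export
write_scenario_report <- function(params, lifetable, dir,
                                  ratios = list(c(6, 14), c(3.6, 38.7)),
                                  config_path = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- scenario_ratio_analysis(params, lifetable, ratios)
  readr::write_csv(tab, file.path(dir, "scenarios.csv"))
  write_manifest(dir, config_path, seed = NA, files = "scenarios.csv")
  invisible(tab)
}

#' Parse a scenario ratio specification string
#'
#' Parses the command-line form `"6,14;3.6,38.7"` into a list of length-2
#' numeric vectors, one per scenario.
#'
#' @param spec Semicolon-separated scenarios, each a comma-separated pair of
#'   positive ratios (BD-I, BD-II).
#' @return A list of numeric vectors.
#' @export
parse_ratio_spec <- function(spec) {
  pairs <- strsplit(spec, ";", fixed = TRUE)[[1]]
  out <- lapply(pairs, function(p) {
    vals <- suppressWarnings(as.numeric(strsplit(p, ",", fixed = TRUE)[[1]]))
    if (length(vals) != 2 || anyNA(vals) || any(vals <= 0)) {
      abort(paste0("malformed ratio pair: '", p,
                   "' (need two positive numbers)"))
    }
    vals
  })
  if (!length(out)) abort("empty ratio specification")
  out
}
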