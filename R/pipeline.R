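#' Pipeline run configuration
#'
#' Collects every knob of an end-to-end run. The configuration is serialized
#' to `config.yaml` in the output directory so a rerun with the saved config
#' and the same seed reproduces all result files bit-identically.
#'
#' @param out_dir output directory.
#' @param seed master seed (also passed to the generator unless a custom
#'   `generator` is supplied).
#' @param generator a [generator_config()], or `NULL` to read real data.
#' @param manifest_path kinematics ensemble manifest (used when
#'   `generator` is `NULL`).
#' @param constants a [metric_constants()].
#' @param q summary percentile (default 95).
#' @param top_fraction high-strain element fraction (default 0.05).
#' @param fiber_convention `"realtime"` or `"reference"` fiber direction.
#' @param heatmap_metrics strain metrics for which element-level heatmaps
#'   are written (curve-level heatmaps are always written per location).
#' @param write_kinematics also materialise the synthetic kinematics files?
#' @return a named list of class `run_config`.
#' @export
run_config <- function(out_dir,
                       seed = 1,
                       generator = generator_config(seed = seed),
                       manifest_path = NULL,
                       constants = metric_constants(),
                       q = 95,
                       top_fraction = 0.05,
                       fiber_convention = c("realtime", "reference"),
                       heatmap_metrics = "MPS",
                       write_kinematics = FALSE) {
  if (is.null(generator) && is.null(manifest_path)) {
    abort("either a generator config or a manifest_path is required",
      class = c("helmstrain_config_error", "helmstrain_error")
    )
  }
  structure(
    list(
      out_dir = out_dir, seed = as.integer(seed), generator = generator,
      manifest_path = manifest_path, constants = constants, q = q,
      top_fraction = top_fraction,
      fiber_convention = match.arg(fiber_convention),
      heatmap_metrics = heatmap_metrics,
      write_kinematics = write_kinematics
    ),
    class = "run_config"
  )
}

config_hash <- function(config) {
  # the hash identifies the analysis, not where it is written
  rlang::hash(unclass(config)[setdiff(names(config), "out_dir")])
}

output_header <- function(config) {
  sprintf(
    "# helmstrain %s; seed=%d; config=%s",
    as.character(packageVersion("helmstrain")),
    config$seed, config_hash(config)
  )
}

write_result_csv <- function(df, path, config) {
  lines <- c(
    output_header(config),
    readr::format_csv(df)
  )
  writeLines(sub("\n$", "", paste(lines, collapse = "\n")), path)
  invisible(path)
}

write_heatmap_csv <- function(cm, path, config) {
  df <- as_tibble(cm$r, rownames = "helmet_id")
  write_result_csv(df, path, config)
}

serialize_config <- function(config, path) {
  # drop matrices/vectors down to plain lists for YAML
  simplify <- function(x) {
    if (is.matrix(x)) {
      apply(x, 1, as.numeric, simplify = FALSE)
    } else if (is.list(x)) {
      lapply(x, simplify)
    } else {
      x
    }
  }
  yaml::write_yaml(simplify(unclass(config)), path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Orchestrates synthesis (or loading) of the kinematics ensemble, the
#' kinematic metric table, synthetic strain fields, per-element peak tables
#' and percentile summaries, curve- and element-level correlation heatmaps,
#' the location-effect tests, the helmet ranking with Kendall's Tau, and
#' the cross-metric correlation table. Results are written to
#' `config$out_dir` as delimited text, every file headed by a comment line
#' with the package version, seed and config hash; `config.yaml` and a
#' `run.log` (stage list plus element-exclusion counts) sit alongside.
#'
#' Any stage failure aborts with the stage name and the offending input id
#' in the condition message.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with all in-memory results (`records`,
#'   `metric_table`, `peak_tables`, `strain_summaries`, `full_table`,
#'   `curve_heatmaps`, `element_heatmaps`, `location_effects`, `ranking`,
#'   `kendall`, `metric_correlations`).
#' @export
run_full <- function(config) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  log_stage <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    message("[helmstrain] ", line)
  }
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(
        sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
        class = c("helmstrain_pipeline_error", class(e)[1], "helmstrain_error"),
        parent = e
      )
    })
  }
  serialize_config(config, file.path(out, "config.yaml"))

  records <- stage("kinematics", {
    if (!is.null(config$generator)) {
      log_stage("generating synthetic kinematics ensemble (seed %d)", config$seed)
      generate_kinematics_ensemble(config$generator)
    } else {
      log_stage("reading kinematics ensemble from %s", config$manifest_path)
      read_kinematics_ensemble(config$manifest_path)
    }
  })
  log_stage("kinematics: %d records", length(records))
  if (isTRUE(config$write_kinematics)) {
    stage("kinematics-io", write_kinematics_ensemble(
      records, file.path(out, "kinematics")
    ))
  }

  kin_tbl <- stage("metrics", metric_table(records, config$constants))
  write_result_csv(kin_tbl, file.path(out, "metric_table.csv"), config)
  log_stage("metric table: %d rows", nrow(kin_tbl))

  locations <- unique(vapply(records, function(r) attr(r, "location"), character(1)))
  curve_maps <- stage("curve-similarity", {
    setNames(
      lapply(locations, function(loc) curve_similarity_matrix(records, loc)),
      locations
    )
  })
  for (loc in locations) {
    write_heatmap_csv(
      curve_maps[[loc]],
      file.path(out, sprintf("heatmap_curve_%s.csv", loc)), config
    )
  }
  log_stage(
    "curve similarity: %d pair correlations",
    sum(vapply(curve_maps, function(m) choose(length(m$labels), 2), numeric(1)))
  )

  setup <- NULL
  peak_tables <- stage("strain", {
    if (is.null(config$generator)) {
      stop_data("no strain source configured (generator is NULL)")
    }
    setup <- strain_field_setup(config$generator)
    purrr::imap(records, function(rec, nm) {
      sim <- generate_strain_sim(rec, setup, config$generator)
      pt <- strain_peak_table(
        sim,
        realtime_fiber = config$fiber_convention == "realtime"
      )
      rm(sim)
      pt
    })
  })
  n_invalid <- sum(vapply(peak_tables, function(x) attr(x, "n_invalid"), numeric(1)))
  log_stage(
    "strain peaks: %d simulations x %d elements; %d invalid element(s) excluded",
    length(peak_tables), nrow(peak_tables[[1]]), n_invalid
  )

  summaries <- stage("strain-summaries", {
    purrr::map_dfr(peak_tables, strain_summary, q = config$q)
  })
  write_result_csv(summaries, file.path(out, "strain_summaries.csv"), config)

  element_maps <- stage("element-similarity", {
    maps <- list()
    for (loc in locations) {
      for (met in config$heatmap_metrics) {
        maps[[paste(met, loc, sep = "_")]] <-
          strain_similarity_matrix(peak_tables, loc, met)
      }
    }
    maps
  })
  for (nm in names(element_maps)) {
    write_heatmap_csv(
      element_maps[[nm]],
      file.path(out, sprintf("heatmap_element_%s.csv", nm)), config
    )
  }
  log_stage("element similarity: %d heatmaps", length(element_maps))

  loc_fx <- stage("location-effects", location_effect_test(summaries))
  write_result_csv(loc_fx, file.path(out, "location_effects.csv"), config)

  rk <- stage("ranking", helmet_ranking(summaries))
  write_result_csv(
    tidyr::pivot_wider(rk$ranks, names_from = metric, values_from = rank),
    file.path(out, "ranking.csv"), config
  )
  tau <- stage("kendall", kendall_tau_matrix(rk))
  write_result_csv(
    as_tibble(tau, rownames = "metric"),
    file.path(out, "kendall_tau.csv"), config
  )
  log_stage("ranking: %d helmets, tau range [%.2f, %.2f]",
    length(unique(rk$ranks$helmet_id)),
    min(tau[lower.tri(tau)]), max(tau[lower.tri(tau)])
  )

  full_tbl <- stage("metric-correlations", full_metric_table(kin_tbl, summaries))
  corr <- stage("metric-correlations", metric_correlations(full_tbl))
  write_result_csv(full_tbl, file.path(out, "full_metric_table.csv"), config)
  write_result_csv(corr, file.path(out, "metric_correlations.csv"), config)
  log_stage(
    "metric correlations: %d kinematic x strain, %d strain x strain",
    sum(corr$block == "kinematic_strain"), sum(corr$block == "strain_strain")
  )

  log_lines <- c(log_lines, sprintf("excluded elements: %d", n_invalid))
  writeLines(c(output_header(config), log_lines), file.path(out, "run.log"))

  invisible(list(
    records = records,
    metric_table = kin_tbl,
    peak_tables = peak_tables,
    strain_summaries = summaries,
    full_table = full_tbl,
    curve_heatmaps = curve_maps,
    element_heatmaps = element_maps,
    location_effects = loc_fx,
    ranking = rk,
    kendall = tau,
    metric_correlations = corr
  ))
}
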