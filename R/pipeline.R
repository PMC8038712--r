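# End-to-end orchestration: (simulate | load) -> preprocess -> per-region PCA
# -> ratios -> stats -> report. Driven by a single YAML/list configuration.

default_config <- function() {
  list(
    seed = 1L,
    alpha = 0.05,
    input = list(scenario = "coriell"),
    simulate = list(n_samples_per_group = 2L, replicates_per_sample = 3L,
                    grid_low = 600, grid_high = 4000, grid_spacing = 2,
                    noise_sd = 2e-4),
    preprocess = list(baseline = "rubberband", normalization = "area",
                      sg_half_width = 3L, sg_polyorder = 4L,
                      derivative_order = 2L,
                      regions = list(c(2800, 3000), c(1500, 1800), c(900, 1200))),
    pca = list(k = 4L, min_prominence = 0.1),
    stats = list(adjustment = "bonferroni", pool_replicates = TRUE,
                 control = NULL)
  )
}

merge_config <- function(base, user) {
  for (k in names(user)) {
    # "input" and "regions" are replaced wholesale, not key-merged: an input
    # source is exactly one of scenario / file paths.
    if (is.list(base[[k]]) && is.list(user[[k]]) && !k %in% c("regions", "input")) {
      base[[k]] <- merge_config(base[[k]], user[[k]])
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

read_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      abort("ftirfp_io_error", sprintf("config file not found: %s", config))
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("ftirfp_config_error", "config must be a list or a YAML path")
  config
}

#' Validate a pipeline configuration
#'
#' Checks key names, types, ranges, region bounds and Savitzky-Golay window
#' admissibility without running the pipeline. Unknown keys are hard errors
#' (no silent typos). Regions given in either order are normalized to
#' (low, high).
#'
#' @param config a configuration list or a YAML file path.
#' @return the merged, normalized configuration (invisibly usable by
#'   [run_pipeline()]); errors of class `ftirfp_config_error` describe every
#'   problem found.
#' @export
validate_config <- function(config) {
  user <- read_config(config)
  base <- default_config()
  problems <- character(0)
  check_keys <- function(u, b, prefix = "") {
    for (k in names(u)) {
      if (prefix == "" && k == "input") {
        bad <- setdiff(names(u[[k]]), .input_keys)
        if (length(bad) > 0) {
          problems <<- c(problems, sprintf("unknown config key: input.%s", bad))
        }
      } else if (!k %in% names(b)) {
        problems <<- c(problems, sprintf("unknown config key: %s%s", prefix, k))
      } else if (is.list(b[[k]]) && !is.null(names(b[[k]])) && is.list(u[[k]]) &&
                 k != "regions") {
        check_keys(u[[k]], b[[k]], paste0(prefix, k, "."))
      }
    }
  }
  check_keys(user, base)
  cfg <- merge_config(base, user)
  if (!is.numeric(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha >= 1) {
    problems <- c(problems, "alpha must be in (0, 1)")
  }
  src <- cfg$input
  has_scenario <- !is.null(src$scenario)
  has_files <- !is.null(src$spectra_csv)
  if (has_scenario == has_files) {
    problems <- c(problems,
                  "input must give exactly one of: scenario, spectra_csv")
  }
  if (has_scenario && !src$scenario %in% c("coriell", "neurolab", "null")) {
    problems <- c(problems, sprintf("unknown scenario '%s'", src$scenario))
  }
  pp <- cfg$preprocess
  if (pp$sg_half_width < 1) problems <- c(problems, "sg_half_width must be >= 1")
  if (2 * pp$sg_half_width + 1 <= pp$sg_polyorder) {
    problems <- c(problems, "SG window (2*half_width+1) must exceed sg_polyorder")
  }
  if (pp$derivative_order > pp$sg_polyorder) {
    problems <- c(problems, "derivative_order must be <= sg_polyorder")
  }
  cfg$preprocess$regions <- lapply(pp$regions, function(r) {
    r <- sort(as.numeric(unlist(r)))
    if (length(r) != 2 || r[1] >= r[2]) {
      problems <<- c(problems, "each region must be two distinct bounds")
    }
    r
  })
  if (cfg$simulate$noise_sd < 0) problems <- c(problems, "noise_sd must be >= 0")
  if (cfg$simulate$grid_spacing <= 0) problems <- c(problems, "grid_spacing must be > 0")
  if (cfg$pca$k < 1) problems <- c(problems, "pca k must be >= 1")
  if (length(problems) > 0) {
    abort("ftirfp_config_error",
          paste(c("invalid configuration:", paste("-", problems)), collapse = "\n"))
  }
  cfg
}

# Default input sub-config also accepts spectra_csv/metadata_csv keys.
.input_keys <- c("scenario", "spectra_csv", "metadata_csv")

#' Run the full analysis pipeline
#'
#' Input spectra come from exactly one of a synthetic scenario
#' ([default_profiles()]) or CSV paths. Stages: preprocessing
#' ([preprocess_pipeline()]), per-region PCA with side/quadrant/loading-peak
#' readouts, lipid intensity ratios, and the nonparametric statistical
#' battery. When `out_dir` is given, writes `report.json`, `spectra.csv`,
#' `ratios.csv`, `stats.csv`, one `pca_region_<lo>-<hi>.csv` per region, and
#' a `run.log` recording every preprocessing parameter applied. The report
#' content is deterministic for a fixed config and seed.
#'
#' @param config configuration list or YAML path; see [validate_config()].
#' @param out_dir optional output directory.
#' @return an `ftir_report` list: `provenance`, `regions` (per-region PCA
#'   summaries), `ratios`, `stats`, `alpha`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  cfg <- validate_config(config)
  seed <- as.integer(cfg$seed)
  truth <- NULL
  if (!is.null(cfg$input$scenario)) {
    sim_cfg <- default_profiles(
      cfg$input$scenario,
      n_samples_per_group = cfg$simulate$n_samples_per_group,
      replicates_per_sample = cfg$simulate$replicates_per_sample,
      grid_low = cfg$simulate$grid_low, grid_high = cfg$simulate$grid_high,
      grid_spacing = cfg$simulate$grid_spacing,
      noise_sd = cfg$simulate$noise_sd)
    sim <- simulate_cohort(sim_cfg, seed = seed)
    set <- sim$set; truth <- sim$truth
  } else {
    set <- read_spectra_csv(cfg$input$spectra_csv, cfg$input$metadata_csv)
  }
  pp_cfg <- preprocess_config(
    baseline = cfg$preprocess$baseline,
    normalization = cfg$preprocess$normalization,
    sg_half_width = cfg$preprocess$sg_half_width,
    sg_polyorder = cfg$preprocess$sg_polyorder,
    derivative_order = cfg$preprocess$derivative_order,
    regions = cfg$preprocess$regions)
  deriv <- preprocess_pipeline(set, pp_cfg)

  btab <- band_table()
  regions <- lapply(cfg$preprocess$regions, function(r) {
    reg <- select_region(deriv, r[1], r[2])
    k <- min(cfg$pca$k, n_spectra(reg) - 1L, length(reg$grid))
    pca <- spectra_pca(reg, k = k)
    sides <- lapply(seq_len(k), function(j) pc_side_separation(pca, j))
    disc <- which(vapply(sides, function(s) s$clean_separation, logical(1)))
    quad <- quadrant_assign(pca, 1L, min(2L, k))
    peaks <- lapply(seq_len(k), function(j) {
      pk <- loading_peaks(pca, j, cfg$pca$min_prominence)
      if (nrow(pk) > 0) {
        pk$assignment <- vapply(pk$wavenumber, function(w) {
          hit <- assign_band(w, btab)
          if (is.null(hit)) NA_character_ else hit$assignment
        }, character(1))
      }
      pk
    })
    list(region = r, explained_variance_pct = pca$explained_variance_pct,
         side_tables = lapply(sides, function(s) s$table),
         clean_separation_pcs = disc,
         quadrants = quad$group_summary,
         loading_peaks = peaks)
  })
  names(regions) <- vapply(cfg$preprocess$regions,
                           function(r) sprintf("%g-%g", r[1], r[2]), character(1))

  ratios <- compute_ratios(deriv)
  stats_tab <- ratio_stats(ratios, control = cfg$stats$control,
                           adjustment = cfg$stats$adjustment,
                           alpha = cfg$alpha,
                           pool_replicates = cfg$stats$pool_replicates)

  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA, null = "null")
  tf <- tempfile(fileext = ".json"); writeLines(cfg_json, tf)
  cfg_hash <- unname(tools::md5sum(tf)); unlink(tf)

  report <- structure(
    list(provenance = list(config = cfg, config_md5 = cfg_hash, seed = seed,
                           package_version = as.character(utils::packageVersion("ftirfp"))),
         regions = regions, ratios = ratios, stats = stats_tab,
         alpha = cfg$alpha, truth = truth),
    class = "ftir_report")

  if (!is.null(out_dir)) write_report(report, set, deriv, out_dir)
  report
}

write_report <- function(report, set, deriv, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_spectra_csv(set, file.path(out_dir, "spectra.csv"),
                    file.path(out_dir, "metadata.csv"))
  utils::write.csv(report$ratios, file.path(out_dir, "ratios.csv"), row.names = FALSE)
  utils::write.csv(report$stats, file.path(out_dir, "stats.csv"), row.names = FALSE)
  for (nm in names(report$regions)) {
    reg <- report$regions[[nm]]
    tabs <- do.call(rbind, lapply(seq_along(reg$side_tables), function(j) {
      cbind(pc = j, reg$side_tables[[j]])
    }))
    utils::write.csv(tabs, file.path(out_dir, sprintf("pca_region_%s.csv", nm)),
                     row.names = FALSE)
  }
  core <- report[c("provenance", "regions", "ratios", "stats", "alpha")]
  jsonlite::write_json(core, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       null = "null", na = "null", pretty = TRUE)
  pp <- report$provenance$config$preprocess
  log_lines <- c(
    sprintf("run at %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("seed: %d", report$provenance$seed),
    sprintf("baseline: %s", pp$baseline),
    sprintf("normalization: %s", pp$normalization),
    sprintf("sg_half_width: %d (window %d points)", pp$sg_half_width,
            2 * pp$sg_half_width + 1),
    sprintf("sg_polyorder: %d", pp$sg_polyorder),
    sprintf("derivative_order: %d", pp$derivative_order),
    sprintf("regions: %s", paste(vapply(pp$regions, function(r)
      sprintf("[%g, %g]", r[1], r[2]), character(1)), collapse = " ")),
    sprintf("alpha: %g", report$alpha),
    sprintf("config md5: %s", report$provenance$config_md5))
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' Structural validation of a pipeline report
#'
#' Checks the report against the committed structural schema
#' (`inst/extdata/report_schema.json`): required fields, p-values in [0, 1],
#' and that every reported loading-peak wavenumber lies on its region's grid
#' span.
#'
#' @param report an `ftir_report` from [run_pipeline()].
#' @return `TRUE` invisibly; errors of class `ftirfp_validation_error`
#'   otherwise.
#' @export
validate_report <- function(report) {
  need <- c("provenance", "regions", "ratios", "stats", "alpha")
  missing <- setdiff(need, names(report))
  if (length(missing) > 0) {
    abort("ftirfp_validation_error",
          sprintf("report lacks fields: %s", paste(missing, collapse = ", ")))
  }
  p <- report$stats$p_value
  p <- p[!is.na(p)]
  if (any(p < 0 | p > 1)) {
    abort("ftirfp_validation_error", "p-values outside [0, 1]")
  }
  for (nm in names(report$regions)) {
    reg <- report$regions[[nm]]
    for (pk in reg$loading_peaks) {
      if (nrow(pk) > 0 &&
          (any(pk$wavenumber < reg$region[1] - 1e-9) ||
           any(pk$wavenumber > reg$region[2] + 1e-9))) {
        abort("ftirfp_validation_error",
              sprintf("region %s reports a peak outside its bounds", nm))
      }
    }
  }
  invisible(TRUE)
}
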