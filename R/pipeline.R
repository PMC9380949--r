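#' Analysis configuration
#'
#' Bundles every path, window, threshold and seed the full pipeline needs.
#' All defaults that the analysis does not pin down scientifically
#' (percentile estimator, completeness threshold, QC thresholds, rose bins)
#' surface here so a run can state them explicitly; `seed` drives every
#' stochastic stage.
#'
#' @param records_dir Directory of per-site instrument CSVs named
#'   `<site_id>.csv`.
#' @param metadata Path to the site metadata CSV.
#' @param sst Optional path to an SST CSV (`date, grid_id, sst_c[, n_days]`).
#' @param window_start,window_end Common analysis window (UTC).
#' @param qc A [qc_config()].
#' @param min_completeness Daily completeness threshold.
#' @param n_perm Permutations for the variability tests.
#' @param seed Master seed.
#' @param n_sectors,speed_edges Rose/polar binning.
#' @param model_responses Daily responses to model (see [model_spec()]).
#' @param out_dir Output directory.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(records_dir, metadata, sst = NULL,
                            window_start, window_end,
                            qc = qc_config(), min_completeness = 0.8,
                            n_perm = 5000, seed = 1,
                            n_sectors = 12,
                            speed_edges = DEFAULT_SPEED_EDGES,
                            model_responses = c("speed_mean", "temp_mean"),
                            out_dir = "reefcurrents-output") {
  structure(list(records_dir = records_dir, metadata = metadata, sst = sst,
                 window_start = window_start, window_end = window_end,
                 qc = qc, min_completeness = min_completeness,
                 n_perm = n_perm, seed = seed, n_sectors = n_sectors,
                 speed_edges = speed_edges,
                 model_responses = model_responses, out_dir = out_dir),
            class = "analysis_config")
}

.read_meta <- function(path) {
  m <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("site_id", "reef_type", "deployment_start", "deployment_end")
  missing_cols <- setdiff(required, names(m))
  if (length(missing_cols)) {
    abort(paste0("metadata missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad <- setdiff(unique(m$reef_type), REEF_TYPES)
  if (length(bad)) abort(paste0("unknown reef_type: ", paste(bad, collapse = ", ")))
  dplyr::mutate(m,
    deployment_start = lubridate::as_datetime(.data$deployment_start, tz = "UTC"),
    deployment_end = lubridate::as_datetime(.data$deployment_end, tz = "UTC"))
}

#' Run the full reef-current analysis pipeline
#'
#' Ingest -> QC -> common-window standardisation -> hourly/daily
#' aggregation -> seasonal averages -> robust variability + permutation
#' tests -> group models -> rose/polar tables -> SST comparison, writing
#' every result as CSV under `config$out_dir` together with a JSON run
#' manifest (config snapshot, package version, per-stage row counts,
#' seeds). Identical config and seed reproduce byte-identical CSV outputs.
#'
#' @param config An [analysis_config()].
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  if (!file.exists(config$metadata)) {
    abort(paste0("metadata file not found: ", config$metadata))
  }
  meta <- .read_meta(config$metadata)
  paths <- file.path(config$records_dir, paste0(meta$site_id, ".csv"))
  missing_files <- paths[!file.exists(paths)]
  if (length(missing_files)) {
    abort(paste0("record file(s) not found: ",
                 paste(missing_files, collapse = ", ")))
  }
  if (!is.null(config$sst) && !file.exists(config$sst)) {
    abort(paste0("SST file not found: ", config$sst))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- list()
  note <- function(stage, rows) stages[[stage]] <<- rows
  emit <- function(df, name) {
    readr::write_csv(df, file.path(config$out_dir, paste0(name, ".csv")))
    note(name, nrow(df))
  }

  records <- purrr::map2_dfr(paths, meta$site_id, read_records)
  note("records_read", nrow(records))

  records <- apply_qc(records, meta, config$qc)
  emit(qc_report(records), "qc_report")

  records <- standardise_window(records, config$window_start, config$window_end)
  emit(attr(records, "coverage"), "window_coverage")

  daily <- daily_summaries(records, config$min_completeness)
  emit(daily, "daily_summaries")
  hourly <- hourly_means(records)
  emit(hourly, "hourly_means")

  emit(seasonal_daily_averages(daily, meta, "site"), "seasonal_site_averages")
  emit(seasonal_daily_averages(daily, meta, "reef_type"),
       "seasonal_reef_type_averages")

  by_type <- dplyr::left_join(daily,
                              dplyr::select(meta, "site_id", "reef_type"),
                              by = "site_id")
  disp <- purrr::map_dfr(split(by_type, by_type$reef_type),
                         function(d) dispersion_summary(d$speed_mean,
                                                        d$reef_type[1]))
  emit(disp, "dispersion_summaries")
  emit(pairwise_group_tests(by_type, "speed_mean", "reef_type",
                            n_perm = config$n_perm, seed = config$seed,
                            adjust = "holm"),
       "permutation_tests")

  for (resp in config$model_responses) {
    fit <- fit_group_model(daily, meta, model_spec(resp))
    emit(marginal_means(fit), paste0("model_", resp, "_means"))
    emit(pairwise_contrasts(fit), paste0("model_", resp, "_contrasts"))
  }

  emit(rose_table(hourly, config$n_sectors, config$speed_edges), "rose_table")
  emit(polar_temperature_table(hourly, config$n_sectors, config$speed_edges),
       "polar_temperature_table")

  if (!is.null(config$sst)) {
    sst <- readr::read_csv(config$sst, show_col_types = FALSE)
    cmp <- sst_offset(daily, sst)
    emit(cmp$pairs, "sst_pairs")
    emit(dplyr::bind_rows(
      dplyr::mutate(tidy(cmp), season = "annual"),
      dplyr::rename(cmp$by_season, estimate = "offset")),
      "sst_offset")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("reefcurrents")),
    generated_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    seed = config$seed,
    window = list(start = as.character(config$window_start),
                  end = as.character(config$window_end)),
    settings = list(min_completeness = config$min_completeness,
                    n_perm = config$n_perm,
                    percentile_method = "type7",
                    trim_hours = config$qc$trim_hours,
                    n_sectors = config$n_sectors),
    stage_rows = stages)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Write a small demonstration dataset
#'
#' Simulates a 3-site fleet (one site per reef archetype) at 1-minute
#' cadence over 60 days, plus an 8-day composite SST series, and writes the
#' instrument CSVs, metadata, SST and a ground-truth sidecar to `dir`.
#' Used by the examples, vignette and end-to-end tests.
#'
#' @param dir Output directory.
#' @param seed Master seed (default 42).
#' @param days Deployment length, days.
#' @param sampling_interval Cadence in seconds (default 60).
#' @return `dir`, invisibly.
#' @export
demo_dataset <- function(dir, seed = 42, days = 60, sampling_interval = 60) {
  start <- lubridate::as_datetime("2018-09-01", tz = "UTC")
  specs <- list(
    site_sim_spec("near_01", "nearshore_emergent",
                  archetype_regimes("nearshore_emergent")$speed,
                  archetype_regimes("nearshore_emergent")$direction,
                  archetype_regimes("nearshore_emergent")$thermal,
                  start - 6 * 3600, start + days * 86400 + 6 * 3600,
                  sampling_interval = sampling_interval),
    site_sim_spec("off_01", "offshore_emergent",
                  archetype_regimes("offshore_emergent")$speed,
                  archetype_regimes("offshore_emergent")$direction,
                  archetype_regimes("offshore_emergent")$thermal,
                  start - 6 * 3600, start + days * 86400 + 6 * 3600,
                  sampling_interval = sampling_interval),
    site_sim_spec("pin_01", "pinnacle",
                  archetype_regimes("pinnacle")$speed,
                  archetype_regimes("pinnacle")$direction,
                  archetype_regimes("pinnacle")$thermal,
                  start - 6 * 3600, start + days * 86400 + 6 * 3600,
                  sampling_interval = sampling_interval))
  fleet <- simulate_fleet(specs, seed)
  write_fleet(fleet, dir)
  insitu <- dplyr::bind_rows(fleet$records) |>
    dplyr::mutate(date = lubridate::as_date(.data$timestamp)) |>
    dplyr::group_by(.data$date) |>
    dplyr::summarise(temp_c = mean(.data$temp_c), .groups = "drop")
  sst <- simulate_sst(insitu, sst_sim_spec(offset_mean = 2.05, offset_sd = 0.3),
                      seed = seed + 1)
  readr::write_csv(sst, file.path(dir, "sst.csv"))
  invisible(dir)
}

#' Default analysis configuration for a [demo_dataset()] directory
#'
#' @param dir Directory written by [demo_dataset()].
#' @param out_dir Output directory for [run_full_analysis()].
#' @param ... Overrides passed to [analysis_config()].
#' @return An [analysis_config()].
#' @export
demo_config <- function(dir, out_dir = file.path(dir, "output"), ...) {
  meta <- .read_meta(file.path(dir, "metadata.csv"))
  analysis_config(
    records_dir = dir, metadata = file.path(dir, "metadata.csv"),
    sst = file.path(dir, "sst.csv"),
    window_start = min(meta$deployment_start) + 6 * 3600,
    window_end = max(meta$deployment_end) - 6 * 3600,
    n_perm = 999, out_dir = out_dir, ...)
}
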