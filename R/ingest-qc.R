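QC_FLAGS <- c("EDGE_TRIMMED", "RANGE_FAIL", "CONSISTENCY_FAIL")

#' QC configuration
#'
#' Thresholds for the record-level quality checks. The physical ranges
#' bracket everything a sub-surface tropical reef deployment plausibly
#' records (speed at 25-30 m stays well under 3 m s^-1; water temperature
#' between 20 and 40 degC); the spike check compares each sample with a
#' running median over `spike_window` samples (360 samples = 1 h at 10-s
#' cadence) and flags deviations beyond `spike_mad_threshold` running MADs.
#' All defaults are explicit package choices, configurable per run.
#'
#' @param trim_hours Hours trimmed at each end of the deployment (default 2).
#' @param speed_max Maximum plausible speed, m s^-1.
#' @param temp_range Length-2 plausible temperature range, degC.
#' @param spike_window Running-median window, samples (odd; even values are
#'   rounded up).
#' @param spike_mad_threshold Spike threshold in running-MAD units.
#' @param spike_floor Absolute floor (m s^-1) applied to the running MAD so
#'   that a smooth, locally noise-free signal does not make the spike
#'   threshold vanish; defaults to 1e-4, below any real drag-tilt
#'   measurement resolution.
#' @param flatline_span Minimum run length of exactly repeated speed values
#'   flagged as a stuck sensor, samples.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(trim_hours = 2, speed_max = 3.0,
                      temp_range = c(20, 40), spike_window = 360,
                      spike_mad_threshold = 10, spike_floor = 1e-4,
                      flatline_span = 360) {
  stopifnot(trim_hours >= 0, speed_max > 0, length(temp_range) == 2,
            temp_range[1] < temp_range[2], spike_window >= 3,
            spike_mad_threshold > 0, spike_floor >= 0, flatline_span > 1)
  structure(list(trim_hours = trim_hours, speed_max = speed_max,
                 temp_range = temp_range, spike_window = spike_window,
                 spike_mad_threshold = spike_mad_threshold,
                 spike_floor = spike_floor, flatline_span = flatline_span),
            class = "qc_config")
}

.ensure_flag_col <- function(records) {
  if (!"qc_flag" %in% names(records)) records$qc_flag <- ""
  records
}

#' Read an instrument record file
#'
#' Reads a current-meter CSV (`timestamp, speed_ms, direction_deg, temp_c`,
#' ISO 8601 timestamps treated as UTC), sorts chronologically, and reports —
#' rather than silently dropping — rows whose timestamp fails to parse.
#'
#' @param path CSV path.
#' @param site_id Site identifier attached to every record.
#' @return Tibble of records (`timestamp`, `site_id`, `speed_ms`,
#'   `direction_deg`, `temp_c`, `qc_flag` initialised to `""`), with an
#'   `n_malformed` attribute counting unparseable rows (excluded from the
#'   output).
#' @export
read_records <- function(path, site_id) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  required <- c("timestamp", "speed_ms", "direction_deg", "temp_c")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    abort(paste0("missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  ts <- lubridate::ymd_hms(raw$timestamp, tz = "UTC", quiet = TRUE)
  bad <- is.na(ts)
  out <- tibble::tibble(
    timestamp = ts[!bad],
    site_id = site_id,
    speed_ms = as.numeric(raw$speed_ms[!bad]),
    direction_deg = as.numeric(raw$direction_deg[!bad]),
    temp_c = as.numeric(raw$temp_c[!bad]),
    qc_flag = "") |>
    dplyr::arrange(.data$timestamp)
  attr(out, "n_malformed") <- sum(bad)
  out
}

#' Flag deployment-edge records
#'
#' Flags `EDGE_TRIMMED` every record within `trim_hours` of either end of
#' the site's deployment window, excluding the handling/surface-exposure
#' period from analysis. Boundaries are half-open: a record exactly
#' `trim_hours` after deployment start (or before end) is retained, so
#' exactly `trim_hours` hours are excluded at each end.
#'
#' @param records Record tibble (see [read_records()]).
#' @param meta One-row site metadata (needs `deployment_start`,
#'   `deployment_end`), or a multi-row table covering all sites present.
#' @param trim_hours Hours to trim (default 2).
#' @return `records` with `qc_flag` updated. Records are never dropped, only
#'   flagged.
#' @export
trim_deployment <- function(records, meta, trim_hours = 2) {
  records <- .ensure_flag_col(records)
  if (trim_hours == 0) return(records)
  meta <- dplyr::filter(meta, .data$site_id %in% unique(records$site_id))
  for (i in seq_len(nrow(meta))) {
    ds <- lubridate::as_datetime(meta$deployment_start[i], tz = "UTC")
    de <- lubridate::as_datetime(meta$deployment_end[i], tz = "UTC")
    if (as.numeric(difftime(de, ds, units = "hours")) < 2 * trim_hours) {
      abort(paste0("deployment window at ", meta$site_id[i],
                   " shorter than twice the trim span."))
    }
    sel <- records$site_id == meta$site_id[i] &
      (records$timestamp < ds + trim_hours * 3600 |
         records$timestamp > de - trim_hours * 3600)
    records$qc_flag[sel] <- "EDGE_TRIMMED"
  }
  records
}

#' Flag records outside physical measurement limits
#'
#' Flags `RANGE_FAIL` any record whose speed lies outside \[0, speed_max\],
#' direction outside \[0, 360), or temperature outside the configured range
#' — the "limits of each measurement" consistency check. Records already
#' flagged `EDGE_TRIMMED` keep that flag (precedence EDGE > RANGE >
#' CONSISTENCY, so the QC report partitions the records).
#'
#' @param records Record tibble.
#' @param cfg A [qc_config()].
#' @return `records` with `qc_flag` updated.
#' @export
range_check <- function(records, cfg = qc_config()) {
  records <- .ensure_flag_col(records)
  bad <- records$speed_ms < 0 | records$speed_ms > cfg$speed_max |
    records$direction_deg < 0 | records$direction_deg >= 360 |
    records$temp_c < cfg$temp_range[1] | records$temp_c > cfg$temp_range[2]
  bad[is.na(bad)] <- TRUE
  sel <- bad & records$qc_flag != "EDGE_TRIMMED"
  records$qc_flag[sel] <- "RANGE_FAIL"
  records
}

running_median <- function(x, k) {
  k <- min(k, length(x))
  if (k %% 2 == 0) k <- k + 1
  if (k > length(x)) k <- if (length(x) %% 2 == 0) length(x) - 1 else length(x)
  if (k < 3) return(x)
  as.numeric(stats::runmed(x, k, endrule = "median"))
}

#' Flag temporally inconsistent records
#'
#' Two checks for "abnormally high or low values and/or variability":
#' (1) spike check — a record whose speed deviates from the running median
#' by more than `spike_mad_threshold` times the running MAD (computed as a
#' running median of absolute deviations over the same window) is flagged
#' `CONSISTENCY_FAIL`; (2) flatline check — runs of exactly repeated speed
#' values longer than `flatline_span` samples are flagged (stuck sensor).
#' Near-constant stretches with zero running MAD are only flagged through
#' the flatline rule, not the spike rule.
#'
#' @param records Record tibble, chronologically sorted, single or multiple
#'   sites (checks run per site).
#' @param cfg A [qc_config()].
#' @return `records` with `qc_flag` updated (precedence preserved: only
#'   unflagged records can gain `CONSISTENCY_FAIL`).
#' @export
consistency_check <- function(records, cfg = qc_config()) {
  records <- .ensure_flag_col(records)
  for (id in unique(records$site_id)) {
    idx <- which(records$site_id == id)
    x <- records$speed_ms[idx]
    n <- length(x)
    if (n < 3) next
    med <- running_median(x, cfg$spike_window)
    dev <- abs(x - med)
    rmad <- pmax(running_median(dev, cfg$spike_window), cfg$spike_floor)
    spike <- dev > cfg$spike_mad_threshold * rmad
    r <- rle(x)
    flat <- inverse.rle(list(lengths = r$lengths,
                             values = r$lengths > cfg$flatline_span))
    bad <- (spike | flat) & records$qc_flag[idx] == ""
    records$qc_flag[idx][bad] <- "CONSISTENCY_FAIL"
  }
  records
}

#' Run the full QC sequence on a set of record tables
#'
#' Applies [trim_deployment()], [range_check()] and [consistency_check()] in
#' precedence order. QC only flags; no record is mutated or deleted, and
#' re-running QC on its own output changes nothing.
#'
#' @param records Record tibble (one or many sites).
#' @param meta Site metadata table.
#' @param cfg A [qc_config()].
#' @return Flagged record tibble.
#' @export
apply_qc <- function(records, meta, cfg = qc_config()) {
  records |>
    trim_deployment(meta, cfg$trim_hours) |>
    range_check(cfg) |>
    consistency_check(cfg)
}

#' Retained (QC-passing) view of a record table
#'
#' @param records Flagged record tibble.
#' @return Records whose `qc_flag` is empty.
#' @export
qc_passed <- function(records) {
  records <- .ensure_flag_col(records)
  dplyr::filter(records, .data$qc_flag == "")
}

#' Per-site QC accounting
#'
#' @param records Flagged record tibble.
#' @return Tibble with one row per site: `read`, `edge_trimmed`,
#'   `range_fail`, `consistency_fail`, `retained` (these partition `read`),
#'   and the retained window start/end. Flag precedence (EDGE > RANGE >
#'   CONSISTENCY) guarantees the partition.
#' @export
qc_report <- function(records) {
  records <- .ensure_flag_col(records)
  records |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(
      read = dplyr::n(),
      edge_trimmed = sum(.data$qc_flag == "EDGE_TRIMMED"),
      range_fail = sum(.data$qc_flag == "RANGE_FAIL"),
      consistency_fail = sum(.data$qc_flag == "CONSISTENCY_FAIL"),
      retained = sum(.data$qc_flag == ""),
      retained_start = suppressWarnings(min(.data$timestamp[.data$qc_flag == ""])),
      retained_end = suppressWarnings(max(.data$timestamp[.data$qc_flag == ""])),
      .groups = "drop")
}

#' Clip all sites to a common analysis window
#'
#' Restricts records to `[window_start, window_end)` so every site spans the
#' same annual analysis period, and reports per-site temporal coverage of
#' the window (fraction of the window overlapped by the site's record
#' span).
#'
#' @param records Record tibble (any number of sites).
#' @param window_start,window_end Window bounds (UTC, parseable).
#' @return Clipped tibble with a `coverage` attribute (tibble `site_id`,
#'   `coverage`). Errors, naming the site, if any site has no records inside
#'   the window.
#' @export
standardise_window <- function(records, window_start, window_end) {
  ws <- lubridate::as_datetime(window_start, tz = "UTC")
  we <- lubridate::as_datetime(window_end, tz = "UTC")
  if (we <= ws) abort("analysis window is empty.")
  sites <- unique(records$site_id)
  out <- dplyr::filter(records, .data$timestamp >= ws, .data$timestamp < we)
  missing <- setdiff(sites, unique(out$site_id))
  if (length(missing)) {
    abort(paste0("no records inside the analysis window for site(s): ",
                 paste(missing, collapse = ", ")))
  }
  cov <- out |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(
      coverage = as.numeric(difftime(max(.data$timestamp), min(.data$timestamp),
                                     units = "secs")) /
        as.numeric(difftime(we, ws, units = "secs")),
      .groups = "drop")
  attr(out, "coverage") <- cov
  out
}
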