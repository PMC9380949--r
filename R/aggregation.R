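#' Four-season tropical calendar
#'
#' Month-to-season mapping for a monsoonal tropical setting with no classic
#' four-season climate: Transitional Period 1 (`T1`, Sep-Nov), Wet Season
#' (`WET`, Dec-Feb), Transitional Period 2 (`T2`, Mar-May) and Windy Season
#' (`WINDY`, Jun-Aug). Every month maps to exactly one season; supply a
#' named vector to override.
#'
#' @param mapping Character vector of length 12, season per month 1..12.
#' @return Character vector of length 12 (class `season_calendar`).
#' @export
season_calendar <- function(mapping = NULL) {
  default <- c("WET", "WET", "T2", "T2", "T2", "WINDY",
               "WINDY", "WINDY", "T1", "T1", "T1", "WET")
  m <- mapping %||% default
  if (length(m) != 12 || any(is.na(m))) {
    abort("season calendar must assign all 12 months.")
  }
  structure(m, class = "season_calendar")
}

#' Assign seasons to dates
#'
#' @param dates Date (or coercible) vector.
#' @param calendar A [season_calendar()].
#' @return Character vector of season labels.
#' @examples
#' assign_season(as.Date("2018-12-15")) # "WET"
#' @export
assign_season <- function(dates, calendar = season_calendar()) {
  unname(calendar[lubridate::month(as.Date(dates))])
}

.infer_interval <- function(timestamps) {
  if (length(timestamps) < 2) return(NA_real_)
  median(diff(as.numeric(sort(timestamps))))
}

#' Daily summaries of QC-passed records
#'
#' Collapses high-frequency records into one row per site per UTC calendar
#' day: scalar mean/max/min of speed and temperature, the
#' magnitude-weighted vector-mean direction `theta_bar`, and the Yamartino
#' directional SD `sigma_theta` computed over all of the day's retained
#' samples. Days whose sample completeness (observed / expected samples at
#' the inferred or supplied cadence) falls below `min_completeness` are
#' omitted and counted in the `omitted_days` attribute.
#'
#' @param records Record tibble; rows with a non-empty `qc_flag` are
#'   excluded first.
#' @param min_completeness Minimum fraction of a day's expected samples
#'   (default 0.8).
#' @param sampling_interval Cadence in seconds; inferred from the data when
#'   NULL.
#' @param calendar A [season_calendar()].
#' @return Tibble: `site_id`, `date`, `season`, `speed_mean`, `speed_max`,
#'   `speed_min`, `temp_mean`, `temp_max`, `temp_min`, `theta_bar`,
#'   `sigma_theta`, `n_samples`, `completeness`; attribute `omitted_days`
#'   (tibble `site_id`, `n_omitted`).
#' @export
daily_summaries <- function(records, min_completeness = 0.8,
                            sampling_interval = NULL,
                            calendar = season_calendar()) {
  rec <- qc_passed(records)
  if (nrow(rec) == 0) abort("no QC-passed records.")
  # cadence is inferred per site: pooled multi-site series interleave
  intervals <- if (is.null(sampling_interval)) {
    rec |>
      dplyr::group_by(.data$site_id) |>
      dplyr::summarise(.interval = .infer_interval(.data$timestamp),
                       .groups = "drop")
  } else {
    tibble::tibble(site_id = unique(rec$site_id),
                   .interval = sampling_interval)
  }
  th <- rec$direction_deg * DEG2RAD
  rec <- rec |>
    dplyr::mutate(date = lubridate::as_date(.data$timestamp),
                  .u = .data$speed_ms * sin(th), .v = .data$speed_ms * cos(th),
                  .un = sin(th), .vn = cos(th))
  all_days <- rec |>
    dplyr::group_by(.data$site_id, .data$date) |>
    dplyr::summarise(
      speed_mean = mean(.data$speed_ms),
      speed_max = max(.data$speed_ms),
      speed_min = min(.data$speed_ms),
      temp_mean = mean(.data$temp_c),
      temp_max = max(.data$temp_c),
      temp_min = min(.data$temp_c),
      theta_bar = .theta_bar(mean(.data$.u), mean(.data$.v)),
      sigma_theta = .sigma_theta(mean(.data$.un), mean(.data$.vn)),
      n_samples = dplyr::n(),
      .groups = "drop") |>
    dplyr::left_join(intervals, by = "site_id") |>
    dplyr::mutate(completeness = pmin(1, .data$n_samples /
                                        (86400 / .data$.interval)),
                  season = assign_season(.data$date, calendar)) |>
    dplyr::select(-".interval") |>
    dplyr::relocate("season", .after = "date")
  keep <- all_days$completeness >= min_completeness
  omitted <- all_days[!keep, ] |>
    dplyr::count(.data$site_id, name = "n_omitted")
  out <- all_days[keep, ]
  attr(out, "omitted_days") <- omitted
  out
}

#' Hourly means of QC-passed records
#'
#' Calendar-hour bins (UTC) per site: scalar mean speed, vector-mean
#' direction, mean temperature. These hourly means are the inputs to the
#' current-rose and polar-temperature summaries.
#'
#' @param records Record tibble; flagged rows excluded.
#' @return Tibble: `site_id`, `hour` (POSIXct), `speed_mean`, `theta_bar`,
#'   `temp_mean`, `n_samples`. Hours with no retained samples produce no
#'   row.
#' @export
hourly_means <- function(records) {
  rec <- qc_passed(records)
  if (nrow(rec) == 0) abort("no QC-passed records.")
  th <- rec$direction_deg * DEG2RAD
  rec |>
    dplyr::mutate(hour = lubridate::floor_date(.data$timestamp, "hour"),
                  .u = .data$speed_ms * sin(th),
                  .v = .data$speed_ms * cos(th)) |>
    dplyr::group_by(.data$site_id, .data$hour) |>
    dplyr::summarise(
      speed_mean = mean(.data$speed_ms),
      theta_bar = .theta_bar(mean(.data$.u), mean(.data$.v)),
      temp_mean = mean(.data$temp_c),
      n_samples = dplyr::n(),
      .groups = "drop")
}

#' Annual and seasonal averages of daily summaries
#'
#' Averages daily means (and daily maxima/minima) within each season and
#' over the whole record (`season = "annual"`), grouped by site or by reef
#' type. For reef-type grouping two pooling rules are emitted, one row set
#' each: `"site_means"` (average of per-site averages — sites are the
#' replicates, matching the group-model logic; the default headline
#' numbers) and `"pooled"` (all days of the reef type weighted equally).
#' For site grouping the two coincide and only `"site_means"` is emitted.
#'
#' @param daily Output of [daily_summaries()].
#' @param meta Site metadata (needed for `grouping = "reef_type"`).
#' @param grouping `"site"` or `"reef_type"`.
#' @return Tibble: `group`, `season` (four seasons plus `"annual"`),
#'   `pooling`, `speed_mean`, `speed_max`, `speed_min`, `temp_mean`,
#'   `temp_max`, `temp_min`, `n_days` (days contributing; for
#'   `"site_means"` the total across sites).
#' @export
seasonal_daily_averages <- function(daily, meta = NULL,
                                    grouping = c("site", "reef_type")) {
  grouping <- match.arg(grouping)
  d <- daily
  if (grouping == "reef_type") {
    if (is.null(meta)) abort("`meta` is required for reef_type grouping.")
    d <- dplyr::left_join(d, dplyr::select(meta, "site_id", "reef_type"),
                          by = "site_id")
    d$group <- d$reef_type
  } else {
    d$group <- d$site_id
  }
  with_annual <- dplyr::bind_rows(d, dplyr::mutate(d, season = "annual"))
  vars <- c("speed_mean", "speed_max", "speed_min",
            "temp_mean", "temp_max", "temp_min")
  pooled <- with_annual |>
    dplyr::group_by(.data$group, .data$season) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(vars), mean),
                     n_days = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(pooling = "pooled")
  site_means <- with_annual |>
    dplyr::group_by(.data$group, .data$season, .data$site_id) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(vars), mean),
                     n_days = dplyr::n(), .groups = "drop") |>
    dplyr::group_by(.data$group, .data$season) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(vars), mean),
                     n_days = sum(.data$n_days), .groups = "drop") |>
    dplyr::mutate(pooling = "site_means")
  out <- if (grouping == "site") site_means else
    dplyr::bind_rows(site_means, pooled)
  dplyr::relocate(out, "pooling", .after = "season")
}
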