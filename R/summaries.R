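DEFAULT_SPEED_EDGES <- c(0, 0.1, 0.2, 0.3, 0.4, Inf)

.dir_sector <- function(theta, n_sectors) {
  w <- 360 / n_sectors
  floor(((theta + w / 2) %% 360) / w)
}

.speed_bin_labels <- function(edges) {
  lo <- head(edges, -1); hi <- tail(edges, -1)
  ifelse(is.infinite(hi), paste0(">=", lo), paste0("[", lo, ",", hi, ")"))
}

.bin_hourly <- function(hourly, n_sectors, speed_edges) {
  labels <- .speed_bin_labels(speed_edges)
  hourly |>
    dplyr::filter(!is.na(.data$theta_bar)) |>
    dplyr::mutate(
      dir_bin_center = .dir_sector(.data$theta_bar, n_sectors) * (360 / n_sectors),
      speed_bin = as.character(cut(.data$speed_mean, speed_edges,
                                   labels = labels, right = FALSE)))
}

#' Current-rose frequency table
#'
#' The numeric backbone of a current-rose plot: for each site, the
#' percentage of hourly mean currents falling in each direction sector x
#' speed class cell, plus the site's net heading (magnitude-weighted vector
#' average of the hourly means over the whole period). Sectors are
#' `n_sectors` equal arcs with the first centred on north, so with 12
#' sectors a heading of 14.9 degrees falls in the north sector
#' \[-15, 15).
#'
#' @param hourly Output of [hourly_means()].
#' @param n_sectors Number of direction sectors (default 12, 30-degree
#'   arcs).
#' @param speed_edges Ascending speed class edges in m s^-1; the last class
#'   is open-ended (default `c(0, 0.1, 0.2, 0.3, 0.4, Inf)`).
#' @return Tibble of class `reef_rose_table`, one row per site x sector x
#'   speed class (zero cells included): `site_id`, `dir_bin_center`,
#'   `speed_bin`, `percent`, `n`, `net_heading`. Percentages sum to 100
#'   within each site.
#' @export
rose_table <- function(hourly, n_sectors = 12,
                       speed_edges = DEFAULT_SPEED_EDGES) {
  if (nrow(hourly) == 0) abort("`hourly` must be non-empty.")
  binned <- .bin_hourly(hourly, n_sectors, speed_edges)
  labels <- .speed_bin_labels(speed_edges)
  grid <- tidyr::expand_grid(
    site_id = unique(binned$site_id),
    dir_bin_center = (0:(n_sectors - 1)) * (360 / n_sectors),
    speed_bin = labels)
  counts <- binned |>
    dplyr::count(.data$site_id, .data$dir_bin_center, .data$speed_bin)
  net <- binned |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(
      net_heading = vector_average(.data$speed_mean, .data$theta_bar)$theta_bar,
      total = dplyr::n(), .groups = "drop")
  out <- grid |>
    dplyr::left_join(counts, by = c("site_id", "dir_bin_center", "speed_bin")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L)) |>
    dplyr::left_join(net, by = "site_id") |>
    dplyr::mutate(percent = 100 * .data$n / .data$total) |>
    dplyr::select("site_id", "dir_bin_center", "speed_bin", "percent", "n",
                  "net_heading") |>
    dplyr::arrange(.data$site_id, .data$dir_bin_center, .data$speed_bin)
  class(out) <- c("reef_rose_table", class(out))
  out
}

#' Direction x speed mean-temperature table
#'
#' Polar-plot backbone: mean temperature of the hourly means contributing
#' to each direction sector x speed class cell. Only populated cells are
#' returned — an empty cell carries no temperature.
#'
#' @inheritParams rose_table
#' @return Tibble of class `reef_polar_table`: `site_id`,
#'   `dir_bin_center`, `speed_bin`, `mean_temp`, `n`. Empty input gives an
#'   empty table.
#' @export
polar_temperature_table <- function(hourly, n_sectors = 12,
                                    speed_edges = DEFAULT_SPEED_EDGES) {
  if (nrow(hourly) == 0) {
    out <- tibble::tibble(site_id = character(), dir_bin_center = numeric(),
                          speed_bin = character(), mean_temp = numeric(),
                          n = integer())
    class(out) <- c("reef_polar_table", class(out))
    return(out)
  }
  out <- .bin_hourly(hourly, n_sectors, speed_edges) |>
    dplyr::group_by(.data$site_id, .data$dir_bin_center, .data$speed_bin) |>
    dplyr::summarise(mean_temp = mean(.data$temp_mean), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::arrange(.data$site_id, .data$dir_bin_center, .data$speed_bin)
  class(out) <- c("reef_polar_table", class(out))
  out
}

#' In-situ versus satellite SST offset
#'
#' Pairs in-situ daily mean sub-surface temperatures with a composite
#' satellite SST series and estimates the systematic offset (in-situ minus
#' SST; positive when the loggers run warmer). With `alignment = "expand"`
#' (default) each composite SST value is expanded to its member days and
#' paired with every in-situ day it covers; with `"collapse"` the in-situ
#' series is averaged into the composite windows and paired once per
#' window. The offset CI is a t-interval on the paired differences; daily
#' differences are autocorrelated, so the interval is optimistic — an
#' optional weekly block bootstrap is available via `ci = "block"`.
#'
#' @param daily Output of [daily_summaries()]; in-situ temperatures are the
#'   across-site mean of `temp_mean` per date.
#' @param sst Tibble with columns `date` (composite window start), `sst_c`
#'   and optionally `n_days` (window length in days; inferred from date
#'   spacing otherwise).
#' @param alignment `"expand"` or `"collapse"`.
#' @param ci `"t"` (default) or `"block"` (weekly block bootstrap, 2000
#'   resamples).
#' @param level Confidence level.
#' @param seed RNG seed for the block bootstrap.
#' @return Object of class `reef_sst_comparison`: list with `pairs` (tibble
#'   `date`, `insitu`, `sst`, `diff`), `offset`, `lower`, `upper`, `n`,
#'   `alignment`, and `by_season` (tibble of per-season offsets).
#' @export
sst_offset <- function(daily, sst, alignment = c("expand", "collapse"),
                       ci = c("t", "block"), level = 0.95, seed = 1) {
  alignment <- match.arg(alignment)
  ci <- match.arg(ci)
  insitu <- daily |>
    dplyr::group_by(.data$date) |>
    dplyr::summarise(insitu = mean(.data$temp_mean), .groups = "drop")
  sst <- dplyr::arrange(sst, .data$date)
  len <- if ("n_days" %in% names(sst)) sst$n_days else {
    gaps <- diff(as.numeric(sst$date))
    rep_len(c(gaps, if (length(gaps)) median(gaps) else 1), nrow(sst))
  }
  if (alignment == "expand") {
    expanded <- tibble::tibble(
      date = sst$date[rep(seq_len(nrow(sst)), len)] +
        unlist(lapply(len, function(k) seq_len(k) - 1)),
      sst = rep(sst$sst_c, len))
    pairs <- dplyr::inner_join(insitu, expanded, by = "date")
  } else {
    win_start <- sst$date[rep(seq_len(nrow(sst)), len)] # member-day lookup
    member <- tibble::tibble(
      date = win_start + unlist(lapply(len, function(k) seq_len(k) - 1)),
      window = win_start)
    pairs <- insitu |>
      dplyr::inner_join(member, by = "date") |>
      dplyr::group_by(.data$window) |>
      dplyr::summarise(insitu = mean(.data$insitu), .groups = "drop") |>
      dplyr::rename(date = "window") |>
      dplyr::inner_join(dplyr::select(sst, "date", sst = "sst_c"),
                        by = "date")
  }
  if (nrow(pairs) == 0) abort("no overlapping dates between in-situ and SST.")
  pairs <- dplyr::mutate(pairs, diff = .data$insitu - .data$sst)
  est <- mean(pairs$diff)
  n <- nrow(pairs)
  if (ci == "t" || n < 3) {
    se <- sd(pairs$diff) / sqrt(n)
    tq <- qt(1 - (1 - level) / 2, n - 1)
    lo <- est - tq * se; hi <- est + tq * se
  } else {
    set.seed(as.integer(seed %% .Machine$integer.max))
    blk <- split(pairs$diff, floor(as.numeric(pairs$date - min(pairs$date)) / 7))
    boots <- replicate(2000, mean(unlist(
      sample(blk, length(blk), replace = TRUE))))
    qs <- quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
    lo <- qs[1]; hi <- qs[2]
  }
  by_season <- pairs |>
    dplyr::mutate(season = assign_season(.data$date)) |>
    dplyr::group_by(.data$season) |>
    dplyr::summarise(offset = mean(.data$diff), n = dplyr::n(),
                     .groups = "drop")
  structure(list(pairs = pairs, offset = est, lower = lo, upper = hi,
                 n = n, alignment = alignment, by_season = by_season),
            class = "reef_sst_comparison")
}

#' @export
print.reef_sst_comparison <- function(x, ...) {
  cat(sprintf(
    "In-situ minus satellite SST offset: %.2f degC (95%% CI %.2f-%.2f), %d paired %s\n",
    x$offset, x$lower, x$upper, x$n,
    if (x$alignment == "expand") "days" else "composite windows"))
  invisible(x)
}

#' @rdname sst_offset
#' @param x A `reef_sst_comparison`.
#' @param ... Unused.
#' @export
tidy.reef_sst_comparison <- function(x, ...) {
  tibble::tibble(estimate = x$offset, lower = x$lower, upper = x$upper,
                 n = x$n, alignment = x$alignment)
}
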