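test_that("the four-season calendar partitions the year", {
  expect_equal(assign_season(as.Date("2018-12-15")), "WET")
  expect_equal(assign_season(as.Date("2019-03-01")), "T2")
  expect_equal(assign_season(as.Date("2018-09-30")), "T1")
  expect_equal(assign_season(as.Date("2019-06-01")), "WINDY")
  days <- seq(as.Date("2018-09-01"), as.Date("2019-08-31"), by = "day")
  seasons <- assign_season(days)
  expect_false(anyNA(seasons))
  expect_setequal(unique(seasons), c("T1", "WET", "T2", "WINDY"))
  expect_error(season_calendar(c("T1", "WET")), "12 months")
})

test_that("daily summaries aggregate scalar and circular fields per day", {
  rec <- make_records(start = "2018-09-01 00:00:00", n = 2 * 8640, by = 10,
                      speed = rep(c(0.02, 0.08), 8640),
                      direction = 45, temp = 30)
  d <- daily_summaries(rec, sampling_interval = 10)
  expect_equal(nrow(d), 2)
  expect_equal(d$speed_mean, c(0.05, 0.05))
  expect_equal(d$speed_max, c(0.08, 0.08))
  expect_equal(d$speed_min, c(0.02, 0.02))
  expect_equal(d$n_samples, c(8640L, 8640L))
  expect_equal(d$completeness, c(1, 1))
  expect_equal(d$theta_bar, c(45, 45))
  expect_equal(d$sigma_theta, c(0, 0))
  expect_equal(d$season, c("T1", "T1"))
})

test_that("incomplete days are omitted and counted", {
  full <- make_records(start = "2018-09-01", n = 8640, by = 10)
  half <- make_records(start = "2018-09-02", n = 4320, by = 10)
  d <- daily_summaries(dplyr::bind_rows(full, half), min_completeness = 0.8,
                       sampling_interval = 10)
  expect_equal(as.character(d$date), "2018-09-01")
  omitted <- attr(d, "omitted_days")
  expect_equal(omitted$n_omitted, 1L)
})

test_that("daily direction uses vector averaging across the north wrap", {
  rec <- make_records(n = 100, by = 10, direction = rep(c(359, 1), 50))
  d <- daily_summaries(rec, min_completeness = 0, sampling_interval = 10)
  wrap_dist <- min(d$theta_bar, 360 - d$theta_bar)
  expect_lt(wrap_dist, 1e-6) # 0 (mod 360), not the arithmetic 180
})

test_that("hourly means bin by calendar hour per site without mixing", {
  rec <- dplyr::bind_rows(
    make_records(start = "2018-09-01 00:00:00", n = 720, by = 10,
                 site_id = "a", speed = 0.04),
    make_records(start = "2018-09-01 00:00:00", n = 360, by = 10,
                 site_id = "b", speed = 0.10))
  h <- hourly_means(rec)
  expect_equal(nrow(h), 3) # a: 2 hours, b: 1 hour
  expect_equal(h$n_samples, c(360L, 360L, 360L))
  expect_equal(h$speed_mean[h$site_id == "b"], 0.10)
  expect_equal(sort(unique(h$site_id)), c("a", "b"))
})

test_that("aggregation is invariant to record order", {
  set.seed(13)
  rec <- make_records(n = 500, by = 180,
                      speed = rgamma(500, 2, scale = 0.04),
                      direction = runif(500, 0, 360))
  shuffled <- rec[sample.int(500), ]
  expect_equal(daily_summaries(rec, min_completeness = 0,
                               sampling_interval = 180),
               daily_summaries(shuffled, min_completeness = 0,
                               sampling_interval = 180),
               ignore_attr = TRUE)
})

test_that("seasonal averages pool per the two documented rules", {
  days <- seq(as.Date("2018-12-01"), as.Date("2019-01-30"), by = "day")
  daily <- dplyr::bind_rows(
    tibble::tibble(site_id = "a", date = days, speed_mean = 0.04),
    tibble::tibble(site_id = "b", date = days, speed_mean = 0.06)) |>
    dplyr::mutate(season = assign_season(date),
                  speed_max = speed_mean, speed_min = speed_mean,
                  temp_mean = 30, temp_max = 30, temp_min = 30)
  meta <- dplyr::bind_rows(meta_row("a", "pinnacle"), meta_row("b", "pinnacle"))
  out <- seasonal_daily_averages(daily, meta, "reef_type")
  ann_site <- out[out$season == "annual" & out$pooling == "site_means", ]
  ann_pool <- out[out$season == "annual" & out$pooling == "pooled", ]
  expect_equal(ann_site$speed_mean, 0.05) # equal days: both rules agree
  expect_equal(ann_pool$speed_mean, 0.05)
  expect_true(all(out$season %in% c("annual", "WET")))
  # seasonal n_days sum to the annual n_days within each pooling rule
  for (p in c("site_means", "pooled")) {
    sub <- out[out$pooling == p, ]
    expect_equal(sum(sub$n_days[sub$season != "annual"]),
                 sub$n_days[sub$season == "annual"])
  }
  # unbalanced days separate the two rules
  daily2 <- daily[-(1:30), ] # site a loses its December
  out2 <- seasonal_daily_averages(daily2, meta, "reef_type")
  ann2 <- out2[out2$season == "annual", ]
  expect_equal(ann2$speed_mean[ann2$pooling == "site_means"], 0.05)
  expect_gt(ann2$speed_mean[ann2$pooling == "pooled"], 0.05)
})
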