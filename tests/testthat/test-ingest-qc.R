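write_fixture_csv <- function(df, path) {
  readr::write_csv(df, path)
  path
}

test_that("record files are read, sorted and malformed rows reported", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  df <- tibble::tibble(
    timestamp = c("2018-09-01T02:00:00Z", "2018-09-01T00:00:00Z",
                  "2018-09-01T01:00:00Z"),
    speed_ms = c(0.3, 0.1, 0.2), direction_deg = c(10, 20, 30),
    temp_c = c(30, 30, 30))
  write_fixture_csv(df, tmp)
  rec <- read_records(tmp, "s1")
  expect_equal(nrow(rec), 3)
  expect_equal(rec$speed_ms, c(0.1, 0.2, 0.3)) # chronological
  expect_equal(attr(rec, "n_malformed"), 0)

  df$timestamp[2] <- "not-a-time"
  write_fixture_csv(df, tmp)
  rec2 <- read_records(tmp, "s1")
  expect_equal(nrow(rec2), 2)
  expect_equal(attr(rec2, "n_malformed"), 1)

  write_fixture_csv(df[, -2], tmp)
  expect_error(read_records(tmp, "s1"), "speed_ms")
  expect_error(read_records(file.path(tempdir(), "nope.csv"), "s1"),
               "no such file")
})

test_that("deployment trimming is half-open at exactly trim_hours", {
  meta <- meta_row(start = "2018-09-01 00:00:00", end = "2018-09-02 00:00:00")
  rec <- make_records(start = "2018-09-01 00:00:00", n = 49, by = 1800)
  rec$timestamp[2] <- utc("2018-09-01 00:30:00")
  out <- trim_deployment(rec, meta, 2)
  flagged <- out$qc_flag == "EDGE_TRIMMED"
  # < start + 2h flagged; exactly start + 2h retained
  expect_true(all(flagged[out$timestamp < utc("2018-09-01 02:00:00")]))
  expect_false(flagged[out$timestamp == utc("2018-09-01 02:00:00")])
  # > end - 2h flagged; exactly end - 2h retained
  expect_false(flagged[out$timestamp == utc("2018-09-01 22:00:00")])
  expect_true(all(flagged[out$timestamp > utc("2018-09-01 22:00:00")]))
  expect_identical(trim_deployment(rec, meta, 0)$qc_flag, rec$qc_flag)
  short_meta <- meta_row(start = "2018-09-01 00:00:00",
                         end = "2018-09-01 03:00:00")
  expect_error(trim_deployment(rec, short_meta, 2), "shorter")
})

test_that("range check flags out-of-limit values with edge precedence", {
  rec <- make_records(n = 6)
  rec$speed_ms[1] <- -0.01
  rec$direction_deg[2] <- 361
  rec$direction_deg[3] <- 359.9
  rec$temp_c[4] <- 45
  rec$qc_flag[5] <- "EDGE_TRIMMED"
  rec$speed_ms[5] <- -1 # edge flag wins
  out <- range_check(rec)
  expect_equal(out$qc_flag,
               c("RANGE_FAIL", "RANGE_FAIL", "", "RANGE_FAIL",
                 "EDGE_TRIMMED", ""))
})

test_that("consistency check flags spikes but not smooth signal", {
  n <- 600
  rec <- make_records(n = n, by = 10,
                      speed = 0.05 + 0.01 * sin(seq_len(n) / 40))
  clean <- consistency_check(rec, qc_config(spike_window = 61,
                                            spike_mad_threshold = 10))
  expect_equal(sum(clean$qc_flag != ""), 0)
  rec$speed_ms[300] <- 0.05 * 50
  spiked <- consistency_check(rec, qc_config(spike_window = 61,
                                             spike_mad_threshold = 10))
  expect_equal(which(spiked$qc_flag == "CONSISTENCY_FAIL"), 300)
})

test_that("flatlined runs longer than the span are flagged; short ones are not", {
  rec <- make_records(n = 500, by = 10, speed = 0.05)
  rec$speed_ms <- 0.04 + 0.001 * (seq_len(500) %% 7)
  rec$speed_ms[100:220] <- 0.05 # 121-sample flatline
  out <- consistency_check(rec, qc_config(spike_window = 31,
                                          flatline_span = 100))
  expect_true(all(out$qc_flag[100:220] == "CONSISTENCY_FAIL"))
  short <- make_records(n = 50, by = 10, speed = 0.05)
  out2 <- consistency_check(short, qc_config(spike_window = 31,
                                             flatline_span = 100))
  expect_equal(sum(out2$qc_flag != ""), 0)
})

test_that("QC is idempotent, non-destructive, and its report partitions reads", {
  spec <- quiet_spec(edge_hours = 2, start = "2018-09-01", end = "2018-09-04",
                     interval = 60)
  rec <- simulate_site(spec, 11)
  rec$qc_flag <- ""
  rec$direction_deg[2000] <- 380 # mid-deployment range failure
  meta <- meta_row(start = "2018-09-01", end = "2018-09-04")
  cfg <- qc_config(spike_window = 61)
  once <- apply_qc(rec, meta, cfg)
  twice <- apply_qc(once, meta, cfg)
  expect_identical(once, twice)
  expect_equal(nrow(once), nrow(rec)) # flag-only, never drop
  rep <- qc_report(once)
  expect_equal(rep$read,
               rep$edge_trimmed + rep$range_fail + rep$consistency_fail +
                 rep$retained)
  expect_equal(rep$read, nrow(rec))
  expect_gt(rep$edge_trimmed, 0)
  expect_gt(rep$range_fail, 0)
})

test_that("window standardisation clips, reports coverage, and names absent sites", {
  rec <- dplyr::bind_rows(
    make_records(start = "2018-09-01", n = 14 * 24, by = 3600, site_id = "a"),
    make_records(start = "2018-09-08", n = 7 * 24, by = 3600, site_id = "b"))
  out <- standardise_window(rec, "2018-09-03", "2018-09-10")
  expect_true(all(out$timestamp >= utc("2018-09-03")))
  expect_true(all(out$timestamp < utc("2018-09-10")))
  cov <- attr(out, "coverage")
  expect_equal(cov$coverage[cov$site_id == "a"], 1, tolerance = 0.01)
  expect_equal(cov$coverage[cov$site_id == "b"], 2 / 7, tolerance = 0.03)
  expect_error(standardise_window(rec, "2020-01-01", "2020-02-01"),
               "a, b")
  expect_error(standardise_window(rec, "2018-09-10", "2018-09-03"), "empty")
})
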