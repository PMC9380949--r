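test_that("degenerate regimes collapse to near-constant series", {
  spec <- site_sim_spec(
    "s1", "pinnacle",
    speed = speed_regime(1e6, 0.05 / 1e6),     # variance -> 0 at mean 0.05
    direction = direction_regime(90, Inf),
    thermal = thermal_regime(30),
    deployment_start = "2018-09-01", deployment_end = "2018-09-02",
    sampling_interval = 600, edge_artifact_hours = 0)
  rec <- simulate_site(spec, 1)
  expect_equal(nrow(rec), 144)
  expect_true(all(abs(rec$speed_ms - 0.05) < 1e-3))
  expect_true(all(rec$direction_deg == 90))
  expect_true(all(rec$temp_c == 30))
})

test_that("gamma marginal mean is recovered within 3 SE", {
  spec <- site_sim_spec(
    "s1", "pinnacle",
    speed = speed_regime(2, 0.04), # mean 0.08, sd sqrt(2)*0.04
    direction = direction_regime(0, 0),
    thermal = thermal_regime(30),
    deployment_start = "2018-09-01", deployment_end = "2018-09-13",
    sampling_interval = 10, edge_artifact_hours = 0)
  rec <- simulate_site(spec, 2)
  n <- nrow(rec)
  expect_gte(n, 1e5)
  se <- sqrt(2) * 0.04 / sqrt(n) # iid draws (ar1 = 0)
  expect_lt(abs(mean(rec$speed_ms) - 0.08), 3 * se)
})

test_that("a concentrated direction component recovers its location", {
  spec <- quiet_spec(interval = 60, start = "2018-09-01", end = "2018-09-08")
  spec$direction <- direction_regime(330, 50)
  rec <- simulate_site(spec, 3)
  va <- vector_average(rep(1, nrow(rec)), rec$direction_deg)
  expect_lt(min(abs(va$theta_bar - 330), 360 - abs(va$theta_bar - 330)), 2)
})

test_that("simulation is deterministic and seed-sensitive", {
  spec <- quiet_spec()
  a <- simulate_site(spec, 99)
  b <- simulate_site(spec, 99)
  c <- simulate_site(spec, 100)
  expect_identical(a, b)
  expect_false(identical(a$speed_ms, c$speed_ms))
})

test_that("pulses multiply speeds only inside their windows", {
  spec <- quiet_spec(start = "2018-09-01", end = "2018-10-01", interval = 600)
  spec$speed <- speed_regime(2, 0.04, ar1_coeff = 0, pulse_rate = 0.5,
                             pulse_multiplier = 3, pulse_duration = 2)
  rec <- simulate_site(spec, 8)
  gt <- attr(rec, "ground_truth")
  expect_gt(nrow(gt$pulse_windows), 0)
  in_pulse <- rep(FALSE, nrow(rec))
  for (i in seq_len(nrow(gt$pulse_windows))) {
    in_pulse <- in_pulse | (rec$timestamp >= gt$pulse_windows$start[i] &
                              rec$timestamp < gt$pulse_windows$end[i])
  }
  # identical seed with pulses disabled isolates the multiplier
  spec0 <- spec
  spec0$speed <- speed_regime(2, 0.04)
  base <- simulate_site(spec0, 8)
  expect_equal(rec$speed_ms[in_pulse], 3 * base$speed_ms[in_pulse])
  expect_equal(rec$speed_ms[!in_pulse], base$speed_ms[!in_pulse])
})

test_that("edge artifacts perturb exactly the flagged windows", {
  spec <- quiet_spec(edge_hours = 2, start = "2018-09-01", end = "2018-09-05")
  rec <- simulate_site(spec, 5)
  gt <- attr(rec, "ground_truth")
  expect_equal(nrow(gt$edge_windows), 2)
  spec0 <- quiet_spec(edge_hours = 0, start = "2018-09-01", end = "2018-09-05")
  base <- simulate_site(spec0, 5)
  in_edge <- rec$timestamp < gt$edge_windows$end[1] |
    rec$timestamp >= gt$edge_windows$start[2]
  expect_equal(sum(in_edge), 2 * 2 * 6) # 2 ends x 2 h x 6 samples/h
  expect_true(all(rec$speed_ms[in_edge] > base$speed_ms[in_edge]))
  expect_equal(rec$speed_ms[!in_edge], base$speed_ms[!in_edge])
})

test_that("fleet simulation produces per-site series and metadata", {
  specs <- list(quiet_spec("a", "pinnacle"),
                quiet_spec("b", "offshore_emergent"),
                quiet_spec("c", "nearshore_emergent"))
  fleet <- simulate_fleet(specs, 4)
  expect_named(fleet$records, c("a", "b", "c"))
  expect_equal(nrow(fleet$meta), 3)
  expect_setequal(fleet$meta$reef_type,
                  c("pinnacle", "offshore_emergent", "nearshore_emergent"))
  fleet2 <- simulate_fleet(specs, 4)
  expect_identical(fleet$records, fleet2$records)
  # distinct sub-seeds: sites differ from each other
  expect_false(identical(fleet$records$a$speed_ms, fleet$records$b$speed_ms))
  expect_error(simulate_fleet(list(quiet_spec("a"), quiet_spec("a")), 1),
               "duplicate")
})

test_that("the 11-site study design yields 11 series", {
  specs <- archetype_fleet(deployment_start = "2018-09-01",
                           deployment_end = "2018-09-02",
                           sampling_interval = 3600,
                           edge_artifact_hours = 0)
  expect_length(specs, 11)
  fleet <- simulate_fleet(specs, 1)
  expect_length(fleet$records, 11)
  expect_equal(sum(fleet$meta$reef_type == "pinnacle"), 3)
  expect_equal(sum(fleet$meta$reef_type == "nearshore_emergent"), 4)
})

test_that("SST simulation applies the offset per composite window", {
  daily <- tibble::tibble(date = as.Date("2018-09-01") + 0:79,
                          temp_c = 30 + sin(0:79 / 10))
  sst <- simulate_sst(daily, sst_sim_spec(offset_mean = 2, offset_sd = 0,
                                          composite_days = 8), seed = 1)
  expect_equal(nrow(sst), 10)
  win_means <- vapply(split(daily$temp_c, rep(1:10, each = 8)), mean,
                      numeric(1))
  expect_equal(sst$sst_c, unname(win_means) - 2)
  expect_error(simulate_sst(daily[0, ], sst_sim_spec()), "non-empty")
})

test_that("noisy SST offset is recovered within 3 SE over a year", {
  daily <- tibble::tibble(date = as.Date("2018-09-01") + 0:364,
                          temp_c = 30.5 + 0.8 * cospi(2 * (0:364) / 365.25))
  sst <- simulate_sst(daily, sst_sim_spec(offset_mean = 2, offset_sd = 0.3),
                      seed = 7)
  win <- floor(as.numeric(sst$date - sst$date[1]) / 8) + 1
  insitu_win <- vapply(seq_len(nrow(sst)), function(i) {
    days <- daily$temp_c[daily$date >= sst$date[i] &
                           daily$date < sst$date[i] + 8]
    mean(days)
  }, numeric(1))
  offs <- insitu_win - sst$sst_c
  expect_lt(abs(mean(offs) - 2), 3 * 0.3 / sqrt(length(offs)))
})
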