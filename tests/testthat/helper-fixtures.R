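# Shared fixture builders. Everything is generated in code; nothing is read
# from disk unless a test writes it first.

utc <- function(x) lubridate::as_datetime(x, tz = "UTC")

# A regular record tibble with fully controlled values.
make_records <- function(start = "2018-09-01", n = 24, by = 3600,
                         site_id = "s1", speed = 0.05, direction = 90,
                         temp = 30) {
  tibble::tibble(
    timestamp = utc(start) + (seq_len(n) - 1) * by,
    site_id = site_id,
    speed_ms = rep_len(speed, n),
    direction_deg = rep_len(direction, n),
    temp_c = rep_len(temp, n),
    qc_flag = "")
}

meta_row <- function(site_id = "s1", reef_type = "pinnacle",
                     start = "2018-09-01", end = "2018-09-02") {
  tibble::tibble(site_id = site_id, name = site_id, reef_type = reef_type,
                 lat = -5.5, lon = 150.1, depth_m = 27,
                 deployment_start = utc(start), deployment_end = utc(end))
}

# Quick constant-regime spec for structural tests.
quiet_spec <- function(site_id = "s1", reef_type = "pinnacle",
                       start = "2018-09-01", end = "2018-09-03",
                       interval = 600, edge_hours = 0, ...) {
  site_sim_spec(site_id, reef_type,
                speed = speed_regime(2, 0.04, ...),
                direction = direction_regime(330, 5),
                thermal = thermal_regime(30, noise_sd = 0.1),
                deployment_start = start, deployment_end = end,
                sampling_interval = interval,
                edge_artifact_hours = edge_hours)
}

# Independent oracle for percentile permutation tests: enumerate every
# relabelling with stats::quantile (type 7) directly.
brute_force_perm_p <- function(a, b, stat_fn) {
  pool <- c(a, b)
  n <- length(pool); na <- length(a)
  obs <- stat_fn(a) - stat_fn(b)
  idx <- utils::combn(n, na)
  t_perm <- apply(idx, 2, function(i) stat_fn(pool[i]) - stat_fn(pool[-i]))
  mean(abs(t_perm) >= abs(obs) - 1e-12)
}
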