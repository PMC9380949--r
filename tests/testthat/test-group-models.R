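# Shared simulated daily dataset: 3 reef types x 2 sites x 120 days.
sim_daily <- function(seed, group_means = c(nearshore_emergent = 0.051,
                                            offshore_emergent = 0.052,
                                            pinnacle = 0.083),
                      site_sd = 0.1, days = 120, sites_per_group = 2,
                      shape = 40) {
  set.seed(seed)
  purrr::imap_dfr(group_means, function(mu, rt) {
    purrr::map_dfr(seq_len(sites_per_group), function(i) {
      site_mu <- exp(log(mu) + rnorm(1, 0, site_sd))
      tibble::tibble(
        site_id = sprintf("%s_%d", rt, i),
        reef_type = rt,
        date = as.Date("2018-09-01") + seq_len(days) - 1,
        speed_mean = rgamma(days, shape, scale = site_mu / shape),
        temp_mean = rnorm(days, 30 + match(rt, names(group_means)), 0.3))
    })
  })
}

sim_meta <- function(daily) {
  daily |>
    dplyr::distinct(.data$site_id, .data$reef_type) |>
    dplyr::mutate(name = site_id, lat = -5.5, lon = 150.1, depth_m = 27,
                  deployment_start = utc("2018-09-01"),
                  deployment_end = utc("2019-09-01"))
}

test_that("family defaults follow the response", {
  expect_equal(model_spec("speed_mean")$family, "gamma_log")
  expect_equal(model_spec("temp_min")$family, "gaussian_identity")
  expect_error(model_spec("chlorophyll"))
})

test_that("with negligible site variance, marginal means equal raw group means", {
  daily <- sim_daily(1, site_sd = 0, days = 200, shape = 400)
  meta <- sim_meta(daily)
  fit <- fit_group_model(daily, meta, model_spec("temp_mean"))
  expect_true(fit$converged)
  mm <- marginal_means(fit)
  raw <- daily |>
    dplyr::group_by(reef_type) |>
    dplyr::summarise(m = mean(temp_mean)) |>
    dplyr::arrange(reef_type)
  expect_equal(mm$estimate[order(mm$group)], raw$m, tolerance = 1e-3)
})

test_that("gamma-log fits recover the response-scale group ordering", {
  daily <- sim_daily(2)
  meta <- sim_meta(daily)
  fit <- fit_group_model(daily, meta, model_spec("speed_mean"))
  expect_true(fit$converged)
  mm <- marginal_means(fit)
  est <- setNames(mm$estimate, mm$group)
  expect_gt(est[["pinnacle"]], est[["offshore_emergent"]])
  expect_gt(est[["pinnacle"]], est[["nearshore_emergent"]])
  expect_true(all(mm$lower < mm$estimate & mm$estimate < mm$upper))
})

test_that("non-positive responses are rejected under gamma_log with row detail", {
  daily <- sim_daily(3)
  daily$speed_mean[7] <- 0
  expect_error(fit_group_model(daily, sim_meta(daily), model_spec("speed_mean")),
               "positive")
})

test_that("one site per group is fit but flagged unidentifiable", {
  daily <- sim_daily(4, sites_per_group = 1)
  fit <- fit_group_model(daily, sim_meta(daily), model_spec("temp_mean"))
  expect_false(fit$site_sd_identifiable)
  mm <- marginal_means(fit)
  expect_equal(nrow(mm), 3)
})

test_that("contrasts cover all pairs, are antisymmetric, and Tukey widens", {
  daily <- sim_daily(5)
  meta <- sim_meta(daily)
  for (resp in c("temp_mean", "speed_mean")) {
    fit <- fit_group_model(daily, meta, model_spec(resp))
    tk <- pairwise_contrasts(fit, adjust = "tukey")
    un <- pairwise_contrasts(fit, adjust = "none")
    expect_equal(nrow(tk), 3)
    # adjusted intervals contain the unadjusted ones
    expect_true(all(tk$lower <= un$lower + 1e-12))
    expect_true(all(tk$upper >= un$upper - 1e-12))
    # significance flag mirrors the CI-excludes-zero rule
    expect_equal(tk$significant, tk$lower > 0 | tk$upper < 0)
    # contrast(A,B) equals the difference of marginal means, so reversing
    # the pair negates the estimate
    mm <- marginal_means(fit)
    est <- setNames(mm$estimate, mm$group)
    expect_equal(tk$estimate,
                 unname(est[tk$group_a] - est[tk$group_b]),
                 tolerance = 1e-6)
  }
})

test_that("identical groups produce null contrasts spanning zero", {
  daily <- sim_daily(6,
                     group_means = c(nearshore_emergent = 0.05,
                                     offshore_emergent = 0.05,
                                     pinnacle = 0.05),
                     site_sd = 0, days = 150)
  fit <- fit_group_model(daily, sim_meta(daily), model_spec("speed_mean"))
  tk <- pairwise_contrasts(fit)
  expect_true(all(tk$lower < 0 & tk$upper > 0))
  expect_true(all(abs(tk$estimate) < 0.005))
})

test_that("tidy and glance expose broom-style summaries", {
  daily <- sim_daily(7)
  fit <- fit_group_model(daily, sim_meta(daily), model_spec("speed_mean"))
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std.error", "p.value") %in% names(td)))
  expect_equal(nrow(td), 3) # intercept + 2 contrasts on the link scale
  gl <- glance(fit)
  expect_equal(gl$n_obs, nrow(daily))
  expect_equal(gl$family, "gamma_log")
  expect_true(is.finite(gl$AIC))
})
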