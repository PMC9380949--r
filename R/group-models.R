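MODEL_RESPONSES <- c("temp_mean", "temp_max", "temp_min",
                     "speed_mean", "speed_max", "speed_min")

#' Group-comparison model specification
#'
#' Declares which daily response to model and with what error structure.
#' Temperature responses default to a gaussian family with identity link;
#' current-speed responses, being positive and right-skewed, default to a
#' gamma family with log link. All models compare reef types with a random
#' intercept per site, absorbing between-site variability and the repeated
#' daily measures within sites.
#'
#' @param response One of `"temp_mean"`, `"temp_max"`, `"temp_min"`,
#'   `"speed_mean"`, `"speed_max"`, `"speed_min"` (columns of
#'   [daily_summaries()]).
#' @param family `"gaussian_identity"` or `"gamma_log"`; default chosen from
#'   the response.
#' @param season Restrict the fit to one season label, or `NULL` (default)
#'   for the annual model.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(response, family = NULL, season = NULL) {
  response <- match.arg(response, MODEL_RESPONSES)
  family <- family %||%
    if (startsWith(response, "speed")) "gamma_log" else "gaussian_identity"
  family <- match.arg(family, c("gaussian_identity", "gamma_log"))
  structure(list(response = response, family = family, season = season),
            class = "model_spec")
}

#' Fit a random-intercept reef-type comparison model
#'
#' Fits `response ~ reef_type + (1 | site_id)` to daily summary values with
#' the family declared in `spec`, via [glmmTMB::glmmTMB()] (maximum
#' likelihood). With a single site per group, the site random intercept is
#' confounded with the group effect; the fit proceeds but is flagged
#' (`site_sd_identifiable = FALSE`).
#'
#' @param daily Output of [daily_summaries()] (any number of sites).
#' @param meta Site metadata carrying `site_id` and `reef_type`.
#' @param spec A [model_spec()].
#' @return Object of class `reef_group_model`: list with the fitted
#'   `glmmTMB` model (`fit`), `spec`, and bookkeeping (`n_obs`, `n_sites`,
#'   `n_groups`, `converged`, `site_sd`, `site_sd_identifiable`). Supports
#'   [marginal_means()], [pairwise_contrasts()], `tidy()` and `glance()`.
#' @export
fit_group_model <- function(daily, meta, spec = model_spec("speed_mean")) {
  if (!inherits(spec, "model_spec")) abort("`spec` must be a model_spec.")
  d <- daily |>
    dplyr::select(-dplyr::any_of("reef_type")) |>
    dplyr::left_join(dplyr::select(meta, "site_id", "reef_type"),
                     by = "site_id")
  if (!is.null(spec$season)) d <- dplyr::filter(d, .data$season == spec$season)
  d <- d[!is.na(d[[spec$response]]), ]
  if (dplyr::n_distinct(d$reef_type) < 2) abort("need >= 2 reef types.")
  if (dplyr::n_distinct(d$site_id) < 2) abort("need >= 2 sites.")
  if (spec$family == "gamma_log" && any(d[[spec$response]] <= 0)) {
    bad <- which(d[[spec$response]] <= 0)
    abort(paste0("gamma_log requires a strictly positive response; ",
                 "non-positive rows: ", paste(head(bad, 5), collapse = ", "),
                 if (length(bad) > 5) " ..." else ""))
  }
  d$reef_type <- factor(d$reef_type)
  fam <- if (spec$family == "gamma_log") stats::Gamma(link = "log")
         else stats::gaussian()
  form <- as.formula(paste(spec$response, "~ reef_type + (1 | site_id)"))
  fit <- glmmTMB::glmmTMB(form, data = d, family = fam)
  converged <- isTRUE(fit$fit$convergence == 0) &&
    isTRUE(fit$sdr$pdHess)
  vc <- glmmTMB::VarCorr(fit)$cond$site_id
  site_sd <- if (is.null(vc)) NA_real_ else attr(vc, "stddev")[[1]]
  sites_per_group <- d |>
    dplyr::distinct(.data$reef_type, .data$site_id) |>
    dplyr::count(.data$reef_type)
  identifiable <- all(sites_per_group$n > 1)
  structure(list(fit = fit, spec = spec, data = d,
                 n_obs = nrow(d),
                 n_sites = dplyr::n_distinct(d$site_id),
                 n_groups = nlevels(d$reef_type),
                 converged = converged,
                 site_sd = unname(site_sd),
                 site_sd_identifiable = identifiable),
            class = "reef_group_model")
}

# Sites, not days, are the units of replication, so intervals use the
# naive between-site degrees of freedom (n_sites - n_groups) instead of
# the backend's asymptotic default; with few sites per group the z
# intervals undercover. Below 2 df (e.g. one site per group, already
# flagged unidentifiable) t/studentized-range quantiles are unusable, so
# the residual df is kept instead.
.site_df <- function(x) {
  df <- x$n_sites - x$n_groups
  if (df >= 2) df else stats::df.residual(x$fit)
}

#' Estimated marginal means on the response scale
#'
#' Model-based group means balanced over the design, back-transformed
#' through the link for gamma-log fits, with 95% confidence intervals on
#' naive between-site degrees of freedom (`n_sites - n_groups`).
#'
#' @param x A `reef_group_model`.
#' @param level Confidence level (default 0.95).
#' @return Tibble: `group`, `estimate` (response scale), `se`, `lower`,
#'   `upper`, `n_obs`.
#' @export
marginal_means <- function(x, level = 0.95) {
  stopifnot(inherits(x, "reef_group_model"))
  if (!x$converged) warn("model did not converge; estimates may be unreliable.")
  emm <- emmeans::emmeans(x$fit, ~reef_type, type = "response")
  emm <- stats::update(emm, df = .site_df(x))
  s <- as.data.frame(confint(emm, level = level))
  est_col <- intersect(c("response", "emmean"), names(s))[1]
  lcl <- intersect(c("lower.CL", "asymp.LCL"), names(s))[1]
  ucl <- intersect(c("upper.CL", "asymp.UCL"), names(s))[1]
  counts <- dplyr::count(x$data, .data$reef_type)
  tibble::tibble(group = as.character(s$reef_type),
                 estimate = s[[est_col]], se = s$SE,
                 lower = s[[lcl]], upper = s[[ucl]]) |>
    dplyr::left_join(dplyr::rename(counts, group = "reef_type",
                                   n_obs = "n") |>
                       dplyr::mutate(group = as.character(.data$group)),
                     by = "group")
}

#' Tukey-adjusted pairwise contrasts on the response scale
#'
#' All pairwise differences between reef-type marginal means, on the
#' response scale (the fit is re-gridded before contrasting, so a contrast
#' is a difference of means in the response units for both families), with
#' multiplicity-adjusted confidence intervals for the all-pairs family. A
#' pair is flagged significant when its adjusted interval excludes zero.
#'
#' @param x A `reef_group_model`.
#' @param adjust Multiplicity adjustment passed to emmeans (default
#'   `"tukey"`; `"none"` gives unadjusted intervals).
#' @param level Confidence level (default 0.95).
#' @return Tibble: `contrast`, `group_a`, `group_b`, `estimate`, `se`,
#'   `lower`, `upper`, `significant`.
#' @export
pairwise_contrasts <- function(x, adjust = "tukey", level = 0.95) {
  stopifnot(inherits(x, "reef_group_model"))
  emm <- emmeans::regrid(emmeans::emmeans(x$fit, ~reef_type))
  emm <- stats::update(emm, df = .site_df(x))
  ci <- as.data.frame(confint(emmeans::contrast(emm, "pairwise"),
                              level = level, adjust = adjust))
  lcl <- intersect(c("lower.CL", "asymp.LCL"), names(ci))[1]
  ucl <- intersect(c("upper.CL", "asymp.UCL"), names(ci))[1]
  parts <- strsplit(as.character(ci$contrast), " - ", fixed = TRUE)
  tibble::tibble(
    contrast = as.character(ci$contrast),
    group_a = vapply(parts, `[`, character(1), 1),
    group_b = vapply(parts, `[`, character(1), 2),
    estimate = ci$estimate, se = ci$SE,
    lower = ci[[lcl]], upper = ci[[ucl]]) |>
    dplyr::mutate(significant = .data$lower > 0 | .data$upper < 0)
}

#' @export
print.reef_group_model <- function(x, ...) {
  cat("Reef-type group model:", x$spec$response,
      sprintf("(%s)\n", x$spec$family))
  cat(sprintf("  %d observations, %d sites, %d groups; converged: %s\n",
              x$n_obs, x$n_sites, x$n_groups, x$converged))
  cat(sprintf("  site random-intercept SD: %.4g%s\n", x$site_sd,
              if (x$site_sd_identifiable) "" else " (unidentifiable: one site per group)"))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy fixed-effect coefficients of a reef group model
#'
#' @param x A `reef_group_model`.
#' @param ... Unused.
#' @return Tibble: `term`, `estimate`, `std.error`, `statistic`, `p.value`
#'   (link scale).
#' @export
tidy.reef_group_model <- function(x, ...) {
  co <- summary(x$fit)$coefficients$cond
  tibble::tibble(term = rownames(co), estimate = co[, 1],
                 std.error = co[, 2], statistic = co[, 3],
                 p.value = co[, 4])
}

#' One-row model summary
#'
#' @param x A `reef_group_model`.
#' @param ... Unused.
#' @return Tibble: `response`, `family`, `n_obs`, `n_sites`, `site_sd`,
#'   `logLik`, `AIC`, `converged`.
#' @export
glance.reef_group_model <- function(x, ...) {
  tibble::tibble(response = x$spec$response, family = x$spec$family,
                 n_obs = x$n_obs, n_sites = x$n_sites,
                 site_sd = x$site_sd,
                 logLik = as.numeric(stats::logLik(x$fit)),
                 AIC = stats::AIC(x$fit),
                 converged = x$converged)
}
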