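#' Reef-archetype generator regimes
#'
#' Default generative regimes for the three reef morphologies the package
#' contrasts. The speed regimes are calibrated so that, over a simulated
#' year, annual mean daily current speeds sit near 0.083 (pinnacle), 0.052
#' (offshore emergent) and 0.051 (nearshore emergent) m s^-1, the pinnacle
#' daily-mean IQR is roughly twice the nearshore IQR, and the dispersion
#' ordering is pinnacle > offshore > nearshore — the qualitative regime
#' structure the analysis is designed to resolve. Direction regimes give
#' pinnacles a dominant north-northwest component, offshore reefs
#' near-uniform headings, and nearshore reefs two narrow sector modes.
#' No field dataset fixes these values; they are free modelling choices,
#' documented in the methods vignette.
#'
#' @param reef_type One of `"nearshore_emergent"`, `"offshore_emergent"`,
#'   `"pinnacle"`.
#' @return A list with elements `speed`, `direction`, `thermal`.
#' @export
archetype_regimes <- function(reef_type) {
  reef_type <- match.arg(reef_type, REEF_TYPES)
  switch(reef_type,
    pinnacle = list(
      speed = speed_regime(gamma_shape = 2.2, gamma_scale = 0.0758 / 2.2,
                           ar1_coeff = 0.99955, pulse_rate = 1.2,
                           pulse_multiplier = 2.2, pulse_duration = 2),
      direction = direction_regime(mean_deg = 340, concentration = 2.5),
      thermal = thermal_regime(annual_mean = 30.4, seasonal_amplitude = 0.7,
                               seasonal_phase = 105, diurnal_amplitude = 0.25,
                               noise_sd = 0.12, site_offset_sd = 0.25)),
    offshore_emergent = list(
      speed = speed_regime(gamma_shape = 2.2, gamma_scale = 0.0500 / 2.2,
                           ar1_coeff = 0.99975, pulse_rate = 0.8,
                           pulse_multiplier = 2.0, pulse_duration = 2),
      direction = direction_regime(mean_deg = 0, concentration = 0.25),
      thermal = thermal_regime(annual_mean = 31.2, seasonal_amplitude = 0.8,
                               seasonal_phase = 190, diurnal_amplitude = 0.35,
                               noise_sd = 0.18, site_offset_sd = 0.35)),
    nearshore_emergent = list(
      speed = speed_regime(gamma_shape = 2.2, gamma_scale = 0.0513 / 2.2,
                           ar1_coeff = 0.9988, pulse_rate = 0.15,
                           pulse_multiplier = 1.6, pulse_duration = 1),
      direction = direction_regime(mean_deg = c(30, 225),
                                   concentration = c(6, 6),
                                   weight = c(0.6, 0.4)),
      thermal = thermal_regime(annual_mean = 30.9, seasonal_amplitude = 0.8,
                               seasonal_phase = 190, diurnal_amplitude = 0.5,
                               noise_sd = 0.25, site_offset_sd = 0.4)))
}

#' Build the 11-site study-design fleet specification
#'
#' Assembles [site_sim_spec()]s mirroring the surveyed design: 4 nearshore
#' emergent reefs, 4 offshore emergent reefs and 3 submerged pinnacles, all
#' drawing their regimes from [archetype_regimes()].
#'
#' @param n_nearshore,n_offshore,n_pinnacle Site counts per morphology.
#' @param deployment_start,deployment_end Deployment window (UTC).
#' @param sampling_interval Cadence in seconds (default 10).
#' @param edge_artifact_hours Edge-artifact span per end, hours.
#' @return A list of [site_sim_spec()]s.
#' @export
archetype_fleet <- function(n_nearshore = 4, n_offshore = 4, n_pinnacle = 3,
                            deployment_start = "2018-08-15",
                            deployment_end = "2019-09-15",
                            sampling_interval = 10,
                            edge_artifact_hours = 2) {
  counts <- c(nearshore_emergent = n_nearshore,
              offshore_emergent = n_offshore,
              pinnacle = n_pinnacle)
  prefix <- c(nearshore_emergent = "near", offshore_emergent = "off",
              pinnacle = "pin")
  specs <- list()
  for (rt in names(counts)) {
    for (i in seq_len(counts[[rt]])) {
      reg <- archetype_regimes(rt)
      specs[[length(specs) + 1]] <- site_sim_spec(
        site_id = sprintf("%s_%02d", prefix[[rt]], i), reef_type = rt,
        speed = reg$speed, direction = reg$direction, thermal = reg$thermal,
        deployment_start = deployment_start,
        deployment_end = deployment_end,
        sampling_interval = sampling_interval,
        edge_artifact_hours = edge_artifact_hours)
    }
  }
  specs
}

#' Write a simulated fleet to disk in the instrument CSV schema
#'
#' Emits one `<site_id>.csv` per site (columns `timestamp, speed_ms,
#' direction_deg, temp_c`), a `metadata.csv` site table, and a
#' `ground_truth.yml` sidecar holding the generative parameters (for tests
#' and provenance; the analysis pipeline never reads it).
#'
#' @param fleet Result of [simulate_fleet()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fleet <- function(fleet, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(fleet$records)) {
    rec <- fleet$records[[id]]
    readr::write_csv(
      dplyr::mutate(rec,
        timestamp = format(.data$timestamp, "%Y-%m-%dT%H:%M:%SZ")),
      file.path(dir, paste0(id, ".csv")))
  }
  meta_out <- dplyr::mutate(fleet$meta,
    deployment_start = format(.data$deployment_start, "%Y-%m-%dT%H:%M:%SZ"),
    deployment_end = format(.data$deployment_end, "%Y-%m-%dT%H:%M:%SZ"))
  readr::write_csv(meta_out, file.path(dir, "metadata.csv"))
  gt <- lapply(fleet$records, function(rec) {
    g <- attr(rec, "ground_truth")
    list(seed = g$seed,
         site_temp_offset = g$site_temp_offset,
         reef_type = g$spec$reef_type,
         speed = unclass(g$spec$speed),
         edge_artifact_hours = g$spec$edge_artifact_hours)
  })
  yaml::write_yaml(gt, file.path(dir, "ground_truth.yml"))
  invisible(dir)
}
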