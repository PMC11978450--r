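#' Parameters for a synthetic frog-like reflectance spectrum
#'
#' The generated shape mimics measured spectra of green leaf-sitting frogs
#' and painted models: a low baseline, a Gaussian reflectance peak in the
#' green, and a logistic rise at the red edge to a near-infrared plateau
#' that is high (leaf-matching) or low (leaf-contrasting).
#'
#' @param green_peak_nm Centre of the green peak (default 550 nm).
#' @param green_peak_height Peak height above baseline, as a reflectance
#'   fraction (default 0.15).
#' @param green_width_nm Gaussian SD of the green peak (default 40 nm).
#' @param nir_plateau NIR plateau reflectance fraction (0.55 for the
#'   high-NIR preset, 0.10 for low-NIR).
#' @param nir_rise_nm Inflection of the logistic NIR rise (default 720 nm,
#'   the red edge).
#' @param nir_rise_width_nm Logistic scale of the rise (default 25 nm).
#' @param baseline Baseline reflectance fraction (default 0.05).
#' @param noise_sd Gaussian measurement noise SD, reflectance fraction
#'   (default 0.005).
#' @param seed Integer seed; every generator is bit-reproducible per seed.
#' @return A list of class `spectrum_params`.
#' @export
spectrum_params <- function(green_peak_nm = 550, green_peak_height = 0.15,
                            green_width_nm = 40, nir_plateau = 0.55,
                            nir_rise_nm = 720, nir_rise_width_nm = 25,
                            baseline = 0.05, noise_sd = 0.005, seed = 1L) {
  p <- list(green_peak_nm = green_peak_nm,
            green_peak_height = green_peak_height,
            green_width_nm = green_width_nm, nir_plateau = nir_plateau,
            nir_rise_nm = nir_rise_nm, nir_rise_width_nm = nir_rise_width_nm,
            baseline = baseline, noise_sd = noise_sd, seed = as.integer(seed))
  fr <- c("green_peak_height", "nir_plateau", "baseline")
  if (any(unlist(p[fr]) < 0 | unlist(p[fr]) > 1))
    stop_nirtherm("reflectance fractions must be within [0, 1]")
  if (green_width_nm <= 0 || nir_rise_width_nm <= 0)
    stop_nirtherm("widths must be positive")
  class(p) <- "spectrum_params"
  p
}

#' High- and low-NIR spectrum presets
#'
#' @param ... Overrides passed to [spectrum_params()].
#' @return A `spectrum_params` object.
#' @rdname spectrum_presets
#' @export
hnir_params <- function(...) spectrum_params(nir_plateau = 0.55, ...)

#' @rdname spectrum_presets
#' @export
lnir_params <- function(...) spectrum_params(nir_plateau = 0.10, ...)

#' Generate a synthetic reflectance spectrum
#'
#' Baseline + Gaussian green peak + logistic NIR rise, plus Gaussian noise
#' clipped at zero, on a 1 nm grid from 300 to 1700 nm. Deterministic per
#' seed.
#'
#' @param params A [spectrum_params()].
#' @param label Label for the spectrum.
#' @return A reflectance [spectrum()].
#' @examples
#' s_hi <- synth_spectrum(hnir_params(seed = 7), "HNIR preset")
#' s_lo <- synth_spectrum(lnir_params(seed = 7), "LNIR preset")
#' @export
synth_spectrum <- function(params, label = "synthetic") {
  stopifnot(inherits(params, "spectrum_params"))
  wl <- seq(300, 1700, by = 1)
  shape <- params$baseline +
    params$green_peak_height *
      exp(-((wl - params$green_peak_nm)^2) / (2 * params$green_width_nm^2)) +
    (params$nir_plateau - params$baseline) *
      plogis((wl - params$nir_rise_nm) / params$nir_rise_width_nm)
  noise <- with_seed(substream_seed(params$seed, "noise"),
                     rnorm(length(wl), 0, params$noise_sd))
  spectrum(wl, pmax(shape + noise, 0), kind = "reflectance", label = label)
}

#' Parameters for synthetic chamber heating traces
#'
#' A lumped first-order thermal model: under illumination the model
#' temperature relaxes exponentially (time constant `tau_s`) toward an
#' equilibrium offset above ambient proportional to the absorbed fraction of
#' the incident radiation, `gain_C_per_min * (1 - R/100)` scaled by the
#' energy fraction of the illumination band. Uncoated (evaporating) models
#' sit `evap_offset_C` below that equilibrium.
#'
#' @param T_env_C Chamber ambient temperature (default 18, a water-jacketed
#'   chamber).
#' @param gain_C_per_min Initial heating rate of a perfect absorber (R = 0)
#'   under full-band illumination at the chamber's ~1000 W m^-2 (default
#'   1.6 C/min, the scale observed for dark surfaces at that intensity).
#' @param tau_s Thermal relaxation time (default 450 s, the scale of a few-cm
#'   agar body).
#' @param evap_offset_C Equilibrium depression for uncoated models from
#'   evaporative cooling (default 2).
#' @param noise_sd Thermocouple noise SD in C (default 0.05).
#' @param seed Integer seed.
#' @return A list of class `heat_params`.
#' @export
heat_params <- function(T_env_C = 18, gain_C_per_min = 1.6, tau_s = 450,
                        evap_offset_C = 2, noise_sd = 0.05, seed = 1L) {
  if (tau_s <= 0) stop_nirtherm("tau_s must be positive")
  if (gain_C_per_min < 0) stop_nirtherm("gain must be non-negative")
  structure(list(T_env_C = T_env_C, gain_C_per_min = gain_C_per_min,
                 tau_s = tau_s, evap_offset_C = evap_offset_C,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "heat_params")
}

#' Simulate a chamber heating trace for a surface of known reflectivity
#'
#' Steps the lumped first-order model exactly (exponential update per 20 s
#' sample) through a [regime_schedule()]: during a heating phase the
#' equilibrium is `T_env + tau_s * a / 60` with forcing
#' `a = gain * (1 - R/100) * f_band` (C/min), where `f_band` is the energy
#' fraction of the phase's illumination band within the full 300--1700 nm
#' lamp output; during cooling the equilibrium is ambient. Both internal and
#' surface channels are produced, the surface responding with a faster time
#' constant and stronger forcing, as thermocouples on an illuminated surface
#' do.
#'
#' @param R_percent Solar-weighted reflectivity of the surface in percent
#'   (0--100).
#' @param schedule A [regime_schedule()].
#' @param params A [heat_params()].
#' @param irradiance Irradiance [spectrum()] of the lamp (default the
#'   synthetic AM1.5G-like spectrum).
#' @param treatment,size,label Metadata for the returned trace.
#' @param dt_s Sampling interval (default 20 s).
#' @param uncoated Apply the evaporative equilibrium depression?
#'   Defaults to `treatment == "uncoated"`.
#' @return A [heating_trace()] with `internal_C`, `surface_C` and `air_C`.
#' @export
synth_heating_trace <- function(R_percent, schedule, params = heat_params(),
                                irradiance = NULL,
                                treatment = "HNIR", size = "small",
                                label = paste0(treatment, "_", size),
                                dt_s = 20,
                                uncoated = identical(treatment, "uncoated")) {
  stopifnot(inherits(schedule, "regime_schedule"),
            inherits(params, "heat_params"))
  if (R_percent < 0 || R_percent > 100)
    stop_nirtherm("R_percent must be within [0, 100]")
  if (is.null(irradiance)) irradiance <- solar_spectrum_synthetic()
  total <- sum(schedule$duration_s)
  time_s <- seq(0, total - dt_s, by = dt_s)
  absorbed <- 1 - R_percent / 100

  f_band <- vapply(seq_len(nrow(schedule)), function(i) {
    if (schedule$mode[i] != "heating") return(0)
    band_energy_fraction(irradiance,
                         band(schedule$lo_nm[i], schedule$hi_nm[i]),
                         band(300, 1700))
  }, numeric(1))

  run_channel <- function(tau, gain_scale, depress) {
    Tn <- numeric(length(time_s))
    Tcur <- params$T_env_C
    for (j in seq_along(time_s)) {
      i <- findInterval(time_s[j], c(schedule$start_s, total))
      a <- params$gain_C_per_min * gain_scale * absorbed * f_band[i]
      Teq <- params$T_env_C + tau * a / 60 - if (a > 0 && depress)
        params$evap_offset_C else 0
      if (j > 1L) Tcur <- Teq + (Tcur - Teq) * exp(-dt_s / tau)
      Tn[j] <- Tcur
    }
    Tn
  }
  internal <- run_channel(params$tau_s, 1.0, uncoated)
  surface <- run_channel(params$tau_s / 3, 2.5, uncoated)

  noise <- with_seed(substream_seed(params$seed, "noise"),
                     matrix(rnorm(3 * length(time_s), 0, params$noise_sd),
                            ncol = 3))
  heating_trace(time_s,
                internal_C = internal + noise[, 1L],
                surface_C = surface + noise[, 2L],
                air_C = params$T_env_C + noise[, 3L] * 0.5,
                label = label, treatment = treatment, size = size)
}

#' Parameters for synthetic field deployments
#'
#' Emulates a rainforest deployment: several sites per day, each holding a
#' large and a small coated pair (LNIR with HNIR on one leaf) plus an
#' uncoated large/small pair; a site-level diurnal temperature course shared
#' by co-located models; AR1 logger noise; and rare transient sunspot events
#' whose magnitude depends on the coating (low-NIR surfaces absorb more).
#'
#' @param diurnal_mean_C,diurnal_amplitude_C Mean and half-range of the
#'   site-level diurnal course over the deployment window (defaults 25 and 3,
#'   shaded tropical understorey in the wet-season build-up).
#' @param phi AR1 coefficient of the logger noise (default 0.8).
#' @param innovation_sd AR1 innovation SD in C (default 0.15).
#' @param sunspot_rate_per_day Expected number of sunspot exposures per site
#'   per day (default 0.15: dappled shade, direct sun rare).
#' @param sunspot_C Named vector of peak sunspot magnitudes by treatment in
#'   C (defaults HNIR 2.5, LNIR 4.0, uncoated 3.0: the low-NIR surface gains
#'   the most under direct sun).
#' @param sunspot_duration_min Range of event durations (default 15--25 min).
#' @param evap_offset_C Temperature depression of uncoated models (default 2).
#' @param n_sites Sites per day (default 5).
#' @param n_days Deployment days (default 3).
#' @param samples_per_day Logger samples per deployment window (default 96:
#'   8 h at 5 min).
#' @param seed Integer seed.
#' @return A list of class `field_params`.
#' @export
field_params <- function(diurnal_mean_C = 25, diurnal_amplitude_C = 3,
                         phi = 0.8, innovation_sd = 0.15,
                         sunspot_rate_per_day = 0.15,
                         sunspot_C = c(HNIR = 2.5, LNIR = 4.0, uncoated = 3.0),
                         sunspot_duration_min = c(15, 25),
                         evap_offset_C = 2, n_sites = 5, n_days = 3,
                         samples_per_day = 96, seed = 1L) {
  if (abs(phi) >= 1) stop_nirtherm("|phi| must be < 1")
  if (n_sites < 1 || n_days < 1) stop_nirtherm("counts must be >= 1")
  structure(list(diurnal_mean_C = diurnal_mean_C,
                 diurnal_amplitude_C = diurnal_amplitude_C, phi = phi,
                 innovation_sd = innovation_sd,
                 sunspot_rate_per_day = sunspot_rate_per_day,
                 sunspot_C = sunspot_C,
                 sunspot_duration_min = sunspot_duration_min,
                 evap_offset_C = evap_offset_C, n_sites = as.integer(n_sites),
                 n_days = as.integer(n_days),
                 samples_per_day = as.integer(samples_per_day),
                 seed = as.integer(seed)),
            class = "field_params")
}

ar1_noise <- function(n, phi, innovation_sd) {
  e <- rnorm(n, 0, innovation_sd)
  x <- numeric(n)
  x[1L] <- e[1L] / sqrt(1 - phi^2)   # stationary start
  for (i in seq_len(n)[-1L]) x[i] <- phi * x[i - 1L] + e[i]
  x
}

#' Generate a synthetic field study
#'
#' Builds the full deployment described in [field_params()]: logger series
#' for every model (site-level diurnal signal, shared sunspot event times
#' within a site, per-series AR1 noise, treatment-specific sunspot
#' magnitudes and the uncoated evaporative depression), an air-temperature
#' series per site, and thermal-image observations at two sessions per day
#' with the leaf tracking the diurnal signal.
#'
#' Event times are drawn from a dedicated random substream, so changing the
#' noise level never shifts the events. Deterministic per seed.
#'
#' @param params A [field_params()].
#' @return A list: `series` (list of [field_series()]), `air` (named list of
#'   air series per site-day), `observations` (thermal-image data frame).
#' @export
synth_field_study <- function(params = field_params()) {
  stopifnot(inherits(params, "field_params"))
  n <- params$samples_per_day
  time_s <- seq(0, by = 300, length.out = n)        # 5 min sampling
  day_frac <- time_s / max(time_s)                   # 0 = 09:00, 1 = 17:00
  # diurnal course peaking mid-afternoon within the deployment window
  diurnal_shape <- sin(pi * (0.15 + 0.85 * day_frac))

  layout <- data.frame(
    pair = c("coated_large", "coated_large", "coated_small", "coated_small",
             "uncoated", "uncoated"),
    treatment = c("LNIR", "HNIR", "LNIR", "HNIR", "uncoated", "uncoated"),
    size = c("large", "large", "small", "small", "large", "small"),
    stringsAsFactors = FALSE)

  series <- list(); air <- list(); obs <- list()
  for (d in seq_len(params$n_days)) {
    for (s in seq_len(params$n_sites)) {
      site_id <- sprintf("d%d_s%d", d, s)
      site_seed <- substream_seed(params$seed, paste0("site_", site_id))
      site_level <- with_seed(substream_seed(site_seed, "level"),
                              rnorm(1, 0, 0.8))
      signal <- params$diurnal_mean_C + site_level +
        params$diurnal_amplitude_C * diurnal_shape

      # shared sunspot events for the site (times from their own substream)
      ev <- with_seed(substream_seed(site_seed, "events"), {
        k <- rpois(1, params$sunspot_rate_per_day)
        if (k == 0) NULL else data.frame(
          start = runif(k, 0.1, 0.8) * max(time_s),
          dur = runif(k, params$sunspot_duration_min[1L],
                      params$sunspot_duration_min[2L]) * 60)
      })
      spike <- function(magnitude) {
        out <- numeric(n)
        if (is.null(ev)) return(out)
        for (i in seq_len(nrow(ev))) {
          inwin <- time_s >= ev$start[i] & time_s <= ev$start[i] + ev$dur[i]
          # half-sine pulse: rises and falls within the event
          ph <- (time_s[inwin] - ev$start[i]) / ev$dur[i]
          out[inwin] <- pmax(out[inwin], magnitude * sin(pi * ph))
        }
        out
      }

      air_t <- signal + with_seed(substream_seed(site_seed, "air"),
                                  ar1_noise(n, params$phi,
                                            params$innovation_sd))
      air[[site_id]] <- field_series(time_s, pmin(pmax(air_t, -10), 90),
                                     model_id = paste0("air_", site_id),
                                     treatment = "uncoated", size = "small",
                                     pair_id = paste0(site_id, "_air"),
                                     site_id = site_id, day = d)

      for (r in seq_len(nrow(layout))) {
        trt <- layout$treatment[r]; sz <- layout$size[r]
        pair_id <- paste0(site_id, "_", layout$pair[r])
        model_id <- paste0(pair_id, "_", trt, "_", sz)
        logger_id <- paste0("ib_", ((s - 1) * nrow(layout) + r))  # reused across days
        offset <- if (trt == "uncoated") -params$evap_offset_C else 0
        noise <- with_seed(substream_seed(site_seed, paste0("noise_", r)),
                           ar1_noise(n, params$phi, params$innovation_sd))
        temp <- signal + offset + spike(params$sunspot_C[[trt]]) + noise
        series[[model_id]] <- field_series(
          time_s, pmin(pmax(temp, -10), 90), model_id = model_id,
          treatment = trt, size = sz, pair_id = pair_id, site_id = site_id,
          logger_id = logger_id, day = d)

        for (session in c("morning", "afternoon")) {
          t_idx <- if (session == "morning") round(n * 0.3) else round(n * 0.8)
          onoise <- with_seed(
            substream_seed(site_seed, paste0("obs_", r, "_", session)),
            rnorm(2, 0, 0.3))
          leaf <- signal[t_idx] + onoise[1L]
          obs[[length(obs) + 1L]] <- data.frame(
            pair_id = pair_id, model_id = model_id, site_id = site_id,
            day = d, session = session, coating = trt, size = sz,
            model_surface_C = leaf + offset + onoise[2L],
            leaf_surface_C = leaf, air_C = air_t[t_idx],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  list(series = series, air = air, observations = do.call(rbind, obs))
}

#' Paired differences for every pair in a synthetic (or real) study
#'
#' Convenience wrapper: groups a list of [field_series()] by pair and day
#' and stacks the [pair_difference()] tables, attaching the site's air
#' series when provided.
#'
#' @param series List of [field_series()].
#' @param air Optional named list of air series keyed by site id.
#' @param tolerance_s Timestamp matching tolerance.
#' @return A stacked data frame of paired differences.
#' @export
all_pair_differences <- function(series, air = NULL, tolerance_s = 150) {
  keys <- vapply(series, function(s) paste(s$pair_id, s$day, sep = "@"),
                 character(1))
  out <- list()
  for (k in unique(keys)) {
    members <- series[keys == k]
    if (length(members) != 2L) next
    a_series <- if (!is.null(air)) air[[members[[1L]]$site_id]] else NULL
    out[[k]] <- pair_difference(members[[1L]], members[[2L]],
                                air = a_series, tolerance_s = tolerance_s)
  }
  if (!length(out)) stop_nirtherm("no complete pairs found")
  do.call(rbind, c(out, make.row.names = FALSE))
}
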