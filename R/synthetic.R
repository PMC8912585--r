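#' Synthetic growth-curve configuration
#'
#' Parameters of the double-logistic annual EVI curve used to emulate
#' the semi-deciduous growth cycle: a high winter plateau at
#' `max_evi`, a falling logistic spring drop spanning `sdo`..`sde`, a
#' summer trough at `min_evi`, and a rising logistic autumn revival
#' spanning `aro`..`are` (which may exceed 365 and wrap into the next
#' calendar year). The logistic rate convention places 5% and 95% of
#' each transition at its stated onset and end. Defaults mirror the
#' long-term mean events of a xeric Mediterranean shrubland site.
#'
#' @param max_evi,min_evi Winter plateau and summer trough EVI.
#' @param sdo,sde Spring drop onset and end (day of year).
#' @param aro,are Autumn revival onset and end (day of year; `are`
#'   above 365 wraps).
#' @param noise_sd Gaussian observation noise SD (EVI units).
#' @param dropout_prob Probability a composite is cloud-depressed.
#' @param dropout_depth Range (EVI units) of the uniform negative bias
#'   applied to depressed composites.
#' @param seed Seed for the observation-noise draws.
#' @return A validated list of class `curve_config`.
#' @export
curve_config <- function(max_evi = 0.45, min_evi = 0.18,
                         sdo = 95, sde = 212, aro = 268, are = 345,
                         noise_sd = 0.01, dropout_prob = 0.1,
                         dropout_depth = c(0.05, 0.2), seed = 42L) {
  stopifnot(
    min_evi <= max_evi,
    sdo < sde, sde < aro, aro < are,
    noise_sd >= 0, dropout_prob >= 0, dropout_prob <= 1,
    length(dropout_depth) == 2L, dropout_depth[1] <= dropout_depth[2],
    dropout_depth[1] >= 0
  )
  structure(
    list(max_evi = max_evi, min_evi = min_evi, sdo = sdo, sde = sde,
         aro = aro, are = are, noise_sd = noise_sd,
         dropout_prob = dropout_prob, dropout_depth = dropout_depth,
         seed = as.integer(seed)),
    class = "curve_config"
  )
}

#' Synthetic climate configuration
#'
#' Daily temperature is an annual sinusoid (peak in late July) with
#' AR(1) noise; each day rains with its month's probability and rain
#' amounts are gamma-distributed. Defaults approximate a coastal
#' Mediterranean station: annual mean near 18 degrees C, amplitude 8,
#' wet winters and nearly dry summers totalling roughly 760 mm over
#' about 85 rain days per year.
#'
#' @param t_annual_mean,t_amplitude Annual mean and sinusoid
#'   amplitude of daily mean temperature (degrees C).
#' @param t_noise_sd Marginal SD of the AR(1) temperature noise.
#' @param t_ar1 AR(1) coefficient of the temperature noise.
#' @param rain_prob Twelve monthly probabilities that a day rains.
#' @param rain_shape,rain_scale Gamma shape and scale of daily rain
#'   amounts (mm).
#' @param seed Seed for the climate draws.
#' @return A validated list of class `climate_config`.
#' @export
climate_config <- function(t_annual_mean = 17.9, t_amplitude = 8,
                           t_noise_sd = 1.5, t_ar1 = 0.7,
                           rain_prob = c(0.40, 0.37, 0.33, 0.25, 0.15,
                                         0.07, 0.04, 0.05, 0.13, 0.25,
                                         0.40, 0.43),
                           rain_shape = 0.9, rain_scale = 9.5,
                           seed = 42L) {
  stopifnot(
    length(rain_prob) == 12L, all(rain_prob >= 0), all(rain_prob <= 1),
    rain_shape > 0, rain_scale > 0, t_noise_sd >= 0,
    abs(t_ar1) < 1
  )
  structure(
    list(t_annual_mean = t_annual_mean, t_amplitude = t_amplitude,
         t_noise_sd = t_noise_sd, t_ar1 = t_ar1, rain_prob = rain_prob,
         rain_shape = rain_shape, rain_scale = rain_scale,
         seed = as.integer(seed)),
    class = "climate_config"
  )
}

#' Climate-phenology coupling configuration
#'
#' Per-event linear couplings that displace the true event days from
#' their base values: named coefficient vectors on climate-window
#' anomalies (days per unit of the window variable), linear year
#' trends (days per year), and residual event noise.
#'
#' @param coefficients Named list, one element per event (`sdo`,
#'   `sde`, `aro`, `are`), each a named numeric vector whose names are
#'   climate-window names (`"Pr_1_0"`, `"T_2_1"`, ...).
#' @param trends Named numeric vector of days-per-year trends.
#' @param event_noise_sd Residual event noise SD (days).
#' @param seed Seed for the event-noise draws.
#' @return A validated list of class `coupling_config`.
#' @export
coupling_config <- function(coefficients = list(), trends = c(),
                            event_noise_sd = 0, seed = 42L) {
  events <- c("sdo", "sde", "aro", "are")
  stopifnot(
    all(names(coefficients) %in% events),
    all(names(trends) %in% events),
    event_noise_sd >= 0
  )
  for (co in coefficients) stopifnot(all(is.finite(co)),
                                     !is.null(names(co)))
  structure(
    list(coefficients = coefficients, trends = trends,
         event_noise_sd = event_noise_sd, seed = as.integer(seed)),
    class = "coupling_config"
  )
}

# Double-logistic shape on an absolute-day axis; events_abs is a data
# frame with one row per year giving absolute-day event positions.
# 5%-95% of each transition spans onset..end.
logistic_shape <- function(t_abs, events_abs) {
  g <- rep(1, length(t_abs))
  for (i in seq_len(nrow(events_abs))) {
    e <- events_abs[i, ]
    k1 <- 2 * log(19) / (e$sde - e$sdo)
    k2 <- 2 * log(19) / (e$are - e$aro)
    c1 <- (e$sdo + e$sde) / 2
    c2 <- (e$aro + e$are) / 2
    g <- g - stats::plogis(k1 * (t_abs - c1)) +
      stats::plogis(k2 * (t_abs - c2))
  }
  g
}

#' Noiseless synthetic annual EVI curve
#'
#' One year of the double-logistic growth curve sampled at the 46
#' composite start days.
#'
#' @param config A [curve_config()] object.
#' @return Tibble with `doy` and `evi` (46 rows).
#' @export
gen_annual_curve <- function(config) {
  stopifnot(inherits(config, "curve_config"))
  d <- composite_doys()
  events <- data.frame(sdo = config$sdo, sde = config$sde,
                       aro = config$aro, are = config$are)
  g <- logistic_shape(d, events)
  tibble::tibble(
    doy = d,
    evi = config$min_evi + (config$max_evi - config$min_evi) * g
  )
}

# Multi-year noiseless series from per-year true events.
gen_curve_series <- function(events, config, site_id = "site-a",
                             pixel_id = "site-mean") {
  dates <- composite_dates(events$year)
  t_abs <- as.numeric(dates)
  starts <- as.numeric(as.Date(sprintf("%d-01-01", events$year)))
  events_abs <- data.frame(
    sdo = starts + events$sdo - 1, sde = starts + events$sde - 1,
    aro = starts + events$aro - 1, are = starts + events$are - 1
  )
  g <- logistic_shape(t_abs, events_abs)
  tibble::tibble(
    site = site_id, pixel = pixel_id, date = dates,
    evi = config$min_evi + (config$max_evi - config$min_evi) * g,
    flag = "observed"
  )
}

#' Add observation noise and cloud dropouts to a clean series
#'
#' Additive Gaussian noise plus, with probability `dropout_prob`, a
#' negative bias drawn uniformly from `dropout_depth` — mimicking the
#' one-sided depression that residual cloud contamination inflicts on
#' vegetation indices (and that the BISE step is meant to remove).
#' Deterministic for a fixed `config$seed`.
#'
#' @param series EVI series table (or the `doy`/`evi` tibble from
#'   [gen_annual_curve()]).
#' @param config A [curve_config()] object supplying `noise_sd`,
#'   `dropout_prob`, `dropout_depth` and `seed`.
#' @return The perturbed series.
#' @export
add_observation_noise <- function(series, config) {
  stopifnot(inherits(config, "curve_config"), "evi" %in% names(series))
  series <- tibble::as_tibble(series)
  n <- nrow(series)
  set.seed(config$seed)
  evi <- series$evi + stats::rnorm(n, 0, config$noise_sd)
  hit <- stats::runif(n) < config$dropout_prob
  depth <- stats::runif(n, config$dropout_depth[1],
                        config$dropout_depth[2])
  series$evi <- evi - hit * depth
  series
}

#' Generate synthetic daily climate records
#'
#' @param config A [climate_config()] object.
#' @param years Integer vector of calendar years to cover.
#' @return Tibble with `date`, `tavg_c`, `prcp_mm`, one row per day.
#' @export
gen_climate <- function(config, years) {
  stopifnot(inherits(config, "climate_config"))
  years <- sort(unique(as.integer(years)))
  dates <- seq(as.Date(sprintf("%d-01-01", min(years))),
               as.Date(sprintf("%d-12-31", max(years))), by = "day")
  yr <- date_year(dates)
  n_in_year <- as.integer(table(yr))[match(yr, sort(unique(yr)))]
  phase <- 2 * pi * (doy(dates) - 209) / n_in_year
  n <- length(dates)
  set.seed(config$seed)
  t_det <- config$t_annual_mean + config$t_amplitude * cos(phase)
  if (config$t_noise_sd > 0) {
    innov_sd <- config$t_noise_sd * sqrt(1 - config$t_ar1^2)
    noise <- stats::filter(stats::rnorm(n, 0, innov_sd), config$t_ar1,
                           method = "recursive",
                           init = stats::rnorm(1, 0, config$t_noise_sd))
    t_det <- t_det + as.numeric(noise)
  }
  p_wet <- config$rain_prob[date_month(dates)]
  wet <- stats::runif(n) < p_wet
  amounts <- stats::rgamma(n, shape = config$rain_shape,
                           scale = config$rain_scale)
  tibble::tibble(date = dates, tavg_c = t_det,
                 prcp_mm = ifelse(wet, amounts, 0))
}

#' @keywords internal
month_of_doy <- function(d) {
  d <- ((d - 1) %% 365) + 1
  date_month(as.Date("2001-01-01") + d - 1)
}

#' Generate a climate-coupled synthetic EVI + climate dataset
#'
#' The full study-design emulator: daily climate is generated first;
#' each year's true event days are then the base curve events plus
#' linear couplings to climate-window anomalies (anchored at the month
#' of the base event), plus a year trend and residual noise; the
#' multi-year EVI curve is built from those events and observation
#' noise is added. The ground truth (per-year true events, anchor
#' months, window values and all configurations) is returned so every
#' downstream stage can be validated against it. Years whose drawn
#' events fall out of order are redrawn with fresh noise (logged via a
#' message).
#'
#' @param curve A [curve_config()] object (base events and noise).
#' @param climate A [climate_config()] object.
#' @param coupling A [coupling_config()] object.
#' @param n_years Number of EVI years to generate.
#' @param start_year First EVI calendar year; climate starts one year
#'   earlier so lagged windows are always available.
#' @param site_id,pixel_id Labels for the generated series.
#' @return A list with `evi` (noisy series), `evi_clean` (noiseless),
#'   `climate` (daily records), and `truth` (per-year true events,
#'   anchors, window values, configs and seeds).
#' @export
gen_coupled_dataset <- function(curve, climate, coupling,
                                n_years = 21, start_year = 2000,
                                site_id = "site-a",
                                pixel_id = "site-mean") {
  stopifnot(inherits(curve, "curve_config"),
            inherits(climate, "climate_config"),
            inherits(coupling, "coupling_config"))
  years <- start_year + seq_len(n_years) - 1L
  daily <- gen_climate(climate, c(start_year - 1L, years))
  monthly <- aggregate_monthly(daily)
  events <- c("sdo", "sde", "aro", "are")
  base <- unlist(lapply(events, function(e) curve[[e]]))
  names(base) <- events
  # deterministic climate-driven shifts
  shift <- matrix(0, n_years, length(events),
                  dimnames = list(NULL, events))
  window_values <- list()
  for (e in events) {
    coefs <- coupling$coefficients[[e]]
    if (is.null(coefs) || length(coefs) == 0L) next
    anchor_month <- month_of_doy(base[[e]])
    anchor_offset <- if (base[[e]] > 365) 1L else 0L
    specs <- parse_window_name(names(coefs))
    for (j in seq_len(nrow(specs))) {
      vals <- vapply(years, function(y) {
        window_value(monthly, specs$variable[j], specs$n_months[j],
                     specs$lag_months[j], y + anchor_offset,
                     anchor_month)
      }, 0)
      window_values[[paste(e, specs$name[j], sep = ".")]] <-
        tibble::tibble(year = years, event = e,
                       window = specs$name[j], value = vals)
      shift[, e] <- shift[, e] + coefs[[j]] * (vals - mean(vals))
    }
  }
  for (e in names(coupling$trends)) {
    shift[, e] <- shift[, e] +
      coupling$trends[[e]] * (seq_len(n_years) - 1L)
  }
  set.seed(coupling$seed)
  true_events <- matrix(NA_real_, n_years, length(events),
                        dimnames = list(NULL, events))
  redraws <- 0L
  for (i in seq_len(n_years)) {
    for (try in 1:100) {
      noise <- stats::rnorm(length(events), 0, coupling$event_noise_sd)
      ev <- base + shift[i, ] + noise
      if (ev[["sdo"]] < ev[["sde"]] && ev[["sde"]] < ev[["aro"]] &&
          ev[["aro"]] < ev[["are"]]) {
        true_events[i, ] <- ev
        break
      }
      redraws <- redraws + 1L
    }
    if (anyNA(true_events[i, ])) {
      stop("could not draw ordered events for year ", years[i],
           "; couplings/noise too extreme", call. = FALSE)
    }
  }
  if (redraws > 0L) {
    message("gen_coupled_dataset: ", redraws,
            " out-of-order event draw(s) regenerated")
  }
  truth_events <- tibble::as_tibble(true_events)
  truth_events$year <- years
  truth_events <- truth_events[c("year", events)]
  clean <- gen_curve_series(truth_events, curve, site_id, pixel_id)
  noisy <- add_observation_noise(clean, curve)
  list(
    evi = noisy,
    evi_clean = clean,
    climate = daily,
    truth = list(
      events = truth_events,
      shifts = tibble::as_tibble(shift) |>
        dplyr::mutate(year = years, .before = 1L),
      window_values = purrr::list_rbind(window_values),
      curve = curve, climate = climate, coupling = coupling,
      max_evi = curve$max_evi, min_evi = curve$min_evi
    )
  )
}
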