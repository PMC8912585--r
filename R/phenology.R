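#' Event-detection parameters
#'
#' Tunables of the derivative and threshold rules that extract the
#' thirteen phenology metrics from a smoothed EVI series.
#'
#' @param dry_threshold EVI value whose crossings delimit the summer
#'   dry period (default 0.3, the midpoint between the long-term
#'   maximum and minimum of the study series; see
#'   [compute_threshold()] for a data-driven alternative).
#' @param deriv_epsilon_fraction "Near zero" for the first derivative,
#'   as a fraction of the largest absolute derivative inside the
#'   search window.
#' @param min_run Composites a derivative excursion must persist to
#'   count as a transition (guards against ripple).
#' @param spring_search_window Day-of-year range searched for the
#'   spring drop (and for the annual maximum preceding it).
#' @param autumn_search_window Day-of-year range searched for the
#'   autumn revival; values above 365 wrap into the next calendar year.
#' @return A validated list of class `detection_params`.
#' @export
detection_params <- function(dry_threshold = 0.3,
                             deriv_epsilon_fraction = 0.16,
                             min_run = 2L,
                             spring_search_window = c(1, 264),
                             autumn_search_window = c(210, 400)) {
  stopifnot(
    dry_threshold > 0, dry_threshold < 1,
    deriv_epsilon_fraction > 0, deriv_epsilon_fraction < 1,
    min_run >= 1,
    length(spring_search_window) == 2L,
    spring_search_window[1] < spring_search_window[2],
    length(autumn_search_window) == 2L,
    autumn_search_window[1] < autumn_search_window[2]
  )
  structure(
    list(dry_threshold = dry_threshold,
         deriv_epsilon_fraction = deriv_epsilon_fraction,
         min_run = as.integer(min_run),
         spring_search_window = spring_search_window,
         autumn_search_window = autumn_search_window),
    class = "detection_params"
  )
}

#' First derivative of an EVI series
#'
#' Central differences on interior composites, one-sided at the ends;
#' units are EVI per composite step (8 days).
#'
#' @param data EVI series table (typically smoothed).
#' @return Tibble with `site`, `pixel`, `date`, `devi`.
#' @export
first_derivative <- function(data) {
  data <- check_evi_series(data, complete = FALSE)
  d_one <- function(g) {
    v <- g$evi
    n <- length(v)
    if (n < 3L) stop("first_derivative needs at least 3 composites",
                     call. = FALSE)
    d <- c(v[2L] - v[1L],
           (v[3:n] - v[1:(n - 2L)]) / 2,
           v[n] - v[n - 1L])
    tibble::tibble(site = g$site, pixel = g$pixel, date = g$date, devi = d)
  }
  data |>
    dplyr::group_split(.data$site, .data$pixel) |>
    purrr::map(d_one) |>
    purrr::list_rbind()
}

# Run-based departure/return detection on a derivative segment.
# ext: extended DOYs of the composites, d: derivative values. The
# qualifying run is the one containing the window's steepest point in
# the signed direction (the transition proper), which makes the rule
# robust to near-threshold noise excursions on the plateaus.
run_transition <- function(ext, d, sign, eps, min_run) {
  beyond <- sign * d > eps
  r <- rle(as.vector(beyond))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values & r$lengths >= min_run)
  if (length(cand) == 0L) return(c(onset = NA_real_, end = NA_real_))
  peak <- which.max(sign * d)
  holds_peak <- vapply(cand, function(i) {
    starts[i] <= peak && peak <= ends[i]
  }, TRUE)
  cand <- if (any(holds_peak)) cand[holds_peak] else cand[1L]
  i0 <- starts[cand[1L]]
  i1 <- ends[cand[1L]]
  onset <- ext[i0]
  if (i1 >= length(d)) return(c(onset = onset, end = NA_real_))
  inside <- abs(d) < eps
  tail_idx <- (i1 + 1L):length(d)
  r2 <- rle(as.vector(inside[tail_idx]))
  ends2 <- cumsum(r2$lengths)
  starts2 <- ends2 - r2$lengths + 1L
  cand2 <- which(r2$values & r2$lengths >= min_run)
  if (length(cand2) == 0L) return(c(onset = onset, end = NA_real_))
  c(onset = onset, end = ext[tail_idx[starts2[cand2[1L]]]])
}

#' Detect a derivative-based phenological transition
#'
#' Locates where the first derivative of the smoothed EVI curve
#' departs from near-zero values (transition onset) and where it
#' returns to near zero (transition end). "Near zero" is
#' `deriv_epsilon_fraction` times the largest absolute derivative in
#' the search window, and an excursion must persist `min_run`
#' composites. Falling transitions give the spring drop (SDO/SDE),
#' rising ones the autumn revival (ARO/ARE).
#'
#' @param data Smoothed EVI series for a single site/pixel.
#' @param direction `"falling"` or `"rising"`.
#' @param year Calendar year the window is anchored to.
#' @param window Extended day-of-year range (relative to `year`;
#'   values above 365 reach into the next year) searched.
#' @param params A [detection_params()] object.
#' @param deriv Optional precomputed [first_derivative()] table.
#' @return Named numeric vector `c(onset, end)` of composite start
#'   days of year (extended); `NA` when no qualifying run exists.
#' @export
detect_transition <- function(data, direction = c("falling", "rising"),
                              year, window,
                              params = detection_params(),
                              deriv = NULL) {
  direction <- match.arg(direction)
  data <- check_evi_series(data, complete = FALSE)
  if (dplyr::n_distinct(paste(data$site, data$pixel)) != 1L) {
    stop("detect_transition expects a single site/pixel series",
         call. = FALSE)
  }
  if (is.null(deriv)) deriv <- first_derivative(data)
  ext <- doy_ext(deriv$date, year)
  sel <- ext >= window[1] & ext <= window[2]
  if (!any(sel)) {
    stop("search window lies outside the series span", call. = FALSE)
  }
  d <- deriv$devi[sel]
  sgn <- if (direction == "falling") -1 else 1
  # "near zero" scales with the window's extreme derivative in the
  # direction of interest, so an opposite-signed transition sharing
  # the window does not inflate the band
  eps <- params$deriv_epsilon_fraction * max(sgn * d)
  if (eps <= 0) return(c(onset = NA_real_, end = NA_real_))
  run_transition(ext[sel], d, sgn, eps, params$min_run)
}

#' Midpoint threshold from the full series
#'
#' (Global maximum + global minimum) / 2 over the whole multi-year
#' smoothed series; a data-driven alternative to the fixed default
#' dry-period threshold of 0.3.
#'
#' @param data Smoothed multi-year EVI series.
#' @return The midpoint EVI value (one value per site if several).
#' @export
compute_threshold <- function(data) {
  data <- check_evi_series(data, complete = FALSE)
  if (nrow(data) == 0L) stop("empty series", call. = FALSE)
  out <- data |>
    dplyr::group_by(.data$site) |>
    dplyr::summarise(threshold = (max(.data$evi) + min(.data$evi)) / 2)
  if (nrow(out) == 1L) out$threshold else out
}

#' Annual EVI extrema
#'
#' The annual maximum is searched from 1 January up to the end of the
#' spring search window (the pre-drop winter/spring plateau, where it
#' falls in this growth cycle; values later in the calendar year
#' belong to the next phenological year). The minimum is then searched
#' from the maximum date forward to the following spring. Ties are
#' broken by the earlier date.
#'
#' @inheritParams detect_transition
#' @return Named numeric vector `c(max_evi, max_date, min_evi,
#'   min_date)`; dates are (extended) days of year.
#' @export
extrema_metrics <- function(data, year, params = detection_params()) {
  data <- check_evi_series(data, complete = FALSE)
  ext <- doy_ext(data$date, year)
  yr_sel <- ext >= 1 & ext <= 365
  if (sum(yr_sel) < 46L) {
    stop("incomplete year ", year, ": extrema undefined", call. = FALSE)
  }
  max_sel <- ext >= 1 & ext <= params$spring_search_window[2]
  i_max <- which(max_sel)[which.max(data$evi[max_sel])]
  max_doy <- ext[i_max]
  min_sel <- ext > max_doy & ext <= 365 + 120
  if (!any(min_sel)) {
    stop("no composites after the annual maximum in year ", year,
         call. = FALSE)
  }
  i_min <- which(min_sel)[which.min(data$evi[min_sel])]
  c(max_evi = data$evi[i_max], max_date = max_doy,
    min_evi = data$evi[i_min], min_date = ext[i_min])
}

# Threshold crossing between bracketing composites, linearly
# interpolated and rounded to the nearest integer (extended) DOY.
cross_doy <- function(d0, v0, d1, v1, thr) {
  round(d0 + (v0 - thr) / (v0 - v1) * (d1 - d0))
}

#' Detect the summer dry period by threshold crossing
#'
#' Dry-period onset (DPO) is the first downward crossing of the
#' threshold after the annual maximum; dry-period end (DPE) is the
#' first upward crossing after the subsequent minimum. Crossings are
#' located by linear interpolation between the bracketing composites
#' and rounded to the nearest integer day; DPE may exceed 365 when the
#' recovery happens in the next calendar year.
#'
#' @inheritParams detect_transition
#' @param extrema Optional precomputed [extrema_metrics()] result.
#' @return Named numeric vector `c(dpo, dpe)`; both `NA` (with a
#'   message) when the series never falls below the threshold.
#' @export
detect_dry_period <- function(data, year, params = detection_params(),
                              extrema = NULL) {
  data <- check_evi_series(data, complete = FALSE)
  if (is.null(extrema)) extrema <- extrema_metrics(data, year, params)
  thr <- params$dry_threshold
  ext <- doy_ext(data$date, year)
  v <- data$evi
  if (extrema[["min_evi"]] >= thr) {
    message("site ", data$site[1], ", year ", year,
            ": EVI never falls below ", thr, "; dry period undetected")
    return(c(dpo = NA_real_, dpe = NA_real_))
  }
  # downward crossing between max date and min date
  sel <- which(ext >= extrema[["max_date"]] & ext <= extrema[["min_date"]])
  dpo <- NA_real_
  for (i in utils::head(sel, -1L)) {
    if (v[i] >= thr && v[i + 1L] < thr) {
      dpo <- cross_doy(ext[i], v[i], ext[i + 1L], v[i + 1L], thr)
      break
    }
  }
  # upward crossing from the min date onward (may wrap past DOY 365)
  sel <- which(ext >= extrema[["min_date"]] & ext <= 365 + 180)
  dpe <- NA_real_
  for (i in utils::head(sel, -1L)) {
    if (v[i] < thr && v[i + 1L] >= thr) {
      dpe <- cross_doy(ext[i], v[i], ext[i + 1L], v[i + 1L], thr)
      break
    }
  }
  c(dpo = dpo, dpe = dpe)
}

metric_columns <- function() {
  c("sdo", "sde", "sdd", "aro", "are", "ard",
    "dpo", "dpe", "dpd", "max_evi", "max_date", "min_evi", "min_date")
}

#' Extract all thirteen phenology metrics, per site and year
#'
#' Combines the derivative rule (spring drop SDO/SDE, autumn revival
#' ARO/ARE), the threshold rule (dry period DPO/DPE) and the annual
#' extrema into one row per site and year. Durations are differences
#' of end and onset (SDD = SDE - SDO, ARD = ARE - ARO,
#' DPD = DPE - DPO). Events that wrap into the next calendar year
#' carry extended days of year (above 365) and are attributed to the
#' year of the spring drop. Undetected events are `NA`.
#'
#' @param data Smoothed EVI series, one pixel (or the site mean) per
#'   site, complete composite calendar.
#' @param params A [detection_params()] object.
#' @return Tibble with `site`, `year` and the 13 metric columns
#'   `sdo, sde, sdd, aro, are, ard, dpo, dpe, dpd, max_evi, max_date,
#'   min_evi, min_date`.
#' @export
extract_all_metrics <- function(data, params = detection_params()) {
  data <- check_evi_series(data, complete = TRUE)
  per_pixel <- data |>
    dplyr::distinct(.data$site, .data$pixel) |>
    dplyr::count(.data$site)
  if (any(per_pixel$n > 1L)) {
    stop("multiple pixels per site; run average_pixels() first",
         call. = FALSE)
  }
  one_site <- function(g) {
    deriv <- first_derivative(g)
    years <- sort(unique(date_year(g$date)))
    rows <- purrr::map(years, function(y) {
      ex <- extrema_metrics(g, y, params)
      spring <- detect_transition(g, "falling", y,
                                  params$spring_search_window,
                                  params, deriv)
      autumn <- detect_transition(g, "rising", y,
                                  params$autumn_search_window,
                                  params, deriv)
      dp <- detect_dry_period(g, y, params, extrema = ex)
      tibble::tibble(
        site = g$site[1L], year = y,
        sdo = spring[["onset"]], sde = spring[["end"]],
        sdd = spring[["end"]] - spring[["onset"]],
        aro = autumn[["onset"]], are = autumn[["end"]],
        ard = autumn[["end"]] - autumn[["onset"]],
        dpo = dp[["dpo"]], dpe = dp[["dpe"]],
        dpd = dp[["dpe"]] - dp[["dpo"]],
        max_evi = ex[["max_evi"]], max_date = ex[["max_date"]],
        min_evi = ex[["min_evi"]], min_date = ex[["min_date"]]
      )
    })
    purrr::list_rbind(rows)
  }
  data |>
    dplyr::group_split(.data$site) |>
    purrr::map(one_site) |>
    purrr::list_rbind()
}

#' Compare phenology metrics between two sites
#'
#' Pairs the per-year metric tables of two sites by year (years with a
#' missing value in either site are dropped pairwise per metric) and
#' reports per-site means and standard deviations, the difference of
#' means (site a minus site b), and a two-sided paired t-test p-value.
#'
#' @param metrics_a,metrics_b Tables from [extract_all_metrics()].
#' @return Tibble with one row per metric: `metric`, `mean_a`, `sd_a`,
#'   `mean_b`, `sd_b`, `difference`, `n_pairs`, `p_value`. With fewer
#'   than 3 complete pairs, or a degenerate zero-variance difference,
#'   the p-value is `NA` (identical values give p = 1).
#' @export
compare_sites <- function(metrics_a, metrics_b) {
  cols <- metric_columns()
  long <- function(m, side) {
    tibble::as_tibble(m) |>
      dplyr::select("year", dplyr::any_of(cols)) |>
      tidyr::pivot_longer(-"year", names_to = "metric",
                          values_to = side)
  }
  paired <- dplyr::inner_join(long(metrics_a, "a"), long(metrics_b, "b"),
                              by = c("year", "metric"))
  one <- function(g) {
    ok <- stats::complete.cases(g$a, g$b)
    a <- g$a[ok]
    b <- g$b[ok]
    n <- length(a)
    p <- NA_real_
    if (n >= 3L) {
      d <- a - b
      if (stats::sd(d) < 1e-12) {
        p <- if (abs(mean(d)) < 1e-12) 1 else {
          warning("constant nonzero difference for ", g$metric[1L],
                  "; paired t-test degenerate (p -> 0)", call. = FALSE)
          0
        }
      } else {
        p <- stats::t.test(a, b, paired = TRUE)$p.value
      }
    }
    tibble::tibble(
      metric = g$metric[1L],
      mean_a = mean(a), sd_a = stats::sd(a),
      mean_b = mean(b), sd_b = stats::sd(b),
      difference = mean(a) - mean(b),
      n_pairs = n, p_value = p
    )
  }
  paired |>
    dplyr::group_split(.data$metric) |>
    purrr::map(one) |>
    purrr::list_rbind() |>
    dplyr::arrange(match(.data$metric, cols))
}
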