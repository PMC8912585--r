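#' Aggregate daily climate records to monthly values
#'
#' Monthly mean of daily mean temperature, total precipitation, and
#' rain-day count (days with precipitation at or above
#' `rain_day_min`). Months missing more than 20% of their days are
#' kept as rows but flagged incomplete with `NA` values.
#'
#' @param daily Data frame with columns `date`, `tavg_c` (daily mean
#'   temperature, degrees C) and `prcp_mm` (daily precipitation, mm,
#'   non-negative).
#' @param rain_day_min Minimum daily precipitation (mm) for a day to
#'   count as a rain day.
#' @return Tibble with `year`, `month`, `t_mean`, `p_total`,
#'   `rain_days`, `n_days`, `complete`.
#' @export
aggregate_monthly <- function(daily, rain_day_min = 1) {
  daily <- tibble::as_tibble(daily)
  need <- c("date", "tavg_c", "prcp_mm")
  miss <- setdiff(need, names(daily))
  if (length(miss) > 0L) {
    stop("daily climate is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!inherits(daily$date, "Date")) daily$date <- as.Date(daily$date)
  if (any(daily$prcp_mm < 0, na.rm = TRUE)) {
    stop("precipitation must be non-negative", call. = FALSE)
  }
  out <- daily |>
    dplyr::mutate(year = date_year(.data$date),
                  month = date_month(.data$date)) |>
    dplyr::group_by(.data$year, .data$month) |>
    dplyr::summarise(
      t_mean = mean(.data$tavg_c, na.rm = TRUE),
      p_total = sum(.data$prcp_mm, na.rm = TRUE),
      rain_days = sum(.data$prcp_mm >= rain_day_min, na.rm = TRUE),
      n_days = sum(!is.na(.data$tavg_c) | !is.na(.data$prcp_mm)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      complete = .data$n_days >= 0.8 * days_in_month(.data$year, .data$month)
    )
  out$t_mean[!out$complete] <- NA_real_
  out$p_total[!out$complete] <- NA_real_
  out$rain_days[!out$complete] <- NA_integer_
  out
}

#' Enumerate lagged climate-window predictors
#'
#' For each climate variable (mean temperature `T`, total
#' precipitation `Pr`, rain days `RD`) the candidate predictors are
#' the aggregations over 1 to `max_n_lag0` consecutive months ending
#' at the event month (lag 0), plus 1 to `max_n_lagged` consecutive
#' months ending 1 to `max_lag` months before it. A window is named
#' `VAR_n_lag`: `T_2_1` is the mean temperature of the two months
#' ending one month before the event.
#'
#' @param max_n_lag0 Largest window length at lag 0 (months).
#' @param max_n_lagged Largest window length at positive lags.
#' @param max_lag Largest lag (months).
#' @return Tibble with `variable`, `n_months`, `lag_months`, `name`,
#'   in deterministic (variable, lag, n) order. Defaults give
#'   3 x (6 + 5 x 5) = 93 windows.
#' @export
#' @examples
#' nrow(enumerate_windows())
enumerate_windows <- function(max_n_lag0 = 6, max_n_lagged = 5,
                              max_lag = 5) {
  vars <- c("T", "Pr", "RD")
  rows <- list()
  for (v in vars) {
    rows[[length(rows) + 1L]] <-
      tibble::tibble(variable = v, n_months = seq_len(max_n_lag0),
                     lag_months = 0L)
    if (max_lag >= 1) {
      for (l in seq_len(max_lag)) {
        rows[[length(rows) + 1L]] <-
          tibble::tibble(variable = v, n_months = seq_len(max_n_lagged),
                         lag_months = as.integer(l))
      }
    }
  }
  out <- purrr::list_rbind(rows)
  out$name <- sprintf("%s_%d_%d", out$variable, out$n_months,
                      out$lag_months)
  out
}

#' @keywords internal
parse_window_name <- function(name) {
  parts <- strsplit(name, "_", fixed = TRUE)
  tibble::tibble(
    variable = vapply(parts, `[[`, "", 1L),
    n_months = as.integer(vapply(parts, `[[`, "", 2L)),
    lag_months = as.integer(vapply(parts, `[[`, "", 3L)),
    name = name
  )
}

#' Value of one climate window for one event
#'
#' The window ends at `event_month - lag_months` and spans `n_months`
#' backwards, crossing year boundaries as needed; a lag of 0 includes
#' the event month itself. Temperature windows are averaged,
#' precipitation and rain-day windows are summed.
#'
#' @param monthly Monthly climate table from [aggregate_monthly()].
#' @param variable `"T"`, `"Pr"` or `"RD"`.
#' @param n_months,lag_months Window length and lag (months).
#' @param event_year,event_month Calendar anchor of the event.
#' @return A single numeric value, or `NA` when any month in the
#'   window is absent or incomplete.
#' @export
#' @examples
#' # Pr_2_0 anchored at October aggregates October + September
window_value <- function(monthly, variable, n_months, lag_months,
                         event_year, event_month) {
  end <- event_year * 12L + (event_month - 1L) - lag_months
  mons <- end - seq_len(n_months) + 1L
  key <- monthly$year * 12L + (monthly$month - 1L)
  idx <- match(mons, key)
  if (anyNA(idx)) return(NA_real_)
  col <- switch(variable, "T" = "t_mean", Pr = "p_total",
                RD = "rain_days",
                stop("unknown climate variable: ", variable,
                     call. = FALSE))
  vals <- monthly[[col]][idx]
  if (anyNA(vals)) return(NA_real_)
  if (variable == "T") mean(vals) else sum(vals)
}

#' Build a predictor matrix of climate windows for a set of anchors
#'
#' Computes every window in `windows` for every anchor row, returning
#' a wide tibble whose predictor columns are named `VAR_n_lag`.
#'
#' @param monthly Monthly climate table from [aggregate_monthly()].
#' @param anchors Data frame with columns `year` and `month` (one row
#'   per event or per EVI month); other columns are carried through.
#' @param windows Window table from [enumerate_windows()].
#' @return `anchors` with one numeric column per window appended.
#' @export
window_predictors <- function(monthly, anchors,
                              windows = enumerate_windows()) {
  anchors <- tibble::as_tibble(anchors)
  stopifnot(all(c("year", "month") %in% names(anchors)))
  key <- monthly$year * 12L + (monthly$month - 1L)
  series <- list("T" = monthly$t_mean, Pr = monthly$p_total,
                 RD = as.numeric(monthly$rain_days))
  a_end <- anchors$year * 12L + (anchors$month - 1L)
  for (i in seq_len(nrow(windows))) {
    w <- windows[i, ]
    mons_end <- a_end - w$lag_months
    acc <- rep(0, nrow(anchors))
    ok <- rep(TRUE, nrow(anchors))
    for (j in seq_len(w$n_months) - 1L) {
      idx <- match(mons_end - j, key)
      vals <- series[[w$variable]][idx]
      ok <- ok & !is.na(vals)
      vals[is.na(vals)] <- 0
      acc <- acc + vals
    }
    if (w$variable == "T") acc <- acc / w$n_months
    acc[!ok] <- NA_real_
    anchors[[w$name]] <- acc
  }
  anchors
}
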