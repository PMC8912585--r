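#' The 8-day composite calendar
#'
#' Satellite surface-reflectance composites restart on 1 January every
#' year and advance in 8-day steps, so every year holds exactly 46
#' composites whose start days-of-year are 1, 9, ..., 361 (the final
#' composite absorbs the 365th/366th day).
#'
#' @return Integer vector of the 46 composite start days-of-year.
#' @export
#' @examples
#' composite_doys()
composite_doys <- function() seq(1L, 361L, by = 8L)

#' Composite start dates for a set of years
#'
#' @param years Integer vector of calendar years.
#' @return A `Date` vector with 46 composite start dates per year, in
#'   calendar order.
#' @export
composite_dates <- function(years) {
  doys <- composite_doys()
  out <- lapply(sort(unique(as.integer(years))), function(y) {
    as.Date(sprintf("%d-01-01", y)) + (doys - 1L)
  })
  do.call(c, out)
}

#' @keywords internal
date_year <- function(date) as.integer(format(date, "%Y"))

#' @keywords internal
date_month <- function(date) as.integer(format(date, "%m"))

#' Day of year (1-based)
#' @param date A `Date` vector.
#' @return Integer day of year, 1 on 1 January.
#' @export
doy <- function(date) as.POSIXlt(date)$yday + 1L

#' Extended day of year relative to a base year
#'
#' Phenological events late in the cycle can fall in the calendar year
#' after the one they are attributed to. Days are counted past 365 in
#' that case (370 = 5 January of the following year), using a fixed
#' 365-day year offset so values are comparable across leap years.
#'
#' @param date A `Date` vector.
#' @param base_year Year the value is expressed relative to.
#' @return Numeric extended day of year.
#' @export
doy_ext <- function(date, base_year) {
  (date_year(date) - as.integer(base_year)) * 365 + doy(date)
}

#' @keywords internal
days_in_month <- function(year, month) {
  first <- as.Date(sprintf("%d-%02d-01", year, month))
  nxt_y <- ifelse(month == 12L, year + 1L, year)
  nxt_m <- ifelse(month == 12L, 1L, month + 1L)
  as.integer(as.Date(sprintf("%d-%02d-01", nxt_y, nxt_m)) - first)
}

#' Validate an EVI series table
#'
#' Checks the contract every series-processing function relies on:
#' columns `site`, `pixel`, `date`, `evi` (and optionally `flag`),
#' strictly increasing dates within each site/pixel, finite EVI, and a
#' complete composite calendar (exactly 46 composites at start
#' days-of-year 1, 9, ..., 361) for every covered year.
#'
#' @param data A data frame with one row per site/pixel/composite.
#' @param complete Require the full 46-composite calendar per year?
#' @return `data` (as a tibble), invisibly usable in pipes.
#' @export
check_evi_series <- function(data, complete = TRUE) {
  data <- tibble::as_tibble(data)
  need <- c("site", "pixel", "date", "evi")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0L) {
    stop("EVI series is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!inherits(data$date, "Date")) data$date <- as.Date(data$date)
  if (!all(is.finite(data$evi))) {
    stop("EVI series contains non-finite values", call. = FALSE)
  }
  cal <- composite_doys()
  groups <- split(data, paste(data$site, data$pixel, sep = "\r"))
  for (g in groups) {
    if (is.unsorted(g$date, strictly = TRUE)) {
      stop("dates must be strictly increasing within each site/pixel",
           call. = FALSE)
    }
    if (!all(doy(g$date) %in% cal)) {
      bad <- g$date[!doy(g$date) %in% cal]
      stop("dates off the 8-day composite calendar: ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
    if (complete) {
      tab <- table(date_year(g$date))
      if (any(tab != 46L)) {
        yrs <- names(tab)[tab != 46L]
        stop("incomplete composite calendar (expected 46/year) in year(s): ",
             paste(yrs, collapse = ", "),
             "; gap-fill with complete_composites() first", call. = FALSE)
      }
    }
  }
  data
}

#' Fill missing composites by linear interpolation
#'
#' Completes each site/pixel series to the full 46-composite calendar
#' between its first and last covered year, interpolating EVI linearly
#' over composite index and flagging inserted points `"gap-filled"`.
#' Smoothing requires a gapless calendar; cleaning (BISE) runs on the
#' observed points only, so run this between the two.
#'
#' @param data EVI series table (`site`, `pixel`, `date`, `evi`, `flag`).
#' @return Completed tibble on the full calendar.
#' @export
complete_composites <- function(data) {
  data <- check_evi_series(data, complete = FALSE)
  if (!"flag" %in% names(data)) data$flag <- "observed"
  fill_one <- function(g) {
    yrs <- seq(min(date_year(g$date)), max(date_year(g$date)))
    grid <- composite_dates(yrs)
    idx <- match(g$date, grid)
    if (anyNA(idx)) stop("dates off the composite grid", call. = FALSE)
    evi <- stats::approx(idx, g$evi, xout = seq_along(grid), rule = 2)$y
    flag <- rep("gap-filled", length(grid))
    flag[idx] <- g$flag
    tibble::tibble(site = g$site[1], pixel = g$pixel[1],
                   date = grid, evi = evi, flag = flag)
  }
  data |>
    dplyr::group_split(.data$site, .data$pixel) |>
    purrr::map(fill_one) |>
    purrr::list_rbind()
}
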