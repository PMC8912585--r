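#' Read an EVI or surface-reflectance CSV
#'
#' Accepts either dialect: an index file with columns
#' `site,pixel,date,evi` or a reflectance file with columns
#' `site,pixel,date,r_blue,r_red,r_nir` (EVI is then computed).
#' Dates are ISO-8601.
#'
#' @param path CSV file path.
#' @return EVI series tibble (`site`, `pixel`, `date`, `evi`, `flag`).
#' @export
read_evi_csv <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE)
  if (all(c("r_blue", "r_red", "r_nir") %in% names(data))) {
    data <- compute_evi(data)
    data <- data[setdiff(names(data), c("r_blue", "r_red", "r_nir"))]
  }
  if (!"flag" %in% names(data)) data$flag <- "observed"
  check_evi_series(data, complete = FALSE)
}

#' Write an EVI series CSV
#'
#' @param data EVI series tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_evi_csv <- function(data, path) {
  readr::write_csv(
    data[intersect(c("site", "pixel", "date", "evi", "flag"),
                   names(data))], path)
  invisible(path)
}

#' Read a daily climate CSV
#'
#' Expects columns `date,tavg_c,prcp_mm` (station-record style, ISO
#' dates, temperature in degrees C, precipitation in mm).
#'
#' @param path CSV file path.
#' @return Tibble with the three columns.
#' @export
read_climate_csv <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("date", "tavg_c", "prcp_mm")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0L) {
    stop("climate CSV ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  data$date <- as.Date(data$date)
  tibble::as_tibble(data[need])
}
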