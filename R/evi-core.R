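#' Smoothing and cleaning parameters
#'
#' Bundles the tunables of the two series-conditioning steps: BISE
#' (Best Index Slope Extraction) rejection of cloud-depressed
#' composites and Fourier-harmonic smoothing with optional
#' upper-envelope reweighting.
#'
#' @param n_harmonics Harmonics retained per year (cycles/year) by
#'   [fft_smooth()]. 0 keeps only the series mean.
#' @param envelope_iterations Upper-envelope passes in [fft_smooth()]:
#'   in each pass, points lying above the current fit get double weight
#'   and the fit is recomputed, biasing the fit toward the upper
#'   envelope because residual cloud contamination only depresses EVI.
#' @param bise_slide_composites Sliding-window length (composites, ~8
#'   days each) that BISE searches forward for a recovery.
#' @param bise_recovery_fraction Fraction of a drop that a subsequent
#'   point must regain for the dropped point to be rejected as noise.
#' @return A validated list of class `smoothing_params`.
#' @export
#' @examples
#' smoothing_params()
smoothing_params <- function(n_harmonics = 5L,
                             envelope_iterations = 2L,
                             bise_slide_composites = 5L,
                             bise_recovery_fraction = 0.5) {
  stopifnot(
    length(n_harmonics) == 1L, n_harmonics >= 0,
    length(envelope_iterations) == 1L, envelope_iterations >= 0,
    length(bise_slide_composites) == 1L, bise_slide_composites >= 1,
    length(bise_recovery_fraction) == 1L,
    bise_recovery_fraction > 0, bise_recovery_fraction <= 1
  )
  structure(
    list(n_harmonics = as.integer(n_harmonics),
         envelope_iterations = as.integer(envelope_iterations),
         bise_slide_composites = as.integer(bise_slide_composites),
         bise_recovery_fraction = bise_recovery_fraction),
    class = "smoothing_params"
  )
}

#' Compute the Enhanced Vegetation Index from surface reflectance
#'
#' EVI = 2.5 (R_nir - R_red) / (R_nir + 6 R_red - 7.5 R_blue + 1),
#' with R_nir, R_red, R_blue the near-infrared (841-875 nm), red
#' (620-670 nm) and blue (459-479 nm) surface reflectances.
#'
#' @param data Data frame with columns `r_blue`, `r_red`, `r_nir`
#'   (each in \[0, 1\]); any other columns (`site`, `pixel`, `date`)
#'   are carried through.
#' @return `data` as a tibble with `evi` and `flag = "observed"`
#'   columns added and the reflectance columns retained.
#' @export
#' @examples
#' compute_evi(tibble::tibble(r_blue = 0.02, r_red = 0.05, r_nir = 0.3))
compute_evi <- function(data) {
  data <- tibble::as_tibble(data)
  need <- c("r_blue", "r_red", "r_nir")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0L) {
    stop("reflectance input is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  refl <- as.matrix(data[need])
  if (!all(is.finite(refl))) {
    stop("reflectances must be finite", call. = FALSE)
  }
  if (any(refl < 0 | refl > 1)) {
    stop("reflectances must lie in [0, 1]", call. = FALSE)
  }
  den <- data$r_nir + 6 * data$r_red - 7.5 * data$r_blue + 1
  bad <- abs(den) < 1e-9
  if (any(bad)) {
    where <- if ("date" %in% names(data)) {
      paste(utils::head(data$date[bad], 5), collapse = ", ")
    } else {
      paste("row", paste(utils::head(which(bad), 5), collapse = ", "))
    }
    stop("invalid sample: near-zero EVI denominator at ", where,
         call. = FALSE)
  }
  data$evi <- 2.5 * (data$r_nir - data$r_red) / den
  data$flag <- "observed"
  data
}

# One forward BISE scan: returns logical vector, FALSE = rejected.
# A point that drops relative to the last accepted value is rejected
# when some later point inside the sliding window climbs back above
# the dropped value by at least `frac` of the drop (the quick recovery
# marks the low value as a cloud artefact, not vegetation change).
bise_scan <- function(v, window, frac) {
  n <- length(v)
  keep <- rep(TRUE, n)
  acc <- v[1L]
  for (i in 2:n) {
    if (v[i] >= acc) {
      acc <- v[i]
      next
    }
    drop_i <- acc - v[i]
    j_hi <- min(n, i + window)
    if (j_hi > i && any(v[(i + 1):j_hi] >= v[i] + frac * drop_i)) {
      keep[i] <- FALSE
    } else {
      acc <- v[i]
    }
  }
  keep
}

#' Reject cloud-depressed composites (BISE)
#'
#' Forward-scanning Best Index Slope Extraction: a composite whose EVI
#' drops relative to the previously accepted value and recovers within
#' the sliding window is treated as cloud contamination, removed, and
#' replaced by linear interpolation between accepted neighbours
#' (flagged `"bise-replaced"`). Accepted composites are unchanged. The
#' scan-and-replace pass is iterated to a fixed point so the operation
#' is idempotent.
#'
#' @param data EVI series table (`site`, `pixel`, `date`, `evi`, and
#'   optionally `flag`).
#' @param params A [smoothing_params()] object.
#' @return The corrected series as a tibble.
#' @export
bise_correct <- function(data, params = smoothing_params()) {
  stopifnot(inherits(params, "smoothing_params"))
  data <- check_evi_series(data, complete = FALSE)
  if (!"flag" %in% names(data)) data$flag <- "observed"
  window <- params$bise_slide_composites
  frac <- params$bise_recovery_fraction
  fix_one <- function(g) {
    v <- g$evi
    n <- length(v)
    if (n < window + 2L) {
      stop("BISE needs at least ", window + 2L, " composites; ",
           g$site[1], "/", g$pixel[1], " has ", n, call. = FALSE)
    }
    flag <- g$flag
    for (pass in 1:10) {
      keep <- bise_scan(v, window, frac)
      if (sum(keep) < 2L) {
        stop("BISE rejected nearly all composites for ",
             g$site[1], "/", g$pixel[1], call. = FALSE)
      }
      v_new <- v
      if (any(!keep)) {
        v_new[!keep] <- stats::approx(which(keep), v[keep],
                                      xout = which(!keep), rule = 2)$y
        flag[!keep] <- "bise-replaced"
      }
      if (max(abs(v_new - v)) < 1e-12) {
        v <- v_new
        break
      }
      v <- v_new
    }
    g$evi <- v
    g$flag <- flag
    g
  }
  data |>
    dplyr::group_split(.data$site, .data$pixel) |>
    purrr::map(fix_one) |>
    purrr::list_rbind()
}

# Truncated discrete Fourier reconstruction keeping the mean plus all
# harmonics up to keep_k cycles per series length.
fourier_truncate <- function(v, keep_k) {
  n <- length(v)
  if (keep_k >= floor(n / 2)) return(v)
  co <- stats::fft(v)
  k <- 0:(n - 1)
  cyc <- pmin(k, n - k)
  co[cyc > keep_k] <- 0
  Re(stats::fft(co, inverse = TRUE)) / n
}

# Harmonic design matrix: intercept plus cos/sin pairs for 1..keep_k
# cycles per series. Used only for the weighted envelope passes, where
# the orthogonality that makes the FFT shortcut exact no longer holds.
harmonic_basis <- function(n, keep_k) {
  keep_k <- min(keep_k, floor((n - 1) / 2))
  t <- (0:(n - 1)) / n
  cols <- vector("list", 2L * keep_k + 1L)
  cols[[1L]] <- rep(1, n)
  for (j in seq_len(keep_k)) {
    cols[[2L * j]] <- cos(2 * pi * j * t)
    cols[[2L * j + 1L]] <- sin(2 * pi * j * t)
  }
  do.call(cbind, cols)
}

#' Fourier-harmonic smoothing with upper-envelope adjustment
#'
#' Decomposes the full multi-year series into Fourier harmonics,
#' retains the mean plus all harmonics up to `n_harmonics` cycles per
#' year, and optionally applies envelope passes in which input points
#' above the current fit receive double weight before the harmonic fit
#' is recomputed. Because residual cloud contamination only depresses
#' the index, the reweighting pulls the reconstruction toward the
#' upper envelope of the data.
#'
#' @inheritParams bise_correct
#' @return The smoothed series as a tibble, flagged `"smoothed"`.
#' @export
fft_smooth <- function(data, params = smoothing_params()) {
  stopifnot(inherits(params, "smoothing_params"))
  data <- check_evi_series(data, complete = TRUE)
  smooth_one <- function(g) {
    v <- g$evi
    n <- length(v)
    n_years <- n / 46L
    keep_k <- params$n_harmonics * n_years
    fit <- fourier_truncate(v, keep_k)
    if (params$envelope_iterations > 0L && keep_k < floor(n / 2)) {
      basis <- harmonic_basis(n, keep_k)
      for (it in seq_len(params$envelope_iterations)) {
        w <- 1 + as.numeric(v > fit)
        beta <- stats::lm.wfit(basis, v, w)$coefficients
        beta[is.na(beta)] <- 0
        fit <- drop(basis %*% beta)
      }
    }
    g$evi <- fit
    g$flag <- "smoothed"
    g
  }
  data |>
    dplyr::group_split(.data$site, .data$pixel) |>
    purrr::map(smooth_one) |>
    purrr::list_rbind()
}

#' Average pixel series into one series per site
#'
#' Per-site, per-date arithmetic mean over pixels; the result carries
#' `pixel = "site-mean"`. All pixels of a site must share an identical
#' composite date grid.
#'
#' @param data EVI series table holding one or more pixels per site;
#'   a list of such tables is also accepted and row-bound first.
#' @return One averaged series per site.
#' @export
average_pixels <- function(data) {
  if (is.list(data) && !is.data.frame(data)) data <- purrr::list_rbind(
    purrr::map(data, tibble::as_tibble))
  data <- check_evi_series(data, complete = FALSE)
  if (!"flag" %in% names(data)) data$flag <- "observed"
  avg_one <- function(g) {
    grids <- split(g$date, g$pixel)
    ref <- grids[[1L]]
    for (p in names(grids)) {
      if (length(grids[[p]]) != length(ref) || any(grids[[p]] != ref)) {
        off <- c(setdiff(grids[[p]], ref), setdiff(ref, grids[[p]]))
        stop("pixel date grids differ for site ", g$site[1], " at: ",
             paste(utils::head(as.Date(off, origin = "1970-01-01"), 5),
                   collapse = ", "), call. = FALSE)
      }
    }
    g |>
      dplyr::group_by(.data$site, .data$date) |>
      dplyr::summarise(
        evi = mean(.data$evi),
        flag = if (dplyr::n_distinct(.data$flag) == 1L)
          .data$flag[1L] else "observed",
        .groups = "drop"
      ) |>
      dplyr::mutate(pixel = "site-mean", .after = "site")
  }
  data |>
    dplyr::group_split(.data$site) |>
    purrr::map(avg_one) |>
    purrr::list_rbind()
}

#' Monthly mean EVI
#'
#' Assigns each composite to the calendar month containing its start
#' date and averages within site, year and month.
#'
#' @inheritParams bise_correct
#' @return Tibble with `site`, `year`, `month`, `evi`.
#' @export
monthly_mean_evi <- function(data) {
  data <- check_evi_series(data, complete = FALSE)
  data |>
    dplyr::mutate(year = date_year(.data$date),
                  month = date_month(.data$date)) |>
    dplyr::group_by(.data$site, .data$year, .data$month) |>
    dplyr::summarise(evi = mean(.data$evi), .groups = "drop")
}

#' Average annual EVI profile
#'
#' Cross-year mean and sample standard deviation of EVI for each of
#' the 46 composite positions.
#'
#' @inheritParams bise_correct
#' @return Tibble with `site`, `composite` (1-46), `doy` (composite
#'   start day of year), `mean_evi`, `sd_evi`.
#' @export
annual_profile <- function(data) {
  data <- check_evi_series(data, complete = TRUE)
  n_years <- data |>
    dplyr::group_by(.data$site) |>
    dplyr::summarise(n = dplyr::n_distinct(date_year(.data$date)))
  if (any(n_years$n < 2L)) {
    stop("annual_profile needs at least 2 complete years (SD undefined); ",
         "got ", min(n_years$n), call. = FALSE)
  }
  cal <- composite_doys()
  data |>
    dplyr::mutate(composite = match(doy(.data$date), cal)) |>
    dplyr::group_by(.data$site, .data$composite) |>
    dplyr::summarise(mean_evi = mean(.data$evi),
                     sd_evi = stats::sd(.data$evi),
                     .groups = "drop") |>
    dplyr::mutate(doy = cal[.data$composite], .after = "composite")
}
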