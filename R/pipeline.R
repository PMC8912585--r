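# Anchor metric used to place the climate windows of each response:
# durations and extrema values anchor at the date-type event that ends
# or locates them.
anchor_metric <- function(metric) {
  switch(metric,
         sdd = "sde", ard = "are", dpd = "dpe",
         max_evi = "max_date", min_evi = "min_date",
         metric)
}

#' Run the full phenology pipeline
#'
#' Executes the stages end to end for one or more sites: preprocess
#' (EVI construction, BISE cleaning, Fourier smoothing, pixel
#' averaging), phenology metric extraction, two-site comparison,
#' climate-driver attribution of every metric (Pearson screening +
#' stepwise MLR on lagged climate windows anchored at the long-term
#' mean month of each event), interannual trend fits, and monthly-EVI
#' models (best-pair MLR vs random forest).
#'
#' @param sites Named list, one element per site, each a list with
#'   `evi` (EVI/reflectance tibble or CSV path) and `climate` (daily
#'   climate tibble or CSV path).
#' @param detection A [detection_params()] object.
#' @param smoothing A [smoothing_params()] object.
#' @param windows Climate-window table from [enumerate_windows()].
#' @param rain_day_min Rain-day threshold (mm/day).
#' @param k Screened candidates kept for stepwise/model selection.
#' @param seed Seed for the random-forest stage.
#' @param out_dir Optional directory; when given, all stage products
#'   are written as CSV/JSON together with a manifest (config hash,
#'   seed, stages).
#' @return A list of class `pheno_pipeline` with elements `series`
#'   (smoothed site series), `metrics`, `comparison` (two-site runs
#'   only), `drivers`, `trends`, `evi_models`, and `manifest`.
#' @export
run_pipeline <- function(sites,
                         detection = detection_params(),
                         smoothing = smoothing_params(),
                         windows = enumerate_windows(),
                         rain_day_min = 1, k = 10, seed = 1L,
                         out_dir = NULL) {
  if (is.null(names(sites)) || any(names(sites) == "")) {
    stop("`sites` must be a named list", call. = FALSE)
  }
  for (nm in names(sites)) {
    s <- sites[[nm]]
    if (is.null(s$evi)) {
      stop("site ", nm, ": missing `evi` input", call. = FALSE)
    }
    if (is.null(s$climate)) {
      stop("site ", nm, ": missing `climate` input", call. = FALSE)
    }
    if (is.character(s$evi) && !file.exists(s$evi)) {
      stop("site ", nm, ": EVI path does not exist: ", s$evi,
           call. = FALSE)
    }
    if (is.character(s$climate) && !file.exists(s$climate)) {
      stop("site ", nm, ": climate path does not exist: ", s$climate,
           call. = FALSE)
    }
  }
  stages <- character(0)
  run_stage <- function(name, expr) {
    out <- tryCatch(force(expr), error = function(e) {
      stop("pipeline stage '", name, "' failed: ",
           conditionMessage(e), call. = FALSE)
    })
    stages <<- c(stages, name)
    out
  }

  series <- run_stage("preprocess", {
    purrr::imap(sites, function(s, nm) {
      evi <- if (is.character(s$evi)) read_evi_csv(s$evi) else {
        d <- tibble::as_tibble(s$evi)
        if (all(c("r_blue", "r_red", "r_nir") %in% names(d))) {
          d <- compute_evi(d)
        }
        if (!"flag" %in% names(d)) d$flag <- "observed"
        d
      }
      evi$site <- nm
      evi |>
        bise_correct(smoothing) |>
        complete_composites() |>
        fft_smooth(smoothing) |>
        average_pixels()
    }) |> purrr::list_rbind()
  })

  climate_monthly <- purrr::imap(sites, function(s, nm) {
    daily <- if (is.character(s$climate)) read_climate_csv(s$climate)
             else tibble::as_tibble(s$climate)
    aggregate_monthly(daily, rain_day_min)
  })

  metrics <- run_stage("phenology",
                       extract_all_metrics(series, detection))

  comparison <- run_stage("compare", {
    if (length(sites) == 2L) {
      nms <- names(sites)
      compare_sites(metrics[metrics$site == nms[1L], ],
                    metrics[metrics$site == nms[2L], ])
    } else NULL
  })

  drivers <- run_stage("drivers", {
    rows <- list()
    for (nm in names(sites)) {
      m <- metrics[metrics$site == nm, ]
      monthly <- climate_monthly[[nm]]
      for (metric in metric_columns()) {
        resp <- m[[metric]]
        if (sum(!is.na(resp)) < 8L) next
        anchor <- anchor_metric(metric)
        mean_doy <- mean(m[[anchor]], na.rm = TRUE)
        anchors <- tibble::tibble(
          year = m$year + as.integer(mean_doy > 365),
          month = month_of_doy(mean_doy)
        )
        x <- window_predictors(monthly, anchors, windows)
        x$.response <- resp
        fit <- stepwise_mlr(x, ".response", candidates = windows$name,
                            k = k)
        rows[[paste(nm, metric)]] <- tibble::tibble(
          site = nm, metric = metric,
          selected = paste(fit$selected, collapse = "+"),
          n_selected = length(fit$selected),
          r_squared = fit$r_squared, p_value = fit$p_value,
          n_years = fit$n
        )
      }
    }
    purrr::list_rbind(rows)
  })

  trends <- run_stage("trends", {
    rows <- list()
    for (nm in names(sites)) {
      m <- metrics[metrics$site == nm, ]
      for (metric in metric_columns()) {
        if (sum(!is.na(m[[metric]])) < 3L) next
        tr <- trend_fit(m, metric)
        tr$site <- nm
        rows[[paste(nm, metric)]] <- tr[c("site", "series", "slope",
                                          "intercept", "p", "n_years")]
      }
    }
    purrr::list_rbind(rows)
  })

  evi_models <- run_stage("evi-models", {
    purrr::imap(sites, function(s, nm) {
      evi_m <- monthly_mean_evi(series[series$site == nm, ])
      mlr <- mlr_evi_model(evi_m, climate_monthly[[nm]], windows, k)
      rf <- rf_evi_model(evi_m, climate_monthly[[nm]], seed = seed,
                         windows = windows)
      list(mlr = mlr, rf = rf, comparison = compare_models(mlr, rf))
    })
  })

  config <- list(
    sites = names(sites), detection = unclass(detection),
    smoothing = unclass(smoothing), rain_day_min = rain_day_min,
    k = k, seed = as.integer(seed), n_windows = nrow(windows)
  )
  manifest <- list(
    package = "phenoevi",
    version = as.character(utils::packageVersion("phenoevi")),
    config_hash = rlang::hash(config),
    seed = as.integer(seed),
    stages = stages
  )

  result <- structure(
    list(series = series, metrics = metrics, comparison = comparison,
         drivers = drivers, trends = trends, evi_models = evi_models,
         climate_monthly = climate_monthly, manifest = manifest,
         config = config),
    class = "pheno_pipeline"
  )
  if (!is.null(out_dir)) write_pipeline(result, out_dir)
  result
}

#' @keywords internal
write_pipeline <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_evi_csv(result$series, file.path(out_dir, "series_smoothed.csv"))
  readr::write_csv(result$metrics, file.path(out_dir, "metrics.csv"))
  if (!is.null(result$comparison)) {
    readr::write_csv(result$comparison,
                     file.path(out_dir, "site_comparison.csv"))
  }
  readr::write_csv(result$drivers, file.path(out_dir, "drivers.csv"))
  readr::write_csv(result$trends, file.path(out_dir, "trends.csv"))
  models <- purrr::imap(result$evi_models, function(m, nm) {
    list(mlr = list(selected = m$mlr$selected,
                    coefficients = as.list(m$mlr$coefficients),
                    r_squared = m$mlr$r_squared, rmse = m$mlr$rmse),
         rf = list(seed = m$rf$seed, r2_test = m$rf$r2_test,
                   rmse_test = m$rf$rmse_test,
                   nodesize = m$rf$nodesize,
                   top10 = utils::head(m$rf$importance$name, 10)))
  })
  jsonlite::write_json(models, file.path(out_dir, "evi_models.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(result$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Human-readable pipeline summary
#'
#' Renders the stage products of a [run_pipeline()] result as aligned
#' text tables: phenology metric means with site differences and
#' p-values, per-event climate-driver models, interannual trends, and
#' the MLR-vs-random-forest comparison. Every number shown is taken
#' from the stored stage products.
#'
#' @param result A `pheno_pipeline` object.
#' @return `result`, invisibly; the report is printed.
#' @export
pheno_report <- function(result) {
  stopifnot(inherits(result, "pheno_pipeline"))
  fmt <- function(x, d = 2) ifelse(is.na(x), "-",
                                   formatC(x, digits = d,
                                           format = "f"))
  cat("== Phenology pipeline report ==\n")
  cat("sites:", paste(result$config$sites, collapse = ", "),
      "| config", result$manifest$config_hash, "\n\n")
  if (!is.null(result$comparison)) {
    cat("-- Site comparison (paired by year) --\n")
    cmp <- result$comparison
    print(data.frame(metric = cmp$metric,
                     mean_a = fmt(cmp$mean_a), sd_a = fmt(cmp$sd_a),
                     mean_b = fmt(cmp$mean_b), sd_b = fmt(cmp$sd_b),
                     diff = fmt(cmp$difference),
                     p = format.pval(cmp$p_value, digits = 3)),
          row.names = FALSE)
    cat("\n")
  }
  cat("-- Climate drivers of phenological events --\n")
  if (is.null(result$drivers) || nrow(result$drivers) == 0L) {
    cat("none selected\n")
  } else {
    d <- result$drivers
    d$selected[d$selected == ""] <- "none selected"
    print(data.frame(site = d$site, metric = d$metric,
                     predictors = d$selected,
                     R2 = fmt(d$r_squared),
                     p = format.pval(d$p_value, digits = 3)),
          row.names = FALSE)
  }
  cat("\n-- Interannual trends --\n")
  tr <- result$trends
  print(data.frame(site = tr$site, metric = tr$series,
                   slope_per_year = fmt(tr$slope),
                   p = format.pval(tr$p, digits = 3)),
        row.names = FALSE)
  cat("\n-- Monthly-EVI models (MLR vs random forest) --\n")
  for (nm in names(result$evi_models)) {
    m <- result$evi_models[[nm]]
    cat(sprintf(
      "%s: MLR [%s] R^2=%.3f RMSE=%.4f | RF R^2(test)=%.3f RMSE=%.4f | overlap %d/%d\n",
      nm, paste(m$mlr$selected, collapse = "+"), m$mlr$r_squared,
      m$mlr$rmse, m$rf$r2_test, m$rf$rmse_test,
      m$comparison$overlap, length(m$mlr$selected)))
  }
  invisible(result)
}

#' @export
print.pheno_pipeline <- function(x, ...) {
  cat("<pheno_pipeline>", length(x$config$sites), "site(s),",
      nrow(x$metrics), "site-years;",
      "stages:", paste(x$manifest$stages, collapse = " -> "), "\n")
  invisible(x)
}
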