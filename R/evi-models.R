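# Shared assembly: monthly EVI joined with its lagged climate windows.
evi_model_frame <- function(evi_monthly, climate_monthly,
                            windows = enumerate_windows()) {
  evi_monthly <- tibble::as_tibble(evi_monthly)
  stopifnot(all(c("year", "month", "evi") %in% names(evi_monthly)))
  if ("site" %in% names(evi_monthly) &&
      dplyr::n_distinct(evi_monthly$site) > 1L) {
    stop("one site at a time; split the monthly EVI table first",
         call. = FALSE)
  }
  anchors <- evi_monthly[c("year", "month", "evi")]
  out <- window_predictors(climate_monthly, anchors, windows)
  out[stats::complete.cases(out), , drop = FALSE]
}

#' Best-pair linear model of monthly EVI on climate windows
#'
#' Screens the climate-window predictors by single correlations with
#' monthly EVI, then picks the subset of at most `n_predictors`
#' (default: the best pair) of the top-`k` candidates with the highest
#' adjusted R^2. Ties prefer the smaller model.
#'
#' @param evi_monthly Monthly EVI table from [monthly_mean_evi()]
#'   (one site).
#' @param climate_monthly Monthly climate table from
#'   [aggregate_monthly()].
#' @param windows Window table from [enumerate_windows()].
#' @param k Screened candidates kept for the subset search.
#' @param n_predictors Largest subset size examined.
#' @return An object of class `evi_mlr` with the selected windows,
#'   coefficients, R^2 (squared correlation of fitted vs observed),
#'   RMSE, model p-value and per-month predictions.
#' @export
mlr_evi_model <- function(evi_monthly, climate_monthly,
                          windows = enumerate_windows(), k = 10,
                          n_predictors = 2) {
  data <- evi_model_frame(evi_monthly, climate_monthly, windows)
  screened <- pearson_screen(data, "evi",
                             intersect(windows$name, names(data)))
  top <- screen_top(screened, k)
  best <- NULL
  best_adj <- -Inf
  for (size in seq_len(min(n_predictors, length(top)))) {
    for (combo in utils::combn(top, size, simplify = FALSE)) {
      f <- stats::reformulate(combo, response = "evi")
      adj <- summary(stats::lm(f, data = data))$adj.r.squared
      if (adj > best_adj + 1e-9) {
        best <- combo
        best_adj <- adj
      }
    }
  }
  fit <- stats::lm(stats::reformulate(best, response = "evi"),
                   data = data)
  sm <- summary(fit)
  pred <- stats::fitted(fit)
  structure(
    list(selected = best, coefficients = stats::coef(fit),
         r_squared = unname(stats::cor(pred, data$evi)^2),
         adj_r_squared = sm$adj.r.squared,
         rmse = sqrt(mean((pred - data$evi)^2)),
         p_value = unname(stats::pf(sm$fstatistic[1L], sm$fstatistic[2L],
                                    sm$fstatistic[3L],
                                    lower.tail = FALSE)),
         predictions = tibble::tibble(year = data$year,
                                      month = data$month,
                                      observed = data$evi,
                                      predicted = unname(pred)),
         screened = screened, n = nrow(data), model = fit),
    class = "evi_mlr"
  )
}

#' @export
print.evi_mlr <- function(x, ...) {
  cat("Monthly-EVI linear model:", paste(x$selected, collapse = " + "),
      "\n")
  cat(sprintf("  R^2 = %.3f, RMSE = %.4f, n = %d months\n",
              x$r_squared, x$rmse, x$n))
  invisible(x)
}

#' @export
tidy.evi_mlr <- function(x, ...) tidy.stepwise_fit(x, ...)

#' @export
glance.evi_mlr <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared,
                 adj_r_squared = x$adj_r_squared, rmse = x$rmse,
                 p_value = x$p_value, n = x$n)
}

#' Random-forest model of monthly EVI on all climate windows
#'
#' Fits a random forest of monthly EVI on the full climate-window
#' predictor matrix. Months are split at random into training (64%),
#' validation (16%, used to pick the minimum node size over a small
#' grid) and test (20%, the remainder after floor-rounding the first
#' two) sets; the final forest is refit on training plus validation
#' months and assessed on the held-out test months. With fewer than 50
#' months the split is refused and out-of-bag evaluation is used
#' instead.
#'
#' @inheritParams mlr_evi_model
#' @param seed Integer seed controlling the split and the forest.
#' @param ntree Trees per forest.
#' @param nodesize_grid Candidate minimum node sizes tuned on the
#'   validation set.
#' @param mode `"split"` (default) or `"oob"` to force all-data
#'   fitting with out-of-bag evaluation (the overall-comparison mode).
#' @return An object of class `evi_rf` with test R^2 (squared
#'   correlation of predicted vs observed), test RMSE, ranked
#'   permutation importances and the forest.
#' @export
rf_evi_model <- function(evi_monthly, climate_monthly,
                         seed, windows = enumerate_windows(),
                         ntree = 500, nodesize_grid = c(1, 3, 5),
                         mode = c("split", "oob")) {
  mode <- match.arg(mode)
  data <- evi_model_frame(evi_monthly, climate_monthly, windows)
  preds <- intersect(windows$name, names(data))
  x <- as.matrix(data[preds])
  y <- data$evi
  n <- nrow(data)
  set.seed(as.integer(seed))
  if (n < 50L && mode == "split") {
    message("rf_evi_model: only ", n,
            " months; falling back to out-of-bag evaluation")
    mode <- "oob"
  }
  if (mode == "oob") {
    fit <- randomForest::randomForest(x, y, ntree = ntree,
                                      importance = TRUE)
    pred <- stats::predict(fit)  # OOB predictions
    split <- list(train = n, validation = 0L, test = 0L)
    nodesize <- 5
    pred_tbl <- tibble::tibble(year = data$year, month = data$month,
                               observed = y, predicted = unname(pred))
  } else {
    perm <- sample.int(n)
    n_tr <- floor(0.64 * n)
    n_val <- floor(0.16 * n)
    i_tr <- perm[seq_len(n_tr)]
    i_val <- perm[n_tr + seq_len(n_val)]
    i_te <- perm[(n_tr + n_val + 1L):n]
    val_rmse <- vapply(nodesize_grid, function(ns) {
      f <- randomForest::randomForest(x[i_tr, , drop = FALSE], y[i_tr],
                                      ntree = ntree, nodesize = ns)
      p <- stats::predict(f, x[i_val, , drop = FALSE])
      sqrt(mean((p - y[i_val])^2))
    }, 0)
    nodesize <- nodesize_grid[which.min(val_rmse)]
    i_fit <- c(i_tr, i_val)
    fit <- randomForest::randomForest(x[i_fit, , drop = FALSE],
                                      y[i_fit], ntree = ntree,
                                      nodesize = nodesize,
                                      importance = TRUE)
    pred <- stats::predict(fit, x[i_te, , drop = FALSE])
    split <- list(train = n_tr, validation = n_val,
                  test = length(i_te))
    pred_tbl <- tibble::tibble(year = data$year[i_te],
                               month = data$month[i_te],
                               observed = y[i_te],
                               predicted = unname(pred))
  }
  imp <- randomForest::importance(fit, type = 1, scale = TRUE)
  imp_tbl <- tibble::tibble(name = rownames(imp),
                            importance = imp[, 1L])
  imp_tbl <- imp_tbl[order(-imp_tbl$importance), , drop = FALSE]
  obs <- pred_tbl$observed
  structure(
    list(seed = as.integer(seed), mode = mode, split = split,
         fractions = c(train = 0.64, validation = 0.16, test = 0.20),
         ntree = ntree, nodesize = nodesize,
         r2_test = unname(stats::cor(pred_tbl$predicted, obs)^2),
         rmse_test = sqrt(mean((pred_tbl$predicted - obs)^2)),
         importance = imp_tbl, predictions = pred_tbl, n = n,
         model = fit),
    class = "evi_rf"
  )
}

#' @export
print.evi_rf <- function(x, ...) {
  cat("Monthly-EVI random forest (", x$ntree, " trees, nodesize ",
      x$nodesize, ", ", x$mode, " evaluation)\n", sep = "")
  cat(sprintf("  test R^2 = %.3f, test RMSE = %.4f (n = %d months)\n",
              x$r2_test, x$rmse_test, x$n))
  cat("  top importances:",
      paste(utils::head(x$importance$name, 5), collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.evi_rf <- function(x, ...) x$importance

#' @export
glance.evi_rf <- function(x, ...) {
  tibble::tibble(r2_test = x$r2_test, rmse_test = x$rmse_test,
                 nodesize = x$nodesize, ntree = x$ntree,
                 n = x$n, seed = x$seed)
}

#' Compare the linear and random-forest monthly-EVI models
#'
#' Puts the two models side by side: R^2 and RMSE of each, both
#' additionally evaluated on the forest's held-out test months, and
#' the overlap between the linear model's selected windows and the
#' forest's ten most important ones.
#'
#' @param mlr An [mlr_evi_model()] fit.
#' @param rf An [rf_evi_model()] fit on the same site's data.
#' @return An object of class `model_comparison`: a `summary` tibble
#'   (`model`, `r2`, `rmse`, `r2_test`, `rmse_test`), the overlap
#'   count and the window sets.
#' @export
compare_models <- function(mlr, rf) {
  stopifnot(inherits(mlr, "evi_mlr"), inherits(rf, "evi_rf"))
  shared <- dplyr::inner_join(
    mlr$predictions, rf$predictions,
    by = c("year", "month"), suffix = c("_mlr", "_rf")
  )
  mlr_test_r2 <- NA_real_
  mlr_test_rmse <- NA_real_
  if (nrow(shared) >= 3L) {
    mlr_test_r2 <- unname(
      stats::cor(shared$predicted_mlr, shared$observed_mlr)^2)
    mlr_test_rmse <- sqrt(
      mean((shared$predicted_mlr - shared$observed_mlr)^2))
  }
  rf_top10 <- utils::head(rf$importance$name, 10)
  overlap <- intersect(mlr$selected, rf_top10)
  summary <- tibble::tibble(
    model = c("MLR", "RF"),
    r2 = c(mlr$r_squared, rf$r2_test),
    rmse = c(mlr$rmse, rf$rmse_test),
    r2_test = c(mlr_test_r2, rf$r2_test),
    rmse_test = c(mlr_test_rmse, rf$rmse_test)
  )
  structure(
    list(summary = summary, overlap = length(overlap),
         shared_windows = overlap, mlr_selected = mlr$selected,
         rf_top10 = rf_top10),
    class = "model_comparison"
  )
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Monthly-EVI model comparison\n")
  print(as.data.frame(x$summary), row.names = FALSE)
  cat("MLR windows in RF top-10:", x$overlap, "of",
      length(x$mlr_selected),
      if (x$overlap) paste0("(", paste(x$shared_windows,
                                       collapse = ", "), ")") else "",
      "\n")
  invisible(x)
}
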