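screen_frame <- function(n = 21, seed = 4) {
  set.seed(seed)
  tibble::tibble(
    x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n), x4 = rnorm(n)
  )
}

test_that("pearson_screen ranks exact (anti)correlations first", {
  d <- screen_frame()
  d$y <- d$x2
  out <- pearson_screen(d, "y")
  expect_equal(out$name[1], "x2")
  expect_equal(out$r[1], 1, tolerance = 1e-12)
  d$y <- -d$x3
  out2 <- pearson_screen(d, "y")
  expect_equal(out2$name[1], "x3")
  expect_equal(out2$r[1], -1, tolerance = 1e-12)
})

test_that("pearson_screen skips degenerate predictors with a message", {
  d <- screen_frame()
  d$flatline <- 1
  d$y <- d$x1
  expect_message(out <- pearson_screen(d, "y"), "zero-variance")
  expect_false("flatline" %in% out$name)
})

test_that("stepwise_mlr solves an exact linear relation", {
  d <- screen_frame()
  d$y <- 2 * d$x1 + 1
  fit <- stepwise_mlr(d, "y")
  expect_equal(fit$selected, "x1")
  expect_equal(unname(fit$coefficients["x1"]), 2, tolerance = 1e-9)
  expect_equal(unname(fit$coefficients["(Intercept)"]), 1,
               tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})

test_that("stepwise_mlr drops perfectly collinear duplicates", {
  d <- screen_frame()
  d$dup <- d$x1
  d$y <- 3 * d$x1 + rnorm(nrow(d), 0, 0.1)
  fit <- stepwise_mlr(d, "y")
  expect_length(intersect(c("x1", "dup"), fit$selected), 1L)
  expect_true(length(fit$dropped_collinear) >= 1L)
})

test_that("stepwise_mlr returns an empty model when nothing correlates", {
  set.seed(10)
  d <- screen_frame(seed = 10)
  d$y <- rnorm(nrow(d)) * 1e3  # independent of all candidates
  fit <- stepwise_mlr(d, "y", p_enter = 1e-6)
  expect_length(fit$selected, 0L)
  expect_equal(fit$r_squared, 0)
})

test_that("model R^2 never falls as informative terms accumulate", {
  set.seed(11)
  d <- screen_frame(seed = 11)
  d$y <- 1.5 * d$x1 - 2 * d$x2 + rnorm(nrow(d), 0, 0.3)
  fit <- stepwise_mlr(d, "y")
  expect_setequal(fit$selected, c("x1", "x2"))
  r2_first <- summary(stats::lm(
    stats::reformulate(fit$selected[1], "y"), data = d))$r.squared
  expect_gte(fit$r_squared, r2_first)
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "p_value") %in% names(td)))
  expect_equal(glance(fit)$n_selected, 2L)
})

test_that("trend_fit recovers exact lines and degenerate constants", {
  d <- tibble::tibble(year = 2000:2014)
  d$v <- 3 * (d$year - 2000)
  tr <- trend_fit(d, "v")
  expect_equal(tr$slope, 3, tolerance = 1e-9)
  expect_lt(tr$p, 1e-12)
  d$c <- 5
  trc <- trend_fit(d, "c")
  expect_equal(trc$slope, 0)
  expect_equal(trc$p, 1)
  expect_error(trend_fit(d[1:2, ], "v"), "at least 3")
})

# small but realistic monthly frame for the EVI models
evi_model_fixture <- function(seed = 12, n_years = 8) {
  cl <- climate_config(seed = seed)
  daily <- gen_climate(cl, 1999:(1999 + n_years))
  monthly <- aggregate_monthly(daily)
  anchors <- tidyr::expand_grid(year = 2000:(1999 + n_years),
                                month = 1:12)
  x <- window_predictors(monthly, anchors)
  list(monthly = monthly, x = x)
}

test_that("mlr_evi_model recovers an EVI equal to a single window", {
  fix <- evi_model_fixture()
  evi_m <- fix$x[c("year", "month")]
  evi_m$evi <- fix$x$T_2_1 / 100  # EVI proportional to one window
  evi_m$site <- "a"
  fit <- suppressWarnings(mlr_evi_model(evi_m, fix$monthly))
  expect_true("T_2_1" %in% fit$selected)
  expect_lt(fit$rmse, 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})

test_that("rf split sizes follow floor rounding with remainder to test", {
  fix <- evi_model_fixture(seed = 13, n_years = 21)
  evi_m <- fix$x[c("year", "month")]
  set.seed(1)
  evi_m$evi <- 0.3 + fix$x$RD_3_0 / 200 + rnorm(nrow(evi_m), 0, 0.01)
  evi_m <- evi_m[seq_len(252), ]
  fit <- rf_evi_model(evi_m, fix$monthly, seed = 99, ntree = 100)
  expect_equal(fit$split$train, 161L)
  expect_equal(fit$split$validation, 40L)
  expect_equal(fit$split$test, 51L)
  expect_equal(sum(unlist(fit$split)), 252L)
})

test_that("rf_evi_model is reproducible under a fixed seed and ranks a
           deterministic driver first", {
  fix <- evi_model_fixture(seed = 14, n_years = 6)
  evi_m <- fix$x[c("year", "month")]
  evi_m$evi <- 0.25 + fix$x$T_3_0 / 120
  f1 <- rf_evi_model(evi_m, fix$monthly, seed = 7, ntree = 150)
  f2 <- rf_evi_model(evi_m, fix$monthly, seed = 7, ntree = 150)
  expect_identical(f1$r2_test, f2$r2_test)
  expect_identical(f1$importance, f2$importance)
  # the generating window (or an overlapping neighbour) dominates
  top3 <- phenoevi:::parse_window_name(utils::head(f1$importance$name, 3))
  expect_true(any(top3$variable == "T" &
                    abs(top3$n_months - 3) + abs(top3$lag_months) <= 2))
})

test_that("rf_evi_model falls back to out-of-bag mode when months are few", {
  fix <- evi_model_fixture(seed = 15, n_years = 4)
  evi_m <- fix$x[c("year", "month")]
  evi_m$evi <- 0.3 + fix$x$Pr_1_0 / 500
  evi_m <- evi_m[seq_len(40), ]
  expect_message(fit <- rf_evi_model(evi_m, fix$monthly, seed = 3,
                                     ntree = 100), "out-of-bag")
  expect_equal(fit$mode, "oob")
  expect_equal(fit$split$train, 40L)
})

test_that("compare_models reports matched metrics and window overlap", {
  fix <- evi_model_fixture(seed = 16, n_years = 8)
  evi_m <- fix$x[c("year", "month")]
  set.seed(2)
  evi_m$evi <- 0.3 + fix$x$T_2_1 / 150 + fix$x$RD_3_0 / 300 +
    rnorm(nrow(evi_m), 0, 0.005)
  mlr <- mlr_evi_model(evi_m, fix$monthly)
  rf <- rf_evi_model(evi_m, fix$monthly, seed = 5, ntree = 200)
  cmp <- compare_models(mlr, rf)
  expect_equal(cmp$summary$model, c("MLR", "RF"))
  expect_equal(cmp$summary$r2[2], rf$r2_test)
  expect_true(cmp$overlap <= length(mlr$selected))
  expect_true(all(cmp$shared_windows %in% rf$rf_top10 |
                    cmp$shared_windows %in% utils::head(
                      rf$importance$name, 10)))
})
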