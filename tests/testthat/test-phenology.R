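test_that("first_derivative is exact on constant and linear series", {
  flat <- make_series(rep(0.3, 46))
  expect_true(all(first_derivative(flat)$devi == 0))
  lin <- make_series(0.2 + 0.005 * (0:45))
  d <- first_derivative(lin)$devi
  expect_equal(d[2:45], rep(0.005, 44), tolerance = 1e-12)
  expect_error(first_derivative(make_series(c(0.1, 0.2))), "at least 3")
})

test_that("first_derivative of a sinusoid tracks the analytic cosine", {
  s <- sine_series(n_years = 2, mean = 0.3, amp = 0.1)
  d <- first_derivative(s)$devi
  t <- (seq_len(92) - 1) / 46
  analytic <- 0.1 * (2 * pi / 46) * cos(2 * pi * t)
  # second-order accuracy: error bounded by the step^2 term
  bound <- 0.1 * (2 * pi / 46)^3 / 6 * 1.01
  expect_lt(max(abs(d[2:91] - analytic[2:91])), bound)
})

test_that("detect_transition reports a flat series as missing", {
  flat <- make_series(rep(0.3, 46))
  out <- detect_transition(flat, "falling", 2000, c(1, 240))
  expect_true(all(is.na(out)))
})

test_that("detect_transition brackets a clean falling sigmoid", {
  d <- composite_doys()
  v <- 0.2 + 0.25 * stats::plogis(-0.08 * (d - 150))
  out <- detect_transition(make_series(v), "falling", 2000, c(1, 300))
  expect_lt(out[["onset"]], out[["end"]])
  expect_gt(out[["onset"]], 60)
  expect_lt(out[["end"]], 250)
})

test_that("dry-period crossings are interpolated between composites", {
  # decline passing exactly midway between threshold brackets:
  # EVI 0.32 at DOY 129 and 0.28 at DOY 137 -> crossing at DOY 133
  d <- composite_doys()
  v <- 0.32 - 0.04 * (d - 129) / 8
  v[d < 129] <- seq(0.45, 0.33, length.out = sum(d < 129))
  s <- make_series(pmax(v, 0.1))
  out <- detect_dry_period(s, 2000,
                           extrema = c(max_evi = 0.45, max_date = 1,
                                       min_evi = 0.1, min_date = 361))
  expect_equal(out[["dpo"]], 133)
})

test_that("a series that never crosses the threshold yields missing values", {
  s <- make_series(seq(0.45, 0.36, length.out = 46))
  expect_message(out <- detect_dry_period(s, 2000), "never falls")
  expect_true(all(is.na(out)))
})

test_that("compute_threshold is the midpoint of the series extremes", {
  s <- make_series(seq(0.179, 0.439, length.out = 46))
  expect_equal(compute_threshold(s), 0.309, tolerance = 1e-12)
  expect_equal(compute_threshold(make_series(rep(0.27, 46))), 0.27)
  s2 <- make_series(seq(0.1, 0.5, length.out = 46))
  expect_equal(compute_threshold(s2), 0.3, tolerance = 1e-12)
})

test_that("extrema use the earliest date on ties and handle monotone years", {
  v <- rep(0.3, 46)
  v[c(5, 10)] <- 0.45
  ex <- extrema_metrics(make_series(v), 2000)
  expect_equal(ex[["max_date"]], composite_doys()[5])
  dec <- make_series(seq(0.5, 0.2, length.out = 46))
  expect_equal(extrema_metrics(dec, 2000)[["max_date"]], 1)
})

test_that("smoothed synthetic plateau maximum is recovered closely", {
  fix <- smoothed_synthetic(n_years = 6, seed = 21,
                            curve = curve_config(noise_sd = 0,
                                                 dropout_prob = 0,
                                                 seed = 21))
  ex <- extrema_metrics(fix$smoothed, 2003)
  expect_equal(ex[["max_evi"]], 0.45, tolerance = 0.005 / 0.45)
})

test_that("extract_all_metrics returns one row per year with exact identities", {
  fix <- smoothed_synthetic(n_years = 6, seed = 31)
  m <- suppressMessages(extract_all_metrics(fix$smoothed))
  expect_equal(nrow(m), 6L)
  ok <- !is.na(m$sdd)
  expect_equal(m$sdd[ok], (m$sde - m$sdo)[ok])
  ok <- !is.na(m$ard)
  expect_equal(m$ard[ok], (m$are - m$aro)[ok])
  ok <- !is.na(m$dpd)
  expect_equal(m$dpd[ok], (m$dpe - m$dpo)[ok])
  expect_true(all(m$sdo < m$sde, na.rm = TRUE))
  expect_true(all(m$aro < m$are, na.rm = TRUE))
  expect_true(all(m$min_evi <= m$max_evi, na.rm = TRUE))
})

test_that("events are ordered max -> dry onset -> minimum -> dry end", {
  fix <- smoothed_synthetic(n_years = 6, seed = 41)
  m <- suppressMessages(extract_all_metrics(fix$smoothed))
  ok <- stats::complete.cases(m[c("max_date", "dpo", "min_date", "dpe")])
  expect_true(any(ok))
  expect_true(all(m$max_date[ok] < m$dpo[ok]))
  expect_true(all(m$dpo[ok] < m$min_date[ok]))
  expect_true(all(m$min_date[ok] < m$dpe[ok]))
})

test_that("noiseless round trip recovers every event within one composite", {
  cc <- curve_config(noise_sd = 0, dropout_prob = 0)
  ds <- gen_coupled_dataset(cc, climate_config(), coupling_config(),
                            n_years = 6)
  m <- suppressMessages(extract_all_metrics(fft_smooth(ds$evi_clean)))
  inner <- m[2:5, ]  # interior years, free of series-edge effects
  expect_true(all(abs(inner$sdo - cc$sdo) <= 8))
  expect_true(all(abs(inner$sde - cc$sde) <= 8))
  expect_true(all(abs(inner$aro - cc$aro) <= 8))
  expect_true(all(abs(inner$are - cc$are) <= 8))
})

test_that("raising the dry threshold never shortens the dry period", {
  fix <- smoothed_synthetic(n_years = 4, seed = 51,
                            curve = curve_config(noise_sd = 0.005,
                                                 dropout_prob = 0.05,
                                                 seed = 51))
  prev <- rep(-Inf, 2)
  for (thr in seq(0.22, 0.38, by = 0.04)) {
    m <- suppressMessages(
      extract_all_metrics(fix$smoothed,
                          detection_params(dry_threshold = thr)))
    dpd <- m$dpd[2:3]
    expect_true(all(dpd >= prev, na.rm = TRUE))
    prev <- ifelse(is.na(dpd), prev, dpd)
  }
})

test_that("compare_sites of a table with itself is all-zero with p = 1", {
  fix <- smoothed_synthetic(n_years = 5, seed = 61)
  m <- suppressMessages(extract_all_metrics(fix$smoothed))
  cmp <- compare_sites(m, m)
  expect_true(all(cmp$difference == 0, na.rm = TRUE))
  expect_true(all(cmp$p_value[!is.na(cmp$p_value)] == 1))
})

test_that("compare_sites matches the hand-computed paired t-test", {
  a <- tibble::tibble(year = 1:3, sdo = c(101, 103, 105))
  b <- tibble::tibble(year = 1:3, sdo = c(100, 101, 102))
  cmp <- compare_sites(a, b)
  expect_equal(cmp$difference, 2)
  # differences (1, 2, 3): t = mean/sd * sqrt(3) = 2 sqrt(3)
  p_hand <- 2 * stats::pt(2 * sqrt(3), df = 2, lower.tail = FALSE)
  expect_equal(cmp$p_value, p_hand, tolerance = 1e-12)
  # constant nonzero difference: degenerate, flagged
  b2 <- tibble::tibble(year = 1:4, sdo = c(99, 101, 103, 105))
  a2 <- tibble::tibble(year = 1:4, sdo = b2$sdo + 5)
  expect_warning(cmp2 <- compare_sites(a2, b2), "degenerate")
  expect_equal(cmp2$p_value, 0)
})

test_that("years missing in either site are dropped pairwise", {
  a <- tibble::tibble(year = 1:6, sdo = c(NA, 100, 102, 104, 106, 108))
  b <- tibble::tibble(year = 1:6, sdo = c(95, 96, NA, 98, 100, 101))
  cmp <- compare_sites(a, b)
  expect_equal(cmp$n_pairs, 4L)
})
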