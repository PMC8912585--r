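test_that("compute_evi reproduces hand-evaluated index values", {
  out <- compute_evi(tibble::tibble(
    r_blue = c(0.02, 0.05, 0.04),
    r_red = c(0.05, 0.20, 0.10),
    r_nir = c(0.30, 0.20, 0.40)
  ))
  expect_equal(out$evi[1], 2.5 * 0.25 / 1.45, tolerance = 1e-12)
  expect_equal(out$evi[1], 0.4310, tolerance = 1e-4)
  expect_equal(out$evi[2], 0)           # numerator zero when nir == red
  expect_equal(out$evi[3], 2.5 * 0.30 / 1.70, tolerance = 1e-12)
  expect_equal(out$evi[3], 0.4412, tolerance = 1e-4)
  expect_true(all(out$flag == "observed"))
})

test_that("compute_evi validates inputs and flags degenerate denominators", {
  expect_error(compute_evi(tibble::tibble(r_blue = 1.2, r_red = 0.1,
                                          r_nir = 0.3)),
               "\\[0, 1\\]")
  expect_error(compute_evi(tibble::tibble(r_blue = 0.1, r_red = 0.3)),
               "missing column")
  # r_nir + 6 r_red - 7.5 r_blue + 1 = 0 at blue = 2/15, red = nir = 0
  expect_error(
    compute_evi(tibble::tibble(date = as.Date("2005-03-06"),
                               r_blue = 2 / 15, r_red = 0, r_nir = 0)),
    "2005-03-06")
})

test_that("compute_evi is monotone in nir (up) and red (down)", {
  grid <- tidyr::expand_grid(r_nir = seq(0.2, 0.6, by = 0.1),
                             r_red = seq(0.02, 0.12, by = 0.02))
  grid$r_blue <- 0.03
  out <- compute_evi(grid)
  by_red <- split(out, out$r_red)
  for (g in by_red) {
    expect_true(all(diff(g$evi[order(g$r_nir)]) > 0))
  }
  by_nir <- split(out, out$r_nir)
  for (g in by_nir) {
    expect_true(all(diff(g$evi[order(g$r_red)]) < 0))
  }
})

test_that("bise_correct rejects a recovering drop and interpolates it", {
  s <- make_series(c(0.38, 0.39, 0.40, 0.18, 0.41, 0.42, 0.43))
  out <- bise_correct(s)
  expect_equal(out$evi[4], (0.40 + 0.41) / 2)  # 0.405
  expect_equal(out$flag[4], "bise-replaced")
  expect_equal(out$evi[-4], s$evi[-4])         # accepted points untouched
})

test_that("bise_correct leaves monotone and constant series unchanged", {
  up <- make_series(seq(0.2, 0.4, length.out = 10))
  expect_equal(bise_correct(up)$evi, up$evi)
  flat <- make_series(rep(0.3, 10))
  expect_equal(bise_correct(flat)$evi, flat$evi)
})

test_that("bise_correct is idempotent on noisy synthetic data", {
  ds <- gen_coupled_dataset(curve_config(seed = 5),
                            climate_config(seed = 5),
                            coupling_config(seed = 5), n_years = 4)
  once <- bise_correct(ds$evi)
  twice <- bise_correct(once)
  expect_equal(twice$evi, once$evi, tolerance = 1e-12)
  expect_equal(twice$flag, once$flag)
})

test_that("bise_correct refuses series shorter than its window", {
  expect_error(bise_correct(make_series(c(0.3, 0.31, 0.32))),
               "at least")
})

test_that("fft_smooth reproduces a retained harmonic exactly", {
  s <- sine_series(n_years = 3)
  out <- fft_smooth(s, smoothing_params(n_harmonics = 1,
                                        envelope_iterations = 0))
  expect_lt(sqrt(mean((out$evi - s$evi)^2)), 1e-6)
  expect_true(all(out$flag == "smoothed"))
})

test_that("fft_smooth with zero harmonics returns the series mean", {
  set.seed(1)
  s <- make_series(runif(92, 0.1, 0.5))
  out <- fft_smooth(s, smoothing_params(n_harmonics = 0,
                                        envelope_iterations = 0))
  expect_equal(out$evi, rep(mean(s$evi), 92), tolerance = 1e-9)
})

test_that("fft_smooth at the Nyquist count is the identity and keeps the mean", {
  set.seed(2)
  s <- make_series(runif(92, 0.1, 0.5))
  full <- fft_smooth(s, smoothing_params(n_harmonics = 23,
                                         envelope_iterations = 0))
  expect_lt(sqrt(mean((full$evi - s$evi)^2)), 1e-9)
  part <- fft_smooth(s, smoothing_params(n_harmonics = 3,
                                         envelope_iterations = 0))
  expect_equal(mean(part$evi), mean(s$evi), tolerance = 1e-9)
})

test_that("fft_smooth pulls a negative spike toward the clean signal", {
  clean <- sine_series(n_years = 2, mean = 0.35, amp = 0.08)
  spiked <- clean
  spiked$evi[30] <- spiked$evi[30] - 0.15
  out <- fft_smooth(spiked, smoothing_params(n_harmonics = 4,
                                             envelope_iterations = 2))
  rms_out <- sqrt(mean((out$evi - clean$evi)^2))
  rms_in <- sqrt(mean((spiked$evi - clean$evi)^2))
  expect_lt(rms_out, rms_in)
})

test_that("fft_smooth demands a complete composite calendar", {
  s <- make_series(runif(50, 0.2, 0.4))  # 50 composites: partial year
  expect_error(fft_smooth(s), "gap-fill")
})

test_that("average_pixels averages per date and labels the site mean", {
  a <- make_series(rep(0.2, 46), pixel = "p1")
  b <- make_series(rep(0.4, 46), pixel = "p2")
  out <- average_pixels(dplyr::bind_rows(a, b))
  expect_equal(unique(out$pixel), "site-mean")
  expect_equal(out$evi, rep(0.3, 46))
  # mean of identical series is that series
  same <- average_pixels(dplyr::bind_rows(
    a, dplyr::mutate(a, pixel = "p2")))
  expect_equal(same$evi, a$evi)
})

test_that("average_pixels cancels symmetric deviations and commutes", {
  set.seed(3)
  v <- runif(46, 0.2, 0.5)
  d <- runif(46, 0, 0.05)
  trio <- dplyr::bind_rows(
    make_series(v, pixel = "p1"),
    make_series(v + d, pixel = "p2"),
    make_series(v - d, pixel = "p3")
  )
  expect_equal(average_pixels(trio)$evi, v, tolerance = 1e-12)
  shuffled <- trio[sample(nrow(trio)), ] |>
    dplyr::arrange(site, pixel, date)
  expect_equal(average_pixels(shuffled)$evi, average_pixels(trio)$evi)
})

test_that("average_pixels rejects mismatched date grids", {
  a <- make_series(rep(0.2, 46), pixel = "p1")
  b <- make_series(rep(0.4, 45), pixel = "p2")
  expect_error(average_pixels(dplyr::bind_rows(a, b)), "grids differ")
})

test_that("monthly_mean_evi assigns composites to calendar months", {
  s <- make_series(rep(0.3, 46))
  out <- monthly_mean_evi(s)
  expect_equal(nrow(out), 12L)
  expect_true(all(out$evi == 0.3))
  # January holds composites starting DOY 1, 9, 17, 25
  s2 <- make_series(c(0.1, 0.2, 0.3, 0.4, rep(0.5, 42)))
  jan <- monthly_mean_evi(s2)
  expect_equal(jan$evi[jan$month == 1], 0.25)
})

test_that("annual_profile gives cross-year mean and SD per composite", {
  v <- runif(46, 0.2, 0.5)
  two <- make_series(c(v, v + 0.2))
  out <- annual_profile(two)
  expect_equal(nrow(out), 46L)
  expect_equal(out$mean_evi, v + 0.1, tolerance = 1e-12)
  expect_equal(out$sd_evi, rep(stats::sd(c(0, 0.2)), 46),
               tolerance = 1e-12)
  expect_equal(out$sd_evi[1], 0.1414, tolerance = 1e-3)
  same <- make_series(c(v, v))
  expect_true(all(annual_profile(same)$sd_evi == 0))
  expect_error(annual_profile(make_series(v)), "at least 2")
})

test_that("complete_composites interpolates missing composites", {
  s <- make_series(seq(0.2, 0.65, by = 0.01))  # full year
  gappy <- s[-c(10, 11), ]
  filled <- complete_composites(gappy)
  expect_equal(nrow(filled), 46L)
  expect_equal(filled$evi, s$evi, tolerance = 1e-12)
  expect_equal(filled$flag[10], "gap-filled")
})
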