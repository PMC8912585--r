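# Build an EVI series tibble on the composite calendar from raw values.
make_series <- function(values, start_year = 2000, site = "a",
                        pixel = "p1") {
  n_years <- ceiling(length(values) / 46L)
  dates <- composite_dates(start_year + seq_len(n_years) - 1L)
  tibble::tibble(site = site, pixel = pixel,
                 date = dates[seq_along(values)],
                 evi = values, flag = "observed")
}

# Pure sinusoid with an integer number of cycles per year.
sine_series <- function(n_years = 2, mean = 0.3, amp = 0.1,
                        cycles_per_year = 1, site = "a") {
  n <- 46L * n_years
  t <- (seq_len(n) - 1L) / 46
  make_series(mean + amp * sin(2 * pi * cycles_per_year * t),
              site = site)
}

# A ready-made smoothed synthetic site: default growth curve, noise
# and dropouts, cleaned and smoothed with package defaults.
smoothed_synthetic <- function(n_years = 6, seed = 11,
                               curve = curve_config(seed = seed)) {
  ds <- gen_coupled_dataset(curve, climate_config(seed = seed),
                            coupling_config(seed = seed),
                            n_years = n_years)
  list(smoothed = fft_smooth(bise_correct(ds$evi)), data = ds)
}

# True threshold-crossing days implied by the generator's logistic
# curve family (independent closed form, used as the oracle for
# dry-period detection).
true_dry_period <- function(cc, threshold = 0.3) {
  k1 <- 2 * log(19) / (cc$sde - cc$sdo)
  k2 <- 2 * log(19) / (cc$are - cc$aro)
  s <- 1 - (threshold - cc$min_evi) / (cc$max_evi - cc$min_evi)
  c(dpo = (cc$sdo + cc$sde) / 2 + stats::qlogis(s) / k1,
    dpe = (cc$aro + cc$are) / 2 + stats::qlogis(1 - s) / k2)
}
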