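test_that("fGn generator matches theoretical autocorrelation", {
  # H = 0.5 is white: lag-1 autocorrelation near 0
  r1 <- mean(sapply(1:10, function(s) {
    x <- generate_fgn(0.5, 8192, seed = s)
    cor(x[-1], x[-length(x)])
  }))
  expect_lt(abs(r1), 0.05)

  # H = 0.8: rho(1) = 2^(2H-1) - 1
  r8 <- mean(sapply(1:10, function(s) {
    x <- generate_fgn(0.8, 8192, seed = 100 + s)
    cor(x[-1], x[-length(x)])
  }))
  expect_lt(abs(r8 - (2^0.6 - 1)), 0.05)

  # unit variance, determinism
  expect_lt(abs(var(generate_fgn(0.7, 8192, seed = 1)) - 1), 0.15)
  expect_identical(generate_fgn(0.6, 1024, seed = 5),
                   generate_fgn(0.6, 1024, seed = 5))
  expect_error(generate_fgn(1.2, 100), class = "configuration_error")
})

test_that("generator_spec validates its feasibility constraints", {
  expect_error(generator_spec(100, 40, c(1, 0, 0), lf_freq = 1, hf_freq = 2),
               class = "configuration_error") # mean_nn <= 3 sdnn
  expect_error(generator_spec(100, 5, c(0.5, 0.5), lf_freq = 1, hf_freq = 2),
               class = "configuration_error") # not length 3
  expect_error(
    generator_spec(100, 5, c(0, 0, 1), lf_freq = 1, hf_freq = 9,
                   scheme = band_scheme("20C")),
    class = "configuration_error"
  ) # hf tone outside HF band
})

test_that("modulation hits its target SD and band shares", {
  sp <- preset_spec("old_basal_TN", duration = 1800)
  mod <- generate_modulation(sp, seed = 2)
  expect_lt(abs(sd(mod$nn_dev) - sp$sdnn_target) / sp$sdnn_target, 0.05)

  # single-component case: pure HF
  sp1 <- generator_spec(100, 5, c(0, 0, 1), lf_freq = 1, hf_freq = 2,
                        duration = 600)
  mod1 <- generate_modulation(sp1, seed = 3)
  expect_lt(abs(sd(mod1$nn_dev) - 5) / 5, 0.01)
  spec1 <- estimate_psd(mod1$nn_dev, rate = mod1$rate)
  pk <- spec1$frequencies[which.max(spec1$psd)]
  expect_lt(abs(pk - 2), 0.05)
})

test_that("IPFM emits beats at the commanded rate", {
  mod0 <- list(time = seq(0, by = 1 / 50, length.out = 3000),
               nn_dev = rep(0, 3000), rate = 50)
  rr <- ipfm_beats(mod0, mean_nn = 100)
  expect_true(abs(length(rr$intervals) + 1 - 600) <= 1)
  expect_true(all(abs(rr$intervals - 100) < 0.1))

  # 1-Hz modulation passes through to the analysed spectrum
  sp <- generator_spec(100, 5, c(0, 1, 0), lf_freq = 1, hf_freq = 2,
                       duration = 300)
  rr1 <- simulate_rr(sp, seed = 4)
  est <- estimate_psd(resample_evenly(rr1))
  f_peak <- est$frequencies[which.max(est$psd)]
  expect_lt(abs(f_peak - 1), 0.05)

  mod_bad <- list(time = mod0$time, nn_dev = rep(-200, 3000), rate = 50)
  expect_error(ipfm_beats(mod_bad, 100), class = "generation_error")
})

test_that("presets reproduce the published cell means through the pipeline", {
  rr <- simulate_rr("young_basal_LT", duration = 600, seed = 11)
  td <- summarize_time_domain(rr)
  expect_lt(abs(td$mean_hr - 598) / 598, 0.02)

  rr2 <- simulate_rr("old_basal_TN", duration = 600, seed = 12)
  td2 <- summarize_time_domain(rr2)
  expect_lt(abs(td2$mean_hr - 307) / 307, 0.02)
  expect_lt(abs(td2$sdnn - 11.85) / 11.85, 0.10)
})

test_that("old_basal_TN band shares are recovered by the analysis", {
  shares <- rowMeans(sapply(1:3, function(s) {
    rr <- simulate_rr("old_basal_TN", duration = 1800, seed = 200 + s)
    bp <- band_powers(estimate_psd(resample_evenly(rr)), band_scheme("30C"))
    c(bp$vlf, bp$lf, bp$hf) / bp$total
  }))
  target <- c(267.9, 123.98, 292) / (267.9 + 123.98 + 292)
  expect_true(all(abs(shares - target) / target < 0.10))
})

test_that("pure-VLF spec with beta 2 is recovered by the spectral fit", {
  sp <- generator_spec(100, 5, c(1, 0, 0), spectral_exponent = 2,
                       lf_freq = 1, hf_freq = 2, duration = 1800)
  bs <- mean(sapply(1:3, function(s) {
    rr <- simulate_rr(sp, seed = 500 + s)
    # fit over the broadband component's support [1/30, vlf_high]
    beta_slope(estimate_psd(resample_evenly(rr)), fit_low = 1 / 30,
               fit_high = 0.5)
  }))
  expect_lt(abs(bs - (-2)), 0.25)
})

test_that("generate_cohort is reproducible and carries its truth table", {
  co <- generate_cohort(2, seed = 9, duration = 120)
  expect_equal(length(co$records), 16) # 8 cells x 2
  expect_equal(nrow(co$truth), 16)
  expect_equal(length(unique(co$manifest$animal_id)), 4)
  expect_s3_class(co$manifest, "cohort_manifest")
  # every cell holds exactly n_per_cell records
  cellcount <- table(co$manifest$age_group, co$manifest$temperature,
                     co$manifest$state)
  expect_true(all(cellcount == 2))

  co2 <- generate_cohort(2, seed = 9, duration = 120)
  expect_identical(co$records[[1]]$intervals, co2$records[[1]]$intervals)
  expect_identical(co$truth, co2$truth)
  expect_error(generate_cohort(1), class = "configuration_error")

  # positivity of generated intervals
  expect_true(all(vapply(co$records, function(r) all(r$intervals > 0),
                         logical(1))))
})

test_that("synthesize_ecg places QRS bumps at beat times", {
  rr <- rr_series(intervals = rep(100, 10))
  ecg <- synthesize_ecg(rr, fs = 1000)
  expect_equal(ecg$sampling_rate, 1000)
  # local maxima at each beat time within one sample
  for (b in rr$beat_times[-1]) {
    i <- round(b * 1000)
    win <- ecg$samples[(i - 3):(i + 3)]
    expect_equal(which.max(win), 4)
  }
  expect_error(synthesize_ecg(rr, fs = 100), class = "validation_error")
})
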