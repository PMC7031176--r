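test_that("band schemes encode the temperature-adjusted cut-offs", {
  s20 <- band_scheme("20C")
  expect_equal(c(s20$vlf, s20$lf, s20$hf), c(0, 0.5, 0.5, 1.5, 1.5, 5.0))
  s30 <- band_scheme("30C")
  expect_equal(c(s30$vlf, s30$lf, s30$hf), c(0, 0.2, 0.2, 0.75, 0.75, 3.0))
  expect_error(band_scheme("custom", edges = c(0, 0.5, 0.4, 5)),
               class = "configuration_error")
  expect_error(scheme_for_temperature("25C"), class = "configuration_error")
})

test_that("resampling preserves level and modulation frequency", {
  rr <- rr_series(intervals = rep(100, 1200))
  sig <- resample_evenly(rr)
  expect_true(all(abs(sig$nn - 100) < 1e-6))

  rr1 <- sinusoid_rr(f_mod = 1, amp = 10, duration = 120)
  sig1 <- resample_evenly(rr1, rate = 20)
  # dominant DFT bin of the detrended signal at 1.0 Hz
  y <- sig1$nn - mean(sig1$nn)
  sp <- Mod(stats::fft(y))[2:(length(y) %/% 2)]
  fgrid <- (2:(length(y) %/% 2) - 1) * 20 / length(y)
  expect_lt(abs(fgrid[which.max(sp)] - 1.0), 20 / length(y) * 2)
  # mean preserved within 2%
  expect_lt(abs(mean(sig1$nn) - 100) / 100, 0.02)

  short <- rr_series(intervals = rep(100, 200)) # 20-s span
  expect_error(resample_evenly(short), class = "insufficient_data_error")
})

test_that("Welch PSD satisfies Parseval and sinusoid power recovery", {
  set.seed(31)
  x <- rnorm(20 * 600, sd = 3) # 600 s of white noise at 20 Hz
  sp <- estimate_psd(x, rate = 20)
  expect_true(all(sp$psd >= 0))
  expect_equal(sp$frequencies[1], 0)
  expect_lt(abs(trapz_full(sp$frequencies, sp$psd) - var(x)) / var(x), 0.1)

  t <- seq(0, 600, by = 1 / 20)
  A <- 2
  sine <- A * sin(2 * pi * 2 * t)
  sp2 <- estimate_psd(sine, rate = 20)
  tot <- trapz_full(sp2$frequencies, sp2$psd)
  expect_lt(abs(tot - A^2 / 2) / (A^2 / 2), 0.05)
  # concentrated within one resolution bin of 2 Hz
  df <- sp2$frequencies[2]
  near <- abs(sp2$frequencies - 2) <= 2 * df + 1e-9
  expect_gt(trapz_full(sp2$frequencies[near], sp2$psd[near]) / tot, 0.95)

  expect_equal(max(estimate_psd(rep(0, 20 * 600), rate = 20)$psd), 0)
  expect_error(estimate_psd(rnorm(100), rate = 20),
               class = "insufficient_data_error")
})

test_that("band powers integrate by scheme and conserve total exactly", {
  rr <- sinusoid_rr(f_mod = 2, amp = 8, duration = 300)
  sp <- estimate_psd(resample_evenly(rr))

  bp20 <- band_powers(sp, band_scheme("20C"))
  expect_equal(bp20$total, bp20$vlf + bp20$lf + bp20$hf, tolerance = 1e-12)
  expect_gt(bp20$hf / bp20$total, 0.9) # 2 Hz is HF at 20C
  bp30 <- band_powers(sp, band_scheme("30C"))
  expect_gt(bp30$hf / bp30$total, 0.9) # 2 Hz still HF at 30C

  # 1 Hz: LF at 20C but HF at 30C -- the rate-adjusted cut-off device
  rr1 <- sinusoid_rr(f_mod = 1, amp = 8, duration = 300)
  sp1 <- estimate_psd(resample_evenly(rr1))
  expect_gt(band_powers(sp1, band_scheme("20C"))$lf /
              band_powers(sp1, band_scheme("20C"))$total, 0.9)
  expect_gt(band_powers(sp1, band_scheme("30C"))$hf /
              band_powers(sp1, band_scheme("30C"))$total, 0.9)
})

test_that("white signal spreads power in proportion to band width", {
  set.seed(5)
  sp <- estimate_psd(rnorm(20 * 900), rate = 20)
  bp <- band_powers(sp, band_scheme("20C"))
  widths <- c(0.5, 1.0, 3.5) / 5.0
  shares <- c(bp$vlf, bp$lf, bp$hf) / bp$total
  expect_true(all(abs(shares - widths) / widths < 0.1))
})

test_that("HF top above Nyquist is a configuration error", {
  rr <- sinusoid_rr(f_mod = 1, amp = 5, duration = 300)
  sp <- estimate_psd(resample_evenly(rr, rate = 8)) # Nyquist 4 Hz < 5 Hz
  expect_error(band_powers(sp, band_scheme("20C")),
               class = "configuration_error")
})
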