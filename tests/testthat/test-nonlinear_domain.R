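test_that("sample_entropy equals the brute-force oracle", {
  # toy sequence checked pairwise by hand-enumerable oracle
  x <- c(1, 2, 3, 1, 2, 3, 1, 2, 3, 1)
  expect_identical(sample_entropy(x, m = 2, r = 0.5),
                   sampen_oracle(x, m = 2, r = 0.5))

  set.seed(71)
  for (i in 1:20) {
    n <- sample(100:400, 1)
    y <- rnorm(n)
    r <- 0.15 * sd(y)
    expect_equal(sample_entropy(y, m = 2, r = r),
                 sampen_oracle(y, m = 2, r = r), tolerance = 1e-12)
  }
  # larger series, default m/r path
  z <- runif(5000)
  expect_equal(sample_entropy(z), sampen_oracle(z, 2, 0.15 * sd(z)),
               tolerance = 1e-12)
})

test_that("sample_entropy limits and degenerate inputs", {
  set.seed(72)
  y <- rnorm(300)
  expect_equal(sample_entropy(y, m = 2, r = 1e9), 0) # r -> Inf: A = B
  expect_error(sample_entropy(rep(1, 200)), class = "degenerate_input_error")
  expect_error(sample_entropy(c(1, 2), m = 2),
               class = "insufficient_data_error")
})

test_that("multiscale entropy coarse-grains correctly", {
  set.seed(73)
  y <- rnorm(1200)
  out <- mse(y, scales = 1:5)
  expect_length(out$mse_profile, 5)
  expect_equal(out$mse, mean(out$mse_profile))
  # scale 1 is plain sample entropy with the same tolerance
  expect_equal(unname(out$mse_profile[1]),
               sample_entropy(y, r = 0.15 * sd(y)), tolerance = 1e-12)
  # too-short series truncates the scale axis with a warning
  expect_warning(short <- mse(rnorm(450), scales = 1:10),
                 class = "truncated_scales_warning")
  expect_lt(length(short$mse_profile), 10)
  expect_error(mse(rep(2, 500)), class = "degenerate_input_error")
})

test_that("white-noise MSE profile decreases beyond scale 1", {
  profs <- sapply(1:50, function(s) {
    set.seed(7000 + s)
    mse(rnorm(1000), scales = 1:5)$mse_profile
  })
  avg <- rowMeans(profs)
  expect_true(all(diff(avg) < 0))
})

test_that("beta_slope recovers exact and simulated spectral exponents", {
  f <- seq(0, 10, by = 1 / 60)
  spec <- structure(
    list(frequencies = f, psd = c(0, 2.5 * f[-1]^(-2)),
         resample_rate = 20, segment_length = 60, overlap = 0.5,
         window = "hann"),
    class = "spectral_estimate"
  )
  expect_equal(beta_slope(spec, fit_high = 1.5), -2, tolerance = 1e-9)

  # white spectrum -> beta 0 +/- 0.1
  set.seed(41)
  spw <- estimate_psd(rnorm(20 * 900), rate = 20)
  expect_lt(abs(beta_slope(spw, fit_high = 1.5)), 0.1)

  expect_error(beta_slope(spec, fit_low = 9.9, fit_high = 10),
               class = "insufficient_resolution_error")
})

test_that("DFA recovers known scaling exponents", {
  a_white <- mean(sapply(1:20, function(s) {
    set.seed(s)
    as.numeric(dfa(rnorm(8192)))
  }))
  expect_lt(abs(a_white - 0.5), 0.05)

  a_brown <- mean(sapply(1:20, function(s) {
    set.seed(s)
    as.numeric(dfa(cumsum(rnorm(8192))))
  }))
  expect_lt(abs(a_brown - 1.5), 0.1)

  a_fgn <- mean(sapply(1:20, function(s) {
    as.numeric(dfa(generate_fgn(0.9, 8192, seed = 600 + s)))
  }))
  expect_lt(abs(a_fgn - 0.9), 0.05)

  expect_error(dfa(rnorm(100), box_sizes = c(4, 8)),
               class = "insufficient_scales_error")
})

test_that("Hurst R/S estimator meets its bias bound on fGn", {
  for (H in c(0.5, 0.7, 0.8)) {
    est <- sapply(1:50, function(s) {
      as.numeric(hurst(generate_fgn(H, 4096, seed = 1000 + s)))
    })
    expect_lt(abs(mean(est) - H), 0.05)
  }
  # maximal-persistence limit: a pure ramp
  expect_gte(as.numeric(hurst(seq_len(4096) + 0)), 0.9)
  expect_error(hurst(rnorm(100)), class = "insufficient_data_error")
})

test_that("dfa and hurst are invariant to affine transforms", {
  x <- generate_fgn(0.7, 2048, seed = 99)
  expect_equal(as.numeric(dfa(x)), as.numeric(dfa(5 * x - 40)),
               tolerance = 1e-9)
  expect_equal(as.numeric(hurst(x)), as.numeric(hurst(-2 * x + 7)),
               tolerance = 1e-9)
})
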