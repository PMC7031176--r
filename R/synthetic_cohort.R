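#' Calibration table for the eight design-cell presets
#'
#' One row per cell of the 2x2x2 design (age x temperature x autonomic
#' state). `hr_bpm` and `hr_se` are the published group mean heart rate and
#' its standard error (with group size `n_animals`); `sdnn_ms` and `cv_pct`
#' the group mean SDNN and coefficient of variation;
#' `vlf/lf/hf_ms2` the group mean band powers from which the
#' generator's band fractions are taken; `beta_abs` the magnitude of the
#' log-log spectral slope; `hurst` the group Hurst exponent. LT = 20C
#' (standard laboratory temperature), TN = 30C (thermoneutrality).
#'
#' @return Data frame with one row per preset.
#' @export
hrv_presets <- function() {
  df <- data.frame(
    preset = c("young_basal_LT", "young_intrinsic_LT",
               "young_basal_TN", "young_intrinsic_TN",
               "old_basal_LT", "old_intrinsic_LT",
               "old_basal_TN", "old_intrinsic_TN"),
    age_group = rep(c("young", "old"), each = 4),
    temperature = rep(c("20C", "20C", "30C", "30C"), 2),
    state = rep(c("basal", "intrinsic"), 4),
    hr_bpm = c(598, 539, 371, 443, 622, 499, 307, 442),
    hr_se = c(19, 18, 12, 6, 13, 14, 9, 17),
    n_animals = c(7, 7, 13, 13, 17, 17, 13, 15),
    sdnn_ms = c(5.08, 1.72, 9.82, 3.23, 1.78, 0.97, 11.85, 2.67),
    cv_pct = c(4.92, 1.53, 5.98, 2.39, 1.8, 0.76, 6.06, 1.93),
    vlf_ms2 = c(33.44, 38.82, 152.76, 83.99, 29.21, 54.35, 267.9, 91.09),
    lf_ms2 = c(27.91, 21.19, 76.01, 16.43, 12.39, 23.82, 123.98, 17.26),
    hf_ms2 = c(41.69, 34.29, 185.95, 71.35, 23.43, 56.38, 292, 114.25),
    beta_abs = c(2.14, 3.26, 2.07, 3.05, 3.28, 3.58, 1.78, 3.47),
    hurst = c(0.75, 0.78, 0.74, 0.78, 0.79, 0.79, 0.73, 0.81),
    stringsAsFactors = FALSE
  )
  df
}

# modulation sinusoid placements inside the active scheme's bands; the HF
# tone sits in the lower part of the HF band (respiratory-like), keeping
# beat-sampling attenuation of the modulation small at murine rates
.mod_freqs <- list(
  "20C" = c(lf = 1.0, hf = 2.0),
  "30C" = c(lf = 0.45, hf = 1.0)
)

#' Generator specification for a synthetic RR series
#'
#' @param mean_nn Mean NN interval, ms.
#' @param sdnn_target Target SD of the NN modulation, ms. Must satisfy
#'   `mean_nn > 3 * sdnn_target` so instantaneous intervals stay positive.
#' @param band_fractions Length-3 numeric (vlf, lf, hf) fractions of
#'   modulation variance, summing to 1.
#' @param spectral_exponent Magnitude of the 1/f^beta exponent of the
#'   broadband (VLF) component.
#' @param lf_freq,hf_freq Sinusoid frequencies, Hz; must lie inside the LF
#'   and HF bands of `scheme`.
#' @param duration Record length, seconds.
#' @param animal_sd Between-animal SD of mean heart rate, bpm (used by
#'   [generate_cohort()]).
#' @param scheme A [band_scheme()] the band fractions refer to.
#' @param seed Optional integer seed.
#' @return A validated `generator_spec` list.
#' @export
generator_spec <- function(mean_nn, sdnn_target, band_fractions,
                           spectral_exponent = 2, lf_freq, hf_freq,
                           duration = 1800, animal_sd = 0,
                           scheme = band_scheme("20C"), seed = NULL) {
  band_fractions <- as.numeric(band_fractions)
  if (length(band_fractions) != 3 || any(band_fractions < 0) ||
      abs(sum(band_fractions) - 1) > 1e-9) {
    mhrv_error("configuration_error",
               "band_fractions must be 3 non-negative values summing to 1")
  }
  if (mean_nn <= 3 * sdnn_target) {
    mhrv_error("configuration_error",
               "mean_nn must exceed 3 * sdnn_target to keep intervals positive")
  }
  if (band_fractions[2] > 0 &&
      (lf_freq < scheme$lf[1] || lf_freq >= scheme$lf[2])) {
    mhrv_error("configuration_error",
               sprintf("lf_freq %.2f Hz outside the scheme's LF band", lf_freq))
  }
  if (band_fractions[3] > 0 &&
      (hf_freq < scheme$hf[1] || hf_freq >= scheme$hf[2])) {
    mhrv_error("configuration_error",
               sprintf("hf_freq %.2f Hz outside the scheme's HF band", hf_freq))
  }
  structure(
    list(
      mean_nn = mean_nn, sdnn_target = sdnn_target,
      band_fractions = setNames(band_fractions, c("vlf", "lf", "hf")),
      spectral_exponent = spectral_exponent,
      lf_freq = lf_freq, hf_freq = hf_freq,
      duration = duration, animal_sd = animal_sd,
      scheme = scheme, seed = seed
    ),
    class = "generator_spec"
  )
}

#' Generator specification for a named design-cell preset
#'
#' Builds a [generator_spec()] whose mean NN is 60000 / (cell mean HR),
#' SDNN target is the cell SDNN, band fractions are the cell's VLF/LF/HF
#' powers normalised to their sum, the spectral exponent is the cell's
#' |beta|, and the between-animal SD is SE * sqrt(N) of the cell heart
#' rate.
#'
#' @param preset One of the eight names in `hrv_presets()$preset`.
#' @param duration Record length in seconds, default 1800.
#' @param seed Optional integer seed.
#' @return A `generator_spec`.
#' @export
#' @examples
#' preset_spec("young_basal_LT")$mean_nn # 60000 / 598
preset_spec <- function(preset, duration = 1800, seed = NULL) {
  tab <- hrv_presets()
  row <- tab[tab$preset == preset, ]
  if (nrow(row) != 1) {
    mhrv_error(
      "configuration_error",
      sprintf("unknown preset %s; available: %s", sQuote(preset),
              paste(tab$preset, collapse = ", "))
    )
  }
  fr <- c(row$vlf_ms2, row$lf_ms2, row$hf_ms2)
  freqs <- .mod_freqs[[row$temperature]]
  generator_spec(
    mean_nn = 60000 / row$hr_bpm,
    sdnn_target = row$sdnn_ms,
    band_fractions = fr / sum(fr),
    spectral_exponent = row$beta_abs,
    lf_freq = freqs[["lf"]],
    hf_freq = freqs[["hf"]],
    duration = duration,
    animal_sd = row$hr_se * sqrt(row$n_animals),
    scheme = band_scheme(row$temperature),
    seed = seed
  )
}

#' Fractional Gaussian noise by circulant embedding
#'
#' Exact synthesis (Davies-Harte): the fGn autocovariance
#' `0.5 * (|k+1|^2H - 2|k|^2H + |k-1|^2H)` is embedded in a circulant
#' matrix whose eigenvalues are obtained by FFT; complex Gaussian
#' amplitudes with those variances transform back to a stationary Gaussian
#' sequence with exactly the fGn covariance (unit variance). If the
#' embedding has materially negative eigenvalues (extreme H with short n),
#' they are clipped with a warning (approximate spectral synthesis).
#'
#' @param H Hurst exponent in (0, 1).
#' @param n Length.
#' @param seed Optional integer seed; the output is a pure function of
#'   `(H, n, seed)`.
#' @return Numeric vector of length `n`, unit marginal variance.
#' @export
generate_fgn <- function(H, n, seed = NULL) {
  if (H <= 0 || H >= 1) {
    mhrv_error("configuration_error", "H must lie strictly in (0, 1)")
  }
  with_seed(seed, {
    k <- 0:n
    gk <- 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) +
                   abs(k - 1)^(2 * H))
    cr <- c(gk, rev(gk[2:n])) # circulant first row, length 2n
    lam <- Re(stats::fft(cr))
    if (min(lam) < -1e-8 * max(lam)) {
      mhrv_warn("embedding_warning",
                "circulant embedding not positive definite; clipping eigenvalues")
    }
    lam[lam < 0] <- 0
    m <- 2L * n
    z <- rnorm(m)
    w <- complex(length.out = m)
    w[1] <- sqrt(lam[1] / m) * z[1]
    w[n + 1] <- sqrt(lam[n + 1] / m) * z[2]
    j <- 2:n
    zr <- z[seq(3, by = 2, length.out = n - 1)]
    zi <- z[seq(4, by = 2, length.out = n - 1)]
    w[j] <- sqrt(lam[j] / (2 * m)) * complex(real = zr, imaginary = zi)
    w[m + 2 - j] <- Conj(w[j])
    Re(stats::fft(w))[seq_len(n)]
  })
}

# 1/f^beta Gaussian noise band-limited to [f_low, f_high], unit variance:
# white Gaussian noise filtered in the frequency domain by |f|^(-beta/2)
# (filtering a real signal keeps the spectrum Hermitian automatically)
.powerlaw_noise <- function(n, fs, beta, f_high, f_low = 0, seed = NULL) {
  with_seed(seed, {
    z <- stats::fft(rnorm(n))
    freqs <- (seq_len(n) - 1) * fs / n
    freqs <- ifelse(freqs > fs / 2, fs - freqs, freqs) # two-sided |f|
    amp <- numeric(n)
    sel <- freqs > 0 & freqs >= f_low & freqs <= f_high
    amp[sel] <- freqs[sel]^(-beta / 2)
    x <- Re(stats::fft(z * amp, inverse = TRUE)) / n
    s <- stats::sd(x)
    if (s == 0) return(x)
    (x - mean(x)) / s
  })
}

#' Generate the NN modulation signal for the IPFM simulator
#'
#' The modulation (ms deviations around the mean NN) is the sum of three
#' independent components: an HF sinusoid at `hf_freq`, an LF sinusoid at
#' `lf_freq` whose phase drifts slowly (a Wiener phase walk, which broadens
#' the LF peak as in real data), and broadband 1/f^beta Gaussian noise
#' band-limited to the VLF band. Component variances are scaled so the
#' total SD equals `sdnn_target` and the variance shares equal
#' `band_fractions`.
#'
#' @param spec A [generator_spec()].
#' @param fs_mod Sampling rate of the modulation signal, Hz (default 50).
#' @param seed Optional integer seed (falls back to `spec$seed`).
#' @return A `uniform_nn`-like list: `time` (s), `nn_dev` (ms deviations),
#'   `rate` (Hz).
#' @export
generate_modulation <- function(spec, fs_mod = 50, seed = NULL) {
  stopifnot(inherits(spec, "generator_spec"))
  if (is.null(seed)) seed <- spec$seed
  with_seed(seed, {
    n <- as.integer(round(spec$duration * fs_mod))
    t <- seq(0, by = 1 / fs_mod, length.out = n)
    v <- spec$sdnn_target^2 * spec$band_fractions
    x <- numeric(n)
    if (v[["hf"]] > 0) {
      a <- sqrt(2 * v[["hf"]])
      x <- x + a * sin(2 * pi * spec$hf_freq * t + runif(1, 0, 2 * pi))
    }
    if (v[["lf"]] > 0) {
      a <- sqrt(2 * v[["lf"]])
      drift <- cumsum(rnorm(n, sd = 0.3 / sqrt(fs_mod)))
      x <- x + a * sin(2 * pi * spec$lf_freq * t + runif(1, 0, 2 * pi) +
                         drift)
    }
    if (v[["vlf"]] > 0) {
      # lower edge at 1/30 Hz: fluctuations at or below the Welch
      # resolution (60-s segments, per-segment detrend) are removed by the
      # analyser and would make the generated VLF share unmeasurable
      bb <- .powerlaw_noise(n, fs_mod, spec$spectral_exponent,
                            f_high = spec$scheme$vlf[2], f_low = 1 / 30)
      x <- x + sqrt(v[["vlf"]]) * bb
    }
    list(time = t, nn_dev = x, rate = fs_mod)
  })
}

#' Generate beats by integral pulse frequency modulation
#'
#' The instantaneous NN interval is `mean_nn + modulation` (ms); the
#' instantaneous beat rate is its reciprocal. Beats are emitted each time
#' the running integral of the rate crosses an integer, with the crossing
#' located by linear interpolation between grid points. This separates the
#' modulation spectrum cleanly from the point-process sampling, the usual
#' idealisation of sinoatrial pacing.
#'
#' @param modulation Output of [generate_modulation()] (or any list with
#'   `time`, `nn_dev`, `rate`).
#' @param mean_nn Mean NN interval, ms.
#' @param animal_id Label for the resulting series.
#' @return An [rr_series()] (`cleaned = FALSE`).
#' @export
ipfm_beats <- function(modulation, mean_nn, animal_id = "sim") {
  nn_inst <- mean_nn + modulation$nn_dev
  if (any(nn_inst <= 0)) {
    bad <- modulation$time[which(nn_inst <= 0)[1]]
    mhrv_error(
      "generation_error",
      sprintf("instantaneous NN <= 0 at t = %.2f s; reduce sdnn_target", bad)
    )
  }
  rate <- 1000 / nn_inst # beats per second
  dt <- 1 / modulation$rate
  tt <- modulation$time
  n <- length(rate)
  # cumulative trapezoidal integral of the rate over the modulation grid
  integral <- c(0, cumsum((rate[-1] + rate[-n]) / 2 * dt))
  n_beats <- floor(integral[n] - 1e-9)
  if (n_beats < 2) {
    mhrv_error("insufficient_data_error", "record too short to emit 2 beats")
  }
  ks <- seq_len(n_beats)
  idx <- findInterval(ks, integral)
  frac <- (ks - integral[idx]) / (integral[idx + 1] - integral[idx])
  beat_times <- tt[idx] + frac * dt
  rr_series(beat_times = beat_times, animal_id = animal_id)
}

#' Simulate an RR series from a generator spec or preset
#'
#' Convenience wrapper: [generate_modulation()] followed by [ipfm_beats()].
#'
#' @param spec A [generator_spec()], or a preset name accepted by
#'   [preset_spec()].
#' @param duration Record length in s (used when `spec` is a preset name).
#' @param seed Optional integer seed.
#' @param animal_id Label for the series.
#' @return An [rr_series()].
#' @export
#' @examples
#' rr <- simulate_rr("young_basal_LT", duration = 120, seed = 1)
#' summarize_time_domain(rr)$mean_hr
simulate_rr <- function(spec, duration = 1800, seed = NULL,
                        animal_id = NULL) {
  if (is.character(spec)) {
    if (is.null(animal_id)) animal_id <- spec
    spec <- preset_spec(spec, duration = duration, seed = seed)
  }
  if (is.null(animal_id)) animal_id <- "sim"
  mod <- generate_modulation(spec, seed = if (is.null(seed)) spec$seed
                             else seed)
  ipfm_beats(mod, spec$mean_nn, animal_id = animal_id)
}

#' Generate a synthetic cohort emulating the 2x2x2 study design
#'
#' Creates `n_per_cell` animals per age group; each animal is recorded in
#' all four of its cells (two temperatures x basal/intrinsic), sharing a
#' single standardised animal effect `z` across its records: the animal's
#' mean HR in a cell is the cell mean plus `z` times that cell's
#' between-animal SD (SE * sqrt(N) from the calibration table). Each cell
#' therefore holds `n_per_cell` records and the output has
#' `8 * n_per_cell` records in total.
#'
#' @param n_per_cell Animals per design cell (>= 2).
#' @param seed Integer seed; output is byte-reproducible given the seed.
#' @param duration Record length per recording, seconds.
#' @return A `cohort_dataset`: list with `records` (named list of
#'   [rr_series()]), `manifest` (a `cohort_manifest` whose `path` column is
#'   empty), and `truth` (data frame of the generating parameters per
#'   record).
#' @export
generate_cohort <- function(n_per_cell, seed = 1, duration = 1800) {
  if (n_per_cell < 2) {
    mhrv_error("configuration_error", "n_per_cell must be at least 2")
  }
  tab <- hrv_presets()
  with_seed(seed, {
    animals <- data.frame(
      animal_id = c(sprintf("young_%02d", seq_len(n_per_cell)),
                    sprintf("old_%02d", seq_len(n_per_cell))),
      age_group = rep(c("young", "old"), each = n_per_cell),
      z = rnorm(2 * n_per_cell),
      stringsAsFactors = FALSE
    )
    records <- list()
    manifest <- NULL
    truth <- NULL
    rec_seeds <- sample.int(.Machine$integer.max %/% 2,
                            nrow(animals) * 4)
    k <- 0
    for (a in seq_len(nrow(animals))) {
      cells <- tab[tab$age_group == animals$age_group[a], ]
      for (ci in seq_len(nrow(cells))) {
        k <- k + 1
        cell <- cells[ci, ]
        hr_animal <- cell$hr_bpm + animals$z[a] * cell$hr_se *
          sqrt(cell$n_animals)
        # clamp so mean_nn = 60000/hr stays above 3 * sdnn (and hr sane)
        hr_animal <- min(max(hr_animal, 50),
                         60000 / (3.2 * cell$sdnn_ms))
        fr <- c(cell$vlf_ms2, cell$lf_ms2, cell$hf_ms2)
        freqs <- .mod_freqs[[cell$temperature]]
        spec <- generator_spec(
          mean_nn = 60000 / hr_animal,
          sdnn_target = cell$sdnn_ms,
          band_fractions = fr / sum(fr),
          spectral_exponent = cell$beta_abs,
          lf_freq = freqs[["lf"]], hf_freq = freqs[["hf"]],
          duration = duration,
          scheme = band_scheme(cell$temperature)
        )
        rec_id <- sprintf("%s_%s_%s", animals$animal_id[a],
                          cell$temperature, cell$state)
        records[[rec_id]] <- simulate_rr(spec, seed = rec_seeds[k],
                                         animal_id = animals$animal_id[a])
        manifest <- rbind(manifest, data.frame(
          animal_id = animals$animal_id[a],
          age_group = cell$age_group,
          temperature = cell$temperature,
          state = cell$state,
          path = "",
          stringsAsFactors = FALSE
        ))
        truth <- rbind(truth, data.frame(
          record_id = rec_id,
          animal_id = animals$animal_id[a],
          age_group = cell$age_group,
          temperature = cell$temperature,
          state = cell$state,
          preset = cell$preset,
          true_hr_bpm = hr_animal,
          true_mean_nn_ms = 60000 / hr_animal,
          true_sdnn_ms = cell$sdnn_ms,
          seed = rec_seeds[k],
          stringsAsFactors = FALSE
        ))
      }
    }
    structure(
      list(records = records, manifest = validate_manifest(manifest),
           truth = truth),
      class = "cohort_dataset"
    )
  })
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf(
    "<cohort_dataset: %d records, %d animals>\n",
    length(x$records), length(unique(x$manifest$animal_id))
  ))
  invisible(x)
}

#' Synthesize a single-lead ECG from an RR series
#'
#' Places a Gaussian-bump QRS template (8 ms full width at half maximum,
#' 1 mV amplitude) at each beat time and adds white Gaussian noise at the
#' requested signal-to-noise ratio.
#'
#' @param rr An [rr_series()].
#' @param fs Sampling rate in Hz, >= 250 (murine telemetry is nominally
#'   1 kHz).
#' @param snr_db Signal-to-noise ratio in dB (`Inf` for noise-free).
#' @param seed Optional integer seed for the noise.
#' @return An [ecg_record()].
#' @export
synthesize_ecg <- function(rr, fs = 1000, snr_db = Inf, seed = NULL) {
  stopifnot(inherits(rr, "rr_series"))
  if (fs < 250) {
    mhrv_error("validation_error", "fs must be at least 250 Hz")
  }
  beats <- rr$beat_times
  dur <- max(beats) + 0.05
  n <- as.integer(ceiling(dur * fs))
  t <- seq_len(n) / fs
  sigma <- 0.008 / (2 * sqrt(2 * log(2))) # FWHM 8 ms
  x <- numeric(n)
  half <- as.integer(ceiling(4 * sigma * fs))
  for (b in beats) {
    i0 <- as.integer(round(b * fs))
    lo <- max(1L, i0 - half)
    hi <- min(n, i0 + half)
    if (lo > hi) next
    x[lo:hi] <- x[lo:hi] + exp(-((t[lo:hi] - b)^2) / (2 * sigma^2))
  }
  if (is.finite(snr_db)) {
    p_sig <- mean(x^2)
    noise_sd <- sqrt(p_sig / 10^(snr_db / 10))
    x <- x + with_seed(seed, rnorm(n, sd = noise_sd))
  }
  ecg_record(x, fs)
}
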