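#' Temperature-indexed spectral band scheme
#'
#' Murine heart rate roughly doubles between thermoneutrality (30 C) and
#' standard laboratory temperature (20 C), so fixed VLF/LF/HF cut-offs would
#' assign the same physiological rhythm to different bands at the two
#' temperatures. The band edges therefore shift with ambient temperature:
#' at 20 C, VLF 0-0.5, LF 0.5-1.5, HF 1.5-5.0 Hz; at 30 C, VLF 0-0.2,
#' LF 0.2-0.75, HF 0.75-3.0 Hz.
#'
#' @param label `"20C"`, `"30C"`, or `"custom"` (then supply `edges`).
#' @param edges For `label = "custom"`: increasing numeric vector
#'   `c(vlf_low, vlf_high, lf_high, hf_high)` in Hz.
#' @return A `band_scheme`: list with `label` and `vlf`, `lf`, `hf`
#'   two-element ranges in Hz.
#' @export
#' @examples
#' band_scheme("20C")$hf # 1.5 5.0
band_scheme <- function(label = c("20C", "30C", "custom"), edges = NULL) {
  label <- match.arg(label)
  edges <- switch(label,
    "20C" = c(0, 0.5, 1.5, 5.0),
    "30C" = c(0, 0.2, 0.75, 3.0),
    "custom" = {
      if (is.null(edges) || length(edges) != 4) {
        mhrv_error("configuration_error",
                   "custom scheme needs edges = c(vlf_low, vlf_high, lf_high, hf_high)")
      }
      as.numeric(edges)
    }
  )
  if (any(diff(edges) <= 0) || edges[1] < 0) {
    mhrv_error("configuration_error", "band edges must be increasing and >= 0")
  }
  structure(
    list(
      label = label,
      vlf = edges[1:2],
      lf = edges[2:3],
      hf = edges[3:4]
    ),
    class = "band_scheme"
  )
}

#' Band scheme for a manifest temperature level
#' @param temperature `"20C"` or `"30C"`.
#' @return A [band_scheme()].
#' @export
scheme_for_temperature <- function(temperature) {
  if (!temperature %in% c("20C", "30C")) {
    mhrv_error("configuration_error",
               sprintf("no band scheme mapped to temperature %s", temperature))
  }
  band_scheme(temperature)
}

#' Resample an RR series to a uniform NN signal
#'
#' The NN intervals form an irregularly sampled signal (one value per beat,
#' at the closing beat time). Spectral estimation needs a uniform grid, so
#' the (beat time, NN) pairs are cubic-spline interpolated and sampled at
#' `rate` Hz over the recorded span. Cleaning gaps are bridged by the
#' spline.
#'
#' @param rr An [rr_series()] spanning at least 60 s.
#' @param rate Sampling rate of the uniform signal, Hz. Default 20 Hz puts
#'   Nyquist (10 Hz) comfortably above the highest HF cut-off (5 Hz).
#' @return A `uniform_nn`: list with `time` (s), `nn` (ms), `rate` (Hz).
#' @export
resample_evenly <- function(rr, rate = 20) {
  stopifnot(inherits(rr, "rr_series"))
  tt <- rr$interval_times
  if (diff(range(tt)) < 60) {
    mhrv_error("insufficient_data_error",
               "RR series must span at least 60 s for spectral analysis")
  }
  xout <- seq(tt[1], tt[length(tt)], by = 1 / rate)
  nn <- stats::spline(tt, rr$intervals, xout = xout, method = "fmm")$y
  structure(list(time = xout, nn = nn, rate = rate), class = "uniform_nn")
}

.hann <- function(n) 0.5 * (1 - cos(2 * pi * seq(0, n - 1) / (n - 1)))

.detrend_linear <- function(y) {
  n <- length(y)
  t <- seq_len(n)
  stats::lm.fit(cbind(1, t), y)$residuals
}

#' Welch power spectral density of a uniform NN signal
#'
#' Welch's averaged modified periodogram: the signal is split into
#' `segment_s`-second segments with fractional `overlap`, each segment is
#' linearly detrended, tapered with a Hann window, and its periodogram
#' computed with density scaling (ms^2/Hz, one-sided); segment periodograms
#' are averaged.
#'
#' @param signal A `uniform_nn` from [resample_evenly()], or a plain numeric
#'   vector (then supply `rate`).
#' @param segment_s Segment length, seconds (default 60).
#' @param overlap Fractional overlap between segments (default 0.5).
#' @param rate Sampling rate in Hz when `signal` is a bare vector.
#' @return A `spectral_estimate`: list with `frequencies` (Hz, uniform grid
#'   from 0), `psd` (ms^2/Hz), `resample_rate`, `segment_length`, `overlap`,
#'   `window`.
#' @export
estimate_psd <- function(signal, segment_s = 60, overlap = 0.5, rate = NULL) {
  if (inherits(signal, "uniform_nn")) {
    x <- signal$nn
    fs <- signal$rate
  } else {
    if (is.null(rate)) {
      mhrv_error("configuration_error",
                 "rate must be given for a bare numeric signal")
    }
    x <- as.numeric(signal)
    fs <- rate
  }
  nper <- as.integer(round(segment_s * fs))
  step <- as.integer(round(nper * (1 - overlap)))
  if (step < 1) mhrv_error("configuration_error", "overlap too large")
  n <- length(x)
  if (n < nper + step) {
    mhrv_error(
      "insufficient_data_error",
      sprintf("signal too short for 2 Welch segments of %g s", segment_s)
    )
  }
  starts <- seq(1L, n - nper + 1L, by = step)
  w <- .hann(nper)
  scale <- 1 / (fs * sum(w^2))
  nfreq <- nper %/% 2L + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- .detrend_linear(x[s:(s + nper - 1L)]) * w
    sp <- Mod(stats::fft(seg))[seq_len(nfreq)]^2 * scale
    # one-sided: double everything except DC (and Nyquist when nper even)
    sp[-1] <- sp[-1] * 2
    if (nper %% 2L == 0L) sp[nfreq] <- sp[nfreq] / 2
    acc <- acc + sp
  }
  structure(
    list(
      frequencies = (seq_len(nfreq) - 1L) * fs / nper,
      psd = acc / length(starts),
      resample_rate = fs,
      segment_length = segment_s,
      overlap = overlap,
      window = "hann"
    ),
    class = "spectral_estimate"
  )
}

#' @export
print.spectral_estimate <- function(x, ...) {
  cat(sprintf(
    "<spectral_estimate: %d bins, 0-%.2f Hz, df=%.4f Hz, %s window>\n",
    length(x$frequencies), max(x$frequencies),
    x$frequencies[2] - x$frequencies[1], x$window
  ))
  invisible(x)
}

# trapezoidal integral of (f, p) restricted to [lo, hi], with linear
# interpolation at the band edges so contiguous bands telescope exactly
.trapz_band <- function(f, p, lo, hi) {
  if (hi <= lo) return(0)
  inside <- f > lo & f < hi
  ff <- c(lo, f[inside], hi)
  pp <- c(
    stats::approx(f, p, xout = lo, rule = 2)$y,
    p[inside],
    stats::approx(f, p, xout = hi, rule = 2)$y
  )
  sum(diff(ff) * (pp[-length(pp)] + pp[-1]) / 2)
}

#' Integrate a PSD into VLF/LF/HF band powers
#'
#' Trapezoidal integration of the PSD over each band of the scheme. The DC
#' bin is excluded: integration starts at the first positive frequency of
#' the grid. `total` is defined as the sum of the three bands (power above
#' the HF cut-off is not counted), so VLF + LF + HF = total exactly.
#'
#' @param spec A `spectral_estimate` from [estimate_psd()].
#' @param scheme A [band_scheme()]; its HF top must not exceed the Nyquist
#'   frequency of `spec`.
#' @return A `band_powers`: list with `total`, `vlf`, `lf`, `hf` in ms^2.
#' @export
band_powers <- function(spec, scheme) {
  stopifnot(inherits(spec, "spectral_estimate"),
            inherits(scheme, "band_scheme"))
  f <- spec$frequencies
  p <- spec$psd
  nyquist <- max(f)
  if (scheme$hf[2] > nyquist + 1e-12) {
    mhrv_error(
      "configuration_error",
      sprintf("HF top %.2f Hz exceeds Nyquist %.2f Hz: raise the resample rate",
              scheme$hf[2], nyquist)
    )
  }
  f1 <- f[f > 0][1] # exclude the DC bin
  vlf <- .trapz_band(f, p, max(scheme$vlf[1], f1), scheme$vlf[2])
  lf <- .trapz_band(f, p, max(scheme$lf[1], f1), scheme$lf[2])
  hf <- .trapz_band(f, p, max(scheme$hf[1], f1), scheme$hf[2])
  structure(
    list(total = vlf + lf + hf, vlf = vlf, lf = lf, hf = hf,
         scheme = scheme$label),
    class = "band_powers"
  )
}

#' @export
print.band_powers <- function(x, ...) {
  cat(sprintf(
    "<band_powers (%s): total %.2f, VLF %.2f, LF %.2f, HF %.2f ms^2>\n",
    x$scheme, x$total, x$vlf, x$lf, x$hf
  ))
  invisible(x)
}
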