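#' Construct an RR/NN interval series
#'
#' The central container of the package: an ordered sequence of beat times
#' (seconds from recording start) and the inter-beat (NN) intervals between
#' them, in milliseconds. Either `beat_times` or `intervals` may be supplied;
#' the other is derived. Before cleaning, `intervals[i]` equals
#' `(beat_times[i + 1] - beat_times[i]) * 1000`; after [clean_rr()] the two
#' are no longer redundant because excluded intervals are dropped while beat
#' times of surviving intervals are kept.
#'
#' @param beat_times Numeric vector of beat times in seconds, strictly
#'   increasing. If missing, reconstructed as `c(0, cumsum(intervals)/1000)`.
#' @param intervals Numeric vector of inter-beat intervals in milliseconds,
#'   all positive. If missing, derived by differencing `beat_times`.
#' @param animal_id Opaque label identifying the animal/recording.
#' @param cleaned Logical; `TRUE` once artifact exclusion has been applied.
#' @param n_raw Interval count before cleaning (defaults to the current
#'   count).
#' @param excluded_fraction Fraction of raw intervals removed by cleaning.
#'
#' @return An object of class `rr_series`: a list with elements
#'   `beat_times`, `intervals`, `interval_times` (time of the closing beat of
#'   each interval), `animal_id`, `n_raw`, `n_clean`, `cleaned`,
#'   `excluded_fraction`.
#' @export
#' @examples
#' rr <- rr_series(intervals = c(100, 100, 100), animal_id = "m1")
#' rr$beat_times # 0 0.1 0.2 0.3
rr_series <- function(beat_times = NULL, intervals = NULL, animal_id = "",
                      cleaned = FALSE, n_raw = NULL,
                      excluded_fraction = 0) {
  if (is.null(beat_times) && is.null(intervals)) {
    mhrv_error("empty_input_error", "need beat_times or intervals")
  }
  if (is.null(intervals)) {
    beat_times <- as.numeric(beat_times)
    bad <- which(diff(beat_times) <= 0)
    if (length(bad) > 0) {
      mhrv_error(
        "parse_error",
        sprintf("beat times not strictly increasing at row %d", bad[1] + 1)
      )
    }
    intervals <- diff(beat_times) * 1000
    interval_times <- beat_times[-1]
  } else if (is.null(beat_times)) {
    intervals <- as.numeric(intervals)
    if (any(intervals <= 0)) {
      mhrv_error("parse_error", "all intervals must be positive")
    }
    beat_times <- c(0, cumsum(intervals) / 1000)
    interval_times <- beat_times[-1]
  } else {
    # both supplied (post-cleaning state): intervals need not equal
    # diff(beat_times); interval_times must be given the closing beats
    beat_times <- as.numeric(beat_times)
    intervals <- as.numeric(intervals)
    if (any(intervals <= 0)) {
      mhrv_error("parse_error", "all intervals must be positive")
    }
    interval_times <- beat_times
    beat_times <- NULL
  }
  out <- structure(
    list(
      beat_times = if (is.null(beat_times)) interval_times else beat_times,
      intervals = intervals,
      interval_times = interval_times,
      animal_id = animal_id,
      n_raw = if (is.null(n_raw)) length(intervals) else n_raw,
      n_clean = length(intervals),
      cleaned = cleaned,
      excluded_fraction = excluded_fraction
    ),
    class = "rr_series"
  )
  out
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf(
    "<rr_series '%s': %d intervals, span %.1f s, mean NN %.2f ms%s>\n",
    x$animal_id, length(x$intervals),
    diff(range(x$interval_times)),
    mean(x$intervals),
    if (x$cleaned) sprintf(", cleaned (%.2f%% excluded)",
                           100 * x$excluded_fraction) else ""
  ))
  invisible(x)
}

#' @export
length.rr_series <- function(x) length(x$intervals)

#' Time span of an RR series in seconds
#' @param rr An [rr_series()].
#' @return Numeric scalar, seconds between first and last recorded beat.
#' @export
rr_span <- function(rr) {
  stopifnot(inherits(rr, "rr_series"))
  diff(range(rr$interval_times)) + rr$intervals[1] / 1000
}

#' Construct a single-lead ECG record
#'
#' @param samples Numeric vector of voltage samples (arbitrary units, mV by
#'   convention).
#' @param sampling_rate Sampling rate in Hz (murine telemetry is nominally
#'   1 kHz).
#' @return An `ecg_record`: list with `samples`, `sampling_rate`,
#'   `duration` (seconds).
#' @export
ecg_record <- function(samples, sampling_rate) {
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    mhrv_error("validation_error", "sampling_rate must be positive")
  }
  structure(
    list(
      samples = as.numeric(samples),
      sampling_rate = sampling_rate,
      duration = length(samples) / sampling_rate
    ),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf(
    "<ecg_record: %d samples @ %g Hz (%.1f s)>\n",
    length(x$samples), x$sampling_rate, x$duration
  ))
  invisible(x)
}
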