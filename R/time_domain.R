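#' Time-domain HRV summary
#'
#' Computes the classical time-domain metrics over the analysis window as a
#' single segment: mean NN, mean heart rate (defined as 60000 / mean NN, not
#' the mean of per-beat instantaneous rates), SDNN (sample standard
#' deviation, n - 1 denominator), the coefficient of variation
#' CV = 100 * SDNN / mean NN, and the Poincare axes SD1/SD2.
#'
#' @param rr An [rr_series()] with at least 30 intervals (cleaned input
#'   expected).
#' @return A `time_domain_summary`: list with `mean_nn` (ms), `mean_hr`
#'   (bpm), `sdnn` (ms), `cv` (percent), `sd1` (ms), `sd2` (ms), `n_beats`.
#' @export
#' @examples
#' rr <- rr_series(intervals = rep(c(90, 110), 500))
#' summarize_time_domain(rr)$cv
summarize_time_domain <- function(rr) {
  stopifnot(inherits(rr, "rr_series"))
  x <- rr$intervals
  if (length(x) < 30) {
    mhrv_error("insufficient_data_error",
               "need at least 30 intervals for a time-domain summary")
  }
  mean_nn <- mean(x)
  sdnn <- stats::sd(x)
  pc <- poincare(rr)
  structure(
    list(
      mean_nn = mean_nn,
      mean_hr = 60000 / mean_nn,
      sdnn = sdnn,
      cv = 100 * sdnn / mean_nn,
      sd1 = pc$sd1,
      sd2 = pc$sd2,
      n_beats = length(x)
    ),
    class = "time_domain_summary"
  )
}

#' @export
print.time_domain_summary <- function(x, ...) {
  cat(sprintf(
    paste0("<time_domain_summary: mean HR %.1f bpm, mean NN %.2f ms, ",
           "SDNN %.2f ms, CV %.2f%%, SD1 %.2f, SD2 %.2f, n=%d>\n"),
    x$mean_hr, x$mean_nn, x$sdnn, x$cv, x$sd1, x$sd2, x$n_beats
  ))
  invisible(x)
}

#' Poincare plot descriptors
#'
#' Plots each NN interval against its successor and summarises the scatter
#' by its short axis SD1 = sqrt(var(diff(NN)) / 2) (beat-to-beat
#' variability) and long axis SD2 = sqrt(2 var(NN) - SD1^2) (clamped at 0).
#' The identity SD1^2 + SD2^2 = 2 var(NN) holds by construction.
#'
#' @param rr An [rr_series()] with at least 3 intervals.
#' @return List with `sd1`, `sd2` (ms) and `points`, a two-column matrix of
#'   (NN_i, NN_{i+1}) coordinates.
#' @export
poincare <- function(rr) {
  x <- if (inherits(rr, "rr_series")) rr$intervals else as.numeric(rr)
  n <- length(x)
  if (n < 3) {
    mhrv_error("insufficient_data_error",
               "need at least 3 intervals for Poincare descriptors")
  }
  d <- diff(x)
  sd1 <- sqrt(stats::var(d) / 2)
  sd2sq <- 2 * stats::var(x) - sd1^2
  sd2 <- sqrt(max(sd2sq, 0))
  list(
    sd1 = sd1,
    sd2 = sd2,
    points = cbind(nn = x[-n], nn_next = x[-1])
  )
}
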