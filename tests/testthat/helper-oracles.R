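# Independent oracles and small fixture builders used across the suite.

# Brute-force sample entropy: enumerates all template pairs through full
# Chebyshev distance matrices (vectorised over coordinates, but logically
# the O(n^2) double loop). Kept deliberately independent of the package's
# C++ lag-loop implementation.
sampen_oracle <- function(x, m, r) {
  n <- length(x)
  N <- n - m # template start positions shared by lengths m and m+1
  count_pairs <- function(len) {
    D <- matrix(0, N, N)
    for (k in 0:(len - 1)) {
      v <- x[(1:N) + k]
      D <- pmax(D, abs(outer(v, v, "-")))
    }
    (sum(D <= r) - N) / 2 # upper triangle only, self-matches excluded
  }
  B <- count_pairs(m)
  A <- count_pairs(m + 1)
  if (B == 0 || A == 0) return(Inf)
  -log(A / B)
}

# trapezoid over the full PSD grid (Parseval checks)
trapz_full <- function(f, p) {
  sum(diff(f) * (p[-length(p)] + p[-1]) / 2)
}

# RR series whose NN intervals are sinusoidally modulated at f_mod Hz,
# built directly in the interval domain (no IPFM): interval k closes at
# time t_k and has length mean_nn + a*sin(2 pi f t_k).
sinusoid_rr <- function(f_mod, amp, mean_nn = 100, duration = 300) {
  tt <- 0
  ints <- numeric(0)
  while (tt < duration) {
    nn <- mean_nn + amp * sin(2 * pi * f_mod * tt)
    ints <- c(ints, nn)
    tt <- tt + nn / 1000
  }
  rr_series(intervals = ints, animal_id = "sinusoid")
}

# metric table for a hand-built two-cell design (used by cohort tests)
two_cell_metrics <- function(y1, y2, age = "young", temp = "20C") {
  data.frame(
    animal_id = c(sprintf("a%d", seq_along(y1)),
                  sprintf("b%d", seq_along(y2))),
    age_group = age,
    temperature = temp,
    state = rep(c("basal", "intrinsic"), c(length(y1), length(y2))),
    mean_hr_bpm = c(y1, y2),
    stringsAsFactors = FALSE
  )
}
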