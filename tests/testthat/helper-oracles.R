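# Independent oracles used by the tests.

# Exhaustive least-squares segmentation into n_segments pieces by dynamic
# programming over prefix sums (O(k n^2)); returns the change points as the
# last index of each segment but the final one. Independent of the CUSUM
# implementation under test.
dp_changepoints <- function(x, n_segments) {
  n <- length(x)
  s1 <- cumsum(x); s2 <- cumsum(x^2)
  sse <- function(i, j) { # cost of segment [i, j], vectorized over i
    m <- j - i + 1
    sum1 <- s1[j] - c(0, s1)[i]
    sum2 <- s2[j] - c(0, s2)[i]
    sum2 - sum1^2 / m
  }
  D <- matrix(Inf, n_segments, n)
  back <- matrix(NA_integer_, n_segments, n)
  D[1, ] <- vapply(seq_len(n), function(j) sse(1, j), numeric(1))
  if (n_segments > 1) {
    for (k in 2:n_segments) {
      for (j in k:n) {
        i <- (k - 1):(j - 1)            # last index of previous part
        cand <- D[k - 1, i] + sse(i + 1, j)
        best <- which.min(cand)
        D[k, j] <- cand[best]
        back[k, j] <- i[best]
      }
    }
  }
  cps <- integer(0); j <- n
  if (n_segments > 1) for (k in n_segments:2) {
    j <- back[k, j]
    cps <- c(j, cps)
  }
  cps
}

# Arrival times of a homogeneous Poisson process on [0, t_end].
poisson_arrivals <- function(rate, t_end) {
  n <- stats::rpois(1, rate * t_end)
  sort(stats::runif(n, 0, t_end))
}

# Shared small acquisition/pore objects (full chain defaults).
acq_default <- function(...) acquisition_config(voltage_mv = 150, ...)
pore_default <- function(...) pore_model(...)

# A fast low-rate acquisition for statistics-only trace tests where the
# sampled waveform fidelity is irrelevant.
acq_coarse <- function(duration_s = 6)
  acquisition_config(sampling_hz = 1e5, analog_bandwidth_hz = 2.5e4,
                     digital_cutoff_hz = 1e4, voltage_mv = 150,
                     duration_s = duration_s)
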