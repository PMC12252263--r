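# Independent oracles, deliberately written in the most naive style so
# they share no code path with the package implementation.

# autocorrelation at a single lag, double loop, direct from the defining sum
acf_oracle <- function(x, k) {
  n <- length(x)
  m <- 0
  for (t in 1:n) m <- m + x[t]
  m <- m / n
  num <- 0
  for (t in 1:(n - k)) num <- num + (x[t] - m) * (x[t + k] - m)
  den <- 0
  for (t in 1:n) den <- den + (x[t] - m)^2
  num / den
}

# DTW by exhaustive enumeration of every monotone boundary-to-boundary
# warping path (diagonal / right / down steps); feasible for lengths <= 8
dtw_enum <- function(a, b) {
  n <- length(a)
  m <- length(b)
  best <- Inf
  walk <- function(i, j, acc) {
    acc <- acc + abs(a[i] - b[j])
    if (i == n && j == m) {
      if (acc < best) best <<- acc
      return(invisible(NULL))
    }
    if (i < n) walk(i + 1L, j, acc)
    if (j < m) walk(i, j + 1L, acc)
    if (i < n && j < m) walk(i + 1L, j + 1L, acc)
    invisible(NULL)
  }
  walk(1L, 1L, 0)
  best
}

# build a 6-channel trace where every channel is the given vector (or a
# named list overrides single channels)
make_trace <- function(x, rate = 50, override = list()) {
  n <- length(x)
  mat <- matrix(rep(x, 6), ncol = 6,
                dimnames = list(NULL, trace_channels))
  for (ch in names(override)) mat[, ch] <- override[[ch]]
  inertial_trace(mat, sample_rate_hz = rate)
}
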