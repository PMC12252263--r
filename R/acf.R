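#' Sample autocorrelation profile of a window
#'
#' Computes the autocorrelation function
#' \deqn{r_k = \frac{\sum_{t=1}^{N-k} (x_t - \bar x)(x_{t+k} - \bar x)}
#'                  {\sum_{t=1}^{N} (x_t - \bar x)^2}}
#' for lags \eqn{k = 0, \dots, K}: the numerator runs over the overlapping
#' part of the window only, the denominator over the full window, both
#' centered on the full-window mean. With this normalization \eqn{r_0 = 1},
#' \eqn{|r_k| \le 1}, and the peak height of a periodic waveform of period
#' \eqn{p} decays approximately as \eqn{1 - p/N}, the law the footwork
#' threshold is built on.
#'
#' The "first peak" is the smallest lag \eqn{k \ge 1} that is a strict
#' two-sided local maximum (\eqn{r_k > r_{k-1}} and \eqn{r_k > r_{k+1}}).
#' A value at the last computed lag cannot qualify (no right neighbour),
#' so peaks are searched over \eqn{1 \le k \le K - 1}.
#'
#' @param x Numeric vector, length at least 2.
#' @param max_lag Largest lag \eqn{K} to compute; `1 <= max_lag < length(x)`.
#'   Default `length(x) - 1`.
#' @return An object of class `acf_profile`: list with `lags` (0..K),
#'   `values` (\eqn{r_k}), `first_peak_lag` and `first_peak_value`
#'   (both `NULL` when no interior peak exists).
#' @examples
#' acf_profile(c(1, 2, 3, 4), max_lag = 1)$values  # 1, 0.25
#' @export
acf_profile <- function(x, max_lag = length(x) - 1L) {
  n <- length(x)
  if (n < 2L) stop_preaction("need at least 2 samples", "insufficient_data_error")
  max_lag <- as.integer(max_lag)
  if (max_lag < 1L || max_lag >= n) {
    stop_preaction("max_lag must satisfy 1 <= max_lag < length(x)",
                   "bounds_error")
  }
  y <- x - mean(x)
  denom <- sum(y * y)
  if (!is.finite(denom) || denom == 0) {
    stop_preaction("zero-variance (degenerate) signal", "degenerate_signal_error")
  }
  vals <- c(1, vapply(seq_len(max_lag), function(k) {
    sum(y[1:(n - k)] * y[(k + 1):n]) / denom
  }, numeric(1)))
  peak <- first_acf_peak(vals)
  structure(
    list(lags = 0:max_lag, values = vals,
         first_peak_lag = peak$lag, first_peak_value = peak$value),
    class = "acf_profile"
  )
}

# vals is r_0..r_K; returns smallest k with r_k > r_{k-1} and r_k > r_{k+1}
first_acf_peak <- function(vals) {
  K <- length(vals) - 1L
  if (K >= 2L) {
    for (k in 1:(K - 1L)) {
      if (vals[k + 1L] > vals[k] && vals[k + 1L] > vals[k + 2L]) {
        return(list(lag = k, value = vals[k + 1L]))
      }
    }
  }
  list(lag = NULL, value = NULL)
}

#' @export
print.acf_profile <- function(x, ...) {
  cat(sprintf("<acf_profile> %d lags", length(x$lags)))
  if (!is.null(x$first_peak_lag)) {
    cat(sprintf(", first peak at lag %d (r = %.3f)",
                x$first_peak_lag, x$first_peak_value))
  } else {
    cat(", no interior peak")
  }
  cat("\n")
  invisible(x)
}
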