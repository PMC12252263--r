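#' Channel names of a 6-axis inertial trace
#'
#' Fixed coordinate convention for the wrist-worn sensor: `acc_x` is the
#' punch (forward) direction, `acc_y` is vertical (up-down), `acc_z` is
#' lateral. Acceleration is stored in g, angular velocity in deg/s.
#'
#' @format Character vector of the six channel names, in canonical order.
#' @export
trace_channels <- c("acc_x", "acc_y", "acc_z", "gyro_x", "gyro_y", "gyro_z")

#' Acceleration channel names
#'
#' The three acceleration axes; footwork segmentation runs on these only,
#' because footwork periodicity is not reliably visible in angular velocity.
#'
#' @format Character vector `c("acc_x", "acc_y", "acc_z")`.
#' @export
acc_channels <- c("acc_x", "acc_y", "acc_z")

#' Construct a 6-axis inertial trace
#'
#' The universal input type of the package: a uniformly sampled record of
#' 3-axis acceleration (g) and 3-axis angular velocity (deg/s) from a
#' wrist-worn sensor.
#'
#' @param data Numeric matrix or data frame with the six channels as
#'   columns. Columns are matched by name when names are present
#'   (any order), otherwise taken positionally in the order of
#'   [trace_channels].
#' @param sample_rate_hz Sampling rate in Hz; must be positive. Default 50.
#' @param start_time_s Time of the first sample in seconds. Default 0.
#' @return An object of class `inertial_trace`: a list with elements
#'   `data` (n x 6 numeric matrix, canonical column order),
#'   `sample_rate_hz` and `start_time_s`.
#' @examples
#' tr <- inertial_trace(matrix(rnorm(60), ncol = 6))
#' n_samples(tr)
#' @export
inertial_trace <- function(data, sample_rate_hz = 50, start_time_s = 0) {
  data <- as.matrix(data)
  if (!is.numeric(data)) {
    stop_preaction("trace data must be numeric", "trace_format_error")
  }
  if (ncol(data) != 6L) {
    stop_preaction(
      sprintf("trace needs 6 channels, got %d", ncol(data)),
      "trace_format_error"
    )
  }
  if (!is.null(colnames(data))) {
    missing <- setdiff(trace_channels, colnames(data))
    if (length(missing)) {
      stop_preaction(
        paste0("missing channel column(s): ", paste(missing, collapse = ", ")),
        "trace_format_error"
      )
    }
    data <- data[, trace_channels, drop = FALSE]
  } else {
    colnames(data) <- trace_channels
  }
  if (nrow(data) < 1L) {
    stop_preaction("trace must contain at least one sample", "empty_input_error")
  }
  if (!all(is.finite(data))) {
    bad <- which(!is.finite(data), arr.ind = TRUE)
    stop_preaction(
      sprintf("non-finite value at row %d, channel %s",
              bad[1, 1], colnames(data)[bad[1, 2]]),
      "trace_parse_error"
    )
  }
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1L ||
      !is.finite(sample_rate_hz) || sample_rate_hz <= 0) {
    stop_preaction("sample_rate_hz must be a positive number", "trace_format_error")
  }
  structure(
    list(data = data, sample_rate_hz = as.numeric(sample_rate_hz),
         start_time_s = as.numeric(start_time_s)),
    class = "inertial_trace"
  )
}

#' Number of samples in a trace
#' @param trace An [inertial_trace()].
#' @return Integer sample count.
#' @export
n_samples <- function(trace) {
  stopifnot(inherits(trace, "inertial_trace"))
  nrow(trace$data)
}

#' Extract one channel of a trace
#' @param trace An [inertial_trace()].
#' @param axis One of [trace_channels].
#' @return Numeric vector of that channel.
#' @export
trace_channel <- function(trace, axis) {
  stopifnot(inherits(trace, "inertial_trace"))
  axis <- match.arg(axis, trace_channels)
  trace$data[, axis]
}

#' @export
print.inertial_trace <- function(x, ...) {
  cat(sprintf(
    "<inertial_trace> %d samples @ %g Hz (%.2f s), start %g s\n",
    nrow(x$data), x$sample_rate_hz, nrow(x$data) / x$sample_rate_hz,
    x$start_time_s
  ))
  invisible(x)
}

#' Read an inertial trace from CSV
#'
#' Expects a comma-separated file with a header naming the six channels
#' (see [trace_channels]); an optional `time_s` column is used to recover
#' the sampling rate and start time when `sample_rate_hz` is not given.
#'
#' @param path Path to the CSV file.
#' @param sample_rate_hz Sampling rate in Hz. If `NULL` (default) it is
#'   inferred from the `time_s` column when present, else 50.
#' @return A validated [inertial_trace()].
#' @seealso [write_trace()] for the inverse; the round trip is bit-exact.
#' @export
read_trace <- function(path, sample_rate_hz = NULL) {
  if (!file.exists(path)) {
    stop_preaction(sprintf("file not found: %s", path), "io_error")
  }
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop_preaction(
      sprintf("cannot parse %s: %s", path, conditionMessage(e)), "empty_input_error"
    )
  )
  if (nrow(df) == 0L) {
    stop_preaction(sprintf("empty trace file: %s", path), "empty_input_error")
  }
  missing <- setdiff(trace_channels, names(df))
  if (length(missing)) {
    stop_preaction(
      paste0("missing channel column(s): ", paste(missing, collapse = ", ")),
      "trace_format_error"
    )
  }
  mat <- matrix(NA_real_, nrow = nrow(df), ncol = 6L,
                dimnames = list(NULL, trace_channels))
  for (ch in trace_channels) {
    v <- suppressWarnings(as.numeric(df[[ch]]))
    bad <- which(!is.finite(v))
    if (length(bad)) {
      stop_preaction(
        sprintf("non-numeric or non-finite value in column %s at row %d",
                ch, bad[1]),
        "trace_parse_error"
      )
    }
    mat[, ch] <- v
  }
  start_time_s <- 0
  if (is.null(sample_rate_hz)) {
    if ("time_s" %in% names(df) && nrow(df) >= 2L) {
      tt <- suppressWarnings(as.numeric(df[["time_s"]]))
      if (all(is.finite(tt)) && mean(diff(tt)) > 0) {
        sample_rate_hz <- 1 / mean(diff(tt))
        start_time_s <- tt[1]
      } else {
        sample_rate_hz <- 50
      }
    } else {
      sample_rate_hz <- 50
      if ("time_s" %in% names(df)) {
        tt <- suppressWarnings(as.numeric(df[["time_s"]]))
        if (is.finite(tt[1])) start_time_s <- tt[1]
      }
    }
  } else if ("time_s" %in% names(df)) {
    tt <- suppressWarnings(as.numeric(df[["time_s"]]))
    if (is.finite(tt[1])) start_time_s <- tt[1]
  }
  inertial_trace(mat, sample_rate_hz = sample_rate_hz,
                 start_time_s = start_time_s)
}

#' Write an inertial trace to CSV
#'
#' Writes `time_s` plus the six channels with full double precision, so
#' that [read_trace()] reproduces the trace bit-exactly.
#'
#' @param trace An [inertial_trace()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "inertial_trace"))
  n <- nrow(trace$data)
  if (n < 1L) {
    stop_preaction("empty traces are not serializable", "empty_input_error")
  }
  tt <- trace$start_time_s + (seq_len(n) - 1L) / trace$sample_rate_hz
  cols <- c(list(time_s = tt),
            lapply(trace_channels, function(ch) trace$data[, ch]))
  names(cols) <- c("time_s", trace_channels)
  txt <- vapply(cols, function(v) sprintf("%.17g", v), character(n))
  if (n == 1L) txt <- matrix(txt, nrow = 1L, dimnames = list(NULL, names(cols)))
  lines <- c(paste(names(cols), collapse = ","),
             apply(txt, 1L, paste, collapse = ","))
  ok <- tryCatch({
    writeLines(lines, path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_preaction(sprintf("cannot write %s", path), "io_error")
  invisible(path)
}

#' Slice a contiguous sample range out of a trace
#'
#' 1-based inclusive indexing: the result keeps samples `from..to` and
#' advances `start_time_s` by `(from - 1) / sample_rate_hz`.
#'
#' @param trace An [inertial_trace()].
#' @param from,to First and last sample index to keep (`1 <= from <= to <= n`).
#' @return The sliced [inertial_trace()].
#' @export
slice_trace <- function(trace, from, to) {
  stopifnot(inherits(trace, "inertial_trace"))
  n <- nrow(trace$data)
  if (!(length(from) == 1L && length(to) == 1L &&
        from >= 1L && to <= n && from <= to)) {
    stop_preaction(
      sprintf("slice [%s, %s] out of bounds for trace of length %d",
              from, to, n),
      "bounds_error"
    )
  }
  inertial_trace(
    trace$data[from:to, , drop = FALSE],
    sample_rate_hz = trace$sample_rate_hz,
    start_time_s = trace$start_time_s + (from - 1) / trace$sample_rate_hz
  )
}
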