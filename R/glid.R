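#' Detect the striking timing of a punch
#'
#' The striking timing — the instant the arm is fully extended and the
#' fist reaches the target — shows up as a large negative peak on the
#' forward (X) acceleration axis. Returns the index of the most negative
#' `acc_x` sample, provided it is at or below `-min_magnitude`; on exact
#' ties the earliest sample wins.
#'
#' @param trace An [inertial_trace()].
#' @param min_magnitude Minimum peak magnitude in g (positive number).
#'   Default 1.5.
#' @return 1-based sample index of the striking timing.
#' @export
detect_striking_timing <- function(trace, min_magnitude = 1.5) {
  stopifnot(inherits(trace, "inertial_trace"))
  if (!(is.numeric(min_magnitude) && min_magnitude > 0)) {
    stop_preaction("min_magnitude must be > 0", "bounds_error")
  }
  x <- trace_channel(trace, "acc_x")
  i <- which.min(x)
  if (x[i] > -min_magnitude) {
    stop_preaction(
      sprintf("no acc_x sample at or below -%g g: no strike found", min_magnitude),
      "no_strike_found"
    )
  }
  i
}

#' Cut a punch at its striking timing and reverse it in time
#'
#' Keeps samples `1..strike_idx` of all six channels and reverses them,
#' so sample 1 of the result is the striking-timing sample. Anchoring
#' every punch at its strike and walking backwards in time aligns the
#' (similar) final punch waveforms across recordings, leaving any
#' pre-action as a trailing discrepancy the incremental DTW profile can
#' expose.
#'
#' @param trace An [inertial_trace()].
#' @param strike_idx Striking-timing index, `1 <= strike_idx <= n`.
#' @return The cut, time-reversed [inertial_trace()] (`start_time_s` reset
#'   to 0).
#' @export
cut_and_reverse <- function(trace, strike_idx) {
  stopifnot(inherits(trace, "inertial_trace"))
  n <- n_samples(trace)
  if (!(length(strike_idx) == 1L && strike_idx >= 1L && strike_idx <= n)) {
    stop_preaction(
      sprintf("strike_idx %s out of range [1, %d]", strike_idx, n),
      "bounds_error"
    )
  }
  inertial_trace(trace$data[strike_idx:1L, , drop = FALSE],
                 sample_rate_hz = trace$sample_rate_hz, start_time_s = 0)
}

#' Dynamic time warping distance between two multichannel sequences
#'
#' Classic dynamic-programming DTW with symmetric step pattern (diagonal,
#' horizontal, vertical), absolute-difference local cost, and
#' boundary-to-boundary alignment. Channels are warped independently and
#' their per-channel distances summed, which is robust to per-axis timing
#' jitter.
#'
#' @param a,b [inertial_trace()] objects or numeric matrices (samples x
#'   channels) with the same channel count. Plain vectors are treated as
#'   single-channel.
#' @return The summed optimal path cost, a non-negative number.
#' @export
dtw_distance <- function(a, b) {
  a <- as_channel_matrix(a)
  b <- as_channel_matrix(b)
  if (ncol(a) != ncol(b)) {
    stop_preaction(
      sprintf("channel count mismatch: %d vs %d", ncol(a), ncol(b)),
      "shape_error"
    )
  }
  if (nrow(a) == 0L || nrow(b) == 0L) {
    stop_preaction("sequences must be non-empty", "empty_input_error")
  }
  sum(vapply(seq_len(ncol(a)), function(ch) {
    .dtw_cost_1d(a[, ch], b[, ch])
  }, numeric(1)))
}

as_channel_matrix <- function(x) {
  if (inherits(x, "inertial_trace")) x$data
  else if (is.matrix(x)) x
  else matrix(as.numeric(x), ncol = 1L)
}

#' Bundle pre-action-free punches into a reference set
#'
#' The comparison basis of the detector: punches known to contain no
#' pre-action, each already cut at its striking timing and time-reversed
#' (see [ingest_reference()] for raw recordings).
#'
#' @param punches Non-empty list of [inertial_trace()] objects, each cut
#'   and reversed.
#' @param source_meta Free-text provenance string.
#' @return Object of class `reference_punch_set`.
#' @export
reference_punch_set <- function(punches, source_meta = "") {
  if (!length(punches)) {
    stop_preaction("reference set must be non-empty", "configuration_error")
  }
  ok <- vapply(punches, inherits, logical(1), "inertial_trace")
  if (!all(ok)) {
    stop_preaction("all reference punches must be inertial traces",
                   "configuration_error")
  }
  structure(list(punches = punches, source_meta = source_meta),
            class = "reference_punch_set")
}

#' @export
length.reference_punch_set <- function(x) length(x$punches)

#' @export
print.reference_punch_set <- function(x, ...) {
  cat(sprintf("<reference_punch_set> %d pre-action-free punches\n",
              length(x$punches)))
  invisible(x)
}

#' Normalize a raw punch recording into a reference punch
#'
#' Runs the same striking-timing detection and cut-and-reverse path as
#' the detector input, so stored references and analyzed punches share
#' one anchoring convention.
#'
#' @param trace Raw punch [inertial_trace()].
#' @param min_magnitude Passed to [detect_striking_timing()].
#' @return The cut, reversed [inertial_trace()].
#' @export
ingest_reference <- function(trace, min_magnitude = 1.5) {
  cut_and_reverse(trace, detect_striking_timing(trace, min_magnitude))
}

#' Incremental-window DTW distance profile against a reference set
#'
#' For growing window lengths `w = step, 2*step, ...` up to the full
#' input, computes the DTW distance between the first `w` samples of the
#' (already reversed) input and each full-length reference punch, and
#' aggregates over the reference set. Because the input is reversed, the
#' window grows backwards in time from the strike: once it reaches a
#' pre-action the distance rises, producing the local-minimum /
#' local-maximum gap the decision is based on.
#'
#' @param input_cut Cut-and-reversed input [inertial_trace()] (or matrix).
#' @param refs A [reference_punch_set()].
#' @param step Window increment in samples, at least 1. Default 1.
#' @param aggregate `"mean"` (default) or `"min"` over the reference set.
#' @return Object of class `dtw_profile`: list with `window_lengths`,
#'   `distances` and `aggregation`.
#' @export
glid_profile <- function(input_cut, refs, step = 1L,
                         aggregate = c("mean", "min")) {
  aggregate <- match.arg(aggregate)
  if (!inherits(refs, "reference_punch_set")) {
    stop_preaction("refs must be a reference_punch_set", "configuration_error")
  }
  step <- as.integer(step)
  if (step < 1L) stop_preaction("step must be >= 1", "bounds_error")
  a <- as_channel_matrix(input_cut)
  n <- nrow(a)
  if (n == 0L) stop_preaction("input must be non-empty", "empty_input_error")
  per_ref <- vapply(refs$punches, function(ref) {
    b <- as_channel_matrix(ref)
    if (ncol(b) != ncol(a)) {
      stop_preaction("reference channel count differs from input", "shape_error")
    }
    tot <- numeric(n)
    for (ch in seq_len(ncol(a))) {
      tot <- tot + .dtw_prefix_1d(a[, ch], b[, ch])
    }
    tot
  }, numeric(n))
  per_ref <- matrix(per_ref, nrow = n) # n x n_refs
  agg <- if (aggregate == "mean") rowMeans(per_ref)
         else apply(per_ref, 1L, min)
  w <- seq.int(step, n, by = step)
  structure(
    list(window_lengths = w, distances = agg[w], aggregation = aggregate),
    class = "dtw_profile"
  )
}

#' @export
print.dtw_profile <- function(x, ...) {
  cat(sprintf("<dtw_profile> %d window lengths (%s over references)\n",
              length(x$window_lengths), x$aggregation))
  invisible(x)
}

#' Local-minimum / local-maximum gap of a DTW distance profile
#'
#' The profile starts high (a tiny window cannot match the references),
#' falls as the window grows, and — when a pre-action is present — rises
#' again once the window reaches it. The decision statistic is the gap
#' between the first local minimum and the maximum the profile attains
#' afterwards. The minimum requires `d[i] < d[i-1]` and `d[i] <= d[i+1]`
#' (ties accepted on the right), which skips the initial decreasing
#' transient; the maximum is the largest value at any later point,
#' including the profile's end — a profile still rising when the
#' analysis window runs out (trailing footwork, or a pre-action cut off
#' by the segment boundary) is a sustained mismatch and must count. On a
#' clean unimodal profile this reduces to the local-minimum /
#' local-maximum reading; on noisy profiles it is robust to micro-dips
#' inside the rise. When no minimum exists, or nothing after it exceeds
#' it (e.g. a flat plateau), the gap is 0 with extrema unset.
#'
#' On noisy sensor data the profile carries sample-level wiggles that
#' can present a spurious first extremum; `smooth_window > 1` applies a
#' centered, edge-truncated moving average to the distances before the
#' extremum search. The default (1) leaves the profile untouched.
#'
#' @param profile A `dtw_profile` from [glid_profile()] with at least 3
#'   points.
#' @param smooth_window Moving-average window (profile points) applied
#'   before the search; 1 = none. Default 1.
#' @return List with `gap` (>= 0), `min_at`, `max_at` (window lengths,
#'   `NA` when absent) and the corresponding `min_value`, `max_value`.
#' @export
find_gap <- function(profile, smooth_window = 1L) {
  stopifnot(inherits(profile, "dtw_profile"))
  d <- profile$distances
  if (smooth_window > 1L) d <- moving_average(d, as.integer(smooth_window))
  n <- length(d)
  if (n < 3L) stop_preaction("profile needs at least 3 points", "bounds_error")
  none <- list(gap = 0, min_at = NA_integer_, max_at = NA_integer_,
               min_value = NA_real_, max_value = NA_real_)
  min_i <- NA_integer_
  for (i in 2:(n - 1L)) {
    if (d[i] < d[i - 1L] && d[i] <= d[i + 1L]) { min_i <- i; break }
  }
  if (is.na(min_i) || min_i >= n) return(none)
  after <- (min_i + 1L):n
  max_j <- after[which.max(d[after])]
  if (d[max_j] <= d[min_i]) return(none)
  list(gap = d[max_j] - d[min_i],
       min_at = profile$window_lengths[min_i],
       max_at = profile$window_lengths[max_j],
       min_value = d[min_i], max_value = d[max_j])
}

#' Decide pre-action presence from a DTW distance profile
#'
#' Present if and only if the [find_gap()] statistic strictly exceeds the
#' threshold `tau` ("exceeds" is read strictly: a gap exactly equal to
#' `tau` is absent).
#'
#' @param profile A `dtw_profile` from [glid_profile()].
#' @param tau Decision threshold in DTW distance units, `tau >= 0`.
#'   Usually from [calibrate_tau()].
#' @param mu Striking-timing index of the input, carried through for
#'   reporting. Default `NA`.
#' @param smooth_window Passed to [find_gap()]. Default 1.
#' @return Object of class `preaction_decision`: list with `present`,
#'   `gap`, `min_at`, `max_at`, `tau`, `mu`.
#' @export
decide_preaction <- function(profile, tau, mu = NA_integer_,
                             smooth_window = 1L) {
  if (!(is.numeric(tau) && length(tau) == 1L && tau >= 0)) {
    stop_preaction("tau must be a non-negative number", "bounds_error")
  }
  g <- find_gap(profile, smooth_window = smooth_window)
  structure(
    list(present = g$gap > tau, gap = g$gap, min_at = g$min_at,
         max_at = g$max_at, tau = tau, mu = mu),
    class = "preaction_decision"
  )
}

#' @export
print.preaction_decision <- function(x, ...) {
  cat(sprintf("<preaction_decision> %s (gap %.3f %s tau %.3f)\n",
              if (x$present) "PRE-ACTION PRESENT" else "no pre-action",
              x$gap, if (x$present) ">" else "<=", x$tau))
  invisible(x)
}

#' Calibrate the decision threshold from the reference set
#'
#' Leave-one-out: each reference punch is profiled against the remaining
#' references and its gap recorded; since every reference is
#' pre-action-free, these gaps sample the statistic's null distribution.
#' The threshold is `margin` times their maximum — deterministic given
#' the reference set, with no hand-picked constant.
#'
#' @param refs A [reference_punch_set()] with at least 3 punches.
#' @param margin Safety factor, at least 1. Default 1.2.
#' @param step,aggregate Passed to [glid_profile()].
#' @param smooth_window Passed to [find_gap()]; must match the value the
#'   detector will use, so the calibrated null gaps measure the same
#'   statistic. Default 5.
#' @return The threshold `tau` (non-negative number).
#' @export
calibrate_tau <- function(refs, margin = 1.2, step = 1L,
                          aggregate = c("mean", "min"),
                          smooth_window = 5L) {
  aggregate <- match.arg(aggregate)
  if (!inherits(refs, "reference_punch_set") || length(refs) < 3L) {
    stop_preaction("calibration needs at least 3 reference punches",
                   "calibration_error")
  }
  if (!(is.numeric(margin) && margin >= 1)) {
    stop_preaction("margin must be >= 1", "calibration_error")
  }
  gaps <- vapply(seq_along(refs$punches), function(i) {
    rest <- reference_punch_set(refs$punches[-i], refs$source_meta)
    prof <- glid_profile(refs$punches[[i]], rest, step = step,
                         aggregate = aggregate)
    if (length(prof$distances) < 3L) 0
    else find_gap(prof, smooth_window = smooth_window)$gap
  }, numeric(1))
  margin * max(gaps)
}

#' Write a reference set to a directory
#'
#' One CSV per punch plus a `manifest.json` with provenance and file
#' order.
#'
#' @param refs A [reference_punch_set()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_reference_set <- function(refs, dir) {
  stopifnot(inherits(refs, "reference_punch_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("punch_%03d.csv", seq_along(refs$punches))
  for (i in seq_along(refs$punches)) {
    write_trace(refs$punches[[i]], file.path(dir, files[i]))
  }
  manifest <- list(
    format = "preaction reference set",
    source_meta = refs$source_meta,
    cut = "pre-cut at striking timing and time-reversed",
    n = length(refs$punches),
    files = files
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a reference set written by [write_reference_set()]
#'
#' @param dir Directory containing `manifest.json` and the punch CSVs.
#' @return A [reference_punch_set()].
#' @export
read_reference_set <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) {
    stop_preaction(sprintf("no manifest.json in %s", dir), "io_error")
  }
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  punches <- lapply(file.path(dir, mf$files), read_trace)
  reference_punch_set(punches, source_meta = mf$source_meta %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# centered moving average with edge truncation
moving_average <- function(v, w) {
  n <- length(v)
  h1 <- (w - 1L) %/% 2L
  h2 <- w %/% 2L
  pos <- seq_len(n)
  lo <- pmax(1L, pos - h1)
  hi <- pmin(n, pos + h2)
  cs <- cumsum(c(0, v))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
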