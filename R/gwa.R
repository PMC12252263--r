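#' Constancy decision for one sliding window
#'
#' Classifies a window as footwork (quasi-periodic "constancy" motion) or
#' non-footwork. The window's autocorrelation profile is computed, its
#' first interior peak located at lag \eqn{k}, and the decision threshold
#' set to \eqn{\alpha (1 - k/N)} where \eqn{N} is the window length: the
#' peak height of an ideal periodic waveform decays as \eqn{1 - k/N}, so
#' \eqn{\alpha} expresses the fraction of that ideal height required.
#' The window is footwork when the peak value is at least the threshold.
#'
#' A zero-variance window is classified non-footwork with a `degenerate`
#' flag rather than an error: a motionless limb is not footwork.
#'
#' @param window Numeric vector, the window samples (length \eqn{N}).
#' @param alpha Threshold coefficient in (0, 1]. Default 0.5.
#' @return List with `is_footwork` (logical), `acf` (the
#'   [acf_profile()] or `NULL`), `threshold` (\eqn{\alpha(1 - k/N)}, `NA`
#'   when no peak exists) and `degenerate` (logical).
#' @export
classify_window <- function(window, alpha = 0.5) {
  if (!(is.numeric(alpha) && length(alpha) == 1L && alpha > 0 && alpha <= 1)) {
    stop_preaction("alpha must be in (0, 1]", "bounds_error")
  }
  N <- length(window)
  prof <- tryCatch(
    acf_profile(window, max_lag = N - 1L),
    degenerate_signal_error = function(e) NULL
  )
  if (is.null(prof)) {
    return(list(is_footwork = FALSE, acf = NULL, threshold = NA_real_,
                degenerate = TRUE))
  }
  if (is.null(prof$first_peak_lag)) {
    return(list(is_footwork = FALSE, acf = prof, threshold = NA_real_,
                degenerate = FALSE))
  }
  threshold <- alpha * (1 - prof$first_peak_lag / N)
  list(is_footwork = prof$first_peak_value >= threshold, acf = prof,
       threshold = threshold, degenerate = FALSE)
}

#' Label sliding windows of an acceleration axis as footwork / non-footwork
#'
#' Slides a window of `window_size` samples by `stride` samples over one
#' acceleration channel and applies [classify_window()] at each position.
#' Only acceleration axes are allowed: footwork periodicity is not
#' reliably present in the angular velocity channels.
#'
#' @param trace An [inertial_trace()].
#' @param axis One of [acc_channels].
#' @param alpha Threshold coefficient, see [classify_window()]. Default 0.5.
#' @param window_size Window length in samples. Default 50 (1000 ms at 50 Hz).
#' @param stride Slide in samples. Default 5 (100 ms at 50 Hz).
#' @return Object of class `window_labels`: list with `axis`,
#'   `window_starts` (1-based start index of each window), `labels`
#'   (logical, `TRUE` = footwork), `window_size`, `stride`, `alpha`.
#' @export
label_windows <- function(trace, axis, alpha = 0.5, window_size = 50L,
                          stride = 5L) {
  stopifnot(inherits(trace, "inertial_trace"))
  if (!axis %in% acc_channels) {
    stop_preaction(
      sprintf("footwork labelling runs on acceleration axes only, not %s", axis),
      "axis_error"
    )
  }
  n <- n_samples(trace)
  window_size <- as.integer(window_size)
  stride <- as.integer(stride)
  if (n < window_size) {
    stop_preaction(
      sprintf("trace (%d samples) shorter than one window (%d)", n, window_size),
      "insufficient_data_error"
    )
  }
  x <- trace_channel(trace, axis)
  starts <- seq.int(1L, n - window_size + 1L, by = stride)
  labels <- vapply(starts, function(s) {
    classify_window(x[s:(s + window_size - 1L)], alpha = alpha)$is_footwork
  }, logical(1))
  structure(
    list(axis = axis, window_starts = starts, labels = labels,
         window_size = window_size, stride = stride, alpha = alpha),
    class = "window_labels"
  )
}

#' Refine a segment boundary inside one window by gradually shrinking it
#'
#' The first window of a non-footwork run typically contains the tail of
#' the footwork followed by the start of the technique (and possibly a
#' pre-action). Shrinking the window from its end and tracking the first
#' autocorrelation peak of each prefix isolates the purely periodic part:
#' the peak value is maximal when exactly the footwork remains, and the
#' prefix length attaining the maximum marks the boundary.
#' `shrink_from_start` is the symmetric operation on suffixes, used for
#' the end of a non-footwork segment where footwork resumes.
#'
#' Prefixes shorter than `min_len` are not evaluated (an autocorrelation
#' peak on a handful of samples is meaningless); prefixes without an
#' interior peak contribute \eqn{-\infty}. Ties are broken toward the
#' shortest periodic portion kept (smallest prefix / latest suffix), the
#' conservative choice for the downstream detector; `tol` widens the tie
#' to near-maximal values, because samples that are merely quiet leave
#' the peak value on a noise-flat plateau that would otherwise let the
#' argmax drift arbitrarily across them.
#'
#' @param window_data Numeric vector, the window samples.
#' @param direction `"shrink_from_end"` (boundary = end of periodic
#'   prefix) or `"shrink_from_start"` (boundary = start of periodic
#'   suffix).
#' @param min_len Minimum evaluated prefix/suffix length, at least 3.
#'   Default 10.
#' @param tol Peak values within `tol` of the maximum count as tied.
#'   Default 0.02 (the autocorrelation is dimensionless in \[-1, 1\]).
#' @return The boundary as a 1-based index relative to the window start:
#'   for `shrink_from_end` the length \eqn{l^*} of the best periodic
#'   prefix; for `shrink_from_start` the start index \eqn{s^*} of the
#'   best periodic suffix.
#' @export
refine_boundary <- function(window_data,
                            direction = c("shrink_from_end",
                                          "shrink_from_start"),
                            min_len = 10L, tol = 0.02) {
  direction <- match.arg(direction)
  min_len <- as.integer(min_len)
  if (min_len < 3L) stop_preaction("min_len must be >= 3", "bounds_error")
  L <- length(window_data)
  if (L < min_len) {
    stop_preaction("window shorter than min_len", "insufficient_data_error")
  }
  peak_of <- function(x) {
    prof <- tryCatch(
      acf_profile(x, max_lag = length(x) - 1L),
      degenerate_signal_error = function(e) NULL
    )
    if (is.null(prof) || is.null(prof$first_peak_value)) -Inf
    else prof$first_peak_value
  }
  if (direction == "shrink_from_end") {
    lens <- min_len:L
    vals <- vapply(lens, function(l) peak_of(window_data[1:l]), numeric(1))
    if (all(vals == -Inf)) {
      stop_preaction("no prefix produced an autocorrelation peak",
                     "refinement_failed")
    }
    lens[which(vals >= max(vals) - tol)[1L]] # smallest near-maximal l
  } else {
    starts <- rev(seq_len(L - min_len + 1L)) # descending: largest s first
    vals <- vapply(starts, function(s) peak_of(window_data[s:L]), numeric(1))
    if (all(vals == -Inf)) {
      stop_preaction("no suffix produced an autocorrelation peak",
                     "refinement_failed")
    }
    starts[which(vals >= max(vals) - tol)[1L]] # largest near-maximal s
  }
}

#' Detect non-footwork segments on one axis from window labels
#'
#' Scans the window labels left to right. When `nf_run` consecutive
#' non-footwork windows occur, the first window of that run is refined
#' with [refine_boundary()] (`shrink_from_end`) and the refined boundary
#' becomes the segment start. After a start, when `fw_run` consecutive
#' footwork windows occur, the first window of that run is refined
#' (`shrink_from_start`) and the sample before the refined boundary
#' becomes the segment end. An unterminated segment ends at the trace
#' end. If refinement fails, the raw window start is used as fallback.
#' A non-footwork run starting at the very first window has no
#' footwork/non-footwork transition inside it, so no refinement applies:
#' that segment starts at the trace start.
#'
#' @param labels A `window_labels` object from [label_windows()].
#' @param trace The [inertial_trace()] the labels were computed on.
#' @param nf_run Consecutive non-footwork windows required to open a
#'   segment. Default 7.
#' @param fw_run Consecutive footwork windows required to close it.
#'   Default 2.
#' @param min_prefix `min_len` passed to [refine_boundary()]. Default 10.
#' @return Data frame with one row per non-footwork segment: `start_idx`,
#'   `end_idx` (1-based, inclusive), `start_window`, `end_window` (start
#'   sample of the source windows; `NA` when the segment ran to the trace
#'   end), `start_refined`, `end_refined` (logical: did refinement
#'   succeed).
#' @export
detect_axis_segments <- function(labels, trace, nf_run = 7L, fw_run = 2L,
                                 min_prefix = 10L) {
  stopifnot(inherits(labels, "window_labels"), inherits(trace, "inertial_trace"))
  nf_run <- as.integer(nf_run)
  fw_run <- as.integer(fw_run)
  if (nf_run < 1L || fw_run < 1L) {
    stop_preaction("nf_run and fw_run must be >= 1", "bounds_error")
  }
  x <- trace_channel(trace, labels$axis)
  n <- length(x)
  ws <- labels$window_size
  st <- labels$window_starts
  lab <- labels$labels
  n_w <- length(lab)

  refine_or_fallback <- function(w0, direction) {
    rel <- tryCatch(
      refine_boundary(x[w0:(w0 + ws - 1L)], direction, min_len = min_prefix),
      refinement_failed = function(e) NULL,
      insufficient_data_error = function(e) NULL
    )
    if (is.null(rel)) list(idx = 1L, refined = FALSE)
    else list(idx = rel, refined = TRUE)
  }

  out <- list()
  in_seg <- FALSE
  cur_start <- cur_start_win <- cur_start_ref <- NULL
  prev_end <- 0L
  i <- 1L
  while (i <= n_w) {
    run_end <- i
    while (run_end < n_w && lab[run_end + 1L] == lab[i]) run_end <- run_end + 1L
    run_len <- run_end - i + 1L
    if (!in_seg && !lab[i] && run_len >= nf_run) {
      w0 <- st[i]
      if (i == 1L) {
        # no footwork precedes this run: there is no boundary to refine,
        # the segment starts at the trace start
        r <- list(idx = 1L, refined = FALSE)
      } else {
        r <- refine_or_fallback(w0, "shrink_from_end")
      }
      cur_start <- max(w0 + r$idx - 1L, prev_end + 1L) # keep segments disjoint
      cur_start_win <- w0
      cur_start_ref <- r$refined
      in_seg <- TRUE
    } else if (in_seg && lab[i] && run_len >= fw_run) {
      w0 <- st[i]
      r <- refine_or_fallback(w0, "shrink_from_start")
      end_idx <- max(cur_start, w0 + r$idx - 2L) # sample before resumed footwork
      out[[length(out) + 1L]] <- data.frame(
        start_idx = cur_start, end_idx = end_idx,
        start_window = cur_start_win, end_window = w0,
        start_refined = cur_start_ref, end_refined = r$refined
      )
      prev_end <- end_idx
      in_seg <- FALSE
    }
    i <- run_end + 1L
  }
  if (in_seg) {
    out[[length(out) + 1L]] <- data.frame(
      start_idx = cur_start, end_idx = n,
      start_window = cur_start_win, end_window = NA_integer_,
      start_refined = cur_start_ref, end_refined = NA
    )
  }
  if (!length(out)) {
    return(data.frame(start_idx = integer(), end_idx = integer(),
                      start_window = integer(), end_window = integer(),
                      start_refined = logical(), end_refined = logical()))
  }
  do.call(rbind, out)
}

#' Convert non-footwork segments to a per-sample footwork mask
#'
#' @param segments Data frame from [detect_axis_segments()].
#' @param n Trace length in samples.
#' @return Logical vector of length `n`, `TRUE` where the sample belongs
#'   to footwork (i.e. outside every non-footwork segment).
#' @export
segments_to_footwork_mask <- function(segments, n) {
  mask <- rep(TRUE, n)
  if (nrow(segments)) {
    for (r in seq_len(nrow(segments))) {
      mask[segments$start_idx[r]:segments$end_idx[r]] <- FALSE
    }
  }
  mask
}

#' Fuse per-axis footwork masks into one decision per sample
#'
#' Footwork rarely moves along a single horizontal axis, while its
#' vertical (hopping) component is the most reliable cue. The strict rule
#' therefore requires agreement of both horizontal axes OR any vertical
#' detection: `fused = (X AND Z) OR Y`. The relaxed rule, used when the
#' strict one fails downstream, accepts footwork seen on any axis:
#' `fused = X OR Y OR Z`. The strict mask is pointwise implied by the
#' relaxed one.
#'
#' @param mask_x,mask_y,mask_z Equal-length logical vectors, `TRUE` =
#'   footwork at that sample, for the forward, vertical and lateral
#'   acceleration axes.
#' @param mode `"strict"` or `"relaxed"`.
#' @return Object of class `footwork_mask`: list with `per_axis` (named
#'   list of the three input masks), `fused` (logical) and `mode`.
#' @export
fuse_axes <- function(mask_x, mask_y, mask_z, mode = c("strict", "relaxed")) {
  mode <- match.arg(mode)
  if (length(mask_x) != length(mask_y) || length(mask_y) != length(mask_z)) {
    stop_preaction("axis masks must have equal length", "shape_error")
  }
  fused <- if (mode == "strict") (mask_x & mask_z) | mask_y
           else mask_x | mask_y | mask_z
  structure(
    list(per_axis = list(acc_x = mask_x, acc_y = mask_y, acc_z = mask_z),
         fused = fused, mode = mode),
    class = "footwork_mask"
  )
}

#' Smooth footwork segments with a segment-local moving average
#'
#' Replaces every footwork sample, on all six channels, by the centered
#' moving average over `ma_window` samples computed *within* its footwork
#' segment: the averaging window is truncated at segment edges so that no
#' non-footwork sample ever leaks into an average. Non-footwork samples
#' are returned bit-exact unchanged. This flattens the periodic footwork
#' oscillation so the downstream DTW comparison cannot mistake it for a
#' pre-action.
#'
#' @param trace An [inertial_trace()].
#' @param mask A `footwork_mask` from [fuse_axes()] or a logical vector of
#'   length `n_samples(trace)` (`TRUE` = footwork).
#' @param ma_window Moving-average window in samples, at least 1.
#'   Default 50 (1000 ms at 50 Hz).
#' @return The smoothed [inertial_trace()], same length and metadata.
#' @export
smooth_footwork <- function(trace, mask, ma_window = 50L) {
  stopifnot(inherits(trace, "inertial_trace"))
  if (inherits(mask, "footwork_mask")) mask <- mask$fused
  n <- n_samples(trace)
  if (length(mask) != n) {
    stop_preaction("mask length must equal trace length", "shape_error")
  }
  ma_window <- as.integer(ma_window)
  if (ma_window < 1L) stop_preaction("ma_window must be >= 1", "bounds_error")
  data <- trace$data
  runs <- rle(mask)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  h1 <- (ma_window - 1L) %/% 2L
  h2 <- ma_window %/% 2L
  for (r in which(runs$values)) {
    idx <- starts[r]:ends[r]
    m <- length(idx)
    pos <- seq_len(m)
    lo <- pmax(1L, pos - h1)
    hi <- pmin(m, pos + h2)
    for (ch in seq_len(6L)) {
      v <- data[idx, ch]
      cs <- cumsum(c(0, v))
      data[idx, ch] <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
    }
  }
  inertial_trace(data, sample_rate_hz = trace$sample_rate_hz,
                 start_time_s = trace$start_time_s)
}

#' Export a footwork mask as a per-sample CSV
#'
#' Columns: `sample`, `fw_x`, `fw_y`, `fw_z`, `fw_fused` (0/1), for
#' inspection and plotting.
#'
#' @param mask A `footwork_mask` from [fuse_axes()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mask_csv <- function(mask, path) {
  stopifnot(inherits(mask, "footwork_mask"))
  df <- data.frame(
    sample = seq_along(mask$fused),
    fw_x = as.integer(mask$per_axis$acc_x),
    fw_y = as.integer(mask$per_axis$acc_y),
    fw_z = as.integer(mask$per_axis$acc_z),
    fw_fused = as.integer(mask$fused)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
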