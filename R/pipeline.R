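#' Configuration for the footwork-segmentation + detection pipeline
#'
#' All tunables in one place, with the operational defaults for 50 Hz
#' wrist data: 50-sample (1000 ms) analysis windows slid by 5 samples
#' (100 ms), threshold coefficient `alpha = 0.5`, a non-footwork segment
#' opened after 7 consecutive non-footwork windows and closed after 2
#' consecutive footwork windows, 50-sample moving-average smoothing, and
#' a 1.5 g striking-peak magnitude.
#'
#' @param window_size,stride,alpha,nf_run,fw_run,min_prefix,ma_window
#'   Footwork segmentation parameters, see [label_windows()],
#'   [detect_axis_segments()], [refine_boundary()], [smooth_footwork()].
#' @param fusion `"auto"` (strict with relaxed fallback), `"strict"` or
#'   `"relaxed"`, see [fuse_axes()].
#' @param step,aggregate Detection profile parameters, see
#'   [glid_profile()].
#' @param margin Threshold calibration safety factor, see
#'   [calibrate_tau()].
#' @param gap_smooth Profile smoothing window for the extremum search,
#'   see [find_gap()]. Default 5.
#' @param peak_magnitude Striking-peak magnitude in g, see
#'   [detect_striking_timing()].
#' @return A named list of class `gwa_glid_config`.
#' @export
gwa_glid_config <- function(window_size = 50L, stride = 5L, alpha = 0.5,
                            nf_run = 7L, fw_run = 2L, min_prefix = 10L,
                            ma_window = 50L,
                            fusion = c("auto", "strict", "relaxed"),
                            step = 1L, aggregate = c("mean", "min"),
                            margin = 1.2, gap_smooth = 5L,
                            peak_magnitude = 1.5) {
  structure(
    list(window_size = as.integer(window_size), stride = as.integer(stride),
         alpha = alpha, nf_run = as.integer(nf_run),
         fw_run = as.integer(fw_run), min_prefix = as.integer(min_prefix),
         ma_window = as.integer(ma_window), fusion = match.arg(fusion),
         step = as.integer(step), aggregate = match.arg(aggregate),
         margin = margin, gap_smooth = as.integer(gap_smooth),
         peak_magnitude = peak_magnitude),
    class = "gwa_glid_config"
  )
}

#' Extract punch candidates from a full match recording
#'
#' Every local minimum of the forward acceleration at or below
#' `-min_magnitude`, scanned left to right and kept only when at least
#' `half_window` samples after the previously accepted peak, yields a
#' candidate window of `center +/- half_window` samples clipped to the
#' trace bounds.
#'
#' @param match Full-match [inertial_trace()].
#' @param min_magnitude Peak magnitude threshold in g. Default 1.5.
#' @param half_window Samples kept on each side of the peak, at least 1.
#'   Default 300 (6 s at 50 Hz).
#' @return List of candidates, each a list with `center_idx` (peak index
#'   in match coordinates), `offset` (first sample of the extracted
#'   segment) and `segment` (the extracted [inertial_trace()]).
#' @export
extract_punch_candidates <- function(match, min_magnitude = 1.5,
                                     half_window = 300L) {
  stopifnot(inherits(match, "inertial_trace"))
  half_window <- as.integer(half_window)
  if (half_window < 1L) stop_preaction("half_window must be >= 1", "bounds_error")
  x <- trace_channel(match, "acc_x")
  n <- length(x)
  if (n < 3L) return(list())
  i <- 2:(n - 1L)
  is_min <- x[i] <= x[i - 1L] & x[i] <= x[i + 1L] & x[i] <= -min_magnitude
  peaks <- i[is_min]
  out <- list()
  last <- -Inf
  for (c_idx in peaks) {
    if (c_idx - last < half_window) next
    lo <- max(1L, c_idx - half_window)
    hi <- min(n, c_idx + half_window)
    out[[length(out) + 1L]] <- list(
      center_idx = c_idx, offset = lo,
      segment = slice_trace(match, lo, hi)
    )
    last <- c_idx
  }
  out
}

# non-footwork runs of a fused mask; returns data.frame(start, end)
nonfootwork_runs <- function(fused) {
  runs <- rle(!fused)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values
  data.frame(start = starts[keep], end = ends[keep])
}

# fused-mask failure rule: no non-footwork run, or none containing the strike
fusion_segment_for_strike <- function(fused, strike) {
  nf <- nonfootwork_runs(fused)
  hit <- which(nf$start <= strike & strike <= nf$end)
  if (!length(hit)) NULL else nf[hit[1L], ]
}

#' Run the full footwork-aware pre-action detection on one punch
#'
#' The pipeline: (1) label sliding windows on the three acceleration
#' axes; (2) detect and boundary-refine non-footwork segments per axis;
#' (3) fuse the per-axis footwork masks (strict rule, falling back to the
#' relaxed rule when the strict fused mask yields no non-footwork segment
#' containing the striking timing); (4) smooth footwork on all six
#' channels; (5) detect the striking timing; (6) cut from the
#' non-footwork segment start to the strike and reverse; (7) compute the
#' incremental-window DTW profile against the reference set; (8) decide.
#' A punch whose footwork never ends (or that fails both fusion modes) is
#' flagged unresolvable instead of forced through.
#'
#' @param candidate A candidate from [extract_punch_candidates()] or an
#'   [inertial_trace()] already centered on one punch.
#' @param refs A [reference_punch_set()].
#' @param config A [gwa_glid_config()].
#' @param tau Decision threshold; if `NULL` it is calibrated from `refs`
#'   with [calibrate_tau()] (pass a precomputed value when scoring many
#'   punches).
#' @param id Identifier carried into the report entry.
#' @return A report entry: list with `id`, `resolved`, and when resolved
#'   `fusion_mode`, `segment_start`, `mu` (striking timing), `gap`,
#'   `min_at`, `max_at`, `tau`, `present`; when unresolvable, `reason`.
#' @export
run_gwa_glid <- function(candidate, refs, config = gwa_glid_config(),
                         tau = NULL, id = NA) {
  trace <- if (inherits(candidate, "inertial_trace")) candidate
           else candidate$segment
  stopifnot(inherits(trace, "inertial_trace"))
  unresolved <- function(reason) {
    list(id = id, resolved = FALSE, reason = reason)
  }

  strike <- tryCatch(detect_striking_timing(trace, config$peak_magnitude),
                     no_strike_found = function(e) NULL)
  if (is.null(strike)) return(unresolved("no striking timing found"))

  masks <- tryCatch(
    lapply(acc_channels, function(axis) {
      labs <- label_windows(trace, axis, alpha = config$alpha,
                            window_size = config$window_size,
                            stride = config$stride)
      segs <- detect_axis_segments(labs, trace, nf_run = config$nf_run,
                                   fw_run = config$fw_run,
                                   min_prefix = config$min_prefix)
      segments_to_footwork_mask(segs, n_samples(trace))
    }),
    insufficient_data_error = function(e) NULL
  )
  if (is.null(masks)) return(unresolved("trace shorter than one window"))
  names(masks) <- acc_channels

  modes <- switch(config$fusion,
                  auto = c("strict", "relaxed"),
                  strict = "strict", relaxed = "relaxed")
  fused <- NULL
  seg <- NULL
  for (mode in modes) {
    f <- fuse_axes(masks$acc_x, masks$acc_y, masks$acc_z, mode = mode)
    s <- fusion_segment_for_strike(f$fused, strike)
    if (!is.null(s)) { fused <- f; seg <- s; break }
  }
  if (is.null(fused)) {
    return(unresolved("no non-footwork segment contains the striking timing"))
  }

  smoothed <- smooth_footwork(trace, fused, ma_window = config$ma_window)
  cut <- cut_and_reverse(slice_trace(smoothed, seg$start, strike),
                         strike - seg$start + 1L)
  if (is.null(tau)) {
    tau <- calibrate_tau(refs, margin = config$margin, step = config$step,
                         aggregate = config$aggregate,
                         smooth_window = config$gap_smooth)
  }
  prof <- glid_profile(cut, refs, step = config$step,
                       aggregate = config$aggregate)
  if (length(prof$distances) < 3L) {
    return(unresolved("cut segment too short for a distance profile"))
  }
  dec <- decide_preaction(prof, tau, mu = strike,
                          smooth_window = config$gap_smooth)
  list(id = id, resolved = TRUE, fusion_mode = fused$mode,
       segment_start = seg$start, mu = strike, gap = dec$gap,
       min_at = dec$min_at, max_at = dec$max_at, tau = tau,
       present = dec$present)
}

#' Run the detector without footwork preprocessing
#'
#' The conventional single-stage detector: cut from the trace start to
#' the striking timing, reverse, profile, decide — no footwork
#' segmentation or smoothing. Used as the baseline that footwork
#' contaminates.
#'
#' @inheritParams run_gwa_glid
#' @return A report entry in the same shape as [run_gwa_glid()]
#'   (`fusion_mode` is `"none"`).
#' @export
run_glid_only <- function(candidate, refs, config = gwa_glid_config(),
                          tau = NULL, id = NA) {
  trace <- if (inherits(candidate, "inertial_trace")) candidate
           else candidate$segment
  stopifnot(inherits(trace, "inertial_trace"))
  strike <- tryCatch(detect_striking_timing(trace, config$peak_magnitude),
                     no_strike_found = function(e) NULL)
  if (is.null(strike)) {
    return(list(id = id, resolved = FALSE, reason = "no striking timing found"))
  }
  cut <- cut_and_reverse(trace, strike)
  if (is.null(tau)) {
    tau <- calibrate_tau(refs, margin = config$margin, step = config$step,
                         aggregate = config$aggregate,
                         smooth_window = config$gap_smooth)
  }
  prof <- glid_profile(cut, refs, step = config$step,
                       aggregate = config$aggregate)
  if (length(prof$distances) < 3L) {
    return(list(id = id, resolved = FALSE,
                reason = "cut segment too short for a distance profile"))
  }
  dec <- decide_preaction(prof, tau, mu = strike,
                          smooth_window = config$gap_smooth)
  list(id = id, resolved = TRUE, fusion_mode = "none", segment_start = 1L,
       mu = strike, gap = dec$gap, min_at = dec$min_at, max_at = dec$max_at,
       tau = tau, present = dec$present)
}

#' Score detection reports against ground-truth labels
#'
#' Unresolvable punches are excluded from the confusion counts (but
#' reported), mirroring how segmentation failures are handled in match
#' analysis. Undefined ratios (e.g. precision with no predicted
#' positives) are reported as `NA`, never 0.
#'
#' @param reports List of report entries from [run_gwa_glid()] /
#'   [run_glid_only()].
#' @param truth Logical vector, `TRUE` = punch truly had a pre-action.
#'   Must align with `reports` (same length; when both carry ids they
#'   must match).
#' @return List with the confusion counts (`tp`, `tn`, `fp`, `fn`),
#'   `n_total`, `n_resolved`, `n_unresolvable`, and `accuracy`,
#'   `precision`, `recall`, `f_measure` (accuracy = (TP+TN)/resolved,
#'   F = 2PR/(P+R)).
#' @export
evaluate_detections <- function(reports, truth) {
  if (length(reports) != length(truth)) {
    stop_preaction("reports and truth labels do not align", "alignment_error")
  }
  ids <- vapply(reports, function(r) as.character(r$id %||% NA), character(1))
  if (!is.null(names(truth)) && !all(is.na(ids))) {
    if (!identical(names(truth), ids)) {
      stop_preaction("report ids and truth ids do not match", "alignment_error")
    }
  }
  truth <- as.logical(truth)
  resolved <- vapply(reports, function(r) isTRUE(r$resolved), logical(1))
  pred <- vapply(reports, function(r) isTRUE(r$present), logical(1))
  tp <- sum(resolved & pred & truth)
  tn <- sum(resolved & !pred & !truth)
  fp <- sum(resolved & pred & !truth)
  fn <- sum(resolved & !pred & truth)
  confusion_metrics(tp, tn, fp, fn,
                    n_total = length(reports),
                    n_unresolvable = sum(!resolved))
}

#' Metrics from explicit confusion counts
#'
#' `accuracy = (TP+TN)/(TP+TN+FP+FN)`, `precision = TP/(TP+FP)`,
#' `recall = TP/(TP+FN)`, `F = 2PR/(P+R)`; undefined ratios are `NA`.
#'
#' @param tp,tn,fp,fn Non-negative confusion counts.
#' @param n_total,n_unresolvable Optional totals carried into the result.
#' @return List as in [evaluate_detections()].
#' @export
confusion_metrics <- function(tp, tn, fp, fn, n_total = tp + tn + fp + fn,
                              n_unresolvable = 0L) {
  n_res <- tp + tn + fp + fn
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f_measure <- if (!is.na(precision) && !is.na(recall) &&
                   precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  list(tp = tp, tn = tn, fp = fp, fn = fn,
       n_total = n_total, n_resolved = n_res,
       n_unresolvable = n_unresolvable,
       accuracy = if (n_res > 0) (tp + tn) / n_res else NA_real_,
       precision = precision, recall = recall, f_measure = f_measure)
}
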