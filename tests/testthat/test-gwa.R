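test_that("classify_window applies the alpha * (1 - k/N) threshold", {
  # period-10 sine, N = 50: peak ~0.8 at lag 10, threshold 0.5 * 0.8 = 0.4
  win <- sin(2 * pi * (0:49) / 10)
  res <- classify_window(win, alpha = 0.5)
  expect_true(res$is_footwork)
  expect_equal(res$threshold, 0.4)
  expect_equal(res$acf$first_peak_lag, 10)

  # alpha = 1 demands the ideal peak height; a noisy sine fails it
  set.seed(3)
  noisy <- win + rnorm(50, 0, 0.3)
  res1 <- classify_window(noisy, alpha = 1)
  expect_false(res1$is_footwork)

  expect_error(classify_window(win, alpha = 0), class = "bounds_error")
  expect_error(classify_window(win, alpha = 1.5), class = "bounds_error")
})

test_that("white noise windows are non-footwork, constant windows degenerate", {
  set.seed(4)
  n_fw <- sum(vapply(1:50, function(i) {
    classify_window(rnorm(50), alpha = 0.5)$is_footwork
  }, logical(1)))
  expect_lte(n_fw, 3) # noise essentially never passes

  res <- classify_window(rep(1, 50))
  expect_false(res$is_footwork)
  expect_true(res$degenerate)
})

test_that("label_windows slides correctly and only accepts acceleration axes", {
  tr <- make_trace(sin(2 * pi * (0:299) / 15)) # 3.33 Hz on every channel
  labs <- label_windows(tr, "acc_y", window_size = 50, stride = 5)
  expect_length(labs$labels, 51) # floor((300 - 50)/5) + 1
  expect_equal(labs$window_starts, seq(1, 251, by = 5))
  expect_true(all(labs$labels)) # a pure periodic signal is all footwork

  expect_error(label_windows(tr, "gyro_x"), class = "axis_error")
  short <- make_trace(rnorm(30))
  expect_error(label_windows(short, "acc_x"),
               class = "insufficient_data_error")
})

test_that("refine_boundary finds the end of the periodic prefix", {
  set.seed(5)
  # 30 samples of period-10 sine, then a 20-sample linear ramp
  win <- c(sin(2 * pi * (1:30) / 10), seq(0.1, 2, length.out = 20)) +
    rnorm(50, 0, 0.02)
  l_star <- refine_boundary(win, "shrink_from_end", min_len = 10)
  expect_gte(l_star, 25)
  expect_lte(l_star, 35)

  # no prefix of near-maximal peak value is shorter than the returned one
  peak_of <- function(x) {
    vals <- vapply(seq_len(length(x) - 1), function(k) acf_oracle(x, k),
                   numeric(1))
    best <- NA_real_
    for (k in seq_len(length(vals) - 1)) {
      left <- if (k == 1) 1 else vals[k - 1]
      if (vals[k] > left && vals[k] > vals[k + 1]) { best <- vals[k]; break }
    }
    best
  }
  all_vals <- vapply(10:50, function(l) {
    v <- peak_of(win[1:l]); if (is.na(v)) -Inf else v
  }, numeric(1))
  expect_lte(max(all_vals) - all_vals[l_star - 9], 0.021)

  # mirrored window: refinement from the start finds the suffix boundary
  s_star <- refine_boundary(rev(win), "shrink_from_start", min_len = 10)
  expect_gte(s_star, 50 - 35 + 1)
  expect_lte(s_star, 50 - 25 + 1)
})

test_that("a fully periodic window keeps (nearly) its whole length", {
  win <- sin(2 * pi * (1:50) / 10)
  l_star <- refine_boundary(win, "shrink_from_end", min_len = 10)
  expect_gte(l_star, 40) # >= L - min_len
})

test_that("refinement fails cleanly when no prefix has a peak", {
  expect_error(refine_boundary(as.numeric(1:50), "shrink_from_end"),
               class = "refinement_failed")
  expect_error(refine_boundary(rep(1, 50), "shrink_from_end"),
               class = "refinement_failed")
  expect_error(refine_boundary(rnorm(50), "shrink_from_end", min_len = 2),
               class = "bounds_error")
})

make_labels <- function(labels, stride = 5L, window_size = 50L,
                        axis = "acc_y") {
  structure(
    list(axis = axis,
         window_starts = seq.int(1L, by = stride,
                                 length.out = length(labels)),
         labels = labels, window_size = window_size, stride = stride,
         alpha = 0.5),
    class = "window_labels"
  )
}

test_that("segment detection follows the consecutive-run rules", {
  set.seed(6)
  # trace: 95 samples footwork sine, then quiet noise
  x <- c(sin(2 * pi * (1:95) / 10), rnorm(55, 0, 0.05))
  tr <- make_trace(x)

  # fewer than nf_run consecutive non-footwork windows: no segment
  labs <- make_labels(c(TRUE, TRUE, rep(FALSE, 6), rep(TRUE, 13)))
  expect_equal(nrow(detect_axis_segments(labs, tr, nf_run = 7)), 0)

  # all footwork: no segment
  labs <- make_labels(rep(TRUE, 21))
  expect_equal(nrow(detect_axis_segments(labs, tr)), 0)

  # 10 footwork then 10 non-footwork windows: one segment opening in the
  # 11th window's span, running to the trace end
  labs <- make_labels(c(rep(TRUE, 10), rep(FALSE, 10)))
  segs <- detect_axis_segments(labs, tr, nf_run = 7)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$start_window, 51)
  expect_gte(segs$start_idx, 51)
  expect_lt(segs$start_idx, 51 + 50)
  expect_equal(segs$end_idx, 150)
  # the refined start should be close to the true boundary at 95
  expect_lte(abs(segs$start_idx - 95), 10)
})

test_that("a footwork run after a segment closes it via suffix refinement", {
  set.seed(7)
  x <- c(sin(2 * pi * (1:60) / 10), rnorm(40, 0, 0.05),
         sin(2 * pi * (1:100) / 10))
  tr <- make_trace(x)
  labs <- make_labels(c(rep(TRUE, 3), rep(FALSE, 14), rep(TRUE, 14)))
  segs <- detect_axis_segments(labs, tr, nf_run = 7, fw_run = 2)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$end_window, 86)
  expect_gte(segs$end_idx, segs$start_idx)
  expect_lte(abs(segs$start_idx - 60), 12)
  expect_lte(abs(segs$end_idx - 100), 12)
  # the mask flags exactly the outside of the segment as footwork
  mask <- segments_to_footwork_mask(segs, n_samples(tr))
  expect_false(any(mask[segs$start_idx:segs$end_idx]))
  expect_true(all(mask[-(segs$start_idx:segs$end_idx)]))
})

test_that("axis fusion implements both rules over all boolean combinations", {
  combos <- expand.grid(x = c(FALSE, TRUE), y = c(FALSE, TRUE),
                        z = c(FALSE, TRUE))
  strict <- fuse_axes(combos$x, combos$y, combos$z, "strict")
  relaxed <- fuse_axes(combos$x, combos$y, combos$z, "relaxed")
  expect_equal(strict$fused, (combos$x & combos$z) | combos$y)
  expect_equal(relaxed$fused, combos$x | combos$y | combos$z)
  # strict implies relaxed pointwise
  expect_true(all(relaxed$fused[strict$fused]))
  expect_equal(strict$mode, "strict")
  expect_error(fuse_axes(c(TRUE, FALSE), TRUE, c(TRUE, FALSE)),
               class = "shape_error")
})

test_that("smoothing is segment-local, identity elsewhere", {
  set.seed(8)
  tr <- inertial_trace(matrix(rnorm(600), ncol = 6))

  # all-false mask: bit-exact identity
  out <- smooth_footwork(tr, rep(FALSE, 100))
  expect_identical(out$data, tr$data)

  # constant footwork segment: unchanged values
  const <- make_trace(rep(3, 100))
  out <- smooth_footwork(const, rep(TRUE, 100), ma_window = 50)
  expect_equal(out$data, const$data)

  # ramp fully footwork, window 5: interior samples map to themselves,
  # edges to truncated means (scalar oracle)
  ramp <- make_trace(as.numeric(0:49))
  out <- smooth_footwork(ramp, rep(TRUE, 50), ma_window = 5)
  v <- as.numeric(0:49)
  oracle <- vapply(1:50, function(i) {
    lo <- max(1, i - 2); hi <- min(50, i + 2)
    mean(v[lo:hi])
  }, numeric(1))
  expect_equal(trace_channel(out, "acc_x"), oracle)
  expect_equal(trace_channel(out, "acc_x")[3:48], as.numeric(2:47))

  # random masks: non-footwork samples are never touched
  for (i in 1:20) {
    mask <- runif(100) < 0.4
    out <- smooth_footwork(tr, mask, ma_window = 7)
    expect_identical(out$data[!mask, ], tr$data[!mask, ])
  }
})

test_that("mask export writes the per-sample CSV layout", {
  m <- fuse_axes(c(TRUE, FALSE), c(FALSE, FALSE), c(TRUE, TRUE), "strict")
  path <- withr::local_tempfile(fileext = ".csv")
  write_mask_csv(m, path)
  df <- read.csv(path)
  expect_equal(names(df), c("sample", "fw_x", "fw_y", "fw_z", "fw_fused"))
  expect_equal(df$fw_fused, c(1L, 0L))
})
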