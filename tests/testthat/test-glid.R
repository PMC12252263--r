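test_that("striking timing is the earliest, most negative forward peak", {
  x <- rep(0, 300)
  x[150] <- -3
  tr <- make_trace(rep(0, 300), override = list(acc_x = x))
  expect_equal(detect_striking_timing(tr, 1.5), 150)

  # most-negative rule: deeper peak wins even if later peaks exist
  x2 <- rep(0, 300); x2[100] <- -3; x2[200] <- -2
  tr2 <- make_trace(rep(0, 300), override = list(acc_x = x2))
  expect_equal(detect_striking_timing(tr2, 1.5), 100)

  # exact ties: earliest
  x3 <- rep(0, 300); x3[c(120, 180)] <- -3
  tr3 <- make_trace(rep(0, 300), override = list(acc_x = x3))
  expect_equal(detect_striking_timing(tr3, 1.5), 120)

  flat <- make_trace(rep(0, 50))
  expect_error(detect_striking_timing(flat, 1.5), class = "no_strike_found")
  expect_error(detect_striking_timing(tr, -1), class = "bounds_error")
})

test_that("cut_and_reverse reverses the pre-strike samples and is an involution", {
  tr <- make_trace(as.numeric(0:9))
  cut <- cut_and_reverse(tr, 10)
  expect_equal(trace_channel(cut, "acc_x"), as.numeric(9:0))
  expect_identical(cut_and_reverse(cut, 10)$data, tr$data)

  half <- cut_and_reverse(tr, 4)
  expect_equal(trace_channel(half, "acc_y"), as.numeric(3:0))

  expect_error(cut_and_reverse(tr, 0), class = "bounds_error")
  expect_error(cut_and_reverse(tr, 11), class = "bounds_error")
})

test_that("DTW distance matches exhaustive path enumeration", {
  set.seed(20)
  for (i in 1:40) {
    a <- rnorm(sample(1:8, 1))
    b <- rnorm(sample(1:8, 1))
    expect_equal(dtw_distance(a, b), dtw_enum(a, b), tolerance = 1e-12)
    expect_equal(dtw_distance(a, b), dtw_distance(b, a), tolerance = 1e-12)
  }
})

test_that("DTW basic identities and bounds", {
  set.seed(21)
  x <- matrix(rnorm(60), ncol = 6)
  expect_equal(dtw_distance(x, x), 0)
  expect_equal(dtw_distance(0, 1), 1)

  # multichannel distance is the sum of independent per-channel distances
  a <- matrix(rnorm(24), ncol = 3)
  b <- matrix(rnorm(15), ncol = 3)
  per_ch <- sum(vapply(1:3, function(ch) dtw_distance(a[, ch], b[, ch]),
                       numeric(1)))
  expect_equal(dtw_distance(a, b), per_ch)

  # for equal lengths, never worse than the diagonal (L1) alignment
  for (i in 1:20) {
    u <- rnorm(12); v <- rnorm(12)
    expect_lte(dtw_distance(u, v), sum(abs(u - v)) + 1e-12)
  }

  expect_error(dtw_distance(a, matrix(1, 2, 2)), class = "shape_error")
})

test_that("glid_profile aggregates growing-window distances over references", {
  set.seed(22)
  punch <- inertial_trace(matrix(rnorm(120), ncol = 6))
  refs <- reference_punch_set(list(punch))
  prof <- glid_profile(punch, refs, step = 1)
  expect_equal(length(prof$distances), 20)
  expect_equal(prof$window_lengths, 1:20)
  # full window against its own reference: distance exactly 0
  expect_equal(prof$distances[20], 0)
  # initial window mismatch dominates: first value >= minimum
  expect_gte(prof$distances[1], min(prof$distances))

  prof2 <- glid_profile(punch, refs, step = 3)
  expect_equal(prof2$window_lengths, c(3, 6, 9, 12, 15, 18))

  expect_error(reference_punch_set(list()), class = "configuration_error")
})

test_that("the profile rises once the window reaches a pre-action", {
  base <- synthetic_spec(seed = 30)
  refs <- gen_reference_set(10, base, seed = 31)
  pos <- gen_punch_trace(synthetic_spec(seed = 32, preaction = TRUE))
  strike <- detect_striking_timing(pos$trace)
  cut <- cut_and_reverse(slice_trace(pos$trace,
                                     pos$truth$footwork_end_idx + 1, strike),
                         strike - pos$truth$footwork_end_idx)
  prof <- glid_profile(cut, refs)
  onset_w <- strike - pos$truth$preaction_onset_idx + 1
  pre <- prof$distances[seq_len(min(onset_w - 1, length(prof$distances)))]
  post <- prof$distances[prof$window_lengths >= onset_w]
  expect_gt(max(post), min(pre))
})

test_that("find_gap reads the first minimum and following maximum", {
  mk <- function(d) structure(list(window_lengths = seq_along(d),
                                   distances = d, aggregation = "mean"),
                              class = "dtw_profile")
  g <- find_gap(mk(c(9, 4, 2, 5, 3)))
  expect_equal(g$gap, 3)
  expect_equal(g$min_at, 3)
  expect_equal(g$max_at, 4)

  # plateau after the minimum: no maximum, gap 0
  g <- find_gap(mk(c(9, 4, 2, 2, 2)))
  expect_equal(g$gap, 0)
  expect_true(is.na(g$min_at))

  # strictly decreasing: no minimum
  g <- find_gap(mk(c(9, 7, 5, 3, 1)))
  expect_equal(g$gap, 0)

  # profile still rising at its end: the last point is the maximum
  g <- find_gap(mk(c(9, 4, 2, 3, 4, 6)))
  expect_equal(g$gap, 4)
  expect_equal(g$max_at, 6)

  expect_error(find_gap(mk(c(1, 2))), class = "bounds_error")
})

test_that("decide_preaction uses a strict threshold", {
  mk <- function(d) structure(list(window_lengths = seq_along(d),
                                   distances = d, aggregation = "mean"),
                              class = "dtw_profile")
  prof <- mk(c(9, 4, 2, 5, 3)) # gap 3
  expect_true(decide_preaction(prof, tau = 1)$present)
  expect_false(decide_preaction(prof, tau = 3)$present) # gap == tau: absent
  expect_false(decide_preaction(mk(c(9, 7, 5)), tau = 0)$present)
  expect_error(decide_preaction(prof, tau = -1), class = "bounds_error")
})

test_that("tau calibration is deterministic, scales with margin, and separates", {
  base <- synthetic_spec(seed = 40)
  refs <- gen_reference_set(10, base, seed = 41)
  tau1 <- calibrate_tau(refs, margin = 1.2)
  tau2 <- calibrate_tau(refs, margin = 1.2)
  expect_identical(tau1, tau2)
  expect_equal(calibrate_tau(refs, margin = 2.4), 2 * tau1)

  # identical references: every leave-one-out gap is 0
  one <- gen_reference_set(1, base, seed = 42)$punches[[1]]
  same <- reference_punch_set(list(one, one, one, one))
  expect_equal(calibrate_tau(same), 0)

  expect_error(calibrate_tau(reference_punch_set(refs$punches[1:2])),
               class = "calibration_error")
  expect_error(calibrate_tau(refs, margin = 0.5), class = "calibration_error")

  # desk-scale separation: every pre-action punch exceeds tau
  cfg <- gwa_glid_config()
  tau <- calibrate_tau(refs, smooth_window = cfg$gap_smooth)
  coh <- gen_cohort(5, 5, base, seed = 43)
  for (x in coh) {
    rep <- run_gwa_glid(x$trace, refs, cfg, tau = tau)
    expect_true(rep$resolved)
    if (x$truth$label == "with_preaction") expect_true(rep$present)
  }
})

test_that("reference sets round-trip through disk with their manifest", {
  refs <- gen_reference_set(3, synthetic_spec(seed = 50), seed = 51)
  dir <- withr::local_tempdir()
  write_reference_set(refs, dir)
  back <- read_reference_set(dir)
  expect_equal(length(back), 3)
  for (i in 1:3) {
    expect_identical(back$punches[[i]]$data, refs$punches[[i]]$data)
  }
  expect_error(read_reference_set(withr::local_tempdir()), class = "io_error")
})

test_that("ingestion anchors each reference at its striking timing", {
  g <- gen_punch_trace(synthetic_spec(seed = 52))
  ref <- ingest_reference(g$trace)
  # first sample of the reversed cut is the strike sample itself
  expect_equal(unname(ref$data[1, "acc_x"]),
               trace_channel(g$trace, "acc_x")[g$truth$strike_idx])
  expect_equal(n_samples(ref), g$truth$strike_idx)
})
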