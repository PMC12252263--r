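# run code under a fixed RNG seed without disturbing the caller's RNG state
local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic kumite punch recording
#'
#' Parameters of the seeded generator that emulates the wrist inertial
#' signature of a forefist punch in a sparring match: quasi-periodic
#' vertical-dominant footwork, an optional low-amplitude pre-action bump
#' between footwork and punch, a sharp negative forward-axis punch
#' transient with rebound, and additive Gaussian noise. Ground-truth
#' boundaries are exact by construction.
#'
#' @param seed Integer RNG seed.
#' @param rate_hz Sampling rate, Hz. Default 50.
#' @param footwork_period_s Footwork hop period, s. Default 0.4 (the
#'   realistic range is about 0.3-0.5; cohort generation jitters inside
#'   it).
#' @param footwork_amp_y Vertical footwork amplitude, g. Default 0.8.
#' @param footwork_amp_xz Forward/lateral footwork amplitude, g.
#'   Default 0.2.
#' @param footwork_dur_s Footwork duration, s (0 = no footwork, as in an
#'   isolated static punch). Default 6.
#' @param settle_dur_s Pause between footwork end and pre-action onset,
#'   s (used only when `preaction` is `TRUE`: a player preparing a
#'   pre-action stops hopping momentarily first). Default 0.4.
#' @param launch_dur_s Lead between the end of footwork / pre-action and
#'   the punch wind-up, s — the punch is launched straight out of
#'   motion, so this is short. Default 0.2.
#' @param preaction Logical: include a pre-action bump? Default `FALSE`.
#' @param preaction_amp Pre-action amplitude on the forward axis, g.
#'   Default 0.3 (well below the punch peak, as real pre-actions are).
#' @param preaction_dur_s Pre-action duration, s (0.3-0.8 realistic).
#'   Default 0.5.
#' @param punch_peak Punch peak on the forward axis, g; must be negative.
#'   Default -3.
#' @param punch_width_s Gaussian width of the punch transient, s.
#'   Default 0.06.
#' @param tail_dur_s Follow-through tail after the punch, s. Default 1.
#' @param noise_sd Accelerometer noise standard deviation, g. Default 0.05.
#' @param gyro_scale Angular-velocity scale, deg/s per g of the
#'   corresponding acceleration pattern. Default 50.
#' @param gyro_noise_sd Gyroscope noise standard deviation, deg/s.
#'   Default 1.
#' @return Object of class `synthetic_spec` (a validated list).
#' @export
synthetic_spec <- function(seed = 1L, rate_hz = 50, footwork_period_s = 0.4,
                           footwork_amp_y = 0.8, footwork_amp_xz = 0.2,
                           footwork_dur_s = 6, settle_dur_s = 0.4,
                           launch_dur_s = 0.2,
                           preaction = FALSE, preaction_amp = 0.3,
                           preaction_dur_s = 0.5, punch_peak = -3,
                           punch_width_s = 0.06, tail_dur_s = 1,
                           noise_sd = 0.05, gyro_scale = 50,
                           gyro_noise_sd = 1) {
  spec <- list(seed = as.integer(seed), rate_hz = rate_hz,
               footwork_period_s = footwork_period_s,
               footwork_amp_y = footwork_amp_y,
               footwork_amp_xz = footwork_amp_xz,
               footwork_dur_s = footwork_dur_s,
               settle_dur_s = settle_dur_s, launch_dur_s = launch_dur_s,
               preaction = isTRUE(preaction), preaction_amp = preaction_amp,
               preaction_dur_s = preaction_dur_s, punch_peak = punch_peak,
               punch_width_s = punch_width_s, tail_dur_s = tail_dur_s,
               noise_sd = noise_sd, gyro_scale = gyro_scale,
               gyro_noise_sd = gyro_noise_sd)
  if (spec$rate_hz <= 0) stop_preaction("rate_hz must be > 0", "spec_error")
  if (spec$punch_peak >= 0) stop_preaction("punch_peak must be < 0", "spec_error")
  if (spec$footwork_dur_s < 0 || spec$settle_dur_s <= 0 ||
      spec$launch_dur_s <= 0 ||
      spec$preaction_dur_s <= 0 || spec$tail_dur_s <= 0 ||
      spec$footwork_period_s <= 0 || spec$punch_width_s <= 0) {
    stop_preaction("durations must be positive (footwork may be 0)", "spec_error")
  }
  if (spec$noise_sd < 0 || spec$gyro_noise_sd < 0) {
    stop_preaction("noise_sd must be >= 0", "spec_error")
  }
  structure(spec, class = "synthetic_spec")
}

# zero-padded backward shift, used to derive gyro channels from acc patterns
shift_vec <- function(v, k) {
  n <- length(v)
  if (k <= 0) return(v)
  c(rep(0, k), v[seq_len(n - k)])
}

#' Generate one synthetic punch trace with ground truth
#'
#' Layout in time: footwork (sinusoid plus second harmonic, vertical
#' dominant, fading over its last half period) -> optional settle pause
#' plus pre-action (a Hann pulse on the forward acceleration and
#' forearm-rotation gyro axes) -> short launch lead -> punch transient
#' (sharp negative forward spike with rebound and cross-axis
#' transients) -> tail. Gyro
#' channels are phase-shifted, scaled copies of the acceleration patterns
#' with independent noise. The same spec (same seed) always produces a
#' bit-identical trace.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `trace` (an [inertial_trace()]) and `truth` (list
#'   with `footwork_end_idx` — 0 when there is no footwork,
#'   `strike_idx`, `preaction_onset_idx` — `NA` when absent, `label`
#'   ("with_preaction" / "without_preaction"), and `period_samples`).
#' @export
gen_punch_trace <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  local_seed(spec$seed, {
    r <- spec$rate_hz
    p <- spec$footwork_period_s * r
    nf <- round(spec$footwork_dur_s * r)
    # footwork is a sequence of discrete hops: it ends at the final
    # landing, i.e. after a whole number of cycles
    if (nf > 0) nf <- round(max(1, round(nf / p)) * p)
    dp <- if (spec$preaction) round(spec$preaction_dur_s * r) else 0L
    nset <- if (spec$preaction) round(spec$settle_dur_s * r) else 0L
    nl <- round(spec$launch_dur_s * r)
    nq <- nset + dp + nl            # footwork end -> punch onset
    np <- round(0.6 * r)            # punch transient segment (incl. wind-up)
    nt <- round(spec$tail_dur_s * r)
    n <- nf + nq + np + nt

    ax <- ay <- az <- numeric(n)
    if (nf > 0) {
      tt <- seq_len(nf)
      ph <- runif(3, 0, 2 * pi)
      ay[1:nf] <- spec$footwork_amp_y *
        (sin(2 * pi * tt / p) + 0.4 * sin(4 * pi * tt / p + ph[1]))
      ax[1:nf] <- spec$footwork_amp_xz * sin(2 * pi * tt / p + ph[2])
      az[1:nf] <- spec$footwork_amp_xz * sin(2 * pi * tt / p + ph[3])
      # short landing decay (~3 samples) so the final hop ends crisply
      # without an instantaneous jump to zero
      ntap <- min(nf, 3L)
      taper <- seq(1, 0.2, length.out = ntap)
      idx <- (nf - ntap + 1L):nf
      ax[idx] <- ax[idx] * taper
      ay[idx] <- ay[idx] * taper
      az[idx] <- az[idx] * taper
    }

    pre_onset <- NA_integer_
    if (spec$preaction) {
      pre_onset <- nf + nset + 1L
      hann <- 0.5 * (1 - cos(2 * pi * seq_len(dp) / (dp + 1)))
      idx <- pre_onset:(pre_onset + dp - 1L)
      ax[idx] <- ax[idx] + spec$preaction_amp * hann
    }

    so <- round(0.2 * r)            # strike offset inside punch segment
    strike <- nf + nq + so
    i <- seq_len(np)
    w <- spec$punch_width_s * r
    # wind-up: the arm drives forward before impact, a smooth negative ramp
    windup <- ifelse(i <= so, (i / so)^2, 0)
    spike <- exp(-((i - so) / w)^2)
    reb <- exp(-((i - so - 6) / 4)^2)
    pidx <- (nf + nq + 1L):(nf + nq + np)
    ax[pidx] <- ax[pidx] - 0.15 * abs(spec$punch_peak) * windup +
      spec$punch_peak * spike + 0.4 * abs(spec$punch_peak) * reb
    ay[pidx] <- ay[pidx] - 0.3 * windup + 0.6 * exp(-((i - so - 2) / 3)^2)
    az[pidx] <- az[pidx] - 0.5 * exp(-((i - so - 1) / 3)^2)

    s4 <- max(1L, round(0.06 * r))  # small phase shift for the gyro copies
    gx <- spec$gyro_scale * 0.6 * shift_vec(ay, s4)
    gy <- spec$gyro_scale * 0.8 * shift_vec(ax, s4)
    gz <- spec$gyro_scale * 0.7 * shift_vec(az, s4)
    if (spec$preaction) {
      hann <- 0.5 * (1 - cos(2 * pi * seq_len(dp) / (dp + 1)))
      idx <- pre_onset:(pre_onset + dp - 1L)
      gz[idx] <- gz[idx] + spec$gyro_scale * 0.3 * spec$preaction_amp * hann
    }

    ax <- ax + rnorm(n, 0, spec$noise_sd)
    ay <- ay + rnorm(n, 0, spec$noise_sd)
    az <- az + rnorm(n, 0, spec$noise_sd)
    gx <- gx + rnorm(n, 0, spec$gyro_noise_sd)
    gy <- gy + rnorm(n, 0, spec$gyro_noise_sd)
    gz <- gz + rnorm(n, 0, spec$gyro_noise_sd)

    trace <- inertial_trace(
      cbind(acc_x = ax, acc_y = ay, acc_z = az,
            gyro_x = gx, gyro_y = gy, gyro_z = gz),
      sample_rate_hz = r
    )
    truth <- list(
      footwork_end_idx = nf,
      strike_idx = strike,
      preaction_onset_idx = pre_onset,
      label = if (spec$preaction) "with_preaction" else "without_preaction",
      period_samples = p
    )
    list(trace = trace, truth = truth)
  })
}

# draw one sub-seed (31-bit) from the current RNG stream
draw_seed <- function() sample.int(.Machine$integer.max, 1L)

#' Generate a synthetic pre-action-free reference set
#'
#' `n` isolated punches (no footwork, no pre-action) with jittered punch
#' amplitude, transient width and lead duration, each normalized through
#' the standard ingestion path ([detect_striking_timing()] +
#' [cut_and_reverse()]).
#'
#' @param n Number of reference punches, at least 1.
#' @param base_spec A [synthetic_spec()] providing the nominal
#'   parameters. Default `synthetic_spec()`.
#' @param seed Integer RNG seed for the jitter. Default 1.
#' @return A [reference_punch_set()].
#' @export
gen_reference_set <- function(n, base_spec = synthetic_spec(), seed = 1L) {
  if (n < 1L) stop_preaction("n must be >= 1", "spec_error")
  local_seed(seed, {
    punches <- lapply(seq_len(n), function(i) {
      sp <- base_spec
      sp$seed <- draw_seed()
      sp$footwork_dur_s <- 0
      sp$launch_dur_s <- 1.5 + runif(1, -0.2, 0.2) # still stance before the punch
      sp$preaction <- FALSE
      sp$punch_peak <- base_spec$punch_peak * runif(1, 0.85, 1.15)
      sp$punch_width_s <- base_spec$punch_width_s * runif(1, 0.8, 1.2)
      sp <- do.call(synthetic_spec, sp[setdiff(names(sp), character(0))])
      ingest_reference(gen_punch_trace(sp)$trace)
    })
    reference_punch_set(punches, source_meta = "synthetic pre-action-free punches")
  })
}

#' Generate a labeled synthetic cohort for end-to-end evaluation
#'
#' `n_pos` punches with a pre-action followed by `n_neg` without, all
#' with footwork, with per-trace jitter: footwork period uniform in
#' 0.3-0.5 s, amplitudes and punch peak within +/-20% of the base spec,
#' pre-action duration uniform in 0.3-0.8 s, footwork, settle and launch
#' durations mildly varied.
#'
#' @param n_pos,n_neg Class counts (`n_pos + n_neg >= 1`).
#' @param base_spec A [synthetic_spec()]. Default `synthetic_spec()`.
#' @param seed Integer RNG seed. Default 1.
#' @return List of `n_pos + n_neg` elements, each `list(trace, truth)` as
#'   returned by [gen_punch_trace()].
#' @export
gen_cohort <- function(n_pos, n_neg, base_spec = synthetic_spec(), seed = 1L) {
  if (n_pos + n_neg < 1L) stop_preaction("need at least one trace", "spec_error")
  local_seed(seed, {
    flags <- c(rep(TRUE, n_pos), rep(FALSE, n_neg))
    lapply(flags, function(pos) {
      sp <- base_spec
      sp$seed <- draw_seed()
      sp$footwork_period_s <- runif(1, 0.3, 0.5)
      sp$footwork_amp_y <- base_spec$footwork_amp_y * runif(1, 0.8, 1.2)
      sp$footwork_amp_xz <- base_spec$footwork_amp_xz * runif(1, 0.8, 1.2)
      sp$footwork_dur_s <- base_spec$footwork_dur_s + runif(1, -1, 1)
      sp$settle_dur_s <- base_spec$settle_dur_s * runif(1, 0.8, 1.2)
      sp$launch_dur_s <- base_spec$launch_dur_s * runif(1, 0.8, 1.2)
      sp$preaction <- pos
      sp$preaction_dur_s <- runif(1, 0.3, 0.8)
      sp$preaction_amp <- base_spec$preaction_amp * runif(1, 0.8, 1.2)
      sp$punch_peak <- base_spec$punch_peak * runif(1, 0.85, 1.15)
      sp <- do.call(synthetic_spec, sp[names(sp)])
      gen_punch_trace(sp)
    })
  })
}
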