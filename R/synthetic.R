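#' @name synthetic
#' @title Seeded synthetic generators for every modality
#'
#' @description
#' The generators in this file produce inputs with the statistical structure
#' the analysis pipelines assume, together with machine-readable ground
#' truth, so that every stage is testable without participant data.
#'
#' Fluctuation injection works by inverse construction. A spike-train
#' deviation field `d(t)` is built as a train of smooth bumps separated by
#' single-sample valleys. For each bump, a target spike amplitude
#' `m ~ Gamma(shape, scale)` is drawn and the bump's shape (a linear blend of
#' a narrow peak profile and a wide plateau profile, both equal to the bump
#' height at the centre) is solved so that the min-to-min window average `A`
#' satisfies `m = P / (P + A)`. The raw signal is then `C - d(t)` for a
#' baseline `C`: its local peaks sit at the (jittered) valleys, so the
#' pipeline's first-stage Gamma mean lands at `C` minus the mean valley
#' jitter, and the deviation series reproduces `d` up to that jitter scale
#' (~1e-4 of the bump scale). Downstream spike amplitudes therefore follow
#' the requested Gamma law to within a negligible construction error, and
#' the solver itself is unit-tested round-trip.
#'
#' Because the window average can never exceed its own peak, spike amplitudes
#' live in [0.5, 1); the default targets are therefore high-shape Gamma laws
#' (shape 240, scale ~2.9e-3: mean 0.7, sd 0.045) whose mass fits the
#' achievable band of the bump solver.
NULL

# Discrete bump shape profiles on the 2k-1 interior samples of a
# valley-to-valley window of 2k+1 samples. Both profiles equal 1 at the
# centre sample so the bump height is the blend-invariant peak.
bump_shapes <- function(k, peak_sigma = 0.06) {
  u <- seq_len(2 * k - 1) / (2 * k)
  narrow <- 0.1 * sin(pi * u)^2 + 0.9 * exp(-(u - 0.5)^2 / (2 * peak_sigma^2))
  ramp <- 0.15
  wide <- ifelse(u < ramp, (1 - cos(pi * u / ramp)) / 2,
    ifelse(u > 1 - ramp, (1 - cos(pi * (1 - u) / ramp)) / 2, 1)
  )
  narrow[k] <- 1
  wide[k] <- 1
  list(narrow = narrow, wide = wide)
}

# Solve the blend coefficient so the inclusive window mean hits the target
# spike amplitude m = P/(P+A). Returns the blend and the realized amplitude
# (equal to the target unless clamped to the achievable range).
solve_bump <- function(P, m, eps_l, eps_r, shapes) {
  L <- length(shapes$narrow) + 2
  A_target <- P * (1 - m) / m
  cc <- (A_target * L - eps_l - eps_r - P * sum(shapes$narrow)) /
    (P * (sum(shapes$wide) - sum(shapes$narrow)))
  cc <- min(max(cc, 0), 1)
  interior <- P * ((1 - cc) * shapes$narrow + cc * shapes$wide)
  A_real <- (eps_l + eps_r + sum(interior)) / L
  list(
    blend = cc, interior = interior,
    m_realized = P / (P + A_real)
  )
}

#' Build a deviation field with Gamma-distributed spike amplitudes
#'
#' Low-level constructor shared by all modality generators (see
#' [synthetic]). Returns the nonnegative deviation field `d` and the ground
#' truth of every bump.
#'
#' @param n_spikes Number of bumps.
#' @param mms_shape,mms_scale Target Gamma shape and scale of the spike
#'   amplitudes.
#' @param peak_scale Typical bump height in signal units.
#' @param peak_jitter Relative uniform jitter of bump heights (default 0.2).
#' @param valley_jitter Valley jitter as a fraction of `peak_scale`
#'   (default 1e-4); gives the raw-series peak fit nonzero variance.
#' @param k Half-width of each bump in samples (window spans `2k+1` samples
#'   valley to valley).
#' @param peak_sigma Relative width of the narrow peak profile as a fraction
#'   of the window (default 0.06). Signals that pass through smoothing
#'   (e.g. spline-differentiated landmark trajectories) need the absolute
#'   width `peak_sigma * 2k` to span a few samples.
#' @return A list with `d` (length `n_spikes * 2k + 1`), `truth` (a tibble
#'   with target and realized amplitudes, peak heights, blend coefficients),
#'   and `k`.
#' @export
spike_train <- function(n_spikes, mms_shape = 240, mms_scale = 0.7 / 240,
                        peak_scale = 1, peak_jitter = 0.2,
                        valley_jitter = 1e-4, k = 8, peak_sigma = 0.06) {
  stopifnot(n_spikes >= 1, mms_shape > 0, mms_scale > 0, peak_scale > 0, k >= 2)
  m <- stats::rgamma(n_spikes, shape = mms_shape, scale = mms_scale)
  P <- peak_scale * stats::runif(n_spikes, 1 - peak_jitter, 1 + peak_jitter)
  eps <- stats::runif(n_spikes + 1, 0, valley_jitter * peak_scale)
  shapes <- bump_shapes(k, peak_sigma)
  d <- numeric(n_spikes * 2 * k + 1)
  m_real <- blend <- numeric(n_spikes)
  d[1] <- eps[1]
  for (i in seq_len(n_spikes)) {
    sol <- solve_bump(P[i], m[i], eps[i], eps[i + 1], shapes)
    at <- (i - 1) * 2 * k + 1
    d[(at + 1):(at + 2 * k - 1)] <- sol$interior
    d[at + 2 * k] <- eps[i + 1]
    m_real[i] <- sol$m_realized
    blend[i] <- sol$blend
  }
  list(
    d = d,
    truth = tibble::tibble(
      m_target = m, m_realized = m_real, peak = P, blend = blend
    ),
    k = k
  )
}

with_seed_maybe <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

#' Generate a synthetic inter-beat-interval series
#'
#' Emulates an RR series with a controllable baseline, low- and
#' high-frequency oscillatory content (the 0.1 Hz and 0.25 Hz bands used for
#' sympatho-vagal balance), and Gamma-structured spike fluctuations injected
#' by inverse construction (see [synthetic]). Ground truth is attached as the
#' `truth` attribute; it is exact when both oscillation amplitudes are zero.
#'
#' @param duration Recording length in seconds (>= 60).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param rr0 Baseline RR interval in seconds (default 0.9).
#' @param a_lf,a_hf Oscillation amplitudes in seconds at `f_lf`/`f_hf` Hz
#'   (defaults 0.03 each).
#' @param f_lf,f_hf Oscillation frequencies in Hz (defaults 0.1, 0.25).
#' @param fluct_scale Bump height of the RR fluctuation field in seconds
#'   (default 0.15); 0 disables the fluctuation term.
#' @param mms_shape,mms_scale Target Gamma law of the downstream spike
#'   amplitudes.
#' @param k Bump half-width in beats (default 4).
#' @return An [ibi_series()] with a `truth` attribute (list: `mms_shape`,
#'   `mms_scale`, `spikes` tibble, `exact` flag).
#' @examples
#' tr <- gen_ibi(duration = 120, seed = 1)
#' attr(tr, "truth")$exact
#' @export
gen_ibi <- function(duration = 300, seed = NULL, rr0 = 0.9,
                    a_lf = 0.03, a_hf = 0.03, f_lf = 0.1, f_hf = 0.25,
                    fluct_scale = 0.15, mms_shape = 240,
                    mms_scale = 0.7 / 240, k = 4) {
  if (duration < 60) stop("`duration` must be at least 60 s", call. = FALSE)
  if (rr0 - 1.2 * fluct_scale - a_lf - a_hf <= 0) {
    stop("parameters imply nonpositive RR intervals", call. = FALSE)
  }
  with_seed_maybe(seed, {
    rr_mean_guess <- rr0 - 0.45 * fluct_scale
    n_int <- max(ceiling(duration / rr_mean_guess), 2 * k + 1)
    if (fluct_scale > 0) {
      n_spikes <- max(1L, floor((n_int - 1) / (2 * k)))
      st <- spike_train(n_spikes,
        mms_shape = mms_shape, mms_scale = mms_scale,
        peak_scale = fluct_scale, k = k
      )
      d <- st$d
      truth_spikes <- st$truth
    } else {
      d <- rep(0, n_int)
      truth_spikes <- NULL
    }
    n_beats <- length(d) + 1
    beat_times <- numeric(n_beats)
    rr <- numeric(length(d))
    t <- 0
    for (j in seq_along(d)) {
      rr[j] <- rr0 - d[j] +
        a_lf * sin(2 * pi * f_lf * t) + a_hf * sin(2 * pi * f_hf * t)
      t <- t + rr[j]
      beat_times[j + 1] <- t
    }
    out <- ibi_series(beat_times)
    attr(out, "truth") <- list(
      mms_shape = mms_shape, mms_scale = mms_scale,
      spikes = truth_spikes, rr0 = rr0,
      exact = (a_lf == 0 && a_hf == 0 && fluct_scale > 0)
    )
    out
  })
}

#' Generate a synthetic ECG trace from known beat times
#'
#' Superimposes a Mexican-hat QRS-like template (second derivative of a
#' Gaussian, sharp central R peak with small flanking troughs) at each beat
#' time, plus optional white noise. Feeds [detect_rpeaks()] with exact ground
#' truth.
#'
#' @param beat_times Beat times in seconds.
#' @param fs Sampling rate in Hz (default 250).
#' @param width QRS template width parameter sigma in seconds (default 0.012).
#' @param amplitude R-peak amplitude in mV (default 1).
#' @param noise_sd White-noise standard deviation in mV (default 0).
#' @param seed Integer seed for the noise.
#' @return A [uniform_series()] in mV with attribute `truth` (the beat times
#'   snapped to the sampling grid).
#' @export
gen_ecg <- function(beat_times, fs = 250, width = 0.012, amplitude = 1,
                    noise_sd = 0, seed = NULL) {
  if (length(beat_times) >= 2 && min(diff(beat_times)) < 8 * width) {
    stop("beat separation smaller than the QRS template width", call. = FALSE)
  }
  dur <- if (length(beat_times)) max(beat_times) + 0.5 else 1
  n <- ceiling(dur * fs)
  tm <- (seq_len(n) - 1) / fs
  x <- numeric(n)
  snapped <- round(beat_times * fs) / fs
  half <- ceiling(4 * width * fs)
  for (bt in snapped) {
    ctr <- round(bt * fs) + 1
    idx <- max(1, ctr - half):min(n, ctr + half)
    tt <- (idx - ctr) / fs
    x[idx] <- x[idx] + amplitude * (1 - (tt / width)^2) * exp(-tt^2 / (2 * width^2))
  }
  with_seed_maybe(seed, {
    if (noise_sd > 0) x <- x + stats::rnorm(n, 0, noise_sd)
    out <- uniform_series(tm, x, sampling_rate = fs, units = "mV")
    attr(out, "truth") <- list(beat_times = snapped)
    out
  })
}

# Task profiles: bump amplitude (g) tracks physical exertion; the spike
# Gamma law keeps mean 0.7 while its dispersion (hence the NSR = scale)
# grows with task demand.
imu_task_profiles <- function(mms_mean = 0.7) {
  sd <- c(resting = 0.03, pointing = 0.045, walking = 0.06, daily = 0.05, sleep = 0.025)
  tibble::tibble(
    task = names(sd),
    fluct_scale = c(0.02, 0.10, 0.30, 0.15, 0.01),
    osc_amp = c(0, 0.05, 0.20, 0.05, 0),
    osc_freq = c(0, 0.5, 2.0, 1.0, 0),
    mms_shape = mms_mean^2 / sd^2,
    mms_scale = sd^2 / mms_mean
  )
}

#' Generate synthetic triaxial accelerometry
#'
#' Gravity baseline of 1 g plus task-dependent oscillatory bursts and a
#' Gamma-structured fluctuation field on the acceleration magnitude (see
#' [synthetic]). Task profiles set both the bump amplitude (physical
#' exertion) and the target spike Gamma scale (fluctuation dispersion), so
#' that tasks are separable in the (NSR, amplitude) plane as in real
#' wearable data.
#'
#' @param duration Recording length in seconds (>= 60).
#' @param seed Integer seed.
#' @param location Body location label.
#' @param task Task label; selects the default profile row of
#'   `imu_task_profiles()`.
#' @param fs Sampling rate in Hz (default 31.25).
#' @param fluct_scale,osc_amp,osc_freq,mms_shape,mms_scale Overrides of the
#'   task profile (`NULL` = profile default).
#' @param k Bump half-width in samples (default 6).
#' @param direction Unit 3-vector carrying the magnitude (default z axis).
#' @param participant Participant id for the metadata.
#' @return A [triaxial_series()] with a `truth` attribute.
#' @export
gen_imu <- function(duration = 120, seed = NULL, location = "pectoralis",
                    task = "resting", fs = 31.25, fluct_scale = NULL,
                    osc_amp = NULL, osc_freq = NULL, mms_shape = NULL,
                    mms_scale = NULL, k = 6, direction = c(0, 0, 1),
                    participant = "sim") {
  if (duration < 60) stop("`duration` must be at least 60 s", call. = FALSE)
  prof <- imu_task_profiles()
  prof <- prof[prof$task == task, ]
  if (nrow(prof) != 1) stop("unknown task profile: ", task, call. = FALSE)
  fluct_scale <- fluct_scale %||% prof$fluct_scale
  osc_amp <- osc_amp %||% prof$osc_amp
  osc_freq <- osc_freq %||% prof$osc_freq
  mms_shape <- mms_shape %||% prof$mms_shape
  mms_scale <- mms_scale %||% prof$mms_scale
  direction <- direction / sqrt(sum(direction^2))
  with_seed_maybe(seed, {
    n <- ceiling(duration * fs)
    tm <- (seq_len(n) - 1) / fs
    if (fluct_scale > 0) {
      n_spikes <- max(1L, floor((n - 1) / (2 * k)))
      st <- spike_train(n_spikes,
        mms_shape = mms_shape, mms_scale = mms_scale,
        peak_scale = fluct_scale, k = k
      )
      d <- c(st$d, rep(st$d[length(st$d)], n - length(st$d)))[seq_len(n)]
      truth_spikes <- st$truth
    } else {
      d <- rep(0, n)
      truth_spikes <- NULL
    }
    norm <- 1 - d + osc_amp * sin(2 * pi * osc_freq * tm)
    out <- triaxial_series(tm,
      x = direction[1] * norm, y = direction[2] * norm, z = direction[3] * norm,
      location = location, task = task, sampling_rate = fs,
      participant = participant
    )
    attr(out, "truth") <- list(
      mms_shape = mms_shape, mms_scale = mms_scale, spikes = truth_spikes,
      fluct_scale = fluct_scale, exact = (osc_amp == 0 && fluct_scale > 0)
    )
    out
  })
}

# Stylized 68-landmark base face in the iBUG numbering, centred at the
# origin with unit distance scatter. Geometry is schematic; only the
# region membership and the kinematics matter to the analyses.
face_base_shape <- function() {
  jaw <- cbind(
    seq(-1.2, 1.2, length.out = 17),
    -0.4 - 1.1 * cos(seq(-1.1, 1.1, length.out = 17))
  )
  brow_l <- cbind(seq(-0.9, -0.25, length.out = 5), 0.85 + 0.1 * sin(seq(0, pi, length.out = 5)))
  brow_r <- cbind(seq(0.25, 0.9, length.out = 5), 0.85 + 0.1 * sin(seq(0, pi, length.out = 5)))
  nose_ridge <- cbind(rep(0, 4), seq(0.55, 0.05, length.out = 4))
  nostrils <- cbind(seq(-0.25, 0.25, length.out = 5), -0.1 + 0.05 * cos(seq(-1, 1, length.out = 5)))
  eye <- function(cx) {
    a <- seq(0, 2 * pi, length.out = 7)[-7]
    cbind(cx + 0.22 * cos(a), 0.55 + 0.12 * sin(a))
  }
  a <- seq(0, 2 * pi, length.out = 13)[-13]
  mouth_out <- cbind(0.45 * cos(a), -0.75 + 0.22 * sin(a))
  a2 <- seq(0, 2 * pi, length.out = 9)[-9]
  mouth_in <- cbind(0.28 * cos(a2), -0.75 + 0.1 * sin(a2))
  pts <- rbind(
    jaw, brow_l, brow_r, nose_ridge, nostrils,
    eye(-0.55), eye(0.55), mouth_out, mouth_in
  )
  pts <- sweep(pts, 2, colMeans(pts))
  pts / stats::sd(sqrt(rowSums(pts^2)))
}

#' Generate a synthetic 68-landmark facial recording
#'
#' Builds a stylized face (centred, unit landmark-distance scatter) and
#' animates selected landmarks so that their speed fields carry
#' Gamma-structured spike amplitudes per trigeminal region (see
#' [synthetic]). Each moving landmark oscillates along a fixed direction
#' orthogonal to its centred base position (so the per-frame centroid/scale
#' normalization perturbs the injected structure only at second order), with
#' displacement sign alternating bump by bump to keep excursions bounded.
#' Static landmarks acquire only the 1/68-scale common-mode counter-motion,
#' which region fits exclude via the reported `min_prominence`.
#'
#' @param n_frames Number of frames (default 150: a 5-s clip at 30 Hz).
#' @param fps Frame rate in Hz (default 30).
#' @param seed Integer seed.
#' @param region_map A region map as from [face_region_map()].
#' @param region_params Tibble with columns `region`, `mms_shape`,
#'   `mms_scale` (defaults: shape 240 and scales giving spike sd 0.035,
#'   0.045, 0.055 for V1, V2, V3).
#' @param movers_per_region Number of animated landmarks per region; `NULL`
#'   (default) animates every landmark. Small values (2-4) give the cleanest
#'   ground truth because common-mode contamination scales with the number of
#'   independent movers.
#' @param k Bump half-width in frames (default 3 for 150-frame clips; use
#'   larger with longer clips).
#' @param speed_scale Bump height of the speed field in normalized units/s
#'   (default 0.5).
#' @param orbit_radius Radius of each mover's circular excursion in
#'   normalized units (default 0.12); the orbital phase advances at
#'   speed/radius, about 1 Hz at the default speeds.
#' @param peak_sigma Relative bump-peak width (see [spike_train()]); choose
#'   so the absolute width `peak_sigma * 2k` spans >= 2.5 frames when the
#'   grid will be spline-differentiated.
#' @param regions Restrict the animated regions (default all three).
#' @param counterweights Mirror each mover's displacement onto a landmark of
#'   an inactive region so per-frame centroid motion cancels exactly;
#'   requires `regions` to leave at least one region inactive. The mirrored
#'   landmarks duplicate their mover's speed law, so only active regions
#'   carry interpretable ground truth.
#' @param emotion Optional emotion label.
#' @param pixel_scale,pixel_offset Similarity transform applied to express
#'   the output in pixel-like coordinates; [normalize_face()] removes it
#'   exactly.
#' @return A `face_grid` tibble (columns `frame`, `time`, `landmark`, `x`,
#'   `y`) with attributes `fps`, `emotion` and `truth` (per-region Gamma
#'   targets, spike truth per mover, and the `min_prominence`, in normalized
#'   speed units, that excludes common-mode copies).
#' @export
gen_face <- function(n_frames = 150, fps = 30, seed = NULL,
                     region_map = face_region_map(),
                     region_params = NULL, movers_per_region = NULL,
                     k = 3, speed_scale = 0.5, orbit_radius = 0.12,
                     peak_sigma = 0.06, regions = NULL,
                     counterweights = FALSE, emotion = NULL,
                     pixel_scale = 100, pixel_offset = c(320, 240)) {
  if (is.null(region_params)) {
    sd0 <- c(V1 = 0.035, V2 = 0.045, V3 = 0.055)
    region_params <- tibble::tibble(
      region = names(sd0), mms_shape = 0.7^2 / sd0^2,
      mms_scale = sd0^2 / 0.7
    )
  }
  with_seed_maybe(seed, {
    base <- face_base_shape()
    base <- sweep(base, 2, colMeans(base))
    base <- base / stats::sd(sqrt(rowSums(base^2)))
    disp_x <- matrix(0, n_frames, 68)
    disp_y <- matrix(0, n_frames, 68)
    truth_regions <- list()
    baseline_speed <- 1.5 * speed_scale
    active_regions <- regions %||% unique(region_map$region)
    partner_pool <- if (counterweights) {
      region_map$landmark[!(region_map$region %in% active_regions)] + 1L
    } else {
      integer(0)
    }
    partners_used <- integer(0)
    for (rg in active_regions) {
      idx <- region_map$landmark[region_map$region == rg] + 1L
      movers <- if (is.null(movers_per_region)) {
        idx
      } else {
        sample(idx, min(movers_per_region, length(idx)))
      }
      pr <- region_params[region_params$region == rg, ]
      n_spikes <- max(1L, floor((n_frames - 1) / (2 * k)))
      spikes <- list()
      speeds_truth <- list()
      partner_of <- integer(0)
      for (lm in movers) {
        st <- spike_train(n_spikes,
          mms_shape = pr$mms_shape, mms_scale = pr$mms_scale,
          peak_scale = speed_scale, k = k, peak_sigma = peak_sigma
        )
        speed <- baseline_speed - c(st$d, rep(0, max(0, n_frames - length(st$d))))[seq_len(n_frames)]
        # circular motion of fixed radius: phase advances at speed/radius,
        # so the speed scalar is reproduced exactly while the excursion
        # stays strictly bounded and the trajectory is smooth everywhere
        phi <- stats::runif(1, 0, 2 * pi) +
          c(0, cumsum((speed[-1] + speed[-n_frames]) / 2)) /
            (orbit_radius * fps)
        disp_x[, lm] <- orbit_radius * cos(phi)
        disp_y[, lm] <- orbit_radius * sin(phi)
        if (counterweights) {
          # mirror the displacement onto a landmark of an inactive region
          # (summed velocity zero: the per-frame centroid never moves), then
          # add two compensation pairs solving a1*(q1-q2) + a2*(q3-q4) =
          # -(p_mover - p_partner) so the per-frame scatter derivative
          # d(s^2)/dt = (2/68) * sum <x_i, v_i> also vanishes identically;
          # both sources of normalization-induced speed contamination cancel
          avail <- setdiff(partner_pool, partners_used)
          if (length(avail)) {
            dists <- rowSums((base[avail, , drop = FALSE] -
              matrix(base[lm, ], length(avail), 2, byrow = TRUE))^2)
            pt <- avail[which.min(dists)]
            partners_used <- c(partners_used, pt)
            partner_of[as.character(lm)] <- pt
            disp_x[, pt] <- -disp_x[, lm]
            disp_y[, pt] <- -disp_y[, lm]
          }
        }
        spikes[[length(spikes) + 1]] <-
          dplyr::mutate(st$truth, landmark = lm - 1L)
        speeds_truth[[as.character(lm - 1L)]] <- speed
      }
      truth_regions[[rg]] <- list(
        mms_shape = pr$mms_shape, mms_scale = pr$mms_scale,
        movers = movers - 1L, partners = unname(partner_of) - 1L,
        spikes = dplyr::bind_rows(spikes), speeds = speeds_truth
      )
    }
    # frame-major long layout; disp matrices are frames x landmarks
    fr <- rep(seq_len(n_frames), each = 68)
    lmk <- rep(0:67, times = n_frames)
    frames <- tibble::tibble(
      frame = fr, time = (fr - 1) / fps, landmark = lmk,
      x = pixel_offset[1] + pixel_scale * (base[lmk + 1L, 1] + disp_x[cbind(fr, lmk + 1L)]),
      y = pixel_offset[2] + pixel_scale * (base[lmk + 1L, 2] + disp_y[cbind(fr, lmk + 1L)])
    )
    out <- new_face_grid(frames, fps = fps, emotion = emotion)
    attr(out, "truth") <- list(
      regions = truth_regions,
      min_prominence = 0.1 * speed_scale,
      baseline_speed = baseline_speed,
      exact = !is.null(movers_per_region) && movers_per_region <= 4
    )
    out
  })
}

#' Generate a synthetic speech-like envelope and waveform
#'
#' Builds a burst-structured amplitude envelope: each burst rises linearly
#' from the base level to a peak in a fixed attack time (so the attack slope
#' is an exact Gamma draw), falls back just above base, then dwells with a
#' small supra-base wiggle before the next burst. The session median lands in
#' the dwell band, so the median-threshold segmentation recovers exactly one
#' maximum per burst and the burst's rise start as its minimum. Optionally
#' modulates a carrier tone in the 4-7 kHz band to produce audio for the
#' gammatone path.
#'
#' @param n_bursts Number of bursts (default 60).
#' @param seed Integer seed.
#' @param env_fs Envelope sampling rate in Hz (default 200).
#' @param attack_shape,attack_scale Gamma law of the attack slopes in
#'   amplitude/s (defaults 4 and 2: mean slope 8/s).
#' @param tau_attack Attack duration in seconds (default 0.05, snapped to the
#'   envelope grid).
#' @param tau_decay Fall duration in seconds (default 0.065).
#' @param base Base (inter-burst) amplitude (default 0.05).
#' @param dwell_range Dwell duration range in seconds (default c(0.1, 0.3)).
#' @param carrier Carrier frequency in Hz for the audio render (default 5600).
#' @param audio_fs Audio sampling rate in Hz (default 16000).
#' @param synth_audio If `TRUE` also return the modulated waveform.
#' @return A list with `envelope` (a [uniform_series()]), optionally `audio`
#'   (a [uniform_series()] in [-1, 1]), and `truth` (attack slopes, decay
#'   slopes, burst peak times, `n_bursts`).
#' @export
gen_voice <- function(n_bursts = 60, seed = NULL, env_fs = 200,
                      attack_shape = 4, attack_scale = 2,
                      tau_attack = 0.05, tau_decay = 0.065, base = 0.05,
                      dwell_range = c(0.1, 0.3), carrier = 5600,
                      audio_fs = 16000, synth_audio = FALSE) {
  with_seed_maybe(seed, {
    step <- 1 / env_fs
    na <- max(2L, round(tau_attack * env_fs))
    nd <- max(2L, round(tau_decay * env_fs))
    slopes <- if (n_bursts > 0) stats::rgamma(n_bursts, shape = attack_shape, scale = attack_scale) else numeric(0)
    env <- numeric(0)
    min_idx <- max_idx <- integer(0)
    decay_slopes <- numeric(0)
    # leading dwell
    env <- c(env, dwell_samples(round(0.2 * env_fs), base))
    for (i in seq_len(n_bursts)) {
      ndw <- round(stats::runif(1, dwell_range[1], dwell_range[2]) * env_fs)
      peak <- base + slopes[i] * na * step
      min_idx <- c(min_idx, length(env) + 1L)
      rise <- base + (seq_len(na) / na) * (peak - base)
      max_idx <- c(max_idx, length(env) + 1L + na)
      fall_to <- base + 0.005
      fall <- peak + (seq_len(nd) / nd) * (fall_to - peak)
      env <- c(env, base, rise, fall, dwell_samples(ndw, base))
    }
    env <- c(env, base + 0.02)
    tm <- (seq_along(env) - 1) * step
    # decay slopes as the segmentation measures them: retained maximum to the
    # next retained minimum (the next burst's rise start); last burst has no
    # following minimum and is a discarded partial phase
    if (n_bursts >= 2) {
      pk <- base + slopes * na * step
      decay_slopes <- (base - pk[-n_bursts]) /
        (tm[min_idx[-1]] - tm[max_idx[-n_bursts]])
    }
    envelope <- uniform_series(tm, env, sampling_rate = env_fs, units = "amplitude")
    out <- list(
      envelope = envelope,
      truth = list(
        attack_slopes = slopes, decay_slopes = decay_slopes,
        n_bursts = n_bursts,
        min_times = tm[min_idx], max_times = tm[max_idx],
        attack_shape = attack_shape, attack_scale = attack_scale
      )
    )
    if (synth_audio) {
      ta <- (seq_len(ceiling(max(tm) * audio_fs)) - 1) / audio_fs
      ea <- stats::approx(tm, env, xout = ta, rule = 2)$y
      wave <- ea * sin(2 * pi * carrier * ta)
      wave <- wave / max(abs(wave))
      out$audio <- uniform_series(ta, wave, sampling_rate = audio_fs, units = "")
    }
    out
  })
}

# Strictly decreasing inter-burst dwell from just under the fall landing
# toward (but never touching) the burst-minimum level: monotone, so the
# dwell contributes no local extrema and the next retained minimum is
# unambiguously the following burst's rise start.
dwell_samples <- function(n, base) {
  if (n <= 0) {
    return(numeric(0))
  }
  steps <- stats::runif(n)
  base + 0.0008 + 0.004 * rev(cumsum(steps)) / sum(steps)
}
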