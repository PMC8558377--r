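#' Genotype presets for the synthetic-session generator
#'
#' Parameterization of one genotype's thermal-induction phenomenology.
#' Printed values from the study anchor the presets: ripple oscillator
#' frequency at 36 degC (WT 175 Hz, DS 135 Hz), DS discharge onsets
#' (interictal spikes 37.8 degC, myoclonus 38.8 degC, GTC 38.9 degC), a DS
#' SPW-R rate profile peaking at 37.5 degC, a DS sharp-wave amplitude step
#' at 38 degC, and a 40 degC induction cap for seizure-free WT. Quantities
#' the study does not print (ramp rate, SNR, burst-follower distribution,
#' suppression multipliers, frequency slope) are free parameters with
#' defaults documented in the methods vignette.
#'
#' @param label `"WT"` or `"DS"`.
#' @return object of class `genotype_preset` (a named list).
#' @export
genotype_preset <- function(label = c("WT", "DS")) {
  label <- match.arg(label)
  common <- list(
    label = label,
    ripple_freq_slope = 8,        # Hz per degC (free)
    ripple_freq_jitter = 3,       # per-event SD, Hz (free)
    ripple_amp = 60,              # uV envelope peak (free; sets SNR)
    ripple_sigma = 0.012,         # s, Gaussian ripple envelope (free)
    spw_amp = 200,                # uV (free)
    spw_sigma = 0.030,            # s (free)
    spw_carrier = 12,             # Hz, inside the 10-20 Hz SPW band
    burst_follower_probs = c(0.45, 0.25, 0.20, 0.10),  # 0-3 followers
    burst_gap_range = c(0.08, 0.20),                   # s
    post_spike_suppression = list(duration = 1, multiplier = 0.15),
    post_gtc_suppression = list(duration = 120, multiplier = 0.05),
    emg_burst = list(amp_factor = 6, duration = 0.12),
    noise_model = list(exponent = 1.5, lfp_sd = 40, lfp_white_sd = 12,
                       lfp_mid_sd = 40, emg_sd = 15),
    spike_amp = 900,              # uV (free)
    ramp_rate = 0.5 / 60,         # degC per s (free; "slowly increased")
    baseline_temp = 36,
    max_temperature = 40,
    cooling_tau = 60, cooling_duration = 120)
  preset <- if (label == "WT") {
    c(common, list(
      ripple_freq_at_36C = 175,
      spwr_rate_profile = list(type = "linear", base = 0.25, slope = 0.15),
      spw_amp_step_temperature = NA_real_, spw_amp_step_factor = 1,
      spike_onset_temp = NA_real_, spike_rate = c(base = 0, slope = 0),
      mc_onset_temp = NA_real_, mc_rate = c(base = 0, slope = 0),
      gtc_temp = NA_real_))
  } else {
    c(common, list(
      ripple_freq_at_36C = 135,
      spwr_rate_profile = list(type = "peak", base = 0.22, amp = 0.33,
                               peak = 37.5, sigma = 0.35),
      spw_amp_step_temperature = 38, spw_amp_step_factor = 1.6,
      spike_onset_temp = 37.8, spike_rate = c(base = 0.3, slope = 0.5),
      mc_onset_temp = 38.8, mc_rate = c(base = 0.6, slope = 1.0),
      gtc_temp = 38.9))
  }
  structure(preset, class = "genotype_preset")
}

spwr_rate_at <- function(preset, temp) {
  p <- preset$spwr_rate_profile
  if (p$type == "linear") pmax(0, p$base + p$slope * (temp - 36))
  else p$base + p$amp * exp(-(temp - p$peak)^2 / (2 * p$sigma^2))
}

onset_rate_at <- function(rate, onset, temp) {
  if (is.na(onset)) return(rep(0, length(temp)))
  ifelse(temp >= onset, rate["base"] + rate["slope"] * (temp - onset), 0)
}

stream_seed <- function(seed, stage) (abs(seed) %% 20000000L) * 101L + stage

#' Synthetic core-temperature profile for one thermal-induction session
#'
#' Baseline plateau near 36 degC, a slow linear ramp (0.5 degC/min by
#' default) with small smooth jitter, terminating at the genotype's seizure
#' temperature (DS) or the 40 degC induction cap (WT), followed by passive
#' exponential cooling. Sampled at 10 Hz.
#'
#' @param preset a `genotype_preset`.
#' @param seed integer seed (deterministic output).
#' @param baseline_duration plateau length, s.
#' @return temperature `time_series` (degC, 10 Hz).
#' @export
generate_temperature_profile <- function(preset, seed,
                                         baseline_duration = 180) {
  fs <- 10
  target <- if (is.na(preset$gtc_temp)) preset$max_temperature
            else preset$gtc_temp
  # overshoot past the target so the crossing exists despite ramp jitter
  overshoot <- 0.15
  ramp_dur <- (target + overshoot - preset$baseline_temp) / preset$ramp_rate
  t_base <- seq(0, baseline_duration - 1 / fs, by = 1 / fs)
  t_ramp <- seq(0, ramp_dur - 1 / fs, by = 1 / fs)
  t_cool <- seq(0, preset$cooling_duration - 1 / fs, by = 1 / fs)
  base <- c(rep(preset$baseline_temp, length(t_base)),
            preset$baseline_temp + preset$ramp_rate * t_ramp,
            36.5 + (target + overshoot - 36.5) *
              exp(-t_cool / preset$cooling_tau))
  set.seed(stream_seed(seed, 1L))
  jit <- moving_average(stats::rnorm(length(base)), 101)
  jit <- jit * 0.02 / stats::sd(jit)
  time_series(base + jit, fs, units = "degC")
}

draw_inhomogeneous <- function(rate, fs, t0 = 0) {
  counts <- stats::rpois(length(rate), rate / fs)
  idx <- rep(seq_along(counts), counts)
  if (length(idx) == 0) return(numeric(0))
  sort(t0 + (idx - 1) / fs + stats::runif(length(idx)) / fs)
}

enforce_min_gap <- function(times, gap) {
  if (length(times) < 2) return(rep(TRUE, length(times)))
  keep <- logical(length(times))
  last <- -Inf
  for (i in seq_along(times)) {
    if (times[i] - last >= gap) { keep[i] <- TRUE; last <- times[i] }
  }
  keep
}

away_from <- function(times, anchors, margin) {
  if (length(anchors) == 0) return(rep(TRUE, length(times)))
  vapply(times, function(t) all(abs(t - anchors) > margin), logical(1))
}

#' Sample an event schedule from a temperature profile
#'
#' SPW-R seed events are drawn from an inhomogeneous Poisson process whose
#' intensity follows the preset's temperature-dependent rate profile; each
#' seed spawns 0-3 burst followers at 80-200 ms gaps. Interictal spikes and
#' myoclonic events are drawn from rate curves that are zero below their
#' onset temperatures and increase above them; the GTC is placed at the
#' first crossing of the seizure temperature. SPW-R intensity is
#' multiplicatively suppressed for 1 s after each discharge and deeply
#' suppressed after the GTC. Events are kept clear of active-exploration
#' epochs, record edges, and one another (minimum separations documented in
#' the methods vignette).
#'
#' @param preset a `genotype_preset`.
#' @param temperature temperature `time_series` from
#'   [generate_temperature_profile()].
#' @param seed integer seed.
#' @param active_epochs data.frame (start, end) of scheduled exploration
#'   epochs, or NULL.
#' @return list: `events` (data.frame type, time), `gtc_time` (s or NA).
#' @export
sample_event_times <- function(preset, temperature, seed,
                               active_epochs = NULL) {
  fs <- temperature$fs
  temps <- temperature$values
  dur <- ts_duration(temperature)
  gtc_time <- if (is.na(preset$gtc_temp)) NA_real_
              else temperature_crossing(temperature, preset$gtc_temp)
  set.seed(stream_seed(seed, 2L))
  pre_gtc <- function(t) if (is.na(gtc_time)) rep(TRUE, length(t))
                         else t < gtc_time - 3
  in_active <- function(t) {
    if (is.null(active_epochs) || nrow(active_epochs) == 0)
      return(rep(FALSE, length(t)))
    in_intervals(t, data.frame(start = active_epochs$start - 0.5,
                               end = active_epochs$end + 0.5))
  }
  usable <- function(t) t > 3 & t < dur - 3 & pre_gtc(t) & !in_active(t)

  spikes <- draw_inhomogeneous(
    onset_rate_at(preset$spike_rate, preset$spike_onset_temp, temps), fs)
  mcs <- draw_inhomogeneous(
    onset_rate_at(preset$mc_rate, preset$mc_onset_temp, temps), fs)
  disc <- rbind(
    data.frame(type = rep("interictal_spike", length(spikes)), time = spikes),
    data.frame(type = rep("myoclonic", length(mcs)), time = mcs))
  disc <- disc[usable(disc$time), , drop = FALSE]
  disc <- disc[order(disc$time), , drop = FALSE]
  disc <- disc[enforce_min_gap(disc$time, 0.3), , drop = FALSE]

  seeds <- draw_inhomogeneous(spwr_rate_at(preset, temps), fs)
  nf <- sample(0:3, length(seeds), replace = TRUE,
               prob = preset$burst_follower_probs)
  followers <- unlist(lapply(seq_along(seeds), function(i) {
    if (nf[i] == 0) return(numeric(0))
    seeds[i] + cumsum(stats::runif(nf[i], preset$burst_gap_range[1],
                                   preset$burst_gap_range[2]))
  }))
  spwr <- sort(c(seeds, followers))
  # post-discharge and post-ictal suppression by thinning
  supp <- rep(1, length(spwr))
  ps <- preset$post_spike_suppression
  for (td in disc$time) {
    w <- spwr > td & spwr <= td + ps$duration
    supp[w] <- supp[w] * ps$multiplier
  }
  if (!is.na(gtc_time)) {
    pg <- preset$post_gtc_suppression
    w <- spwr > gtc_time & spwr <= gtc_time + pg$duration
    supp[w] <- supp[w] * pg$multiplier
    supp[spwr > gtc_time - 1 & spwr <= gtc_time + 20] <- 0
  }
  spwr <- spwr[stats::runif(length(spwr)) < supp]
  spwr <- spwr[usable(spwr)]
  if (nrow(disc) > 0)
    spwr <- spwr[away_from(spwr, disc$time, 0.15)]
  spwr <- spwr[enforce_min_gap(spwr, 0.08)]

  events <- rbind(
    data.frame(type = rep("spwr", length(spwr)), time = spwr), disc)
  events <- events[order(events$time), , drop = FALSE]
  rownames(events) <- NULL
  list(events = events, gtc_time = gtc_time)
}

band_noise <- function(n, fs, lo, hi, sd_target) {
  m <- if (n %% 2 == 0) n else n + 1L
  half <- m %/% 2L
  f <- (1:half) * fs / m
  mag <- as.numeric(f >= lo & f <= hi)
  z <- complex(real = stats::rnorm(half), imaginary = stats::rnorm(half)) * mag
  X <- complex(length.out = m)
  X[2:(half + 1L)] <- z
  X[half + 1L] <- complex(real = Re(z[half]), imaginary = 0)
  X[(half + 2L):m] <- Conj(z[(half - 1L):1L])
  x <- Re(stats::fft(X, inverse = TRUE))[seq_len(n)]
  x * sd_target / stats::sd(x)
}

colored_noise <- function(n, fs, exponent, sd_target) {
  m <- if (n %% 2 == 0) n else n + 1L
  half <- m %/% 2L
  f <- (1:half) * fs / m
  mag <- pmax(f, 1)^(-exponent / 2)
  z <- complex(real = stats::rnorm(half), imaginary = stats::rnorm(half)) * mag
  X <- complex(length.out = m)
  X[2:(half + 1L)] <- z
  X[half + 1L] <- complex(real = Re(z[half]), imaginary = 0)
  X[(half + 2L):m] <- Conj(z[(half - 1L):1L])
  x <- Re(stats::fft(X, inverse = TRUE))
  x <- x[seq_len(n)]
  x * sd_target / stats::sd(x)
}

add_waveform <- function(x, fs, center, wave_fun, half_width) {
  i0 <- max(1L, as.integer(round((center - half_width) * fs)) + 1L)
  i1 <- min(length(x), as.integer(round((center + half_width) * fs)) + 1L)
  if (i1 <= i0) return(x)
  t <- ((i0:i1) - 1L) / fs - center
  x[i0:i1] <- x[i0:i1] + wave_fun(t)
  x
}

raised_cosine <- function(t, dur) {
  ifelse(t >= 0 & t <= dur, 0.5 - 0.5 * cos(2 * pi * t / dur), 0)
}

spike_shape <- function(t, amp) {
  # sharp negative deflection (~25 ms at base) with a slower rebound wave
  -amp * exp(-t^2 / (2 * 0.004^2)) +
    0.4 * amp * exp(-(t - 0.015)^2 / (2 * 0.010^2))
}

#' Render a scheduled session into LFP, EMG, and ground truth
#'
#' The LFP is 1/f^1.5 background noise plus per-event waveforms: a sharp
#' wave (Gaussian-windowed 15 Hz deflection, amplitude stepped up above the
#' DS step temperature), a ripple (Gaussian-enveloped sinusoid whose
#' frequency follows `f(T) = f36 + slope (T - 36)` plus per-event jitter,
#' clipped to 100-250 Hz), biphasic sharp transients for discharges
#' (myoclonic ones trigger an EMG burst starting at the spike peak), and a
#' 6 Hz polyspike train with sustained EMG for the GTC. Two LFP channels
#' (events attenuated on the second) and one EMG channel are produced at
#' 2048 Hz. Every injected event is logged in the ground-truth ledger.
#'
#' @param schedule list from [sample_event_times()].
#' @param preset a `genotype_preset`.
#' @param temperature temperature `time_series`.
#' @param seed integer seed.
#' @param active_epochs data.frame (start, end) of exploration epochs with
#'   elevated EMG, theta, and movement transients; or NULL.
#' @param subject_id subject label.
#' @param annotate_gtc record the GTC time as an annotation (off by
#'   default, so seizure localization is exercised).
#' @return list: `recording`, `truth` (ground-truth data.frame).
#' @export
render_session <- function(schedule, preset, temperature, seed,
                           active_epochs = NULL, subject_id = "sim",
                           annotate_gtc = FALSE) {
  fs <- 2048
  dur <- ts_duration(temperature)
  n <- as.integer(round(dur * fs))
  set.seed(stream_seed(seed, 3L))
  nm <- preset$noise_model
  lfp1 <- colored_noise(n, fs, nm$exponent, nm$lfp_sd) +
    stats::rnorm(n, sd = nm$lfp_white_sd) +
    band_noise(n, fs, 20, 60, nm$lfp_mid_sd)
  lfp2 <- colored_noise(n, fs, nm$exponent, nm$lfp_sd) +
    stats::rnorm(n, sd = nm$lfp_white_sd) +
    band_noise(n, fs, 20, 60, nm$lfp_mid_sd)
  emg <- stats::rnorm(n, sd = nm$emg_sd)
  ev <- schedule$events
  truth <- list()

  for (i in seq_len(nrow(ev))) {
    t0 <- ev$time[i]
    temp_here <- ts_value_at(temperature, t0)
    if (ev$type[i] == "spwr") {
      f <- preset$ripple_freq_at_36C +
        preset$ripple_freq_slope * (temp_here - 36) +
        stats::rnorm(1, 0, preset$ripple_freq_jitter)
      f <- min(max(f, 100), 250)
      ra <- preset$ripple_amp * stats::runif(1, 0.8, 1.2)
      sa <- preset$spw_amp * stats::runif(1, 0.85, 1.15)
      if (!is.na(preset$spw_amp_step_temperature) &&
          temp_here >= preset$spw_amp_step_temperature)
        sa <- sa * preset$spw_amp_step_factor
      rs <- preset$ripple_sigma; ss <- preset$spw_sigma
      wave <- function(t)
        -sa * exp(-t^2 / (2 * ss^2)) * cos(2 * pi * preset$spw_carrier * t) -
          ra * exp(-t^2 / (2 * rs^2)) * cos(2 * pi * f * t)
      lfp1 <- add_waveform(lfp1, fs, t0, wave, 4 * ss)
      lfp2 <- add_waveform(lfp2, fs, t0, function(t) 0.5 * wave(t), 4 * ss)
      truth[[length(truth) + 1L]] <- data.frame(
        type = "spwr", time = t0, frequency = f, spw_amp = sa,
        temperature = temp_here)
    } else {
      amp <- preset$spike_amp * stats::runif(1, 0.9, 1.2)
      wave <- function(t) spike_shape(t, amp)
      lfp1 <- add_waveform(lfp1, fs, t0, wave, 0.06)
      lfp2 <- add_waveform(lfp2, fs, t0, function(t) 0.6 * wave(t), 0.06)
      if (ev$type[i] == "myoclonic") {
        eb <- preset$emg_burst
        burst_amp <- nm$emg_sd * eb$amp_factor
        i0 <- as.integer(round(t0 * fs)) + 1L
        i1 <- min(n, i0 + as.integer(round(eb$duration * fs)))
        tt <- ((i0:i1) - i0) / fs
        emg[i0:i1] <- emg[i0:i1] +
          stats::rnorm(length(tt), sd = burst_amp) *
            raised_cosine(tt, eb$duration)
      }
      truth[[length(truth) + 1L]] <- data.frame(
        type = ev$type[i], time = t0, frequency = NA_real_,
        spw_amp = NA_real_, temperature = temp_here)
    }
  }

  if (!is.na(schedule$gtc_time)) {
    g0 <- schedule$gtc_time
    gdur <- 15
    for (ts_k in seq(0, gdur, by = 1 / 6)) {
      lfp1 <- add_waveform(lfp1, fs, g0 + ts_k,
                           function(t) spike_shape(t, 1100), 0.06)
      lfp2 <- add_waveform(lfp2, fs, g0 + ts_k,
                           function(t) spike_shape(t, 850), 0.06)
    }
    i0 <- as.integer(round(g0 * fs)) + 1L
    i1 <- min(n, i0 + as.integer(round(gdur * fs)))
    tt <- ((i0:i1) - i0) / fs
    emg[i0:i1] <- emg[i0:i1] +
      stats::rnorm(length(tt), sd = nm$emg_sd * 8) *
        pmin(1, raised_cosine(tt, gdur) * 4)
    truth[[length(truth) + 1L]] <- data.frame(
      type = "gtc", time = g0, frequency = NA_real_, spw_amp = NA_real_,
      temperature = ts_value_at(temperature, g0))
  }

  if (!is.null(active_epochs) && nrow(active_epochs) > 0) {
    for (j in seq_len(nrow(active_epochs))) {
      a0 <- active_epochs$start[j]; a1 <- active_epochs$end[j]
      i0 <- as.integer(round(a0 * fs)) + 1L
      i1 <- min(n, as.integer(round(a1 * fs)))
      tt <- ((i0:i1) - i0) / fs
      env <- pmin(1, raised_cosine(tt, a1 - a0) * 3)
      emg[i0:i1] <- emg[i0:i1] + stats::rnorm(length(tt), sd = nm$emg_sd * 4) * env
      theta <- 60 * sin(2 * pi * 7 * tt) * env
      lfp1[i0:i1] <- lfp1[i0:i1] + theta
      lfp2[i0:i1] <- lfp2[i0:i1] + theta
      for (k in 1:3) {  # movement transients on both channels
        tc <- a0 + (a1 - a0) * k / 4
        mov <- function(t) 400 * exp(-t^2 / (2 * 0.08^2))
        lfp1 <- add_waveform(lfp1, fs, tc, mov, 0.3)
        lfp2 <- add_waveform(lfp2, fs, tc, mov, 0.3)
      }
    }
  }

  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(type = character(0), time = numeric(0),
               frequency = numeric(0), spw_amp = numeric(0),
               temperature = numeric(0))
  ann <- list()
  if (annotate_gtc && !is.na(schedule$gtc_time))
    ann$gtc_onset <- schedule$gtc_time
  rec <- recording(
    lfp = list(ca1_left = time_series(lfp1, fs, units = "uV"),
               ca1_right = time_series(lfp2, fs, units = "uV")),
    emg = list(neck = time_series(emg, fs, units = "uV")),
    temperature = temperature, annotations = ann,
    subject_id = subject_id, genotype = preset$label)
  list(recording = rec, truth = truth)
}

#' Simulate one complete synthetic session
#'
#' Drives the profile, schedule and rendering stages from a single session
#' seed (sub-stage seeds are derived from it, so equal seeds give
#' bit-identical sessions). A full thermal-induction session is generated
#' by default; passing `constant_temperature` produces a baseline recording
#' at a fixed temperature with no ramp (used for frequency-recovery
#' studies).
#'
#' @param preset a `genotype_preset` (or `"WT"`/`"DS"`).
#' @param seed integer seed.
#' @param baseline_duration plateau length for induction sessions, s.
#' @param constant_temperature if non-NULL, hold this temperature (degC).
#' @param duration session length for constant-temperature sessions, s.
#' @param active_epochs `"auto"` (one 30 s exploration epoch during the
#'   baseline plateau of induction sessions), NULL, or a data.frame
#'   (start, end).
#' @param subject_id subject label (defaults to genotype + seed).
#' @param annotate_gtc record the GTC annotation (default FALSE).
#' @return list of class `synthetic_session`: `recording`, `truth`,
#'   `schedule`, `preset`, `seed`.
#' @export
simulate_session <- function(preset, seed, baseline_duration = 180,
                             constant_temperature = NULL, duration = 600,
                             active_epochs = "auto", subject_id = NULL,
                             annotate_gtc = FALSE) {
  if (is.character(preset)) preset <- genotype_preset(preset)
  if (is.null(subject_id))
    subject_id <- sprintf("%s_%d", preset$label, seed)
  if (!is.null(constant_temperature)) {
    set.seed(stream_seed(seed, 1L))
    jit <- moving_average(stats::rnorm(duration * 10), 101)
    jit <- jit * 0.02 / stats::sd(jit)
    temp <- time_series(constant_temperature + jit, 10, units = "degC")
    pre2 <- preset
    pre2$gtc_temp <- NA_real_   # no induction: ramp never reaches seizure
    if (identical(active_epochs, "auto")) active_epochs <- NULL
    schedule <- sample_event_times(pre2, temp, seed, active_epochs)
    rend <- render_session(schedule, pre2, temp, seed, active_epochs,
                           subject_id, annotate_gtc)
  } else {
    temp <- generate_temperature_profile(preset, seed, baseline_duration)
    if (identical(active_epochs, "auto"))
      active_epochs <- data.frame(start = 60, end = 90)
    schedule <- sample_event_times(preset, temp, seed, active_epochs)
    rend <- render_session(schedule, preset, temp, seed, active_epochs,
                           subject_id, annotate_gtc)
  }
  structure(list(recording = rend$recording, truth = rend$truth,
                 schedule = schedule, preset = preset, seed = seed),
            class = "synthetic_session")
}

#' Match detections against ground truth
#'
#' Greedy one-to-one matching by time difference (closest pairs first,
#' within the tolerance), yielding precision, recall, and for matched
#' ripples the distribution of frequency errors.
#'
#' @param truth_times,detected_times numeric vectors (s).
#' @param tolerance matching tolerance, s (default 0.025).
#' @param truth_values,detected_values optional per-event values (e.g.
#'   ripple frequencies) for matched-pair error statistics.
#' @return list: precision, recall, n_truth, n_detected, matches
#'   (data.frame truth_idx, det_idx, dt), and when values are supplied
#'   `errors`, `bias`, `mae`.
#' @export
evaluate_detection <- function(truth_times, detected_times,
                               tolerance = 0.025,
                               truth_values = NULL, detected_values = NULL) {
  if (tolerance <= 0) stop("tolerance must be positive")
  nt <- length(truth_times); nd <- length(detected_times)
  pairs <- NULL
  if (nt > 0 && nd > 0) {
    dt <- outer(truth_times, detected_times, function(a, b) abs(a - b))
    cand <- which(dt <= tolerance, arr.ind = TRUE)
    if (nrow(cand) > 0) {
      cand <- cand[order(dt[cand]), , drop = FALSE]
      used_t <- logical(nt); used_d <- logical(nd)
      keep <- logical(nrow(cand))
      for (i in seq_len(nrow(cand))) {
        r <- cand[i, 1]; c <- cand[i, 2]
        if (!used_t[r] && !used_d[c]) {
          keep[i] <- TRUE; used_t[r] <- TRUE; used_d[c] <- TRUE
        }
      }
      cand <- cand[keep, , drop = FALSE]
      pairs <- data.frame(truth_idx = cand[, 1], det_idx = cand[, 2],
                          dt = detected_times[cand[, 2]] -
                               truth_times[cand[, 1]])
    }
  }
  n_match <- if (is.null(pairs)) 0L else nrow(pairs)
  out <- list(precision = if (nd > 0) n_match / nd else NA_real_,
              recall = if (nt > 0) n_match / nt else NA_real_,
              n_truth = nt, n_detected = nd, matches = pairs)
  if (!is.null(truth_values) && !is.null(detected_values) && n_match > 0) {
    err <- detected_values[pairs$det_idx] - truth_values[pairs$truth_idx]
    out$errors <- err
    out$bias <- mean(err)
    out$mae <- mean(abs(err))
  }
  out
}
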