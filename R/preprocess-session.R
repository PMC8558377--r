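smooth_ts <- function(ts, win_s) {
  if (win_s <= 0) return(ts)
  time_series(moving_average(ts$values, next_odd(win_s * ts$fs)),
              ts$fs, ts$start_time, ts$units, validate = FALSE)
}

central_derivative <- function(ts) {
  x <- ts$values
  n <- length(x)
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * ts$fs / 2
  d[1] <- d[2]; d[n] <- d[n - 1]
  time_series(d, ts$fs, ts$start_time, units = paste0(ts$units, "/s"),
              validate = FALSE)
}

#' Preprocess a session for detection
#'
#' Runs the shared signal chain once: EMG-band power and behavioral-state
#' classification, baseline-epoch selection (unless supplied), ripple- and
#' sharp-wave-band filtering, Hilbert power, per-quantity baseline
#' statistics from the NREM epoch, and z-scored traces for every detector.
#' Separate baseline statistics are kept per quantity tag (ripple power,
#' SPW power, EMG power, LFP amplitude, LFP derivative, broadband power).
#'
#' Samples within one filter length of the record boundaries are marked as
#' an edge guard and excluded from downstream detection.
#'
#' @param rec a `recording` at 2048 Hz.
#' @param params a `detection_params`.
#' @param baseline_epoch optional numeric length-2 manual NREM epoch (s).
#' @param channel index of the LFP channel to analyze (default 1).
#' @return object of class `preprocessed_session`.
#' @export
preprocess_session <- function(rec, params = detection_params(),
                               baseline_epoch = NULL, channel = 1L) {
  stopifnot(inherits(rec, "recording"))
  bands <- default_bands()
  lfp <- rec$lfp[[channel]]
  emg <- rec$emg[[1]]
  fs <- lfp$fs

  emg_spec <- fir_bandpass(bands$emg, fs)
  emg_pow <- instantaneous_power(bandpass_zero_phase(emg, emg_spec))
  if (is.null(baseline_epoch)) {
    # a representative NREM epoch must be normothermic and pre-induction:
    # post-ictal quiet has suppressed SPW-R and would deflate the baseline
    # variance every threshold is anchored to
    allowed <- NULL
    temp <- rec$temperature
    if (!is.null(temp) && diff(range(temp$values)) > 1) {
      iv <- runs_to_intervals(temp$values < 36.6, temp$fs, temp$start_time)
      tmax <- ts_times(temp)[which.max(temp$values)]
      iv <- iv[iv$start < tmax, , drop = FALSE]
      iv$end <- pmin(iv$end, tmax)
      iv <- iv[iv$end - iv$start >= params$baseline_min_duration, ,
               drop = FALSE]
      if (nrow(iv) > 0) allowed <- iv
    }
    baseline_epoch <- select_baseline_epoch(emg_pow, lfp,
                                            params$baseline_min_duration,
                                            allowed = allowed)
  }

  # A kernel at the default 3 fs / low length leaves a transition slope
  # across the lower ripple band that tilts slow (~135 Hz) ripples' spectra
  # and biases their inter-trough frequency upward by ~3 Hz; doubling the
  # length flattens the passband over 100-260 Hz.
  ripple_spec <- fir_bandpass(bands$ripple, fs,
                              taps = next_odd(6 * fs / bands$ripple$low))
  spw_spec <- fir_bandpass(bands$spw, fs)
  ripple_band <- bandpass_zero_phase(lfp, ripple_spec)
  ripple_pow <- smooth_ts(instantaneous_power(ripple_band),
                          params$power_smooth)
  spw_pow <- instantaneous_power(bandpass_zero_phase(lfp, spw_spec))
  # The discharge-defining steep deflection lies below the ripple band;
  # differentiating the raw trace instead would be dominated by ripple-band
  # oscillation and wideband noise. Low-pass before the derivative.
  lp_taps <- next_odd(2048 * 3 / 18)
  lp <- signal::fir1(lp_taps - 1L, params$deriv_lowpass / (fs / 2),
                     type = "low", window = signal::hanning(lp_taps))
  lfp_slow <- time_series(conv_centered(lfp$values, as.numeric(lp)),
                          fs, lfp$start_time, lfp$units, validate = FALSE)
  deriv <- central_derivative(lfp_slow)
  bb_pow <- smooth_ts(instantaneous_power(lfp), params$gtc_smooth)
  emg_bb <- smooth_ts(emg_pow, params$gtc_smooth)

  bl <- function(q, tag) compute_baseline_stats(q, baseline_epoch, tag,
                                                min_duration = 30)
  stats <- list(
    ripple_power = bl(ripple_pow, "ripple-power"),
    spw_power = bl(spw_pow, "spw-power"),
    emg_power = bl(emg_pow, "emg-power"),
    lfp_amplitude = bl(lfp, "lfp-amplitude"),
    lfp_derivative = bl(deriv, "lfp-derivative"),
    broadband_power = bl(bb_pow, "broadband-power"),
    emg_power_slow = bl(emg_bb, "emg-power-slow"))

  emg_z <- zscore(emg_pow, stats$emg_power)
  states <- classify_behavioral_state(emg_z, params)

  lfp_z_all <- lapply(rec$lfp, function(ch)
    zscore(ch, bl(ch, "lfp-amplitude"), tag = "lfp-amplitude"))

  guard_s <- max(ripple_spec$taps, spw_spec$taps, emg_spec$taps) / fs
  dur <- rec_duration(rec)
  edge_guard <- data.frame(start = c(lfp$start_time, lfp$start_time + dur - guard_s),
                           end = c(lfp$start_time + guard_s, lfp$start_time + dur))

  structure(list(
    recording = rec,
    channel = channel,
    baseline_epoch = baseline_epoch,
    stats = stats,
    ripple_band = ripple_band,
    ripple_z_power = zscore(ripple_pow, stats$ripple_power),
    spw_z_power = zscore(spw_pow, stats$spw_power),
    emg_z_power = emg_z,
    lfp_z = lfp_z_all[[channel]],
    lfp_z_all = lfp_z_all,
    deriv_z = zscore(deriv, stats$lfp_derivative),
    broadband_z_power = zscore(bb_pow, stats$broadband_power),
    emg_slow_z_power = zscore(emg_bb, stats$emg_power_slow),
    states = states,
    temperature = rec$temperature,
    annotations = rec$annotations,
    edge_guard = edge_guard),
    class = "preprocessed_session")
}

#' @export
print.preprocessed_session <- function(x, ...) {
  cat(sprintf("<preprocessed_session> %s, baseline [%.1f, %.1f] s, %d state segments\n",
              x$recording$subject_id, x$baseline_epoch[1], x$baseline_epoch[2],
              nrow(x$states)))
  invisible(x)
}
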