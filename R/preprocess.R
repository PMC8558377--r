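next_odd <- function(x) {
  n <- ceiling(x)
  if (n %% 2 == 0) n + 1L else as.integer(n)
}

#' Centered moving average with shrinking edge windows
#' @param x numeric vector.
#' @param k window length in samples.
#' @return smoothed vector, same length.
#' @keywords internal
moving_average <- function(x, k) {
  k <- as.integer(k)
  if (k <= 1L) return(x)
  n <- length(x)
  cs <- c(0, cumsum(x))
  half <- k %/% 2L
  i <- seq_len(n)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Linear-phase convolution aligned to zero delay, with mirror padding so the
# full series length is preserved. One forward pass of a symmetric kernel.
conv_centered <- function(x, b) {
  nb <- length(b)
  half <- (nb - 1L) %/% 2L
  n <- length(x)
  if (n <= half + 1L) stop("series too short for this filter")
  left <- rev(x[seq_len(half) + 1L])
  right <- x[n - seq_len(half)]
  y <- signal::fftfilt(b, c(left, x, right))
  y[(2L * half + 1L):(2L * half + n)]
}

#' Design a zero-phase FIR bandpass filter
#'
#' Windowed-sinc FIR bandpass with a Hanning window and linear phase,
#' applied forward-backward so the net phase shift is zero. The default tap
#' count is the next odd integer at or above `3 * fs / low`, which sets the
#' transition width from the low band edge.
#'
#' @param band a `band_definition`.
#' @param fs sampling rate of the target series (Hz).
#' @param taps odd FIR length; default from the rule above.
#' @return object of class `filter_spec` with the kernel in `$b`.
#' @export
fir_bandpass <- function(band, fs, taps = NULL) {
  stopifnot(inherits(band, "band_definition"))
  if (band$high >= fs / 2)
    stop("band must lie below the Nyquist frequency")
  if (is.null(taps)) taps <- next_odd(3 * fs / band$low)
  if (taps %% 2 == 0) stop("taps must be odd")
  b <- signal::fir1(taps - 1L, c(band$low, band$high) / (fs / 2),
                    type = "pass", window = signal::hanning(taps))
  structure(list(band = band, fs = fs, taps = as.integer(taps),
                 window_shape = "hanning", application = "zero-phase",
                 b = as.numeric(b)),
            class = "filter_spec")
}

#' Bandpass filter a series with zero net phase
#'
#' Applies the linear-phase FIR kernel forward and backward (equivalent to
#' filtering with the kernel's autocorrelation), so a band-interior
#' sinusoid emerges with zero lag.
#'
#' @param series a `time_series`.
#' @param spec a `filter_spec` from [fir_bandpass()], designed at the same
#'   sampling rate.
#' @return filtered `time_series` (same length, same units).
#' @export
bandpass_zero_phase <- function(series, spec) {
  stopifnot(inherits(series, "time_series"), inherits(spec, "filter_spec"))
  if (abs(series$fs - spec$fs) > 1e-9)
    stop("filter was designed for a different sampling rate")
  if (length(series$values) < 3L * spec$taps)
    stop("series shorter than 3 filter lengths")
  y <- conv_centered(series$values, spec$b)
  y <- rev(conv_centered(rev(y), spec$b))
  time_series(y, series$fs, series$start_time, series$units,
              validate = FALSE)
}

#' Resample a raw channel to the working rate of 2048 Hz
#'
#' An anti-alias FIR low-pass at 1024 Hz is applied before rate reduction.
#' Integer decimation is used when the raw rate is a multiple of 2048 Hz;
#' otherwise polyphase rational resampling. Upsampling is refused.
#'
#' @param raw `time_series` at an integer rate of at least 2048 Hz.
#' @param target_fs output rate (default 2048).
#' @return `time_series` at `target_fs`.
#' @export
ingest_resample <- function(raw, target_fs = 2048) {
  stopifnot(inherits(raw, "time_series"))
  fs <- raw$fs
  if (fs < target_fs) stop("upsampling refused: raw rate below 2048 Hz")
  if (abs(fs - round(fs)) > 1e-6) stop("raw rate must be an integer in Hz")
  fs <- round(fs)
  if (fs == target_fs) return(raw)
  cutoff <- target_fs / 2
  taps <- next_odd(fs / 50)  # ~1 ms kernel; transition well under cutoff
  b <- signal::fir1(taps - 1L, cutoff / (fs / 2), type = "low",
                    window = signal::hanning(taps))
  xf <- conv_centered(raw$values, as.numeric(b))
  if (fs %% target_fs == 0) {
    y <- xf[seq(1L, length(xf), by = fs %/% target_fs)]
  } else {
    # rational rates: Fourier resampling of the already anti-aliased signal
    # (flat passband, unlike a short polyphase kernel)
    n_out <- as.integer(round(length(xf) * target_fs / fs))
    y <- resample_fft(xf, n_out)
  }
  time_series(y, target_fs, raw$start_time, raw$units, validate = FALSE)
}

resample_fft <- function(x, n_out) {
  n <- length(x)
  X <- stats::fft(x)
  Y <- complex(length.out = n_out)
  k <- min((n_out - 1L) %/% 2L, (n - 1L) %/% 2L)
  Y[1] <- X[1]
  Y[2:(k + 1L)] <- X[2:(k + 1L)]
  Y[(n_out - k + 1L):n_out] <- X[(n - k + 1L):n]
  Re(stats::fft(Y, inverse = TRUE)) * n_out / (n * n_out)  # 1/n normalization
}

#' Instantaneous power by Hilbert transform
#'
#' Squared magnitude of the analytic signal: for a band-limited input the
#' squared instantaneous amplitude envelope.
#'
#' @param series a band-limited `time_series`.
#' @return `time_series` of instantaneous power (input units squared).
#' @export
instantaneous_power <- function(series) {
  stopifnot(inherits(series, "time_series"))
  x <- series$values
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  a <- stats::fft(X * h, inverse = TRUE) / n
  time_series(Mod(a)^2, series$fs, series$start_time,
              units = paste0(series$units, "2"), validate = FALSE)
}

#' Baseline mean and SD of a quantity over a reference epoch
#'
#' @param quantity `time_series` of the quantity to be normalized later.
#' @param epoch numeric length-2: start and end of the reference NREM epoch
#'   in seconds.
#' @param tag quantity tag recorded in the result (e.g. `"ripple-power"`).
#' @param min_duration minimum epoch length in seconds (default 30).
#' @return a `baseline_stats` object.
#' @export
compute_baseline_stats <- function(quantity, epoch, tag = "quantity",
                                   min_duration = 30) {
  stopifnot(inherits(quantity, "time_series"), length(epoch) == 2)
  if (diff(epoch) < min_duration)
    stop(sprintf("baseline epoch shorter than %g s", min_duration))
  w <- ts_window(quantity, epoch[1], epoch[2])
  m <- mean(w$values)
  s <- stats::sd(w$values)
  if (!is.finite(s) || s <= 0)
    stop("baseline epoch is constant: sd = 0")
  baseline_stats(m, s, epoch, tag)
}

#' z-score a series against baseline statistics
#'
#' Pointwise `(value - mean) / sd` with the mean and SD of the reference
#' NREM epoch, the normalization used for every detection threshold.
#'
#' @param quantity `time_series` to normalize.
#' @param stats a `baseline_stats` object.
#' @param tag optional tag; when given it must match `stats$tag`.
#' @return `time_series` in z units.
#' @export
zscore <- function(quantity, stats, tag = NULL) {
  stopifnot(inherits(quantity, "time_series"),
            inherits(stats, "baseline_stats"))
  if (!is.null(tag) && !identical(tag, stats$tag))
    stop(sprintf("tag mismatch: quantity '%s' vs baseline '%s'",
                 tag, stats$tag))
  time_series((quantity$values - stats$mean) / stats$sd,
              quantity$fs, quantity$start_time, units = "z",
              validate = FALSE)
}

theta_delta_ratio <- function(lfp, veto_fs = 64) {
  dec <- as.integer(round(lfp$fs / veto_fs))
  taps <- next_odd(3 * lfp$fs / 25)
  b <- signal::fir1(taps - 1L, 25 / (lfp$fs / 2), type = "low",
                    window = signal::hanning(taps))
  low <- conv_centered(lfp$values, as.numeric(b))[seq(1L, length(lfp$values),
                                                      by = dec)]
  lowts <- time_series(low, lfp$fs / dec, lfp$start_time, lfp$units,
                       validate = FALSE)
  th <- instantaneous_power(bandpass_zero_phase(
    lowts, fir_bandpass(band_definition("theta", 6, 10), lowts$fs)))
  de <- instantaneous_power(bandpass_zero_phase(
    lowts, fir_bandpass(band_definition("delta", 1, 4), lowts$fs)))
  list(theta = th, delta = de)
}

#' Select a representative quiet (NREM-like) baseline epoch
#'
#' Scans candidate windows of length `min_duration` (1 s steps) and returns
#' the one minimizing mean EMG power, subject to a theta-dominance veto: a
#' window is disqualified when its 6-10 Hz LFP power exceeds its 1-4 Hz
#' power (exploratory theta activity). Ties go to the earliest window. This
#' is a deterministic proxy for manual NREM identification and can be
#' overridden with an explicit epoch in the run configuration.
#'
#' @param emg_power `time_series` of instantaneous EMG-band power (raw, not
#'   z-scored).
#' @param lfp broadband LFP `time_series` used for the theta veto.
#' @param min_duration epoch length in seconds (default 60).
#' @param allowed optional data.frame (start, end) of intervals the epoch
#'   must lie within (e.g. the normothermic pre-induction span; post-ictal
#'   quiet is not representative NREM).
#' @return numeric length-2: epoch start and end (s).
#' @export
select_baseline_epoch <- function(emg_power, lfp, min_duration = 60,
                                  allowed = NULL) {
  stopifnot(inherits(emg_power, "time_series"))
  dur <- ts_duration(emg_power)
  if (dur < min_duration) stop("recording shorter than the baseline window")
  starts <- seq(0, floor(dur - min_duration), by = 1)
  if (!is.null(allowed) && nrow(allowed) > 0) {
    fits <- vapply(starts, function(s)
      any(s >= allowed$start & s + min_duration <= allowed$end), logical(1))
    starts <- starts[fits]
    if (length(starts) == 0)
      stop("no quiet baseline window found; supply a manual epoch in config")
  }
  k <- as.integer(round(min_duration * emg_power$fs))
  cs <- c(0, cumsum(emg_power$values))
  i0 <- as.integer(round(starts * emg_power$fs)) + 1L
  emg_mean <- (cs[pmin(i0 + k, length(cs))] - cs[i0]) / k
  td <- theta_delta_ratio(lfp)
  kf <- as.integer(round(min_duration * td$theta$fs))
  cth <- c(0, cumsum(td$theta$values)); cde <- c(0, cumsum(td$delta$values))
  j0 <- as.integer(round(starts * td$theta$fs)) + 1L
  j1 <- pmin(j0 + kf, length(cth))
  ratio <- (cth[j1] - cth[j0]) / pmax(cde[j1] - cde[j0], .Machine$double.eps)
  ok <- ratio < 1
  if (!any(ok))
    stop("no quiet baseline window found; supply a manual epoch in config")
  best <- which(ok)[which.min(emg_mean[ok])]
  c(starts[best], starts[best] + min_duration)
}

#' Classify behavioral state from z-scored EMG power
#'
#' Samples whose smoothed EMG power z exceeds the state threshold are
#' labelled active exploration; everything else is pooled awake immobility /
#' NREM. Power is smoothed with a centered moving average (`state_smooth`
#' seconds) before thresholding, and any resulting segment shorter than
#' `min_state_segment` is absorbed into its neighbors (shortest first,
#' earliest on ties), so the output tiles the record with half-open
#' intervals.
#'
#' @param emg_z_power `time_series` of EMG power z-scored against the NREM
#'   baseline.
#' @param params a `detection_params`.
#' @return a `state_segments` data.frame.
#' @export
classify_behavioral_state <- function(emg_z_power, params = detection_params()) {
  stopifnot(inherits(emg_z_power, "time_series"))
  fs <- emg_z_power$fs
  sm <- moving_average(emg_z_power$values,
                       next_odd(params$state_smooth * fs))
  active <- sm > params$emg_state_threshold
  min_n <- as.integer(round(params$min_state_segment * fs))
  # two-phase absorption: first drop sub-minimum active runs (a brief EMG
  # transient such as a myoclonic jerk is not exploration), then fill
  # sub-minimum immobile gaps inside genuine exploration
  for (phase in c(TRUE, FALSE)) {
    r <- rle(active)
    repeat {
      short <- which(r$values == phase & r$lengths < min_n)
      if (length(short) == 0L || length(r$lengths) == 1L) break
      i <- short[which.min(r$lengths[short])]   # earliest shortest
      r$values[i] <- !r$values[i]
      active <- inverse.rle(r)
      r <- rle(active)
    }
  }
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- c(0L, ends[-length(ends)])
  t0 <- emg_z_power$start_time
  state_segments(t0 + starts / fs, t0 + ends / fs,
                 ifelse(r$values, "active", "immobile_nrem"))
}
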