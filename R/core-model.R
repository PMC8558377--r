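#' Uniformly sampled time series
#'
#' Lightweight container for a uniformly sampled signal: a numeric vector of
#' values, a sampling rate in Hz, a start time in seconds from recording
#' onset, and a units tag (`"uV"`, `"degC"`, `"z"`, `"uV2"`, ...).
#'
#' @param values numeric vector of samples; must be finite after ingest.
#' @param fs sampling rate in Hz (> 0).
#' @param start_time time of the first sample in seconds (default 0).
#' @param units units label for the samples.
#' @param validate check finiteness of values (disable for internal calls).
#' @return object of class `time_series`.
#' @export
time_series <- function(values, fs, start_time = 0, units = "uV",
                        validate = TRUE) {
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("sampling rate must be a single positive number")
  values <- as.numeric(values)
  if (validate && anyNA(values)) stop("time series contains NA values")
  if (validate && any(!is.finite(values)))
    stop("time series contains non-finite values")
  structure(list(values = values, fs = fs,
                 start_time = as.numeric(start_time), units = units),
            class = "time_series")
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("<time_series> %d samples @ %g Hz, start %.3f s, units %s\n",
              length(x$values), x$fs, x$start_time, x$units))
  invisible(x)
}

#' @export
length.time_series <- function(x) length(x$values)

#' Duration of a time series in seconds
#' @param x a `time_series`.
#' @return duration in seconds (n / fs).
#' @export
ts_duration <- function(x) length(x$values) / x$fs

#' Sample times of a time series
#' @param x a `time_series`.
#' @return numeric vector of absolute times (s) for each sample.
#' @export
ts_times <- function(x) x$start_time + (seq_along(x$values) - 1L) / x$fs

#' End time of a time series
#' @param x a `time_series`.
#' @return time just past the last sample (s), i.e. start + n/fs.
#' @export
ts_end <- function(x) x$start_time + length(x$values) / x$fs

#' Extract a half-open time window [from, to) from a time series
#' @param x a `time_series`.
#' @param from,to window bounds in seconds (absolute time).
#' @return a `time_series` covering the requested window.
#' @export
ts_window <- function(x, from, to) {
  if (to <= from) stop("window end must exceed start")
  i0 <- ceiling((from - x$start_time) * x$fs - 1e-9) + 1
  i1 <- ceiling((to - x$start_time) * x$fs - 1e-9)
  i0 <- max(1L, as.integer(i0)); i1 <- min(length(x$values), as.integer(i1))
  if (i1 < i0) stop("window contains no samples")
  time_series(x$values[i0:i1], x$fs,
              start_time = x$start_time + (i0 - 1L) / x$fs,
              units = x$units, validate = FALSE)
}

#' Index of the sample nearest to a given time
#' @param x a `time_series`.
#' @param t time(s) in seconds.
#' @return integer index (vectorized), clipped to the valid range.
#' @export
ts_index_at <- function(x, t) {
  i <- round((t - x$start_time) * x$fs) + 1L
  pmin(pmax(as.integer(i), 1L), length(x$values))
}

#' Value of the sample nearest to a given time
#' @param x a `time_series`.
#' @param t time(s) in seconds.
#' @return sample value(s) at the nearest index.
#' @export
ts_value_at <- function(x, t) x$values[ts_index_at(x, t)]

#' Frequency band definition
#'
#' @param name band label (e.g. `"ripple"`).
#' @param low,high band edges in Hz, 0 < low < high.
#' @return object of class `band_definition`.
#' @export
band_definition <- function(name, low, high) {
  if (!(low > 0 && high > low)) stop("require 0 < low < high")
  structure(list(name = name, low = low, high = high),
            class = "band_definition")
}

#' Standard analysis bands
#'
#' Ripple 100-260 Hz, sharp wave 10-20 Hz, EMG 200-700 Hz.
#' @return named list of `band_definition` objects.
#' @export
default_bands <- function() {
  list(ripple = band_definition("ripple", 100, 260),
       spw    = band_definition("spw", 10, 20),
       emg    = band_definition("emg", 200, 700))
}

#' Multi-channel session recording
#'
#' Container for one thermal-induction session: LFP channels and EMG
#' channels in microvolts at a common electrophysiology rate (2048 Hz after
#' preprocessing), a core body temperature trace in degrees C at 10 Hz, and
#' typed annotations (e.g. `gtc_onset`).
#'
#' @param lfp named list of `time_series` (LFP channels, uV).
#' @param emg named list of `time_series` (EMG channels, uV).
#' @param temperature `time_series` in degC (may be NULL only for raw
#'   interchange ingest; all thermal analyses require it).
#' @param annotations named list of numeric time markers in seconds.
#' @param subject_id subject identifier.
#' @param genotype `"WT"` or `"DS"`.
#' @return object of class `recording`.
#' @export
recording <- function(lfp, emg, temperature = NULL, annotations = list(),
                      subject_id = "subject", genotype = c("WT", "DS")) {
  genotype <- match.arg(genotype)
  if (is.null(names(lfp)) || is.null(names(emg)))
    stop("lfp and emg channel lists must be named")
  chans <- c(lfp, emg)
  if (length(chans) == 0L) stop("at least one electrophysiology channel")
  fs <- vapply(chans, function(ch) ch$fs, numeric(1))
  ns <- vapply(chans, function(ch) length(ch$values), numeric(1))
  if (length(unique(fs)) != 1L)
    stop("all electrophysiology channels must share one sampling rate")
  if (length(unique(ns)) != 1L)
    stop(sprintf("channel length mismatch: %s",
                 paste(sprintf("%s=%d", names(chans), ns), collapse = ", ")))
  dur <- ns[[1]] / fs[[1]]
  if (!is.null(temperature)) {
    stopifnot(inherits(temperature, "time_series"))
    if (ts_end(temperature) + 1 / temperature$fs < dur - 1e-9)
      stop("temperature trace must cover the electrophysiology span")
  }
  structure(list(lfp = lfp, emg = emg, temperature = temperature,
                 annotations = annotations, subject_id = subject_id,
                 genotype = genotype),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> subject %s (%s): %d LFP + %d EMG @ %g Hz, %.1f s%s\n",
              x$subject_id, x$genotype, length(x$lfp), length(x$emg),
              x$lfp[[1]]$fs, rec_duration(x),
              if (is.null(x$temperature)) ", no temperature" else ""))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec a `recording`.
#' @return duration (s) of the electrophysiology channels.
#' @export
rec_duration <- function(rec) ts_duration(rec$lfp[[1]])

#' Baseline statistics from a reference NREM epoch
#'
#' Mean and standard deviation of one normalized quantity over a reference
#' epoch of NREM sleep / quiet immobility; anchors all z-scoring.
#'
#' @param mean,sd epoch mean and standard deviation (sd > 0).
#' @param epoch numeric length-2, epoch start/end in seconds.
#' @param tag quantity tag, e.g. `"ripple-power"`, `"lfp-amplitude"`.
#' @return object of class `baseline_stats`.
#' @export
baseline_stats <- function(mean, sd, epoch, tag) {
  if (!is.finite(sd) || sd <= 0) stop("baseline sd must be positive")
  structure(list(mean = mean, sd = sd, epoch = as.numeric(epoch), tag = tag),
            class = "baseline_stats")
}

#' Detection parameters
#'
#' All thresholds used by the ripple and discharge detectors, in baseline
#' standard-deviation (z) units unless noted.
#'
#' @param ripple_power_threshold z threshold on ripple-band power (default 3).
#' @param spike_amp_threshold z threshold on LFP amplitude (default 1).
#' @param spike_deriv_threshold z threshold on the LFP first derivative
#'   (default 5).
#' @param emg_state_threshold z threshold on smoothed EMG power separating
#'   active exploration from immobility (default 1.5; meaningful range 1-2).
#' @param cycle_period_min,cycle_period_max accepted inter-trough interval in
#'   ms (defaults 4 and 10, i.e. ripple cycles at 100-250 Hz).
#' @param emg_window EMG averaging window around a spike, ms (default 100).
#' @param emg_ratio_threshold post/pre EMG power ratio above which a spike is
#'   classified myoclonic (default 2, strict).
#' @param alignment_temperature anchor for seizure-free sessions, degC
#'   (default 38.5).
#' @param max_temperature thermal-induction cap, degC (default 40).
#' @param spw_split_temperature split for the sharp-wave amplitude paired
#'   comparison, degC (default 38).
#' @param envelope_threshold z level to which candidate epochs are extended
#'   around each supra-threshold crossing (default 0.5).
#' @param merge_gap gap below which candidate epochs are merged, s
#'   (default 0.02).
#' @param min_troughs minimum accepted troughs per ripple event (default 4).
#' @param trough_depth_frac fraction of the deepest trough a local minimum
#'   must reach to count as a ripple cycle (default 0.3); shallower minima
#'   inside a candidate epoch are band noise, not cycles.
#' @param spike_dead_time one discharge per this window, s (default 0.1).
#' @param state_smooth EMG power smoothing window for state classification,
#'   s (default 0.2).
#' @param min_state_segment shortest allowed behavioral-state segment, s
#'   (default 0.5).
#' @param baseline_min_duration minimum baseline epoch, s (default 60).
#' @param gtc_guard exclusion guard around GTC onset, s (default 2).
#' @param power_smooth moving-average window applied to ripple-band
#'   instantaneous power before z-scoring, s (default 0.02, about three
#'   ripple cycles).
#' @param gtc_smooth smoothing window for the broadband power traces used
#'   for seizure localization, s (default 1).
#' @param gtc_z_threshold z level both LFP and EMG power must exceed for a
#'   GTC (default 5).
#' @param gtc_sustain minimum duration of the sustained crossing, s
#'   (default 5).
#' @param morphology_min_amp minimum |amplitude z| an accepted discharge
#'   must reach (default 8). Candidates below it have background or
#'   sharp-wave morphology rather than epileptiform morphology (a stepped
#'   sharp wave with a superimposed ripple trough reaches about 7.5 z,
#'   genuine discharges 13+) and are flagged artifact; this is the
#'   deterministic stand-in for manual review of "unusual morphology".
#' @param deriv_lowpass cutoff (Hz) of the low-pass applied to the LFP
#'   before the first-derivative trace used for discharge detection
#'   (default 70, keeping the steep epileptiform deflection while
#'   excluding ripple-band oscillation).
#' @return object of class `detection_params`.
#' @export
detection_params <- function(ripple_power_threshold = 3,
                             spike_amp_threshold = 1,
                             spike_deriv_threshold = 5,
                             emg_state_threshold = 1.5,
                             cycle_period_min = 4,
                             cycle_period_max = 10,
                             emg_window = 100,
                             emg_ratio_threshold = 2,
                             alignment_temperature = 38.5,
                             max_temperature = 40,
                             spw_split_temperature = 38,
                             envelope_threshold = 0.5,
                             merge_gap = 0.02,
                             min_troughs = 4,
                             trough_depth_frac = 0.3,
                             spike_dead_time = 0.1,
                             state_smooth = 0.2,
                             min_state_segment = 0.5,
                             baseline_min_duration = 60,
                             gtc_guard = 2,
                             power_smooth = 0.02,
                             gtc_smooth = 1,
                             gtc_z_threshold = 5,
                             gtc_sustain = 5,
                             morphology_min_amp = 8,
                             deriv_lowpass = 70) {
  p <- list(ripple_power_threshold = ripple_power_threshold,
            spike_amp_threshold = spike_amp_threshold,
            spike_deriv_threshold = spike_deriv_threshold,
            emg_state_threshold = emg_state_threshold,
            cycle_period_min = cycle_period_min,
            cycle_period_max = cycle_period_max,
            emg_window = emg_window,
            emg_ratio_threshold = emg_ratio_threshold,
            alignment_temperature = alignment_temperature,
            max_temperature = max_temperature,
            spw_split_temperature = spw_split_temperature,
            envelope_threshold = envelope_threshold,
            merge_gap = merge_gap,
            min_troughs = min_troughs,
            trough_depth_frac = trough_depth_frac,
            spike_dead_time = spike_dead_time,
            state_smooth = state_smooth,
            min_state_segment = min_state_segment,
            baseline_min_duration = baseline_min_duration,
            gtc_guard = gtc_guard,
            power_smooth = power_smooth,
            gtc_smooth = gtc_smooth,
            gtc_z_threshold = gtc_z_threshold,
            gtc_sustain = gtc_sustain,
            morphology_min_amp = morphology_min_amp,
            deriv_lowpass = deriv_lowpass)
  thr <- c("ripple_power_threshold", "spike_amp_threshold",
           "spike_deriv_threshold", "emg_state_threshold",
           "cycle_period_min", "cycle_period_max", "emg_window",
           "emg_ratio_threshold")
  for (nm in thr)
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0)
      stop(sprintf("detection parameter %s must be positive", nm))
  if (p$cycle_period_min >= p$cycle_period_max)
    stop("cycle_period_min must be below cycle_period_max")
  structure(p, class = "detection_params")
}

#' Behavioral-state segments
#'
#' Non-overlapping, ordered intervals labelled `active` (exploration) or
#' `immobile_nrem` (awake immobility pooled with NREM sleep), tiling the
#' recording with half-open intervals [start, end).
#'
#' @param start,end numeric vectors of interval bounds in seconds.
#' @param label character vector in `c("active", "immobile_nrem")`.
#' @return data.frame of class `state_segments`.
#' @export
state_segments <- function(start, end, label) {
  stopifnot(length(start) == length(end), length(end) == length(label))
  if (any(!label %in% c("active", "immobile_nrem")))
    stop("labels must be 'active' or 'immobile_nrem'")
  if (length(start) > 0) {
    if (any(end <= start)) stop("segments must have positive length")
    if (is.unsorted(start)) stop("segments must be ordered")
    if (length(start) > 1 && any(abs(start[-1] - end[-length(end)]) > 1e-9))
      stop("segments must tile the recording without gaps or overlap")
  }
  structure(data.frame(start = start, end = end, label = label,
                       stringsAsFactors = FALSE),
            class = c("state_segments", "data.frame"))
}

#' Segments of a given state label
#' @param states a `state_segments` object.
#' @param label state label to keep.
#' @return data.frame with columns start, end.
#' @export
state_intervals <- function(states, label = "immobile_nrem") {
  states[states$label == label, c("start", "end"), drop = FALSE]
}

ripple_event_cols <- c("start", "end", "frequency", "n_cycles",
                       "ripple_power_avg", "ripple_power_max",
                       "spw_power_avg", "spw_power_max", "temperature",
                       "burst_id", "trough_times", "peak_times")

epileptic_event_cols <- c("trough_time", "event_class", "amplitude",
                          "emg_power_pre", "emg_power_post", "emg_ratio",
                          "temperature")

#' Empty ripple-event table
#'
#' One row per detected SPW-R. `start`/`end` are the first and last accepted
#' trough times (s); `frequency` is the internal ripple frequency (Hz) from
#' middle-cycle inter-trough intervals; power features are z-scored Hilbert
#' powers; `trough_times`/`peak_times` are list columns of cycle times.
#' @return zero-row data.frame with ripple-event columns.
#' @export
empty_ripple_events <- function() {
  df <- data.frame(start = numeric(0), end = numeric(0),
                   frequency = numeric(0), n_cycles = integer(0),
                   ripple_power_avg = numeric(0), ripple_power_max = numeric(0),
                   spw_power_avg = numeric(0), spw_power_max = numeric(0),
                   temperature = numeric(0), burst_id = integer(0))
  df$trough_times <- list(); df$peak_times <- list()
  class(df) <- c("ripple_events", "data.frame")
  df
}

#' Empty epileptic-event table
#'
#' One row per detected discharge, aligned to the largest-|z| extremum
#' (`trough_time`, s). `event_class` is one of `interictal_spike`,
#' `myoclonic`, `artifact`, `gtc`, `unclassified`; `emg_ratio` is the
#' post/pre EMG power ratio used for myoclonus discrimination.
#' @return zero-row data.frame with epileptic-event columns.
#' @export
empty_epileptic_events <- function() {
  df <- data.frame(trough_time = numeric(0),
                   event_class = character(0), amplitude = numeric(0),
                   emg_power_pre = numeric(0), emg_power_post = numeric(0),
                   emg_ratio = numeric(0), temperature = numeric(0),
                   stringsAsFactors = FALSE)
  class(df) <- c("epileptic_events", "data.frame")
  df
}

event_table_type <- function(events) {
  if (inherits(events, "ripple_events") ||
      all(ripple_event_cols %in% names(events))) return("ripple")
  if (inherits(events, "epileptic_events") ||
      all(epileptic_event_cols %in% names(events))) return("epileptic")
  stop("not a recognized event table")
}
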