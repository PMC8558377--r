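#' Detect candidate epileptiform discharges
#'
#' A discharge candidate is any sample where the broadband LFP amplitude
#' exceeds the amplitude threshold (|z| > 1) and, simultaneously, the first
#' derivative exceeds the slope threshold (|z| > 5). Thresholds are
#' polarity-agnostic because depth-electrode polarity varies with electrode
#' position. Seed samples within one dead time (100 ms) of each other
#' collapse to a single event aligned to the largest-|z| amplitude
#' extremum.
#'
#' @param lfp_z broadband LFP amplitude in z units.
#' @param lfp_deriv_z central-difference first derivative in z units.
#' @param params a `detection_params`.
#' @param temperature optional temperature `time_series` to annotate events.
#' @return an `epileptic_events` data.frame (classes `unclassified`).
#' @export
detect_spike_candidates <- function(lfp_z, lfp_deriv_z,
                                    params = detection_params(),
                                    temperature = NULL) {
  stopifnot(inherits(lfp_z, "time_series"))
  z <- lfp_z$values
  fs <- lfp_z$fs
  seed <- which(abs(z) > params$spike_amp_threshold &
                abs(lfp_deriv_z$values) > params$spike_deriv_threshold)
  out <- empty_epileptic_events()
  if (length(seed) == 0) return(out)
  gap <- c(Inf, diff(seed)) / fs
  grp <- cumsum(gap > params$spike_dead_time)
  rows <- lapply(split(seed, grp), function(ix) {
    span <- ix[1]:ix[length(ix)]
    j <- span[which.max(abs(z[span]))]
    data.frame(trough_time = lfp_z$start_time + (j - 1) / fs,
               event_class = "unclassified",
               amplitude = z[j],
               emg_power_pre = NA_real_, emg_power_post = NA_real_,
               emg_ratio = NA_real_,
               temperature = NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(temperature))
    out$temperature <- ts_value_at(temperature, out$trough_time)
  class(out) <- c("epileptic_events", "data.frame")
  out
}

#' Classify discharges as myoclonic or interictal by EMG power ratio
#'
#' Mean normalized EMG power is measured in the 100 ms windows before and
#' after each spike extremum. A post/pre ratio above the threshold (strictly
#' greater than 2) is consistent with a myoclonic jerk; otherwise the event
#' is an interictal spike. Because z scores can be zero or negative, both
#' window means are re-centered by +1 z (the baseline SD) and floored at
#' 0.01 before the ratio, so quiet EMG yields a ratio near 1 and the
#' classification is invariant to global EMG gain. Events closer than one
#' window to the record edge are left unclassified with a warning.
#'
#' @param events an `epileptic_events` data.frame.
#' @param emg_z_power EMG instantaneous power in z units.
#' @param params a `detection_params`.
#' @return the events with classes and EMG fields filled in.
#' @export
classify_myoclonic <- function(events, emg_z_power,
                               params = detection_params()) {
  if (nrow(events) == 0) return(events)
  w <- params$emg_window / 1000
  zt <- emg_z_power
  lo <- zt$start_time
  hi <- ts_end(zt)
  edge <- events$trough_time - w < lo | events$trough_time + w > hi
  if (any(edge))
    warning(sprintf("%d event(s) within %g ms of the record edge left unclassified",
                    sum(edge), params$emg_window))
  for (i in which(!edge & events$event_class != "artifact")) {
    t <- events$trough_time[i]
    pre <- mean(ts_window(zt, t - w, t)$values)
    post <- mean(ts_window(zt, t, t + w)$values)
    ratio <- max(post + 1, 0.01) / max(pre + 1, 0.01)
    events$emg_power_pre[i] <- pre
    events$emg_power_post[i] <- post
    events$emg_ratio[i] <- ratio
    events$event_class[i] <- if (ratio > params$emg_ratio_threshold)
      "myoclonic" else "interictal_spike"
  }
  events
}

emg_elevated_before <- function(emg_z, t, threshold, min_dur, lead = 0.15) {
  # sustained elevated EMG (>= min_dur) that begins clearly before time t
  # and is still elevated at t. The lead margin exceeds the smoothing
  # half-window, so a spike-triggered burst (which starts at the spike and
  # is smeared backward by centered smoothing) does not count as
  # pre-existing movement.
  iv <- runs_to_intervals(emg_z$values > threshold, emg_z$fs,
                          emg_z$start_time)
  if (nrow(iv) == 0) return(FALSE)
  any(iv$start < t - lead & iv$end >= t & (iv$end - iv$start) >= min_dur)
}

#' Flag artifact discharges
#'
#' Deterministic stand-in for manual artifact review: an event is flagged
#' `artifact` when (a) coincident supra-threshold deflections appear on at
#' least two LFP channels together with sustained (>= 250 ms) elevated EMG
#' that begins before the spike, (b) the event lies inside an
#' active-exploration segment, or (c) its aligned amplitude extremum stays
#' below `morphology_min_amp` SD -- the morphology of a background or
#' sharp-wave deflection whose derivative grazed the threshold, not of an
#' epileptiform discharge. A CSV of manual verdicts (columns `time`,
#' `verdict` with values `artifact`/`keep`), matched within 10 ms, takes
#' precedence over all rules.
#'
#' @param events an `epileptic_events` data.frame.
#' @param prep a `preprocessed_session` (provides all LFP channels, EMG and
#'   states).
#' @param params a `detection_params`.
#' @param overrides optional data.frame of manual verdicts.
#' @return the events with artifact classes assigned.
#' @export
reject_artifacts <- function(events, prep, params = detection_params(),
                             overrides = NULL) {
  if (nrow(events) == 0) return(events)
  active <- state_intervals(prep$states, "active")
  smoothed_emg <- smooth_ts(prep$emg_z_power,
                            params$state_smooth)
  co_win <- 0.010
  for (i in seq_len(nrow(events))) {
    t <- events$trough_time[i]
    in_active <- nrow(active) > 0 && any(t >= active$start & t < active$end)
    multi <- sum(vapply(prep$lfp_z_all, function(zch) {
      w <- ts_window(zch, max(zch$start_time, t - co_win),
                     min(ts_end(zch), t + co_win))
      max(abs(w$values)) > params$spike_amp_threshold
    }, logical(1))) >= 2
    sustained <- emg_elevated_before(smoothed_emg, t,
                                     params$emg_state_threshold, 0.25)
    low_morph <- abs(events$amplitude[i]) < params$morphology_min_amp
    if (in_active || low_morph || (multi && sustained))
      events$event_class[i] <- "artifact"
  }
  if (!is.null(overrides) && nrow(overrides) > 0) {
    for (j in seq_len(nrow(overrides))) {
      d <- abs(events$trough_time - overrides$time[j])
      i <- which.min(d)
      if (length(i) && d[i] <= 0.010) {
        events$event_class[i] <- if (overrides$verdict[j] == "artifact")
          "artifact" else "unclassified"
      }
    }
  }
  events
}

locate_gtc_span <- function(prep, params = detection_params()) {
  mask <- prep$broadband_z_power$values > params$gtc_z_threshold &
          prep$emg_slow_z_power$values > params$gtc_z_threshold
  iv <- runs_to_intervals(mask, prep$broadband_z_power$fs,
                          prep$broadband_z_power$start_time)
  iv <- iv[iv$end - iv$start >= params$gtc_sustain, , drop = FALSE]
  if (nrow(iv) == 0) return(NULL)
  c(iv$start[1], iv$end[1])
}

#' Locate generalized tonic-clonic seizure onset
#'
#' Returns the annotated `gtc_onset` when the recording carries one.
#' Otherwise the onset is the start of the first period of at least 5 s in
#' which both smoothed broadband LFP power and EMG power stay above 5 z.
#' Returns NA when neither is available (e.g. WT sessions, which never
#' seize).
#'
#' @param prep a `preprocessed_session`.
#' @param params a `detection_params`.
#' @return onset time in seconds, or NA.
#' @export
locate_gtc <- function(prep, params = detection_params()) {
  ann <- prep$annotations
  if (!is.null(ann$gtc_onset)) return(as.numeric(ann$gtc_onset))
  span <- locate_gtc_span(prep, params)
  if (is.null(span)) NA_real_ else span[1]
}

#' Average traces around event times
#'
#' Mean across events of each supplied trace in a symmetric window around
#' the event extremum, the construction behind spike-aligned grand-average
#' LFP and EMG panels.
#'
#' @param traces named list of `time_series`.
#' @param events an `epileptic_events` data.frame or numeric event times.
#' @param window half-window in seconds.
#' @return named list of data.frames (`time` relative to the event, `mean`).
#' @export
peri_event_average <- function(traces, events, window) {
  times <- if (is.data.frame(events)) events$trough_time else as.numeric(events)
  lapply(traces, function(tr) {
    k <- as.integer(round(window * tr$fs))
    centers <- ts_index_at(tr, times)
    ok <- centers - k >= 1 & centers + k <= length(tr$values)
    if (!any(ok)) stop("no event window lies fully inside the record")
    rel <- -k:k
    m <- rowMeans(vapply(centers[ok], function(c0) tr$values[c0 + rel],
                         numeric(2L * k + 1L)))
    data.frame(time = rel / tr$fs, mean = m)
  })
}

#' Detect and classify epileptiform discharges in a session
#'
#' Orchestrates candidate detection, myoclonus classification, artifact
#' rejection and GTC localization. Discharges inside the GTC span plus a
#' +/- 2 s guard are reclassified `gtc` and excluded from interictal
#' statistics.
#'
#' @param prep a `preprocessed_session`.
#' @param params a `detection_params`.
#' @param overrides optional manual artifact verdicts (see
#'   [reject_artifacts()]).
#' @return list of class `epileptic_detection`: `events`, `gtc_onset`
#'   (NA when absent) and `gtc_span`.
#' @export
detect_epileptic <- function(prep, params = detection_params(),
                             overrides = NULL) {
  ev <- detect_spike_candidates(prep$lfp_z, prep$deriv_z, params,
                                temperature = prep$temperature)
  ev <- reject_artifacts(ev, prep, params, overrides)
  ev <- classify_myoclonic(ev, prep$emg_z_power, params)
  gtc_onset <- locate_gtc(prep, params)
  gtc_span <- locate_gtc_span(prep, params)
  if (is.null(gtc_span) && !is.na(gtc_onset))
    gtc_span <- c(gtc_onset, gtc_onset)
  if (!is.null(gtc_span) && nrow(ev) > 0) {
    g <- params$gtc_guard
    inside <- ev$trough_time >= gtc_span[1] - g &
              ev$trough_time <= gtc_span[2] + g
    ev$event_class[inside] <- "gtc"
  }
  structure(list(events = ev, gtc_onset = gtc_onset, gtc_span = gtc_span),
            class = "epileptic_detection")
}

#' Exclusion intervals implied by detected discharges
#'
#' Non-artifact discharges (plus the GTC span with its guard) define
#' intervals that the SPW-R detector must skip: an epileptiform transient
#' also carries broadband power in the ripple band and would otherwise be
#' double-counted as a ripple.
#'
#' @param det an `epileptic_detection`.
#' @param params a `detection_params`.
#' @param half_width half-width of the guard around each discharge, s
#'   (default one dead time, 0.1 s).
#' @return data.frame with columns start, end.
#' @export
epileptic_exclusion_intervals <- function(det, params = detection_params(),
                                          half_width = NULL) {
  if (is.null(half_width)) half_width <- params$spike_dead_time
  ev <- det$events
  keep <- ev$event_class != "artifact"
  iv <- data.frame(start = ev$trough_time[keep] - half_width,
                   end = ev$trough_time[keep] + half_width)
  if (!is.null(det$gtc_span))
    iv <- rbind(iv, data.frame(start = det$gtc_span[1] - params$gtc_guard,
                               end = det$gtc_span[2] + params$gtc_guard))
  iv[order(iv$start), , drop = FALSE]
}
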