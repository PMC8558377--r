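# Temperature bins are [center - w/2, center + w/2) with centers at integer
# multiples of the width anchored at 36.0 degC.
temp_bin_center <- function(temp, width) {
  36 + width * floor((temp - 36 + width / 2) / width)
}

in_intervals <- function(t, iv) {
  if (is.null(iv)) return(rep(TRUE, length(t)))
  out <- rep(FALSE, length(t))
  for (i in seq_len(nrow(iv)))
    out <- out | (t >= iv$start[i] & t < iv$end[i])
  out
}

#' Dwell-time-normalized event rates in temperature bins
#'
#' The rate in each bin is the number of events whose temperature falls in
#' the bin divided by the time spent at that temperature (dwell time, from
#' the 10 Hz temperature trace), optionally restricted to analysis
#' intervals (pre-ictal immobility). Bins with zero dwell are flagged
#' undefined rather than zero-filled.
#'
#' @param events data.frame with `temperature` and a time column
#'   (`start` or `trough_time`), or a numeric vector of event temperatures.
#' @param temperature temperature `time_series` (degC).
#' @param bin_width bin width in degC (default 0.5).
#' @param restrict optional data.frame (start, end) limiting both dwell and
#'   events to analyzed intervals.
#' @return data.frame: bin_center, bin_width, dwell_time, event_count,
#'   rate, defined.
#' @export
dwell_and_rate <- function(events, temperature, bin_width = 0.5,
                           restrict = NULL) {
  stopifnot(inherits(temperature, "time_series"))
  tt <- ts_times(temperature)
  keep <- in_intervals(tt, restrict)
  dwell_bins <- temp_bin_center(temperature$values[keep], bin_width)
  dwell <- table(dwell_bins) / temperature$fs
  if (is.data.frame(events)) {
    tcol <- if ("start" %in% names(events)) "start" else "trough_time"
    ev_keep <- in_intervals(events[[tcol]], restrict)
    ev_temp <- events$temperature[ev_keep]
  } else {
    ev_temp <- as.numeric(events)
  }
  ev_bins <- temp_bin_center(ev_temp, bin_width)
  centers <- sort(unique(c(as.numeric(names(dwell)), ev_bins)))
  out <- data.frame(
    bin_center = centers,
    bin_width = bin_width,
    dwell_time = as.numeric(dwell[as.character(centers)]),
    event_count = as.integer(table(factor(ev_bins, levels = centers))))
  out$dwell_time[is.na(out$dwell_time)] <- 0
  out$defined <- out$dwell_time > 0
  out$rate <- ifelse(out$defined, out$event_count / out$dwell_time, NA_real_)
  out[, c("bin_center", "bin_width", "dwell_time", "event_count", "rate",
          "defined")]
}

#' Per-bin mean and SEM of an event feature by temperature
#'
#' @param events event data.frame carrying `temperature` and the feature.
#' @param feature name of the feature column (e.g. `"frequency"`).
#' @param bin_width bin width in degC (default 0.25).
#' @return data.frame: bin_center, mean, sem, n (occupied bins only).
#' @export
feature_by_temperature <- function(events, feature, bin_width = 0.25) {
  stopifnot(feature %in% names(events))
  v <- events[[feature]]
  ok <- is.finite(v) & is.finite(events$temperature)
  v <- v[ok]
  b <- temp_bin_center(events$temperature[ok], bin_width)
  if (length(v) == 0)
    return(data.frame(bin_center = numeric(0), mean = numeric(0),
                      sem = numeric(0), n = integer(0)))
  agg <- lapply(split(v, b), function(g)
    c(mean = mean(g),
      sem = if (length(g) > 1) stats::sd(g) / sqrt(length(g)) else 0,
      n = length(g)))
  centers <- as.numeric(names(agg))
  m <- do.call(rbind, agg)
  data.frame(bin_center = centers, mean = m[, "mean"], sem = m[, "sem"],
             n = as.integer(m[, "n"]), row.names = NULL)
}

#' Welch power spectral density
#'
#' Hanning-windowed segment averaging (0.5 s segments, 50% overlap by
#' default).
#'
#' @param x numeric signal.
#' @param fs sampling rate (Hz).
#' @param seg_dur segment duration, s.
#' @param overlap fractional overlap between segments.
#' @return data.frame with columns freq (Hz) and power.
#' @export
welch_psd <- function(x, fs, seg_dur = 0.5, overlap = 0.5) {
  nseg <- as.integer(round(seg_dur * fs))
  if (length(x) < nseg) stop("signal shorter than one Welch segment")
  step <- max(1L, as.integer(round(nseg * (1 - overlap))))
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))
  starts <- seq(1L, length(x) - nseg + 1L, by = step)
  acc <- numeric(nseg %/% 2L + 1L)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    seg <- (seg - mean(seg)) * w
    P <- Mod(stats::fft(seg))^2 / (fs * sum(w^2))
    acc <- acc + P[seq_len(nseg %/% 2L + 1L)]
  }
  data.frame(freq = (seq_len(nseg %/% 2L + 1L) - 1L) * fs / nseg,
             power = acc / length(starts))
}

gaussian_peak_fit <- function(freq, power) {
  i0 <- which.max(power)
  start <- list(a = max(power) - min(power), mu = freq[i0], s = 20,
                c = min(power))
  fit <- tryCatch(
    minpack.lm::nlsLM(power ~ a * exp(-(freq - mu)^2 / (2 * s^2)) + c,
                      start = start,
                      lower = c(a = 0, mu = min(freq), s = 1, c = -Inf),
                      upper = c(a = Inf, mu = max(freq), s = Inf, c = Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cf <- stats::coef(fit)
  list(mu = unname(cf["mu"]), a = unname(cf["a"]),
       resid_sd = stats::sd(stats::resid(fit)))
}

#' Spectral ripple-frequency estimate per temperature bin
#'
#' Immobility LFP samples are concatenated by temperature in 1 degC bins;
#' each bin's Welch spectrum is fitted with a Gaussian (plus constant
#' offset) over the ripple band, and the fitted center is the bin's ripple
#' frequency. Bins with under 4 s of immobility signal are skipped; fits
#' whose amplitude does not exceed twice the residual SD are flagged as
#' having no significant peak.
#'
#' @param lfp broadband LFP `time_series`.
#' @param temperature temperature `time_series` (degC).
#' @param states `state_segments` (only `immobile_nrem` data are used).
#' @param bin_width bin width in degC (default 1).
#' @param band a `band_definition` (default ripple 100-260 Hz).
#' @param min_seconds minimum immobility signal per bin (default 4).
#' @param restrict optional intervals further limiting the data (pre-ictal).
#' @return data.frame: bin_center, frequency, n_seconds, flagged.
#' @export
spectral_peak_frequency <- function(lfp, temperature, states, bin_width = 1,
                                    band = default_bands()$ripple,
                                    min_seconds = 4, restrict = NULL) {
  tt <- ts_times(lfp)
  keep <- in_intervals(tt, state_intervals(states, "immobile_nrem"))
  if (!is.null(restrict)) keep <- keep & in_intervals(tt, restrict)
  temps <- temperature$values[ts_index_at(temperature, tt)]
  bins <- temp_bin_center(temps, bin_width)
  out <- list()
  for (b in sort(unique(bins[keep]))) {
    x <- lfp$values[keep & bins == b]
    secs <- length(x) / lfp$fs
    if (secs < min_seconds) next
    psd <- welch_psd(x, lfp$fs)
    sl <- psd$freq >= band$low & psd$freq <= band$high
    fit <- gaussian_peak_fit(psd$freq[sl], psd$power[sl])
    flagged <- is.null(fit) || fit$a < 2 * fit$resid_sd
    out[[length(out) + 1L]] <- data.frame(
      bin_center = b,
      frequency = if (is.null(fit)) NA_real_ else fit$mu,
      n_seconds = secs, flagged = flagged)
  }
  if (length(out) == 0)
    return(data.frame(bin_center = numeric(0), frequency = numeric(0),
                      n_seconds = numeric(0), flagged = logical(0)))
  do.call(rbind, out)
}

#' First upward crossing of a temperature
#' @param temperature temperature `time_series`.
#' @param threshold temperature (degC).
#' @return crossing time (s) or NA.
#' @export
temperature_crossing <- function(temperature, threshold) {
  v <- temperature$values
  i <- which(v[-1] >= threshold & v[-length(v)] < threshold)
  if (length(i) == 0) {
    if (v[1] >= threshold) return(temperature$start_time)
    return(NA_real_)
  }
  temperature$start_time + i[1] / temperature$fs
}

#' Align event times or sampled values to a session anchor
#'
#' The anchor is the GTC onset when one exists (seizing DS sessions);
#' otherwise the first upward crossing of the alignment temperature
#' (38.5 degC, the published DS seizure temperature, used for seizure-free
#' WT sessions). Errors when neither anchor is available.
#'
#' @param times numeric event or sample times (s).
#' @param temperature temperature `time_series`.
#' @param params a `detection_params`.
#' @param gtc_onset GTC onset (s) or NA.
#' @param values optional values carried alongside the times.
#' @return list of class `aligned_series`: anchor_type, anchor_time,
#'   relative_times, values.
#' @export
align_to_anchor <- function(times, temperature, params = detection_params(),
                            gtc_onset = NA, values = NULL) {
  if (!is.na(gtc_onset)) {
    anchor <- gtc_onset; type <- "gtc"
  } else {
    anchor <- temperature_crossing(temperature, params$alignment_temperature)
    type <- "temperature_crossing"
    if (is.na(anchor))
      stop("no anchor: no GTC and temperature never reaches the alignment level")
  }
  structure(list(anchor_type = type, anchor_time = anchor,
                 relative_times = times - anchor, values = values),
            class = "aligned_series")
}

#' Temperature at the first event of each discharge class
#'
#' @param events an `epileptic_events` data.frame (with temperatures).
#' @param gtc_onset GTC onset time (s) or NA.
#' @param temperature temperature `time_series` (needed for the GTC class).
#' @param classes discharge classes to report.
#' @return named numeric vector of onset temperatures (NA when a class is
#'   absent).
#' @export
onset_temperatures <- function(events, gtc_onset = NA, temperature = NULL,
                               classes = c("interictal_spike", "myoclonic")) {
  out <- stats::setNames(rep(NA_real_, length(classes) + 1L),
                         c(classes, "gtc"))
  for (cl in classes) {
    sel <- events$event_class == cl
    if (any(sel)) {
      first <- which.min(events$trough_time[sel])
      out[cl] <- events$temperature[sel][first]
    }
  }
  if (!is.na(gtc_onset) && !is.null(temperature))
    out["gtc"] <- ts_value_at(temperature, gtc_onset)
  out
}

#' Peri-event SPW-R rate histogram
#'
#' Counts of SPW-R starts in relative-time bins around trigger events,
#' normalized to events/s by the bin width and the number of triggers.
#' Triggers whose window extends past the record are skipped.
#'
#' @param spwr_times numeric SPW-R start times (s).
#' @param trigger_times numeric trigger times (s).
#' @param bin bin width, s (default 0.25).
#' @param window half-window, s (default 2).
#' @param record_span optional numeric length-2; triggers within `window` of
#'   either end are dropped.
#' @return data.frame: time (bin center, s), count, rate (events/s).
#' @export
peri_event_rate <- function(spwr_times, trigger_times, bin = 0.25,
                            window = 2, record_span = NULL) {
  if (!is.null(record_span))
    trigger_times <- trigger_times[trigger_times - window >= record_span[1] &
                                   trigger_times + window <= record_span[2]]
  if (length(trigger_times) == 0) stop("no usable trigger events")
  edges <- seq(-window, window, by = bin)
  counts <- numeric(length(edges) - 1L)
  for (tr in trigger_times) {
    rel <- spwr_times - tr
    rel <- rel[rel >= -window & rel < window]
    if (length(rel))
      counts <- counts + tabulate(findInterval(rel, edges),
                                  nbins = length(counts))
  }
  data.frame(time = edges[-length(edges)] + bin / 2,
             count = counts,
             rate = counts / (bin * length(trigger_times)))
}

#' Paired pre/post suppression test of SPW-R rate around discharges
#'
#' For each session, the mean SPW-R rate in the 1 s before and the 1 s
#' after its trigger events; a two-sided paired t-test across sessions asks
#' whether the post rate is reduced.
#'
#' @param sessions list; each element a list with `spwr_times` and
#'   `trigger_times` (numeric, s), optionally `record_span`.
#' @param window pre/post window, s (default 1).
#' @return list: per-session `pre` and `post` rates (events/s), `t`, `p`,
#'   `df`.
#' @export
pre_post_rate_test <- function(sessions, window = 1) {
  rates <- vapply(sessions, function(s) {
    trig <- s$trigger_times
    if (!is.null(s$record_span))
      trig <- trig[trig - window >= s$record_span[1] &
                   trig + window <= s$record_span[2]]
    if (length(trig) == 0) return(c(NA_real_, NA_real_))
    pre <- mean(vapply(trig, function(tr)
      sum(s$spwr_times >= tr - window & s$spwr_times < tr), numeric(1)))
    post <- mean(vapply(trig, function(tr)
      sum(s$spwr_times > tr & s$spwr_times <= tr + window), numeric(1)))
    c(pre, post) / window
  }, numeric(2))
  ok <- stats::complete.cases(t(rates))
  if (sum(ok) < 2) stop("need at least 2 sessions with usable triggers")
  d <- rates[2, ok] - rates[1, ok]
  if (stats::sd(d) == 0) {
    # degenerate pairing (e.g. identical pre/post in every session)
    tt <- list(statistic = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
               p.value = if (mean(d) == 0) 1 else 0,
               parameter = length(d) - 1)
  } else {
    tt <- stats::t.test(rates[1, ok], rates[2, ok], paired = TRUE)
  }
  list(pre = rates[1, ok], post = rates[2, ok],
       t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter))
}

#' Paired comparison of sharp-wave amplitude below vs above 38 degC
#'
#' Per-session mean SPW power of detected SPW-R below and at-or-above the
#' split temperature, compared with a paired t-test across sessions.
#' Sessions with events on only one side are excluded with a warning.
#'
#' @param session_events list of `ripple_events` data.frames, one per
#'   session.
#' @param params a `detection_params` (supplies the split temperature).
#' @return list: per-session `below` and `above` means, `t`, `p`, `df`,
#'   `n_sessions`.
#' @export
spw_amplitude_split_test <- function(session_events,
                                     params = detection_params()) {
  split <- params$spw_split_temperature
  m <- vapply(session_events, function(ev) {
    lo <- ev$spw_power_avg[ev$temperature < split]
    hi <- ev$spw_power_avg[ev$temperature >= split]
    c(if (length(lo)) mean(lo) else NA_real_,
      if (length(hi)) mean(hi) else NA_real_)
  }, numeric(2))
  ok <- stats::complete.cases(t(m))
  if (any(!ok))
    warning(sprintf("%d session(s) with events on one side of %g degC excluded",
                    sum(!ok), split))
  if (sum(ok) < 2) stop("need at least 2 two-sided sessions")
  tt <- stats::t.test(m[1, ok], m[2, ok], paired = TRUE)
  list(below = m[1, ok], above = m[2, ok], t = unname(tt$statistic),
       p = tt$p.value, df = unname(tt$parameter), n_sessions = sum(ok))
}

#' Four-parameter logistic trend fit
#'
#' Least-squares fit of `y = floor + (ceiling - floor) / (1 + exp(-(x -
#' midpoint)/scale))`, the sigmoid used to summarize rate-vs-temperature
#' trends. Non-convergent or flat fits are flagged rather than fabricated;
#' the raw points are always returned.
#'
#' @param x,y numeric vectors (at least 5 points).
#' @return list: parameters (floor, ceiling, midpoint, scale), converged,
#'   degenerate, x, y.
#' @export
fit_sigmoid_trend <- function(x, y) {
  if (length(x) < 5) stop("need at least 5 points for a 4-parameter fit")
  st <- list(fl = min(y), ce = max(y), mid = stats::median(x),
             sc = max(diff(range(x)) / 5, 1e-3))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ fl + (ce - fl) / (1 + exp(-(x - mid) / sc)),
                      start = st,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(parameters = NULL, converged = FALSE, degenerate = TRUE,
                x = x, y = y))
  cf <- stats::coef(fit)
  pars <- c(floor = unname(cf["fl"]), ceiling = unname(cf["ce"]),
            midpoint = unname(cf["mid"]), scale = unname(cf["sc"]))
  degen <- abs(pars["ceiling"] - pars["floor"]) <
    max(1e-8, 1e-6 * max(abs(y), 1))
  list(parameters = pars, converged = TRUE, degenerate = unname(degen),
       x = x, y = y)
}

#' Pearson trend and per-subject grand average
#'
#' Standard Pearson correlation with a two-sided test (alpha 0.05 by
#' convention here), plus the grand-average scheme used throughout: the
#' mean of per-subject means with SEM over subjects (events are never
#' pooled across subjects).
#'
#' @param x,y numeric vectors for the correlation (n >= 3).
#' @param per_subject optional numeric vector of per-subject means.
#' @return list: r, p, n, and (when per_subject given) grand_mean, sem,
#'   n_subjects.
#' @export
trend_and_group_stats <- function(x = NULL, y = NULL, per_subject = NULL) {
  out <- list()
  if (!is.null(x)) {
    if (length(x) < 3) stop("need at least 3 points for a correlation")
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      stop("zero variance: correlation undefined")
    ct <- stats::cor.test(x, y, method = "pearson")
    out$r <- unname(ct$estimate)
    out$p <- ct$p.value
    out$n <- length(x)
  }
  if (!is.null(per_subject)) {
    out$grand_mean <- mean(per_subject)
    out$sem <- stats::sd(per_subject) / sqrt(length(per_subject))
    out$n_subjects <- length(per_subject)
  }
  out
}
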