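# interval helpers -----------------------------------------------------------

runs_to_intervals <- function(mask, fs, t0) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- c(0L, ends[-length(ends)])
  keep <- r$values
  data.frame(start = t0 + starts[keep] / fs, end = t0 + ends[keep] / fs)
}

merge_close_intervals <- function(iv, gap) {
  if (nrow(iv) < 2) return(iv)
  keep_start <- iv$start[1]; out_s <- c(); out_e <- c()
  cur_s <- iv$start[1]; cur_e <- iv$end[1]
  for (i in 2:nrow(iv)) {
    if (iv$start[i] - cur_e < gap) {
      cur_e <- max(cur_e, iv$end[i])
    } else {
      out_s <- c(out_s, cur_s); out_e <- c(out_e, cur_e)
      cur_s <- iv$start[i]; cur_e <- iv$end[i]
    }
  }
  data.frame(start = c(out_s, cur_s), end = c(out_e, cur_e))
}

intervals_overlap <- function(s, e, iv) {
  if (is.null(iv) || nrow(iv) == 0) return(rep(FALSE, length(s)))
  vapply(seq_along(s), function(i)
    any(s[i] < iv$end & e[i] > iv$start), logical(1))
}

# detection -------------------------------------------------------------------

#' Candidate SPW-R epochs from normalized ripple power
#'
#' Finds maximal intervals where the z-scored, smoothed ripple-band power
#' exceeds the detection threshold (3 SD by default), extends each to the
#' surrounding region above the envelope threshold (0.5 z) so the first and
#' last ripple cycles are not truncated, merges epochs separated by less
#' than the merge gap, and removes any epoch overlapping active-exploration
#' segments or explicitly excluded intervals.
#'
#' @param ripple_z_power `time_series` of ripple-band power in z units.
#' @param states `state_segments` (detections during `active` are dropped).
#' @param params a `detection_params`.
#' @param exclude optional data.frame (start, end) of intervals to reject
#'   (e.g. filter edges, spike/GTC guards).
#' @return data.frame with columns start, end (s).
#' @export
detect_candidate_epochs <- function(ripple_z_power, states = NULL,
                                    params = detection_params(),
                                    exclude = NULL) {
  z <- ripple_z_power$values
  fs <- ripple_z_power$fs
  t0 <- ripple_z_power$start_time
  core <- runs_to_intervals(z > params$ripple_power_threshold, fs, t0)
  if (nrow(core) == 0) return(data.frame(start = numeric(0), end = numeric(0)))
  env <- runs_to_intervals(z > params$envelope_threshold, fs, t0)
  # each core run lies inside exactly one envelope run; keep those envelopes
  hit <- intervals_overlap(env$start, env$end, core)
  cand <- merge_close_intervals(env[hit, , drop = FALSE], params$merge_gap)
  drop <- rep(FALSE, nrow(cand))
  if (!is.null(states))
    drop <- drop | intervals_overlap(cand$start, cand$end,
                                     state_intervals(states, "active"))
  if (!is.null(exclude))
    drop <- drop | intervals_overlap(cand$start, cand$end, exclude)
  out <- cand[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

interp_extrema <- function(x, idx, fs, t0) {
  # quadratic vertex refinement of discrete extrema; clamp to half a sample
  y0 <- x[idx - 1L]; y1 <- x[idx]; y2 <- x[idx + 1L]
  den <- y0 - 2 * y1 + y2
  off <- ifelse(abs(den) > .Machine$double.eps, 0.5 * (y0 - y2) / den, 0)
  off <- pmin(pmax(off, -0.5), 0.5)
  t0 + (idx - 1L + off) / fs
}

#' Extract validated ripple cycles within a candidate epoch
#'
#' Local peaks and troughs of the ripple-bandpassed trace are located by
#' sign change of the discrete derivative (ties to the earlier sample) and
#' refined by quadratic interpolation. Successive trough pairs are accepted
#' only when their interval lies within the cycle-period bounds (4-10 ms by
#' default, i.e. 100-250 Hz); out-of-range pairs are excluded and the scan
#' continues. Epochs yielding fewer than `min_troughs` accepted troughs are
#' discarded (returns NULL).
#'
#' A 10 microsecond numerical guard is applied at the bounds so that
#' interpolated intervals sitting exactly on a bound are accepted.
#'
#' @param ripple_band_lfp ripple-bandpassed `time_series`.
#' @param epoch numeric length-2 candidate interval (s).
#' @param params a `detection_params`.
#' @return object of class `ripple_cycles` (trough/peak times in s and the
#'   accepted inter-trough intervals), or NULL when the epoch is discarded.
#' @export
extract_ripple_cycles <- function(ripple_band_lfp, epoch,
                                  params = detection_params()) {
  w <- ts_window(ripple_band_lfp, epoch[1], epoch[2])
  x <- w$values
  n <- length(x)
  if (n < 3) return(NULL)
  i <- 2:(n - 1)
  tr_idx <- i[x[i - 1] > x[i] & x[i] <= x[i + 1]]
  pk_idx <- i[x[i - 1] < x[i] & x[i] >= x[i + 1]]
  # only troughs reaching a fraction of the event's deepest trough count as
  # ripple cycles; shallow wiggles at the epoch margins are band noise
  tr_idx <- tr_idx[x[tr_idx] < params$trough_depth_frac * min(x)]
  if (length(tr_idx) < params$min_troughs) return(NULL)
  tr_t <- interp_extrema(x, tr_idx, w$fs, w$start_time)
  pk_t <- if (length(pk_idx)) interp_extrema(x, pk_idx, w$fs, w$start_time)
          else numeric(0)
  tol <- 1e-5
  dt <- diff(tr_t)
  ok <- dt >= params$cycle_period_min / 1000 - tol &
        dt <= params$cycle_period_max / 1000 + tol
  if (sum(ok) < params$min_troughs - 1L) return(NULL)
  acc <- sort(unique(c(tr_t[which(ok)], tr_t[which(ok) + 1L])))
  if (length(acc) < params$min_troughs) return(NULL)
  span <- range(acc)
  pk_keep <- pk_t[pk_t > span[1] & pk_t < span[2]]
  structure(list(trough_times = acc, peak_times = pk_keep,
                 intervals = dt[ok]),
            class = "ripple_cycles")
}

middle_interval_idx <- function(n) {
  # middle five inter-trough intervals; middle three when the ripple has
  # fewer than six cycles
  k <- if (n >= 6) 5L else 3L
  k <- min(k, n)
  s <- (n - k) %/% 2L
  seq.int(s + 1L, s + k)
}

#' Assemble a ripple event from accepted cycles
#'
#' Start and end are the first and last accepted troughs. The internal
#' ripple frequency is the reciprocal of the mean inter-trough interval over
#' the five middle cycles (three when the ripple has fewer than six cycles).
#' Power features are the mean and maximum of the z-scored ripple-band and
#' sharp-wave-band power over the event span; the event temperature is the
#' temperature sample nearest the event start.
#'
#' @param cycles a `ripple_cycles` object.
#' @param ripple_z_power,spw_z_power z-scored power `time_series`.
#' @param temperature temperature `time_series` (degC) or NULL.
#' @return one-row `ripple_events` data.frame.
#' @export
build_ripple_event <- function(cycles, ripple_z_power, spw_z_power,
                               temperature = NULL) {
  stopifnot(inherits(cycles, "ripple_cycles"))
  iv <- cycles$intervals
  sel <- middle_interval_idx(length(iv))
  freq <- 1 / mean(iv[sel])
  start <- cycles$trough_times[1]
  end <- cycles$trough_times[length(cycles$trough_times)]
  span_val <- function(zp) {
    i0 <- ts_index_at(zp, start); i1 <- ts_index_at(zp, end)
    v <- zp$values[i0:i1]
    c(mean(v), max(v))
  }
  rp <- span_val(ripple_z_power)
  sp <- span_val(spw_z_power)
  df <- data.frame(start = start, end = end, frequency = freq,
                   n_cycles = length(iv),
                   ripple_power_avg = rp[1], ripple_power_max = rp[2],
                   spw_power_avg = sp[1], spw_power_max = sp[2],
                   temperature = if (is.null(temperature)) NA_real_
                                 else ts_value_at(temperature, start),
                   burst_id = NA_integer_)
  df$trough_times <- list(cycles$trough_times)
  df$peak_times <- list(cycles$peak_times)
  class(df) <- c("ripple_events", "data.frame")
  df
}

#' Group SPW-R events into burst complexes
#'
#' Events are chained when successive starts differ by at most 200 ms (the
#' scale on which SPW-R occur in burst complexes of three or four events).
#' Chains of two or more share a burst id; singletons get NA.
#'
#' @param events a time-sorted `ripple_events` data.frame.
#' @param max_gap chaining gap between successive starts, s (default 0.2).
#' @return the events with `burst_id` filled in.
#' @export
group_burst_complexes <- function(events, max_gap = 0.2) {
  if (nrow(events) == 0) return(events)
  if (is.unsorted(events$start)) stop("events must be time-sorted")
  new_chain <- c(TRUE, diff(events$start) > max_gap)
  chain <- cumsum(new_chain)
  sizes <- table(chain)
  multi <- as.integer(names(sizes)[sizes > 1])
  id_map <- stats::setNames(seq_along(multi), multi)
  events$burst_id <- ifelse(chain %in% multi,
                            unname(id_map[as.character(chain)]),
                            NA_integer_)
  events
}

#' Detect SPW-R events in a preprocessed session
#'
#' Full detection chain: candidate epochs from thresholded ripple power,
#' cycle extraction with the inter-trough interval rule, per-event feature
#' computation, and burst grouping. Epochs overlapping active exploration,
#' filter-edge guards, or the supplied exclusion intervals (typically
#' detected epileptic discharges and the GTC guard) are rejected.
#'
#' @param prep a `preprocessed_session` from [preprocess_session()].
#' @param params a `detection_params`.
#' @param exclude optional data.frame (start, end) of additional intervals
#'   to reject.
#' @return a `ripple_events` data.frame.
#' @export
detect_ripples <- function(prep, params = detection_params(), exclude = NULL) {
  stopifnot(inherits(prep, "preprocessed_session"))
  guard <- rbind(prep$edge_guard, exclude)
  cands <- detect_candidate_epochs(prep$ripple_z_power, prep$states, params,
                                   exclude = guard)
  out <- empty_ripple_events()
  if (nrow(cands) > 0) {
    rows <- vector("list", nrow(cands))
    for (i in seq_len(nrow(cands))) {
      cyc <- extract_ripple_cycles(prep$ripple_band,
                                   c(cands$start[i], cands$end[i]), params)
      if (is.null(cyc)) next
      rows[[i]] <- build_ripple_event(cyc, prep$ripple_z_power,
                                      prep$spw_z_power, prep$temperature)
    }
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows)) {
      out <- do.call(rbind, rows)
      out <- out[order(out$start), , drop = FALSE]
      rownames(out) <- NULL
      class(out) <- c("ripple_events", "data.frame")
    }
  }
  group_burst_complexes(out)
}
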