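intersect_intervals <- function(iv, span) {
  s <- pmax(iv$start, span[1]); e <- pmin(iv$end, span[2])
  keep <- e > s
  data.frame(start = s[keep], end = e[keep])
}

#' Analyze one session end to end
#'
#' Runs preprocessing, discharge detection (whose non-artifact events and
#' GTC span become exclusion guards for the ripple detector), SPW-R
#' detection, and the standard thermal aggregations: 0.5 degC dwell-
#' normalized SPW-R and discharge rates and 0.25 degC ripple-frequency
#' bins, all restricted to pre-ictal immobility; per-class onset
#' temperatures; and the frequency-temperature Pearson trend.
#'
#' @param rec a `recording` (or a `synthetic_session`, whose recording is
#'   used).
#' @param params a `detection_params`.
#' @param baseline_epoch optional manual NREM epoch (s).
#' @param overrides optional manual artifact verdicts.
#' @return list of class `session_analysis`.
#' @export
analyze_session <- function(rec, params = detection_params(),
                            baseline_epoch = NULL, overrides = NULL) {
  if (inherits(rec, "synthetic_session")) rec <- rec$recording
  prep <- preprocess_session(rec, params, baseline_epoch)
  epi <- detect_epileptic(prep, params, overrides)
  excl <- epileptic_exclusion_intervals(epi, params)
  ripples <- detect_ripples(prep, params, exclude = excl)
  temp <- rec$temperature
  dur <- rec_duration(rec)
  gtc <- epi$gtc_onset
  pre_end <- if (is.na(gtc)) dur else gtc - params$gtc_guard
  restrict <- intersect_intervals(state_intervals(prep$states,
                                                  "immobile_nrem"),
                                  c(0, pre_end))
  interictal <- epi$events[epi$events$event_class == "interictal_spike", ,
                           drop = FALSE]
  myoclonic <- epi$events[epi$events$event_class == "myoclonic", ,
                          drop = FALSE]
  rate_bins <- dwell_and_rate(ripples, temp, 0.5, restrict)
  spike_rate_bins <- dwell_and_rate(interictal, temp, 0.5, restrict)
  mc_rate_bins <- dwell_and_rate(myoclonic, temp, 0.5, restrict)
  pre_ripples <- ripples[ripples$start < pre_end, , drop = FALSE]
  freq_bins <- feature_by_temperature(pre_ripples, "frequency", 0.25)
  onsets <- onset_temperatures(epi$events, gtc, temp)
  freq_trend <- if (nrow(pre_ripples) >= 3 &&
                    stats::sd(pre_ripples$temperature) > 0)
    trend_and_group_stats(pre_ripples$temperature, pre_ripples$frequency)
  else NULL
  structure(list(
    subject_id = rec$subject_id, genotype = rec$genotype,
    baseline_epoch = prep$baseline_epoch,
    states = prep$states,
    ripples = ripples, epileptic = epi$events,
    gtc_onset = gtc, gtc_span = epi$gtc_span,
    pre_ictal_end = pre_end, restrict = restrict,
    rate_bins = rate_bins, spike_rate_bins = spike_rate_bins,
    mc_rate_bins = mc_rate_bins,
    freq_bins = freq_bins, onsets = onsets, freq_trend = freq_trend,
    params = params), class = "session_analysis")
}

#' Genotype grand averages over a cohort of session analyses
#'
#' Aggregation is per-subject first, then across subjects (events are never
#' pooled): per-bin SPW-R rates are averaged across sessions, onset
#' temperatures are grand-averaged with SEM, and the peak-rate bin of the
#' cohort-average rate profile is reported.
#'
#' @param analyses list of `session_analysis` objects (one genotype).
#' @return list: `rate_by_bin` (bin_center, mean_rate, sem, n_sessions),
#'   `peak_rate_bin` (degC), `onsets` (per-class grand mean, sem, n),
#'   `freq_by_bin`.
#' @export
cohort_summary <- function(analyses) {
  centers <- sort(unique(unlist(lapply(analyses, function(a)
    a$rate_bins$bin_center[a$rate_bins$defined]))))
  rate_mat <- vapply(analyses, function(a) {
    m <- match(centers, a$rate_bins$bin_center)
    r <- a$rate_bins$rate[m]
    r[!is.na(m) & !a$rate_bins$defined[m]] <- NA
    r
  }, numeric(length(centers)))
  rate_mat <- matrix(rate_mat, nrow = length(centers))
  mean_rate <- rowMeans(rate_mat, na.rm = TRUE)
  nses <- rowSums(!is.na(rate_mat))
  sem <- apply(rate_mat, 1, function(v)
    stats::sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v))))
  rate_by_bin <- data.frame(bin_center = centers, mean_rate = mean_rate,
                            sem = sem, n_sessions = nses)
  occupied <- rate_by_bin[rate_by_bin$n_sessions == length(analyses), ,
                          drop = FALSE]
  peak_src <- if (nrow(occupied) > 0) occupied else rate_by_bin
  peak_bin <- peak_src$bin_center[which.max(peak_src$mean_rate)]

  classes <- c("interictal_spike", "myoclonic", "gtc")
  onsets <- lapply(classes, function(cl) {
    v <- vapply(analyses, function(a) a$onsets[[cl]], numeric(1))
    v <- v[!is.na(v)]
    list(mean = if (length(v)) mean(v) else NA_real_,
         sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
         n = length(v))
  })
  names(onsets) <- classes

  fcent <- sort(unique(unlist(lapply(analyses, function(a)
    a$freq_bins$bin_center))))
  fmat <- vapply(analyses, function(a) {
    a$freq_bins$mean[match(fcent, a$freq_bins$bin_center)]
  }, numeric(length(fcent)))
  fmat <- matrix(fmat, nrow = length(fcent))
  freq_by_bin <- data.frame(
    bin_center = fcent,
    mean_frequency = rowMeans(fmat, na.rm = TRUE),
    sem = apply(fmat, 1, function(v)
      stats::sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v)))),
    n_sessions = rowSums(!is.na(fmat)))

  list(rate_by_bin = rate_by_bin, peak_rate_bin = peak_bin,
       onsets = onsets, freq_by_bin = freq_by_bin,
       n_sessions = length(analyses))
}

#' Run configuration for the pipeline
#'
#' Validates detection-parameter overrides eagerly (an invalid override is
#' rejected before any computation).
#'
#' @param input path to a session container, or NULL to simulate.
#' @param preset genotype label for simulation (`"WT"`/`"DS"`).
#' @param seed integer seed for simulation and any stochastic step.
#' @param params_overrides named list of `detection_params` overrides.
#' @param baseline_epoch optional manual NREM epoch (s).
#' @param output_dir directory for result files.
#' @param simulate_args extra arguments passed to [simulate_session()].
#' @return list of class `run_config`.
#' @export
run_config <- function(input = NULL, preset = "DS", seed = 1,
                       params_overrides = list(), baseline_epoch = NULL,
                       output_dir = tempfile("thermoripple_run_"),
                       simulate_args = list()) {
  params <- do.call(detection_params, params_overrides)
  structure(list(input = input, preset = preset, seed = seed,
                 params = params, baseline_epoch = baseline_epoch,
                 output_dir = output_dir, simulate_args = simulate_args),
            class = "run_config")
}

json_out <- function(x, path) {
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = 10,
                              pretty = TRUE, null = "null", na = "null"),
             path)
}

#' Run the full pipeline and write a result bundle
#'
#' simulate (or load) -> preprocess -> detect -> analyze, writing event
#' tables, bin summaries, a statistics report and a run manifest to the
#' output directory. Identical configuration and seed produce byte-
#' identical outputs.
#'
#' @param config a `run_config`.
#' @return the `session_analysis`, invisibly; files in
#'   `config$output_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$input)) {
    rec <- read_session(config$input)
    truth <- NULL
  } else {
    sim <- do.call(simulate_session,
                   c(list(preset = config$preset, seed = config$seed),
                     config$simulate_args))
    rec <- sim$recording
    truth <- sim$truth
  }
  ana <- analyze_session(rec, config$params, config$baseline_epoch)
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write_events(ana$ripples, file.path(out, "ripple_events.csv"))
  write_events(ana$epileptic, file.path(out, "epileptic_events.csv"))
  wb <- function(df, f) utils::write.csv(
    format(df, digits = 10, trim = TRUE, scientific = FALSE),
    file.path(out, f), row.names = FALSE)
  wb(ana$rate_bins, "spwr_rate_bins.csv")
  wb(ana$spike_rate_bins, "spike_rate_bins.csv")
  wb(ana$mc_rate_bins, "mc_rate_bins.csv")
  wb(ana$freq_bins, "ripple_frequency_bins.csv")
  defined <- ana$rate_bins[ana$rate_bins$defined, , drop = FALSE]
  sig <- if (nrow(defined) >= 5)
    fit_sigmoid_trend(defined$bin_center, defined$rate) else NULL
  stats_report <- list(
    subject_id = ana$subject_id, genotype = ana$genotype,
    baseline_epoch = ana$baseline_epoch,
    n_ripples = nrow(ana$ripples),
    n_interictal = sum(ana$epileptic$event_class == "interictal_spike"),
    n_myoclonic = sum(ana$epileptic$event_class == "myoclonic"),
    n_artifact = sum(ana$epileptic$event_class == "artifact"),
    gtc_onset = ana$gtc_onset,
    onset_temperatures = as.list(ana$onsets),
    frequency_temperature_trend = ana$freq_trend,
    rate_sigmoid = if (!is.null(sig) && sig$converged)
      as.list(sig$parameters) else NULL)
  json_out(stats_report, file.path(out, "statistics.json"))
  manifest <- list(
    package = "thermoripple",
    version = as.character(utils::packageVersion("thermoripple")),
    seed = config$seed,
    preset = if (is.null(config$input)) config$preset else NULL,
    input = config$input,
    params = unclass(config$params),
    baseline_epoch = config$baseline_epoch)
  json_out(manifest, file.path(out, "run_manifest.json"))
  if (!is.null(truth))
    utils::write.csv(format(truth, digits = 10, trim = TRUE,
                            scientific = FALSE),
                     file.path(out, "ground_truth.csv"), row.names = FALSE)
  invisible(ana)
}
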