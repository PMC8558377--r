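#' Write a session container to disk
#'
#' The native container is a directory holding a `manifest.json` plus one
#' plain-text file per channel (`lfp_<name>.txt`, `emg_<name>.txt`,
#' `temperature.txt`), one sample per line printed with 17 significant
#' digits so that doubles round-trip bit-exactly. The manifest records
#' sampling rates, units, start times, annotations and subject metadata.
#'
#' @param rec a `recording`.
#' @param path directory to create (overwritten if it exists).
#' @return `path`, invisibly.
#' @export
write_session <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  ser <- function(ts, file) writeLines(sprintf("%.17g", ts$values),
                                       file.path(path, file))
  meta_ts <- function(ts) list(fs = ts$fs, start_time = ts$start_time,
                               units = ts$units, n = length(ts$values))
  manifest <- list(
    format = "thermoripple-session", version = 1L,
    subject_id = rec$subject_id, genotype = rec$genotype,
    lfp = lapply(rec$lfp, meta_ts), emg = lapply(rec$emg, meta_ts),
    temperature = if (!is.null(rec$temperature)) meta_ts(rec$temperature),
    annotations = rec$annotations)
  for (nm in names(rec$lfp)) ser(rec$lfp[[nm]], paste0("lfp_", nm, ".txt"))
  for (nm in names(rec$emg)) ser(rec$emg[[nm]], paste0("emg_", nm, ".txt"))
  if (!is.null(rec$temperature)) ser(rec$temperature, "temperature.txt")
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              null = "null", pretty = TRUE),
             file.path(path, "manifest.json"))
  invisible(path)
}

#' Read a session container
#'
#' Reads a directory written by [write_session()]. The temperature trace is
#' mandatory: a container without one is rejected.
#'
#' @param path container directory.
#' @return a validated `recording`.
#' @export
read_session <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("not a session container: manifest.json missing")
  manifest <- jsonlite::fromJSON(mf, simplifyVector = TRUE)
  de <- function(file, meta) {
    v <- scan(file.path(path, file), what = double(), quiet = TRUE)
    if (length(v) != meta$n)
      stop(sprintf("channel %s: expected %d samples, found %d",
                   file, meta$n, length(v)))
    time_series(v, meta$fs, meta$start_time, meta$units)
  }
  if (is.null(manifest$temperature))
    stop("temperature required: container has no temperature trace")
  lfp <- lapply(seq_along(manifest$lfp), function(i)
    de(paste0("lfp_", names(manifest$lfp)[i], ".txt"), manifest$lfp[[i]]))
  names(lfp) <- names(manifest$lfp)
  emg <- lapply(seq_along(manifest$emg), function(i)
    de(paste0("emg_", names(manifest$emg)[i], ".txt"), manifest$emg[[i]]))
  names(emg) <- names(manifest$emg)
  temp <- de("temperature.txt", manifest$temperature)
  ann <- manifest$annotations
  if (length(ann) == 0) ann <- list()
  recording(lfp, emg, temp, annotations = as.list(ann),
            subject_id = manifest$subject_id, genotype = manifest$genotype)
}

#' Read an EDF file (ingest only)
#'
#' Minimal reader for European Data Format (EDF) continuous recordings, the
#' interchange format commonly used for electrophysiology exports. Signals
#' whose labels start with "EMG" (case-insensitive) become EMG channels; all
#' others become LFP channels. Digital values are mapped to physical units
#' by the per-signal calibration in the header. All signals must share one
#' sampling rate. EDF carries no temperature trace, so one must be supplied
#' separately before thermal analysis.
#'
#' @param path EDF file.
#' @param temperature optional `time_series` (degC) to attach.
#' @param subject_id,genotype metadata for the returned recording.
#' @return a `recording` (temperature may be NULL).
#' @export
read_edf <- function(path, temperature = NULL, subject_id = "edf",
                     genotype = "WT") {
  con <- file(path, "rb"); on.exit(close(con))
  rd <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  rd(8)                    # version
  rd(80); rd(80)           # patient / recording id
  rd(8); rd(8)             # start date / time
  header_bytes <- as.integer(rd(8))
  rd(44)                   # reserved
  n_records <- as.integer(rd(8))
  record_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  fld <- function(w) vapply(seq_len(ns), function(i) rd(w), character(1))
  labels <- fld(16)
  fld(80); fld(8)                       # transducer, dimension
  phys_min <- as.numeric(fld(8)); phys_max <- as.numeric(fld(8))
  dig_min <- as.numeric(fld(8));  dig_max <- as.numeric(fld(8))
  fld(80)                               # prefiltering
  nsamp <- as.integer(fld(8))
  fld(32)                               # reserved
  stopifnot(seek(con, where = NA) == header_bytes)
  chans <- vector("list", ns)
  for (i in seq_len(ns)) chans[[i]] <- vector("list", n_records)
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      chans[[i]][[r]] <- readBin(con, "integer", n = nsamp[i], size = 2,
                                 signed = TRUE, endian = "little")
    }
  }
  fs <- nsamp / record_dur
  if (length(unique(fs)) != 1L)
    stop("EDF signals with mixed sampling rates are not supported")
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  series <- lapply(seq_len(ns), function(i) {
    dig <- unlist(chans[[i]], use.names = FALSE)
    time_series(phys_min[i] + gain[i] * (dig - dig_min[i]), fs[i],
                units = "uV")
  })
  is_emg <- grepl("^emg", labels, ignore.case = TRUE)
  clean <- make.unique(gsub("[^A-Za-z0-9]+", "_", labels))
  lfp <- series[!is_emg]; names(lfp) <- clean[!is_emg]
  emg <- series[is_emg];  names(emg) <- clean[is_emg]
  recording(lfp, emg, temperature, subject_id = subject_id,
            genotype = genotype)
}

fmt_times <- function(x) vapply(x, function(v)
  paste(sprintf("%.9f", v), collapse = ";"), character(1))

#' Write an event table to CSV
#'
#' One row per event; times in seconds with nanosecond precision (lossless
#' well beyond the documented 1 ms requirement). Ripple cycle times are
#' packed as semicolon-separated lists. Mixed event types are refused.
#'
#' @param events a ripple- or epileptic-event data.frame.
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  type <- event_table_type(events)
  df <- as.data.frame(events)
  if (type == "ripple") {
    df$trough_times <- fmt_times(df$trough_times)
    df$peak_times <- fmt_times(df$peak_times)
    df <- df[, ripple_event_cols, drop = FALSE]
  } else {
    df <- df[, epileptic_event_cols, drop = FALSE]
  }
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.9f", v))
  # integer-ish columns stay readable
  if (type == "ripple") {
    df$n_cycles <- as.integer(events$n_cycles)
    df$burst_id <- events$burst_id
  }
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

parse_times <- function(s) lapply(strsplit(ifelse(is.na(s), "", s), ";"),
                                  function(v) as.numeric(v[nzchar(v)]))

#' Read an event table written by [write_events()]
#' @param path CSV file.
#' @param type `"ripple"` or `"epileptic"` (auto-detected from columns when
#'   omitted).
#' @return event data.frame of the matching class.
#' @export
read_events <- function(path, type = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (is.null(type))
    type <- if ("trough_times" %in% names(df)) "ripple" else "epileptic"
  if (nrow(df) == 0)
    return(if (type == "ripple") empty_ripple_events()
           else empty_epileptic_events())
  if (type == "ripple") {
    tt <- parse_times(df$trough_times); pt <- parse_times(df$peak_times)
    num <- setdiff(ripple_event_cols, c("trough_times", "peak_times",
                                        "n_cycles", "burst_id"))
    df[num] <- lapply(df[num], as.numeric)
    df$n_cycles <- as.integer(df$n_cycles)
    df$burst_id <- suppressWarnings(as.integer(df$burst_id))
    df$trough_times <- tt; df$peak_times <- pt
    class(df) <- c("ripple_events", "data.frame")
  } else {
    num <- setdiff(epileptic_event_cols, "event_class")
    df[num] <- lapply(df[num], as.numeric)
    class(df) <- c("epileptic_events", "data.frame")
  }
  df
}
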