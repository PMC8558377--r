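# Shared fixtures built in code. Everything is seeded and small; full
# sessions are only simulated where a test genuinely needs the whole chain.

fs_ephys <- 2048

sine_ts <- function(freq, duration, fs = fs_ephys, amp = 1, phase = 0) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  time_series(amp * sin(2 * pi * freq * t + phase), fs)
}

# a ripple-like burst: Gaussian-enveloped cosine with a trough at `center`
ripple_burst <- function(n, fs = fs_ephys, center, freq, amp = 60,
                         sigma = 0.012) {
  t <- (seq_len(n) - 1) / fs - center
  -amp * exp(-t^2 / (2 * sigma^2)) * cos(2 * pi * freq * t)
}

# minimal two-channel recording around a given LFP vector
quick_recording <- function(lfp1, lfp2 = NULL, emg = NULL, temp_value = 36.5,
                            fs = fs_ephys, genotype = "WT") {
  n <- length(lfp1)
  if (is.null(lfp2)) lfp2 <- lfp1
  if (is.null(emg)) emg <- lfp1 / 4
  dur <- n / fs
  recording(
    lfp = list(a = time_series(lfp1, fs, validate = FALSE),
               b = time_series(lfp2, fs, validate = FALSE)),
    emg = list(neck = time_series(emg, fs, validate = FALSE)),
    temperature = time_series(rep(temp_value, ceiling(dur * 10)), 10,
                              units = "degC"),
    genotype = genotype)
}

# Independent minimal EDF writer (continuous, int16, little-endian), built
# from the published format layout so read_edf() is tested against an
# implementation that shares no code with it.
write_edf_fixture <- function(path, signals, labels, fs, phys_range = 1000) {
  ns <- length(signals)
  nsamp <- fs                      # one-second data records
  n_records <- length(signals[[1]]) %/% nsamp
  con <- file(path, "wb"); on.exit(close(con))
  pad <- function(s, w) {
    s <- substr(s, 1, w)
    writeChar(formatC(s, width = -w), con, nchars = w, eos = NULL)
  }
  pad("0", 8); pad("patient", 80); pad("recording", 80)
  pad("01.01.20", 8); pad("00.00.00", 8)
  pad(as.character(256 + ns * 256), 8); pad("", 44)
  pad(as.character(n_records), 8); pad("1", 8); pad(as.character(ns), 4)
  for (l in labels) pad(l, 16)
  for (i in seq_len(ns)) pad("transducer", 80)
  for (i in seq_len(ns)) pad("uV", 8)
  for (i in seq_len(ns)) pad(as.character(-phys_range), 8)
  for (i in seq_len(ns)) pad(as.character(phys_range), 8)
  for (i in seq_len(ns)) pad("-32768", 8)
  for (i in seq_len(ns)) pad("32767", 8)
  for (i in seq_len(ns)) pad("", 80)
  for (i in seq_len(ns)) pad(as.character(nsamp), 8)
  for (i in seq_len(ns)) pad("", 32)
  dig <- lapply(signals, function(x)
    as.integer(round((x + phys_range) / (2 * phys_range) * 65535 - 32768)))
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      idx <- ((r - 1) * nsamp + 1):(r * nsamp)
      writeBin(dig[[i]][idx], con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

# cache expensive simulated sessions across test files within one run
.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, force(expr), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

baseline_session <- function(genotype, seed = 1, duration = 240) {
  cached(sprintf("base_%s_%d_%d", genotype, seed, duration),
         simulate_session(genotype, seed = seed,
                          constant_temperature = 36, duration = duration))
}

ds_induction <- function(seed = 3) {
  cached(sprintf("ds_ind_%d", seed), simulate_session("DS", seed = seed))
}

analyzed_ds <- function(seed = 3) {
  cached(sprintf("ds_ana_%d", seed), analyze_session(ds_induction(seed)))
}
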