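mk_z <- function(v, fs = fs_ephys) time_series(v, fs, units = "z",
                                               validate = FALSE)

test_that("spike candidates need simultaneous amplitude and slope", {
  p <- detection_params()
  n <- 4 * fs_ephys
  smooth <- mk_z(0.3 * sin(2 * pi * 2 * (1:n) / fs_ephys))
  expect_equal(nrow(detect_spike_candidates(smooth, mk_z(rep(0, n)), p)), 0)

  # biphasic transient: peak |z| = 8, derivative |z| = 20 -> one event at
  # the amplitude extremum
  z <- rep(0, n); dz <- rep(0, n)
  i0 <- 2 * fs_ephys
  z[(i0 - 20):(i0 + 20)] <- -8 * exp(-((-20:20) / 8)^2)
  dz[(i0 - 25):(i0 + 25)] <- 20 * sin((-25:25) / 8)
  ev <- detect_spike_candidates(mk_z(z), mk_z(dz), p)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$trough_time, (i0 - 1) / fs_ephys)
  expect_equal(ev$amplitude, -8)

  # high amplitude but slow rise -> rejected
  ev2 <- detect_spike_candidates(mk_z(z * 3 / 8), mk_z(dz * 2 / 20), p)
  expect_equal(nrow(ev2), 0)

  # two seed clusters within one dead time collapse to one event
  z2 <- rep(0, n); dz2 <- rep(0, n)
  for (off in c(0, 120)) {             # 59 ms apart < 100 ms dead time
    z2[i0 + off] <- c(-8, -6)[1 + (off > 0)]
    dz2[i0 + off] <- 20
  }
  ev3 <- detect_spike_candidates(mk_z(z2), mk_z(dz2), p)
  expect_equal(nrow(ev3), 1)
  expect_equal(ev3$amplitude, -8)
})

test_that("myoclonus classification follows the strict post/pre ratio rule", {
  p <- detection_params()
  n <- 2 * fs_ephys
  mk_ev <- function() {
    df <- empty_epileptic_events()
    df[1, ] <- list(1.0, "unclassified", -10, NA, NA, NA, 38)
    class(df) <- c("epileptic_events", "data.frame")
    df
  }
  post_window <- (1 * fs_ephys + 1):(1.1 * fs_ephys)
  # post mean z = 3 -> recentered ratio (3+1)/(0+1) = 4 > 2 -> myoclonic
  z <- rep(0, n); z[post_window] <- 3
  ev <- classify_myoclonic(mk_ev(), mk_z(z), p)
  expect_equal(ev$event_class, "myoclonic")
  expect_equal(ev$emg_ratio, 4, tolerance = 0.05)
  # post = pre -> ratio 1 -> interictal
  ev2 <- classify_myoclonic(mk_ev(), mk_z(rep(0, n)), p)
  expect_equal(ev2$event_class, "interictal_spike")
  # ratio exactly 2 -> interictal (strict >)
  z3 <- rep(0, n); z3[(1 * fs_ephys + 1):(1.2 * fs_ephys)] <- 1  # (1+1)/(0+1) = 2
  ev3 <- classify_myoclonic(mk_ev(), mk_z(z3), p)
  expect_equal(ev3$emg_ratio, 2, tolerance = 1e-6)
  expect_equal(ev3$event_class, "interictal_spike")
  # event too close to the record edge -> unclassified with warning
  edge <- mk_ev(); edge$trough_time <- 0.05
  expect_warning(out <- classify_myoclonic(edge, mk_z(rep(0, n)), p),
                 "unclassified")
  expect_equal(out$event_class, "unclassified")
})

test_that("myoclonus classification is invariant to global EMG gain", {
  set.seed(31)
  n <- 80 * fs_ephys
  emg <- rnorm(n, sd = 10)
  burst <- (40 * fs_ephys):(40.12 * fs_ephys)
  emg[burst] <- emg[burst] * 6
  lfp <- rnorm(n, sd = 40)
  classify_with_gain <- function(gain) {
    rec <- quick_recording(lfp, emg = emg * gain)
    prep <- preprocess_session(rec, baseline_epoch = c(0, 35))
    df <- empty_epileptic_events()
    df[1, ] <- list(40.0, "unclassified", -10, NA, NA, NA, 36.5)
    classify_myoclonic(df, prep$emg_z_power)
  }
  a <- classify_with_gain(1)
  b <- classify_with_gain(7.5)
  expect_equal(a$event_class, "myoclonic")
  expect_equal(a$emg_ratio, b$emg_ratio, tolerance = 1e-6)
})

test_that("artifact rules: active state, morphology, multi-channel + EMG", {
  p <- detection_params()
  n <- 20 * fs_ephys
  mk_ev <- function(t, amp) {
    df <- empty_epileptic_events()
    df[1, ] <- list(t, "unclassified", amp, NA, NA, NA, 37)
    class(df) <- c("epileptic_events", "data.frame")
    df
  }
  quiet <- rep(0, n)
  base_prep <- list(
    states = state_segments(c(0, 8, 12), c(8, 12, 20),
                            c("immobile_nrem", "active", "immobile_nrem")),
    lfp_z_all = list(a = mk_z(quiet), b = mk_z(quiet)),
    emg_z_power = mk_z(quiet))

  # (b) event during active exploration -> artifact; oracle: exhaustive
  # labeling of which rule fires for each constructed case
  ev <- reject_artifacts(mk_ev(10, -12), base_prep, p)
  expect_equal(ev$event_class, "artifact")

  # isolated large single-channel spike in immobility -> retained
  prep1 <- base_prep
  z1 <- quiet; z1[5 * fs_ephys] <- -12
  prep1$lfp_z_all$a <- mk_z(z1)
  ev1 <- reject_artifacts(mk_ev(5, -12), prep1, p)
  expect_equal(ev1$event_class, "unclassified")

  # (c) low-amplitude morphology -> artifact
  ev2 <- reject_artifacts(mk_ev(5, -2), prep1, p)
  expect_equal(ev2$event_class, "artifact")

  # (a) both channels deflect and EMG was already elevated -> artifact
  prep2 <- base_prep
  zz <- quiet; zz[(5 * fs_ephys - 10):(5 * fs_ephys + 10)] <- -12
  prep2$lfp_z_all <- list(a = mk_z(zz), b = mk_z(zz))
  emg <- quiet; emg[(4.5 * fs_ephys):(5.1 * fs_ephys)] <- 3
  prep2$emg_z_power <- mk_z(emg)
  ev3 <- reject_artifacts(mk_ev(5, -12), prep2, p)
  expect_equal(ev3$event_class, "artifact")
  # same deflections but EMG quiet -> retained (bilateral discharge)
  prep3 <- prep2; prep3$emg_z_power <- mk_z(quiet)
  ev4 <- reject_artifacts(mk_ev(5, -12), prep3, p)
  expect_equal(ev4$event_class, "unclassified")

  # manual override takes precedence
  ev5 <- reject_artifacts(mk_ev(10, -12), base_prep, p,
                          overrides = data.frame(time = 10, verdict = "keep"))
  expect_equal(ev5$event_class, "unclassified")
})

test_that("GTC localization: annotation priority, recovery, WT absence", {
  # annotation short-circuits signal search
  fake_prep <- list(annotations = list(gtc_onset = 900))
  expect_equal(locate_gtc(fake_prep), 900)

  # synthetic DS seizure recovered within 1 s without annotation
  sim <- ds_induction()
  ana <- analyzed_ds()
  expect_false(is.na(ana$gtc_onset))
  expect_lt(abs(ana$gtc_onset - sim$schedule$gtc_time), 1)
  # discharges inside the guarded seizure span are classed gtc
  expect_true(all(abs(ana$epileptic$trough_time[
    ana$epileptic$event_class == "gtc"] - sim$schedule$gtc_time) < 25))

  # WT baseline never seizes
  wt <- cached("base_ana_WT", analyze_session(baseline_session("WT")))
  expect_true(is.na(wt$gtc_onset))
})

test_that("peri-event averaging: identity, cancellation, sqrt-n noise gain", {
  n <- 40 * fs_ephys
  shape <- function(t) -5 * exp(-t^2 / (2 * 0.01^2))
  tt <- (seq_len(n) - 1) / fs_ephys
  clean <- rep(0, n)
  centers <- seq(2, 38, by = 2)
  for (c0 in centers) clean <- clean + shape(tt - c0)
  tr <- time_series(clean, fs_ephys, validate = FALSE)
  avg <- peri_event_average(list(lfp = tr), centers, window = 0.1)$lfp
  expect_equal(min(avg$mean), -5, tolerance = 1e-6)
  expect_equal(avg$time[which.min(avg$mean)], 0)

  # transient + its negation average to zero
  two <- rep(0, n)
  two <- two + shape(tt - 10) - shape(tt - 30)
  avg2 <- peri_event_average(list(x = time_series(two, fs_ephys,
                                                  validate = FALSE)),
                             c(10, 30), window = 0.1)$x
  expect_lt(max(abs(avg2$mean)), 1e-9)

  # sqrt-n law: averaging 100 noisy copies improves SNR about 10-fold
  set.seed(32)
  n2 <- 220 * fs_ephys
  tt2 <- (seq_len(n2) - 1) / fs_ephys
  noisy <- rnorm(n2, sd = 2)
  centers2 <- seq(2, 218, length.out = 100)
  for (c0 in centers2) noisy <- noisy + shape(tt2 - c0)
  avg3 <- peri_event_average(list(x = time_series(noisy, fs_ephys,
                                                  validate = FALSE)),
                             centers2, window = 0.1)$x
  resid <- avg3$mean[abs(avg3$time) > 0.05]
  gain <- 2 / sd(resid)
  expect_gt(gain, 6); expect_lt(gain, 16)

  expect_error(peri_event_average(list(x = tr), numeric(0), 0.1), "window")
})
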