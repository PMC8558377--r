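const_temp <- function(value, dur) time_series(rep(value, dur * 10), 10,
                                               units = "degC")

test_that("dwell-normalized rates follow their definition", {
  temp <- const_temp(37.0, 100)
  ev <- data.frame(start = seq(5, 95, length.out = 5),
                   temperature = rep(37, 5))
  br <- dwell_and_rate(ev, temp, 0.5)
  expect_equal(nrow(br[br$event_count > 0, ]), 1)
  expect_equal(br$rate[br$bin_center == 37], 0.05)
  expect_equal(br$dwell_time[br$bin_center == 37], 100)

  # 10 events over 20 s of dwell in one bin -> 0.5 /s
  temp2 <- const_temp(38.2, 20)
  ev2 <- data.frame(start = seq(1, 19, length.out = 10),
                    temperature = rep(38.2, 10))
  br2 <- dwell_and_rate(ev2, temp2, 0.5)
  expect_equal(br2$rate[br2$bin_center == 38], 0.5)
})

test_that("rates on a temperature ramp recover a known Poisson intensity", {
  set.seed(41)
  dur <- 400
  temp <- time_series(36 + (0:(dur * 10 - 1)) / (dur * 10) * 4, 10,
                      units = "degC")
  rate_true <- 0.5
  times <- cumsum(rexp(400, rate_true))
  times <- times[times < dur]
  ev <- data.frame(start = times, temperature = ts_value_at(temp, times))
  br <- dwell_and_rate(ev, temp, 0.5)
  occ <- br[br$defined & br$dwell_time > 30, ]
  # each bin within 3 SD of the Poisson expectation
  for (i in seq_len(nrow(occ))) {
    expccount <- rate_true * occ$dwell_time[i]
    expect_lte(abs(occ$event_count[i] - expccount), 3 * sqrt(expccount) + 1)
  }
  # conservation: counts and dwell are partitioned, not lost
  expect_equal(sum(br$event_count), length(times))
  expect_equal(sum(br$dwell_time), dur, tolerance = 0.1)
})

test_that("undefined bins are flagged, not zero-filled", {
  temp <- const_temp(36.0, 50)
  ev <- data.frame(start = 10, temperature = 39.0)  # no dwell at 39
  br <- dwell_and_rate(ev, temp, 0.5)
  row <- br[br$bin_center == 39, ]
  expect_false(row$defined)
  expect_true(is.na(row$rate))
})

test_that("per-bin feature means and SEM follow the formulas", {
  ev <- data.frame(temperature = rep(36.1, 4), frequency = rep(150, 4))
  fb <- feature_by_temperature(ev, "frequency")
  expect_equal(fb$mean, 150); expect_equal(fb$sem, 0)

  ev2 <- data.frame(temperature = c(36.05, 36.1), frequency = c(140, 160))
  fb2 <- feature_by_temperature(ev2, "frequency")
  expect_equal(fb2$mean, 150); expect_equal(fb2$sem, 10)

  # linear f(T): per-bin means recover the slope
  set.seed(42)
  Tv <- runif(400, 36, 39)
  ev3 <- data.frame(temperature = Tv,
                    frequency = 135 + 8 * (Tv - 36) + rnorm(400, sd = 3))
  fb3 <- feature_by_temperature(ev3, "frequency")
  fit <- lm(mean ~ bin_center, data = fb3, weights = n)
  ci <- confint(fit)["bin_center", ]
  expect_gt(8, ci[1]); expect_lt(8, ci[2])
})

test_that("spectral peak frequency recovers embedded ripple frequencies", {
  set.seed(43)
  mk_lfp <- function(freqs, dur = 30) {
    n <- dur * fs_ephys
    x <- rnorm(n, sd = 20)
    centers <- seq(1, dur - 1, by = 0.5)
    for (i in seq_along(centers))
      x <- x + ripple_burst(n, center = centers[i],
                            freq = freqs[1 + (i %% length(freqs))], amp = 60)
    x
  }
  states <- state_segments(0, 60, "immobile_nrem")
  # one bin at 36 with 175 Hz ripples
  lfp <- time_series(c(mk_lfp(175), rnorm(30 * fs_ephys, sd = 20)),
                     fs_ephys, validate = FALSE)
  temp <- time_series(c(rep(36.2, 300), rep(38.2, 300)), 10, units = "degC")
  sp <- spectral_peak_frequency(lfp, temp, states)
  row36 <- sp[sp$bin_center == 36, ]
  expect_false(row36$flagged)
  expect_lt(abs(row36$frequency - 175), 5)
  # white-noise-only bin -> flagged, not fabricated
  row38 <- sp[sp$bin_center == 38, ]
  expect_true(nrow(row38) == 0 || row38$flagged)

  # two bins with 140 and 180 Hz ripples -> ordered centers
  lfp2 <- time_series(c(mk_lfp(140), mk_lfp(180)), fs_ephys,
                      validate = FALSE)
  sp2 <- spectral_peak_frequency(lfp2, temp, states)
  f36 <- sp2$frequency[sp2$bin_center == 36]
  f38 <- sp2$frequency[sp2$bin_center == 38]
  expect_lt(f36, f38)
  expect_lt(abs(f36 - 140), 8); expect_lt(abs(f38 - 180), 8)
})

test_that("anchor alignment prefers GTC and falls back to 38.5 degC", {
  p <- detection_params()
  temp <- time_series(36 + (0:9999) / 10000 * 4, 10, units = "degC")
  al <- align_to_anchor(890, temp, p, gtc_onset = 900)
  expect_equal(al$anchor_type, "gtc")
  expect_equal(al$relative_times, -10)

  cross <- temperature_crossing(temp, 38.5)
  al2 <- align_to_anchor(cross, temp, p, gtc_onset = NA)
  expect_equal(al2$anchor_type, "temperature_crossing")
  expect_equal(al2$relative_times, 0, tolerance = 0.11)

  flat <- const_temp(36, 10)
  expect_error(align_to_anchor(1, flat, p, gtc_onset = NA), "anchor")
})

test_that("onset temperatures report the first event of each class", {
  ev <- empty_epileptic_events()
  ev[1, ] <- list(100, "interictal_spike", -10, 0, 0, 1, 37.6)
  ev[2, ] <- list(50, "interictal_spike", -10, 0, 0, 1, 37.2)
  ev[3, ] <- list(200, "artifact", -2, 0, 0, 1, 38.5)
  on <- onset_temperatures(ev)
  expect_equal(unname(on["interictal_spike"]), 37.2)   # earliest event
  expect_true(is.na(on["myoclonic"]))                  # class absent
  temp <- const_temp(38.9, 300)
  on2 <- onset_temperatures(ev, gtc_onset = 250, temperature = temp)
  expect_equal(unname(on2["gtc"]), 38.9)
})

test_that("peri-event rate histogram has the documented normalization", {
  # single trigger, single SPW-R 0.1 s later -> 4 events/s in one bin
  pr <- peri_event_rate(10.1, 10, bin = 0.25, window = 1)
  expect_equal(pr$rate[pr$time == 0.125], 4)
  expect_equal(sum(pr$count), 1)

  # homogeneous events against unrelated triggers -> flat at the true rate
  set.seed(44)
  spwr <- cumsum(rexp(3000, 1))
  trig <- seq(50, max(spwr) - 50, by = 9.7)
  pr2 <- peri_event_rate(spwr, trig, bin = 0.25, window = 2)
  expect_lt(abs(mean(pr2$rate) - 1), 0.05)
  expect_lt(max(abs(pr2$rate - 1)), 0.3)
  expect_error(peri_event_rate(spwr, numeric(0)), "trigger")
})

test_that("pre/post suppression test behaves at the null and the edge", {
  # symmetric event times around every trigger -> identical rates, t = 0
  sessions <- lapply(1:4, function(k) {
    trig <- seq(20, 180, by = 20)
    list(spwr_times = sort(c(trig - 0.4, trig + 0.4)),
         trigger_times = trig, record_span = c(0, 200))
  })
  out <- pre_post_rate_test(sessions)
  expect_equal(out$t, 0)
  expect_equal(out$pre, out$post)
  # trigger too close to the record edge is skipped
  s2 <- list(list(spwr_times = c(0.3, 5), trigger_times = c(0.5, 10),
                  record_span = c(0, 20)),
             list(spwr_times = c(1, 2), trigger_times = 10,
                  record_span = c(0, 20)))
  out2 <- pre_post_rate_test(s2)
  expect_equal(length(out2$pre), 2)
  expect_error(pre_post_rate_test(sessions[1]), "at least 2")
})

test_that("SPW amplitude split test detects a step and accepts the null", {
  mk_session <- function(step) {
    ne <- 60
    temp <- runif(ne, 36.5, 39.5)
    df <- empty_ripple_events()[0, c("spw_power_avg", "temperature")]
    df <- data.frame(spw_power_avg = 2 + rnorm(ne, sd = 0.3) +
                       step * (temp >= 38),
                     temperature = temp)
    df
  }
  set.seed(45)
  with_step <- lapply(1:6, function(i) mk_session(1.5))
  res <- spw_amplitude_split_test(with_step)
  expect_true(all(res$above > res$below))
  expect_lt(res$p, 0.05)
  null_case <- lapply(1:6, function(i) mk_session(0))
  res0 <- spw_amplitude_split_test(null_case)
  expect_gt(res0$p, 0.05)
  # one-sided sessions are excluded with a warning
  one_sided <- c(with_step[1:3],
                 list(data.frame(spw_power_avg = rnorm(10, 2),
                                 temperature = runif(10, 36, 37.5))))
  expect_warning(res1 <- spw_amplitude_split_test(one_sided), "one side")
  expect_equal(res1$n_sessions, 3)
})

test_that("sigmoid trend fit recovers parameters and flags degeneracy", {
  x <- seq(36, 40, by = 0.25)
  logi <- function(x, fl, ce, mid, sc) fl + (ce - fl) / (1 + exp(-(x - mid) / sc))
  y <- logi(x, 0.1, 0.9, 38, 0.4)
  fit <- fit_sigmoid_trend(x, y)
  expect_true(fit$converged); expect_false(fit$degenerate)
  expect_equal(unname(fit$parameters), c(0.1, 0.9, 38, 0.4), tolerance = 1e-3)

  flat <- fit_sigmoid_trend(x, rep(0.5, length(x)))
  expect_true(is.null(flat$parameters) || flat$degenerate)

  set.seed(46)
  noisy <- y + rnorm(length(y), sd = 0.05)
  fit2 <- fit_sigmoid_trend(x, noisy)
  expect_true(fit2$converged)
  expect_lt(abs(fit2$parameters["midpoint"] - 38), 0.3)
  expect_error(fit_sigmoid_trend(1:4, 1:4), "at least 5")
})

test_that("Pearson trend and grand averages follow the formulas", {
  x <- 1:10
  out <- trend_and_group_stats(x, 2 * x)
  expect_equal(out$r, 1)
  g <- trend_and_group_stats(per_subject = c(10, 20, 30))
  expect_equal(g$grand_mean, 20)
  expect_equal(g$sem, 10 / sqrt(3))
  expect_error(trend_and_group_stats(rep(1, 5), 1:5), "variance")
  expect_error(trend_and_group_stats(1:2, 1:2), "at least 3")
})
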