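test_that("instantaneous frequency recovers carrier and excursions", {
  sr <- 40000
  t <- seq(0, 1, by = 1 / sr)
  # constant 800 Hz carrier
  ft <- instantaneous_frequency(t, sin(2 * pi * 800 * t), "voltage")
  expect_lt(max(abs(ft$frequency - 800)), 0.5)
  # injected Gaussian frequency bump recovered within 2 Hz
  finst <- 800 + 60 * exp(-(t - 0.5)^2 / (2 * 0.014^2))
  v <- sin(2 * pi * cumsum(finst) / sr)
  fb <- instantaneous_frequency(t, v, "voltage")
  expect_lt(abs(max(fb$frequency) - 860), 2)
  expect_lt(abs(fb$time[which.max(fb$frequency)] - 0.5), 0.01)
  # frequency input passes through unchanged
  fp <- instantaneous_frequency(t, finst, "frequency")
  expect_equal(fp$frequency, finst)
  # resampling onto a uniform grid
  fr <- instantaneous_frequency(t, v, "voltage", resample = 1000)
  expect_equal(fr$sample_rate, 1000)
  expect_equal(diff(fr$time), rep(1e-3, length(fr$time) - 1),
               tolerance = 1e-9)
  expect_error(instantaneous_frequency(t, rep(1, length(t)), "voltage"),
               "zero crossings")
})

test_that("chirp detection thresholds, times and merges events", {
  t <- seq(0, 4, by = 1e-3)
  bump <- function(center, df) df * exp(-(t - center)^2 / (2 * 0.014^2))
  mk <- function(f) list(time = t, frequency = f)
  # 25 Hz excursion stays below the 30 Hz criterion
  ev <- detect_chirps(mk(800 + bump(2, 25)), t0 = 1)
  expect_equal(nrow(ev), 0)
  # two 60 Hz excursions 500 ms apart: two events, accurate peak times
  ev2 <- detect_chirps(mk(800 + bump(2, 60) + bump(2.5, 60)), t0 = 1)
  expect_equal(nrow(ev2), 2)
  expect_lt(max(abs(ev2$time - c(2, 2.5))), 0.005)
  expect_true(all(abs(ev2$peak_excursion - 60) < 1))
  # excursions 10 ms apart merge into one event keeping the larger peak
  ev3 <- detect_chirps(mk(800 + bump(2, 60) + bump(2.01, 90)), t0 = 1)
  expect_equal(nrow(ev3), 1)
  expect_gt(ev3$peak_excursion, 80)
  # pre-stimulus window of a quiet trace contains no events
  ev4 <- detect_chirps(mk(800 + bump(2, 60)), t0 = 1)
  expect_true(all(ev4$time > 1))
})

test_that("chirp typing splits big and small excursions", {
  expect_equal(classify_chirp_type(60), "II")
  expect_equal(classify_chirp_type(300), "I")
  expect_equal(classify_chirp_type(c(100, 200), big_threshold = 150),
               c("II", "I"))
})

test_that("echo metrics count windows and latency by hand-checkable rules", {
  m <- echo_metrics(10 + c(0.2, 0.6, 1.5), stimulus_onset = 10)
  expect_equal(m$cr_chirp, 2)
  expect_equal(m$cr_beat, 1)
  expect_equal(m$latency, 0.2)
  expect_equal(m$behavior_response, log(2))
  none <- echo_metrics(numeric(0), 10)
  expect_equal(none$cr_chirp, 0)
  expect_true(is.na(none$latency))
  expect_equal(none$behavior_response, 0)
  late <- echo_metrics(10 + c(1.2, 1.7), 10)
  expect_lt(late$behavior_response, 0)
  expect_error(echo_metrics(numeric(0), 10, trace_end = 11),
               "at least 2 s")
})

test_that("behavioral PSTH pools events linearly", {
  zero <- behavioral_psth(numeric(0), 10)
  expect_true(all(zero$rate == 0))
  ev <- c(0.1, 0.3, 0.5, 0.8)
  one <- behavioral_psth(ev, 10)
  two <- behavioral_psth(c(ev, ev), 10)
  expect_equal(two$raw_rate, 2 * one$raw_rate)
  expect_equal(max(two$rate), 2 * max(one$rate), tolerance = 1e-12)
})

test_that("block bootstrap SEM matches the i.i.d. closed form", {
  expect_equal(block_bootstrap_sem(rep(3, 100), seed = 1), 0)
  # with 270 samples there are only 10 blocks per resample, so a single
  # series gives a noisy (and slightly downward-biased) SEM; average over
  # independent series and compare to the closed form sigma / sqrt(n)
  sems <- vapply(1:25, function(s) {
    x <- withr::with_seed(s, rnorm(270, sd = 2))
    block_bootstrap_sem(x, block = 27, n_boot = 500, seed = 100 + s)
  }, numeric(1))
  target <- 2 / sqrt(270)
  expect_lt(abs(mean(sems) - target) / target, 0.15)
  x <- withr::with_seed(21, rnorm(270, sd = 2))
  expect_equal(block_bootstrap_sem(x, block = 27, n_boot = 200, seed = 7),
               block_bootstrap_sem(x, block = 27, n_boot = 200, seed = 7))
  expect_error(block_bootstrap_sem(rnorm(10), block = 27),
               "shorter than one block")
})

test_that("detection is complete and sound on generator ground truth", {
  # chirp-free traces: zero false positives over 50 seeded traces
  for (seed in 1:50) {
    quiet <- simulate_echo_experiment(p_echo = 0, n_repeats = 1, seed = seed)
    ev <- detect_chirps(list(time = quiet$time,
                             frequency = quiet$eod_frequency),
                        baseline_window = c(quiet$stimuli$onset[1] - 0.2,
                                            quiet$stimuli$onset[1]))
    expect_equal(nrow(ev), 0)
  }
  # every injected excursion above 40 Hz is detected within 10 ms
  for (seed in 51:80) {
    ex <- simulate_echo_experiment(n_repeats = 1, seed = seed)
    ev <- detect_chirps(list(time = ex$time, frequency = ex$eod_frequency),
                        baseline_window = c(ex$stimuli$onset[1] - 0.2,
                                            ex$stimuli$onset[1]))
    for (et in ex$true_echo_times[ex$true_echo_df > 40])
      expect_true(any(abs(ev$time - et) < 0.01))
  }
})

test_that("phase-independent echo generation shows no phase trend", {
  ex <- simulate_echo_experiment(n_repeats = 25, seed = 23)
  stats <- analyze_echo_experiment(ex)
  # trend in the echo rate (the log-ratio response is floored to 0 for the
  # common 0/1-event presentations, which degenerates the regression)
  fit <- lm(cr_chirp ~ phase, data = stats)
  ci <- confint(fit)["phase", ]
  expect_true(ci[1] < 0 && ci[2] > 0)
  lat_fit <- lm(latency ~ phase, data = stats)
  lat_ci <- confint(lat_fit)["phase", ]
  expect_true(lat_ci[1] < 0 && lat_ci[2] > 0)
})

test_that("event log writer emits the annotated delimited schema", {
  ev <- detect_chirps(list(time = seq(0, 4, 1e-3),
                           frequency = 800 + 60 * exp(-(seq(0, 4, 1e-3) - 2)^2 /
                                                      (2 * 0.014^2))),
                      t0 = 1)
  path <- tempfile(fileext = ".tsv")
  write_event_log(ev, path, fish_id = "f1", stimulus_index = 3,
                  phase_deg = 90)
  tab <- read.table(path, header = TRUE, sep = "\t")
  expect_named(tab, c("fish_id", "stimulus_index", "phase_deg",
                      "event_time_s", "peak_excursion_hz", "type"))
  expect_equal(nrow(tab), nrow(ev))
})
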