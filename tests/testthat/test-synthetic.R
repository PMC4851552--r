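test_that("afferent simulation is seeded, refractory and rate-accurate", {
  model <- neuron_model("afferent")
  a <- simulate_afferent_trials(model, canonical_waves$S1, 10, seed = 11)
  b <- simulate_afferent_trials(model, canonical_waves$S1, 10, seed = 11)
  expect_identical(a$spikes, b$spikes)
  # spike-time monotonicity and zero refractory violations in every trial
  for (tr in trial_spikes(a)) {
    expect_true(!is.unsorted(tr, strictly = TRUE))
    if (length(tr) > 1) expect_gte(min(diff(tr)), model$refractory)
  }
  expect_error(simulate_afferent_trials(model, canonical_waves$S1, 0),
               "at least 1")
  # unmodulated process recovers the baseline rate
  flat <- neuron_model("afferent", gain = 0)
  set.seed(12)
  s <- simulate_afferent_trials(flat, canonical_waves$S1, 20)
  rate <- nrow(s$spikes) / (20 * s$duration)
  se <- sqrt(380 / (20 * s$duration))
  expect_lt(abs(rate - 380), 3 * se)
})

test_that("afferent PSTH tracks the driving rate at high trial counts", {
  model <- neuron_model("afferent")
  s <- simulate_afferent_trials(model, canonical_waves$S1, 200, seed = 13)
  p <- compute_psth(trial_spikes(s), s$duration)
  r <- pmax(0, 380 * (1 + 0.9 * canonical_waves$S1$samples))
  r_on_grid <- approx(canonical_waves$S1$time, r, p$time, rule = 2)$y
  ok <- !is.na(p$rate)
  expect_gt(cor(p$rate[ok], r_on_grid[ok]), 0.8)
})

test_that("afferent pairs carry stimulus-locked but no noise correlation", {
  pr <- simulate_afferent_pair(neuron_model("afferent"),
                               neuron_model("afferent"),
                               canonical_waves$S1, n_trials = 100, seed = 5)
  cnt <- function(tr, center, w = 0.04) vapply(tr, function(sp)
    sum(sp >= center - w / 2 & sp < center + w / 2), numeric(1))
  ti <- trial_spikes(pr$i)
  tj <- trial_spikes(pr$j)
  # signed count correlation across trials is positive during a '+' chirp
  expect_gt(cor(cnt(ti, canonical_onset + 0.015),
                cnt(tj, canonical_onset + 0.015)), 0.5)
  # residual correlation over beat-only epochs vanishes (independence)
  beat_centers <- c(seq(0.1, 0.8, by = 0.1), seq(1.3, 1.9, by = 0.1))
  res_cor <- vapply(beat_centers, function(ce)
    cor(cnt(ti, ce), cnt(tj, ce)), numeric(1))
  expect_lt(abs(mean(res_cor)), 0.05)
})

test_that("identical seeds give a degenerate perfectly correlated pair", {
  model <- neuron_model("afferent")
  ti <- trial_spikes(simulate_afferent_trials(model, canonical_waves$S2, 10,
                                              seed = 14))
  tj <- trial_spikes(simulate_afferent_trials(model, canonical_waves$S2, 10,
                                              seed = 14))
  sc <- sliding_correlation(ti, tj, 2, step = 0.01)
  expect_true(all(abs(sc$rho[sc$defined] - 1) < 1e-12))
})

test_that("ON and OFF pyramidal drives respond with opposite signs", {
  on <- neuron_model("ELL_ON")
  off <- neuron_model("ELL_OFF")
  # deterministic drive-level chirp responses: '+' waveform excites ON,
  # suppresses OFF; a '-' waveform does the opposite
  for (lb in c("S1", "S5")) {
    r_on <- response_measure(pyramidal_drive(on, canonical_waves[[lb]]),
                             canonical_onset, "ELL")$value
    r_off <- response_measure(pyramidal_drive(off, canonical_waves[[lb]]),
                              canonical_onset, "ELL")$value
    if (lb == "S1") {
      expect_gt(r_on, 0)
      expect_lt(r_off, 0)
    } else {
      expect_lt(r_on, 0)
      expect_gt(r_off, 0)
    }
  }
  # spiking PSTHs of ON and OFF cells anticorrelate in the chirp window
  set.seed(3)
  r <- vapply(names(canonical_waves), function(lb) {
    pon <- compute_psth(trial_spikes(
      simulate_pyramidal_trials(on, canonical_waves[[lb]], 100)), 2)
    poff <- compute_psth(trial_spikes(
      simulate_pyramidal_trials(off, canonical_waves[[lb]], 100)), 2)
    cor(chirp_window(pon, canonical_onset), chirp_window(poff, canonical_onset))
  }, numeric(1))
  expect_true(all(r < -0.45))
  # unmodulated pyramidal cell sits at its 12.1 Hz baseline
  set.seed(15)
  s <- simulate_pyramidal_trials(neuron_model("ELL_ON", gain = 0),
                                 canonical_waves$S1, 50)
  rate <- nrow(s$spikes) / (50 * s$duration)
  expect_lt(abs(rate - 12.1), 3 * sqrt(12.1 / (50 * 2)))
})

test_that("TS units are excited by both chirp polarities", {
  on <- neuron_model("ELL_ON")
  off <- neuron_model("ELL_OFF")
  ts <- neuron_model("TS")
  # both drives at baseline give exactly the TS baseline rate
  flat <- structure(list(time = 1:100, rate = rep(12.1, 100), baseline = 12.1,
                         stage = "ELL_ON", sample_rate = 100),
                    class = "rate_drive")
  expect_equal(ts_rate(flat, flat, ts)$rate, rep(3.35, 100))
  # zero convergence weight leaves an unmodulated baseline drive
  w0 <- ts_rate(pyramidal_drive(on, canonical_waves$S1),
                pyramidal_drive(off, canonical_waves$S1),
                neuron_model("TS", gain = 0))
  expect_equal(w0$rate, rep(3.35, length(w0$rate)))
  expect_error(ts_rate(flat, structure(list(rate = 1:5), class = "rate_drive"),
                       ts),
               "mismatched lengths")
  # Eq. 2 responses positive for a '+' and a '-' chirp alike
  set.seed(16)
  for (lb in c("S1", "S5")) {
    s <- simulate_ts_trials(pyramidal_drive(on, canonical_waves[[lb]]),
                            pyramidal_drive(off, canonical_waves[[lb]]),
                            ts, 20)
    ps <- compute_psth(trial_spikes(s), s$duration)
    expect_gt(response_measure(ps, canonical_onset, "TS")$value, 0)
  }
})

test_that("echo experiments follow the protocol and echo statistics", {
  ex <- simulate_echo_experiment(seed = 17)
  expect_equal(nrow(ex$stimuli), 40)
  expect_equal(as.integer(table(ex$stimuli$phase)), rep(5L, 8))
  expect_true(all(ex$true_echo_df >= 35))
  expect_true(all(diff(ex$stimuli$onset) >= 12 & diff(ex$stimuli$onset) <= 18))
  # injected echoes land within (0, 1 s] of their stimulus onset
  for (et in ex$true_echo_times) {
    lat <- et - ex$stimuli$onset
    expect_true(any(lat > 0 & lat <= 1))
  }
  # p_echo = 0: no events injected, detection yields CR_chirp = 0 throughout
  quiet <- simulate_echo_experiment(p_echo = 0, n_repeats = 2, seed = 18)
  expect_length(quiet$true_echo_times, 0)
  stats <- analyze_echo_experiment(quiet)
  expect_true(all(stats$cr_chirp == 0))
  expect_true(all(is.na(stats$latency)))
  # small-chirp statistics: >= 95% type II
  ev <- attr(analyze_echo_experiment(
    simulate_echo_experiment(seed = 19)), "events")
  expect_gte(mean(ev$type == "II"), 0.95)
})

test_that("spike sets round-trip through the delimited writer", {
  s <- simulate_afferent_trials(neuron_model("afferent"),
                                canonical_waves$S1, 5, seed = 20)
  path <- tempfile(fileext = ".tsv")
  write_spike_set(s, path)
  back <- read_spike_set(path)
  expect_equal(back$spikes$time, s$spikes$time, tolerance = 1e-12)
  expect_equal(back$n_trials, 5)
  expect_equal(back$duration, s$duration)
  expect_equal(back$meta$seed, 20)
})
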