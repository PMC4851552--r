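test_that("response measure is the log rate ratio with stage windows", {
  tm <- seq(5e-5, 2, by = 1e-4)
  onset <- 1
  mk <- function(chirp_level) {
    rate <- rep(1, length(tm))
    rate[abs(tm - onset) <= 0.1] <- chirp_level
    list(time = tm, rate = rate)
  }
  expect_equal(response_measure(mk(1), onset, "afferent")$value, 0)
  expect_equal(response_measure(mk(exp(1)), onset, "afferent")$value, 1,
               tolerance = 1e-9)
  # log base option
  expect_equal(response_measure(mk(10), onset, "afferent",
                                log_base = 10)$value, 1, tolerance = 1e-9)
  # stage defaults: 15 ms window for afferent/ELL, 20 ms for TS
  expect_equal(response_measure(mk(2), onset, "afferent")$t_chirp, 0.015)
  expect_equal(response_measure(mk(2), onset, "ELL")$t_chirp, 0.015)
  expect_equal(response_measure(mk(2), onset, "TS")$t_chirp, 0.020)
  expect_error(response_measure(mk(1), 1.999, "afferent"),
               "outside the trace")
  # silent chirp window is floored and flagged
  silent <- list(time = tm, rate = rep(c(1, 0), c(9000, 11000)))
  rv <- response_measure(silent, onset, "afferent")
  expect_true(rv$flagged)
  expect_true(is.finite(rv$value))
})

test_that("waveform sign classification follows the population mean", {
  resp <- rbind(c(1, 0.5, -0.2, 2), c(0.8, 0.1, -0.4, 1.5))
  colnames(resp) <- c("S1", "S2", "S3", "S4")
  expect_equal(unname(classify_chirp_sign(resp)), c("+", "+", "-", "+"))
  expect_warning(classify_chirp_sign(cbind(S1 = c(0, 0))), "tied")
  s <- suppressWarnings(classify_chirp_sign(cbind(S1 = c(0, 0))))
  expect_equal(unname(s), "-")
})

test_that("trace normalization is affine-invariant and bounded", {
  x <- sin(seq(0, 2 * pi, length.out = 200))
  nx <- normalize_trace(x)
  expect_equal(max(abs(nx)), 1)
  expect_equal(normalize_trace(3.7 * x + 11), nx, tolerance = 1e-12)
  cz <- normalize_trace(rep(2, 10))
  expect_true(attr(cz, "constant"))
  expect_equal(as.numeric(cz), rep(0, 10))
})

test_that("trace distance satisfies its defining identities", {
  set.seed(1)
  x <- rnorm(50)
  y <- rnorm(50)
  expect_equal(as.numeric(trace_distance(x, x)), 0)
  expect_equal(as.numeric(trace_distance(x, y)),
               as.numeric(trace_distance(y, x)))
  # x = -y, zero mean, half-range 1: D = 2 * RMS(x)
  z <- x - mean(x)
  z <- z / ((max(z) - min(z)) / 2)
  expect_equal(as.numeric(trace_distance(z, -z)),
               2 * sqrt(mean(z^2)), tolerance = 1e-12)
  # squared convention = rms distance squared times the half-range
  hr <- max((max(x) - min(x)) / 2, (max(y) - min(y)) / 2)
  expect_equal(as.numeric(trace_distance(x, y, "squared")),
               as.numeric(trace_distance(x, y, "rms"))^2 * hr,
               tolerance = 1e-12)
  cc <- trace_distance(rep(1, 5), rep(3, 5))
  expect_equal(as.numeric(cc), 0)
  expect_true(attr(cc, "constant"))
})

test_that("invariance score hits its analytic anchors", {
  same <- lapply(canonical_stim_win, function(w) rep_len(sin(1:300), 300))
  expect_equal(invariance_score(same, canonical_stim_win)$value, 1)
  expect_equal(invariance_score(canonical_stim_win,
                                canonical_stim_win)$value, 0)
})

test_that("subset accounting uses ordered-pair counts 56 / 24 / 32", {
  sc_all <- invariance_score(canonical_stim_win, canonical_stim_win)
  sc_same <- invariance_score(canonical_stim_win, canonical_stim_win,
                              subset = "same", signs = canonical_signs)
  sc_opp <- invariance_score(canonical_stim_win, canonical_stim_win,
                             subset = "opposite", signs = canonical_signs)
  expect_equal(sc_all$n_pairs, 56L)
  expect_equal(sc_same$n_pairs, 24L)
  expect_equal(sc_opp$n_pairs, 32L)
  expect_error(invariance_score(canonical_stim_win, canonical_stim_win,
                                subset = "same"),
               "requires waveform signs")
})

test_that("invariance score rejects malformed input", {
  bad <- canonical_stim_win
  names(bad)[1] <- "X9"
  expect_error(invariance_score(bad, canonical_stim_win),
               "same waveforms")
  degen <- lapply(canonical_stim_win, function(w) rep(1, length(w)))
  expect_error(invariance_score(canonical_stim_win, degen),
               "degenerate stimulus set")
})

test_that("score agrees with the literal oracle on 100 random fixtures", {
  for (seed in 1:100) {
    set.seed(seed)
    n <- sample(4:8, 1)
    labs <- paste0("S", seq_len(n))
    len <- sample(c(40, 80, 160), 1)
    stim <- stats::setNames(lapply(labs, function(l) rnorm(len)), labs)
    resp <- stats::setNames(lapply(labs, function(l)
      cumsum(rnorm(len)) / 4), labs)
    conv <- if (seed %% 2) "rms" else "squared"
    expect_equal(invariance_score(resp, stim, convention = conv)$value,
                 oracle_invariance(resp, stim, conv), tolerance = 1e-12)
  }
})

test_that("expected score decreases with added response noise", {
  base <- lapply(canonical_stim_win, function(w)
    sin(seq(0, 3, length.out = length(w))))
  levels <- c(0.05, 0.2, 0.8)
  scores <- sapply(1:50, function(seed) {
    withr::with_seed(seed, vapply(levels, function(lv) {
      noisy <- lapply(base, function(b) b + rnorm(length(b), 0, lv))
      invariance_score(noisy, canonical_stim_win)$value
    }, numeric(1)))
  })
  means <- rowMeans(scores)
  expect_true(all(diff(means) < 0))
  expect_true(all(scores <= 1))
})

test_that("chirp window extraction covers [onset, onset + length)", {
  w <- canonical_waves$S1
  seg <- chirp_window(w, length = 0.03)
  expect_length(seg, 0.03 * w$sample_rate)
  idx <- which(w$time >= canonical_onset & w$time < canonical_onset + 0.03)
  expect_equal(seg, w$samples[idx])
  expect_error(chirp_window(list(time = 1:5, rate = 1:5), onset = 2),
               "unsupported trace type")
})

test_that("tuning curves require complete phases and normalize to unit peak", {
  resp <- matrix(c(1, 2, -4, 3), 1, dimnames = list(NULL, c(0, 90, 180, 270)))
  tc <- build_tuning_curve(resp)
  expect_equal(tc$phase, c(0, 90, 180, 270))
  expect_equal(unname(tc$sem), rep(0, 4))
  expect_equal(max(abs(tc$normalized)), 1)
  expect_error(build_tuning_curve(cbind(resp, "315" = NA)),
               "every phase")
  flat <- matrix(rep(2, 16), 2, dimnames = list(NULL, seq(0, 315, 45)))
  tcf <- build_tuning_curve(flat)
  expect_equal(unname(tcf$mean), rep(2, 8))
  expect_equal(unname(tcf$sem), rep(0, 8))
})
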