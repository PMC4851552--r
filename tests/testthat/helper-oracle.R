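# Shared fixtures and independent literal re-implementations used as oracles.

# canonical stimulus set and 30 ms analysis windows
canonical_waves <- make_waveform_set(beat_spec(), chirp_spec())
canonical_onset <- canonical_waves$S1$chirp_onset_time
canonical_stim_win <- lapply(canonical_waves, chirp_window, length = 0.03)
canonical_signs <- stats::setNames(rep(c("+", "-"), each = 4),
                                   names(canonical_waves))

# literal normalization: mean-subtract, divide by max absolute deviation
oracle_normalize <- function(x) {
  x <- x[!is.na(x)]
  d <- x - mean(x)
  m <- max(abs(d))
  if (m == 0) d else d / m
}

# literal distance between already-normalized traces
oracle_distance <- function(x, y, convention = "rms") {
  hr <- max((max(x) - min(x)) / 2, (max(y) - min(y)) / 2)
  if (hr == 0) return(0)
  acc <- 0
  for (k in seq_along(x))
    acc <- acc + ((x[k] - mean(x)) - (y[k] - mean(y)))^2
  num <- acc / length(x)
  if (convention == "rms") num <- sqrt(num)
  num / hr
}

# literal invariance: explicit double loop over ordered pairs i != j,
# sum of distance ratios divided by N * (N - 1)
oracle_invariance <- function(responses, stimuli, convention = "rms") {
  labs <- names(responses)
  n <- length(labs)
  acc <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    dr <- oracle_distance(oracle_normalize(responses[[labs[i]]]),
                          oracle_normalize(responses[[labs[j]]]), convention)
    ds <- oracle_distance(oracle_normalize(stimuli[[labs[i]]]),
                          oracle_normalize(stimuli[[labs[j]]]), convention)
    acc <- acc + dr / ds
  }
  1 - acc / (n * (n - 1))
}

# homogeneous Poisson spike trains, one list element per trial
poisson_trains <- function(n_trials, rate, duration) {
  lapply(seq_len(n_trials), function(k)
    sort(stats::runif(stats::rpois(1, rate * duration), 0, duration)))
}
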