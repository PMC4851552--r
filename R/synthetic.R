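# Synthetic electrosensory hierarchy: seeded spike-train and EOD-trace
# generators with the statistical structure the analysis assumes.
#
# Spiking is an inhomogeneous Poisson process with an absolute refractory
# period. The underlying Poisson intensity is hazard-corrected,
# h(t) = r(t) / (1 - r(t) * refractory), so that after refractory deletion
# the realized rate matches the requested r(t) (exactly for constant rates).

#' Neuron model parameters
#'
#' @param stage One of \code{"afferent"} (P-unit electroreceptor afferent,
#'   ~380 Hz baseline), \code{"ELL_ON"} / \code{"ELL_OFF"} (hindbrain
#'   pyramidal cells, ~12.1 Hz baseline, opposite-signed responses to AM
#'   up/down strokes), \code{"TS"} (midbrain torus semicircularis,
#'   ~3.35 Hz baseline, excited by both chirp polarities).
#' @param baseline_rate Baseline firing rate in Hz (stage default used when
#'   \code{NULL}).
#' @param gain Dimensionless modulation gain (stage default when \code{NULL}:
#'   0.9 for afferents, 4 for pyramidal cells; for TS this is the convergence
#'   weight w, default 4).
#' @param refractory Absolute refractory period in seconds (1 ms for
#'   afferents, 2 ms centrally).
#' @param smooth Synaptic integration (boxcar) length in seconds: for
#'   pyramidal cells it low-passes the drive signal (default 20 ms,
#'   synaptic/burst integration merging the fast AM strokes of a chirp into
#'   one response envelope); for TS neurons it integrates the summed rectified
#'   ON/OFF input. Ignored for afferents.
#' @param adapt Adaptation (slow-subtraction boxcar) length in seconds for the
#'   pyramidal drive (default 40 ms): subtracting the running mean removes
#'   most of the slow 4 Hz beat from the drive while the faster chirp
#'   transient passes.
#' @param latency Synaptic/axonal conduction delay in seconds applied to the
#'   pyramidal drive (default 0); ignored for other stages.
#' @return Object of class \code{neuron_model}.
#' @export
neuron_model <- function(stage = c("afferent", "ELL_ON", "ELL_OFF", "TS"),
                         baseline_rate = NULL, gain = NULL,
                         refractory = NULL, smooth = 0.020, adapt = 0.04,
                         latency = 0) {
  stage <- match.arg(stage)
  defaults <- list(
    afferent = list(baseline = 380, gain = 0.9, refractory = 0.001),
    ELL_ON   = list(baseline = 12.1, gain = 4, refractory = 0.002),
    ELL_OFF  = list(baseline = 12.1, gain = 4, refractory = 0.002),
    TS       = list(baseline = 3.35, gain = 4, refractory = 0.002))[[stage]]
  if (is.null(baseline_rate)) baseline_rate <- defaults$baseline
  if (is.null(gain)) gain <- defaults$gain
  if (is.null(refractory)) refractory <- defaults$refractory
  stopifnot(baseline_rate > 0, refractory >= 0)
  structure(list(stage = stage, baseline_rate = baseline_rate, gain = gain,
                 refractory = refractory, smooth = smooth, adapt = adapt,
                 latency = latency),
            class = "neuron_model")
}

#' @export
print.neuron_model <- function(x, ...) {
  cat(sprintf("Neuron model [%s]: baseline %g Hz, gain %g, refractory %g ms\n",
              x$stage, x$baseline_rate, x$gain, 1000 * x$refractory))
  invisible(x)
}

# boxcar smoothing with partial windows at the edges (no NA padding)
.boxcar <- function(x, w) {
  if (w <= 1) return(x)
  cs <- cumsum(c(0, x))
  n <- length(x)
  lo <- pmax(0L, seq_len(n) - ceiling(w / 2))
  hi <- pmin(n, seq_len(n) + floor(w / 2) - 1L) + 1L
  (cs[hi] - cs[lo + 1L]) / (hi - lo - 1L)
}

# greedy enforcement of an absolute refractory period on sorted spike times
.prune_refractory <- function(tt, refractory) {
  n <- length(tt)
  if (n < 2 || refractory <= 0) return(tt)
  keep <- logical(n)
  keep[1] <- TRUE
  last <- tt[1]
  for (i in 2:n) {
    if (tt[i] - last >= refractory) {
      keep[i] <- TRUE
      last <- tt[i]
    }
  }
  tt[keep]
}

# one trial of refractory-Poisson spiking from a sampled rate trace (Hz)
.sim_spike_train <- function(rate, sample_rate, duration, refractory) {
  r <- pmax(rate, 0)
  h <- r / (1 - pmin(r * refractory, 0.9))
  hmax <- max(h)
  if (hmax <= 0) return(numeric(0))
  n <- stats::rpois(1, hmax * duration)
  if (n == 0) return(numeric(0))
  cand <- sort(stats::runif(n, 0, duration))
  idx <- pmin(floor(cand * sample_rate) + 1L, length(h))
  times <- cand[stats::runif(n) < h[idx] / hmax]
  .prune_refractory(times, refractory)
}

# shift a sampled trace by delta seconds (positive delta delays the trace),
# padding edges with the boundary value
.shift_trace <- function(x, delta, sample_rate) {
  m <- round(delta * sample_rate)
  if (m == 0) return(x)
  n <- length(x)
  x[pmin(pmax(seq_len(n) - m, 1L), n)]
}

.as_set <- function(trial_times, duration, neuron_id, waveform, meta) {
  spike_train_set(
    data.frame(
      neuron_id = neuron_id, waveform = waveform,
      trial = rep(seq_along(trial_times), lengths(trial_times)),
      time = unlist(trial_times)),
    duration = duration, n_trials = length(trial_times), meta = meta)
}

#' Simulate afferent responses to one AM waveform
#'
#' P-unit rate model r(t) = max(0, baseline * (1 + gain * S(t - delta_k))),
#' where delta_k is an optional per-trial stimulus-alignment jitter emulating
#' imperfect alignment between stimulus delivery and the animal's EOD. Trials
#' are independent given the (jittered) stimulus.
#'
#' @param model A \code{\link{neuron_model}} with stage \code{"afferent"}.
#' @param wave An \code{am_waveform}.
#' @param n_trials Number of trials (>= 1).
#' @param seed Integer seed; identical seed and parameters reproduce the set
#'   bit-for-bit.
#' @param jitter_sd SD of the per-trial alignment jitter in seconds (default
#'   0: perfectly aligned trials).
#' @param trial_jitter Optional explicit jitter vector (one value per trial),
#'   overriding \code{jitter_sd}; this is how a stimulus protocol shares its
#'   per-trial alignment across neurons.
#' @param neuron_id Id recorded in the output set.
#' @return A \code{\link{spike_train_set}} for one neuron and one waveform.
#' @export
simulate_afferent_trials <- function(model, wave, n_trials = 20, seed = NULL,
                                     jitter_sd = 0, trial_jitter = NULL,
                                     neuron_id = "afferent_1") {
  stopifnot(inherits(model, "neuron_model"), model$stage == "afferent",
            inherits(wave, "am_waveform"))
  if (n_trials < 1) stop("n_trials must be at least 1")
  sim <- function() {
    if (is.null(trial_jitter))
      trial_jitter <- if (jitter_sd > 0)
        stats::rnorm(n_trials, 0, jitter_sd) else rep(0, n_trials)
    dur <- length(wave$samples) / wave$sample_rate
    trials <- lapply(seq_len(n_trials), function(k) {
      s <- .shift_trace(wave$samples, trial_jitter[k], wave$sample_rate)
      r <- pmax(0, model$baseline_rate * (1 + model$gain * s))
      .sim_spike_train(r, wave$sample_rate, dur, model$refractory)
    })
    .as_set(trials, dur, neuron_id, wave$label,
            list(model = unclass(model), seed = seed, jitter_sd = jitter_sd,
                 trial_jitter = trial_jitter))
  }
  if (is.null(seed)) sim() else withr::with_seed(seed, sim())
}

#' Simulate a pair of afferents with shared stimulus drive
#'
#' Both members respond to the identical effective stimulus on every trial but
#' spike independently given that stimulus, so all across-trial count
#' correlation is stimulus-induced. The effective stimulus varies from trial
#' to trial in two shared ways: an alignment jitter delta_k shifting the whole
#' waveform, and a chirp-intensity fluctuation b_k scaling the received
#' amplitude modulation in proportion to the chirp's Gaussian frequency
#' excursion envelope E(t) (relative movement of the emitting fish changes how
#' strongly its chirp is received). Each member's rate on trial k is
#' r(t) = max(0, baseline * (1 + gain * S(t - delta_k)) * (1 + b_k * E(t))).
#' Because E(t) is zero away from the chirp, trials are exchangeable and
#' residual (noise) correlations vanish over beat-only epochs, while during
#' the chirp the shared intensity fluctuation evokes across-trial count
#' correlation whose time course follows the phase-invariant envelope.
#'
#' @inheritParams simulate_afferent_trials
#' @param model_i,model_j Afferent \code{\link{neuron_model}}s.
#' @param jitter_sd SD of the shared per-trial alignment jitter in seconds
#'   (default 0).
#' @param chirp_gain_sd SD of the shared per-trial chirp-intensity
#'   fluctuation b_k (dimensionless, default 0.5); the factor
#'   1 + b_k * E(t) is clipped at 0.
#' @return List of two \code{\link{spike_train_set}}s (\code{i}, \code{j}).
#' @export
simulate_afferent_pair <- function(model_i, model_j, wave, n_trials = 60,
                                   seed = NULL, jitter_sd = 0,
                                   chirp_gain_sd = 0.5) {
  stopifnot(inherits(model_i, "neuron_model"), model_i$stage == "afferent",
            inherits(model_j, "neuron_model"), model_j$stage == "afferent",
            inherits(wave, "am_waveform"))
  run <- function() {
    jit <- if (jitter_sd > 0) stats::rnorm(n_trials, 0, jitter_sd)
           else rep(0, n_trials)
    b <- if (chirp_gain_sd > 0) stats::rnorm(n_trials, 0, chirp_gain_sd)
         else rep(0, n_trials)
    env <- exp(-(wave$time - wave$chirp_center_time)^2 / (2 * wave$sigma^2))
    dur <- length(wave$samples) / wave$sample_rate
    one <- function(model, id) {
      trials <- lapply(seq_len(n_trials), function(k) {
        s <- .shift_trace(wave$samples, jit[k], wave$sample_rate)
        r <- pmax(0, model$baseline_rate * (1 + model$gain * s) *
                       pmax(0, 1 + b[k] * env))
        .sim_spike_train(r, wave$sample_rate, dur, model$refractory)
      })
      .as_set(trials, dur, id, wave$label,
              list(model = unclass(model), seed = seed, jitter_sd = jitter_sd,
                   chirp_gain_sd = chirp_gain_sd, trial_jitter = jit,
                   trial_chirp_gain = b))
    }
    list(i = one(model_i, "pair_i"), j = one(model_j, "pair_j"))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Pyramidal-cell rate drive for one AM waveform
#'
#' The ON/OFF drive signal H(t) is the band-pass filtered AM deviation:
#' a fast boxcar (\code{smooth}, synaptic integration) minus a slow boxcar
#' (\code{adapt}, rate adaptation) applied to the AM. The rate is
#' r(t) = max(0, baseline * (1 + gain * H(t))) for ON cells and
#' r(t) = max(0, baseline * (1 - gain * H(t))) for OFF cells, so ON cells are
#' excited on AM upstrokes and OFF cells on downstrokes, with the fast chirp
#' transient passing at higher gain than the slow beat.
#'
#' @param model \code{\link{neuron_model}} with stage \code{"ELL_ON"} or
#'   \code{"ELL_OFF"}.
#' @param wave An \code{am_waveform}.
#' @return Object of class \code{rate_drive}: list with \code{time},
#'   \code{rate}, \code{baseline}, \code{stage}, \code{sample_rate}.
#' @export
pyramidal_drive <- function(model, wave) {
  stopifnot(model$stage %in% c("ELL_ON", "ELL_OFF"))
  w <- max(1L, round(model$smooth * wave$sample_rate))
  slow <- max(1L, round(model$adapt * wave$sample_rate))
  h <- .boxcar(wave$samples, w) - .boxcar(wave$samples, slow)
  h <- .shift_trace(h, model$latency, wave$sample_rate)
  sgn <- if (model$stage == "ELL_ON") 1 else -1
  structure(list(time = wave$time,
                 rate = pmax(0, model$baseline_rate * (1 + sgn * model$gain * h)),
                 baseline = model$baseline_rate, stage = model$stage,
                 sample_rate = wave$sample_rate),
            class = "rate_drive")
}

#' Simulate ELL pyramidal-cell responses to one AM waveform
#'
#' @inheritParams simulate_afferent_trials
#' @param model \code{\link{neuron_model}} with stage \code{"ELL_ON"} or
#'   \code{"ELL_OFF"}.
#' @return A \code{\link{spike_train_set}}.
#' @export
simulate_pyramidal_trials <- function(model, wave, n_trials = 20, seed = NULL,
                                      jitter_sd = 0, trial_jitter = NULL,
                                      neuron_id = "pyramidal_1") {
  stopifnot(inherits(model, "neuron_model"),
            model$stage %in% c("ELL_ON", "ELL_OFF"))
  if (n_trials < 1) stop("n_trials must be at least 1")
  drive <- pyramidal_drive(model, wave)
  sim <- function() {
    if (is.null(trial_jitter))
      trial_jitter <- if (jitter_sd > 0)
        stats::rnorm(n_trials, 0, jitter_sd) else rep(0, n_trials)
    dur <- length(drive$rate) / drive$sample_rate
    trials <- lapply(seq_len(n_trials), function(k) {
      r <- .shift_trace(drive$rate, trial_jitter[k], drive$sample_rate)
      .sim_spike_train(r, drive$sample_rate, dur, model$refractory)
    })
    .as_set(trials, dur, neuron_id, wave$label,
            list(model = unclass(model), seed = seed, jitter_sd = jitter_sd))
  }
  if (is.null(seed)) sim() else withr::with_seed(seed, sim())
}

#' TS rate from converging rectified ON and OFF drives
#'
#' r(t) = max(0, baseline + w * E(t)) where E is the synaptically integrated
#' (boxcar of length \code{model$smooth}) sum of the rectified ON and OFF
#' drive deviations (on - baseline_ON)_+ + (off - baseline_OFF)_+ : midbrain
#' TS neurons receive excitatory-only input from both pyramidal populations,
#' so both chirp polarities excite them, and their synaptic integration pools
#' the fast alternation of ON and OFF excitation within a chirp into one
#' response envelope.
#'
#' @param on_drive,off_drive \code{rate_drive} objects from
#'   \code{\link{pyramidal_drive}} for the same waveform.
#' @param model \code{\link{neuron_model}} with stage \code{"TS"}; its
#'   \code{gain} is the convergence weight w and its \code{smooth} the
#'   integration window.
#' @return A \code{rate_drive} for the TS unit.
#' @export
ts_rate <- function(on_drive, off_drive, model) {
  stopifnot(model$stage == "TS")
  if (length(on_drive$rate) != length(off_drive$rate))
    stop("ON and OFF drive traces have mismatched lengths")
  exc <- pmax(on_drive$rate - on_drive$baseline, 0) +
         pmax(off_drive$rate - off_drive$baseline, 0)
  exc <- .boxcar(exc, max(1L, round(model$smooth * on_drive$sample_rate)))
  structure(list(time = on_drive$time,
                 rate = pmax(0, model$baseline_rate + model$gain * exc),
                 baseline = model$baseline_rate, stage = "TS",
                 sample_rate = on_drive$sample_rate),
            class = "rate_drive")
}

#' Simulate TS neuron responses from ON and OFF pyramidal drives
#'
#' @inheritParams simulate_afferent_trials
#' @param on_drive,off_drive \code{rate_drive} objects for the same waveform.
#' @param model \code{\link{neuron_model}} with stage \code{"TS"}.
#' @return A \code{\link{spike_train_set}}.
#' @export
simulate_ts_trials <- function(on_drive, off_drive, model, n_trials = 20,
                               seed = NULL, neuron_id = "ts_1",
                               waveform = NA_character_) {
  if (n_trials < 1) stop("n_trials must be at least 1")
  drive <- ts_rate(on_drive, off_drive, model)
  sim <- function() {
    dur <- length(drive$rate) / drive$sample_rate
    trials <- lapply(seq_len(n_trials), function(k)
      .sim_spike_train(drive$rate, drive$sample_rate, dur, model$refractory))
    .as_set(trials, dur, neuron_id, waveform,
            list(model = unclass(model), seed = seed))
  }
  if (is.null(seed)) sim() else withr::with_seed(seed, sim())
}

#' Simulate a behavioral echo-response experiment
#'
#' Generates an EOD instantaneous-frequency trace for one fish: constant
#' baseline plus Gaussian echo-chirp excursions injected after each stimulus
#' chirp with probability \code{p_echo}, at a gamma-distributed latency
#' truncated to (0, 1 s]. The default protocol presents 40 stimulus chirps
#' (each of the 8 beat phases five times, shuffled) at uniform 15 +/- 3 s
#' intervals. Echo probability is independent of stimulus phase unless
#' \code{p_echo} is a named per-phase vector.
#'
#' @param n_repeats Presentations per phase (default 5).
#' @param phases Stimulus beat phases in degrees (default canonical eight).
#' @param p_echo Echo probability per presentation: scalar, or named numeric
#'   vector over \code{phases}.
#' @param latency_shape,latency_scale Gamma parameters of the echo latency in
#'   seconds (defaults give mean 0.4 s); draws above 1 s are redrawn.
#' @param isi_range Uniform range of inter-stimulus intervals in seconds.
#' @param eod_baseline Baseline EOD frequency in Hz.
#' @param echo_df_mean,echo_df_sd Mean and SD of the echo peak frequency
#'   excursion in Hz (draws below 35 Hz are redrawn so every injected echo
#'   exceeds the 30 Hz detection criterion).
#' @param echo_sigma SD of the Gaussian echo excursion in seconds.
#' @param sample_rate Sample rate of the frequency trace in Hz.
#' @param seed Integer seed.
#' @return Object of class \code{echo_experiment}: list with \code{time},
#'   \code{eod_frequency}, \code{sample_rate}, \code{baseline},
#'   \code{stimuli} (data frame: index, onset, phase),
#'   \code{true_echo_times}, \code{true_echo_df}.
#' @export
simulate_echo_experiment <- function(n_repeats = 5,
                                     phases = seq(0, 315, by = 45),
                                     p_echo = 0.5,
                                     latency_shape = 4, latency_scale = 0.1,
                                     isi_range = c(12, 18),
                                     eod_baseline = 800,
                                     echo_df_mean = 60, echo_df_sd = 10,
                                     echo_sigma = 0.014,
                                     sample_rate = 1000, seed = NULL) {
  if (length(p_echo) == 1) {
    p_echo <- stats::setNames(rep(p_echo, length(phases)),
                              as.character(phases))
  }
  stopifnot(all(p_echo >= 0 & p_echo <= 1),
            setequal(names(p_echo), as.character(phases)))
  run <- function() {
    phase_seq <- sample(rep(phases, n_repeats))
    n_stim <- length(phase_seq)
    onsets <- 5 + cumsum(stats::runif(n_stim, isi_range[1], isi_range[2]))
    echoed <- stats::runif(n_stim) < p_echo[as.character(phase_seq)]
    lat <- rep(NA_real_, n_stim)
    for (k in which(echoed)) {
      repeat {
        l <- stats::rgamma(1, shape = latency_shape, scale = latency_scale)
        if (l > 0 && l <= 1) break
      }
      lat[k] <- l
    }
    echo_times <- onsets[echoed] + lat[echoed]
    df <- vapply(seq_along(echo_times), function(k) {
      repeat {
        d <- stats::rnorm(1, echo_df_mean, echo_df_sd)
        if (d >= 35) return(d)
      }
    }, numeric(1))
    dur <- max(onsets) + 3
    t <- seq(0, dur, by = 1 / sample_rate)
    f <- rep(eod_baseline, length(t))
    for (k in seq_along(echo_times))
      f <- f + df[k] * exp(-(t - echo_times[k])^2 / (2 * echo_sigma^2))
    structure(list(time = t, eod_frequency = f, sample_rate = sample_rate,
                   baseline = eod_baseline,
                   stimuli = data.frame(index = seq_len(n_stim),
                                        onset = onsets, phase = phase_seq),
                   true_echo_times = echo_times, true_echo_df = df),
              class = "echo_experiment")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @export
print.echo_experiment <- function(x, ...) {
  cat(sprintf(
    "Echo experiment: %d stimuli over %.0f s, %d injected echoes, EOD baseline %g Hz\n",
    nrow(x$stimuli), max(x$time), length(x$true_echo_times), x$baseline))
  invisible(x)
}

#' Write / read a spike-train set as delimited text plus a JSON sidecar
#'
#' Columns: \code{neuron_id}, \code{waveform_label}, \code{trial},
#' \code{spike_time_s}; the sidecar holds duration, trial count and generator
#' metadata.
#'
#' @param set A \code{\link{spike_train_set}}.
#' @param path Output file path.
#' @return \code{path} (write) or the reconstructed set (read).
#' @export
write_spike_set <- function(set, path) {
  utils::write.table(
    data.frame(neuron_id = set$spikes$neuron_id,
               waveform_label = set$spikes$waveform,
               trial = set$spikes$trial,
               spike_time_s = set$spikes$time),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(duration = set$duration, n_trials = set$n_trials,
                            meta = set$meta),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_spike_set
#' @export
read_spike_set <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = c("character", "character",
                                          "integer", "numeric"))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  spike_train_set(
    data.frame(neuron_id = tab$neuron_id, waveform = tab$waveform_label,
               trial = tab$trial, time = tab$spike_time_s),
    duration = meta$duration, n_trials = meta$n_trials,
    meta = as.list(meta$meta))
}
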