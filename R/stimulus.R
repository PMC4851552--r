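# Synthesis of chirp-on-beat amplitude-modulation (AM) stimulus waveforms.
#
# The beat is the sinusoidal AM a receiver fish experiences when a conspecific
# is nearby; a (type II, "small") chirp is a brief Gaussian excursion of the
# emitter's EOD frequency that transiently accelerates, and thereby resets,
# the beat. All downstream analysis operates on the AM itself, so the AM
# envelope is modelled directly as sin(phi(t)) rather than riding on an EOD
# carrier.

#' Chirp parameter set
#'
#' Describes one chirp identity: a Gaussian electric-organ-discharge (EOD)
#' frequency excursion riding on the beat.
#'
#' @param delta_f Peak EOD frequency excursion in Hz (> 0 unless explicitly 0
#'   for a chirp-free control).
#' @param sigma Standard deviation of the Gaussian excursion in seconds.
#' @param onset_phase Beat phase label of the waveform in degrees (see
#'   Details).
#'
#' @details Beat phase is referenced to the upward zero crossing of the beat
#' sinusoid (0 deg), increasing so that 90 deg is the beat peak. A waveform's
#' label indexes where in the beat cycle the chirp occurs; the physical beat
#' phase at the chirp's peak-excursion time is the label plus a fixed
#' calibration offset of the preparation (see
#' \code{\link{synthesize_am_waveform}}, argument \code{phase_offset}). The
#' canonical set uses labels 0, 45, ..., 315 deg.
#'
#' @return An object of class \code{chirp_spec}.
#' @export
chirp_spec <- function(delta_f = 60, sigma = 0.014, onset_phase = 0) {
  stopifnot(is.numeric(delta_f), length(delta_f) == 1, delta_f >= 0,
            is.numeric(sigma), length(sigma) == 1, sigma > 0,
            is.numeric(onset_phase), length(onset_phase) == 1)
  structure(list(delta_f = delta_f, sigma = sigma,
                 onset_phase = onset_phase %% 360),
            class = "chirp_spec")
}

#' Beat parameter set
#'
#' @param f_beat Beat frequency in Hz (difference between the two fishes' EOD
#'   frequencies).
#' @param duration Trace length in seconds.
#' @param sample_rate Samples per second (Hz); must allow at least one full
#'   beat cycle on either side of the chirp.
#'
#' @return An object of class \code{beat_spec}.
#' @export
beat_spec <- function(f_beat = 4, duration = 2, sample_rate = 10000) {
  stopifnot(f_beat > 0, sample_rate >= 2000, duration > 0)
  if (duration < 2 / f_beat)
    stop("duration must cover at least one full beat cycle before and after the chirp")
  structure(list(f_beat = f_beat, duration = duration,
                 sample_rate = sample_rate),
            class = "beat_spec")
}

#' Gaussian EOD frequency excursion
#'
#' Evaluates the chirp's frequency excursion g(t) = delta_f *
#' exp(-(t - center)^2 / (2 sigma^2)) on a time grid.
#'
#' @param spec A \code{\link{chirp_spec}}.
#' @param t Uniformly sampled time grid (seconds).
#' @param center Time of peak excursion (seconds); must lie inside \code{t}.
#' @return Numeric vector of frequency excursions (Hz), same length as
#'   \code{t}.
#' @export
gaussian_frequency_excursion <- function(spec, t, center) {
  stopifnot(inherits(spec, "chirp_spec"), is.numeric(t), length(t) >= 2)
  if (center < min(t) || center > max(t))
    stop("chirp center lies outside the time grid")
  spec$delta_f * exp(-(t - center)^2 / (2 * spec$sigma^2))
}

# cumulative trapezoid integral of y on a uniform grid with spacing dt
.cumtrapz <- function(y, dt) {
  n <- length(y)
  c(0, cumsum((y[-1] + y[-n]) / 2)) * dt
}

#' Synthesize one chirp-on-beat AM waveform
#'
#' Builds S(t) = sin(phi(t)) with phi(t) = 2 pi * integral of
#' (f_beat + g(tau)) dtau + phi0, where g is the chirp's Gaussian frequency
#' excursion and phi0 is chosen so that the beat phase at the peak-excursion
#' time equals the chirp's phase label plus \code{phase_offset}.
#'
#' @param beat A \code{\link{beat_spec}}.
#' @param chirp A \code{\link{chirp_spec}}.
#' @param chirp_center Time of peak frequency excursion in seconds (default:
#'   middle of the trace).
#' @param onset_sigma Analysis anchor: the chirp onset time recorded on the
#'   waveform is \code{chirp_center - onset_sigma * sigma}, the point where
#'   the frequency excursion becomes appreciable. Response and distance
#'   windows downstream are referenced to this onset.
#' @param phase_offset Fixed offset in degrees between the labelling
#'   convention and the synthesis anchor: the physical beat phase at the
#'   peak-excursion time is \code{onset_phase + phase_offset}. The default is
#'   calibrated once, deterministically, so that the canonical waveform set
#'   reproduces the '+'/'-' grouping (phases below 180 degrees excite model
#'   afferents, the rest inhibit them) under the default analysis windows.
#' @param label Optional waveform id (e.g. "S1").
#'
#' @return An object of class \code{am_waveform}: a list with elements
#'   \code{time}, \code{samples}, \code{sample_rate}, \code{f_beat},
#'   \code{chirp_center_time}, \code{chirp_onset_time}, \code{onset_phase},
#'   \code{delta_f}, \code{sigma}, \code{label}.
#' @export
synthesize_am_waveform <- function(beat, chirp,
                                   chirp_center = beat$duration / 2,
                                   onset_sigma = 1.75, phase_offset = 232.8,
                                   label = NA_character_) {
  stopifnot(inherits(beat, "beat_spec"), inherits(chirp, "chirp_spec"))
  dt <- 1 / beat$sample_rate
  t <- seq(0, beat$duration - dt, by = dt)
  g <- gaussian_frequency_excursion(chirp, t, chirp_center)
  cycles <- beat$f_beat * t + .cumtrapz(g, dt)
  cyc_center <- stats::approx(t, cycles, chirp_center)$y
  phi <- 2 * pi * (cycles - cyc_center +
                   (chirp$onset_phase + phase_offset) / 360)
  onset <- chirp_center - onset_sigma * chirp$sigma
  if (onset <= t[1] || onset >= t[length(t)])
    stop("chirp onset time is not strictly inside the trace")
  structure(list(time = t, samples = sin(phi),
                 sample_rate = beat$sample_rate, f_beat = beat$f_beat,
                 chirp_center_time = chirp_center, chirp_onset_time = onset,
                 onset_phase = chirp$onset_phase, delta_f = chirp$delta_f,
                 sigma = chirp$sigma, label = label),
            class = "am_waveform")
}

#' Canonical set of eight chirp-on-beat waveforms
#'
#' Generates the AM waveforms produced by one chirp identity occurring at the
#' eight canonical beat phases 0, 45, ..., 315 deg, labelled S1 to S8 in
#' phase order.
#'
#' @inheritParams synthesize_am_waveform
#' @param chirp_template A \code{\link{chirp_spec}} whose \code{onset_phase}
#'   is ignored and replaced by each canonical phase.
#' @return Named list of eight \code{am_waveform} objects ("S1" ... "S8").
#' @export
make_waveform_set <- function(beat, chirp_template,
                              chirp_center = beat$duration / 2,
                              onset_sigma = 1.75, phase_offset = 232.8) {
  phases <- seq(0, 315, by = 45)
  waves <- lapply(seq_along(phases), function(i) {
    ch <- chirp_spec(chirp_template$delta_f, chirp_template$sigma, phases[i])
    synthesize_am_waveform(beat, ch, chirp_center, onset_sigma, phase_offset,
                           label = paste0("S", i))
  })
  names(waves) <- paste0("S", seq_along(phases))
  waves
}

#' Read back the beat phase of a waveform at a given time
#'
#' Inverts S = sin(phi) using the local derivative sign to disambiguate the
#' arcsin branch; used to verify the phase convention.
#'
#' @param wave An \code{am_waveform}.
#' @param time Time (seconds) at which to read the phase.
#' @return Phase in degrees in [0, 360).
#' @export
beat_phase_at <- function(wave, time) {
  stopifnot(inherits(wave, "am_waveform"))
  i <- which.min(abs(wave$time - time))
  if (i == length(wave$time)) i <- i - 1L
  s <- max(-1, min(1, wave$samples[i]))
  rising <- wave$samples[i + 1L] >= wave$samples[i]
  ph <- asin(s)                      # [-pi/2, pi/2]
  if (!rising) ph <- pi - ph
  (ph * 180 / pi) %% 360
}

#' @export
print.am_waveform <- function(x, ...) {
  cat(sprintf(
    "AM waveform %s: %.3g s at %g Hz, beat %g Hz, chirp df=%g Hz sd=%g ms\n",
    ifelse(is.na(x$label), "<unlabelled>", x$label),
    length(x$samples) / x$sample_rate, x$sample_rate, x$f_beat,
    x$delta_f, 1000 * x$sigma))
  cat(sprintf("  phase label %g deg; chirp onset %.4f s, peak %.4f s\n",
              x$onset_phase, x$chirp_onset_time, x$chirp_center_time))
  invisible(x)
}

#' Write / read an AM waveform as delimited text plus a JSON sidecar
#'
#' The waveform samples go to a two-column tab-separated file
#' (\code{time_s}, \code{amplitude}); parameters go to \code{<path>.json}.
#'
#' @param wave An \code{am_waveform}.
#' @param path Output file path.
#' @return \code{write_am_waveform} returns \code{path} invisibly;
#'   \code{read_am_waveform} returns the reconstructed \code{am_waveform}.
#' @export
write_am_waveform <- function(wave, path) {
  stopifnot(inherits(wave, "am_waveform"))
  utils::write.table(
    data.frame(time_s = wave$time, amplitude = wave$samples),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- wave[c("sample_rate", "f_beat", "chirp_center_time",
                 "chirp_onset_time", "onset_phase", "delta_f", "sigma",
                 "label")]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_am_waveform
#' @export
read_am_waveform <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(c(list(time = tab$time_s, samples = tab$amplitude), meta),
            class = "am_waveform")
}
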