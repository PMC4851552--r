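# Phase-invariance statistics: log-ratio chirp responses, tuning curves,
# normalized trace distances, and the invariance score
#
#   Invariance = 1 - mean over waveform pairs i != j of
#                    D(resp_i, resp_j) / D(S_i, S_j)
#
# where D is a normalized distance between traces restricted to a 30 ms
# window after chirp onset. A score near 1 means all response traces are the
# same; near 0 means responses are as heterogeneous as the stimulus waveforms
# themselves (faithful encoding).

#' Chirp-response measure: log firing-rate ratio
#'
#' Response = log(FR_chirp / FR_beat), where FR_chirp is the mean rate over a
#' window of duration \code{t_chirp} centered 15 ms after chirp onset, and
#' FR_beat is the mean rate over beat-only epochs (all samples further than
#' \code{beat_exclusion} from the chirp onset). Rates are floored at
#' \code{rate_floor} before taking the ratio; a floored window is flagged.
#'
#' @param psth A \code{\link{compute_psth}} object (or a list with
#'   \code{time} and \code{rate}).
#' @param chirp_onset Chirp onset time in seconds.
#' @param stage One of \code{"afferent"}, \code{"ELL"}, \code{"TS"}; sets the
#'   default \code{t_chirp} (15 ms for afferents and ELL pyramidal cells,
#'   20 ms for TS neurons).
#' @param t_chirp Response-window duration in seconds (overrides the stage
#'   default).
#' @param rate_floor Floor applied to both rates, in Hz (default 0.1).
#' @param beat_exclusion Half-width of the epoch excluded around the chirp
#'   when estimating FR_beat, in seconds (default 0.1).
#' @param log_base Base of the logarithm (default natural).
#' @return An object of class \code{response_value}: list with \code{value},
#'   \code{fr_chirp}, \code{fr_beat}, \code{flagged}.
#' @export
response_measure <- function(psth, chirp_onset,
                             stage = c("afferent", "ELL", "TS"),
                             t_chirp = NULL, rate_floor = 0.1,
                             beat_exclusion = 0.1, log_base = exp(1)) {
  stage <- match.arg(stage)
  if (is.null(t_chirp)) t_chirp <- if (stage == "TS") 0.020 else 0.015
  tm <- psth$time
  center <- chirp_onset + 0.015
  if (center - t_chirp / 2 < min(tm) || center + t_chirp / 2 > max(tm))
    stop("chirp response window lies outside the trace")
  in_win <- tm >= center - t_chirp / 2 & tm < center + t_chirp / 2
  in_beat <- abs(tm - chirp_onset) > beat_exclusion
  fr_chirp <- mean(psth$rate[in_win], na.rm = TRUE)
  fr_beat <- mean(psth$rate[in_beat], na.rm = TRUE)
  flagged <- fr_chirp < rate_floor || fr_beat < rate_floor || fr_beat <= 0
  value <- log(max(fr_chirp, rate_floor) / max(fr_beat, rate_floor),
               base = log_base)
  structure(list(value = value, fr_chirp = fr_chirp, fr_beat = fr_beat,
                 t_chirp = t_chirp, stage = stage, flagged = flagged),
            class = "response_value")
}

#' Classify waveforms as '+ chirps' or '- chirps'
#'
#' A waveform is a '+ chirp' if the population-mean afferent response to it is
#' positive (excitation) and a '- chirp' otherwise. Exact-zero population
#' means are broken toward '-' with a warning.
#'
#' @param responses Numeric matrix of response values, units in rows and
#'   waveforms in columns (column names kept).
#' @return Named character vector of \code{"+"} / \code{"-"} per waveform.
#' @export
classify_chirp_sign <- function(responses) {
  responses <- rbind(responses)
  m <- colMeans(responses)
  if (any(m == 0))
    warning("tied (exactly zero) population response; broken toward '-'")
  stats::setNames(ifelse(m > 0, "+", "-"), colnames(responses))
}

#' Normalize a response trace over the chirp window
#'
#' Subtracts the mean and divides by the maximum absolute deviation, mapping
#' the trace into [-1, 1]. Constant traces pass through as all-zero with a
#' \code{constant} attribute set.
#'
#' @param x Numeric trace.
#' @return Normalized numeric trace, with attribute \code{constant}.
#' @export
normalize_trace <- function(x) {
  x <- x[!is.na(x)]
  d <- x - mean(x)
  m <- max(abs(d))
  if (m == 0) return(structure(d, constant = TRUE))
  structure(d / m, constant = FALSE)
}

#' Normalized distance between two traces
#'
#' Default convention: root-mean-square difference of the mean-centered traces
#' divided by the larger half-range, D(x, y) = sqrt(mean((x' - y')^2)) /
#' max(hr_x, hr_y) with x' = x - mean(x) and hr = (max - min) / 2. The
#' \code{"squared"} convention keeps the squared numerator. D(x, x) = 0 and D
#' is symmetric under both. Two constant traces give D = 0 with a flag.
#'
#' @param x,y Equal-length numeric traces over the chirp window.
#' @param convention \code{"rms"} (default) or \code{"squared"}.
#' @return Non-negative scalar with attribute \code{constant}.
#' @export
trace_distance <- function(x, y, convention = c("rms", "squared")) {
  convention <- match.arg(convention)
  stopifnot(length(x) == length(y))
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  hr <- max((max(x) - min(x)) / 2, (max(y) - min(y)) / 2)
  if (hr == 0) return(structure(0, constant = TRUE))
  num <- mean(((x - mean(x)) - (y - mean(y)))^2)
  if (convention == "rms") num <- sqrt(num)
  structure(num / hr, constant = FALSE)
}

# unordered waveform index pairs for a subset selection
.select_pairs <- function(labels, subset, signs) {
  pairs <- utils::combn(seq_along(labels), 2)
  if (subset == "all") return(pairs)
  if (is.null(signs))
    stop("subset selection requires waveform signs (see classify_chirp_sign)")
  s <- signs[labels]
  same <- s[pairs[1, ]] == s[pairs[2, ]]
  pairs[, if (subset == "same") same else !same, drop = FALSE]
}

#' Phase-invariance score
#'
#' One minus the mean, over selected waveform pairs i != j, of the ratio of
#' the normalized response distance to the normalized stimulus distance (the
#' sum over ordered pairs divided by N(N-1) equals the unordered-pair mean
#' because the distance is symmetric). All traces are normalized with
#' \code{\link{normalize_trace}} first; the caller restricts them to the
#' 30 ms window after chirp onset (see \code{\link{chirp_window}}).
#'
#' @param responses Named list of response traces, one per waveform: PSTH
#'   rates (single unit or summed population), correlation-coefficient traces,
#'   or behavioral PSTHs.
#' @param stimuli Named list of stimulus traces with the same names.
#' @param subset \code{"all"} (default), \code{"same"} ('++/--' pairs only) or
#'   \code{"opposite"} ('+-' pairs only).
#' @param signs Named \code{"+"}/\code{"-"} vector from
#'   \code{\link{classify_chirp_sign}}; required for subset selection.
#' @param convention Distance convention, see \code{\link{trace_distance}}.
#' @param level Free-form label recorded on the result (e.g. "single_unit",
#'   "population", "correlation", "behavior").
#' @return Object of class \code{invariance_score}: list with \code{value}
#'   (<= 1), \code{n_pairs} (ordered pair count), \code{subset},
#'   \code{level}, \code{ratios}.
#' @export
invariance_score <- function(responses, stimuli,
                             subset = c("all", "same", "opposite"),
                             signs = NULL, convention = c("rms", "squared"),
                             level = "single_unit") {
  subset <- match.arg(subset)
  convention <- match.arg(convention)
  labels <- names(responses)
  if (is.null(labels) || !setequal(labels, names(stimuli)))
    stop("responses and stimuli must be named lists over the same waveforms")
  stimuli <- stimuli[labels]
  rn <- lapply(responses, normalize_trace)
  sn <- lapply(stimuli, normalize_trace)
  pairs <- .select_pairs(labels, subset, signs)
  ratios <- apply(pairs, 2, function(p) {
    ds <- trace_distance(sn[[p[1]]], sn[[p[2]]], convention)
    if (ds == 0)
      stop(sprintf("degenerate stimulus set: D(%s, %s) = 0",
                   labels[p[1]], labels[p[2]]))
    trace_distance(rn[[p[1]]], rn[[p[2]]], convention) / ds
  })
  structure(list(value = 1 - mean(ratios), n_pairs = 2L * ncol(pairs),
                 subset = subset, level = level, convention = convention,
                 ratios = ratios),
            class = "invariance_score")
}

#' @export
print.invariance_score <- function(x, ...) {
  cat(sprintf("Invariance score (%s, %s pairs, %d ordered): %.3f\n",
              x$level, x$subset, x$n_pairs, x$value))
  invisible(x)
}

#' Extract the chirp analysis window from a trace
#'
#' Returns the trace samples in [onset, onset + length), the window over
#' which response and stimulus distances are compared.
#'
#' @param x An \code{am_waveform}, \code{psth}, \code{correlation_trace}, or a
#'   list with \code{time} and a value vector.
#' @param onset Chirp onset time in seconds (defaults to the waveform's own
#'   \code{chirp_onset_time} when present).
#' @param length Window length in seconds (default 30 ms).
#' @return Numeric vector of samples in the window.
#' @export
chirp_window <- function(x, onset = NULL, length = 0.03) {
  if (is.null(onset)) onset <- x$chirp_onset_time
  if (is.null(onset)) stop("onset must be given for this trace type")
  value <- if (inherits(x, "am_waveform")) x$samples
    else if (inherits(x, "psth")) x$rate
    else if (inherits(x, "correlation_trace")) x$rho
    else stop("unsupported trace type")
  value[x$time >= onset & x$time < onset + length]
}

#' Tuning curve over the eight beat phases
#'
#' Per-unit response-vs-phase curves plus the population mean and SEM. The
#' normalized variant divides the population curve by its maximum absolute
#' value (unit peak), for cross-stage comparison.
#'
#' @param responses Numeric matrix of response values, units in rows,
#'   waveforms in columns; column names are phase labels in degrees (or
#'   coercible to them).
#' @param phases Numeric vector of phases in degrees (default parsed from
#'   column names, falling back to the canonical 0, 45, ..., 315).
#' @return Object of class \code{tuning_curve}: list with \code{phase},
#'   \code{units} (matrix), \code{mean}, \code{sem}, \code{normalized}.
#' @export
build_tuning_curve <- function(responses, phases = NULL) {
  responses <- rbind(responses)
  if (is.null(phases)) {
    phases <- suppressWarnings(as.numeric(colnames(responses)))
    if (any(is.na(phases))) phases <- seq(0, 315, by = 45)
  }
  if (ncol(responses) != length(phases) || anyNA(responses))
    stop("one response per unit is required for every phase")
  m <- colMeans(responses)
  sem <- if (nrow(responses) > 1)
    apply(responses, 2, stats::sd) / sqrt(nrow(responses)) else rep(0, ncol(responses))
  peak <- max(abs(m))
  structure(list(phase = phases, units = responses, mean = m, sem = sem,
                 normalized = if (peak > 0) m / peak else m),
            class = "tuning_curve")
}

#' @export
print.tuning_curve <- function(x, ...) {
  cat(sprintf("Tuning curve: %d unit(s) x %d phases\n", nrow(x$units),
              length(x$phase)))
  print(round(rbind(phase_deg = x$phase, mean = x$mean, sem = x$sem), 3))
  invisible(x)
}
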