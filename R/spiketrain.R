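# Core spike-train statistics: binarization, trial-averaged PSTHs, and the
# time-varying across-trial spike-count correlation coefficient.

#' Spike-train set container
#'
#' Spike times organized by neuron, waveform and trial, stored as a long-format
#' data frame.
#'
#' @param spikes Data frame with columns \code{neuron_id}, \code{waveform},
#'   \code{trial}, \code{time} (seconds, strictly increasing within a trial).
#' @param duration Recording duration per trial in seconds.
#' @param n_trials Number of trials per neuron and waveform.
#' @param meta Optional list of generator parameters (seed, model, ...).
#' @return An object of class \code{spike_train_set}.
#' @export
spike_train_set <- function(spikes, duration, n_trials, meta = list()) {
  stopifnot(is.data.frame(spikes),
            all(c("neuron_id", "waveform", "trial", "time") %in% names(spikes)))
  structure(list(spikes = spikes, duration = duration, n_trials = n_trials,
                 meta = meta),
            class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  cat(sprintf(
    "Spike train set: %d spikes, %d neuron(s), %d waveform(s), %d trial(s), %.3g s\n",
    nrow(x$spikes), length(unique(x$spikes$neuron_id)),
    length(unique(x$spikes$waveform)), x$n_trials, x$duration))
  invisible(x)
}

#' Extract per-trial spike-time vectors
#'
#' @param set A \code{\link{spike_train_set}}.
#' @param neuron_id,waveform Selectors; \code{NULL} keeps everything (valid
#'   only when the set holds a single neuron / waveform).
#' @return List of numeric vectors, one per trial (1 .. n_trials), empty
#'   trials included.
#' @export
trial_spikes <- function(set, neuron_id = NULL, waveform = NULL) {
  sp <- set$spikes
  if (!is.null(neuron_id)) sp <- sp[sp$neuron_id == neuron_id, ]
  if (!is.null(waveform)) sp <- sp[sp$waveform == waveform, ]
  lapply(seq_len(set$n_trials), function(k) sort(sp$time[sp$trial == k]))
}

#' Binarize spike times
#'
#' Bins spike times into counts on a half-open grid: bin k covers
#' [origin + k*binwidth, origin + (k+1)*binwidth), so a spike landing exactly
#' on an edge is assigned to the bin on the right.
#'
#' @param spikes Numeric vector of spike times (seconds).
#' @param binwidth Bin width in seconds (default 0.5 ms).
#' @param span Two-element numeric: time span covered, \code{[span[1],
#'   span[2])}.
#' @return An object of class \code{binary_sequence}: list with \code{counts}
#'   (integer), \code{binwidth}, \code{origin}.
#' @export
binarize <- function(spikes, binwidth = 5e-4, span) {
  stopifnot(binwidth > 0, length(span) == 2)
  if (span[2] <= span[1]) stop("empty span")
  nbins <- ceiling((span[2] - span[1]) / binwidth - 1e-9)
  k <- floor((spikes - span[1]) / binwidth)
  k <- k[k >= 0 & k < nbins]
  structure(list(counts = tabulate(k + 1L, nbins), binwidth = binwidth,
                 origin = span[1]),
            class = "binary_sequence")
}

#' Trial-averaged peristimulus time histogram (PSTH)
#'
#' Averages spike counts across repeated presentations of one waveform and
#' smooths with a centered boxcar filter. Samples within half a boxcar of the
#' trace edges are returned as \code{NA} (the smoothed trace is truncated).
#'
#' @param trains List of spike-time vectors, one per trial.
#' @param duration Trial duration in seconds.
#' @param binwidth PSTH bin width in seconds (default 0.1 ms).
#' @param smooth Boxcar filter length in seconds (default 6 ms); a length of
#'   one bin leaves the raw histogram rate untouched.
#' @return An object of class \code{psth}: list with \code{time} (bin
#'   centers), \code{rate} (Hz), \code{raw_rate} (unsmoothed), plus the
#'   parameters.
#' @export
compute_psth <- function(trains, duration, binwidth = 1e-4, smooth = 0.006) {
  stopifnot(is.list(trains), length(trains) >= 1, binwidth > 0)
  n_trials <- length(trains)
  nbins <- ceiling(duration / binwidth - 1e-9)
  counts <- tabulate(
    {k <- floor(unlist(trains) / binwidth); k[k >= 0 & k < nbins] + 1L},
    nbins)
  raw <- counts / (n_trials * binwidth)
  w <- max(1L, round(smooth / binwidth))
  rate <- if (w > 1L) {
    as.numeric(stats::filter(raw, rep(1 / w, w), sides = 2))
  } else raw
  structure(list(time = (seq_len(nbins) - 0.5) * binwidth, rate = rate,
                 raw_rate = raw, binwidth = binwidth, smooth = smooth,
                 n_trials = n_trials, duration = duration),
            class = "psth")
}

#' @export
print.psth <- function(x, ...) {
  cat(sprintf(
    "PSTH: %d bins of %.2g ms, %d trials, boxcar %.2g ms, mean rate %.3g Hz\n",
    length(x$rate), 1000 * x$binwidth, x$n_trials, 1000 * x$smooth,
    mean(x$rate, na.rm = TRUE)))
  invisible(x)
}

# windowed spike counts per trial: counts in [center - w/2, center + w/2)
# for each trial (rows) and window center (columns)
.window_counts <- function(trains, centers, window) {
  h <- window / 2
  t(vapply(trains, function(sp) {
    findInterval(centers + h, sp) - findInterval(centers - h, sp)
  }, numeric(length(centers))))
}

# columnwise |Pearson| between two trials-by-centers count matrices;
# zero-variance columns give NA
.abs_pearson_cols <- function(x, y) {
  xc <- sweep(x, 2, colMeans(x))
  yc <- sweep(y, 2, colMeans(y))
  vx <- colSums(xc^2)
  vy <- colSums(yc^2)
  rho <- abs(colSums(xc * yc)) / sqrt(vx * vy)
  rho[vx == 0 | vy == 0] <- NA_real_
  rho
}

#' Time-varying across-trial spike-count correlation
#'
#' For each window center t, counts the spikes of the two neurons in
#' [t - window/2, t + window/2) on every trial and computes the absolute
#' Pearson correlation of the two count vectors across trials. Windows where
#' either neuron has zero count variance are undefined and returned as
#' \code{NA} with the mask recorded.
#'
#' @param trains_i,trains_j Lists of spike-time vectors (one per trial) for
#'   the two neurons; equal trial counts required.
#' @param duration Trial duration in seconds.
#' @param window Window length in seconds (default 31.25 ms).
#' @param step Translation step of the window in seconds (default 0.25 ms).
#' @param pairing \code{"simultaneous"} pairs trials by index;
#'   \code{"recombined"} applies a seeded random permutation to the trials of
#'   neuron j before pairing, destroying any trial-locked shared variability.
#' @param seed Seed for the recombined permutation.
#' @return An object of class \code{correlation_trace}: list with \code{time}
#'   (window centers), \code{rho} (in [0, 1] where defined), \code{defined}
#'   (logical mask), plus parameters.
#' @export
sliding_correlation <- function(trains_i, trains_j, duration,
                                window = 0.03125, step = 2.5e-4,
                                pairing = c("simultaneous", "recombined"),
                                seed = NULL) {
  pairing <- match.arg(pairing)
  stopifnot(length(trains_i) == length(trains_j))
  if (length(trains_i) < 3)
    stop("at least 3 trials are required to correlate counts across trials")
  if (pairing == "recombined") {
    perm <- if (is.null(seed)) sample(length(trains_j)) else
      withr::with_seed(seed, sample(length(trains_j)))
    trains_j <- trains_j[perm]
  }
  centers <- seq(window / 2, duration - window / 2, by = step)
  rho <- .abs_pearson_cols(.window_counts(trains_i, centers, window),
                           .window_counts(trains_j, centers, window))
  structure(list(time = centers, rho = rho, defined = !is.na(rho),
                 window = window, step = step, n_trials = length(trains_i),
                 pairing = pairing),
            class = "correlation_trace")
}

#' @export
print.correlation_trace <- function(x, ...) {
  cat(sprintf(
    "Correlation trace: %d centers, window %.3g ms, step %.3g ms, %d trials; mean rho %.3f (%d undefined)\n",
    length(x$rho), 1000 * x$window, 1000 * x$step, x$n_trials,
    mean(x$rho, na.rm = TRUE), sum(!x$defined)))
  invisible(x)
}

#' Fixed-window spike-count correlation (oracle estimator)
#'
#' Absolute Pearson correlation of spike counts across trials in one fixed
#' window (default 40 ms). This single-window estimator serves as the
#' independent check of \code{\link{sliding_correlation}}.
#'
#' @inheritParams sliding_correlation
#' @param center Window center time in seconds.
#' @param window Window length in seconds (default 40 ms).
#' @return A single numeric value in [0, 1], or \code{NA} if either neuron's
#'   counts have zero variance.
#' @export
count_correlation <- function(trains_i, trains_j, center, window = 0.040) {
  stopifnot(length(trains_i) == length(trains_j))
  if (length(trains_i) < 3)
    stop("at least 3 trials are required to correlate counts across trials")
  h <- window / 2
  ci <- vapply(trains_i, function(sp)
    sum(sp >= center - h & sp < center + h), numeric(1))
  cj <- vapply(trains_j, function(sp)
    sum(sp >= center - h & sp < center + h), numeric(1))
  if (stats::sd(ci) == 0 || stats::sd(cj) == 0) return(NA_real_)
  abs(stats::cor(ci, cj))
}

#' Write / read a sampled trace (PSTH or correlation trace) as delimited text
#'
#' Two tab-separated columns (\code{time_s}, \code{value}) plus a JSON sidecar
#' with the object's parameters.
#'
#' @param x A \code{psth} or \code{correlation_trace}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_trace <- function(x, path) {
  value <- if (inherits(x, "psth")) x$rate else x$rho
  utils::write.table(data.frame(time_s = x$time, value = value), path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- x[setdiff(names(x), c("time", "rate", "raw_rate", "rho", "defined"))]
  meta$class <- class(x)[1]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
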