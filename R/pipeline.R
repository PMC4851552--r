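# Orchestration: seeded, configured end-to-end runs over the synthetic
# electrosensory hierarchy, producing tuning curves and invariance scores at
# every stage plus the behavioral pipeline.

#' Default run configuration
#'
#' Nested list of all stimulus, generator and analysis parameters. The
#' defaults reproduce the canonical study conditions: a 4 Hz beat carrying a
#' 60 Hz / 14 ms Gaussian chirp at the eight canonical phases; 18 single
#' afferents, 8 afferent pairs, 22 ON + 9 OFF pyramidal cells, 25 TS units
#' (each waveform presented 20 times); 29 fish with 40 stimulus chirps each
#' (5 per phase).
#'
#' @param seed Integer seed for the whole run.
#' @return Configuration list (class \code{run_config}).
#' @export
default_config <- function(seed = 1) {
  structure(list(
    seed = seed,
    stimulus = list(f_beat = 4, delta_f = 60, sigma = 0.014, duration = 2,
                    sample_rate = 10000, chirp_center = 1, onset_sigma = 1.75,
                    phase_offset = 232.8),
    afferent = list(n_units = 18, n_trials = 20, baseline = 380,
                    baseline_sd = 72, gain = 0.9, gain_sd = 0.12,
                    refractory = 0.001, jitter_sd = 0),
    pairs = list(n_pairs = 8, n_trials = 60, jitter_sd = 0,
                 chirp_gain_sd = 0.5),
    ell = list(n_on = 22, n_off = 9, n_trials = 20, baseline = 12.1,
               baseline_sd = 1.74, gain = 4, gain_sd = 0.5, smooth = 0.020,
               adapt = 0.04, refractory = 0.002),
    ts = list(n_units = 25, n_trials = 20, baseline = 3.35, baseline_sd = 1,
              weight = 4, weight_sd = 0.5, refractory = 0.002),
    behavior = list(n_fish = 29, n_repeats = 5, p_echo = 0.5,
                    latency_shape = 4, latency_scale = 0.1,
                    psth_binwidth = 0.001, psth_smooth = 1),
    analysis = list(corr_window = 0.03125, corr_step = 2.5e-4, window = 0.03,
                    distance = "rms", psth_binwidth = 1e-4,
                    psth_smooth = 0.006, rate_floor = 0.1)),
    class = "run_config")
}

#' Validate a run configuration
#'
#' Checks the configuration against the default template; unknown keys raise
#' an error listing the offenders, and missing keys are filled from the
#' defaults.
#'
#' @param config Configuration list (possibly partial).
#' @return Completed configuration (class \code{run_config}).
#' @export
validate_config <- function(config) {
  template <- default_config()
  bad <- setdiff(names(config), names(template))
  for (sect in intersect(names(config), setdiff(names(template), "seed"))) {
    extra <- setdiff(names(config[[sect]]), names(template[[sect]]))
    if (length(extra)) bad <- c(bad, paste0(sect, "$", extra))
  }
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  out <- template
  if (!is.null(config$seed)) out$seed <- config$seed
  for (sect in setdiff(names(template), "seed"))
    for (key in names(config[[sect]]))
      out[[sect]][[key]] <- config[[sect]][[key]]
  out
}

#' Write / read a run configuration as JSON
#'
#' @param config A configuration list.
#' @param path File path.
#' @return \code{path} (write) or the configuration (read).
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configurations requires the 'yaml' package")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  validate_config(cfg)
}

# truncated-normal draw (positive), vectorized over n
.draw_pos <- function(n, mean, sd, floor = 0.25 * mean) {
  pmax(stats::rnorm(n, mean, sd), floor)
}

# per-unit analysis over one waveform set: PSTHs, windowed traces, responses
.unit_responses <- function(sim_one, waves, stage, analysis) {
  onset <- waves[[1]]$chirp_onset_time
  out <- lapply(waves, function(wv) {
    trains <- sim_one(wv)
    ps <- compute_psth(trains, duration = length(wv$samples) / wv$sample_rate,
                       binwidth = analysis$psth_binwidth,
                       smooth = analysis$psth_smooth)
    list(trace = chirp_window(ps, onset, analysis$window),
         response = response_measure(ps, onset, stage = stage,
                                     rate_floor = analysis$rate_floor)$value)
  })
  list(traces = lapply(out, `[[`, "trace"),
       responses = vapply(out, `[[`, numeric(1), "response"))
}

.stage_scores <- function(unit_traces, stim_win, signs, analysis, level) {
  per_unit <- function(subset) vapply(unit_traces, function(tr)
    invariance_score(tr, stim_win, subset = subset, signs = signs,
                     convention = analysis$distance, level = level)$value,
    numeric(1))
  pop_traces <- lapply(names(stim_win), function(lb)
    Reduce(`+`, lapply(unit_traces, `[[`, lb)))
  names(pop_traces) <- names(stim_win)
  list(all = per_unit("all"), same = per_unit("same"),
       opposite = per_unit("opposite"),
       population = invariance_score(pop_traces, stim_win,
                                     convention = analysis$distance,
                                     level = paste0(level, "_population"))$value)
}

#' Run the full synthetic pipeline
#'
#' Generates the waveform set, simulates the requested stages, and computes
#' PSTHs, time-varying correlations, chirp responses, tuning curves and
#' invariance scores (all waveform pairs plus '++/--' and '+-' subsets, unit
#' and population level), and the behavioral echo pipeline. The run is
#' reproducible bit-for-bit from the configuration and its seed.
#'
#' @param config Configuration from \code{\link{default_config}} /
#'   \code{\link{validate_config}} (partial configurations are completed).
#' @param stages Character vector of stages to run, any of
#'   \code{"afferent"}, \code{"pairs"}, \code{"ell"}, \code{"ts"},
#'   \code{"behavior"}.
#' @param store_spikes Keep one example spike-train set per stage in the
#'   result (default \code{FALSE}).
#' @return Object of class \code{pipeline_result}: list with \code{config},
#'   \code{waves}, \code{signs}, per-stage results (responses, tuning,
#'   invariance) and \code{summary} (see \code{\link{summarize_run}}).
#' @export
run_pipeline <- function(config = default_config(),
                         stages = c("afferent", "pairs", "ell", "ts",
                                    "behavior"),
                         store_spikes = FALSE) {
  config <- validate_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  an <- config$analysis
  st <- config$stimulus
  withr::with_seed(config$seed, {
    beat <- beat_spec(st$f_beat, st$duration, st$sample_rate)
    waves <- make_waveform_set(beat, chirp_spec(st$delta_f, st$sigma),
                               chirp_center = st$chirp_center,
                               onset_sigma = st$onset_sigma,
                               phase_offset = st$phase_offset)
    onset <- waves[[1]]$chirp_onset_time
    phases <- vapply(waves, `[[`, numeric(1), "onset_phase")
    stim_win <- lapply(waves, chirp_window, length = an$window)
    res <- list(config = config, waves = waves, chirp_onset = onset)
    # canonical classification; replaced by the measured one when the
    # afferent stage runs
    signs <- stats::setNames(ifelse(phases < 180, "+", "-"), names(waves))

    if ("afferent" %in% stages) {
      cf <- config$afferent
      units <- lapply(seq_len(cf$n_units), function(u) {
        model <- neuron_model("afferent",
                              baseline_rate = .draw_pos(1, cf$baseline,
                                                        cf$baseline_sd),
                              gain = .draw_pos(1, cf$gain, cf$gain_sd),
                              refractory = cf$refractory)
        .unit_responses(function(wv)
          trial_spikes(simulate_afferent_trials(model, wv, cf$n_trials,
                                                jitter_sd = cf$jitter_sd)),
          waves, "afferent", an)
      })
      resp <- do.call(rbind, lapply(units, `[[`, "responses"))
      colnames(resp) <- as.character(phases)
      signs <- stats::setNames(
        classify_chirp_sign(resp)[as.character(phases)], names(waves))
      res$afferent <- list(
        responses = resp, tuning = build_tuning_curve(resp),
        invariance = .stage_scores(lapply(units, `[[`, "traces"), stim_win,
                                   signs, an, "afferent"))
      if (store_spikes) {
        model <- neuron_model("afferent")
        res$afferent$example_spikes <- simulate_afferent_trials(
          model, waves[[1]], cf$n_trials)
      }
    }
    res$signs <- signs

    if ("pairs" %in% stages) {
      cf <- config$pairs
      af <- config$afferent
      pair_traces <- lapply(seq_len(cf$n_pairs), function(p) {
        mi <- neuron_model("afferent",
                           baseline_rate = .draw_pos(1, af$baseline,
                                                     af$baseline_sd),
                           gain = .draw_pos(1, af$gain, af$gain_sd),
                           refractory = af$refractory)
        mj <- neuron_model("afferent",
                           baseline_rate = .draw_pos(1, af$baseline,
                                                     af$baseline_sd),
                           gain = .draw_pos(1, af$gain, af$gain_sd),
                           refractory = af$refractory)
        lapply(waves, function(wv) {
          pr <- simulate_afferent_pair(mi, mj, wv, cf$n_trials,
                                       jitter_sd = cf$jitter_sd,
                                       chirp_gain_sd = cf$chirp_gain_sd)
          rho <- sliding_correlation(trial_spikes(pr$i), trial_spikes(pr$j),
                                     duration = pr$i$duration,
                                     window = an$corr_window,
                                     step = an$corr_step)
          rho$chirp_onset_time <- onset
          chirp_window(rho, onset, an$window)
        })
      })
      res$pairs <- list(
        invariance = .stage_scores(pair_traces, stim_win, signs, an,
                                   "correlation"),
        traces = pair_traces)
    }

    if ("ell" %in% stages) {
      cf <- config$ell
      sim_ell <- function(stage, n) lapply(seq_len(n), function(u) {
        model <- neuron_model(stage,
                              baseline_rate = .draw_pos(1, cf$baseline,
                                                        cf$baseline_sd),
                              gain = .draw_pos(1, cf$gain, cf$gain_sd),
                              refractory = cf$refractory,
                              smooth = cf$smooth, adapt = cf$adapt)
        .unit_responses(function(wv)
          trial_spikes(simulate_pyramidal_trials(model, wv, cf$n_trials)),
          waves, "ELL", an)
      })
      on_units <- sim_ell("ELL_ON", cf$n_on)
      off_units <- sim_ell("ELL_OFF", cf$n_off)
      resp_on <- do.call(rbind, lapply(on_units, `[[`, "responses"))
      resp_off <- do.call(rbind, lapply(off_units, `[[`, "responses"))
      colnames(resp_on) <- colnames(resp_off) <- as.character(phases)
      all_traces <- c(lapply(on_units, `[[`, "traces"),
                      lapply(off_units, `[[`, "traces"))
      res$ell <- list(
        responses_on = resp_on, responses_off = resp_off,
        tuning_on = build_tuning_curve(resp_on),
        tuning_off = build_tuning_curve(resp_off),
        invariance = .stage_scores(all_traces, stim_win, signs, an, "ELL"))
    }

    if ("ts" %in% stages) {
      cf <- config$ts
      ell_cf <- config$ell
      on_model <- neuron_model("ELL_ON", baseline_rate = ell_cf$baseline,
                               gain = ell_cf$gain, smooth = ell_cf$smooth,
                               adapt = ell_cf$adapt)
      off_model <- neuron_model("ELL_OFF", baseline_rate = ell_cf$baseline,
                                gain = ell_cf$gain, smooth = ell_cf$smooth,
                                adapt = ell_cf$adapt)
      drives <- lapply(waves, function(wv)
        list(on = pyramidal_drive(on_model, wv),
             off = pyramidal_drive(off_model, wv)))
      units <- lapply(seq_len(cf$n_units), function(u) {
        model <- neuron_model("TS",
                              baseline_rate = .draw_pos(1, cf$baseline,
                                                        cf$baseline_sd,
                                                        floor = 0.5),
                              gain = .draw_pos(1, cf$weight, cf$weight_sd),
                              refractory = cf$refractory)
        .unit_responses(function(wv)
          trial_spikes(simulate_ts_trials(drives[[wv$label]]$on,
                                          drives[[wv$label]]$off,
                                          model, cf$n_trials)),
          waves, "TS", an)
      })
      resp <- do.call(rbind, lapply(units, `[[`, "responses"))
      colnames(resp) <- as.character(phases)
      res$ts <- list(
        responses = resp, tuning = build_tuning_curve(resp),
        invariance = .stage_scores(lapply(units, `[[`, "traces"), stim_win,
                                   signs, an, "TS"))
    }

    if ("behavior" %in% stages) {
      cf <- config$behavior
      fish <- lapply(seq_len(cf$n_fish), function(fi) {
        ex <- simulate_echo_experiment(
          n_repeats = cf$n_repeats, phases = phases, p_echo = cf$p_echo,
          latency_shape = cf$latency_shape, latency_scale = cf$latency_scale)
        stats <- analyze_echo_experiment(ex)
        ev <- attr(stats, "events")
        # event times relative to each presentation onset, tagged by phase
        rel <- do.call(rbind, lapply(seq_len(nrow(stats)), function(k) {
          tt <- ev$time - stats$onset[k]
          tt <- tt[tt > -0.2 & tt <= 2]
          if (!length(tt)) return(NULL)
          data.frame(phase = stats$phase[k], t = tt)
        }))
        list(stats = stats, rel = rel)
      })
      stats_all <- do.call(rbind, lapply(fish, `[[`, "stats"))
      rel_all <- do.call(rbind, lapply(fish, `[[`, "rel"))
      n_pres <- cf$n_fish * cf$n_repeats
      psths <- lapply(phases, function(ph) behavioral_psth(
        rel_all$t[rel_all$phase == ph], n_pres,
        binwidth = cf$psth_binwidth, smooth = cf$psth_smooth))
      names(psths) <- names(waves)
      # behavioral response epoch: the 1 s echo window after stimulus onset
      # (the 30 ms neural window is below the 1 s boxcar's resolution)
      beh_win <- lapply(psths, function(p)
        p$rate[p$time >= 0 & p$time < 1])
      beh_inv <- invariance_score(beh_win, stim_win,
                                  convention = an$distance,
                                  level = "behavior")$value
      per_phase <- do.call(rbind, lapply(phases, function(ph) {
        s <- stats_all[stats_all$phase == ph, ]
        data.frame(phase = ph, cr_chirp = mean(s$cr_chirp),
                   cr_beat = mean(s$cr_beat),
                   latency = mean(s$latency, na.rm = TRUE),
                   response = mean(s$behavior_response))
      }))
      res$behavior <- list(stats = stats_all, per_phase = per_phase,
                           psths = psths, invariance = beh_inv)
    }

    res$summary <- summarize_run(res)
    structure(res, class = "pipeline_result")
  })
}

#' Summarize a pipeline run
#'
#' Per-stage invariance mean, SEM, max, min and population-level score, the
#' behavior invariance, and the subset ('++/--' vs '+-') table. Neural SEMs
#' are standard errors across units; the behavioral response SEM uses the
#' sequential block bootstrap (block size 27) over the pooled
#' per-presentation log-ratio series.
#'
#' @param result A partially built or complete \code{pipeline_result}.
#' @return List with \code{stages} (data frame), \code{subsets} (data frame),
#'   \code{behavior_invariance}, \code{behavior_response_sem}.
#' @export
summarize_run <- function(result) {
  if (is.null(result$config)) stop("empty result bundle")
  stage_row <- function(name, inv) {
    v <- inv$all
    data.frame(stage = name, mean = mean(v),
               sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v))
                     else NA_real_,
               max = max(v), min = min(v), population = inv$population,
               n_units = length(v))
  }
  rows <- list()
  subsets <- list()
  for (nm in c("afferent", "pairs", "ell", "ts")) {
    if (is.null(result[[nm]])) next
    inv <- result[[nm]]$invariance
    rows[[nm]] <- stage_row(nm, inv)
    subsets[[nm]] <- data.frame(
      stage = nm, all = mean(inv$all), same_type = mean(inv$same),
      opposite_type = mean(inv$opposite))
  }
  out <- list(stages = do.call(rbind, rows),
              subsets = do.call(rbind, subsets))
  if (!is.null(result$behavior)) {
    out$behavior_invariance <- result$behavior$invariance
    br <- result$behavior$stats$behavior_response
    out$behavior_response_sem <- if (length(br) >= 27)
      block_bootstrap_sem(br, block = 27, n_boot = 500, seed = 1)
      else NA_real_
  }
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline run (seed", x$config$seed, ")\n")
  if (!is.null(x$summary$stages)) {
    cat("Invariance by stage:\n")
    print(x$summary$stages, row.names = FALSE, digits = 3)
  }
  if (!is.null(x$summary$behavior_invariance))
    cat(sprintf("Behavioral invariance: %.3f\n",
                x$summary$behavior_invariance))
  invisible(x)
}

#' Write the tables and JSON summary of a pipeline run
#'
#' Writes delimited invariance and tuning tables plus a JSON summary carrying
#' the full configuration (including the seed). Every table gets a JSON
#' sidecar with the run seed and the MD5 hash of the serialized configuration,
#' and a \code{run.log} records versions, seed and hash.
#'
#' @param result A \code{pipeline_result}.
#' @param outdir Output directory (created if needed).
#' @return \code{outdir}, invisibly.
#' @export
write_run <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg_file <- file.path(outdir, "config.json")
  write_config(result$config, cfg_file)
  cfg_hash <- unname(tools::md5sum(cfg_file))
  sidecar <- function(path)
    jsonlite::write_json(list(seed = result$config$seed,
                              config_md5 = cfg_hash),
                         paste0(path, ".json"), auto_unbox = TRUE)
  write_table <- function(df, name) {
    path <- file.path(outdir, name)
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
    sidecar(path)
  }
  if (!is.null(result$summary$stages))
    write_table(result$summary$stages, "invariance_by_stage.tsv")
  if (!is.null(result$summary$subsets))
    write_table(result$summary$subsets, "invariance_subsets.tsv")
  for (nm in c("afferent", "ts")) {
    if (is.null(result[[nm]])) next
    tc <- result[[nm]]$tuning
    write_table(data.frame(phase_deg = tc$phase, mean = tc$mean,
                           sem = tc$sem),
                paste0("tuning_", nm, ".tsv"))
  }
  summary <- result$summary
  summary$config <- unclass(result$config)
  summary$config_md5 <- cfg_hash
  summary$versions <- list(
    r = as.character(getRversion()),
    chirpinvar = as.character(utils::packageVersion("chirpinvar")))
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  writeLines(c(
    sprintf("run at %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    sprintf("R %s, chirpinvar %s", getRversion(),
            utils::packageVersion("chirpinvar")),
    sprintf("seed %s", result$config$seed),
    sprintf("config md5 %s", cfg_hash)),
    file.path(outdir, "run.log"))
  invisible(outdir)
}
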