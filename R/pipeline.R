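#' Run configuration
#'
#' Collects every tunable of the pipeline with its default. Values are
#' overridable individually or from a YAML file ([read_run_config()]).
#'
#' @param resample_rate Uniform resampling rate for spectral analysis, Hz.
#' @param segment_s Welch segment length, s.
#' @param overlap Welch segment overlap fraction.
#' @param clean_min_ms,clean_max_ms,clean_max_rel_dev Artifact thresholds
#'   for [clean_rr()].
#' @param mse_scales Scales for multiscale entropy.
#' @param dfa_order DFA detrending order.
#' @param window Optional analysis window `c(start_s, length_s)` applied to
#'   each recording before analysis (`NULL` = whole record).
#' @param scheme_override Optional [band_scheme()] used for every recording
#'   regardless of manifest temperature.
#' @param figures Write PNG figures from [run_study()].
#' @param seed Integer seed recorded with the outputs.
#' @return A `run_config` list.
#' @export
run_config <- function(resample_rate = 20, segment_s = 60, overlap = 0.5,
                       clean_min_ms = 50, clean_max_ms = 350,
                       clean_max_rel_dev = 0.3, mse_scales = 1:10,
                       dfa_order = 1, window = NULL,
                       scheme_override = NULL, figures = FALSE, seed = 1) {
  structure(
    list(
      resample_rate = resample_rate, segment_s = segment_s,
      overlap = overlap, clean_min_ms = clean_min_ms,
      clean_max_ms = clean_max_ms, clean_max_rel_dev = clean_max_rel_dev,
      mse_scales = mse_scales, dfa_order = dfa_order, window = window,
      scheme_override = scheme_override, figures = figures, seed = seed
    ),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected; missing keys keep their defaults.
#'
#' @param path YAML file whose top-level keys match [run_config()]
#'   arguments (`scheme_override` may be given as `"20C"`/`"30C"`).
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  allowed <- names(formals(run_config))
  bad <- setdiff(names(vals), allowed)
  if (length(bad) > 0) {
    mhrv_error("configuration_error",
               sprintf("unknown config key(s): %s; allowed: %s",
                       paste(bad, collapse = ", "),
                       paste(allowed, collapse = ", ")))
  }
  if (!is.null(vals$scheme_override) && is.character(vals$scheme_override)) {
    vals$scheme_override <- band_scheme(vals$scheme_override)
  }
  do.call(run_config, vals)
}

#' Analyse one recording across all three HRV domains
#'
#' Cleans the series (unless already cleaned), optionally restricts it to
#' the configured analysis window, selects the band scheme by the
#' recording's temperature, and computes the time-domain,
#' frequency-domain, and non-linear summaries. A domain failing its
#' data-sufficiency preconditions is recorded as `NULL` and the record is
#' flagged incomplete; the other domains are still computed.
#'
#' @param rr An [rr_series()].
#' @param temperature `"20C"` or `"30C"` (selects the band scheme unless
#'   `config$scheme_override` is set).
#' @param config A [run_config()].
#' @param age_group,state Optional design labels carried into the record
#'   key.
#' @return An `hrv_record`: list with `key`, `time`, `bands`, `nonlinear`,
#'   `spectrum` (the `spectral_estimate`), `incomplete`, `errors`.
#' @export
analyze_recording <- function(rr, temperature, config = run_config(),
                              age_group = "", state = "") {
  stopifnot(inherits(rr, "rr_series"))
  if (!rr$cleaned) {
    rr <- clean_rr(rr, min_ms = config$clean_min_ms,
                   max_ms = config$clean_max_ms,
                   max_rel_dev = config$clean_max_rel_dev)
  }
  if (!is.null(config$window)) {
    sel <- rr$interval_times >= config$window[1] &
      rr$interval_times <= config$window[1] + config$window[2]
    rr <- rr_series(beat_times = rr$interval_times[sel],
                    intervals = rr$intervals[sel],
                    animal_id = rr$animal_id, cleaned = TRUE,
                    n_raw = rr$n_raw,
                    excluded_fraction = rr$excluded_fraction)
  }
  scheme <- if (!is.null(config$scheme_override)) {
    config$scheme_override
  } else {
    scheme_for_temperature(temperature)
  }
  errors <- character(0)
  grab <- function(expr) {
    tryCatch(expr, mousehrv_error = function(e) {
      errors <<- c(errors, conditionMessage(e))
      NULL
    })
  }
  td <- grab(summarize_time_domain(rr))
  spec <- grab({
    sig <- resample_evenly(rr, rate = config$resample_rate)
    estimate_psd(sig, segment_s = config$segment_s,
                 overlap = config$overlap)
  })
  bp <- if (is.null(spec)) NULL else grab(band_powers(spec, scheme))
  nl <- if (is.null(spec)) NULL else {
    grab(summarize_nonlinear(rr, spec, scheme,
                             mse_scales = config$mse_scales,
                             dfa_order = config$dfa_order))
  }
  structure(
    list(
      key = c(animal_id = rr$animal_id, age_group = age_group,
              temperature = temperature, state = state),
      time = td, bands = bp, nonlinear = nl, spectrum = spec,
      incomplete = is.null(td) || is.null(bp) || is.null(nl),
      errors = errors
    ),
    class = "hrv_record"
  )
}

#' @export
print.hrv_record <- function(x, ...) {
  cat(sprintf("<hrv_record %s [%s/%s/%s]%s>\n",
              x$key[["animal_id"]], x$key[["age_group"]],
              x$key[["temperature"]], x$key[["state"]],
              if (x$incomplete) " (incomplete)" else ""))
  invisible(x)
}

#' Analyse every record of an in-memory cohort
#'
#' @param cohort A `cohort_dataset` from [generate_cohort()].
#' @param config A [run_config()].
#' @return List with `records` (list of `hrv_record`) and `metrics`
#'   (the flat [hrv_table()]).
#' @export
analyze_cohort <- function(cohort, config = run_config()) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  mf <- cohort$manifest
  recs <- vector("list", nrow(mf))
  for (i in seq_len(nrow(mf))) {
    rec_id <- sprintf("%s_%s_%s", mf$animal_id[i], mf$temperature[i],
                      mf$state[i])
    recs[[i]] <- analyze_recording(
      cohort$records[[rec_id]], temperature = mf$temperature[i],
      config = config, age_group = mf$age_group[i], state = mf$state[i]
    )
  }
  list(records = recs, metrics = hrv_table(recs))
}

.study_metrics <- c("mean_hr_bpm", "sdnn_ms", "cv_pct", "total_ms2",
                    "vlf_ms2", "lf_ms2", "hf_ms2", "beta", "mse",
                    "dfa_alpha", "hurst")

#' Run the full study pipeline over a manifest
#'
#' For every manifest row: read the RR series, clean, analyse all domains
#' with the temperature-selected band scheme; then assemble the
#' per-recording metric table, per-cell group summaries, paired
#' basal-minus-intrinsic deltas, the mean NN-SDNN power law, and
#' mixed-model contrasts. All tables are written as CSV under `out_dir`
#' together with a plain-text run log (package version, config, seed).
#' Unreadable recordings are skipped with a warning and counted in the
#' log.
#'
#' @param manifest A `cohort_manifest` (or path to one).
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `metrics`, `group_summaries`, `deltas`,
#'   `powerlaw`, `contrasts`, `n_failed`.
#' @export
run_study <- function(manifest, config = run_config(), out_dir = ".") {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  stopifnot(inherits(manifest, "cohort_manifest"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  recs <- list()
  n_failed <- 0
  for (i in seq_len(nrow(manifest))) {
    rec <- tryCatch({
      rr <- read_rr(manifest$path[i], animal_id = manifest$animal_id[i])
      analyze_recording(rr, temperature = manifest$temperature[i],
                        config = config,
                        age_group = manifest$age_group[i],
                        state = manifest$state[i])
    }, error = function(e) {
      warning(sprintf("skipping %s: %s", manifest$path[i],
                      conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (is.null(rec)) {
      n_failed <- n_failed + 1
    } else {
      recs[[length(recs) + 1]] <- rec
    }
  }
  if (length(recs) == 0) {
    mhrv_error("empty_input_error", "no recording could be analysed")
  }
  metrics <- hrv_table(recs)
  write_hrv_table(metrics, file.path(out_dir, "metrics.csv"))

  gs <- do.call(rbind, lapply(.study_metrics, function(m) {
    g <- suppressWarnings(group_summary(metrics, m))
    cbind(metric = m, g)
  }))
  write.csv(gs, file.path(out_dir, "group_summary.csv"), row.names = FALSE)

  deltas <- NULL
  for (m in .study_metrics) {
    for (temp in unique(metrics$temperature)) {
      d <- tryCatch(suppressWarnings(paired_delta(metrics, m, temp)),
                    mousehrv_error = function(e) NULL)
      if (!is.null(d)) deltas <- rbind(deltas, d[names(d) != "deltas"])
    }
  }
  if (!is.null(deltas)) {
    write.csv(deltas, file.path(out_dir, "delta_summary.csv"),
              row.names = FALSE)
  }

  pl <- tryCatch(suppressWarnings(nn_sdnn_powerlaw(metrics)),
                 mousehrv_error = function(e) NULL)
  if (!is.null(pl)) {
    write.csv(
      data.frame(pl$points, residual = pl$residuals),
      file.path(out_dir, "nn_sdnn_powerlaw_points.csv"), row.names = FALSE
    )
  }

  cons <- tryCatch({
    do.call(rbind, lapply(.study_metrics, function(m) {
      cc <- suppressWarnings(lmm_contrasts(metrics, m))
      cbind(metric = m, method = cc$method, cc$contrasts)
    }))
  }, error = function(e) NULL)
  if (!is.null(cons)) {
    write.csv(cons, file.path(out_dir, "contrasts.csv"), row.names = FALSE)
  }

  if (isTRUE(config$figures)) {
    .study_figures(recs, metrics, pl, out_dir)
  }

  log_lines <- c(
    sprintf("mousehrv %s", as.character(utils::packageVersion("mousehrv"))),
    sprintf("date: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("seed: %s", config$seed),
    sprintf("records analysed: %d, skipped: %d", length(recs), n_failed),
    sprintf("config: %s", paste(
      vapply(names(config), function(k) {
        v <- config[[k]]
        sprintf("%s=%s", k, paste(format(unlist(v)), collapse = ","))
      }, character(1)),
      collapse = "; "
    ))
  )
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))

  invisible(list(metrics = metrics, group_summaries = gs, deltas = deltas,
                 powerlaw = pl, contrasts = cons, n_failed = n_failed))
}

# Poincare, PSD, and NN-SDNN power-law figures (optional artifacts)
.study_figures <- function(recs, metrics, pl, out_dir) {
  fig_dir <- file.path(out_dir, "figures")
  dir.create(fig_dir, showWarnings = FALSE)
  for (rec in recs) {
    if (is.null(rec$spectrum)) next
    id <- paste(rec$key[c("animal_id", "temperature", "state")],
                collapse = "_")
    grDevices::png(file.path(fig_dir, sprintf("psd_%s.png", id)),
                   width = 600, height = 400)
    plot(rec$spectrum$frequencies, rec$spectrum$psd, type = "l",
         log = "y", xlab = "Frequency (Hz)", ylab = "PSD (ms^2/Hz)",
         main = id)
    grDevices::dev.off()
  }
  if (!is.null(pl)) {
    grDevices::png(file.path(fig_dir, "nn_sdnn_powerlaw.png"),
                   width = 600, height = 400)
    plot(pl$points$ln_nn, pl$points$ln_sdnn, xlab = "ln mean NN",
         ylab = "ln SDNN", main = "NN-SDNN power law")
    graphics::abline(pl$intercept, pl$slope)
    grDevices::dev.off()
  }
}
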