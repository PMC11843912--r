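# File-level commands tying the pipeline together; the thin command-line
# wrapper in inst/cli/courtbeat.R dispatches straight to these.

#' Event-table CSV I/O
#'
#' The interchange schema is `time_s,label,amplitude,probability`.
#'
#' @param events data frame with at least `time_s` and `label`.
#' @param path CSV path.
#' @return the data frame (read) / `path` invisibly (write).
#' @export
write_events_csv <- function(events, path) {
  n <- length(events$time_s)
  df <- data.frame(
    time_s = events$time_s,
    label = rep_len(events$label, n),
    amplitude = if (is.null(events$amplitude)) rep(NA_real_, n)
                else events$amplitude,
    probability = if (is.null(events$probability)) rep(NA_real_, n)
                  else events$probability)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  if (!file.exists(path)) stopf("event CSV not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "label", "amplitude", "probability")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stopf("event CSV %s is missing column(s): %s", path,
          paste(missing, collapse = ", "))
  df
}

#' Run configuration
#'
#' One JSON-serializable document holding every tunable of the pipeline.
#' Unknown keys in a config file are rejected.
#'
#' @param ... overrides for the default keys (see `default_run_config()`).
#' @param path JSON config file to load.
#' @return a `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- default_run_config()
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

default_run_config <- function() {
  list(seed = 42L,
       sample_rate = 48000L,
       peak = unclass(peak_config()),
       filter = unclass(filter_spec()),
       bank = unclass(bank_spec()),
       impact = unclass(impact_config()),
       ensemble = unclass(ensemble_config()),
       k_impact = 40L,
       k_rebound = NULL,
       match_tol_s = 0.020,
       kappa_bin_width_s = 0.04)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- default_run_config()
  unknown <- setdiff(names(raw), names(cfg))
  if (length(unknown))
    stopf("unknown config key(s) in %s: %s", path,
          paste(unknown, collapse = ", "))
  for (nm in names(raw)) {
    if (is.list(cfg[[nm]])) {
      bad <- setdiff(names(raw[[nm]]), names(cfg[[nm]]))
      if (length(bad))
        stopf("unknown config key(s) in %s: %s", nm, paste(bad, collapse = ", "))
      cfg[[nm]][names(raw[[nm]])] <- raw[[nm]]
    } else cfg[[nm]] <- raw[[nm]]
  }
  structure(cfg, class = "run_config")
}

restore_spec <- function(x, builder) do.call(builder, x)

#' Synthesize a bank or preset scene to disk
#'
#' @param what `"bank"` or `"scene"`.
#' @param out_dir output directory.
#' @param config a [run_config()].
#' @param preset scene preset name (see [scene_preset()]), scenes only.
#' @param seed overrides `config$seed`.
#' @return output directory, invisibly.
#' @export
cmd_synth <- function(what = c("bank", "scene"), out_dir,
                      config = run_config(), preset = "rally1", seed = NULL) {
  what <- match.arg(what)
  seed <- if (is.null(seed)) config$seed else seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (what == "bank") {
    spec <- restore_spec(utils::modifyList(config$bank, list(seed = seed)),
                         bank_spec)
    write_bank(gen_sample_bank(spec), out_dir)
  } else {
    sc <- render_scene(scene_preset(preset, seed = seed))
    write_wav(sc$clip, file.path(out_dir, paste0(preset, ".wav")))
    write_events_csv(cbind(sc$truth, probability = 1),
                     file.path(out_dir, paste0(preset, "_truth.csv")))
  }
  invisible(out_dir)
}

#' Train the classifier bundle from a bank directory
#'
#' @param bank_dir directory written by [write_bank()] (or [cmd_synth()]).
#' @param archive_path output model archive (`.rds`).
#' @param config a [run_config()].
#' @param cv also run five-fold CV and write `cv_report.csv` next to the
#'   archive (default `TRUE`).
#' @return the trained bundle, invisibly.
#' @export
cmd_train <- function(bank_dir, archive_path, config = run_config(),
                      cv = TRUE) {
  bank <- read_bank(bank_dir)
  if (nlevels(droplevels(bank$labels)) < 3)
    stopf("bank in %s lacks one of the three classes", bank_dir)
  bundle <- train_court_models(
    bank, k_impact = config$k_impact, k_rebound = config$k_rebound,
    impact_cfg = restore_spec(config$impact, impact_config),
    ensemble_cfg = restore_spec(config$ensemble, ensemble_config),
    seed = config$seed, cv = cv)
  save_bundle(bundle, archive_path)
  if (cv) {
    rep <- data.frame(
      model = rep(c("impact", "rebound"), each = 5L),
      fold = rep(1:5, 2),
      accuracy = c(bundle$cv_reports$impact$fold_accuracy,
                   bundle$cv_reports$rebound$fold_accuracy),
      median_accuracy = rep(c(bundle$cv_reports$impact$median_accuracy,
                              bundle$cv_reports$rebound$median_accuracy),
                            each = 5L))
    utils::write.csv(rep, file.path(dirname(archive_path), "cv_report.csv"),
                     row.names = FALSE)
  }
  invisible(bundle)
}

#' Detect events in a WAV file
#'
#' Rally mode: peak picking on the raw normalized waveform plus the rally
#' rhythm report. Groundstroke mode: band-pass + candidate detection +
#' classifier validation + executive timing (requires a model archive).
#'
#' @param wav_path input WAV.
#' @param mode `"rally"` or `"groundstroke"`.
#' @param out_dir output directory for the event CSV and report JSON.
#' @param archive_path model archive (groundstroke mode only).
#' @param config a [run_config()].
#' @return list with `events` and `report`, invisibly.
#' @export
cmd_detect <- function(wav_path, mode = c("rally", "groundstroke"), out_dir,
                       archive_path = NULL, config = run_config()) {
  mode <- match.arg(mode)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  clip <- normalize_clip(read_wav(wav_path))
  pk_cfg <- restore_spec(config$peak, peak_config)
  if (mode == "rally") {
    peaks <- detect_rally_impacts(clip, pk_cfg)
    events <- data.frame(time_s = peaks$time_s,
                         label = rep("impact", nrow(peaks)),
                         amplitude = peaks$amplitude,
                         probability = rep(NA_real_, nrow(peaks)))
    report <- if (nrow(peaks) >= 2)
      unclass(rally_rhythm(peaks$time_s)) else list(n = nrow(peaks))
  } else {
    if (is.null(archive_path))
      stopf("groundstroke mode requires a model archive")
    bundle <- load_bundle(archive_path)
    events <- classify_events(clip, bundle, pk_cfg,
                              restore_spec(config$filter, filter_spec))
    timings <- executive_timing(events)
    report <- unclass(summarize_timing(timings))
    report$timings_s <- timings$timing_s
  }
  write_events_csv(events, file.path(out_dir, "events.csv"))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(events = events, report = report))
}

#' Compare detected events with reference annotations
#'
#' Matches the two event tables per label, computes detection rates, and the
#' full agreement statistics on the matched pairs' executive timings when
#' both tables carry paired impact/rebound events.
#'
#' @param detected_csv,reference_csv event CSVs
#'   (`time_s,label,amplitude,probability`).
#' @param out_path output JSON path (optional).
#' @param config a [run_config()].
#' @return list with per-label `match_result`s and, when computable, the
#'   timing `agreement_report`.
#' @export
cmd_agree <- function(detected_csv, reference_csv, out_path = NULL,
                      config = run_config()) {
  det <- read_events_csv(detected_csv)
  ref <- read_events_csv(reference_csv)
  labs <- intersect(unique(ref$label), c("impact", "rebound"))
  matches <- lapply(stats::setNames(labs, labs), function(l)
    match_events(det$time_s[det$label == l], ref$time_s[ref$label == l],
                 config$match_tol_s))
  out <- list(matches = matches)
  if (all(c("impact", "rebound") %in% labs)) {
    ref_t <- pair_timings(ref)
    det_t <- pair_timings(det)
    if (nrow(ref_t) >= 3 && nrow(det_t) >= 3) {
      m <- match_events(det_t$impact_time_s, ref_t$impact_time_s,
                        config$match_tol_s)
      if (m$tp >= 3) {
        ref_map <- ref_t$timing_s[match(m$matched$ref_time_s,
                                        ref_t$impact_time_s)]
        det_map <- det_t$timing_s[match(m$matched$det_time_s,
                                        det_t$impact_time_s)]
        out$timing_agreement <- agreement_report(
          cbind(reference = ref_map, system = det_map),
          config$kappa_bin_width_s)
      }
    }
  }
  if (!is.null(out_path)) {
    ser <- list(
      matches = lapply(matches, function(m)
        list(tp = m$tp, fn = m$fn, fp = m$fp,
             detection_rate = m$detection_rate)))
    if (!is.null(out$timing_agreement))
      ser$timing_agreement <- unclass(out$timing_agreement)
    jsonlite::write_json(ser, out_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(out)
}

# impact/rebound pairing for an event table: each impact paired with the
# nearest preceding rebound inside the rebound window
pair_timings <- function(events, window = c(0.4, 1.5)) {
  imps <- events$time_s[events$label == "impact"]
  rebs <- events$time_s[events$label == "rebound"]
  rows <- lapply(imps, function(t) {
    cand <- rebs[rebs >= t - window[2] & rebs <= t - window[1]]
    if (!length(cand)) return(NULL)
    data.frame(impact_time_s = t, rebound_time_s = max(cand),
               timing_s = t - max(cand))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(impact_time_s = numeric(0), rebound_time_s = numeric(0),
                      timing_s = numeric(0))
  out
}
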